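#' Aligned sequence set with species annotations
#'
#' Lightweight container for a gapped alignment over the 20 amino acids plus
#' gap. Rows are sequences, columns are alignment positions; every row carries
#' an identifier and a (possibly missing) species tag parsed from its header.
#'
#' @param mat character matrix of single residues (n rows, L columns)
#' @param ids character vector of sequence identifiers
#' @param species character vector of species names (NA when unparseable)
#' @param headers optional original headers (defaults to ids)
#' @return an object of class `msa`
#' @export
new_msa <- function(mat, ids, species = rep(NA_character_, nrow(mat)),
                    headers = NULL) {
  stopifnot(is.matrix(mat), length(ids) == nrow(mat),
            length(species) == nrow(mat))
  dimnames(mat) <- NULL
  if (is.null(headers)) headers <- ids
  structure(list(mat = mat, ids = as.character(ids),
                 species = as.character(species),
                 headers = as.character(headers)),
            class = "msa")
}

#' @export
dim.msa <- function(x) dim(x$mat)

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns; %d with species tags\n",
              nrow(x$mat), ncol(x$mat), sum(!is.na(x$species))))
  invisible(x)
}

#' Parse a species tag from a sequence header
#'
#' Grammar, in order of precedence: an `OS=` field (UniProt style, terminated
#' by the next `XX=` key, a `|`, or end of header); else a UniProt mnemonic
#' suffix after `_` in the first token (e.g. `HAUS1_HUMAN` -> `HUMAN`); else
#' `NA`.
#'
#' @param header character vector of FASTA/Stockholm headers
#' @return character vector of species names (NA when missing)
#' @export
parse_species <- function(header) {
  vapply(header, function(h) {
    m <- regmatches(h, regexpr("OS=.*", h))
    if (length(m) == 1) {
      s <- sub("^OS=", "", m)
      s <- sub("\\s+[A-Z]{2}=.*$", "", s)   # stop at OX=, GN=, PE=, SV=, ...
      s <- sub("\\|.*$", "", s)
      s <- trimws(s)
      if (nzchar(s)) return(s)
    }
    tok <- strsplit(h, "\\s+")[[1]][1]
    tok <- utils::tail(strsplit(tok, "\\|")[[1]], 1)
    if (grepl("_[A-Z0-9]{2,10}$", tok)) return(sub("^.*_", "", tok))
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read an alignment from FASTA or Stockholm
#'
#' Rows must all have the same length (ragged input is a format error).
#' Residue letters outside the 20-amino-acid + gap alphabet (`.` is treated
#' as a gap; `B`, `Z`, `X`, etc.) are mapped to the gap state with a warning.
#'
#' @param path file path
#' @param format "fasta" or "stockholm" (default guessed from extension:
#'   `.sto`/`.stk` are Stockholm, anything else FASTA)
#' @return an [new_msa()] object
#' @export
read_msa <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  }
  format <- match.arg(format, c("fasta", "stockholm"))
  if (format == "fasta") {
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0) stop("format error: no sequences in ", path)
    w <- Biostrings::width(set)
    if (length(unique(w)) != 1)
      stop("format error: ragged alignment (row lengths ",
           paste(sort(unique(w)), collapse = ", "), ")")
    headers <- names(set)
    seqs <- as.character(set)
  } else {
    parsed <- read_stockholm(path)
    headers <- parsed$headers
    seqs <- parsed$seqs
    if (length(unique(nchar(seqs))) != 1)
      stop("format error: ragged alignment in Stockholm file")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  mat[mat == "."] <- GAP
  bad <- !(mat %in% AA_ALPHABET)
  if (any(bad)) {
    warning(sum(bad), " residue letters outside the 20+gap alphabet mapped to gap")
    mat[bad] <- GAP
  }
  ids <- vapply(headers, function(h) strsplit(h, "\\s+")[[1]][1],
                character(1), USE.NAMES = FALSE)
  new_msa(mat, ids, parse_species(headers), headers)
}

# Minimal Stockholm reader: one alignment block, '#=' annotation lines and
# blank lines skipped, wrapped sequence lines concatenated by name, '//' ends.
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order <- character(0)
  for (ln in lines) {
    if (grepl("^//", ln)) break
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) stop("format error: malformed Stockholm line: ", ln)
    nm <- parts[1]
    if (is.null(seqs[[nm]])) { seqs[[nm]] <- ""; order <- c(order, nm) }
    seqs[[nm]] <- paste0(seqs[[nm]], parts[2])
  }
  if (length(order) == 0) stop("format error: no sequences in ", path)
  list(headers = order, seqs = unlist(seqs[order], use.names = FALSE))
}

#' Write an alignment to FASTA
#'
#' Headers follow the `>id|OS=species` grammar when a species tag is present.
#'
#' @param msa an [new_msa()] object
#' @param path output file
#' @export
write_msa <- function(msa, path) {
  hdr <- ifelse(is.na(msa$species), msa$ids,
                paste0(msa$ids, "|OS=", msa$species))
  out <- character(2L * nrow(msa$mat))
  out[c(TRUE, FALSE)] <- paste0(">", hdr)
  out[c(FALSE, TRUE)] <- apply(msa$mat, 1, paste0, collapse = "")
  writeLines(out, path)
  invisible(path)
}

#' Remove sequences with long contiguous gap runs
#'
#' A row is removed when its longest contiguous run of gap characters exceeds
#' `ceiling(fraction * L)` columns (strictly greater; terminal runs count).
#' The column set is never changed.
#'
#' @param msa an [new_msa()] object
#' @param fraction maximum tolerated gap-run length as a fraction of the
#'   alignment length, in (0, 1)
#' @return the filtered `msa`
#' @export
filter_max_gap_run <- function(msa, fraction) {
  stopifnot(inherits(msa, "msa"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  L <- ncol(msa$mat)
  limit <- ceiling(fraction * L)
  runs <- apply(msa$mat, 1, function(row) {
    r <- rle(row == GAP)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  })
  keep <- runs <= limit
  new_msa(msa$mat[keep, , drop = FALSE], msa$ids[keep],
          msa$species[keep], msa$headers[keep])
}

#' Exact/greedy maximum-total-similarity assignment
#'
#' Pairs rows of a similarity matrix with columns, one-to-one, maximizing the
#' total similarity of the chosen entries; `min(nrow, ncol)` pairs are
#' returned. When both dimensions are at most `exact_max` the optimum is
#' found by exhaustive enumeration; larger problems fall back to a greedy
#' scheme (repeatedly take the best remaining entry). Ties break toward the
#' lowest row index, then the lowest column index.
#'
#' @param S numeric similarity matrix (rows: family-A paralogs, columns:
#'   family-B paralogs)
#' @param exact_max largest dimension for which exhaustive enumeration is used
#' @return two-column integer matrix of (row, col) assignments
#' @export
max_similarity_assignment <- function(S, exact_max = 6L) {
  S <- as.matrix(S)
  nr <- nrow(S); nc <- ncol(S)
  m <- min(nr, nc)
  if (m == 0) return(matrix(integer(0), ncol = 2))
  if (max(nr, nc) <= exact_max) {
    flip <- nr > nc
    A <- if (flip) t(S) else S      # now nrow(A) <= ncol(A)
    best <- NULL; best_val <- -Inf
    cols <- utils::combn(ncol(A), nrow(A), simplify = FALSE)
    perms <- all_permutations(nrow(A))
    for (cs in cols) {
      for (p in perms) {
        val <- sum(A[cbind(seq_len(nrow(A)), cs[p])])
        if (val > best_val + 1e-12) {
          best_val <- val
          best <- cbind(seq_len(nrow(A)), cs[p])
        }
      }
    }
    out <- if (flip) best[, 2:1, drop = FALSE] else best
  } else {
    avail_r <- rep(TRUE, nr); avail_c <- rep(TRUE, nc)
    out <- matrix(integer(0), ncol = 2)
    for (t in seq_len(m)) {
      sub <- S
      sub[!avail_r, ] <- -Inf; sub[, !avail_c] <- -Inf
      idx <- which(sub == max(sub), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
      out <- rbind(out, idx)
      avail_r[idx[1]] <- FALSE; avail_c[idx[2]] <- FALSE
    }
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

percent_identity <- function(a, b) mean(a == b)

#' Paralog-matched concatenation of two family alignments
#'
#' Species present in only one alignment are dropped. Within each shared
#' species, sequences of the two families are paired one-to-one by a
#' progressive scheme: single-copy species are paired first and seed a paired
#' consensus profile; multi-copy species are then processed in order of
#' increasing paralog count, scoring each candidate (A, B) pair by the
#' product of the two sequences' percent identities to the current consensus
#' and solving the maximum-total-similarity assignment (exhaustively for up
#' to 6x6 paralogs, greedily beyond). Each newly paired species updates the
#' consensus. A species contributes `min(copies_A, copies_B)` rows.
#'
#' @param msa_a,msa_b [new_msa()] objects with species tags
#' @param similarity optional override: a function
#'   `(mat_a, mat_b, consensus_a, consensus_b) -> matrix` returning the
#'   similarity used for a species' assignment (rows: A paralogs, columns: B
#'   paralogs); mainly for testing and expert use
#' @return a `paired_msa`: an `msa` whose rows are the concatenated A+B
#'   sequences, with attributes `boundary` (last column of family A),
#'   `parent_rows` (data.frame of source row indices) and per-row species
#' @export
paralog_match_concatenate <- function(msa_a, msa_b, similarity = NULL) {
  stopifnot(inherits(msa_a, "msa"), inherits(msa_b, "msa"))
  sp_a <- msa_a$species; sp_b <- msa_b$species
  shared <- intersect(unique(sp_a[!is.na(sp_a)]), unique(sp_b[!is.na(sp_b)]))
  if (length(shared) == 0)
    stop("empty pairing: the two alignments share no species")
  La <- ncol(msa_a$mat); Lb <- ncol(msa_b$mat)

  rows_a <- split(seq_along(sp_a), sp_a)[shared]
  rows_b <- split(seq_along(sp_b), sp_b)[shared]
  n_copies <- pmax(lengths(rows_a), lengths(rows_b))
  ord <- shared[order(n_copies, shared)]

  # consensus counts over paired rows, per column, per alphabet letter
  cnt_a <- matrix(0L, length(AA_ALPHABET), La)
  cnt_b <- matrix(0L, length(AA_ALPHABET), Lb)
  add_counts <- function(cnt, mat, rows) {
    for (r in rows) {
      idx <- match(mat[r, ], AA_ALPHABET)
      cnt[cbind(idx, seq_len(ncol(mat)))] <- cnt[cbind(idx, seq_len(ncol(mat)))] + 1L
    }
    cnt
  }
  consensus <- function(cnt, mat_all) {
    if (sum(cnt) == 0) {   # no single-copy seed: fall back to whole-family consensus
      cnt <- add_counts(cnt, mat_all, seq_len(nrow(mat_all)))
    }
    AA_ALPHABET[apply(cnt, 2, which.max)]
  }

  pair_a <- integer(0); pair_b <- integer(0); pair_sp <- character(0)

  # seed with single-copy species
  for (s in ord) {
    if (length(rows_a[[s]]) == 1 && length(rows_b[[s]]) == 1) {
      pair_a <- c(pair_a, rows_a[[s]]); pair_b <- c(pair_b, rows_b[[s]])
      pair_sp <- c(pair_sp, s)
      cnt_a <- add_counts(cnt_a, msa_a$mat, rows_a[[s]])
      cnt_b <- add_counts(cnt_b, msa_b$mat, rows_b[[s]])
    }
  }
  for (s in ord) {
    ra <- rows_a[[s]]; rb <- rows_b[[s]]
    if (length(ra) == 1 && length(rb) == 1) next
    cons_a <- consensus(cnt_a, msa_a$mat); cons_b <- consensus(cnt_b, msa_b$mat)
    S <- if (is.null(similarity)) {
      ia <- vapply(ra, function(r) percent_identity(msa_a$mat[r, ], cons_a), 0)
      ib <- vapply(rb, function(r) percent_identity(msa_b$mat[r, ], cons_b), 0)
      outer(ia, ib)
    } else {
      similarity(msa_a$mat[ra, , drop = FALSE], msa_b$mat[rb, , drop = FALSE],
                 cons_a, cons_b)
    }
    asg <- max_similarity_assignment(S)
    pair_a <- c(pair_a, ra[asg[, "row"]]); pair_b <- c(pair_b, rb[asg[, "col"]])
    pair_sp <- c(pair_sp, rep(s, nrow(asg)))
    cnt_a <- add_counts(cnt_a, msa_a$mat, ra[asg[, "row"]])
    cnt_b <- add_counts(cnt_b, msa_b$mat, rb[asg[, "col"]])
  }

  ord2 <- order(pair_a)
  pair_a <- pair_a[ord2]; pair_b <- pair_b[ord2]; pair_sp <- pair_sp[ord2]
  mat <- cbind(msa_a$mat[pair_a, , drop = FALSE], msa_b$mat[pair_b, , drop = FALSE])
  out <- new_msa(mat, paste0(msa_a$ids[pair_a], "+", msa_b$ids[pair_b]), pair_sp)
  out$boundary <- La
  out$parent_rows <- data.frame(row_a = pair_a, row_b = pair_b,
                                species = pair_sp, stringsAsFactors = FALSE)
  class(out) <- c("paired_msa", "msa")
  out
}

#' @export
print.paired_msa <- function(x, ...) {
  cat(sprintf("<paired_msa> %d rows; domain A: columns 1..%d, domain B: %d..%d\n",
              nrow(x$mat), x$boundary, x$boundary + 1, ncol(x$mat)))
  invisible(x)
}

#' Species co-occurrence census across protein families
#'
#' Tabulates which species occur in which family alignment and counts the
#' species present in every family (the complete-set core).
#'
#' @param family_species named list mapping family name to a character vector
#'   of species
#' @return list with `matrix` (logical, species x family), `complete_species`
#'   (species present in all families) and `complete_count`
#' @export
species_cooccurrence <- function(family_species) {
  stopifnot(is.list(family_species), length(family_species) >= 1)
  fams <- names(family_species)
  if (is.null(fams)) fams <- paste0("family", seq_along(family_species))
  sets <- lapply(family_species, function(x) unique(x[!is.na(x)]))
  all_sp <- sort(unique(unlist(sets)))
  mat <- vapply(sets, function(s) all_sp %in% s, logical(length(all_sp)))
  mat <- matrix(mat, nrow = length(all_sp),
                dimnames = list(all_sp, fams))
  complete <- all_sp[rowSums(mat) == length(sets)]
  list(matrix = mat, complete_species = complete,
       complete_count = length(complete))
}
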