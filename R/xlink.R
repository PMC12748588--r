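#' Read a residue-pair crosslink table
#'
#' Accepts tab- or comma-separated files in the residue-pair export dialect
#' (columns `Protein1`, `PepPos1`/`Residue1`/`Res1`, `Protein2`,
#' `PepPos2`/`Residue2`/`Res2`). Unordered duplicate pairs are collapsed
#' with a multiplicity count. Proteins outside the declared roster are
#' flagged, not fatal (copurifying contaminants pass through).
#'
#' @param path file path
#' @param roster optional character vector of expected protein names
#' @return data.frame `protein1`, `residue1`, `protein2`, `residue2`,
#'   `multiplicity`, `known` (in roster; TRUE when no roster given)
#' @export
read_crosslinks <- function(path, roster = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(cands) {
    hit <- match(tolower(cands), tolower(names(df)))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0)
      stop("format error: none of the columns ", paste(cands, collapse = "/"),
           " found in ", path)
    df[[hit[1]]]
  }
  p1 <- as.character(pick(c("Protein1", "Protein 1")))
  p2 <- as.character(pick(c("Protein2", "Protein 2")))
  r1 <- as.integer(pick(c("Residue1", "Res1", "PepPos1", "AbsPos1")))
  r2 <- as.integer(pick(c("Residue2", "Res2", "PepPos2", "AbsPos2")))
  if (any(r1 < 1 | r2 < 1, na.rm = TRUE)) stop("residue positions must be >= 1")

  # canonical unordered key
  a_first <- (p1 < p2) | (p1 == p2 & r1 <= r2)
  P1 <- ifelse(a_first, p1, p2); R1 <- ifelse(a_first, r1, r2)
  P2 <- ifelse(a_first, p2, p1); R2 <- ifelse(a_first, r2, r1)
  key <- paste(P1, R1, P2, R2, sep = "\r")
  tab <- table(key)
  uniq <- !duplicated(key)
  out <- data.frame(protein1 = P1[uniq], residue1 = R1[uniq],
                    protein2 = P2[uniq], residue2 = R2[uniq],
                    multiplicity = as.integer(tab[key[uniq]]),
                    stringsAsFactors = FALSE)
  out$known <- if (is.null(roster)) TRUE
               else out$protein1 %in% roster & out$protein2 %in% roster
  rownames(out) <- NULL
  out
}

#' Map crosslink records onto a coordinate model
#'
#' Each record's residues are converted to author numbering (`author =
#' sequence position + offset`) on the chain(s) its protein maps to. When a
#' protein maps to several chain copies (e.g. the two protomers of a dimer),
#' the copy pairing minimizing the Calpha-Calpha distance is chosen and
#' recorded. Records touching unmodeled residues get status
#' `unresolved-residue`; records of proteins absent from the configuration
#' get `unmapped-protein`.
#'
#' @param records crosslink table from [read_crosslinks()] (or any
#'   data.frame with `protein1`, `residue1`, `protein2`, `residue2`)
#' @param model a [structure_model()]
#' @param chain_config named list: protein -> `list(chains = c(...),
#'   offset = 0)`
#' @return data.frame: the records plus `status`
#'   (mapped/unresolved-residue/unmapped-protein), `distance`, `chain1`,
#'   `chain2`
#' @export
map_distances <- function(records, model, chain_config) {
  ca <- ca_coords(model)
  key <- paste(ca$chain, ca$resno)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(records)
  status <- character(n); dist <- rep(NA_real_, n)
  ch1 <- rep(NA_character_, n); ch2 <- rep(NA_character_, n)
  for (t in seq_len(n)) {
    cfg1 <- chain_config[[records$protein1[t]]]
    cfg2 <- chain_config[[records$protein2[t]]]
    if (is.null(cfg1) || is.null(cfg2)) { status[t] <- "unmapped-protein"; next }
    off1 <- if (is.null(cfg1$offset)) 0 else cfg1$offset
    off2 <- if (is.null(cfg2$offset)) 0 else cfg2$offset
    best <- Inf
    for (c1 in cfg1$chains) {
      i1 <- match(paste(c1, records$residue1[t] + off1), key)
      if (is.na(i1)) next
      for (c2 in cfg2$chains) {
        i2 <- match(paste(c2, records$residue2[t] + off2), key)
        if (is.na(i2)) next
        d <- sqrt(sum((xyz[i1, ] - xyz[i2, ])^2))
        if (d < best) { best <- d; ch1[t] <- c1; ch2[t] <- c2 }
      }
    }
    if (is.finite(best)) { status[t] <- "mapped"; dist[t] <- best }
    else status[t] <- "unresolved-residue"
  }
  cbind(records, data.frame(status = status, distance = dist,
                            chain1 = ch1, chain2 = ch2,
                            stringsAsFactors = FALSE))
}

#' Count crosslinks satisfied under a distance cutoff
#'
#' Strictly-less-than criterion; the fraction's denominator counts mapped
#' records only. An empty mapped set reports count 0 and fraction `NA`.
#'
#' @param mapped output of [map_distances()]
#' @param cutoff distance cutoff in Angstrom (> 0; 35 is the BS3 convention)
#' @return list with `count`, `n_mapped`, `fraction`
#' @export
count_within <- function(mapped, cutoff = 35) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ok <- mapped$status == "mapped"
  cnt <- sum(mapped$distance[ok] < cutoff)
  list(count = cnt, n_mapped = sum(ok),
       fraction = if (sum(ok) > 0) cnt / sum(ok) else NA_real_)
}

#' Compare crosslink satisfaction between two assemblies
#'
#' Maps the same records onto a monomer and a dimer model and, for records
#' mapped in both, reports the distance delta (dimer minus monomer);
#' "shorter in dimer" means a strictly negative delta. Multi-copy chain
#' ambiguity is resolved per [map_distances()] (minimum distance).
#'
#' @param records crosslink table
#' @param model_monomer,model_dimer the two [structure_model()]s
#' @param config_monomer,config_dimer their chain configurations
#' @return list with `records` (per-record statuses, distances and deltas),
#'   `n_mappable_dimer` (records mapped in the dimer) and `n_shorter_dimer`
#'   (mapped in both with delta < 0)
#' @export
compare_assemblies <- function(records, model_monomer, model_dimer,
                               config_monomer, config_dimer) {
  mono <- map_distances(records, model_monomer, config_monomer)
  dim_ <- map_distances(records, model_dimer, config_dimer)
  out <- records
  out$status_monomer <- mono$status; out$d_monomer <- mono$distance
  out$status_dimer <- dim_$status; out$d_dimer <- dim_$distance
  both <- out$status_monomer == "mapped" & out$status_dimer == "mapped"
  out$delta <- ifelse(both, out$d_dimer - out$d_monomer, NA_real_)
  list(records = out,
       n_mappable_dimer = sum(out$status_dimer == "mapped"),
       n_shorter_dimer = sum(both & out$delta < 0))
}
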