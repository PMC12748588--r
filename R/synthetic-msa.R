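#' Planted two-domain Potts model
#'
#' Generative model for paired alignments: two domains of stated lengths over
#' a q-state alphabet (gap included as the last state), with a sparse set of
#' planted inter-domain couplings `J_ij(a, b) = strength * 1[a == b]` and an
#' optional per-site bias toward the first alphabet state.
#'
#' @param length_a,length_b residue counts of domains A and B
#' @param alphabet_size number of states q (default 21: 20 amino acids + gap)
#' @param planted_pairs data.frame with columns `i` (position in A), `j`
#'   (position in B) and `strength` (coupling, energy units); NULL for none
#' @param field_bias scalar or length-(L_A+L_B) vector: field on state 1
#' @param seed integer RNG seed used by [sample_potts_msa()] by default
#' @return an object of class `planted_model`
#' @export
planted_model <- function(length_a, length_b, alphabet_size = 21L,
                          planted_pairs = NULL, field_bias = 0, seed = 1L) {
  if (length_a < 1 || length_b < 1) stop("invalid model: non-positive domain length")
  if (alphabet_size < 2) stop("invalid model: alphabet size q must be >= 2")
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(i = integer(0), j = integer(0), strength = numeric(0))
  stopifnot(all(c("i", "j", "strength") %in% names(planted_pairs)))
  if (nrow(planted_pairs) > 0) {
    if (any(planted_pairs$i < 1 | planted_pairs$i > length_a) ||
        any(planted_pairs$j < 1 | planted_pairs$j > length_b))
      stop("invalid model: planted pair indices outside domain bounds")
    if (any(!is.finite(planted_pairs$strength)))
      stop("invalid model: non-finite coupling strength")
  }
  L <- length_a + length_b
  if (!length(field_bias) %in% c(1L, L))
    stop("invalid model: field_bias must be scalar or length L_A+L_B")
  structure(list(length_a = as.integer(length_a),
                 length_b = as.integer(length_b),
                 q = as.integer(alphabet_size),
                 planted_pairs = planted_pairs,
                 field_bias = field_bias, seed = as.integer(seed)),
            class = "planted_model")
}

#' Sample paired alignments from a planted Potts model
#'
#' Gibbs sampling with sequential per-site sweeps on one long chain (burn-in,
#' then one record every `thin` sweeps). Each recorded chain state is a
#' "species"; a species with `p` paralogs contributes `p` rows per family,
#' paralog `p` carrying `(p-1) * mutations_per_paralog` random substitutions
#' in each domain half. Gap runs are inserted post hoc as contiguous blocks
#' in a random subset of rows. Rows of family B are returned in shuffled
#' order; the ground-truth pairing is returned for evaluation.
#'
#' @param model a [planted_model()]
#' @param n_sequences number of species (base chain states) to record
#' @param n_paralogs paralog count per species: a scalar, or an integer vector
#'   sampled from uniformly per species
#' @param gap_run_fraction fraction of rows (per family) receiving a gap run
#' @param gap_run_length gap-run length as a fraction of the domain length
#' @param mutations_per_paralog substitutions distinguishing successive
#'   paralogs of one species, per domain
#' @param burnin,thin Gibbs burn-in sweeps and sweeps between records
#' @param seed RNG seed (defaults to the model's)
#' @return list with `msa_a`, `msa_b` ([new_msa()]), `pairing` (data.frame of
#'   ground-truth row indices `row_a`, `row_b`), `paired` (the ground-truth
#'   concatenated `paired_msa`) and the `model`
#' @export
sample_potts_msa <- function(model, n_sequences, n_paralogs = 1L,
                             gap_run_fraction = 0, gap_run_length = 0.1,
                             mutations_per_paralog = 10L,
                             burnin = 1000L, thin = 10L, seed = model$seed) {
  stopifnot(inherits(model, "planted_model"))
  if (n_sequences < 1) stop("n_sequences must be >= 1")
  set.seed(seed)
  La <- model$length_a; Lb <- model$length_b; L <- La + Lb; q <- model$q

  h <- matrix(0, L, q)
  h[, 1] <- h[, 1] + model$field_bias
  pp <- model$planted_pairs
  pairs0 <- cbind(pp$i - 1L, La + pp$j - 1L)
  storage.mode(pairs0) <- "integer"
  base <- potts_gibbs_cpp(L, q, h, pairs0, as.numeric(pp$strength),
                          as.integer(n_sequences), as.integer(burnin),
                          as.integer(thin))

  copies <- if (length(n_paralogs) == 1) rep(as.integer(n_paralogs), n_sequences)
            else sample(as.integer(n_paralogs), n_sequences, replace = TRUE)
  species <- sprintf("synthspecies %05d", seq_len(n_sequences))

  mutate <- function(row, k, q) {
    if (k <= 0) return(row)
    pos <- sample(length(row), min(k, length(row)))
    for (p in pos) {
      new <- sample(q - 1L, 1L)           # never mutate INTO a gap
      if (new >= row[p]) new <- new + 1L  # uniform over states != current
      row[p] <- new
    }
    row
  }

  rows_a <- list(); rows_b <- list()
  sp_a <- character(0); sp_b <- character(0)
  truth_a <- integer(0); truth_b <- integer(0)
  for (s in seq_len(n_sequences)) {
    for (p in seq_len(copies[s])) {
      k <- (p - 1L) * mutations_per_paralog
      rows_a[[length(rows_a) + 1L]] <- mutate(base[s, 1:La], k, q)
      rows_b[[length(rows_b) + 1L]] <- mutate(base[s, (La + 1):L], k, q)
      sp_a <- c(sp_a, species[s]); sp_b <- c(sp_b, species[s])
      truth_a <- c(truth_a, length(rows_a)); truth_b <- c(truth_b, length(rows_b))
    }
  }
  mat_a <- do.call(rbind, rows_a); mat_b <- do.call(rbind, rows_b)

  insert_gap_runs <- function(mat, frac, len_frac, q) {
    n_hit <- floor(frac * nrow(mat))
    if (n_hit == 0) return(mat)
    run <- max(1L, ceiling(len_frac * ncol(mat)))
    hit <- sample(nrow(mat), n_hit)
    for (r in hit) {
      start <- sample(ncol(mat) - run + 1L, 1L)
      mat[r, start:(start + run - 1L)] <- q
    }
    mat
  }
  mat_a <- insert_gap_runs(mat_a, gap_run_fraction, gap_run_length, q)
  mat_b <- insert_gap_runs(mat_b, gap_run_fraction, gap_run_length, q)

  ids_a <- sprintf("SYNA%05d", seq_len(nrow(mat_a)))
  ids_b <- sprintf("SYNB%05d", seq_len(nrow(mat_b)))
  shuffle <- sample(nrow(mat_b))
  truth_b_shuffled <- match(truth_b, shuffle)

  msa_a <- new_msa(decode_residues(mat_a, q), ids_a, sp_a)
  msa_b <- new_msa(decode_residues(mat_b[shuffle, , drop = FALSE], q),
                   ids_b[shuffle], sp_b[shuffle])

  # ground-truth pairing: A row t pairs with pre-shuffle B row t
  paired_mat <- cbind(decode_residues(mat_a, q), decode_residues(mat_b, q))
  paired <- new_msa(paired_mat, paste0(ids_a, "+", ids_b), sp_a)
  paired$boundary <- La
  paired$parent_rows <- data.frame(row_a = truth_a, row_b = truth_b_shuffled,
                                   species = sp_a, stringsAsFactors = FALSE)
  class(paired) <- c("paired_msa", "msa")

  list(msa_a = msa_a, msa_b = msa_b,
       pairing = data.frame(row_a = truth_a, row_b = truth_b_shuffled,
                            species = sp_a, stringsAsFactors = FALSE),
       paired = paired, model = model)
}
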