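#' Identity-based sequence reweighting
#'
#' Each row m gets weight `1 / |{m' : identity(m, m') >= threshold}|` (self
#' included); the effective depth is the sum of the weights.
#'
#' @param paired a `paired_msa` (or any [new_msa()])
#' @param identity_threshold fractional identity at or above which two rows
#'   count as neighbours, in (0, 1]
#' @param alphabet state alphabet (default: 20 amino acids + gap)
#' @return list with `weights` and `m_eff`
#' @export
sequence_weights <- function(paired, identity_threshold = 0.8,
                             alphabet = AA_ALPHABET) {
  stopifnot(inherits(paired, "msa"))
  if (nrow(paired$mat) < 1) stop("alignment has no rows")
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  codes <- encode_residues(paired$mat, alphabet)
  w <- seq_weights_cpp(codes, identity_threshold)
  list(weights = w, m_eff = sum(w))
}

#' Reweighted, pseudocount-regularized frequency statistics
#'
#' Single-site frequencies `f_i(a) = (lambda/q + sum_m w_m 1[a at i]) /
#' (lambda + M_eff)` and pair frequencies with a `lambda/q^2` pseudocount.
#' Diagonal pair blocks are tied to the single-site frequencies
#' (`f_ii(a,b) = delta_ab f_i(a)`), the standard mean-field convention. The
#' default pseudocount `lambda = M_eff` weights data and prior equally.
#'
#' @param paired a `paired_msa`
#' @param weights result of [sequence_weights()] (unit weights if NULL)
#' @param lambda pseudocount, >= 0 (default `M_eff`)
#' @param alphabet state alphabet; its length sets q (default: 20 amino
#'   acids + gap, q = 21, gap the last state)
#' @return a `coupling_stats` object: `f_i` (L x q), `f_ij` ((L q) x (L q),
#'   blocks in site-major order), `weights`, `m_eff`, `lambda`, `q`, `L`,
#'   `boundary`
#' @export
frequencies <- function(paired, weights = NULL, lambda = NULL,
                        alphabet = AA_ALPHABET) {
  stopifnot(inherits(paired, "msa"))
  codes <- encode_residues(paired$mat, alphabet)
  n <- nrow(codes); L <- ncol(codes); q <- length(alphabet)
  if (is.null(weights)) weights <- list(weights = rep(1, n), m_eff = n)
  w <- weights$weights; m_eff <- weights$m_eff
  if (is.null(lambda)) lambda <- m_eff
  if (lambda < 0) stop("lambda must be >= 0")

  X <- matrix(0, n, L * q)
  X[cbind(rep(seq_len(n), L),
          as.vector((rep(seq_len(L), each = n) - 1L) * q + codes))] <- 1
  sw <- sqrt(w)
  cnt2 <- crossprod(X * sw)                     # (Lq) x (Lq) weighted pair counts
  cnt1 <- colSums(X * w)

  fi_vec <- (lambda / q + cnt1) / (lambda + m_eff)
  fij <- (lambda / q^2 + cnt2) / (lambda + m_eff)
  # tie diagonal blocks to single-site frequencies
  for (i in seq_len(L)) {
    idx <- ((i - 1) * q + 1):(i * q)
    blk <- matrix(0, q, q)
    diag(blk) <- fi_vec[idx]
    fij[idx, idx] <- blk
  }
  f_i <- matrix(fi_vec, nrow = L, ncol = q, byrow = TRUE)
  structure(list(f_i = f_i, f_ij = fij, weights = w, m_eff = m_eff,
                 lambda = lambda, q = q, L = L,
                 boundary = paired$boundary),
            class = "coupling_stats")
}

#' Mean-field couplings by covariance inversion
#'
#' The connected correlation matrix `C_ij(a,b) = f_ij(a,b) - f_i(a) f_j(b)`
#' over the reduced alphabet (gap is the reference state and is omitted) is
#' inverted; couplings are `e_ij(a,b) = -(C^-1)` on the (i,a),(j,b) block.
#'
#' @param stats a `coupling_stats` from [frequencies()]
#' @return a `coupling_model`: `e` ((L (q-1)) x (L (q-1)) matrix), `q`, `L`,
#'   `boundary`
#' @export
mean_field_couplings <- function(stats) {
  stopifnot(inherits(stats, "coupling_stats"))
  q <- as.integer(stats$q); L <- as.integer(stats$L); qr <- q - 1L
  keep <- as.vector(vapply(seq_len(L), function(i) (i - 1L) * q + seq_len(qr),
                           integer(qr)))
  fi_vec <- as.vector(t(stats$f_i))
  C <- stats$f_ij[keep, keep] - tcrossprod(fi_vec[keep])
  e <- tryCatch(-solve(C),
                error = function(err)
                  stop("covariance matrix is numerically singular; ",
                       "raise the pseudocount lambda (lambda = 0 is singular ",
                       "for finite alignments): ", conditionMessage(err)))
  structure(list(e = e, q = q, L = L, boundary = stats$boundary),
            class = "coupling_model")
}

#' Extract one q x q coupling block
#'
#' Reference-state (gap) row and column are zero by convention.
#'
#' @param model a `coupling_model`
#' @param i,j site indices (1-based, over the concatenated alignment)
#' @return q x q matrix `e_ij(a, b)`
#' @export
coupling_block <- function(model, i, j) {
  q <- model$q; qr <- q - 1L
  blk <- matrix(0, q, q)
  blk[seq_len(qr), seq_len(qr)] <-
    model$e[((i - 1) * qr + 1):(i * qr), ((j - 1) * qr + 1):(j * qr)]
  blk
}

#' Direct Information of every site pair
#'
#' For each pair the two-site direct distribution `P_dir(a,b) proportional to
#' exp(e_ij(a,b)) x_i(a) x_j(b)` is built, with auxiliary fields fixed-point
#' iterated until both marginals match the single-site frequencies within
#' `tol` (at most `maxit` iterations); `DI_ij` is the mutual information of
#' `P_dir` against the product of marginals (natural log). Non-convergent
#' pairs are flagged with `NaN` and a warning.
#'
#' @param model a `coupling_model`
#' @param stats the `coupling_stats` the model was fit from
#' @param tol marginal-matching tolerance (default 1e-4)
#' @param maxit maximum fixed-point iterations (default 200)
#' @return L x L symmetric matrix of DI values in nats (diagonal 0)
#' @export
direct_information <- function(model, stats, tol = 1e-4, maxit = 200L) {
  stopifnot(inherits(model, "coupling_model"), inherits(stats, "coupling_stats"))
  if (model$L != stats$L || model$q != stats$q)
    stop("model and stats are dimensionally inconsistent")
  di <- direct_information_cpp(model$e, stats$f_i, model$L, model$q,
                               tol, as.integer(maxit))
  n_bad <- sum(is.na(di[upper.tri(di)]))
  if (n_bad > 0)
    warning(n_bad, " site pairs did not converge; their DI is NaN and they ",
            "are excluded from ranking")
  di
}

#' Rank inter-domain residue pairs by Direct Information
#'
#' Keeps pairs with `i <= boundary < j`, sorted by DI descending with
#' deterministic (i, j)-ascending tie-break. Residue j is reported in
#' domain-B coordinates (`j - boundary`). Pairs with NaN DI are excluded.
#'
#' @param di DI matrix from [direct_information()]
#' @param boundary last column of domain A (1 <= boundary < L)
#' @param top_n number of pairs to return (Inf for all)
#' @param apc apply the average-product correction over the inter-domain
#'   block before ranking (off by default: raw DI is ranked)
#' @return data.frame `rank`, `i` (domain A), `j` (domain B), `di`
#' @export
rank_interdomain_pairs <- function(di, boundary, top_n = Inf, apc = FALSE) {
  L <- nrow(di)
  if (boundary < 1 || boundary >= L) stop("boundary must be in [1, L)")
  block <- di[seq_len(boundary), (boundary + 1):L, drop = FALSE]
  if (apc) {
    rm <- rowMeans(block, na.rm = TRUE); cm <- colMeans(block, na.rm = TRUE)
    block <- block - outer(rm, cm) / mean(block, na.rm = TRUE)
  }
  idx <- which(!is.na(block), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], di = block[idx])
  out <- out[order(-out$di, out$i, out$j), , drop = FALSE]
  out <- utils::head(out, n = if (is.finite(top_n)) top_n else nrow(out))
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "i", "j", "di")]
}

#' Full mean-field DCA pipeline on a paired alignment
#'
#' Convenience wrapper: reweighting, frequencies, covariance inversion,
#' Direct Information, inter-domain ranking.
#'
#' @param paired a `paired_msa`
#' @param identity_threshold reweighting threshold (default 0.8)
#' @param lambda pseudocount (default `M_eff`)
#' @param top_n inter-domain pairs to report (default all)
#' @param apc apply average-product correction when ranking (default FALSE)
#' @param alphabet state alphabet (default: 20 amino acids + gap)
#' @return list with `weights`, `stats`, `model`, `di` and `pairs` (ranked
#'   inter-domain `DiPair` table)
#' @export
run_dca <- function(paired, identity_threshold = 0.8, lambda = NULL,
                    top_n = Inf, apc = FALSE, alphabet = AA_ALPHABET) {
  stopifnot(inherits(paired, "paired_msa"))
  w <- sequence_weights(paired, identity_threshold, alphabet)
  stats <- frequencies(paired, w, lambda, alphabet)
  model <- mean_field_couplings(stats)
  di <- direct_information(model, stats)
  pairs <- rank_interdomain_pairs(di, paired$boundary, top_n, apc)
  list(weights = w, stats = stats, model = model, di = di, pairs = pairs)
}
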