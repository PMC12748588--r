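#' Right-tailed hypergeometric tail probability
#'
#' `P(X >= k)` for `k` true contacts among `n` top-ranked pairs drawn from a
#' universe of `N` pairs containing `K` contacts; exact tail (no normal
#' approximation).
#'
#' @param k observed true positives
#' @param K contacts in the universe
#' @param n pairs tested
#' @param N universe size
#' @return exact tail probability in (0, 1]
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (K > N || n > N) stop("parameter error: K and n must not exceed N")
  if (k < 0 || k > min(n, K)) stop("parameter error: k outside [0, min(n, K)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Significance class of an enrichment p-value
#'
#' Three-tier coloring: `"red"` for p <= 0.05, `"blue"` for 0.05 < p <= 0.1,
#' `"black"` for 0.1 < p <= 0.2, `"ns"` beyond.
#'
#' @param p numeric vector of p-values
#' @return character vector of classes
#' @export
significance_class <- function(p) {
  ifelse(p <= 0.05, "red",
         ifelse(p <= 0.1, "blue",
                ifelse(p <= 0.2, "black", "ns")))
}

#' Contact enrichment of top-ranked DI pairs
#'
#' Counts how many of the tested DI pairs are true contacts of a reference
#' structure and computes the exact right-tailed hypergeometric enrichment
#' p-value. DI pairs are in domain coordinates; `mapping` places them on the
#' model (author residue number = domain position + offset on the stated
#' chain).
#'
#' @param top_pairs ranked DiPair table ([rank_interdomain_pairs()])
#' @param contacts a contact map of the reference model restricted to the
#'   same inter-domain universe ([structure_contacts()] with
#'   `inter_chain_only = TRUE`)
#' @param universe_size N: number of inter-domain residue pairs in the
#'   universe (all modeled A-B pairs)
#' @param mapping list `list(A = list(chain =, offset =), B = ...)`
#' @param n_contacts K: contacts in the universe (defaults to the number of
#'   pairs in `contacts`)
#' @return an `enrichment_result`: list with `n_top`, `K`, `N`, `k`,
#'   `p_value`, `class`
#' @export
hypergeometric_enrichment <- function(top_pairs, contacts, universe_size,
                                      mapping = list(A = list(chain = "A", offset = 0),
                                                     B = list(chain = "B", offset = 0)),
                                      n_contacts = NULL) {
  n <- nrow(top_pairs)
  if (universe_size < n)
    stop("parameter error: universe_size must be >= number of tested pairs")
  K <- if (is.null(n_contacts)) nrow(contacts) else n_contacts
  if (K > universe_size) stop("parameter error: K > N")
  k <- sum(in_contact(contacts,
                      mapping$A$chain, top_pairs$i + mapping$A$offset,
                      mapping$B$chain, top_pairs$j + mapping$B$offset))
  p <- hypergeom_tail(k, K, n, universe_size)
  structure(list(n_top = n, K = K, N = universe_size, k = k,
                 p_value = p, class = significance_class(p)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> k = %d of n = %d tested (K = %d contacts in N = %d); p = %.4g [%s]\n",
              x$k, x$n_top, x$K, x$N, x$p_value, x$class))
  invisible(x)
}

#' Retain DI pair sets passing the enrichment significance cut
#'
#' Keeps exactly the results with `p <= alpha` (inclusive); no
#' multiple-testing correction is applied.
#'
#' @param results a list of `enrichment_result` objects, or a data.frame
#'   with a `p_value` column
#' @param alpha significance level in (0, 1), default 0.2
#' @return the retained subset (same shape as the input)
#' @export
retain_significant <- function(results, alpha = 0.2) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (is.data.frame(results)) return(results[results$p_value <= alpha, , drop = FALSE])
  results[vapply(results, function(r) r$p_value <= alpha, logical(1))]
}

#' Filter DI pairs by combined solvent accessibility
#'
#' Computes each pair's combined SASA (sum over its two residues, in the
#' complex context) on a heavy-atom model and retains pairs strictly above
#' the threshold; survivors are re-ranked by DI. Pairs touching residues
#' absent from the model are dropped with a warning.
#'
#' @param di_pairs ranked DiPair table (domain coordinates)
#' @param model heavy-atom [structure_model()]
#' @param mapping list `list(A = list(chain =, offset =), B = ...)`
#' @param threshold combined-SASA retention threshold in A^2 (default 100;
#'   strictly greater-than retains)
#' @param top_k optionally keep only the k best survivors by DI
#' @param sasa optional precomputed [residue_sasa()] table
#' @return the filtered, re-ranked DiPair table with an added `sasa_sum`
#'   column
#' @export
pair_sasa_filter <- function(di_pairs, model, mapping, threshold = 100,
                             top_k = NULL, sasa = NULL) {
  if (is.null(sasa)) sasa <- residue_sasa(model)
  key <- paste(sasa$chain, sasa$resno)
  sa <- sasa$sasa[match(paste(mapping$A$chain, di_pairs$i + mapping$A$offset), key)]
  sb <- sasa$sasa[match(paste(mapping$B$chain, di_pairs$j + mapping$B$offset), key)]
  unmapped <- is.na(sa) | is.na(sb)
  if (any(unmapped))
    warning(sum(unmapped), " DI pairs dropped: residue(s) not in the model")
  out <- di_pairs[!unmapped, , drop = FALSE]
  out$sasa_sum <- sa[!unmapped] + sb[!unmapped]
  out <- out[out$sasa_sum > threshold, , drop = FALSE]
  out <- out[order(-out$di, out$i, out$j), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}
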