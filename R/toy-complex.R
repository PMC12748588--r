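#' Construct a toy multi-chain bead complex with a known interface
#'
#' Chains are virtual-Calpha bead strings (consecutive beads 3.6-4.0 A
#' apart). Chain 1 runs along x; every later chain with interface pairs is
#' placed parallel to its partner chain so that each declared pair sits at
#' exactly the target distance (anchor beads offset in +y from their
#' partners, intervening beads interpolated). Chains without interface pairs
#' are parked on a separate z layer. Geometry that cannot realize the
#' declared pairs with legal bead spacing raises a constructive-failure
#' error.
#'
#' @param chain_lengths integer vector of bead counts, one per chain (chain
#'   names A, B, ...)
#' @param interface_pairs NULL, or data.frame with columns `chain_a`,
#'   `res_a`, `chain_b`, `res_b` declaring ground-truth inter-chain contacts
#'   (`chain_a` must come earlier than `chain_b` in chain order)
#' @param target_distance Calpha-Calpha distance (A) at which every declared
#'   pair is realized; must be >= 3.8
#' @param spacing consecutive-bead distance (default 3.8 A)
#' @param seed RNG seed (reserved for jittered variants; construction is
#'   deterministic)
#' @return a `toy_complex`: list with `model` (a [structure_model()]),
#'   `interface_pairs` (with realized distances) and `target_distance`
#' @export
make_toy_complex <- function(chain_lengths, interface_pairs = NULL,
                             target_distance = 8, spacing = 3.8, seed = 1L) {
  if (target_distance < 3.8)
    stop("target distance must be >= 3.8 A (virtual Calpha bond length)")
  n_chains <- length(chain_lengths)
  chain_names <- LETTERS[seq_len(n_chains)]
  if (!is.null(interface_pairs) && nrow(interface_pairs) > 0) {
    ip <- interface_pairs
    stopifnot(all(c("chain_a", "res_a", "chain_b", "res_b") %in% names(ip)))
    ia <- match(ip$chain_a, chain_names); ib <- match(ip$chain_b, chain_names)
    if (any(is.na(ia)) || any(is.na(ib)) || any(ia >= ib))
      stop("interface pairs must reference existing chains with chain_a before chain_b")
    if (any(ip$res_a < 1 | ip$res_a > chain_lengths[ia]) ||
        any(ip$res_b < 1 | ip$res_b > chain_lengths[ib]))
      stop("interface pair residue outside chain bounds")
  } else {
    ip <- data.frame(chain_a = character(0), res_a = integer(0),
                     chain_b = character(0), res_b = integer(0))
  }

  coords <- vector("list", n_chains)
  coords[[1]] <- cbind((seq_len(chain_lengths[1]) - 1) * spacing, 0, 0)
  park_z <- 60
  for (c in seq_len(n_chains)[-1]) {
    anchors <- ip[match(ip$chain_b, chain_names) == c, , drop = FALSE]
    n <- chain_lengths[c]
    if (nrow(anchors) == 0) {
      coords[[c]] <- cbind((seq_len(n) - 1) * spacing, 0, (c - 1) * park_z)
      next
    }
    anchors <- anchors[order(anchors$res_b), , drop = FALSE]
    if (any(duplicated(anchors$res_b)))
      stop("constructive failure: more interface pairs than placeable ",
           "(residue ", anchors$res_b[duplicated(anchors$res_b)][1],
           " anchored twice)")
    apos <- t(vapply(seq_len(nrow(anchors)), function(k) {
      pc <- match(anchors$chain_a[k], chain_names)
      coords[[pc]][anchors$res_a[k], ] + c(0, target_distance, 0)
    }, numeric(3)))
    x <- matrix(NA_real_, n, 3)
    x[anchors$res_b, ] <- apos
    # interpolate between consecutive anchors with uniform steps
    if (nrow(anchors) > 1) {
      for (k in seq_len(nrow(anchors) - 1)) {
        r1 <- anchors$res_b[k]; r2 <- anchors$res_b[k + 1]
        gap <- r2 - r1
        seg <- apos[k + 1, ] - apos[k, ]
        step <- sqrt(sum(seg^2)) / gap
        if (step < 3.6 - 1e-9 || step > 4.0 + 1e-9)
          stop(sprintf(paste0("constructive failure: anchors at residues %d and %d ",
                              "imply a bead step of %.2f A (need 3.6-4.0)"),
                       r1, r2, step))
        for (t in seq_len(gap - 1))
          x[r1 + t, ] <- apos[k, ] + seg * t / gap
      }
    }
    # extend beyond the first/last anchor along the x axis
    first <- anchors$res_b[1]; last <- anchors$res_b[nrow(anchors)]
    if (first > 1)
      for (t in seq_len(first - 1))
        x[first - t, ] <- x[first, ] - c(t * spacing, 0, 0)
    if (last < n)
      for (t in seq_len(n - last))
        x[last + t, ] <- x[last, ] + c(t * spacing, 0, 0)
    coords[[c]] <- x
  }

  names(coords) <- chain_names
  model <- structure_from_chains(coords)

  # validate invariants
  for (c in seq_len(n_chains)) {
    xyz <- coords[[c]]
    if (nrow(xyz) > 1) {
      steps <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                             xyz[-nrow(xyz), , drop = FALSE])^2))
      if (any(steps < 3.6 - 1e-9 | steps > 4.0 + 1e-9))
        stop(sprintf("constructive failure: chain %s has bead steps outside 3.6-4.0 A",
                     chain_names[c]))
    }
  }
  if (nrow(ip) > 0) {
    ip$distance <- vapply(seq_len(nrow(ip)), function(k)
      ca_distance(model, ip$chain_a[k], ip$res_a[k], ip$chain_b[k], ip$res_b[k]),
      numeric(1))
    if (any(abs(ip$distance - target_distance) > 0.1))
      stop("constructive failure: realized interface distance deviates from target")
  }
  structure(list(model = model, interface_pairs = ip,
                 target_distance = target_distance),
            class = "toy_complex")
}

#' Sample a synthetic crosslink table from a toy complex
#'
#' True records are drawn (without replacement) from residue pairs whose
#' Calpha-Calpha distance is at most `max_true_distance`; decoys are drawn
#' uniformly from pairs farther than `decoy_min_distance`. Labels are
#' retained for evaluation.
#'
#' @param complex a [make_toy_complex()] result (or a bare
#'   [structure_model()])
#' @param n_true,n_decoy numbers of true and decoy records (total >= 1)
#' @param max_true_distance upper bound (A) for true pairs (default 35, the
#'   BS3 satisfaction criterion)
#' @param decoy_min_distance lower bound (A) for decoy pairs (defaults to
#'   `max_true_distance`, i.e. decoys come from the remaining pairs)
#' @param inter_chain_only restrict the pair universe to inter-chain pairs
#' @param seed RNG seed
#' @return data.frame `protein1`, `residue1`, `protein2`, `residue2`,
#'   `distance`, `label`
#' @export
make_synthetic_crosslinks <- function(complex, n_true, n_decoy,
                                      max_true_distance = 35,
                                      decoy_min_distance = max_true_distance,
                                      inter_chain_only = TRUE, seed = 1L) {
  if (n_true + n_decoy < 1) stop("n_true + n_decoy must be >= 1")
  model <- if (inherits(complex, "toy_complex")) complex$model else complex
  ca <- ca_coords(model)
  set.seed(seed)
  n <- nrow(ca)
  pr <- utils::combn(n, 2)
  if (inter_chain_only) pr <- pr[, ca$chain[pr[1, ]] != ca$chain[pr[2, ]], drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[pr[1, ], , drop = FALSE] - xyz[pr[2, ], , drop = FALSE])^2))

  pick <- function(idx, k, what) {
    if (k == 0) return(integer(0))
    if (length(idx) < k)
      stop("infeasible: only ", length(idx), " ", what, " pairs available, need ", k)
    sample(idx, k)
  }
  it <- pick(which(d <= max_true_distance), n_true, "true")
  id <- pick(which(d > decoy_min_distance), n_decoy, "decoy")
  sel <- c(it, id)
  out <- data.frame(protein1 = ca$chain[pr[1, sel]], residue1 = ca$resno[pr[1, sel]],
                    protein2 = ca$chain[pr[2, sel]], residue2 = ca$resno[pr[2, sel]],
                    distance = d[sel],
                    label = rep(c("true", "decoy"), c(length(it), length(id))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a crosslink table in the simplified 4-column dialect
#'
#' @param xlinks data.frame with `protein1`, `residue1`, `protein2`,
#'   `residue2` (extra columns are dropped)
#' @param path output TSV path
#' @export
write_crosslinks <- function(xlinks, path) {
  out <- xlinks[, c("protein1", "residue1", "protein2", "residue2")]
  names(out) <- c("Protein1", "Residue1", "Protein2", "Residue2")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
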