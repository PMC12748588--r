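# Independent oracles and fixture builders used across the suite.

# empirical mutual information (nats) between two discrete vectors
empirical_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  s
}

# exhaustive right-tail hypergeometric: enumerate all C(N, n) draws
hypergeom_enum <- function(k, K, n, N) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # contacts are items 1..K
  mean(hits >= k)
}

# independent two-site oracle for DI at q = 2: solve the marginal-matching
# fields by high-precision root finding on the odds ratios (not fixed-point
# iteration), then sum the 4 outcomes
di_two_site_oracle <- function(W, fi, fj) {
  obj <- function(par) {
    x <- c(exp(par[1]), 1); y <- c(exp(par[2]), 1)
    P <- outer(x, y) * W
    P <- P / sum(P)
    sum((rowSums(P) - fi)^2 + (colSums(P) - fj)^2)
  }
  fit <- optim(c(0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 1000))
  x <- c(exp(fit$par[1]), 1); y <- c(exp(fit$par[2]), 1)
  P <- outer(x, y) * W
  P <- P / sum(P)
  sum(P * log(P / outer(fi, fj)))
}

# fabricate a coupling_stats object from a list of single-site frequency
# vectors and (optionally) joint tables for specific pairs; all unspecified
# pairs are independent
make_stats <- function(f_list, joint = list(), boundary = NULL) {
  L <- length(f_list); q <- length(f_list[[1]])
  f_i <- do.call(rbind, f_list)
  fij <- matrix(0, L * q, L * q)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    ii <- ((i - 1) * q + 1):(i * q); jj <- ((j - 1) * q + 1):(j * q)
    if (i == j) {
      blk <- matrix(0, q, q); diag(blk) <- f_list[[i]]
    } else {
      key <- paste(min(i, j), max(i, j))
      blk <- if (!is.null(joint[[key]])) {
        if (i < j) joint[[key]] else t(joint[[key]])
      } else outer(f_list[[i]], f_list[[j]])
    }
    fij[ii, jj] <- blk
  }
  structure(list(f_i = f_i, f_ij = fij, weights = rep(1, 10), m_eff = 10,
                 lambda = 1, q = q, L = L, boundary = boundary),
            class = "coupling_stats")
}

# fine lat-long spherical grid SASA oracle (independent of the golden-spiral
# Shrake-Rupley implementation)
sasa_grid_oracle <- function(xyz, radii, probe = 1.4, n_theta = 300) {
  n <- nrow(xyz)
  out <- numeric(n)
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  for (i in seq_len(n)) {
    R <- radii[i] + probe
    area <- 0
    for (t in th) {
      n_phi <- max(8, round(2 * n_theta * sin(t)))
      ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
      pts <- cbind(xyz[i, 1] + R * sin(t) * cos(ph),
                   xyz[i, 2] + R * sin(t) * sin(ph),
                   xyz[i, 3] + R * cos(t))
      free <- rep(TRUE, n_phi)
      for (j in seq_len(n)) {
        if (j == i) next
        Rj <- radii[j] + probe
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
              (pts[, 3] - xyz[j, 3])^2
        free <- free & d2 >= Rj^2
      }
      # each point represents solid-angle patch sin(t) dtheta dphi
      area <- area + sum(free) * sin(t) * (pi / n_theta) * (2 * pi / n_phi)
    }
    out[i] <- area * R^2
  }
  out
}

# single-atom structure_model fixtures for SASA tests
atom_fixture <- function(xyz, element = "C") {
  n <- nrow(xyz)
  structure_model(data.frame(chain = "A", resno = seq_len(n), resid = "LIG",
                             elety = paste0(element, seq_len(n)),
                             element = element,
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             stringsAsFactors = FALSE))
}

# tiny msa from a character vector of equal-length strings
msa_fixture <- function(seqs, species = NULL, ids = NULL) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  if (is.null(species)) species <- rep(NA_character_, length(seqs))
  new_msa(mat, ids, species)
}

paired_fixture <- function(seqs, boundary) {
  m <- msa_fixture(seqs)
  m$boundary <- boundary
  class(m) <- c("paired_msa", "msa")
  m
}

# standard two-body docking benchmark: receptor A (20 beads), ligand B (10
# beads), 10 interface pairs at 8 A; returns topology (with restraints),
# native coordinates and the DiPair table
docking_benchmark <- function(n_restraints = 10) {
  ip <- data.frame(chain_a = "A", res_a = 6:15, chain_b = "B", res_b = 1:10)
  cx <- make_toy_complex(c(20, 10), ip, target_distance = 8)
  topo <- build_go_topology(cx$model)
  di <- data.frame(rank = 1:10, i = ip$res_a, j = ip$res_b,
                   di = seq(1, 0.1, length.out = 10))
  mapping <- list(A = list(chain = "A", offset = 0),
                  B = list(chain = "B", offset = 0))
  topo <- add_dca_restraints(topo, di, mapping, top_k = n_restraints)
  list(topology = topo, complex = cx, di = di, mapping = mapping,
       native = as.matrix(topo$beads[, c("x", "y", "z")]))
}
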