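#' Build a Calpha structure-based (Go-type) topology
#'
#' One bead per residue (mass 1, reduced units). Per chain of N beads:
#' N-1 harmonic bonds, N-2 harmonic angles, N-3 dihedrals (1x and 3x cosine
#' terms), all with native equilibrium values. Native contacts are Calpha
#' pairs within `contact_cutoff` at sequence separation > `min_seq_sep`
#' (intra-chain; inter-chain native contacts are optional and off by
#' default so that docking is driven by the injected coevolutionary
#' restraints, not by a memorized interface), modeled by the 12-10 potential
#' `eps [5 (s/r)^12 - 6 (s/r)^10]` with s the native distance. Dihedrals
#' whose native geometry is collinear (undefined torsion) are skipped.
#'
#' @param model a [structure_model()] (Calpha coordinates are used)
#' @param contact_cutoff native-contact cutoff in Angstrom (default 8)
#' @param min_seq_sep minimum |i - j| - 1 exclusive bound: pairs need
#'   |i - j| > this (default 3)
#' @param inter_chain_contacts include inter-chain native contacts
#' @param bond_k,angle_k harmonic constants (eps/A^2, eps/rad^2)
#' @param dihedral_k1,dihedral_k3 1x and 3x dihedral strengths (eps)
#' @param contact_eps native-contact well depth (eps)
#' @param sigma_ex,eps_ex excluded-volume diameter (A) and strength (eps)
#' @return a `go_topology`
#' @export
build_go_topology <- function(model, contact_cutoff = 8, min_seq_sep = 3L,
                              inter_chain_contacts = FALSE,
                              bond_k = 100, angle_k = 20,
                              dihedral_k1 = 1, dihedral_k3 = 0.5,
                              contact_eps = 1, sigma_ex = 4, eps_ex = 1) {
  ca <- ca_coords(model)
  n_res <- length(residue_keys(model))
  if (nrow(ca) < n_res)
    warning(n_res - nrow(ca), " residues lack a Calpha and were skipped")
  ca <- ca[order(match(ca$chain, unique(ca$chain)), ca$resno), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(ca)
  chain <- ca$chain

  bonds <- angles <- dihs <- NULL
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    m <- length(idx)
    if (m >= 2) {
      i <- idx[seq_len(m - 1)]; j <- idx[2:m]
      bonds <- rbind(bonds, data.frame(i = i, j = j,
        r0 = sqrt(rowSums((xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE])^2)),
        k = bond_k))
    }
    if (m >= 3) {
      a <- idx[seq_len(m - 2)]; b <- idx[2:(m - 1)]; cc <- idx[3:m]
      th0 <- vapply(seq_along(a), function(t)
        bead_angle(xyz[a[t], ], xyz[b[t], ], xyz[cc[t], ]), numeric(1))
      angles <- rbind(angles, data.frame(i = a, j = b, k = cc,
                                         theta0 = th0, ka = angle_k))
    }
    if (m >= 4) {
      a <- idx[seq_len(m - 3)]; b <- idx[2:(m - 2)]
      cc <- idx[3:(m - 1)]; dd <- idx[4:m]
      ph0 <- vapply(seq_along(a), function(t)
        bead_dihedral(xyz[a[t], ], xyz[b[t], ], xyz[cc[t], ], xyz[dd[t], ]),
        numeric(1))
      ok <- is.finite(ph0)
      if (any(ok))
        dihs <- rbind(dihs, data.frame(i = a[ok], j = b[ok], k = cc[ok],
                                       l = dd[ok], phi0 = ph0[ok],
                                       k1 = dihedral_k1, k3 = dihedral_k3))
    }
  }

  d <- as.matrix(stats::dist(xyz))
  resno <- ca$resno
  contacts <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- chain[i] == chain[j]
      if (same && abs(resno[i] - resno[j]) <= min_seq_sep) next
      if (!same && !inter_chain_contacts) next
      if (d[i, j] <= contact_cutoff)
        contacts <- rbind(contacts, data.frame(i = i, j = j, sigma = d[i, j],
                                               eps = contact_eps))
    }
  }
  empty_pairs <- data.frame(i = integer(0), j = integer(0))
  structure(list(
    beads = data.frame(chain = chain, resno = resno,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
    bonds = if (is.null(bonds)) cbind(empty_pairs, r0 = numeric(0), k = numeric(0)) else bonds,
    angles = if (is.null(angles)) data.frame(i = integer(0), j = integer(0), k = integer(0), theta0 = numeric(0), ka = numeric(0)) else angles,
    dihedrals = if (is.null(dihs)) data.frame(i = integer(0), j = integer(0), k = integer(0), l = integer(0), phi0 = numeric(0), k1 = numeric(0), k3 = numeric(0)) else dihs,
    contacts = if (is.null(contacts)) cbind(empty_pairs, sigma = numeric(0), eps = numeric(0)) else contacts,
    dca = data.frame(i = integer(0), j = integer(0), sigma = numeric(0),
                     eps = numeric(0), kguide = numeric(0), dguide = numeric(0)),
    sigma_ex = sigma_ex, eps_ex = eps_ex), class = "go_topology")
}

bead_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct)))
}

bead_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-10 || sum(n2^2) < 1e-10) return(NA_real_)
  m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

bead_index <- function(topology, chain, resno) {
  match(paste(chain, resno), paste(topology$beads$chain, topology$beads$resno))
}

#' Inject coevolutionary distance restraints into a topology
#'
#' Adds the `min(top_k, available)` best DI pairs as inter-body attractive
#' contacts: a 12-10 well at `target_distance` continued, for separations
#' beyond the well, by a force-capped half-harmonic guiding tail so the
#' restraint exerts a gentle pull at any starting separation. The same pairs
#' enter the exclusion list (they replace generic excluded-volume
#' repulsion). A subset selector supports driving the docking with part of
#' the top-ranked set (e.g. 5 of the top 10).
#'
#' @param topology a `go_topology`
#' @param di_pairs ranked DiPair table (domain coordinates)
#' @param mapping list `list(A = list(chain =, offset =), B = ...)` placing
#'   domain positions on model chains
#' @param top_k how many top-ranked pairs to consider (default 10)
#' @param subset optional integer selector within the top `top_k` (e.g.
#'   `c(1, 3, 5, 7, 9)`)
#' @param epsilon restraint well depth (eps, default 1)
#' @param target_distance restraint target in Angstrom (default 8, matching
#'   the contact definition)
#' @param k_guide guiding-tail spring constant (eps/A^2, default 0.2)
#' @param range_guide tail width before the force cap (A, default 5; the
#'   maximum guiding force is `k_guide * range_guide`)
#' @return the topology with `dca` restraints added
#' @export
add_dca_restraints <- function(topology, di_pairs, mapping, top_k = 10,
                               subset = NULL, epsilon = 1,
                               target_distance = 8,
                               k_guide = 0.2, range_guide = 5) {
  stopifnot(inherits(topology, "go_topology"))
  if (top_k == 0) return(topology)
  sel <- utils::head(di_pairs[order(di_pairs$rank), , drop = FALSE], top_k)
  if (!is.null(subset)) sel <- sel[subset[subset <= nrow(sel)], , drop = FALSE]
  bi <- bead_index(topology, mapping$A$chain, sel$i + mapping$A$offset)
  bj <- bead_index(topology, mapping$B$chain, sel$j + mapping$B$offset)
  drop <- is.na(bi) | is.na(bj)
  if (any(drop))
    warning(sum(drop), " DI restraints dropped: bead not in topology")
  add <- data.frame(i = bi[!drop], j = bj[!drop], sigma = target_distance,
                    eps = epsilon, kguide = k_guide, dguide = range_guide)
  topology$dca <- rbind(topology$dca, add)
  topology
}

# pair exclusion list: bonded 1-2/1-3/1-4 plus native and restraint pairs
topology_exclusions <- function(topology) {
  ex <- rbind(topology$bonds[, c("i", "j")],
              if (nrow(topology$angles)) data.frame(i = topology$angles$i, j = topology$angles$k) else NULL,
              if (nrow(topology$dihedrals)) data.frame(i = topology$dihedrals$i, j = topology$dihedrals$l) else NULL,
              topology$contacts[, c("i", "j")],
              topology$dca[, c("i", "j")])
  if (is.null(ex) || nrow(ex) == 0) return(data.frame(i = integer(0), j = integer(0)))
  unique(data.frame(i = pmin(ex$i, ex$j), j = pmax(ex$i, ex$j)))
}

#' Place the ligand body at a stated center-of-mass separation
#'
#' Rigidly translates the ligand chains along a random (seeded) direction so
#' the receptor-ligand center-of-mass separation equals `distance`,
#' resampling the direction (up to `max_tries`) until no inter-body bead
#' pair is closer than `min_clearance`.
#'
#' @param topology a `go_topology`
#' @param ligand_chains chain id(s) forming the ligand body
#' @param distance target COM separation in Angstrom (default 60)
#' @param seed RNG seed
#' @param min_clearance minimum allowed inter-body bead distance (default 6)
#' @param max_tries placement attempts before failing (default 100)
#' @return n x 3 coordinate matrix for the full system
#' @export
initialize_separation <- function(topology, ligand_chains, distance = 60,
                                  seed = 1L, min_clearance = 6,
                                  max_tries = 100L) {
  if (distance < min_clearance)
    stop("parameter error: separation must exceed the clearance distance ",
         "(bodies would overlap)")
  set.seed(seed)
  x <- as.matrix(topology$beads[, c("x", "y", "z")])
  lig <- topology$beads$chain %in% ligand_chains
  if (!any(lig) || all(lig)) stop("ligand chains must form a proper subset of the system")
  com_r <- colMeans(x[!lig, , drop = FALSE])
  com_l <- colMeans(x[lig, , drop = FALSE])
  for (t in seq_len(max_tries)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    shift <- com_r + distance * u - com_l
    xl <- sweep(x[lig, , drop = FALSE], 2, shift, "+")
    dmin <- min(as.matrix(stats::dist(rbind(x[!lig, , drop = FALSE], xl)))[
      seq_len(sum(!lig)), sum(!lig) + seq_len(sum(lig))])
    if (dmin >= min_clearance) {
      out <- x; out[lig, ] <- xl
      return(out)
    }
  }
  stop("placement error: no clash-free direction found in ", max_tries, " tries")
}

#' Langevin dynamics on a Go topology
#'
#' BAOAB-discretized Langevin integration in reduced units (kB = 1, bead
#' mass 1). With `friction = 0` the scheme is velocity Verlet and conserves
#' energy. The RNG is seeded, so a fixed seed reproduces the trajectory
#' bitwise. Optionally a set of beads is tethered to its starting position
#' by weak harmonic restraints (receptor position restraints).
#'
#' @param topology a `go_topology`
#' @param coords starting n x 3 coordinates (default: the native beads)
#' @param n_steps number of integration steps
#' @param dt timestep in reduced time units (default 5e-4)
#' @param friction Langevin friction gamma (1/time; default 1; 0 = NVE)
#' @param temperature reduced temperature (default 0.5)
#' @param stride steps between recorded snapshots (default 1000)
#' @param seed RNG seed
#' @param tether_chains chain id(s) to tether (NULL for none)
#' @param tether_k tether spring constant (eps/A^2, default 0.02)
#' @return a `docking_trajectory`: list with `coords` (3 x n x n_snap
#'   array), `energies` (data.frame step/epot/ekin/etot), `final`,
#'   `topology`, `params`
#' @export
run_langevin <- function(topology, coords = NULL, n_steps = 1e5, dt = 5e-4,
                         friction = 1, temperature = 0.5, stride = 1000L,
                         seed = 1L, tether_chains = NULL, tether_k = 0.02) {
  stopifnot(inherits(topology, "go_topology"))
  if (is.null(coords)) coords <- as.matrix(topology$beads[, c("x", "y", "z")])
  coords <- as.matrix(coords)
  ex <- topology_exclusions(topology)
  tl <- list(bond_i = as.integer(topology$bonds$i - 1L),
             bond_j = as.integer(topology$bonds$j - 1L),
             bond_r0 = topology$bonds$r0, bond_k = topology$bonds$k,
             angle_i = as.integer(topology$angles$i - 1L),
             angle_j = as.integer(topology$angles$j - 1L),
             angle_k = as.integer(topology$angles$k - 1L),
             angle_theta0 = topology$angles$theta0, angle_ka = topology$angles$ka,
             dih_i = as.integer(topology$dihedrals$i - 1L),
             dih_j = as.integer(topology$dihedrals$j - 1L),
             dih_k = as.integer(topology$dihedrals$k - 1L),
             dih_l = as.integer(topology$dihedrals$l - 1L),
             dih_phi0 = topology$dihedrals$phi0,
             dih_k1 = topology$dihedrals$k1, dih_k3 = topology$dihedrals$k3,
             con_i = as.integer(topology$contacts$i - 1L),
             con_j = as.integer(topology$contacts$j - 1L),
             con_sigma = topology$contacts$sigma, con_eps = topology$contacts$eps,
             dca_i = as.integer(topology$dca$i - 1L),
             dca_j = as.integer(topology$dca$j - 1L),
             dca_sigma = topology$dca$sigma, dca_eps = topology$dca$eps,
             dca_kguide = topology$dca$kguide, dca_dguide = topology$dca$dguide,
             excl_i = as.integer(ex$i - 1L), excl_j = as.integer(ex$j - 1L),
             sigma_ex = topology$sigma_ex, eps_ex = topology$eps_ex,
             rc_ex = 2.5 * topology$sigma_ex)
  if (is.null(tether_chains)) {
    t_idx <- integer(0); t_ref <- matrix(0, 0, 3)
  } else {
    t_idx <- which(topology$beads$chain %in% tether_chains)
    t_ref <- coords[t_idx, , drop = FALSE]
  }
  set.seed(seed)
  res <- run_langevin_cpp(coords, tl, dt, friction, temperature,
                          as.integer(n_steps), as.integer(stride),
                          as.integer(t_idx - 1L), t_ref, tether_k)
  energies <- data.frame(step = res$step, epot = res$epot, ekin = res$ekin,
                         etot = res$epot + res$ekin)
  structure(list(coords = res$traj, energies = energies, final = res$final,
                 topology = topology,
                 params = list(dt = dt, friction = friction,
                               temperature = temperature, n_steps = n_steps,
                               stride = stride, seed = seed)),
            class = "docking_trajectory")
}

#' Extract one snapshot of a trajectory
#'
#' @param traj a `docking_trajectory`
#' @param s snapshot index (1-based; negative counts from the end)
#' @return n x 3 coordinate matrix
#' @export
snapshot <- function(traj, s) {
  dims <- dim(traj$coords)
  if (s < 0) s <- dims[3] + 1 + s
  t(matrix(traj$coords[, , s], nrow = 3))
}

n_snapshots <- function(traj) dim(traj$coords)[3]

#' Docking quality metrics
#'
#' Over the final `window` fraction of snapshots: the mean fraction of DCA
#' restraint pairs formed (distance below `formed_factor` times the
#' restraint target) and, when reference coordinates are supplied, the mean
#' ligand RMSD after optimal (Kabsch) superposition of the receptor beads.
#'
#' @param traj a `docking_trajectory`
#' @param ligand_chains chain id(s) of the ligand body
#' @param reference optional n x 3 reference coordinates (e.g. the native
#'   complex)
#' @param window trailing fraction of snapshots to average (default 0.1)
#' @param formed_factor formation threshold as a multiple of the restraint
#'   target distance (default 1.2)
#' @return list with `contact_fraction`, `ligand_rmsd` (NA without a
#'   reference) and `com_separation` (mean over the window)
#' @export
docking_metrics <- function(traj, ligand_chains, reference = NULL,
                            window = 0.1, formed_factor = 1.2) {
  topo <- traj$topology
  ns <- n_snapshots(traj)
  take <- max(1L, ceiling(window * ns))
  snaps <- (ns - take + 1):ns
  lig <- topo$beads$chain %in% ligand_chains
  rec <- !lig
  fracs <- rmsds <- coms <- numeric(0)
  for (s in snaps) {
    x <- snapshot(traj, s)
    if (nrow(topo$dca) > 0) {
      dd <- sqrt(rowSums((x[topo$dca$i, , drop = FALSE] -
                          x[topo$dca$j, , drop = FALSE])^2))
      fracs <- c(fracs, mean(dd < formed_factor * topo$dca$sigma))
    }
    coms <- c(coms, sqrt(sum((colMeans(x[rec, , drop = FALSE]) -
                              colMeans(x[lig, , drop = FALSE]))^2)))
    if (!is.null(reference)) {
      fit <- kabsch(x[rec, , drop = FALSE], reference[rec, , drop = FALSE])
      xl <- sweep(x[lig, , drop = FALSE], 2, fit$center_from, "-") %*% fit$rotation
      xl <- sweep(xl, 2, fit$center_to, "+")
      rmsds <- c(rmsds, sqrt(mean(rowSums((xl - reference[lig, , drop = FALSE])^2))))
    }
  }
  list(contact_fraction = if (length(fracs)) mean(fracs) else NA_real_,
       ligand_rmsd = if (length(rmsds)) mean(rmsds) else NA_real_,
       com_separation = mean(coms))
}

#' Inter-body center-of-mass distance along a trajectory
#'
#' @param traj a `docking_trajectory`
#' @param ligand_chains chain id(s) of the ligand body
#' @return numeric vector, one value per snapshot
#' @export
com_distance_trace <- function(traj, ligand_chains) {
  topo <- traj$topology
  lig <- topo$beads$chain %in% ligand_chains
  vapply(seq_len(n_snapshots(traj)), function(s) {
    x <- snapshot(traj, s)
    sqrt(sum((colMeans(x[!lig, , drop = FALSE]) -
              colMeans(x[lig, , drop = FALSE]))^2))
  }, numeric(1))
}

# optimal rotation superposing `from` onto `to` (Kabsch)
kabsch <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- crossprod(sweep(from, 2, cf), sweep(to, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, center_from = cf, center_to = ct)
}

#' Export a topology in a Gromos87-style plain-text dialect
#'
#' Sections `[ atoms ]`, `[ bonds ]`, `[ angles ]`, `[ dihedrals ]`,
#' `[ pairs ]` (native contacts then DCA restraints) and `[ exclusions ]`,
#' for interoperability with structure-based-model tooling.
#'
#' @param topology a `go_topology`
#' @param path output file
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("[ atoms ]")
  b <- topology$beads
  for (t in seq_len(nrow(b))) w("%6d CA %6d %s 1.0", t, b$resno[t], b$chain[t])
  w("[ bonds ]")
  for (t in seq_len(nrow(topology$bonds)))
    w("%6d %6d 1 %10.5f %10.3f", topology$bonds$i[t], topology$bonds$j[t],
      topology$bonds$r0[t], topology$bonds$k[t])
  w("[ angles ]")
  for (t in seq_len(nrow(topology$angles)))
    w("%6d %6d %6d 1 %10.5f %10.3f", topology$angles$i[t], topology$angles$j[t],
      topology$angles$k[t], topology$angles$theta0[t], topology$angles$ka[t])
  w("[ dihedrals ]")
  for (t in seq_len(nrow(topology$dihedrals)))
    w("%6d %6d %6d %6d 1 %10.5f %10.3f %10.3f", topology$dihedrals$i[t],
      topology$dihedrals$j[t], topology$dihedrals$k[t], topology$dihedrals$l[t],
      topology$dihedrals$phi0[t], topology$dihedrals$k1[t], topology$dihedrals$k3[t])
  w("[ pairs ]")
  for (t in seq_len(nrow(topology$contacts)))
    w("%6d %6d 1 %10.5f %10.3f", topology$contacts$i[t], topology$contacts$j[t],
      topology$contacts$sigma[t], topology$contacts$eps[t])
  for (t in seq_len(nrow(topology$dca)))
    w("%6d %6d 2 %10.5f %10.3f", topology$dca$i[t], topology$dca$j[t],
      topology$dca$sigma[t], topology$dca$eps[t])
  w("[ exclusions ]")
  ex <- topology_exclusions(topology)
  for (t in seq_len(nrow(ex))) w("%6d %6d", ex$i[t], ex$j[t])
  invisible(path)
}
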