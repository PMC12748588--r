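test_that("topology counts bonded terms per chain", {
  cx <- make_toy_complex(10)
  topo <- build_go_topology(cx$model)
  expect_equal(nrow(topo$bonds), 9)
  expect_equal(nrow(topo$angles), 8)
  # straight native chain: torsions are undefined (collinear) and skipped
  expect_equal(nrow(topo$dihedrals), 0)
  expect_equal(nrow(topo$contacts), 0)   # straight chain, |i-j| > 3 all > 8 A

  set.seed(2)
  xyz <- cbind(seq_len(10) * 2.9, rep(c(0, 2.4), 5), rnorm(10, 0, 0.2))
  m <- structure_from_chains(list(A = xyz))
  t2 <- build_go_topology(m, contact_cutoff = 8)
  expect_equal(nrow(t2$dihedrals), 7)
  # native-contact set matches a brute-force scan under the separation rule
  want <- 0
  for (i in 1:9) for (j in (i + 1):10)
    if (j - i > 3 && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 8) want <- want + 1
  expect_equal(nrow(t2$contacts), want)
})

test_that("restraint injection respects top_k, subsets and exclusions", {
  bench <- docking_benchmark(0)
  topo <- bench$topology
  di12 <- data.frame(rank = 1:12, i = c(6:15, 16, 17), j = c(1:10, 10, 10),
                     di = seq(1.2, 0.1, length.out = 12))
  t10 <- add_dca_restraints(topo, di12, bench$mapping, top_k = 10)
  expect_equal(nrow(t10$dca), 10)
  expect_equal(t10$dca$i, bead_idx <- match(paste("A", 6:15),
               paste(topo$beads$chain, topo$beads$resno)))
  ex <- coevodock:::topology_exclusions(t10)
  expect_true(all(paste(pmin(t10$dca$i, t10$dca$j), pmax(t10$dca$i, t10$dca$j)) %in%
                  paste(ex$i, ex$j)))

  expect_identical(add_dca_restraints(topo, di12, bench$mapping, top_k = 0), topo)
  t5 <- add_dca_restraints(topo, di12, bench$mapping, top_k = 10,
                           subset = c(1, 3, 5, 7, 9))
  expect_equal(nrow(t5$dca), 5)
})

test_that("ligand placement hits the requested separation, seeded", {
  bench <- docking_benchmark()
  x1 <- initialize_separation(bench$topology, "B", 60, seed = 4)
  lig <- bench$topology$beads$chain == "B"
  sep <- sqrt(sum((colMeans(x1[!lig, ]) - colMeans(x1[lig, ]))^2))
  expect_equal(sep, 60, tolerance = 1 / 60)
  expect_identical(x1, initialize_separation(bench$topology, "B", 60, seed = 4))
  expect_false(identical(x1, initialize_separation(bench$topology, "B", 60, seed = 5)))
  expect_error(initialize_separation(bench$topology, "B", 0), "parameter error")
})

test_that("frictionless integration conserves energy on a two-bead bond", {
  m <- structure_from_chains(list(A = rbind(c(0, 0, 0), c(3.8, 0, 0))))
  topo <- build_go_topology(m)
  x0 <- rbind(c(-0.3, 0, 0), c(4.1, 0, 0))   # stretched bond
  tr <- run_langevin(topo, x0, n_steps = 1e5, dt = 5e-4, friction = 0,
                     temperature = 0, stride = 500, seed = 1)
  et <- tr$energies$etot
  expect_gt(abs(et[1]), 0)
  expect_lt(max(abs(et - et[1])) / abs(et[1]), 0.001)
})

test_that("energy is conserved with all force terms active", {
  set.seed(12)
  xyz <- cbind(seq_len(9) * 2.7, rep(c(0, 2.6), length.out = 9), rnorm(9, 0, 0.3))
  m <- structure_from_chains(list(A = xyz))
  topo <- build_go_topology(m, contact_cutoff = 9)
  x0 <- as.matrix(topo$beads[, c("x", "y", "z")]) + matrix(rnorm(27, 0, 0.2), 9, 3)
  tr <- run_langevin(topo, x0, n_steps = 5e4, dt = 5e-4, friction = 0,
                     temperature = 0.2, stride = 500, seed = 2)
  et <- tr$energies$etot
  expect_lt(max(abs(et - et[1])) / abs(et[1]), 0.001)
})

test_that("a native start at zero temperature stays at the minimum", {
  bench <- docking_benchmark()
  tr <- run_langevin(bench$topology, bench$native, n_steps = 2e4, dt = 5e-4,
                     friction = 1, temperature = 0, stride = 2000, seed = 1)
  rmsd <- sqrt(mean(rowSums((snapshot(tr, -1) - bench$native)^2)))
  expect_lt(rmsd, 0.05)
})

test_that("identical seeds give bitwise-identical energy traces", {
  bench <- docking_benchmark()
  x0 <- initialize_separation(bench$topology, "B", 40, seed = 3)
  tr1 <- run_langevin(bench$topology, x0, n_steps = 5e3, seed = 7)
  tr2 <- run_langevin(bench$topology, x0, n_steps = 5e3, seed = 7)
  expect_identical(tr1$energies, tr2$energies)
  expect_identical(tr1$coords, tr2$coords)
})

test_that("kinetic energy equipartitions at the thermostat temperature", {
  set.seed(3)
  xyz <- cbind(seq_len(12) * 2.8, rep(c(0, 2.5), 6), rnorm(12, 0, 0.2))
  topo <- build_go_topology(structure_from_chains(list(A = xyz)))
  tr <- run_langevin(topo, NULL, n_steps = 2e5, dt = 5e-4, friction = 1,
                     temperature = 0.5, stride = 200, seed = 5)
  ek <- tr$energies$ekin
  half <- ek[(length(ek) %/% 2):length(ek)]
  expect_equal(mean(half) / (3 * 12 / 2), 0.5, tolerance = 0.05)
})

test_that("docking metrics read formed restraints and superposed RMSD", {
  bench <- docking_benchmark()
  tr <- run_langevin(bench$topology, bench$native, n_steps = 0, stride = 1000,
                     temperature = 0, seed = 1)
  m <- docking_metrics(tr, "B", reference = bench$native)
  expect_equal(m$contact_fraction, 1)
  expect_equal(m$ligand_rmsd, 0, tolerance = 1e-9)

  # held at 60 A with a short unrestrained run: nothing forms
  topo0 <- build_go_topology(bench$complex$model)
  x0 <- initialize_separation(topo0, "B", 60, seed = 2)
  topo0$dca <- bench$topology$dca[0, ]
  tr0 <- run_langevin(topo0, x0, n_steps = 2e4, stride = 1000, seed = 2,
                      tether_chains = "A")
  d <- snapshot(tr0, -1)
  dd <- sqrt(rowSums((d[bench$topology$dca$i, ] - d[bench$topology$dca$j, ])^2))
  expect_lt(mean(dd < 9.6), 0.05)
})

test_that("restrained docking pulls the ligand down a funnel", {
  bench <- docking_benchmark()
  x0 <- initialize_separation(bench$topology, "B", 60, seed = 11)
  tr <- run_langevin(bench$topology, x0, n_steps = 3e5, dt = 5e-4, friction = 1,
                     temperature = 0.5, stride = 1000, seed = 11,
                     tether_chains = "A")
  trace <- com_distance_trace(tr, "B")
  quarts <- split(trace, cut(seq_along(trace), 4, labels = FALSE))
  med <- vapply(quarts, stats::median, numeric(1))
  expect_true(all(diff(med) < 0))
  m <- docking_metrics(tr, "B", reference = bench$native)
  expect_gte(m$contact_fraction, 0.8)
})

test_that("topology export writes all Gromos-style sections", {
  bench <- docking_benchmark()
  f <- withr::local_tempfile(fileext = ".top")
  write_topology(bench$topology, f)
  txt <- readLines(f)
  for (sec in c("atoms", "bonds", "angles", "dihedrals", "pairs", "exclusions"))
    expect_true(any(grepl(sec, txt, fixed = TRUE)))
  expect_equal(sum(grepl("^\\[", txt)), 6)
})
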