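test_that("planted model validates its inputs", {
  expect_error(planted_model(0, 5), "non-positive")
  expect_error(planted_model(5, 5, alphabet_size = 1), "q must be >= 2")
  expect_error(planted_model(5, 5, planted_pairs = data.frame(i = 9, j = 1, strength = 1)),
               "outside domain bounds")
  expect_error(planted_model(5, 5, planted_pairs = data.frame(i = 1, j = 1, strength = Inf)),
               "non-finite")
})

test_that("sampling is a pure function of the seed", {
  pm <- planted_model(8, 8, 21, seed = 3)
  a <- sample_potts_msa(pm, 50, gap_run_fraction = 0.2)
  b <- sample_potts_msa(pm, 50, gap_run_fraction = 0.2)
  expect_identical(a, b)
  c <- sample_potts_msa(pm, 50, gap_run_fraction = 0.2, seed = 4)
  expect_false(identical(a$msa_a$mat, c$msa_a$mat))
})

test_that("zero couplings give near-zero inter-domain mutual information", {
  pm <- planted_model(4, 4, alphabet_size = 2, seed = 5)
  sim <- sample_potts_msa(pm, 2000)
  codes <- sim$paired$mat
  mis <- c()
  for (i in 1:4) for (j in 5:8)
    mis <- c(mis, empirical_mi(codes[, i], codes[, j]))
  expect_lt(max(abs(mis)), 0.02)
})

test_that("a planted q=2 coupling carries the highest inter-domain MI", {
  pm <- planted_model(6, 6, alphabet_size = 2,
                      planted_pairs = data.frame(i = 3, j = 4, strength = 2),
                      seed = 9)
  sim <- sample_potts_msa(pm, 5000)
  codes <- sim$paired$mat
  mi <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    mi[i, j] <- empirical_mi(codes[, i], codes[, 6 + j])
  best <- which(mi == max(mi), arr.ind = TRUE)
  expect_equal(unname(best[1, ]), c(3, 4))
})

test_that("with zero couplings and fields, column frequencies are uniform", {
  q <- 4
  pm <- planted_model(5, 5, alphabet_size = q, seed = 13)
  sim <- sample_potts_msa(pm, 5000)
  codes <- matrix(match(sim$paired$mat, coevodock:::AA_ALPHABET[1:q]), nrow = 5000)
  n <- 5000
  se <- sqrt((1 / q) * (1 - 1 / q) / n)
  for (col in c(1, 5, 10)) {
    freq <- tabulate(codes[, col], q) / n
    expect_lt(max(abs(freq - 1 / q)), 3 * se)
  }
})

test_that("gap runs appear as contiguous blocks in the requested fraction of rows", {
  pm <- planted_model(20, 20, 21, seed = 2)
  sim <- sample_potts_msa(pm, 100, gap_run_fraction = 0.3, gap_run_length = 0.25)
  runs <- apply(sim$msa_a$mat, 1, function(r) {
    e <- rle(r == "-")
    if (any(e$values)) max(e$lengths[e$values]) else 0L
  })
  expect_equal(sum(runs >= ceiling(0.25 * 20)), 30)
})

test_that("toy complex realizes declared interface pairs exactly", {
  cx <- make_toy_complex(c(10, 10),
                         data.frame(chain_a = "A", res_a = 5, chain_b = "B", res_b = 5),
                         target_distance = 6)
  expect_equal(cx$interface_pairs$distance, 6, tolerance = 0.1 / 6)
  d <- ca_distance(cx$model, "A", 5, "B", 5)
  expect_equal(d, 6, tolerance = 1e-9)
})

test_that("single chain with no interface is valid", {
  cx <- make_toy_complex(10)
  expect_s3_class(cx$model, "structure_model")
  expect_equal(nrow(ca_coords(cx$model)), 10)
})

test_that("toy chains satisfy the virtual-bond invariant", {
  cx <- make_toy_complex(c(15, 12, 8),
                         data.frame(chain_a = c("A", "A"), res_a = c(3, 9),
                                    chain_b = c("B", "B"), res_b = c(2, 8)),
                         target_distance = 8)
  for (ch in c("A", "B", "C")) {
    ca <- ca_coords(cx$model)
    xyz <- as.matrix(ca[ca$chain == ch, c("x", "y", "z")])
    steps <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
    expect_true(all(steps >= 3.6 - 1e-9 & steps <= 4.0 + 1e-9))
  }
})

test_that("planted pairs appear in the structure contact map", {
  ip <- data.frame(chain_a = "A", res_a = c(2, 5, 8),
                   chain_b = "B", res_b = c(2, 5, 8))
  cx <- make_toy_complex(c(10, 10), ip, target_distance = 8)
  cm <- structure_contacts(cx$model, cutoff = 8.5, inter_chain_only = TRUE)
  expect_true(all(in_contact(cm, ip$chain_a, ip$res_a, ip$chain_b, ip$res_b)))
})

test_that("infeasible interface geometry raises a constructive failure", {
  ip <- data.frame(chain_a = c("A", "A"), res_a = c(1, 10),
                   chain_b = c("B", "B"), res_b = c(5, 6))
  expect_error(make_toy_complex(c(12, 12), ip, target_distance = 8),
               "constructive failure")
})

test_that("synthetic crosslink tables honor their composition", {
  ip <- data.frame(chain_a = "A", res_a = 6:15, chain_b = "B", res_b = 1:10)
  cx <- make_toy_complex(c(30, 20), ip, target_distance = 8)
  cfg <- list(A = list(chains = "A", offset = 0), B = list(chains = "B", offset = 0))

  pure_true <- make_synthetic_crosslinks(cx, 5, 0, max_true_distance = 35, seed = 1)
  m <- map_distances(pure_true, cx$model, cfg)
  expect_equal(count_within(m, 35)$count, 5)

  mixed <- make_synthetic_crosslinks(cx, 10, 10, max_true_distance = 35, seed = 2)
  m2 <- map_distances(mixed, cx$model, cfg)
  cw <- count_within(m2, 35)
  expect_equal(cw$count, 10)
  expect_equal(cw$fraction, 0.5)

  # decoys on a far-apart complex land above any 35 A cutoff
  far <- make_toy_complex(c(5, 5))  # parked chains, > 35 A apart
  dec <- make_synthetic_crosslinks(far, 0, 3, max_true_distance = 35, seed = 3)
  cfg2 <- list(A = list(chains = "A", offset = 0), B = list(chains = "B", offset = 0))
  expect_equal(count_within(map_distances(dec, far$model, cfg2), 35)$count, 0)
  expect_error(make_synthetic_crosslinks(far, 1, 0, max_true_distance = 35, seed = 4),
               "infeasible")
})
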