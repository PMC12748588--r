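test_that("sequence weights count identity neighbours", {
  m <- paired_fixture(rep("ACDEF", 4), boundary = 2)
  w <- sequence_weights(m, 0.8)
  expect_equal(w$weights, rep(0.25, 4))
  expect_equal(w$m_eff, 1)

  m2 <- paired_fixture(c("AAAAA", "CCCCC", "GGGGG"), boundary = 2)
  w2 <- sequence_weights(m2, 0.8)
  expect_equal(w2$weights, rep(1, 3))
  expect_equal(w2$m_eff, 3)

  m3 <- paired_fixture(c("AAAAA", "AAAAA", "CCCCC"), boundary = 2)
  w3 <- sequence_weights(m3, 0.8)
  expect_equal(w3$weights, c(0.5, 0.5, 1))
  expect_equal(w3$m_eff, 2)

  expect_error(sequence_weights(m, 0), "identity_threshold")
  expect_error(sequence_weights(m, 1.2), "identity_threshold")
})

test_that("frequencies recover empirical counts and the pseudocount limits", {
  m <- paired_fixture(c("AB", "BB"), boundary = 1)
  ab <- c("A", "B")
  s0 <- frequencies(m, weights = list(weights = c(1, 1), m_eff = 2),
                    lambda = 0, alphabet = ab)
  expect_equal(s0$f_i[1, ], c(0.5, 0.5))
  expect_equal(s0$f_i[2, ], c(0, 1))

  s1 <- frequencies(m, weights = list(weights = c(1, 1), m_eff = 2),
                    lambda = 1, alphabet = ab)
  expect_equal(s1$f_i[1, 1], (0.5 + 1) / (1 + 2))   # hand arithmetic
  expect_equal(rowSums(s1$f_i), c(1, 1))

  shuge <- frequencies(m, weights = list(weights = c(1, 1), m_eff = 2),
                       lambda = 1e9, alphabet = ab)
  expect_equal(shuge$f_i[1, ], c(0.5, 0.5), tolerance = 1e-6)

  # marginal consistency of the pair table
  s <- frequencies(paired_fixture(c("ACD", "AAD", "CCD", "DAA"), boundary = 1),
                   lambda = 2)
  q <- s$q
  for (i in 1:3) {
    ii <- ((i - 1) * q + 1):(i * q)
    jj <- ((3 - 1) * q + 1):(3 * q)
    if (i == 3) next
    expect_equal(rowSums(s$f_ij[ii, jj]), s$f_i[i, ], tolerance = 1e-10)
  }
})

test_that("independent sites give zero couplings and zero DI", {
  fl <- list(c(0.3, 0.7), c(0.6, 0.4), c(0.2, 0.8))
  stats <- make_stats(fl, boundary = 1)
  model <- mean_field_couplings(stats)
  expect_lt(max(abs(model$e[1, 2:3])), 1e-8)
  di <- direct_information(model, stats)
  expect_lt(max(abs(di)), 1e-10)
})

test_that("q=2 couplings match the closed-form 2x2 inversion", {
  f1 <- c(0.6, 0.4); f2 <- c(0.5, 0.5)
  J <- matrix(c(0.35, 0.25, 0.15, 0.25), 2, 2, byrow = TRUE)  # planted joint
  stats <- make_stats(list(f1, f2), joint = list("1 2" = J))
  model <- mean_field_couplings(stats)
  # reduced alphabet keeps state 1 only: C is 2x2 over sites
  c11 <- f1[1] * (1 - f1[1]); c22 <- f2[1] * (1 - f2[1])
  c12 <- J[1, 1] - f1[1] * f2[1]
  det <- c11 * c22 - c12^2
  expect_equal(model$e[1, 2], c12 / det, tolerance = 1e-10)   # -(C^-1)[1,2]
  expect_equal(model$e[2, 1], model$e[1, 2], tolerance = 1e-12)
})

test_that("coupling symmetry holds on sampled alignments", {
  pm <- planted_model(4, 4, alphabet_size = 6,
                      planted_pairs = data.frame(i = c(1, 3), j = c(2, 4),
                                                 strength = c(1, 1.5)),
                      seed = 17)
  sim <- sample_potts_msa(pm, 400)
  res <- run_dca(sim$paired, alphabet = coevodock:::AA_ALPHABET[1:6])
  e <- res$model$e
  q <- res$model$q; qr <- q - 1
  for (i in 1:3) for (j in (i + 1):4) {
    bij <- e[((i - 1) * qr + 1):(i * qr), ((j - 1) * qr + 1):(j * qr)]
    bji <- e[((j - 1) * qr + 1):(j * qr), ((i - 1) * qr + 1):(i * qr)]
    expect_equal(bij, t(bji), tolerance = 1e-10)
  }
})

test_that("DI matches the independent two-site oracle at q=2", {
  set.seed(8)
  rows <- c(replicate(60, paste(sample(c("A", "B"), 4, TRUE), collapse = "")),
            replicate(40, {
              x <- sample(c("A", "B"), 1)
              paste(c(x, sample(c("A", "B"), 2, TRUE), x), collapse = "")
            }))
  m <- paired_fixture(rows, boundary = 2)
  ab <- c("A", "B")
  w <- sequence_weights(m, 0.9, alphabet = ab)
  stats <- frequencies(m, w, lambda = w$m_eff / 2, alphabet = ab)
  model <- mean_field_couplings(stats)
  di <- direct_information(model, stats, tol = 1e-10, maxit = 5000)
  for (i in 1:3) for (j in (i + 1):4) {
    W <- exp(coupling_block(model, i, j))
    oracle <- di_two_site_oracle(W, stats$f_i[i, ], stats$f_i[j, ])
    expect_equal(di[i, j], oracle, tolerance = 1e-6)
  }
  # DI is symmetric and non-negative
  expect_equal(di, t(di))
  expect_true(all(di >= 0))
})

test_that("DI is invariant under relabeling of alphabet states", {
  pm <- planted_model(3, 3, alphabet_size = 4,
                      planted_pairs = data.frame(i = 2, j = 2, strength = 1.5),
                      seed = 23)
  sim <- sample_potts_msa(pm, 500)
  ab4 <- coevodock:::AA_ALPHABET[1:4]
  res <- run_dca(sim$paired, alphabet = ab4)
  # permute state labels and recompute
  perm <- c(3, 1, 4, 2)
  mat2 <- matrix(ab4[perm][match(sim$paired$mat, ab4)], nrow = nrow(sim$paired$mat))
  m2 <- sim$paired; m2$mat <- mat2
  res2 <- run_dca(m2, alphabet = ab4)
  # equal up to the marginal-matching fixed-point tolerance (1e-4)
  expect_equal(res$di, res2$di, tolerance = 1e-4)
})

test_that("increasing the pseudocount shrinks couplings monotonically", {
  pm <- planted_model(4, 4, alphabet_size = 8,
                      planted_pairs = data.frame(i = 1, j = 1, strength = 2),
                      seed = 29)
  sim <- sample_potts_msa(pm, 800)
  ab <- coevodock:::AA_ALPHABET[1:8]
  w <- sequence_weights(sim$paired, 0.8, alphabet = ab)
  means <- vapply(c(0.5, 1, 2) * w$m_eff, function(lam) {
    st <- frequencies(sim$paired, w, lam, alphabet = ab)
    mean(abs(mean_field_couplings(st)$e))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("independent-column alignments yield small inter-domain DI", {
  pm <- planted_model(10, 10, 21, seed = 37)
  sim <- sample_potts_msa(pm, 2000)
  res <- run_dca(sim$paired)
  expect_lt(max(res$pairs$di), 0.05)
})

test_that("inter-domain ranking is ordered, bounded and tie-broken", {
  di <- matrix(0, 6, 6)
  di[2, 5] <- 0.4
  expect_equal(rank_interdomain_pairs(di, 3)[1, c("i", "j")],
               data.frame(i = 2L, j = 2L), ignore_attr = TRUE)

  di[1, 4] <- di[3, 6] <- 0.2          # tie broken by (i, j) ascending
  r <- rank_interdomain_pairs(di, 3, top_n = 100)
  expect_equal(nrow(r), 9)             # top_n larger than pair count -> all
  expect_equal(r$i[1:3], c(2L, 1L, 3L))
  expect_true(all(diff(r$di) <= 0))
  expect_error(rank_interdomain_pairs(di, 6), "boundary")
})
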