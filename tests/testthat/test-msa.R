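test_that("FASTA reading enforces the alignment contract", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1|OS=Arabidopsis thaliana", "ACDEF",
               ">Q2_HUMAN", "AC-EF",
               ">plain", "AAAAA"), f)
  m <- read_msa(f)
  expect_equal(dim(m), c(3L, 5L))
  expect_equal(m$species, c("Arabidopsis thaliana", "HUMAN", NA))

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "AC"), ragged)
  expect_error(read_msa(ragged), "ragged")

  odd <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACX", ">b", "AC."), odd)
  expect_warning(m2 <- read_msa(odd), "mapped to gap")
  expect_equal(m2$mat[1, 3], "-")
  expect_equal(m2$mat[2, 3], "-")
})

test_that("Stockholm alignments parse, including wrapped blocks", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF ID toy",
               "seq1_HUMAN  ACD",
               "seq2_ARATH  A-D",
               "",
               "seq1_HUMAN  EFG",
               "seq2_ARATH  EF-",
               "//"), f)
  m <- read_msa(f)
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(paste(m$mat[1, ], collapse = ""), "ACDEFG")
  expect_equal(m$species, c("HUMAN", "ARATH"))
})

test_that("write -> read round-trips an alignment", {
  m <- msa_fixture(c("AC-EF", "GHIKL"), species = c("Homo sapiens", NA))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_msa(m, f)
  m2 <- read_msa(f)
  expect_equal(m2$mat, m$mat)
  expect_equal(m2$species, m$species)
})

test_that("gap-run filtering removes rows beyond the ceiling threshold", {
  L <- 100
  mk_row <- function(run) paste(c(rep("A", L - run), rep("-", run)), collapse = "")
  m <- msa_fixture(c(mk_row(0), mk_row(20), mk_row(25), mk_row(49), mk_row(51)))
  f20 <- filter_max_gap_run(m, 0.20)
  # run of 20 = ceiling(0.2 * 100) is retained (strictly-greater removes)
  expect_equal(f20$ids, c("s1", "s2"))
  f50 <- filter_max_gap_run(m, 0.50)
  expect_equal(f50$ids, c("s1", "s2", "s3", "s4"))
})

test_that("gap-run filtering is idempotent and monotone in the threshold", {
  set.seed(1)
  rows <- replicate(40, paste(sample(c("A", "C", "-"), 60, TRUE, prob = c(.4, .3, .3)),
                              collapse = ""))
  m <- msa_fixture(rows)
  for (f in c(0.1, 0.3, 0.6)) {
    once <- filter_max_gap_run(m, f)
    expect_identical(filter_max_gap_run(once, f)$ids, once$ids)
  }
  fs <- c(0.1, 0.2, 0.4, 0.7)
  surv <- lapply(fs, function(f) filter_max_gap_run(m, f)$ids)
  for (t in seq_len(length(fs) - 1))
    expect_true(all(surv[[t]] %in% surv[[t + 1]]))
})

test_that("paralog matching handles trivial and missing species", {
  a <- msa_fixture(c("AAAA", "CCCC"), species = c("sp1", "sp2"))
  b <- msa_fixture(c("GGGG", "KKKK"), species = c("sp1", "sp3"))
  p <- paralog_match_concatenate(a, b)
  expect_equal(nrow(p$mat), 1)            # only sp1 is shared
  expect_equal(paste(p$mat[1, ], collapse = ""), "AAAAGGGG")
  expect_equal(p$boundary, 4)

  c_ <- msa_fixture("AAAA", species = "spX")
  expect_error(paralog_match_concatenate(a, c_), "no species")
})

test_that("a stated 2x2 similarity matrix reproduces the enumerated optimum", {
  a <- msa_fixture(c("AAAA", "AAAC", "CCCC"), species = c("sp1", "sp1", "sp2"))
  b <- msa_fixture(c("GGGG", "GGGK", "KKKK"), species = c("sp1", "sp1", "sp2"))
  S <- matrix(c(0.9, 0.2,
                0.1, 0.8), 2, 2, byrow = TRUE)
  # enumerate both pairings: (1,1)+(2,2)=1.7 beats (1,2)+(2,1)=0.3
  p <- paralog_match_concatenate(a, b, similarity = function(...) S)
  rows <- p$parent_rows[p$parent_rows$species == "sp1", ]
  expect_equal(rows$row_a, c(1, 2))
  expect_equal(rows$row_b, c(1, 2))

  S2 <- matrix(c(0.2, 0.9,
                 0.8, 0.1), 2, 2, byrow = TRUE)
  p2 <- paralog_match_concatenate(a, b, similarity = function(...) S2)
  rows2 <- p2$parent_rows[p2$parent_rows$species == "sp1", ]
  expect_equal(rows2[order(rows2$row_a), ]$row_b, c(2, 1))
})

test_that("assignment solver: exact enumeration agrees with greedy on easy cases", {
  set.seed(4)
  for (r in 1:5) {
    S <- matrix(runif(9), 3, 3)
    asg <- max_similarity_assignment(S)
    # brute force over all 6 permutations
    best <- -Inf
    for (p in coevodock:::all_permutations(3))
      best <- max(best, sum(S[cbind(1:3, p)]))
    expect_equal(sum(S[asg]), best)
  }
})

test_that("concatenated row count is the sum of per-species minima", {
  set.seed(2)
  pm <- planted_model(10, 10, 21, field_bias = 4, seed = 21)
  sim <- sample_potts_msa(pm, 12, n_paralogs = c(1, 2, 3), seed = 21)
  # drop some B rows to make copy counts asymmetric
  keep <- sort(sample(nrow(sim$msa_b$mat), nrow(sim$msa_b$mat) - 4))
  b <- new_msa(sim$msa_b$mat[keep, , drop = FALSE], sim$msa_b$ids[keep],
               sim$msa_b$species[keep])
  p <- paralog_match_concatenate(sim$msa_a, b)
  expected <- sum(pmin(table(sim$msa_a$species)[sort(unique(b$species))],
                       table(b$species)))
  expect_equal(nrow(p$mat), unname(expected))
})

test_that("ground-truth paralog pairings are recovered on a conserved family", {
  pm <- planted_model(30, 30, 21, field_bias = 4, seed = 31)
  sim <- sample_potts_msa(pm, 50, n_paralogs = 2, seed = 31)
  p <- paralog_match_concatenate(sim$msa_a, sim$msa_b)
  truth <- paste(sim$pairing$row_a, sim$pairing$row_b)
  got <- paste(p$parent_rows$row_a, p$parent_rows$row_b)
  expect_gte(mean(truth %in% got), 0.95)
})

test_that("species co-occurrence counts the complete-set core", {
  expect_equal(species_cooccurrence(list(A = c("s1", "s2"), B = "s1"))$complete_count, 1)
  same <- list(A = c("x", "y", "z"), B = c("x", "y", "z"))
  expect_equal(species_cooccurrence(same)$complete_count, 3)

  # 9 families over 600 species with a planted 461-species common core
  set.seed(7)
  core <- sprintf("core%03d", 1:461)
  extras <- sprintf("extra%03d", 1:139)
  fams <- lapply(1:9, function(k) core)
  for (e in extras) {
    in_fams <- sample(9, sample(0:8, 1))
    for (k in in_fams) fams[[k]] <- c(fams[[k]], e)
  }
  names(fams) <- paste0("fam", 1:9)
  cc <- species_cooccurrence(fams)
  expect_equal(cc$complete_count, 461)
  expect_equal(dim(cc$matrix), c(length(unique(unlist(fams))), 9L))
})
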