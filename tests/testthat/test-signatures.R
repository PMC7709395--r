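test_that("tetranucleotide z-scores match direct enumeration", {
  set.seed(31)
  for (i in 1:3) {
    s <- random_dna_str(2000, gc = 0.45)
    z <- tetra_signature(s)$zscores
    zo <- tetra_oracle(s)
    expect_equal(unname(z[names(zo)]), unname(zo), tolerance = 1e-9)
  }
})

test_that("tetra signature is strand-symmetric and self-correlates at 1", {
  set.seed(32)
  s <- random_dna_str(5000)
  sig <- tetra_signature(s)
  expect_identical(length(sig$zscores), 256L)
  expect_equal(tetra_signature(revcomp(s))$zscores, sig$zscores)
  expect_equal(tetra_correlation(sig, sig), 1)
  expect_error(tetra_signature("ACG"), "shorter")
  # a degenerate all-zero signature (every tetramer at its Markov
  # expectation) cannot be correlated
  flat <- structure(list(zscores = setNames(rep(0, 256), names(sig$zscores)),
                         n_effective = 0), class = "tetra_signature")
  expect_error(tetra_correlation(flat, sig), "zero-variance")
})

test_that("conserved pairs correlate far above unrelated genomes", {
  set.seed(33)
  a <- random_dna_str(50000, gc = 0.41)
  near <- mutate_genome(a, 0.005)
  other <- random_dna_str(50000, gc = 0.41)
  c_near <- tetra_correlation(tetra_signature(a), tetra_signature(near))
  c_far <- tetra_correlation(tetra_signature(a), tetra_signature(other))
  expect_gt(c_near, 0.95)
  expect_lt(c_far, c_near - 0.5)
})

test_that("ANI is exact on self and tracks planted mutation rates", {
  set.seed(34)
  g <- random_dna_str(60000, gc = 0.41)
  self <- ani(g, g)
  expect_equal(self$ani, 1)
  expect_identical(self$n_reciprocal_pairs, self$n_fragments_a)
  prev <- 1
  for (r in c(0.002, 0.01, 0.05)) {
    res <- ani(g, mutate_genome(g, r))
    n_comp <- res$n_reciprocal_pairs * 1020
    expect_lt(abs(res$ani - (1 - r)), 4 * sqrt(r * (1 - r) / n_comp) + 1e-4)
    expect_lt(res$ani, prev)
    prev <- res$ani
  }
})

test_that("ANI is symmetric by construction", {
  set.seed(35)
  a <- random_dna_str(30000)
  b <- mutate_genome(a, 0.01)
  expect_equal(ani(a, b)$ani, ani(b, a)$ani, tolerance = 1e-12)
  expect_error(ani(a, "ACGT"), "fragment")
})
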