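test_that("reversal distance handles canonical small cases", {
  expect_identical(reversal_distance(1:5), 0L)
  expect_identical(reversal_distance(c(1L, -2L, 3L)), 1L)
  expect_gt(reversal_distance(c(2L, 1L)), 0L)
  expect_error(reversal_distance(c(1L, 1L)), "permutation")
  expect_error(reversal_distance(c(1L, 3L)), "permutation")
})

test_that("distance matches the BFS oracle exhaustively for small n", {
  for (n in 2:4) {
    oracle <- bfs_reversal_distances(n)
    for (p in all_signed_perms(n)) {
      expect_identical(reversal_distance(p),
                       get(perm_key(p), envir = oracle))
    }
  }
})

test_that("circular distance matches a circular BFS oracle", {
  for (n in 2:5) {
    oracle <- bfs_circular_distances(n)
    for (k in ls(oracle)) {
      p <- as.integer(strsplit(k, ",")[[1]])
      expect_identical(reversal_distance(p, topology = "circular"),
                       get(k, envir = oracle))
    }
  }
  # all rotations/reflections of the identity are at distance zero
  expect_identical(reversal_distance(c(3L, 4L, 5L, 1L, 2L), "circular"), 0L)
  expect_identical(reversal_distance(-c(3L, 2L, 1L), "circular"), 0L)
  expect_identical(reversal_distance(c(1L, -2L, 3L), "circular"), 1L)
})

test_that("scenarios are valid sorting sequences of length = distance", {
  expect_identical(reversal_scenario(1:4)$distance, 0L)
  sc <- reversal_scenario(c(1L, -2L, 3L))
  expect_identical(unname(sc$reversals[1, ]), c(2L, 2L))
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    p <- random_signed_perm(n)
    d <- reversal_distance(p)
    sc <- reversal_scenario(p)
    expect_identical(sc$distance, d)
    expect_identical(nrow(sc$reversals), d)
    q <- p
    for (r in seq_len(nrow(sc$reversals))) {
      ij <- sc$reversals[r, ]
      q[ij[1]:ij[2]] <- -rev(q[ij[1]:ij[2]])
    }
    expect_identical(q, seq_len(n))
  }
})

test_that("distance is invariant under inversion of the permutation", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:7, 1)
    p <- random_signed_perm(n)
    inv <- integer(n)
    inv[abs(p)] <- sign(p) * seq_len(n)
    expect_identical(reversal_distance(p), reversal_distance(inv))
    expect_lte(reversal_distance(p), n + 1L)
  }
})

test_that("Mauve backbone files parse into ordered block maps", {
  tf <- tempfile()
  writeLines(c("seq0_leftend\tseq0_rightend\tseq1_leftend\tseq1_rightend",
               "5001\t9000\t-15001\t-19000",
               "1\t5000\t1\t5000",
               "9001\t12000\t5001\t8000",
               "12001\t12500\t0\t0"), tf)
  bm <- read_mauve_blocks(tf)
  expect_identical(nrow(bm$blocks), 3L)
  expect_equal(bm$blocks$start_a, c(1, 5001, 9001))
  expect_identical(bm$blocks$strand_b, c("+", "-", "+"))
  expect_identical(to_signed_permutation(bm), c(1L, 3L, -2L))
  unlink(tf)

  bad <- tempfile()
  writeLines(c("seq0_leftend\tseq0_rightend\tseq1_leftend\tseq1_rightend",
               "1\tfive\t1\t5000"), bad)
  expect_error(read_mauve_blocks(bad), "malformed|invalid")
  unlink(bad)

  three <- tempfile()
  writeLines(paste(c("seq0_leftend", "seq0_rightend", "seq1_leftend",
                     "seq1_rightend", "seq2_leftend", "seq2_rightend"),
                   collapse = "\t"), three)
  writeLines(c(readLines(three), "1\t10\t1\t10\t1\t10"), three)
  expect_error(read_mauve_blocks(three), "more than 2")
  unlink(three)
})

test_that("find_blocks recovers identity and rejects unrelated sequence", {
  set.seed(43)
  a <- random_dna_str(30000)
  bm <- find_blocks(a, a, min_block = 5000)
  expect_identical(nrow(bm$blocks), 1L)
  expect_identical(to_signed_permutation(bm), 1L)
  b <- random_dna_str(30000)
  expect_warning(bm2 <- find_blocks(a, b), "anchors|block")
  expect_identical(nrow(bm2$blocks), 0L)
})

test_that("planted inversions are recovered as blocks and exact distance", {
  sim <- simulate_trio(trio_config(seed = 6))
  g <- sim$genomes
  bm <- find_blocks(g$MBR1, g$CSTR1)
  perm <- to_signed_permutation(bm)
  planted <- sim$truth$planted$n_inversions_between[["MBR1_CSTR1"]]
  expect_identical(reversal_distance(perm, "circular"), as.integer(planted))
  expect_identical(sum(bm$blocks$strand_b == "-"), as.integer(planted))
  # breakpoints localize near the planted intervals (genome A = MBR1
  # carries its own two inversions at the ancestral coordinates)
  ivs <- sim$truth$planted$inversions$MBR1
  for (iv in ivs) {
    expect_true(any(abs(bm$blocks$start_a - iv[1]) < 100) ||
                  any(abs(bm$blocks$end_a - iv[1]) < 100))
  }
  fl <- flank_transposases(bm, g$MBR1, g$CSTR1)
  expect_equal(fl$fraction_flanked, 1)
})

test_that("transposase flank report is empty-safe and honors flank_bp", {
  sim <- simulate_trio(trio_config(seed = 6))
  g <- sim$genomes
  bm <- find_blocks(g$MBR1, g$CSTR1)
  noTn <- g$MBR1
  noTn$features <- noTn$features[!grepl("transposase", noTn$features$product), ]
  fl <- flank_transposases(bm, noTn)
  expect_equal(fl$fraction_flanked, 0)
  fl0 <- flank_transposases(bm, g$MBR1, g$CSTR1, flank_bp = 0)
  expect_lte(fl0$fraction_flanked, 1)
})
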