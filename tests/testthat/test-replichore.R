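test_that("cumulative GC skew behaves on constructed sequences", {
  g <- annotated_genome("allg", strrep("G", 1000), "linear")
  p <- gc_skew_profile(g, window = 100, step = 50)
  expect_true(all(diff(p$cumulative) == 1L))
  expect_identical(p$cumulative[1001], 1000L)
  gc <- annotated_genome("gc", strrep("GC", 500), "linear")
  p2 <- gc_skew_profile(gc, window = 100, step = 50)
  expect_true(all(p2$cumulative %in% c(0L, 1L)))
  expect_identical(p2$cumulative[1001], 0L)
  expect_error(gc_skew_profile(g, window = 2000), "window")
})

test_that("skew minimum localizes the planted origin in simulated genomes", {
  sim <- simulate_trio(trio_config(seed = 3))
  for (g in sim$genomes) {
    p <- gc_skew_profile(g)
    expect_lt(min(p$min_pos, genome_length(g) - p$min_pos),
              sim$truth$planted$ori_pos + p$window)
  }
})

test_that("find_ori prefers the dnaA flanked by dnaN and gyrB", {
  set.seed(21)
  mk <- function(start, len, tag, product) {
    data.frame(locus_tag = tag, type = "CDS", start = start,
               end = start + len - 1L, strand = "+", product = product)
  }
  # cumulative-skew minimum near position 1: G-rich first half
  half1 <- chartr("C", "G", random_dna_str(5000))
  half2 <- chartr("G", "C", random_dna_str(5000))
  seq <- paste0(half1, half2)
  ft <- rbind(
    mk(101, 300, "d1", "chromosomal replication initiator protein DnaA"),
    mk(501, 300, "n1", "DNA polymerase III subunit beta (dnaN)"),
    mk(901, 300, "g1", "DNA gyrase subunit B (gyrB)"),
    mk(3001, 300, "d2", "chromosomal replication initiator protein DnaA"),
    mk(6001, 300, "d3", "chromosomal replication initiator protein DnaA"),
    mk(8001, 300, "x1", "hypothetical protein"))
  g <- annotated_genome("threednaa", seq, "circular", ft)
  oc <- find_ori(g)
  expect_identical(oc$chosen_dnaA, "d1")
  expect_identical(oc$confidence, "high")
  expect_identical(length(oc$dnaA_candidates), 3L)
  # no dnaA at all
  g2 <- g
  g2$features$product <- "hypothetical protein"
  expect_error(find_ori(g2), "no dnaA candidate")
})

test_that("reorient restores a rotated, reverse-complemented genome", {
  sim <- simulate_trio(trio_config(seed = 4))
  g <- sim$genomes$CSTR1
  canonical <- reorient(g) # dnaA starts at position 1
  scrambled <- rotate_genome(revcomp_genome(g), 40321)
  restored <- reorient(scrambled)
  expect_identical(restored$sequence, canonical$sequence)
  # idempotent
  again <- reorient(restored)
  expect_identical(again$sequence, restored$sequence)
  expect_identical(reorient(canonical)$sequence, canonical$sequence)
  expect_error(reorient(annotated_genome("l", "ACGTACGT", "linear")),
               "linear")
})

test_that("reorientation preserves length, GC and tetra signature", {
  sim <- simulate_trio(trio_config(seed = 5))
  g <- sim$genomes$KUST
  scrambled <- rotate_genome(revcomp_genome(g), 12345)
  expect_identical(genome_length(scrambled), genome_length(g))
  gc_of <- function(x) {
    b <- strsplit(x$sequence, "")[[1]]
    mean(b %in% c("G", "C"))
  }
  expect_equal(gc_of(scrambled), gc_of(g))
  # rotation moves which tetramers straddle the origin seam, an O(1/L)
  # edge effect on the counts
  expect_gt(tetra_correlation(tetra_signature(scrambled), tetra_signature(g)),
            0.9999)
})
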