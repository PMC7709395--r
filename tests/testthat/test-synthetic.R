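test_that("simulation is deterministic under the seed", {
  s1 <- simulate_trio(trio_config(seed = 9))
  s2 <- simulate_trio(trio_config(seed = 9))
  for (g in names(s1$genomes)) {
    expect_identical(s1$genomes[[g]]$sequence, s2$genomes[[g]]$sequence)
    expect_identical(s1$genomes[[g]]$features, s2$genomes[[g]]$features)
  }
  s3 <- simulate_trio(trio_config(seed = 10))
  expect_false(identical(s1$genomes[[1]]$sequence, s3$genomes[[1]]$sequence))
})

test_that("the truth log replays byte-for-byte and survives a round trip", {
  sim <- simulate_trio(trio_config(seed = 9))
  seqs <- replay_truth(sim$truth)
  for (g in names(sim$genomes)) {
    expect_identical(seqs[[g]], sim$genomes[[g]]$sequence)
  }
  tf <- tempfile(fileext = ".json")
  write_truth(sim$truth, tf)
  back <- read_truth(tf)
  expect_identical(back$strain_md5, sim$truth$strain_md5)
  expect_identical(length(back$events), length(sim$truth$events))
  seqs2 <- replay_truth(back)
  expect_identical(seqs2$CSTR1, sim$genomes$CSTR1$sequence)
  # a hand-edited log is refused
  txt <- readLines(tf)
  txt <- sub("\"pos\":([0-9]+)", "\"pos\":1", txt)
  tf2 <- tempfile(fileext = ".json")
  writeLines(txt, tf2)
  expect_error(read_truth(tf2), "checksum")
  unlink(c(tf, tf2))
})

test_that("zero-substitution branches leave marker genes identical", {
  cfg <- trio_config(seed = 11,
                     branch_subs = c(KUST = 0, MBR1 = 0, CSTR1 = 0),
                     aa_changes = c(KUST = 0, MBR1 = 0, CSTR1 = 0),
                     bg_subs = c(KUST = 0, MBR1 = 0, CSTR1 = 0))
  sim <- simulate_trio(cfg)
  ms <- extract_markers(sim$genomes, sim$refs$marker_aa)
  counts <- count_apomorphies(align_and_concat(ms), "nt")$counts
  expect_identical(unname(counts), c(0L, 0L, 0L))
})

test_that("planted substitutions avoid repeats and the CRISPR locus", {
  sim <- simulate_trio(trio_config(seed = 12))
  protected <- sim$truth$planted$protected # ancestor frame, like the events
  for (s in names(sim$truth$events)) {
    subs <- Filter(function(e) e$op == "substitute", sim$truth$events[[s]])
    pos <- vapply(subs, function(e) e$pos, numeric(1))
    inside <- vapply(seq_len(nrow(protected)), function(i)
      any(pos >= protected$start[i] & pos <= protected$end[i]), logical(1))
    expect_false(any(inside))
  }
})

test_that("mutate_genome hits close to the requested rate", {
  set.seed(13)
  s <- random_dna_str(50000)
  m <- mutate_genome(s, 0.01)
  diff_frac <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(diff_frac, 0.01, tolerance = 0.25)
  expect_identical(mutate_genome(s, 0), s)
})

test_that("genome editing primitives keep features consistent", {
  ft <- data.frame(locus_tag = c("x", "y"), type = "CDS",
                   start = c(11L, 61L), end = c(40L, 90L),
                   strand = "+", product = "")
  g <- annotated_genome("e", random_dna_str(100), "linear", ft)
  gi <- straintrio:::edit_insert(g, 50L, "AAAA")
  expect_identical(gi$features$start, c(11L, 65L))
  expect_identical(genome_length(gi), 104L)
  gd <- straintrio:::edit_delete(g, 50L, 5L)
  expect_identical(gd$features$end, c(40L, 85L))
  gv <- straintrio:::edit_invert(g, 5L, 95L)
  expect_identical(gv$features$strand, c("-", "-"))
  expect_identical(gv$features$start[2], 5L + (95L - 90L))
  expect_error(straintrio:::edit_invert(g, 20L, 70L), "straddles")
})
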