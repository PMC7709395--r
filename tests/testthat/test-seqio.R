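test_that("revcomp follows the complement table and is an involution", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAGN"), "NCTT")
  expect_error(revcomp("ACGX"), "illegal character")
  set.seed(11)
  for (i in 1:5) {
    s <- random_dna_str(1000)
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("six-frame translation covers all frames and drops partial codons", {
  fr <- six_frame_translate("ATGGCATAA")
  expect_identical(unname(fr["F1"]), "MA*")
  expect_error(six_frame_translate("AT"), "too short")
  set.seed(12)
  s <- random_dna_str(300)
  fr_s <- six_frame_translate(s)
  fr_rc <- six_frame_translate(revcomp(s))
  expect_identical(unname(fr_rc[c("F1", "F2", "F3")]),
                   unname(fr_s[c("R1", "R2", "R3")]))
})

test_that("rotation moves the start, remaps features, and inverts cleanly", {
  ft <- data.frame(locus_tag = c("a", "b"), type = "CDS",
                   start = c(2L, 8L), end = c(4L, 10L),
                   strand = c("+", "-"), product = "")
  g <- annotated_genome("toy", "ACGTACGTAC", "circular", ft)
  expect_identical(rotate_genome(g, 1), g)
  r <- rotate_genome(g, 4)
  expect_identical(r$sequence, paste0(substring("ACGTACGTAC", 4, 10),
                                      substring("ACGTACGTAC", 1, 3)))
  # feature a (2..4) wraps the new junction and is split
  a_parts <- r$features[r$features$locus_tag == "a", ]
  expect_identical(nrow(a_parts), 2L)
  back <- rotate_genome(r, genome_length(g) - 4 + 2)
  expect_identical(back$sequence, g$sequence)
  lin <- annotated_genome("lin", "ACGT", "linear")
  expect_error(rotate_genome(lin, 2), "linear")
})

test_that("GenBank and GFF3 round trips preserve sequence and features", {
  set.seed(13)
  ft <- data.frame(locus_tag = c("g1", "g2", "g3"),
                   type = c("CDS", "CDS", "rRNA"),
                   start = c(11L, 101L, 301L), end = c(70L, 220L, 400L),
                   strand = c("+", "-", "+"),
                   product = c("widget synthase", "hypothetical protein", "16S"))
  g <- annotated_genome("toy3", random_dna_str(500), "circular", ft)
  for (fmt in c("genbank", "gff3")) {
    tf <- tempfile()
    write_genome(g, tf, fmt)
    g2 <- read_genome(tf, fmt)
    expect_identical(g2$sequence, g$sequence)
    expect_identical(g2$features[, c("locus_tag", "type", "start", "end", "strand")],
                     g$features[, c("locus_tag", "type", "start", "end", "strand")])
    unlink(tf)
  }
  tf <- tempfile()
  write_genome(g, tf, "fasta")
  g3 <- read_genome(tf, "fasta")
  expect_identical(g3$sequence, g$sequence)
  unlink(tf)
})

test_that("junction-spanning features survive a GenBank round trip", {
  set.seed(14)
  ft <- data.frame(locus_tag = "wrap", type = "CDS",
                   start = 91L, end = 100L, strand = "+", product = "p")
  g <- annotated_genome("w", random_dna_str(100), "circular", ft)
  r <- rotate_genome(g, 96) # feature now spans the junction
  expect_identical(sum(r$features$locus_tag == "wrap"), 2L)
  tf <- tempfile()
  write_genome(r, tf, "genbank")
  r2 <- read_genome(tf, "genbank")
  expect_identical(r2$features[, c("locus_tag", "start", "end", "part")],
                   r$features[, c("locus_tag", "start", "end", "part")])
  unlink(tf)
})

test_that("ambiguity codes are normalized to N with a warning", {
  expect_warning(g <- annotated_genome("amb", "ACGTRYACGT", "linear"),
                 "normalized to N")
  expect_identical(g$sequence, "ACGTNNACGT")
  expect_error(annotated_genome("bad", "ACGT!!", "linear"), "illegal")
})
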