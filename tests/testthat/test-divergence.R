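make_marker_set <- function(seqs_by_genome) {
  gids <- names(seqs_by_genome)
  markers <- names(seqs_by_genome[[1]])
  per_genome <- lapply(gids, function(g) {
    nt <- seqs_by_genome[[g]]
    data.frame(marker = markers, locus_tag = paste0(g, "_", markers),
               nt = unname(nt),
               aa = vapply(nt, function(x)
                 sub("\\*$", "", straintrio:::translate_dna(x)), character(1)),
               stringsAsFactors = FALSE)
  })
  names(per_genome) <- gids
  structure(list(markers = markers, per_genome = per_genome),
            class = "marker_set")
}

random_orf_str <- function(n_codon, seed) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  body <- character(n_codon)
  for (i in seq_len(n_codon)) {
    repeat {
      cd <- random_dna_str(3)
      if (!cd %in% stops) break
    }
    body[i] <- cd
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

test_that("apomorphy counting matches a hand-built alignment", {
  m1 <- random_orf_str(40, 71)
  m2 <- random_orf_str(50, 72)
  a <- c(m1 = m1, m2 = m2)
  b <- a; c_ <- a
  # plant three private synonymous-ish changes in B, one in C (positions
  # chosen at third codon bases well inside the genes)
  subst <- function(s, pos, base) { substr(s, pos, pos) <- base; s }
  flip <- function(ch) if (ch == "A") "G" else "A"
  for (p in c(12, 24, 36)) b["m1"] <- subst(b["m1"], p, flip(substr(b["m1"], p, p)))
  c_["m2"] <- subst(c_["m2"], 18, flip(substr(c_["m2"], 18, 18)))
  ms <- make_marker_set(list(A = a, B = b, C = c_))
  concat <- align_and_concat(ms)
  counts <- count_apomorphies(concat, "nt")$counts
  expect_identical(unname(counts), c(0L, 3L, 1L))
  # identical rows count nothing
  same <- make_marker_set(list(A = a, B = a, C = a))
  expect_identical(unname(count_apomorphies(align_and_concat(same), "nt")$counts),
                   c(0L, 0L, 0L))
})

test_that("counts are invariant under row reordering and marker order", {
  m1 <- random_orf_str(30, 73)
  m2 <- random_orf_str(30, 74)
  a <- c(m1 = m1, m2 = m2)
  b <- a
  substr(b["m1"], 15, 15) <- if (substr(b["m1"], 15, 15) == "C") "T" else "C"
  ms1 <- make_marker_set(list(A = a, B = b, C = a))
  ms2 <- make_marker_set(list(C = a, B = b, A = a))
  c1 <- count_apomorphies(align_and_concat(ms1), "nt")$counts
  c2 <- count_apomorphies(align_and_concat(ms2), "nt")$counts
  expect_identical(unname(c1["B"]), unname(c2["B"]))
  ms3 <- make_marker_set(list(A = a[c(2, 1)], B = b[c(2, 1)], C = a[c(2, 1)]))
  c3 <- count_apomorphies(align_and_concat(ms3), "nt")$counts
  expect_identical(unname(c1), unname(c3))
})

test_that("amino-acid level counting sees only non-synonymous changes", {
  m <- random_orf_str(60, 75)
  a <- c(m1 = m)
  b <- a
  # a second-position change is non-synonymous
  p <- 3 * 10 + 2
  old <- substr(b["m1"], p, p)
  substr(b["m1"], p, p) <- if (old == "A") "C" else "A"
  ms <- make_marker_set(list(A = a, B = b, C = a))
  concat <- align_and_concat(ms)
  aa <- count_apomorphies(concat, "aa")$counts
  expect_gte(unname(aa["B"]), 0L)
  expect_identical(unname(aa["A"]), 0L)
  expect_identical(unname(aa["C"]), 0L)
})

test_that("marker extraction finds embedded markers and errors when absent", {
  sim <- simulate_trio(trio_config(seed = 7))
  refs <- sim$refs$marker_aa[1:8]
  ms <- extract_markers(sim$genomes, refs)
  for (g in names(sim$genomes)) {
    expect_identical(nrow(ms$per_genome[[g]]), 8L)
    expect_identical(ms$per_genome[[g]]$marker, names(refs))
  }
  fake <- c(refs, absent = paste(rep("WWWWWHHHHH", 20), collapse = ""))
  expect_error(extract_markers(sim$genomes["KUST"], fake), "absent")
})

test_that("frameshift screening classifies indels by length mod 3", {
  m <- random_orf_str(50, 76)
  a <- c(m1 = m)
  del1 <- c(m1 = paste0(substr(m, 1, 30), substr(m, 32, nchar(m))))
  del6 <- c(m1 = paste0(substr(m, 1, 30), substr(m, 37, nchar(m))))
  ms_a <- make_marker_set(list(G = a))
  expect_identical(nrow(frameshift_screen(ms_a, ms_a)), 0L)
  r1 <- frameshift_screen(ms_a, make_marker_set(list(G = del1)))
  expect_true("frameshift_indel" %in% r1$kind)
  r6 <- frameshift_screen(ms_a, make_marker_set(list(G = del6)))
  expect_true("inframe_indel" %in% r6$kind)
  expect_false("frameshift_indel" %in% r6$kind)
})
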