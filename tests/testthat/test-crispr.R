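# toy array machinery: a repeat, a leader and synthetic spacers embedded
# in a random genome
REP <- straintrio:::CRISPR_REPEAT_DEFAULT
LEAD <- straintrio:::CRISPR_LEADER_DEFAULT

build_array_genome <- function(spacers, id = "g", strand = "+",
                               lead = LEAD, pad = 3000) {
  set.seed(sum(utf8ToInt(id)))
  arr <- paste0(lead, paste0(REP, spacers, collapse = ""), REP)
  if (strand == "-") arr <- revcomp(arr)
  annotated_genome(id, paste0(random_dna_str(pad), arr, random_dna_str(pad)),
                   "linear")
}

rand_spacers <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) random_dna_str(35), character(1))
}

test_that("repeat-guided extraction recovers planted spacers verbatim", {
  sp <- rand_spacers(10, 51)
  g <- build_array_genome(sp)
  arrs <- find_array(g, REP)
  expect_identical(length(arrs), 1L)
  expect_identical(arrs[[1]]$spacers, sp)
  # minus strand: spacers read off the matched strand
  gm <- build_array_genome(sp, id = "m", strand = "-")
  am <- find_array(gm, REP)
  expect_identical(length(am), 1L)
  expect_identical(am[[1]]$strand, "-")
  expect_identical(am[[1]]$spacers, sp)
  # genome without the repeat
  expect_identical(find_array(annotated_genome("none", random_dna_str(5000),
                                               "linear"), REP),
                   list())
})

test_that("leader matching orients arrays; flipped input converges", {
  sp <- rand_spacers(8, 52)
  g <- build_array_genome(sp)
  a <- find_array(g, REP)[[1]]
  a1 <- orient_by_leader(a, LEAD)
  expect_true(a1$oriented)
  expect_identical(a1$spacers[1], sp[1])
  flipped <- straintrio:::flip_array(a)
  a2 <- orient_by_leader(flipped, LEAD)
  expect_true(a2$oriented)
  expect_identical(a2$spacers, a1$spacers)
  a3 <- orient_by_leader(a, NULL)
  expect_false(a3$oriented)
})

test_that("context orientation puts shared spacers at the trailer", {
  shared <- rand_spacers(6, 53)
  u1 <- rand_spacers(4, 54)
  u2 <- rand_spacers(5, 55)
  g1 <- build_array_genome(c(u1, shared), id = "c1")
  g2 <- build_array_genome(c(u2, shared), id = "c2")
  a1 <- find_array(g1, REP)[[1]]
  a2 <- find_array(g2, REP)[[1]]
  # feed one array flipped; context must restore it
  arrs <- orient_by_context(list(straintrio:::flip_array(a1), a2))
  expect_true(arrs[[1]]$oriented)
  expect_identical(arrs[[1]]$spacers, c(u1, shared))
})

test_that("spacer clustering is exact by default and fuzzy on request", {
  sp <- rand_spacers(5, 56)
  g1 <- build_array_genome(c(sp, rand_spacers(2, 57)), id = "k1")
  g2 <- build_array_genome(c(sp, rand_spacers(3, 58)), id = "k2")
  a <- lapply(list(g1, g2), function(g) find_array(g, REP)[[1]])
  cl <- cluster_spacers(a)
  expect_identical(length(intersect(cl$ids[[1]], cl$ids[[2]])), 5L)
  # one-mismatch variants merge below identity 1
  v <- sp[1]
  substr(v, 3, 3) <- if (substr(v, 3, 3) == "A") "C" else "A"
  g3 <- build_array_genome(c(v, rand_spacers(2, 59)), id = "k3")
  a3 <- find_array(g3, REP)[[1]]
  cl_strict <- cluster_spacers(list(a[[1]], a3))
  expect_identical(length(intersect(cl_strict$ids[[1]], cl_strict$ids[[2]])), 0L)
  cl_fuzzy <- cluster_spacers(list(a[[1]], a3), identity = 0.9)
  expect_identical(length(intersect(cl_fuzzy$ids[[1]], cl_fuzzy$ids[[2]])), 1L)
  expect_identical(cluster_spacers(list())$clusters, character(0))
})

test_that("array alignment and classification respect presence patterns", {
  sp <- rand_spacers(10, 60)
  ids <- setNames(list(1:10, 1:10, 1:10), c("A", "B", "C"))
  aln <- align_arrays(ids)
  expect_identical(ncol(aln$columns), 10L)
  cls <- classify_spacers(aln)
  expect_identical(unname(cls$counts["shared_all"]), 10L)
  expect_identical(sum(cls$counts), cls$n_columns)
  # one internal deletion leaves a single gap column at the right place
  ids2 <- setNames(list(1:10, c(1:4, 6:10)), c("full", "del"))
  aln2 <- align_arrays(ids2)
  expect_identical(ncol(aln2$columns), 10L)
  gapcol <- which(is.na(aln2$columns["del", ]))
  expect_identical(gapcol, 5L)
  # per-genome non-gap columns equal spacer counts
  expect_identical(sum(!is.na(aln2$columns["del", ])), 9L)
})

test_that("three-genome classification and lineage call match construction", {
  shared_all <- 1:6
  pair_bc <- 7:9
  ua <- 10:12; ub <- 13:16; uc <- 17:21
  ids <- setNames(list(c(ua, shared_all),
                       c(ub, pair_bc, shared_all),
                       c(uc, pair_bc, shared_all)),
                  c("A", "B", "C"))
  aln <- align_arrays(ids)
  cls <- classify_spacers(aln)
  expect_identical(unname(cls$counts["shared_all"]), 6L)
  expect_identical(unname(cls$counts["shared_B_C"]), 3L)
  expect_identical(unname(cls$counts["unique_A"]), 3L)
  expect_identical(unname(cls$counts["unique_B"]), 4L)
  expect_identical(unname(cls$counts["unique_C"]), 5L)
  ord <- infer_order(aln)
  expect_identical(ord$earliest_diverged, "A")
  expect_setequal(ord$sister_pair, c("B", "C"))
  # identical arrays stay undetermined
  same <- align_arrays(setNames(list(1:5, 1:5, 1:5), c("A", "B", "C")))
  expect_identical(infer_order(same)$earliest_diverged, "undetermined")
})

test_that("classification is invariant to genome input order", {
  ids <- setNames(list(c(10:12, 1:6), c(13:16, 7:9, 1:6), c(17:21, 7:9, 1:6)),
                  c("A", "B", "C"))
  c1 <- classify_spacers(align_arrays(ids))
  c2 <- classify_spacers(align_arrays(ids[c(3, 1, 2)]))
  expect_identical(unname(c1$counts["unique_C"]), unname(c2$counts["unique_C"]))
  expect_identical(unname(c1$counts["shared_all"]), unname(c2$counts["shared_all"]))
})

test_that("array diffs report losses and gains from the leader end", {
  sp <- rand_spacers(40, 61)
  old <- find_array(build_array_genome(sp, id = "old"), REP)[[1]]
  # lose spacers 31 and 32 counting from the leader
  new <- find_array(build_array_genome(sp[-c(31, 32)], id = "new"), REP)[[1]]
  d <- diff_arrays(old, new)
  expect_identical(d$lost$position, c(31L, 32L))
  expect_identical(nrow(d$gained), 0L)
  # three leader-end acquisitions
  newer <- find_array(build_array_genome(c(rand_spacers(3, 62), sp),
                                         id = "newer"), REP)[[1]]
  d2 <- diff_arrays(old, newer)
  expect_identical(d2$gained$position, c(1L, 2L, 3L))
  expect_identical(nrow(d2$lost), 0L)
  expect_identical(nrow(diff_arrays(old, old)$lost), 0L)
})
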