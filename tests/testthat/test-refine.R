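test_that("the 60-bp overlap rule removes the shorter unknown gene only", {
  # 59-bp overlap: below threshold, both kept
  d1 <- overlap_refine(cds_frame(list("a", 1, 300), list("b", 242, 600)))
  expect_identical(length(d1$removed), 0L)
  # 100-bp overlap, shorter unexpressed and unknown: removed
  d2 <- overlap_refine(cds_frame(list("long", 1, 600), list("short", 501, 800)))
  expect_identical(names(d2$removed), "short")
  expect_identical(unname(d2$removed), "overlap_shorter_unknown_unexpressed")
  expect_setequal(c(d2$kept, names(d2$removed)), c("long", "short"))
  # expressed genes are exempt
  d3 <- overlap_refine(cds_frame(list("long", 1, 600), list("short", 501, 800)),
                       expressed_ids = "short")
  expect_identical(length(d3$removed), 0L)
  expect_identical(unname(d3$exempted["short"]), "in_proteome")
  # predicted function is exempt
  d4 <- overlap_refine(cds_frame(list("long", 1, 600), list("short", 501, 800)),
                       functional_ids = "short")
  expect_identical(unname(d4$exempted["short"]), "function_predicted")
})

test_that("refinement is order-independent and reaches a fixed point", {
  genes <- cds_frame(list("g1", 1, 500), list("g2", 401, 1000),
                     list("g3", 901, 1100), list("g4", 2000, 2500),
                     list("g5", 2441, 2800))
  d <- overlap_refine(genes)
  d_shuffled <- overlap_refine(genes[c(4, 2, 5, 1, 3), ])
  expect_identical(sort(d$kept), sort(d_shuffled$kept))
  # no >= 60 bp overlap remains among kept genes
  kept <- genes[genes$locus_tag %in% d$kept, ]
  kept <- kept[order(kept$start), ]
  if (nrow(kept) > 1) {
    ov <- pmin(head(kept$end, -1), tail(kept$end, -1)) -
      pmax(head(kept$start, -1), tail(kept$start, -1)) + 1
    expect_true(all(ov < 60))
  }
})

test_that("start-codon misprediction rescues a trimmable overlap", {
  set.seed(91)
  # gene b overlaps a by 90 bp, but has an in-frame ATG just downstream
  # of the overlap and stays > 50% of its length after truncation
  seqlen <- 2000
  s <- random_dna_str(seqlen)
  b_start <- 501
  atg_at <- b_start + 120 # in frame with b, past the overlap end at 590
  substr(s, atg_at, atg_at + 2) <- "ATG"
  g <- annotated_genome("r", s, "linear",
                        cds_frame(list("a", 1, 590), list("b", 501, 1400)))
  d <- overlap_refine(g, genome = g)
  expect_identical(length(d$removed), 0L)
  expect_true("a" %in% names(d$exempted) || "b" %in% names(d$exempted))
})

test_that("homolog mapping is complete on self and fails for aliens", {
  sim <- simulate_trio(trio_config(seed = 8))
  g <- sim$genomes$KUST
  # a compact subset keeps the test quick
  g$features <- g$features[g$features$start < 40000 |
                             g$features$type != "CDS", ]
  hm <- homolog_map(g, g)
  expect_equal(hm$fraction_with_homolog, 1)
  expect_true(all(hm$table$identity >= 0.999))
})

test_that("diverged genes drop out of the homolog map at 40% identity", {
  set.seed(92)
  n_genes <- 8
  mk_orf <- function() {
    stops <- c("TAA", "TAG", "TGA")
    body <- vapply(1:80, function(i) {
      repeat { cd <- random_dna_str(3); if (!cd %in% stops) return(cd) }
    }, character(1))
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  orfs <- vapply(seq_len(n_genes), function(i) mk_orf(), character(1))
  spacers <- vapply(seq_len(n_genes + 1), function(i) random_dna_str(200),
                    character(1))
  assemble <- function(genes) {
    seq <- spacers[1]
    rows <- list()
    for (i in seq_along(genes)) {
      rows[[i]] <- data.frame(locus_tag = sprintf("g%02d", i), type = "CDS",
                              start = nchar(seq) + 1L,
                              end = nchar(seq) + nchar(genes[i]),
                              strand = "+", product = "",
                              stringsAsFactors = FALSE)
      seq <- paste0(seq, genes[i], spacers[i + 1])
    }
    annotated_genome("h", seq, "linear", do.call(rbind, rows))
  }
  q <- assemble(orfs)
  # replace genes 3 and 6 with unrelated ORFs in the target
  orfs2 <- orfs
  orfs2[c(3, 6)] <- vapply(1:2, function(i) mk_orf(), character(1))
  t <- assemble(orfs2)
  hm <- homolog_map(q, t)
  no_hit <- hm$table$locus_tag[!hm$table$has_homolog]
  expect_setequal(no_hit, c("g03", "g06"))
})

test_that("six-frame rescue finds an unannotated homolog", {
  set.seed(93)
  stops <- c("TAA", "TAG", "TGA")
  body <- vapply(1:100, function(i) {
    repeat { cd <- random_dna_str(3); if (!cd %in% stops) return(cd) }
  }, character(1))
  orf <- paste0("ATG", paste(body, collapse = ""), "TAA")
  q <- annotated_genome("q", paste0(random_dna_str(100), orf, random_dna_str(100)),
                        "linear",
                        data.frame(locus_tag = "q1", type = "CDS",
                                   start = 101L, end = 100L + nchar(orf),
                                   strand = "+", product = ""))
  # target carries the gene in its sequence but not in its annotation
  t <- annotated_genome("t", paste0(random_dna_str(500), orf, random_dna_str(500)),
                        "linear",
                        data.frame(locus_tag = "other", type = "CDS",
                                   start = 1L, end = 300L, strand = "+",
                                   product = ""))
  hm <- homolog_map(q, t)
  row <- hm$table[hm$table$locus_tag == "q1", ]
  expect_true(row$has_homolog)
  expect_identical(row$via, "sixframe")
})
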