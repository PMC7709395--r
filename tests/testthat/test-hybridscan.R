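random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

mutate_protein <- function(p, frac, seed) {
  set.seed(seed)
  aa <- strsplit(p, "")[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  k <- round(frac * length(aa))
  at <- sample(seq_along(aa), k)
  aa[at] <- vapply(aa[at], function(x) sample(setdiff(alphabet, x), 1),
                   character(1))
  paste(aa, collapse = "")
}

test_that("global identity matches construction", {
  p <- random_protein(300, 81)
  expect_equal(global_identity(p, p, "protein"), 1)
  q <- mutate_protein(p, 0.10, 82)
  expect_equal(global_identity(p, q, "protein"), 0.9, tolerance = 0.02)
  expect_error(global_identity("", p), "empty")
})

test_that("sliding identity is flat on identical rows and tracks chimeras", {
  p <- random_protein(200, 83)
  msa <- rbind(a = strsplit(p, "")[[1]], b = strsplit(p, "")[[1]])
  prof <- sliding_identity(msa, c("a", "b"))
  expect_true(all(prof$identity == 1))
  expect_error(sliding_identity(msa, c("a", "b"), window = 500), "window")
  # windowed mean approximates global identity without gaps
  q <- mutate_protein(p, 0.15, 84)
  msa2 <- rbind(a = strsplit(p, "")[[1]], b = strsplit(q, "")[[1]])
  prof2 <- sliding_identity(msa2, c("a", "b"))
  expect_equal(mean(prof2$identity), 0.85, tolerance = 0.02)
})

test_that("chimera calling finds the planted breakpoint", {
  pa <- random_protein(400, 85)
  pb <- mutate_protein(pa, 0.45, 86)
  for (bp in c(120, 200, 310)) {
    q <- paste0(substr(pa, 1, bp), substr(pb, bp + 1, nchar(pb)))
    call <- call_chimera(q, pa, pb)
    expect_true(call$is_hybrid)
    expect_lte(min(abs(call$breakpoints - bp)), 20)
    # swapping parents swaps labels only
    sw <- call_chimera(q, pb, pa)
    expect_true(sw$is_hybrid)
    expect_identical(length(sw$breakpoints), length(call$breakpoints))
  }
  pure <- call_chimera(pa, pa, pb)
  expect_false(pure$is_hybrid)
  expect_identical(unique(pure$segments$parent), "A")
})
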