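# Independent oracles used by the tests. These deliberately share no code
# with the package internals they check.

perm_key <- function(p) paste(p, collapse = ",")

# breadth-first search over the reversal graph: exact distances from the
# identity to every signed permutation of 1..n
bfs_reversal_distances <- function(n) {
  dist <- new.env(hash = TRUE, size = as.integer(min(2^n * factorial(n) * 2, 2^20)))
  id <- seq_len(n)
  assign(perm_key(id), 0L, envir = dist)
  frontier <- list(id)
  d <- 0L
  while (length(frontier)) {
    nxt <- vector("list", 0L)
    for (p in frontier) {
      for (i in seq_len(n)) {
        for (j in i:n) {
          q <- p
          q[i:j] <- -rev(q[i:j])
          k <- perm_key(q)
          if (!exists(k, envir = dist, inherits = FALSE)) {
            assign(k, d + 1L, envir = dist)
            nxt[[length(nxt) + 1L]] <- q
          }
        }
      }
    }
    d <- d + 1L
    frontier <- nxt
  }
  dist
}

# circular variant: states are canonicalized (rotate, and reflect if
# needed, so the permutation starts with +1); a circular reversal of a
# wrapping arc equals the reversal of the complementary arc, so linear
# reversal moves plus canonicalization cover all circular moves
canon_circular <- function(p) {
  i <- which(abs(p) == 1L)
  if (p[i] < 0L) {
    p <- -rev(p)
    i <- which(abs(p) == 1L)
  }
  if (i > 1L) p <- c(p[i:length(p)], p[seq_len(i - 1L)])
  p
}

bfs_circular_distances <- function(n) {
  dist <- new.env(hash = TRUE)
  id <- seq_len(n)
  assign(perm_key(id), 0L, envir = dist)
  frontier <- list(id)
  d <- 0L
  while (length(frontier)) {
    nxt <- vector("list", 0L)
    for (p in frontier) {
      for (i in seq_len(n)) {
        for (j in i:n) {
          q <- p
          q[i:j] <- -rev(q[i:j])
          q <- canon_circular(q)
          k <- perm_key(q)
          if (!exists(k, envir = dist, inherits = FALSE)) {
            assign(k, d + 1L, envir = dist)
            nxt[[length(nxt) + 1L]] <- q
          }
        }
      }
    }
    d <- d + 1L
    frontier <- nxt
  }
  dist
}

all_signed_perms <- function(n) {
  orderings <- permutations_of(seq_len(n))
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- vector("list", length(orderings) * nrow(signs))
  t <- 0L
  for (p in orderings) {
    for (r in seq_len(nrow(signs))) {
      t <- t + 1L
      out[[t]] <- p * signs[r, ]
    }
  }
  out
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

random_signed_perm <- function(n) {
  sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
}

# direct-enumeration tetranucleotide z-score oracle (substring counting,
# no Biostrings)
revcomp_simple <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

count_words <- function(seqs, k) {
  lv <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[k:1],
              1, paste, collapse = "")
  words <- unlist(lapply(seqs, function(s)
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))))
  tab <- table(factor(words, levels = sort(lv)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

tetra_oracle <- function(seq) {
  seqs <- c(seq, revcomp_simple(seq))
  n2 <- count_words(seqs, 2)
  n3 <- count_words(seqs, 3)
  n4 <- count_words(seqs, 4)
  z <- numeric(length(n4))
  names(z) <- names(n4)
  for (w in names(n4)) {
    abc <- substr(w, 1, 3); bcd <- substr(w, 2, 4); bc <- substr(w, 2, 3)
    if (n2[bc] == 0) next
    e <- n3[abc] * n3[bcd] / n2[bc]
    v <- e * (n2[bc] - n3[abc]) * (n2[bc] - n3[bcd]) / n2[bc]^2
    if (v > 0) z[w] <- (n4[w] - e) / sqrt(v)
  }
  z
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
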