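#' Tetranucleotide z-score signature
#'
#' Computes, over the sequence together with its reverse complement, the
#' z-score of each of the 256 tetranucleotides against a maximal-order
#' Markov expectation: for w = abcd,
#' `E = n(abc) n(bcd) / n(bc)` and
#' `var = E (n(bc) - n(abc)) (n(bc) - n(bcd)) / n(bc)^2`,
#' with `z = (O - E) / sqrt(var)` and `z = 0` wherever the variance
#' vanishes. Words containing N are skipped.
#'
#' @param x an [annotated_genome()] or a plain nucleotide string.
#' @return A `tetra_signature`: `zscores` (length-256 named vector in
#'   lexicographic tetramer order) and `n_effective` (tetramers counted).
#' @export
tetra_signature <- function(x) {
  seq <- if (inherits(x, "annotated_genome")) x$sequence else x
  if (nchar(seq) < 4L) stop("sequence shorter than 4 nt")
  both <- Biostrings::DNAStringSet(c(seq, revcomp(seq)))
  n2 <- colSums(Biostrings::oligonucleotideFrequency(both, 2L))
  n3 <- colSums(Biostrings::oligonucleotideFrequency(both, 3L))
  n4 <- colSums(Biostrings::oligonucleotideFrequency(both, 4L))
  w <- names(n4)
  abc <- substr(w, 1L, 3L)
  bcd <- substr(w, 2L, 4L)
  bc <- substr(w, 2L, 3L)
  nbc <- n2[bc]
  e <- ifelse(nbc > 0, n3[abc] * n3[bcd] / nbc, 0)
  v <- ifelse(nbc > 0,
              e * (nbc - n3[abc]) * (nbc - n3[bcd]) / nbc^2, 0)
  z <- ifelse(v > 0, (n4 - e) / sqrt(v), 0)
  names(z) <- w
  structure(list(zscores = z, n_effective = sum(n4)),
            class = "tetra_signature")
}

#' Correlation of two tetranucleotide signatures
#'
#' Pearson correlation of the two 256-long z-score vectors; the standard
#' genome-signature similarity read off such signatures.
#'
#' @param sig_a,sig_b `tetra_signature` objects (or objects accepted by
#'   [tetra_signature()]).
#' @return Correlation in `[-1, 1]`.
#' @export
tetra_correlation <- function(sig_a, sig_b) {
  za <- if (inherits(sig_a, "tetra_signature")) sig_a$zscores else tetra_signature(sig_a)$zscores
  zb <- if (inherits(sig_b, "tetra_signature")) sig_b$zscores else tetra_signature(sig_b)$zscores
  if (sd(za) == 0 || sd(zb) == 0) stop("zero-variance signature vector")
  as.numeric(cor(za, zb))
}

#' Orthologous-fragment average nucleotide identity
#'
#' Both genomes are cut into consecutive non-overlapping fragments
#' (trailing remainder discarded). Fragments are matched across genomes by
#' shared k-mer seeding, locally aligned, and per-fragment best hits with
#' aligned span of at least `min_cov` of the fragment are retained.
#' ANI is the mean alignment identity over reciprocal best-hit fragment
#' pairs, averaged over both search directions, so `ani(a, b) = ani(b, a)`.
#'
#' @param genome_a,genome_b [annotated_genome()] objects or nucleotide
#'   strings.
#' @param fragment fragment length in bp (default 1020).
#' @param min_cov minimum aligned fraction of a fragment (default 0.35).
#' @return An `ani_result`: `ani` (fraction), fragment counts, number of
#'   reciprocal pairs and mean fragment coverage.
#' @export
ani <- function(genome_a, genome_b, fragment = 1020, min_cov = 0.35) {
  sa <- if (inherits(genome_a, "annotated_genome")) genome_a$sequence else genome_a
  sb <- if (inherits(genome_b, "annotated_genome")) genome_b$sequence else genome_b
  if (nchar(sa) < fragment || nchar(sb) < fragment) {
    stop("both genomes must be at least one fragment (", fragment, " bp) long")
  }
  fa <- cut_fragments(sa, fragment)
  fb <- cut_fragments(sb, fragment)
  best_ab <- best_fragment_hits(fa, fb, min_cov)
  best_ba <- best_fragment_hits(fb, fa, min_cov)
  pairs <- which(!is.na(best_ab$hit) &
                   best_ba$hit[best_ab$hit] == seq_along(fa))
  if (!length(pairs)) {
    stop("no reciprocal best-hit fragment pairs: ANI undefined")
  }
  ids <- c(best_ab$identity[pairs], best_ba$identity[best_ab$hit[pairs]])
  covs <- c(best_ab$coverage[pairs], best_ba$coverage[best_ab$hit[pairs]])
  structure(list(ani = mean(ids),
                 n_fragments_a = length(fa), n_fragments_b = length(fb),
                 n_reciprocal_pairs = length(pairs),
                 mean_coverage = mean(covs)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> ANI = %.4f over %d reciprocal fragment pairs (%d x %d fragments)\n",
              x$ani, x$n_reciprocal_pairs, x$n_fragments_a, x$n_fragments_b))
  invisible(x)
}

cut_fragments <- function(seq, fragment) {
  n <- nchar(seq) %/% fragment
  starts <- (seq_len(n) - 1L) * fragment + 1L
  substring(seq, starts, starts + fragment - 1L)
}

# per-query best hit among seed-sharing target fragments. Seeds are
# numeric k-mer codes matched in one vectorized pass; each candidate is
# first verified gaplessly at the seed-voted diagonal offset (exact for
# the indel-free case that dominates between near-identical strains),
# with a local alignment fallback when the gapless identity is poor.
# Tie-break: identity, then aligned span, then lower fragment index.
best_fragment_hits <- function(query, target, min_cov,
                               seed_k = 15L, seed_step = 8L, top = 2L) {
  nq <- length(query)
  frag_len <- nchar(query[1])
  # target seed table (both strands)
  tcode <- lapply(target, kmer_codes, k = seed_k)
  tcode_rc <- lapply(target, function(s) kmer_codes(revcomp(s), seed_k))
  lens <- vapply(tcode, length, integer(1))
  tc <- c(unlist(tcode), unlist(tcode_rc))
  tfrag <- c(rep(seq_along(target), lens), rep(seq_along(target), lens))
  tpos <- c(unlist(lapply(lens, seq_len)), unlist(lapply(lens, seq_len)))
  tstrand <- rep(c(1L, -1L), each = sum(lens))
  # sampled query seeds
  qcode <- lapply(query, kmer_codes, k = seed_k)
  qsel <- lapply(qcode, function(x) seq(1L, length(x), by = seed_step))
  qc <- unlist(Map(`[`, qcode, qsel))
  qfrag <- rep(seq_len(nq), vapply(qsel, length, integer(1)))
  qpos <- unlist(qsel)
  m <- match(qc, tc)
  ok <- !is.na(m) & !is.na(qc)
  votes <- data.frame(q = qfrag[ok], frag = tfrag[m[ok]],
                      strand = tstrand[m[ok]],
                      off = tpos[m[ok]] - qpos[ok])
  hit <- rep(NA_integer_, nq)
  identity <- rep(NA_real_, nq)
  coverage <- rep(NA_real_, nq)
  if (!nrow(votes)) return(list(hit = hit, identity = identity, coverage = coverage))
  by_q <- split(votes, votes$q)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  for (qs in names(by_q)) {
    i <- as.integer(qs)
    v <- by_q[[qs]]
    key <- paste(v$frag, v$strand)
    cnt <- sort(table(key), decreasing = TRUE)
    cand_keys <- names(cnt)[seq_len(min(top, length(cnt)))]
    best <- NULL
    for (ck in cand_keys) {
      parts <- as.integer(strsplit(ck, " ")[[1]])
      j <- parts[1]; strnd <- parts[2]
      subj <- if (strnd > 0) target[j] else revcomp(target[j])
      offs <- v$off[key == ck]
      off <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
      res <- gapless_or_align(query[i], subj, off, min_cov, frag_len, submat)
      if (is.null(res)) next
      if (is.null(best) || res$id > best$id + 1e-12 ||
          (abs(res$id - best$id) <= 1e-12 &&
           (res$alen > best$alen || (res$alen == best$alen && j < best$j)))) {
        best <- c(res, j = j)
      }
    }
    if (!is.null(best)) {
      hit[i] <- best$j
      identity[i] <- best$id
      coverage[i] <- min(best$cov, 1)
    }
  }
  list(hit = hit, identity = identity, coverage = coverage)
}

# compare query and subject shifted by `off` (subject position = query
# position + off) without gaps; fall back to local alignment when the
# gapless identity suggests an indel
gapless_or_align <- function(q, subj, off, min_cov, frag_len, submat) {
  nqc <- nchar(q); nsc <- nchar(subj)
  q_from <- max(1L, 1L - off); q_to <- min(nqc, nsc - off)
  if (q_to - q_from + 1L >= min_cov * frag_len) {
    x <- strsplit(substring(q, q_from, q_to), "")[[1]]
    y <- strsplit(substring(subj, q_from + off, q_to + off), "")[[1]]
    idf <- mean(x == y)
    if (idf >= 0.8) {
      return(list(id = idf, alen = length(x),
                  cov = length(x) / frag_len))
    }
  }
  al <- Biostrings::pairwiseAlignment(
    q, subj, type = "local", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 2)
  alen <- nchar(as.character(Biostrings::alignedPattern(al)))
  if (!alen) return(NULL)
  cov <- Biostrings::width(Biostrings::pattern(al)) / frag_len
  if (cov < min_cov) return(NULL)
  list(id = Biostrings::nmatch(al) / alen, alen = alen, cov = cov)
}
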