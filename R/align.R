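# Pairwise and small-multiple alignment helpers shared by the marker
# divergence and hybrid-scan modules. Multiple alignment is center-star
# over pairwise global alignments: exact for the near-identical inputs
# this package targets, and deterministic.

align_scoring <- function(type) {
  if (type == "dna") {
    list(substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
      gapOpening = 5, gapExtension = 1)
  } else {
    list(substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  }
}

pairwise_global <- function(a, b, type = c("dna", "protein")) {
  type <- match.arg(type)
  sc <- align_scoring(type)
  cls <- if (type == "dna") Biostrings::DNAString else Biostrings::AAString
  al <- Biostrings::pairwiseAlignment(
    cls(a), cls(b), type = "global",
    substitutionMatrix = sc$substitutionMatrix,
    gapOpening = sc$gapOpening, gapExtension = sc$gapExtension)
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)))
}

#' Global identity of two sequences
#'
#' Global alignment with affine gaps; identity is matched columns divided
#' by the alignment length excluding terminal gap columns (internal gaps
#' stay in the denominator).
#'
#' @param seq_a,seq_b sequences (auto-detected as DNA if over the
#'   A/C/G/T/N alphabet, protein otherwise; override with `type`).
#' @param type `"dna"` or `"protein"`.
#' @return Identity fraction in `[0, 1]`.
#' @export
global_identity <- function(seq_a, seq_b, type = NULL) {
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  if (is.null(type)) {
    type <- if (!grepl("[^ACGTN]", seq_a) && !grepl("[^ACGTN]", seq_b))
      "dna" else "protein"
  }
  al <- pairwise_global(seq_a, seq_b, type)
  x <- strsplit(al$a, "")[[1]]
  y <- strsplit(al$b, "")[[1]]
  gap <- x == "-" | y == "-"
  # drop terminal gap runs
  core <- which(!gap)
  if (!length(core)) return(0)
  keep <- seq(min(core), max(core))
  mean(x[keep] == y[keep] & x[keep] != "-")
}

# center-star multiple alignment; returns a character matrix of aligned
# rows (names preserved). seqs[[center]] is the star center.
msa_center_star <- function(seqs, type = c("dna", "protein"), center = 1L) {
  type <- match.arg(type)
  k <- length(seqs)
  stopifnot(k >= 2L)
  nm <- names(seqs) %||% paste0("seq", seq_len(k))
  center_seq <- seqs[[center]]
  L <- nchar(center_seq)
  others <- setdiff(seq_len(k), center)
  als <- lapply(others, function(i) pairwise_global(center_seq, seqs[[i]], type))
  # per-alignment insertion counts after each center residue (0 = before 1st)
  ins <- lapply(als, function(al) {
    cc <- strsplit(al$a, "")[[1]]
    res_idx <- cumsum(cc != "-")
    counts <- integer(L + 1L)
    gaps <- which(cc == "-")
    if (length(gaps)) {
      at <- res_idx[gaps] # residue the gap follows (0 allowed)
      t <- table(at)
      counts[as.integer(names(t)) + 1L] <- as.integer(t)
    }
    counts
  })
  maxins <- Reduce(pmax, ins, integer(L + 1L))
  width <- L + sum(maxins)
  rows <- matrix("-", nrow = k, ncol = width, dimnames = list(nm, NULL))
  # center row
  col <- 0L
  center_chars <- strsplit(center_seq, "")[[1]]
  center_col <- integer(L) # alignment column of each center residue
  for (j in 0:L) {
    col <- col + maxins[j + 1L]
    if (j < L) {
      col <- col + 1L
      rows[center, col] <- center_chars[j + 1L]
      center_col[j + 1L] <- col
    }
  }
  # other rows
  for (t in seq_along(others)) {
    i <- others[t]
    cc <- strsplit(als[[t]]$a, "")[[1]]
    ss <- strsplit(als[[t]]$b, "")[[1]]
    out <- character(0)
    jres <- 0L
    pend <- character(0)
    place <- function(res_j, inserted, aligned_char) {
      # columns for insertions after residue res_j-1 block, then residue col
      n_slot <- maxins[res_j + 1L]
      c(inserted, rep("-", n_slot - length(inserted)), aligned_char)
    }
    for (p in seq_along(cc)) {
      if (cc[p] == "-") {
        pend <- c(pend, ss[p])
      } else {
        out <- c(out, place(jres, pend, ss[p]))
        pend <- character(0)
        jres <- jres + 1L
      }
    }
    # trailing insertions after the last center residue
    out <- c(out, pend, rep("-", maxins[L + 1L] - length(pend)))
    rows[i, ] <- out
  }
  rows
}

# identity shortcut: equal-length near-identical pairs score identically
# with or without the aligner (global alignment of such pairs is gap-free
# under affine penalties), so skip it
quick_identity <- function(a, b, type = "protein") {
  if (nchar(a) == nchar(b)) {
    direct <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    if (direct >= 0.9) return(direct)
  }
  global_identity(a, b, type)
}

msa_identity <- function(msa, r1, r2) {
  x <- msa[r1, ]
  y <- msa[r2, ]
  comparable <- !(x == "-" & y == "-")
  sum(x == y & x != "-" & comparable) / sum(comparable)
}
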