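#' @useDynLib straintrio, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor sd rbinom median setNames
#' @importFrom utils head tail read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# uppercase, ambiguity codes (IUPAC beyond N) -> N with a warning,
# anything non-IUPAC is an error
normalize_sequence <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  if (grepl("[^ACGTNRYSWKMBDHVU]", seq)) {
    bad <- regmatches(seq, regexpr("[^ACGTNRYSWKMBDHVU]", seq))
    stop("illegal character '", bad, "' in ", what)
  }
  if (grepl("[RYSWKMBDHVU]", seq)) {
    n <- nchar(gsub("[^RYSWKMBDHVU]", "", seq))
    warning(n, " ambiguity/uracil base(s) normalized to N in ", what)
    seq <- gsub("[RYSWKMBDHV]", "N", seq)
    seq <- gsub("U", "T", seq)
  }
  seq
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# circular distance between two positions on a genome of length len
circ_dist <- function(a, b, len) {
  d <- abs(a - b) %% len
  pmin(d, len - d)
}

# all k-mers of a string as a character vector (empty if too short)
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1), k:n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
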