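# In-place genome editing primitives used by the simulator and its replay
# engine. Every operation updates feature coordinates consistently, so an
# event log can be replayed on the ancestor to reproduce a derived strain
# byte-for-byte.

edit_substitute <- function(genome, pos, base) {
  stopifnot(pos >= 1L, pos <= genome_length(genome))
  substr(genome$sequence, pos, pos) <- base
  genome
}

# insert `seq` so that its first base lands at position `pos`
# (old bases at pos.. shift right)
edit_insert <- function(genome, pos, seq, feature = NULL) {
  len <- genome_length(genome)
  stopifnot(pos >= 1L, pos <= len + 1L)
  n <- nchar(seq)
  genome$sequence <- paste0(substring(genome$sequence, 1L, pos - 1L), seq,
                            substring(genome$sequence, pos, len))
  ft <- genome$features
  if (nrow(ft)) {
    inside <- ft$start < pos & ft$end >= pos
    ft$start <- ifelse(ft$start >= pos, ft$start + n, ft$start)
    ft$end <- ifelse(ft$end >= pos, ft$end + n, ft$end)
    if (any(inside)) ft$end[inside] <- ft$end[inside] # span grows, kept
    genome$features <- ft
  }
  if (!is.null(feature)) {
    feature$start <- feature$start + pos - 1L
    feature$end <- feature$end + pos - 1L
    genome$features <- as_feature_table(rbind(genome$features,
                                              as_feature_table(feature)))
  }
  genome
}

edit_delete <- function(genome, pos, n) {
  len <- genome_length(genome)
  stopifnot(pos >= 1L, pos + n - 1L <= len)
  genome$sequence <- paste0(substring(genome$sequence, 1L, pos - 1L),
                            substring(genome$sequence, pos + n, len))
  ft <- genome$features
  if (nrow(ft)) {
    lo <- pos
    hi <- pos + n - 1L
    gone <- ft$start >= lo & ft$end <= hi
    if (any(gone)) ft <- ft[!gone, , drop = FALSE]
    if (nrow(ft)) {
      ft$start <- ifelse(ft$start > hi, ft$start - n,
                         ifelse(ft$start >= lo, lo, ft$start))
      ft$end <- ifelse(ft$end > hi, ft$end - n,
                       ifelse(ft$end >= lo, lo - 1L + 0L, ft$end))
      # clamp features truncated by the deletion
      ft$end <- pmax(ft$end, ft$start)
    }
    genome$features <- ft
  }
  genome
}

# invert (reverse-complement in place) the segment [start, end];
# features must lie entirely inside or outside the segment
edit_invert <- function(genome, start, end) {
  len <- genome_length(genome)
  stopifnot(start >= 1L, end <= len, start < end)
  seg <- revcomp(substring(genome$sequence, start, end))
  genome$sequence <- paste0(substring(genome$sequence, 1L, start - 1L), seg,
                            substring(genome$sequence, end + 1L, len))
  ft <- genome$features
  if (nrow(ft)) {
    inside <- ft$start >= start & ft$end <= end
    straddle <- (ft$start < start & ft$end >= start) |
      (ft$start <= end & ft$end > end)
    if (any(straddle)) {
      stop("inversion [", start, ",", end, "] straddles feature(s): ",
           paste(ft$locus_tag[straddle], collapse = ", "))
    }
    if (any(inside)) {
      s <- ft$start[inside]
      e <- ft$end[inside]
      ft$start[inside] <- start + (end - e)
      ft$end[inside] <- start + (end - s)
      ft$strand[inside] <- ifelse(ft$strand[inside] == "+", "-", "+")
    }
    genome$features <- ft
  }
  genome
}

# replace the bases of [start, end] by `seq` of the same length
edit_replace <- function(genome, start, end, seq) {
  stopifnot(nchar(seq) == end - start + 1L)
  substr(genome$sequence, start, end) <- seq
  genome
}

# apply one logged event (as stored in a trio truth object)
apply_event <- function(genome, ev) {
  switch(ev$op,
         substitute = edit_substitute(genome, ev$pos, ev$base),
         insert = edit_insert(genome, ev$pos, ev$seq,
                              feature = ev$feature %||% NULL),
         delete = edit_delete(genome, ev$pos, ev$n),
         invert = edit_invert(genome, ev$start, ev$end),
         replace = edit_replace(genome, ev$start, ev$end, ev$seq),
         stop("unknown event op: ", ev$op))
}
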