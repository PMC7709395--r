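#' Sliding-window identity profile along a multiple alignment
#'
#' For one pair of rows, identity per window of alignment columns is the
#' fraction of matched columns among columns where not both sequences are
#' gapped (a gap against a residue counts as mismatch). Windows with
#' fewer than `min_comparable` comparable columns are flagged.
#'
#' @param msa character matrix of aligned rows (from e.g. an S-layer
#'   protein family alignment), rows named.
#' @param pair length-2 vector of row names or indices.
#' @param window window size in alignment columns (default 20).
#' @param step step in columns (default 1).
#' @param min_comparable flag threshold (default 5).
#' @return An `identity_profile`: `positions` (window midpoints in
#'   alignment coordinates), `identity`, `flagged`, `pair`.
#' @export
sliding_identity <- function(msa, pair, window = 20, step = 1,
                             min_comparable = 5) {
  L <- ncol(msa)
  if (window > L) stop("window (", window, ") exceeds alignment length (", L, ")")
  x <- msa[pair[1], ]
  y <- msa[pair[2], ]
  comparable <- !(x == "-" & y == "-")
  matched <- comparable & x == y & x != "-"
  cm <- c(0L, cumsum(comparable))
  mm <- c(0L, cumsum(matched))
  starts <- seq(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  ncomp <- cm[ends + 1L] - cm[starts]
  nmat <- mm[ends + 1L] - mm[starts]
  structure(list(positions = (starts + ends) / 2,
                 identity = ifelse(ncomp > 0L, nmat / ncomp, NA_real_),
                 flagged = ncomp < min_comparable,
                 window = window, step = step,
                 pair = if (is.character(pair)) pair else rownames(msa)[pair]),
            class = "identity_profile")
}

#' @export
print.identity_profile <- function(x, ...) {
  cat(sprintf("<identity_profile> %s vs %s: %d windows (w=%d, step=%d), mean %.3f\n",
              x$pair[1], x$pair[2], length(x$identity), x$window, x$step,
              mean(x$identity, na.rm = TRUE)))
  invisible(x)
}

#' Call a hybrid (chimeric) gene against two candidate parents
#'
#' The query is aligned with both parents; per sliding window, the parent
#' with the higher identity is assigned when identities clear a
#' hysteresis (winner at or above `high`, loser at or below `low`),
#' preventing segment flicker in mid-identity regions. Consecutive
#' same-parent windows merge into segments tiling the alignment; the
#' query is called a hybrid when at least one segment of at least
#' `min_seg` columns is assigned to each parent.
#'
#' @param query,parent_a,parent_b protein sequences.
#' @param high winner identity threshold (default 0.9).
#' @param low loser identity threshold (default 0.7).
#' @param window,step sliding window in alignment columns (20, 1).
#' @param min_seg minimum segment length in columns to support a parent
#'   (default 30).
#' @return A `chimera_call`: `segments` (start, end, parent, mean
#'   identity to each parent), `breakpoints`, `is_hybrid`, and the
#'   underlying profiles.
#' @export
call_chimera <- function(query, parent_a, parent_b, high = 0.9, low = 0.7,
                         window = 20, step = 1, min_seg = 30) {
  msa <- msa_center_star(list(query = query, A = parent_a, B = parent_b),
                         type = "protein", center = 1L)
  pa <- sliding_identity(msa, c("query", "A"), window, step)
  pb <- sliding_identity(msa, c("query", "B"), window, step)
  n <- length(pa$identity)
  state <- character(n)
  cur <- "ambiguous"
  for (i in seq_len(n)) {
    ia <- pa$identity[i]; ib <- pb$identity[i]
    if (!is.na(ia) && !is.na(ib)) {
      if (ia >= high && ib <= low) cur <- "A"
      else if (ib >= high && ia <= low) cur <- "B"
    }
    state[i] <- cur
  }
  # backfill a leading ambiguous run with the first decided state
  first <- which(state != "ambiguous")[1]
  if (!is.na(first) && first > 1L) state[seq_len(first - 1L)] <- state[first]
  # merge windows into segments tiling the alignment columns
  L <- ncol(msa)
  r <- rle(state)
  k <- length(r$values)
  win_end <- cumsum(r$lengths) # last window index per run
  seg_bounds <- integer(0)
  if (k > 1L) {
    for (t in seq_len(k - 1L)) {
      # boundary between window win_end[t] and win_end[t]+1: midpoint
      seg_bounds <- c(seg_bounds,
                      round((pa$positions[win_end[t]] +
                               pa$positions[win_end[t] + 1L]) / 2))
    }
  }
  starts <- c(1L, seg_bounds + 1L)
  ends <- c(seg_bounds, L)
  segs <- data.frame(start = starts, end = ends, parent = r$values,
                     stringsAsFactors = FALSE)
  segs$mean_identity_a <- vapply(seq_len(nrow(segs)), function(i) {
    w <- pa$positions >= segs$start[i] & pa$positions <= segs$end[i]
    if (any(w)) mean(pa$identity[w], na.rm = TRUE) else NA_real_
  }, numeric(1))
  segs$mean_identity_b <- vapply(seq_len(nrow(segs)), function(i) {
    w <- pb$positions >= segs$start[i] & pb$positions <= segs$end[i]
    if (any(w)) mean(pb$identity[w], na.rm = TRUE) else NA_real_
  }, numeric(1))
  seg_len <- segs$end - segs$start + 1L
  is_hybrid <- any(segs$parent == "A" & seg_len >= min_seg) &&
    any(segs$parent == "B" & seg_len >= min_seg)
  structure(list(segments = segs, breakpoints = seg_bounds,
                 is_hybrid = is_hybrid, profiles = list(A = pa, B = pb),
                 alignment = msa),
            class = "chimera_call")
}

#' @export
print.chimera_call <- function(x, ...) {
  cat(sprintf("<chimera_call> %s: %d segment(s)%s\n",
              if (x$is_hybrid) "HYBRID" else "not a hybrid",
              nrow(x$segments),
              if (length(x$breakpoints))
                paste0(", breakpoint(s) at ",
                       paste(x$breakpoints, collapse = ", ")) else ""))
  invisible(x)
}
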