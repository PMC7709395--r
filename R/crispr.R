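#' Extract CRISPR arrays guided by a known repeat
#'
#' Finds approximate occurrences of the direct repeat on both strands,
#' clusters tandem occurrences whose inter-repeat gaps fall within the
#' spacer length bounds into arrays, and extracts the spacers between
#' consecutive repeats. De novo repeat discovery is out of scope: the
#' conserved repeat is an input.
#'
#' @param genome an [annotated_genome()].
#' @param repeat_consensus the direct repeat (at least 20 bp).
#' @param max_mismatch mismatches tolerated per repeat occurrence (3).
#' @param spacer_len allowed spacer length range, default `c(20, 50)`.
#' @param flank_bp genomic context kept on each side of an array (200).
#' @return List of `crispr_array` objects (possibly empty). Spacers are
#'   reported in reading order along the matched strand; index 1 becomes
#'   leader-proximal only after [orient_by_leader()].
#' @export
find_array <- function(genome, repeat_consensus, max_mismatch = 3,
                       spacer_len = c(20, 50), flank_bp = 200) {
  if (nchar(repeat_consensus) < 20L) stop("repeat must be at least 20 bp")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    hits <- Biostrings::matchPattern(repeat_consensus,
                                     Biostrings::DNAString(s),
                                     max.mismatch = max_mismatch)
    st <- Biostrings::start(hits)
    if (!length(st)) next
    st <- sort(st)
    rl <- nchar(repeat_consensus)
    gap_ok <- diff(st) - rl >= spacer_len[1] & diff(st) - rl <= spacer_len[2]
    grp <- cumsum(c(TRUE, !gap_ok))
    for (ix in split(seq_along(st), grp)) {
      if (length(ix) < 2L) next # an array needs at least one spacer
      starts <- st[ix]
      spacers <- substring(s, head(starts, -1) + rl, tail(starts, -1) - 1L)
      a_start <- starts[1]
      a_end <- starts[length(starts)] + rl - 1L
      n <- nchar(s)
      locus <- if (strand == "+") c(a_start, a_end) else
        c(n - a_end + 1L, n - a_start + 1L)
      out[[length(out) + 1L]] <- structure(list(
        genome_id = genome$id,
        locus_start = locus[1], locus_end = locus[2], strand = strand,
        repeat_consensus = repeat_consensus,
        spacers = spacers,
        flank_up = substring(s, max(1L, a_start - flank_bp), a_start - 1L),
        flank_down = substring(s, a_end + 1L, min(n, a_end + flank_bp)),
        oriented = FALSE, orientation_evidence = NULL),
        class = "crispr_array")
    }
  }
  out
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %s [%d..%d] (%s): %d spacer(s)%s\n",
              x$genome_id, x$locus_start, x$locus_end, x$strand,
              length(x$spacers),
              if (x$oriented) ", leader at index 1" else ", unoriented"))
  invisible(x)
}

#' Orient a CRISPR array so index 1 is leader-proximal
#'
#' With a leader sequence, the end whose flank matches the leader best
#' becomes the leader end. Without one, orientation is undetermined here;
#' use [orient_by_context()] across several arrays (unique spacers
#' concentrate toward the leader, where acquisition inserts them).
#'
#' @param array a `crispr_array`.
#' @param leader_seq the leader sequence (e.g. the 138-bp leader of the
#'   large type I-B locus), or NULL.
#' @return The array, oriented (`oriented = TRUE`) or flagged
#'   undetermined.
#' @export
orient_by_leader <- function(array, leader_seq = NULL) {
  if (!length(array$spacers)) stop("empty array")
  if (is.null(leader_seq)) {
    array$oriented <- FALSE
    array$orientation_evidence <- "no leader given; undetermined"
    return(array)
  }
  score_up <- flank_match_score(leader_seq, array$flank_up)
  score_down <- flank_match_score(leader_seq, array$flank_down)
  if (score_up == score_down) {
    array$oriented <- FALSE
    array$orientation_evidence <- "leader matches both flanks equally"
    return(array)
  }
  if (score_down > score_up) array <- flip_array(array)
  array$oriented <- TRUE
  array$orientation_evidence <- sprintf(
    "leader match score up=%d down=%d", score_up, score_down)
  array
}

# best local-alignment score of the leader against a flank, either strand
flank_match_score <- function(leader, flank) {
  if (!nchar(flank)) return(-Inf)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  s1 <- Biostrings::pairwiseAlignment(leader, flank, type = "local",
                                      substitutionMatrix = submat,
                                      gapOpening = 2, gapExtension = 1,
                                      scoreOnly = TRUE)
  s2 <- Biostrings::pairwiseAlignment(revcomp(leader), flank, type = "local",
                                      substitutionMatrix = submat,
                                      gapOpening = 2, gapExtension = 1,
                                      scoreOnly = TRUE)
  max(s1, s2)
}

flip_array <- function(array) {
  array$spacers <- rev(vapply(array$spacers, revcomp, character(1),
                              USE.NAMES = FALSE))
  fu <- array$flank_up
  array$flank_up <- revcomp(array$flank_down)
  array$flank_down <- revcomp(fu)
  array$strand <- if (array$strand == "+") "-" else "+"
  array
}

#' Orient unoriented arrays by cross-array conservation
#'
#' For each unoriented array, both orientations are tried and the one in
#' which spacers shared with the other arrays sit closer to the trailer
#' (high indices) is kept; arrays sharing nothing stay undetermined.
#'
#' @param arrays list of `crispr_array` objects, at least one oriented or
#'   two sharing spacers.
#' @return The list with orientations resolved where possible.
#' @export
orient_by_context <- function(arrays) {
  canon <- function(sp) pmin(sp, vapply(sp, revcomp, character(1)))
  for (i in seq_along(arrays)) {
    if (arrays[[i]]$oriented) next
    others <- unlist(lapply(arrays[-i], function(a) canon(a$spacers)))
    sp <- canon(arrays[[i]]$spacers)
    shared <- sp %in% others
    if (!any(shared) || all(shared)) next
    m <- length(sp)
    # shared (older) spacers should sit at high indices (trailer side)
    if (mean(which(shared)) < mean(which(!shared))) {
      arrays[[i]] <- flip_array(arrays[[i]])
    }
    arrays[[i]]$oriented <- TRUE
    arrays[[i]]$orientation_evidence <- "conservation gradient across arrays"
  }
  arrays
}

#' Cluster spacers across arrays
#'
#' Spacers are grouped by exact sequence identity by default (both strands
#' considered, i.e. a spacer equals its reverse complement's cluster).
#' With `identity < 1`, near-identical spacers within the implied edit
#' distance are merged by single linkage.
#'
#' @param arrays list of `crispr_array` objects.
#' @param identity sequence identity required to share a cluster (1.0).
#' @return List with `ids` (per array, the integer cluster IDs of its
#'   spacers in order) and `clusters` (representative sequence per ID).
#' @export
cluster_spacers <- function(arrays, identity = 1.0) {
  if (!length(arrays)) return(list(ids = list(), clusters = character(0)))
  all_sp <- lapply(arrays, function(a) a$spacers)
  flat <- unlist(all_sp)
  if (!length(flat)) return(list(ids = rep(list(integer(0)), length(arrays)),
                                 clusters = character(0)))
  canon <- vapply(flat, function(s) min(s, revcomp(s)), character(1),
                  USE.NAMES = FALSE)
  if (identity >= 1) {
    reps <- unique(canon)
    id <- match(canon, reps)
  } else {
    reps_all <- unique(canon)
    maxmm <- floor((1 - identity) * stats::median(nchar(reps_all)))
    d <- utils::adist(reps_all)
    link <- d <= maxmm
    # single-linkage components
    comp <- seq_along(reps_all)
    repeat {
      changed <- FALSE
      for (a in seq_along(reps_all)) {
        nb <- which(link[a, ])
        mc <- min(comp[nb])
        if (any(comp[nb] != mc)) { comp[nb] <- mc; changed <- TRUE }
      }
      if (!changed) break
    }
    comp <- match(comp, unique(comp))
    reps <- tapply(reps_all, comp, `[`, 1)
    id <- comp[match(canon, reps_all)]
  }
  lens <- vapply(all_sp, length, integer(1))
  ids <- split(id, rep(seq_along(arrays), lens))
  ids <- lapply(seq_along(arrays), function(i) as.integer(ids[[as.character(i)]] %||% integer(0)))
  names(ids) <- vapply(arrays, function(a) a$genome_id, character(1))
  list(ids = ids, clusters = as.character(reps))
}

#' Align CRISPR arrays over the spacer-cluster alphabet
#'
#' Progressive global alignment of the arrays' cluster-ID strings with
#' match +1, gap -1 and mismatches disallowed (arrays evolve by insertion
#' and deletion of spacers, not substitution); the conserved trailer block
#' anchors itself. Columns run leader to trailer; all arrays must already
#' be oriented.
#'
#' @param ids named list of integer cluster-ID vectors (leader first), as
#'   from [cluster_spacers()].
#' @return A `spacer_alignment`: `columns` (genomes x columns matrix of
#'   IDs and NA gaps) plus per-column presence categories from
#'   [classify_spacers()].
#' @export
align_arrays <- function(ids) {
  k <- length(ids)
  stopifnot(k >= 2L)
  nm <- names(ids) %||% paste0("array", seq_len(k))
  # guide order: start from the pair sharing most clusters
  if (k > 2L) {
    shared <- function(a, b) length(intersect(ids[[a]], ids[[b]]))
    best <- c(1L, 2L); bestv <- -1L
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      if (shared(a, b) > bestv) { bestv <- shared(a, b); best <- c(a, b) }
    }
    ord <- c(best, setdiff(seq_len(k), best))
  } else ord <- seq_len(k)
  prof <- matrix(ids[[ord[1]]], nrow = 1)
  for (j in ord[-1]) prof <- align_to_profile(prof, ids[[j]])
  # restore input row order
  rows <- order(ord)
  prof <- prof[rows, , drop = FALSE]
  rownames(prof) <- nm
  structure(list(columns = prof), class = "spacer_alignment")
}

# NW alignment of one ID vector against a profile: a sequence element may
# only align to a column containing that exact ID (mismatches modelled as
# two gaps); match +1 per agreeing row, gap -1
align_to_profile <- function(prof, s) {
  n <- ncol(prof)
  m <- length(s)
  col_id <- apply(prof, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v)) v[1] else NA_integer_
  })
  col_occ <- colSums(!is.na(prof))
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- c(0, cumsum(rep(-1, n)))
  D[1, ] <- c(0, cumsum(rep(-1, m)))
  P <- matrix(0L, n + 1, m + 1) # 1 diag, 2 up (profile col), 3 left (seq)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      up <- D[i, j + 1] - 1
      left <- D[i + 1, j] - 1
      diag <- if (!is.na(col_id[i]) && col_id[i] == s[j])
        D[i, j] + col_occ[i] else -Inf
      best <- max(diag, up, left)
      D[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (best == diag) 1L else if (best == up) 2L else 3L
    }
  }
  # traceback
  cols <- list()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    mv <- P[i + 1, j + 1]
    if (mv == 1L) {
      cols[[length(cols) + 1L]] <- c(prof[, i], s[j]); i <- i - 1; j <- j - 1
    } else if (mv == 2L) {
      cols[[length(cols) + 1L]] <- c(prof[, i], NA_integer_); i <- i - 1
    } else {
      cols[[length(cols) + 1L]] <- c(rep(NA_integer_, nrow(prof)), s[j]); j <- j - 1
    }
  }
  do.call(cbind, rev(cols))
}

#' @export
print.spacer_alignment <- function(x, ...) {
  cat(sprintf("<spacer_alignment> %d array(s) x %d column(s)\n",
              nrow(x$columns), ncol(x$columns)))
  invisible(x)
}

#' Classify alignment columns by presence pattern
#'
#' Each column is `shared_all`, `shared_<X>_<Y>` (exactly two genomes) or
#' `unique_<X>`. Category counts sum to the number of columns; a genome's
#' non-gap columns equal its spacer count.
#'
#' @param alignment a `spacer_alignment`.
#' @return List with `categories` (per-column label), `counts` (named
#'   count per category), `n_columns` and `n_clusters`.
#' @export
classify_spacers <- function(alignment) {
  M <- alignment$columns
  nm <- rownames(M)
  labs <- apply(M, 2, function(col) {
    pres <- which(!is.na(col))
    if (length(pres) == nrow(M)) "shared_all"
    else if (length(pres) == 1L) paste0("unique_", nm[pres])
    else paste0("shared_", paste(nm[pres], collapse = "_"))
  })
  structure(list(categories = labs, counts = table(labs),
                 n_columns = ncol(M),
                 n_clusters = length(unique(as.vector(M[!is.na(M)])))),
            class = "spacer_classification")
}

#' Infer the differentiation order of three strains from a spacer alignment
#'
#' New spacers enter at the leader end, so spacers shared by exactly two
#' strains and sitting leaderward of the all-shared trailer block mark a
#' period when those two still shared an ancestor after the third had
#' split off. The pair with the strictly largest such support is called
#' sister, and the remaining strain earliest diverged.
#'
#' @param alignment a trailer-anchored, 3-genome `spacer_alignment`.
#' @param min_support minimum pair-shared leaderward columns (1).
#' @return A `lineage_call`: `earliest_diverged`, `sister_pair`,
#'   `support` (per-pair counts).
#' @export
infer_order <- function(alignment, min_support = 1) {
  M <- alignment$columns
  stopifnot(nrow(M) == 3L)
  nm <- rownames(M)
  cls <- classify_spacers(alignment)$categories
  shared_idx <- which(cls == "shared_all")
  if (!length(shared_idx)) {
    return(structure(list(earliest_diverged = "undetermined",
                          sister_pair = NULL,
                          support = setNames(numeric(3), pair_names(nm))),
                     class = "lineage_call"))
  }
  # trailer anchor: maximal run of shared_all columns containing the
  # trailer-most shared_all column
  runs <- split(shared_idx, cumsum(c(1L, diff(shared_idx) != 1L)))
  anchor <- runs[[length(runs)]]
  leaderward <- seq_len(min(anchor) - 1L)
  pairs <- utils::combn(3L, 2L)
  support <- apply(pairs, 2, function(p) {
    lab <- paste0("shared_", paste(nm[sort(p)], collapse = "_"))
    sum(cls[leaderward] == lab)
  })
  names(support) <- apply(pairs, 2, function(p) paste(nm[sort(p)], collapse = "_"))
  top <- which(support == max(support))
  if (length(top) == 1L && support[top] >= min_support) {
    sis <- nm[pairs[, top]]
    structure(list(earliest_diverged = setdiff(nm, sis),
                   sister_pair = sis, support = support),
              class = "lineage_call")
  } else {
    structure(list(earliest_diverged = "undetermined", sister_pair = NULL,
                   support = support),
              class = "lineage_call")
  }
}

pair_names <- function(nm) {
  apply(utils::combn(3L, 2L), 2, function(p) paste(nm[sort(p)], collapse = "_"))
}

#' @export
print.lineage_call <- function(x, ...) {
  cat(sprintf("<lineage_call> earliest diverged: %s%s\n",
              x$earliest_diverged,
              if (!is.null(x$sister_pair))
                paste0(" (sister pair ", paste(x$sister_pair, collapse = " + "), ")")
              else ""))
  invisible(x)
}

#' Spacer gains and losses between two versions of an array
#'
#' Aligns the two arrays (exact spacer matching, insertions/deletions
#' only) and reports losses and gains with their 1-based positions
#' counting from the leader end.
#'
#' @param array_old,array_new oriented `crispr_array` objects.
#' @return List with `lost` (positions in the old array) and `gained`
#'   (positions in the new array), each with the spacer sequences.
#' @export
diff_arrays <- function(array_old, array_new) {
  cl <- cluster_spacers(list(array_old, array_new))
  M <- align_arrays(setNames(cl$ids, c("old", "new")))$columns
  lost_cols <- which(!is.na(M[1, ]) & is.na(M[2, ]))
  gained_cols <- which(is.na(M[1, ]) & !is.na(M[2, ]))
  old_pos <- cumsum(!is.na(M[1, ]))
  new_pos <- cumsum(!is.na(M[2, ]))
  list(lost = data.frame(position = old_pos[lost_cols],
                         spacer = array_old$spacers[old_pos[lost_cols]],
                         stringsAsFactors = FALSE),
       gained = data.frame(position = new_pos[gained_cols],
                           spacer = array_new$spacers[new_pos[gained_cols]],
                           stringsAsFactors = FALSE))
}
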