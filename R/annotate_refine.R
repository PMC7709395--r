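#' Refine a CDS set by the 60-bp overlap rule
#'
#' When two coding sequences overlap by at least `max_overlap` bp and the
#' overlap is not explained by a mispredicted start codon, the shorter is
#' removed -- unless its function is predicted or it was found in the
#' proteome. Start-codon misprediction is operationalized as: the overlap
#' could be removed by truncating one gene to a downstream in-frame start
#' codon while retaining at least half of its length (checked against the
#' genome sequence when supplied).
#'
#' @param cds_list data frame of CDS intervals (`locus_tag`, `start`,
#'   `end`, `strand`), or an [annotated_genome()].
#' @param expressed_ids locus tags found in the proteome.
#' @param functional_ids locus tags with predicted function (a CDS whose
#'   `product` is neither empty nor "hypothetical protein" counts as
#'   functional when a genome is supplied).
#' @param genome optional [annotated_genome()] for the start-codon check.
#' @param max_overlap overlap threshold in bp (default 60).
#' @return A `refinement_decision` with `kept`, `removed` (with reason)
#'   and `exempted` (with reason). Kept and removed partition the input.
#' @export
overlap_refine <- function(cds_list, expressed_ids = character(0),
                           functional_ids = character(0), genome = NULL,
                           max_overlap = 60) {
  if (inherits(cds_list, "annotated_genome")) {
    genome <- genome %||% cds_list
    cds_list <- cds_list$features[cds_list$features$type == "CDS", , drop = FALSE]
  }
  if (is.null(cds_list$part)) cds_list$part <- NA_integer_
  cds <- cds_list[is.na(cds_list$part), , drop = FALSE]
  cds <- cds[order(cds$start, cds$locus_tag), , drop = FALSE]
  if (!is.null(genome) && !is.null(cds$product)) {
    functional_ids <- union(functional_ids,
                            cds$locus_tag[!cds$product %in% c("", "hypothetical protein")])
  }
  removed <- character(0); removed_reason <- character(0)
  exempted <- character(0); exempt_reason <- character(0)
  active <- rep(TRUE, nrow(cds))
  len <- cds$end - cds$start + 1L
  repeat {
    changed <- FALSE
    idx <- which(active)
    for (ai in seq_along(idx)) {
      i <- idx[ai]
      for (bi in seq_along(idx)) {
        j <- idx[bi]
        if (j <= i) next
        if (cds$start[j] > cds$end[i]) break
        ov <- min(cds$end[i], cds$end[j]) - max(cds$start[i], cds$start[j]) + 1L
        if (ov < max_overlap) next
        if (start_misprediction(cds[i, ], cds[j, ], genome, max_overlap)) {
          tag <- cds$locus_tag[c(i, j)][which.min(len[c(i, j)])]
          if (!tag %in% exempted) {
            exempted <- c(exempted, tag)
            exempt_reason <- c(exempt_reason, "start_codon_misprediction")
          }
          next
        }
        shorter <- if (len[i] < len[j] ||
                       (len[i] == len[j] && cds$locus_tag[i] < cds$locus_tag[j]))
          i else j
        tag <- cds$locus_tag[shorter]
        if (tag %in% expressed_ids) {
          if (!tag %in% exempted) {
            exempted <- c(exempted, tag)
            exempt_reason <- c(exempt_reason, "in_proteome")
          }
        } else if (tag %in% functional_ids) {
          if (!tag %in% exempted) {
            exempted <- c(exempted, tag)
            exempt_reason <- c(exempt_reason, "function_predicted")
          }
        } else {
          active[shorter] <- FALSE
          removed <- c(removed, tag)
          removed_reason <- c(removed_reason, "overlap_shorter_unknown_unexpressed")
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  structure(list(kept = cds$locus_tag[active],
                 removed = setNames(removed_reason, removed),
                 exempted = setNames(exempt_reason, exempted)),
            class = "refinement_decision")
}

# can the overlap be explained by a mispredicted start? i.e. one gene has
# an in-frame start codon downstream of the overlap, keeping >= 50% length
start_misprediction <- function(f1, f2, genome, max_overlap) {
  if (is.null(genome)) return(FALSE)
  for (f in list(f1, f2)) {
    other <- if (identical(f, f1)) f2 else f1
    ov_lo <- max(f1$start, f2$start)
    ov_hi <- min(f1$end, f2$end)
    flen <- f$end - f$start + 1L
    if (f$strand == "+") {
      # truncate by moving start past the overlap end (minus tolerated rest)
      target <- ov_hi - max_overlap + 2L
      if (target <= f$start) next
      offs <- seq(f$start, f$end - 2L, by = 3L)
      cand <- offs[offs >= target & (f$end - offs + 1L) >= 0.5 * flen]
      if (!length(cand)) next
      codons <- substring(genome$sequence, cand, cand + 2L)
      if (any(codons %in% c("ATG", "GTG", "TTG"))) return(TRUE)
    } else {
      target <- ov_lo + max_overlap - 2L
      if (target >= f$end) next
      offs <- seq(f$end, f$start + 2L, by = -3L)
      cand <- offs[offs <= target & (offs - f$start + 1L) >= 0.5 * flen]
      if (!length(cand)) next
      codons <- vapply(cand, function(p)
        revcomp(substring(genome$sequence, p - 2L, p)), character(1))
      if (any(codons %in% c("ATG", "GTG", "TTG"))) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.refinement_decision <- function(x, ...) {
  cat(sprintf("<refinement_decision> kept %d, removed %d, exempted %d\n",
              length(x$kept), length(x$removed), length(x$exempted)))
  invisible(x)
}

#' Map homologs of every query CDS in a target genome
#'
#' Protein-against-protein best hit per query CDS; queries without a
#' protein hit are rescued by searching the six-frame translation of the
#' target genome. `has_homolog` is best identity at or above
#' `min_identity` with aligned coverage of at least `min_cov` of the
#' query.
#'
#' @param query_genome,target_genome [annotated_genome()] objects.
#' @param min_identity identity threshold (default 0.40).
#' @param min_cov minimum aligned fraction of the query (default 0.5).
#' @return A `homolog_table` data frame: per query `locus_tag`, best
#'   `target`, `identity`, `coverage`, `via` (protein/sixframe),
#'   `has_homolog`; plus the summary `fraction_with_homolog`.
#' @export
homolog_map <- function(query_genome, target_genome, min_identity = 0.40,
                        min_cov = 0.5) {
  qcds <- query_genome$features[query_genome$features$type == "CDS" &
                                  is.na(query_genome$features$part), , drop = FALSE]
  tcds <- target_genome$features[target_genome$features$type == "CDS" &
                                   is.na(target_genome$features$part), , drop = FALSE]
  qprot <- setNames(vapply(qcds$locus_tag, function(t)
    tryCatch(feature_protein(query_genome, t), error = function(e) ""),
    character(1)), qcds$locus_tag)
  tprot <- setNames(vapply(tcds$locus_tag, function(t)
    tryCatch(feature_protein(target_genome, t), error = function(e) ""),
    character(1)), tcds$locus_tag)
  tk <- lapply(tprot, function(p) unique(kmers_of(p, 5L)))
  frames <- six_frame_translate(target_genome$sequence)
  frame_k <- lapply(frames, function(f) {
    ks <- kmers_of(f, 8L)
    starts <- seq_along(ks)
    split(starts, ks)
  })
  rows <- lapply(qcds$locus_tag, function(tag) {
    q <- qprot[[tag]]
    if (!nchar(q)) {
      return(data.frame(locus_tag = tag, target = NA_character_,
                        identity = NA_real_, coverage = NA_real_,
                        via = NA_character_, has_homolog = FALSE,
                        stringsAsFactors = FALSE))
    }
    qk <- unique(kmers_of(q, 5L))
    score <- vapply(tk, function(p) length(intersect(qk, p)), integer(1))
    cand <- order(score, decreasing = TRUE)
    cand <- cand[score[cand] > 0L][seq_len(min(3L, sum(score > 0L)))]
    best <- NULL
    for (ci in cand) {
      hit <- aligned_identity_cov(q, tprot[[ci]])
      if (hit$coverage < min_cov) next
      if (is.null(best) || hit$identity > best$identity) {
        best <- c(hit, target = tcds$locus_tag[ci], via = "protein")
      }
    }
    if (is.null(best) || best$identity < min_identity) {
      sf <- sixframe_best(q, frames, frame_k, min_cov)
      if (!is.null(sf) &&
          (is.null(best) || sf$identity > best$identity)) best <- sf
    }
    if (is.null(best)) {
      data.frame(locus_tag = tag, target = NA_character_,
                 identity = NA_real_, coverage = NA_real_,
                 via = NA_character_, has_homolog = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(locus_tag = tag, target = best$target,
                 identity = best$identity, coverage = best$coverage,
                 via = best$via,
                 has_homolog = best$identity >= min_identity,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 fraction_with_homolog = mean(tab$has_homolog)),
            class = "homolog_table")
}

#' @export
print.homolog_table <- function(x, ...) {
  cat(sprintf("<homolog_table> %d queries, %.1f%% with homolog\n",
              nrow(x$table), 100 * x$fraction_with_homolog))
  invisible(x)
}

# local alignment identity/coverage of query protein vs target protein
aligned_identity_cov <- function(q, t) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  alen <- nchar(as.character(Biostrings::alignedPattern(al)))
  if (!alen) return(list(identity = 0, coverage = 0))
  list(identity = Biostrings::nmatch(al) / alen,
       coverage = Biostrings::width(Biostrings::pattern(al)) / nchar(q))
}

# best six-frame hit: seed candidate windows by shared 8-mers, align
# locally within the seeded window only
sixframe_best <- function(q, frames, frame_k, min_cov) {
  qk <- unique(kmers_of(q, 8L))
  best <- NULL
  for (fn in names(frames)) {
    hits <- unlist(frame_k[[fn]][qk], use.names = FALSE)
    if (is.null(hits) || !length(hits)) next
    lo <- max(1L, min(hits) - nchar(q))
    hi <- min(nchar(frames[[fn]]), max(hits) + nchar(q))
    windowseq <- substring(frames[[fn]], lo, hi)
    hit <- aligned_identity_cov(q, windowseq)
    if (hit$coverage < min_cov) next
    if (is.null(best) || hit$identity > best$identity) {
      best <- c(hit, target = paste0("frame:", fn), via = "sixframe")
    }
  }
  best
}
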