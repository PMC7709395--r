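#' GC-skew profile of a genome
#'
#' Computes the windowed GC skew (G-C)/(G+C) and the per-base cumulative
#' GC skew (running sum of +1 per G, -1 per C). On a circular bacterial
#' chromosome the cumulative curve typically reaches its minimum at the
#' replication origin and its maximum at the terminus.
#'
#' @param genome an [annotated_genome()].
#' @param window window size in bp (default 10000).
#' @param step step between window starts in bp (default 1000).
#' @return A `skew_profile` with `positions` (window midpoints), `skew`,
#'   `cumulative` (length `L + 1`, starting at 0), and the positions
#'   `min_pos`/`max_pos` of the cumulative extrema.
#' @export
gc_skew_profile <- function(genome, window = 10000, step = 1000) {
  s <- genome$sequence
  len <- nchar(s)
  if (window > len) stop("window (", window, ") exceeds genome length (", len, ")")
  base <- strsplit(s, "")[[1]]
  gc1 <- ifelse(base == "G", 1L, ifelse(base == "C", -1L, 0L))
  cumulative <- c(0L, cumsum(gc1))
  isg <- cumsum(base == "G")
  isc <- cumsum(base == "C")
  starts <- seq(1L, len - window + 1L, by = step)
  ends <- starts + window - 1L
  g <- isg[ends] - c(0L, isg)[starts]
  c_ <- isc[ends] - c(0L, isc)[starts]
  tot <- g + c_
  if (any(tot == 0L)) warning("window(s) with no G or C: skew set to 0")
  skew <- ifelse(tot == 0L, 0, (g - c_) / tot)
  structure(list(window = window, step = step,
                 positions = (starts + ends) / 2,
                 skew = skew, cumulative = cumulative,
                 min_pos = pos_of_extreme(cumulative, len, which.min),
                 max_pos = pos_of_extreme(cumulative, len, which.max)),
            class = "skew_profile")
}

# cumulative[i] is the value after base i-1, i.e. the boundary between
# bases i-1 and i; report the first base after the extremum, wrapped onto
# genome positions 1..L
pos_of_extreme <- function(cumulative, len, which_fun) {
  idx <- which_fun(cumulative)
  ((idx - 1L) %% len) + 1L
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> %d windows (%d bp / step %d); cumulative min @ %s, max @ %s\n",
              length(x$skew), x$window, x$step,
              format(x$min_pos, big.mark = ","),
              format(x$max_pos, big.mark = ",")))
  invisible(x)
}

#' Choose the ori-defining dnaA gene
#'
#' Among all dnaA candidates (CDS whose product mentions dnaA or the
#' chromosomal replication initiator, or whose protein is at least
#' `min_identity` identical to a supplied reference dnaA), the candidate
#' nearest the cumulative GC-skew minimum that also has dnaN and gyrB
#' within `proximity_genes` CDS features is chosen. If no candidate meets
#' both criteria the skew-nearest candidate is returned with low
#' confidence.
#'
#' @param genome an [annotated_genome()] with CDS features.
#' @param profile optional precomputed [gc_skew_profile()].
#' @param proximity_genes how many CDS features away dnaN/gyrB may sit and
#'   still count as "immediate proximity" (default 5).
#' @param dnaa_ref optional reference DnaA protein sequence for homology
#'   matching of unannotated candidates.
#' @param min_identity identity threshold for reference matching (0.40).
#' @return An `ori_call` with `ori_position`, `chosen_dnaA`,
#'   `dnaA_candidates`, per-candidate `evidence`, and `confidence`.
#' @export
find_ori <- function(genome, profile = NULL, proximity_genes = 5,
                     dnaa_ref = NULL, min_identity = 0.40) {
  if (is.null(profile)) profile <- gc_skew_profile(genome)
  ft <- genome$features
  cds <- ft[ft$type == "CDS" & is.na(ft$part) | ft$type == "CDS" & !is.na(ft$part) & ft$part == 1L, , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features: cannot search for dnaA")
  is_dnaa <- grepl("dnaA|chromosomal replication initiat", cds$product,
                   ignore.case = TRUE)
  if (!is.null(dnaa_ref)) {
    for (i in which(!is_dnaa)) {
      aa <- tryCatch(feature_protein(genome, cds$locus_tag[i]),
                     error = function(e) NULL)
      if (!is.null(aa) && nchar(aa) > 0.5 * nchar(dnaa_ref) &&
          global_identity(aa, dnaa_ref) >= min_identity) {
        is_dnaa[i] <- TRUE
      }
    }
  }
  cand <- cds[is_dnaa, , drop = FALSE]
  if (!nrow(cand)) {
    stop("no dnaA candidate found among ", nrow(cds),
         " CDS (searched product text",
         if (!is.null(dnaa_ref)) " and reference homology", ")")
  }
  len <- genome_length(genome)
  has_dnan <- grepl("dnaN|polymerase III.*beta|beta sliding clamp",
                    cds$product, ignore.case = TRUE)
  has_gyrb <- grepl("gyrB|gyrase.*(subunit )?B", cds$product, ignore.case = TRUE)
  evidence <- lapply(seq_len(nrow(cand)), function(i) {
    ci <- which(cds$locus_tag == cand$locus_tag[i])[1]
    nb <- setdiff(seq(ci - proximity_genes, ci + proximity_genes), ci)
    nb <- ((nb - 1L) %% nrow(cds)) + 1L
    start_pos <- if (cand$strand[i] == "+") cand$start[i] else cand$end[i]
    list(locus_tag = cand$locus_tag[i],
         dist_to_min = circ_dist(start_pos, profile$min_pos, len),
         dnaN_nearby = any(has_dnan[nb]),
         gyrB_nearby = any(has_gyrb[nb]))
  })
  dist <- vapply(evidence, `[[`, numeric(1), "dist_to_min")
  ok <- vapply(evidence, function(e) e$dnaN_nearby && e$gyrB_nearby, logical(1))
  pick <- if (any(ok)) which(ok)[which.min(dist[ok])] else which.min(dist)
  chosen <- cand[pick, , drop = FALSE]
  structure(list(
    ori_position = if (chosen$strand == "+") chosen$start else chosen$end,
    chosen_dnaA = chosen$locus_tag,
    dnaA_strand = chosen$strand,
    dnaA_candidates = cand$locus_tag,
    evidence = evidence,
    confidence = if (ok[pick]) "high" else "low"),
    class = "ori_call")
}

#' @export
print.ori_call <- function(x, ...) {
  cat(sprintf("<ori_call> %s @ %s (%s strand), %d candidate(s), confidence %s\n",
              x$chosen_dnaA, format(x$ori_position, big.mark = ","),
              x$dnaA_strand, length(x$dnaA_candidates), x$confidence))
  invisible(x)
}

#' Reorient a circular genome into the canonical dnaA frame
#'
#' Reverse-complements the genome if the chosen dnaA lies on the minus
#' strand, then rotates so the first base of the chosen dnaA becomes
#' position 1 on the plus strand. Applying the operation twice is
#' idempotent. Genome length, GC content, tetranucleotide signature and
#' ANI against any third genome are unchanged.
#'
#' @param genome circular [annotated_genome()].
#' @param ori_call an `ori_call` from [find_ori()]; recomputed if omitted.
#' @return The reoriented `annotated_genome`.
#' @export
reorient <- function(genome, ori_call = NULL) {
  if (genome$topology != "circular") stop("cannot reorient a linear genome")
  if (is.null(ori_call)) ori_call <- find_ori(genome)
  tag <- ori_call$chosen_dnaA
  ft <- genome$features
  row <- ft[ft$locus_tag == tag, , drop = FALSE][1, ]
  if (row$strand == "-") {
    genome <- revcomp_genome(genome)
    ft <- genome$features
    row <- ft[ft$locus_tag == tag, , drop = FALSE][1, ]
  }
  rotate_genome(genome, row$start)
}
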