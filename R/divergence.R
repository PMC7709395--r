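#' Extract a conserved marker set from annotated genomes
#'
#' For every reference marker protein, the best-matching CDS of each
#' genome at or above `min_identity` amino-acid identity is selected,
#' with a full-length requirement (candidate within `len_tol` of the
#' reference length). A missing marker is an error naming the marker and
#' genome; a duplicated marker resolves to the highest-identity copy and
#' errors on an exact tie.
#'
#' @param genomes named list of [annotated_genome()] objects.
#' @param reference_marker_seqs named character vector of marker protein
#'   sequences (the marker manifest; user-replaceable).
#' @param min_identity minimum amino-acid identity (default 0.40).
#' @param len_tol allowed relative length deviation (default 0.1).
#' @return A `marker_set`: per genome a data frame with `marker`,
#'   `locus_tag`, `nt`, `aa`.
#' @export
extract_markers <- function(genomes, reference_marker_seqs,
                            min_identity = 0.40, len_tol = 0.1) {
  stopifnot(length(names(reference_marker_seqs)) == length(reference_marker_seqs))
  out <- lapply(names(genomes), function(gid) {
    g <- genomes[[gid]]
    cds <- cds_table(g)
    prots <- cds$aa
    nts <- cds$nt
    prot_kmers <- lapply(prots, function(p) unique(kmers_of(p, 5L)))
    rows <- lapply(names(reference_marker_seqs), function(mk) {
      ref <- reference_marker_seqs[[mk]]
      rk <- unique(kmers_of(ref, 5L))
      score <- vapply(prot_kmers, function(pk) length(intersect(rk, pk)),
                      integer(1))
      cand <- order(score, decreasing = TRUE)
      cand <- cand[score[cand] >= max(1L, 0.5 * max(score))]
      cand <- cand[seq_len(min(5L, length(cand)))]
      ids <- vapply(cand, function(ci) {
        if (abs(nchar(prots[ci]) - nchar(ref)) > len_tol * nchar(ref))
          return(NA_real_)
        quick_identity(ref, prots[ci])
      }, numeric(1))
      ok <- which(!is.na(ids) & ids >= min_identity)
      if (!length(ok)) {
        stop("marker '", mk, "' not found in genome ", gid,
             " (best identity among full-length candidates: ",
             if (any(!is.na(ids))) sprintf("%.2f", max(ids, na.rm = TRUE)) else "none",
             ")")
      }
      best <- ids[ok]
      top <- ok[which(best == max(best))]
      if (length(top) > 1L) {
        stop("marker '", mk, "' has tied best hits in genome ", gid, ": ",
             paste(cds$locus_tag[cand[top]], collapse = ", "))
      }
      ci <- cand[top]
      data.frame(marker = mk, locus_tag = cds$locus_tag[ci],
                 nt = nts[ci], aa = prots[ci], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(out) <- names(genomes)
  structure(list(markers = names(reference_marker_seqs), per_genome = out),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d marker(s) x %d genome(s)\n",
              length(x$markers), length(x$per_genome)))
  invisible(x)
}

#' Align markers per gene and concatenate
#'
#' Each marker is aligned across the three genomes (center-star over
#' pairwise global alignments, exact for near-identical sequences) and
#' the alignments are concatenated in fixed marker order at nucleotide
#' level; the amino-acid alignment is derived from aligned codons. A
#' marker whose alignment is not codon-consistent is flagged, excluded
#' and reported.
#'
#' @param marker_set a `marker_set` of exactly 3 genomes.
#' @return A `concat_alignment`: `nt` and `aa` (3-row character
#'   matrices), `marker_ranges` (nt column ranges), `mask` (columns with
#'   gap/ambiguity), `excluded` (frame-inconsistent markers).
#' @export
align_and_concat <- function(marker_set) {
  pg <- marker_set$per_genome
  if (length(pg) != 3L) stop("concatenated marker analysis expects 3 genomes")
  gids <- names(pg)
  nt_cols <- list(); aa_cols <- list()
  ranges <- list(); excluded <- character(0)
  for (mk in marker_set$markers) {
    nts <- vapply(pg, function(df) df$nt[df$marker == mk], character(1))
    # equal-length, near-identical sequences stack directly (what the
    # aligner would return, minus its overhead); otherwise center-star
    stackable <- length(unique(nchar(nts))) == 1L && {
      ch <- do.call(rbind, strsplit(nts, ""))
      max(mean(ch[1, ] != ch[2, ]), mean(ch[1, ] != ch[3, ]),
          mean(ch[2, ] != ch[3, ])) <= 0.05
    }
    msa <- if (stackable) do.call(rbind, strsplit(nts, "")) else
      msa_center_star(as.list(nts), type = "dna")
    rownames(msa) <- gids
    aa <- codon_rows_to_aa(msa)
    if (is.null(aa)) {
      excluded <- c(excluded, mk)
      next
    }
    from <- if (length(nt_cols)) sum(vapply(nt_cols, ncol, integer(1))) + 1L else 1L
    nt_cols[[mk]] <- msa
    aa_cols[[mk]] <- aa
    ranges[[mk]] <- c(from = from, to = from + ncol(msa) - 1L)
  }
  nt <- do.call(cbind, nt_cols)
  aa <- do.call(cbind, aa_cols)
  structure(list(nt = nt, aa = aa,
                 marker_ranges = do.call(rbind, ranges),
                 mask_nt = colSums(nt == "-" | nt == "N") > 0,
                 mask_aa = colSums(aa == "-" | aa == "X") > 0,
                 excluded = excluded),
            class = "concat_alignment")
}

# translate each aligned row codon-wise; NULL if not codon-consistent
codon_rows_to_aa <- function(msa) {
  L <- ncol(msa)
  if (L %% 3L != 0L) return(NULL)
  k <- nrow(msa)
  aa <- matrix("", nrow = k, ncol = L %/% 3L, dimnames = list(rownames(msa), NULL))
  for (r in seq_len(k)) {
    chars <- msa[r, ]
    codons <- matrix(chars, nrow = 3L)
    gappy <- colSums(codons == "-")
    if (any(gappy %in% c(1L, 2L))) return(NULL) # indel breaks the frame
    cstr <- paste0(codons[1, ], codons[2, ], codons[3, ])
    tr <- codon_table()[cstr]
    tr[is.na(tr)] <- "X"
    aa[r, ] <- ifelse(gappy == 3L, "-", tr)
  }
  aa
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment> %d nt / %d aa columns, %d marker(s)%s\n",
              ncol(x$nt), ncol(x$aa), nrow(x$marker_ranges),
              if (length(x$excluded))
                paste0(" (", length(x$excluded), " excluded)") else ""))
  invisible(x)
}

#' Count apomorphies in a three-strain concatenated alignment
#'
#' A column counts for strain X when X carries a state different from the
#' state the other two strains share, pointing to a change on X's branch.
#' Columns containing any gap or ambiguity are excluded.
#'
#' @param concat a `concat_alignment`.
#' @param level `"nt"` or `"aa"`.
#' @return An `apomorphy_counts`: named per-genome counts and
#'   `n_columns_counted`.
#' @export
count_apomorphies <- function(concat, level = c("nt", "aa")) {
  level <- match.arg(level)
  M <- concat[[level]]
  mask <- concat[[paste0("mask_", level)]]
  M <- M[, !mask, drop = FALSE]
  gids <- rownames(M)
  counts <- setNames(integer(3), gids)
  for (i in 1:3) {
    oth <- setdiff(1:3, i)
    counts[i] <- sum(M[oth[1], ] == M[oth[2], ] & M[i, ] != M[oth[1], ])
  }
  structure(list(counts = counts, level = level,
                 n_columns_counted = ncol(M)),
            class = "apomorphy_counts")
}

#' @export
print.apomorphy_counts <- function(x, ...) {
  cat(sprintf("<apomorphy_counts> (%s, %d columns) %s\n", x$level,
              x$n_columns_counted,
              paste(names(x$counts), x$counts, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Screen marker differences between two assemblies of one strain
#'
#' Classifies per-marker differences as substitutions, in-frame indels or
#' frame-shifting indels (length not a multiple of 3) -- the signature of
#' sequencing/assembly error in re-sequenced, otherwise unchanged strains.
#'
#' @param marker_set_old,marker_set_new `marker_set`s of the same single
#'   genome (older and newer assembly).
#' @param genome_id which genome of each set to compare (default: first).
#' @return Data frame with `marker`, `kind`
#'   (`substitution` / `inframe_indel` / `frameshift_indel`), `length`.
#' @export
frameshift_screen <- function(marker_set_old, marker_set_new,
                              genome_id = NULL) {
  old <- marker_set_old$per_genome[[genome_id %||% 1L]]
  new <- marker_set_new$per_genome[[genome_id %||% 1L]]
  rows <- list()
  for (mk in intersect(old$marker, new$marker)) {
    a <- old$nt[old$marker == mk]
    b <- new$nt[new$marker == mk]
    if (a == b) next
    al <- pairwise_global(a, b, "dna")
    x <- strsplit(al$a, "")[[1]]
    y <- strsplit(al$b, "")[[1]]
    isgap <- x == "-" | y == "-"
    runs <- rle(isgap)
    pos <- cumsum(c(1L, head(runs$lengths, -1L)))
    for (r in seq_along(runs$values)) {
      if (runs$values[r]) {
        len <- runs$lengths[r]
        rows[[length(rows) + 1L]] <- data.frame(
          marker = mk,
          kind = if (len %% 3L == 0L) "inframe_indel" else "frameshift_indel",
          length = len, stringsAsFactors = FALSE)
      }
    }
    nsub <- sum(!isgap & x != y)
    if (nsub > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, kind = "substitution", length = nsub,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(marker = character(0), kind = character(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
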