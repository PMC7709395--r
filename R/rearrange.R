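#' Signed reversal distance (Hannenhalli-Pevzner, exact)
#'
#' Minimum number of segment reversals converting the signed permutation
#' into the identity, computed exactly on the capped breakpoint graph
#' (`d = (n+1) - c + h + f`, with cycles, hurdles and fortress handled in
#' full). For circular genomes the permutation is first brought into the
#' canonical frame (element 1 first and positive, via rotation and, if
#' needed, reflection -- both symmetries of a circular chromosome pair),
#' after which the distance is the linear distance of the remainder.
#'
#' @param perm signed permutation: integer vector whose absolute values
#'   are exactly `1..n`.
#' @param topology `"linear"` or `"circular"`.
#' @return Non-negative integer distance.
#' @export
reversal_distance <- function(perm, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  perm <- validate_signed_perm(perm)
  if (topology == "linear") return(hp_distance_linear_cpp(perm))
  reduced <- circular_reduce(perm)
  if (!length(reduced)) return(0L)
  hp_distance_linear_cpp(reduced)
}

validate_signed_perm <- function(perm) {
  perm <- as.integer(perm)
  if (!length(perm) || any(perm == 0L) ||
      !identical(sort(abs(perm)), seq_along(perm))) {
    stop("not a valid signed permutation of 1..n")
  }
  perm
}

# canonical frame for a circular signed permutation: rotate (and reflect
# if 1 is negative) until the permutation starts with +1, drop that
# element and renumber the rest down by one
circular_reduce <- function(perm) {
  i <- which(abs(perm) == 1L)
  if (perm[i] < 0L) { # reflect: reverse order, flip signs
    perm <- -rev(perm)
    i <- which(abs(perm) == 1L)
  }
  if (i > 1L) perm <- c(perm[i:length(perm)], perm[seq_len(i - 1L)])
  rest <- perm[-1L]
  as.integer(sign(rest) * (abs(rest) - 1L))
}

apply_reversal <- function(perm, i, j) {
  perm[i:j] <- -rev(perm[i:j])
  perm
}

#' One optimal reversal scenario
#'
#' Returns an ordered list of reversals (index intervals) whose
#' application transforms `perm` into the identity in exactly
#' `reversal_distance(perm)` steps: at each step a reversal that lowers
#' the exact distance by one is taken (one always exists).
#'
#' @param perm signed permutation.
#' @param topology `"linear"` or `"circular"` (circular scenarios are
#'   reported on the canonically rotated frame).
#' @return A `reversal_scenario`: `distance`, `reversals` (two-column
#'   matrix of 1-based inclusive index intervals), and `intermediates`.
#' @export
reversal_scenario <- function(perm, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  perm <- validate_signed_perm(perm)
  work <- if (topology == "circular") circular_reduce(perm) else perm
  d <- if (length(work)) hp_distance_linear_cpp(work) else 0L
  revs <- matrix(integer(0), ncol = 2,
                 dimnames = list(NULL, c("from", "to")))
  inter <- list()
  n <- length(work)
  dd <- d
  while (dd > 0L) {
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in i:n) {
        cand <- apply_reversal(work, i, j)
        if (hp_distance_linear_cpp(cand) == dd - 1L) {
          work <- cand
          revs <- rbind(revs, c(i, j))
          inter[[length(inter) + 1L]] <- work
          dd <- dd - 1L
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-reducing reversal found")
  }
  structure(list(distance = d, reversals = revs, intermediates = inter,
                 topology = topology),
            class = "reversal_scenario")
}

#' @export
print.reversal_scenario <- function(x, ...) {
  cat(sprintf("<reversal_scenario> %d reversal(s) (%s)\n",
              x$distance, x$topology))
  invisible(x)
}

#' Read a two-genome Mauve backbone file into a signed block map
#'
#' Accepts the Mauve backbone TSV (`seq0_leftend seq0_rightend seq1_leftend
#' seq1_rightend`, negative coordinates marking reverse strand) for exactly
#' two genomes. Rows where either genome has a zero interval (genome-
#' specific segments) are dropped.
#'
#' @param path backbone file path.
#' @return A `block_map` (see [find_blocks()]).
#' @export
read_mauve_blocks <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("seq0_leftend", "seq0_rightend", "seq1_leftend", "seq1_rightend")
  if (!all(need %in% names(tab))) {
    if (ncol(tab) > 4L) stop("backbone files with more than 2 genomes are not supported")
    stop("malformed backbone file: expected columns ", paste(need, collapse = ", "))
  }
  if (ncol(tab) > 4L) stop("backbone files with more than 2 genomes are not supported")
  if (!all(vapply(tab[need], is.numeric, logical(1)))) {
    stop("malformed backbone file: non-numeric coordinates in ", path)
  }
  keep <- tab$seq0_leftend != 0 & tab$seq1_leftend != 0
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) stop("no two-genome blocks in ", path)
  la <- abs(tab$seq0_leftend); ra <- abs(tab$seq0_rightend)
  lb <- abs(tab$seq1_leftend); rb <- abs(tab$seq1_rightend)
  blocks <- data.frame(
    start_a = pmin(la, ra), end_a = pmax(la, ra),
    strand_a = ifelse(tab$seq0_leftend < 0, "-", "+"),
    start_b = pmin(lb, rb), end_b = pmax(lb, rb),
    strand_b = ifelse(tab$seq1_leftend < 0, "-", "+"))
  # orientation relative to genome A
  flip <- blocks$strand_a == "-"
  blocks$strand_b[flip] <- ifelse(blocks$strand_b[flip] == "+", "-", "+")
  blocks$strand_a <- "+"
  new_block_map(blocks)
}

new_block_map <- function(blocks) {
  blocks <- blocks[order(blocks$start_a), , drop = FALSE]
  for (g in c("a", "b")) {
    s <- blocks[[paste0("start_", g)]][order(blocks[[paste0("start_", g)]])]
    e <- blocks[[paste0("end_", g)]][order(blocks[[paste0("start_", g)]])]
    if (any(head(e, -1) >= tail(s, -1) + 0)) {
      bad <- which(head(e, -1) >= tail(s, -1))[1]
      stop("overlapping blocks in genome ", toupper(g),
           " (blocks ", bad, " and ", bad + 1L, " after sorting)")
    }
  }
  blocks$block_id <- seq_len(nrow(blocks))
  blocks$length <- blocks$end_a - blocks$start_a + 1L
  rownames(blocks) <- NULL
  structure(list(blocks = blocks), class = "block_map")
}

#' @export
print.block_map <- function(x, ...) {
  cat(sprintf("<block_map> %d collinear block(s), %s bp in genome A\n",
              nrow(x$blocks), format(sum(x$blocks$length), big.mark = ",")))
  invisible(x)
}

#' Find collinear blocks between two near-identical genomes
#'
#' Anchors are k-mers occurring exactly once in each genome (either
#' strand); anchors are chained into collinear blocks (same strand,
#' consistent order, neighbouring anchors within `max_gap` in both
#' genomes) and blocks shorter than `min_block` are discarded. A light
#' stand-in for a whole-genome aligner, adequate for strains of very high
#' identity.
#'
#' @param genome_a,genome_b [annotated_genome()] objects or strings.
#' @param min_block minimum block length in bp (default 5000).
#' @param k anchor k-mer size (default 21).
#' @param max_gap maximum gap between chained anchors (default 5000).
#' @return A `block_map`; empty (with a warning) if no anchors are shared.
#' @export
find_blocks <- function(genome_a, genome_b, min_block = 5000, k = 21,
                        max_gap = 5000) {
  sa <- if (inherits(genome_a, "annotated_genome")) genome_a$sequence else genome_a
  sb <- if (inherits(genome_b, "annotated_genome")) genome_b$sequence else genome_b
  an <- unique_kmer_positions(sa, k)
  bn <- unique_kmer_positions(sb, k)
  m <- match(an$code, bn$code)
  hit <- !is.na(m)
  if (!any(hit)) {
    warning("no unique shared anchors: empty block map")
    return(structure(list(blocks = as_block_frame(NULL)), class = "block_map"))
  }
  pa <- an$pos[hit]
  pb_raw <- bn$pos[m[hit]]
  strand <- ifelse(bn$strand[m[hit]] == an$strand[hit], "+", "-")
  ord <- order(pa)
  pa <- pa[ord]; pb_raw <- pb_raw[ord]; strand <- strand[ord]
  keep <- !duplicated(pa)
  pa <- pa[keep]; pb_raw <- pb_raw[keep]; strand <- strand[keep]
  keep <- supported_anchors(pa, pb_raw, strand)
  pa <- pa[keep]; pb_raw <- pb_raw[keep]; strand <- strand[keep]
  if (!length(pa)) {
    warning("no unique shared anchors: empty block map")
    return(structure(list(blocks = as_block_frame(NULL)), class = "block_map"))
  }
  blocks <- chain_anchors(pa, pb_raw, strand, k, max_gap)
  blocks <- blocks[blocks$end_a - blocks$start_a + 1L >= min_block, , drop = FALSE]
  blocks <- trim_block_overlaps(blocks, k)
  blocks <- blocks[blocks$end_a - blocks$start_a + 1L >= min_block, , drop = FALSE]
  if (!nrow(blocks)) {
    warning("no block of at least ", min_block, " bp: empty block map")
    return(structure(list(blocks = as_block_frame(NULL)), class = "block_map"))
  }
  new_block_map(blocks)
}

# neighbouring chains can share short stretches: anchors overlapping a
# breakpoint (up to k-1 bp), or repeat-junction matches that extend a
# block tail a few hundred bp into a tandem locus; shave the overlap off
# the downstream block
trim_block_overlaps <- function(blocks, k, max_trim = 3000L) {
  if (nrow(blocks) < 2L) return(blocks)
  for (pass in 1:3) {
    blocks <- blocks[order(blocks$start_a), , drop = FALSE]
    for (i in seq_len(nrow(blocks))[-1]) {
      ov <- blocks$end_a[i - 1L] - blocks$start_a[i] + 1L
      if (ov > 0L) {
        if (ov > max_trim) stop("blocks overlap by ", ov, " bp in genome A")
        blocks$start_a[i] <- blocks$start_a[i] + ov
        if (blocks$strand_b[i] == "+")
          blocks$start_b[i] <- blocks$start_b[i] + ov
        else blocks$end_b[i] <- blocks$end_b[i] - ov
      }
    }
    ordb <- order(blocks$start_b)
    for (t in seq_along(ordb)[-1]) {
      i <- ordb[t]; p <- ordb[t - 1L]
      ov <- blocks$end_b[p] - blocks$start_b[i] + 1L
      if (ov > 0L) {
        if (ov > max_trim) stop("blocks overlap by ", ov, " bp in genome B")
        blocks$start_b[i] <- blocks$start_b[i] + ov
        if (blocks$strand_b[i] == "+")
          blocks$start_a[i] <- blocks$start_a[i] + ov
        else blocks$end_a[i] <- blocks$end_a[i] - ov
      }
    }
    ok_a <- all(diff(sort(blocks$start_a)) > 0)
    blocks2 <- blocks[order(blocks$start_a), , drop = FALSE]
    clean <- all(head(blocks2$end_a, -1) < tail(blocks2$start_a, -1)) &&
      { b2 <- blocks[order(blocks$start_b), , drop = FALSE]
        all(head(b2$end_b, -1) < tail(b2$start_b, -1)) }
    if (clean) break
  }
  blocks
}

as_block_frame <- function(blocks) {
  if (is.null(blocks)) {
    data.frame(start_a = integer(0), end_a = integer(0),
               strand_a = character(0), start_b = integer(0),
               end_b = integer(0), strand_b = character(0),
               block_id = integer(0), length = integer(0))
  } else blocks
}

# numeric rolling k-mer codes (base-4; exact in doubles for k <= 25);
# windows containing N yield NA
kmer_codes <- function(seq, k) {
  v <- utf8ToInt(chartr("ACGTN", "\001\002\003\004\005", seq)) - 1L
  v[v > 3L] <- NA_integer_
  x <- stats::filter(v, 4^((k - 1):0), sides = 1)
  as.numeric(x[k:length(v)]) # code of the k-mer starting at i
}

# anchors: k-mers unique in the genome counting both strands and not
# overlapping a high-copy core (any constituent 15-mer seen >= 4 times,
# e.g. CRISPR repeats, IS elements) -- such k-mers breed spurious
# cross-locus matches. pos = forward-strand start of the occurrence.
unique_kmer_positions <- function(seq, k, core_k = 15L, core_max = 3L) {
  n <- nchar(seq)
  rc <- revcomp(seq)
  f <- kmer_codes(seq, k)
  r <- kmer_codes(rc, k)
  all <- c(f, r)
  dup <- duplicated(all, incomparables = NA) |
    duplicated(all, incomparables = NA, fromLast = TRUE)
  keep_f <- !is.na(f) & !dup[seq_along(f)]
  keep_r <- !is.na(r) & !dup[length(f) + seq_along(r)]
  # mask anchors overlapping repeated cores
  bad_f <- repeat_core_mask(seq, rc, k, core_k, core_max)
  keep_f <- keep_f & !bad_f$fwd
  keep_r <- keep_r & !bad_f$rev
  fi <- which(keep_f)
  ri <- which(keep_r)
  list(code = c(f[fi], r[ri]),
       pos = c(fi, n - (ri + k - 1L) + 1L),
       strand = c(rep("+", length(fi)), rep("-", length(ri))))
}

repeat_core_mask <- function(seq, rc, k, core_k, core_max) {
  fc <- kmer_codes(seq, core_k)
  rcc <- kmer_codes(rc, core_k)
  all <- c(fc, rcc)
  tab <- sort(all[!is.na(all)], method = "radix")
  r <- rle(tab)
  freq_of <- function(x) {
    f <- r$lengths[match(x, r$values)]
    f[is.na(f)] <- 0L
    f
  }
  window_any <- function(cores) {
    hot <- as.integer(freq_of(cores) > core_max)
    cs <- c(0L, cumsum(hot))
    m <- length(hot)
    span <- k - core_k + 1L
    idx <- seq_len(m - span + 1L)
    cs[idx + span] - cs[idx] > 0L
  }
  list(fwd = window_any(fc), rev = window_any(rcc))
}

# an anchor is trusted only if another anchor 100-2000 bp away (in A)
# lies on the same diagonal (+/- 50 bp); spurious matches -- e.g. k-mers
# spanning near-identical repeat/spacer junctions -- come in runs a few
# dozen bp wide and have no such support
supported_anchors <- function(pa, pb, strand, near = 100, far = 2000,
                              drift = 50) {
  n <- length(pa)
  if (n < 3L) return(rep(TRUE, n))
  d <- ifelse(strand == "+", pb - pa, pb + pa)
  # bucket anchors by (strand, diagonal); a genuine diagonal extends over
  # at least `near` bp of genome A (checked in two half-shifted bucket
  # grids so a diagonal straddling a bucket edge is not split)
  ext <- pmax(
    stats::ave(pa, paste(strand, floor(d / (2 * drift))),
               FUN = function(x) diff(range(x))),
    stats::ave(pa, paste(strand, floor((d + drift) / (2 * drift))),
               FUN = function(x) diff(range(x))))
  ext >= near
}

chain_anchors <- function(pa, pb, strand, k, max_gap) {
  n <- length(pa)
  brk <- logical(n)
  brk[1] <- TRUE
  if (n > 1L) {
    same <- strand[-1L] == strand[-n]
    gap_a <- diff(pa)
    gap_b <- ifelse(strand[-1L] == "+", diff(pb), -diff(pb))
    brk[-1L] <- !(same & gap_a <= max_gap & gap_b > 0 & gap_b <= max_gap)
  }
  grp <- cumsum(brk)
  out <- lapply(split(seq_len(n), grp), function(ix) {
    st <- strand[ix[1]]
    data.frame(start_a = pa[ix[1]], end_a = pa[ix[length(ix)]] + k - 1L,
               strand_a = "+",
               start_b = min(pb[ix]), end_b = max(pb[ix]) + k - 1L,
               strand_b = st)
  })
  do.call(rbind, out)
}

#' Signed permutation from a block map
#'
#' Blocks are numbered `1..n` in genome A order; the permutation is their
#' order and orientation along genome B.
#'
#' @param block_map a `block_map`.
#' @return Integer signed permutation.
#' @export
to_signed_permutation <- function(block_map) {
  bl <- block_map$blocks
  if (!nrow(bl)) stop("empty block map")
  ord <- order(bl$start_b)
  as.integer(ifelse(bl$strand_b[ord] == "+", 1L, -1L) * bl$block_id[ord])
}

#' Transposase genes at collinear-block flanks
#'
#' For every internal block boundary, reports transposase CDS (product
#' text match, or any locus tag in `families`) within `flank_bp` of the
#' boundary on genome A, and the fraction of boundaries with at least one
#' hit.
#'
#' @param block_map a `block_map`.
#' @param genome the [annotated_genome()] whose coordinates genome A of
#'   the map refers to.
#' @param genome_b optionally, genome B: an inversion carries the
#'   flanking element to the other end of the segment, so a breakpoint
#'   can face its transposase in either genome.
#' @param flank_bp flank width in bp (default 5000); 0 counts only
#'   boundary-overlapping genes.
#' @param pattern regular expression identifying transposase products.
#' @return A list with the per-boundary hit table and
#'   `fraction_flanked`.
#' @export
flank_transposases <- function(block_map, genome, genome_b = NULL,
                               flank_bp = 5000,
                               pattern = "transposase|insertion sequence|IS[0-9]") {
  bl <- block_map$blocks
  tn_of <- function(g) {
    ft <- g$features
    ft[ft$type == "CDS" & grepl(pattern, ft$product, ignore.case = TRUE), ,
       drop = FALSE]
  }
  tn_a <- tn_of(genome)
  tn_b <- if (!is.null(genome_b)) tn_of(genome_b) else NULL
  # boundaries between blocks that are also adjacent and equally oriented
  # in genome B are collinear splits (indel scars), not rearrangement
  # breakpoints; only the latter are examined
  perm <- to_signed_permutation(block_map)
  n <- nrow(bl)
  adjacent_in_b <- function(i) {
    any(perm[-length(perm)] == i & perm[-1L] == i + 1L) ||
      any(perm[-length(perm)] == -(i + 1L) & perm[-1L] == -i)
  }
  which_re <- which(vapply(seq_len(max(n - 1L, 0L)),
                           function(i) !adjacent_in_b(i), logical(1)))
  if (!length(which_re)) {
    return(list(boundaries = data.frame(after_block = integer(0),
                                        n_transposases = integer(0)),
                fraction_flanked = NA_real_))
  }
  near <- function(tab, p) {
    if (is.null(tab)) 0L else sum(tab$end >= p - flank_bp & tab$start <= p + flank_bp)
  }
  hits <- vapply(which_re, function(i) {
    # A-side edges of the junction
    h <- near(tn_a, bl$end_a[i]) + near(tn_a, bl$start_a[i + 1L])
    # corresponding B-side edges
    h <- h + near(tn_b, if (bl$strand_b[i] == "+") bl$end_b[i] else bl$start_b[i])
    h + near(tn_b, if (bl$strand_b[i + 1L] == "+") bl$start_b[i + 1L]
             else bl$end_b[i + 1L])
  }, integer(1))
  list(boundaries = data.frame(after_block = which_re, n_transposases = hits),
       fraction_flanked = mean(hits > 0L))
}
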