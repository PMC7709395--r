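# Three-strain genome simulator. An ancestral circular chromosome is
# built piece by piece (ori cassette, 50 marker genes, transposase
# cassettes, a polarized CRISPR array, a surface-layer gene), then three
# strains are derived on the tree (sister pair + outgroup) by replaying
# branch events: marker and intergenic substitutions, large inversions
# with breakpoints inside transposase cassettes, leader-end spacer
# insertions (and optional internal losses), a diverged surface-gene
# variant, and one chimeric surface gene. Every event is logged so the
# log replayed on the ancestor reproduces each strain byte-for-byte.

# fixed CRISPR repeat and leader used as defaults (arbitrary but frozen,
# like the conserved 30-bp repeat and 138-bp leader of the real locus)
CRISPR_REPEAT_DEFAULT <- "GTTTCAATACCTATGAGGAATTGAAACAGT"
CRISPR_LEADER_DEFAULT <- paste0(
  "ATTACGCCTAAGGTTCATCGGTAACCTATTTAGGACAATCCTTAAGCATT",
  "GGATCAACGTTAGGCTTAATCCGTTAACGGATTACCTTAGGCATAACGTT",
  "AGCCTTAAGGATCCATTAGGCAACTTAGGCAATTCCGA")

#' Configuration for the three-strain simulator
#'
#' Defaults are the study conditions the analyses are calibrated on: a
#' 200-kb circular ancestor at GC 0.41 with a two-replichore GC-skew bias,
#' 50 embedded marker genes, branch-private marker substitutions 2/31/4
#' (8 of the 31 non-synonymous), two large inversions on each sister
#' branch flanked by transposase cassettes, a polarized CRISPR array with
#' 45 all-shared trailer spacers, 12 sister-pair-shared and 19/35/85
#' unique spacers, and a chimeric surface gene.
#'
#' @param seed integer seed driving all randomness.
#' @param ancestor_length ancestor size in bp.
#' @param gc genomic GC fraction.
#' @param skew leading-strand G excess (fraction of intergenic bases).
#' @param n_markers,marker_len conserved marker genes: count and length
#'   (bp, multiple of 3 including start and stop).
#' @param branch_subs named per-strain marker substitution counts.
#' @param aa_changes how many of those are non-synonymous.
#' @param bg_subs per-strain intergenic (background) substitution counts.
#' @param n_inversions per-strain inversion counts (at most 2 each).
#' @param crispr list: `repeat_seq`, `leader`, `spacer_len`,
#'   `n_shared_all`, `n_pair_shared`, `n_unique` (named), and
#'   `internal_losses` (named; spacers deleted internally after all
#'   insertions).
#' @param chimera list: `surface_len_aa`, `parent_divergence` (aa
#'   fraction separating the diverged surface variant),
#'   `minor_divergence` (aa fraction for the second sister's variant),
#'   `breakpoint_aa` (chimera breakpoint).
#' @param strains strain names: `c(outgroup, sister1, sister2)`.
#' @param n_spurious overlapping spurious ORF annotations per genome.
#' @return A `trio_config` list.
#' @export
trio_config <- function(seed = 1,
                        ancestor_length = 200000,
                        gc = 0.41,
                        skew = 0.04,
                        n_markers = 50,
                        marker_len = 636,
                        branch_subs = c(KUST = 2, MBR1 = 31, CSTR1 = 4),
                        aa_changes = c(KUST = 0, MBR1 = 8, CSTR1 = 0),
                        bg_subs = c(KUST = 200, MBR1 = 600, CSTR1 = 300),
                        n_inversions = c(KUST = 0, MBR1 = 2, CSTR1 = 2),
                        crispr = list(),
                        chimera = list(),
                        strains = c("KUST", "MBR1", "CSTR1"),
                        n_spurious = 4) {
  crispr_defaults <- list(repeat_seq = CRISPR_REPEAT_DEFAULT,
                          leader = CRISPR_LEADER_DEFAULT,
                          spacer_len = 35,
                          n_shared_all = 45,
                          n_pair_shared = 12,
                          n_unique = c(KUST = 19, MBR1 = 35, CSTR1 = 85),
                          internal_losses = c(KUST = 0, MBR1 = 0, CSTR1 = 0))
  chimera_defaults <- list(surface_len_aa = 800,
                           parent_divergence = 0.45,
                           minor_divergence = 0.01,
                           breakpoint_aa = 400)
  crispr <- utils::modifyList(crispr_defaults, crispr)
  chimera <- utils::modifyList(chimera_defaults, chimera)
  stopifnot(marker_len %% 3 == 0, length(strains) == 3,
            all(n_inversions <= 2), all(n_inversions >= 0))
  structure(list(seed = seed, ancestor_length = ancestor_length, gc = gc,
                 skew = skew, n_markers = n_markers, marker_len = marker_len,
                 branch_subs = branch_subs, aa_changes = aa_changes,
                 bg_subs = bg_subs, n_inversions = n_inversions,
                 crispr = crispr, chimera = chimera, strains = strains,
                 n_spurious = n_spurious),
            class = "trio_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# random ORF: ATG + random non-stop codons + TAA, at roughly target GC
random_orf <- function(len_bp, gc) {
  n_codon <- len_bp %/% 3L - 2L
  codons <- character(n_codon)
  for (i in seq_len(n_codon)) {
    repeat {
      cd <- random_dna(3L, gc)
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# intergenic sequence with leading-strand G excess (sign +1 first
# replichore, -1 second)
skewed_dna <- function(n, gc, skew, sign) {
  pG <- gc / 2 + sign * skew / 2
  pC <- gc - pG
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, pC, pG, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a three-strain genome trio with ground truth
#'
#' @param config a [trio_config()].
#' @return List with `genomes` (named list of [annotated_genome()]),
#'   `truth` (a `trio_truth` event log; see [write_truth()] and
#'   [replay_truth()]), and `refs` (marker reference proteins, CRISPR
#'   repeat and leader, surface-gene locus tags, expressed locus tags --
#'   the inputs the analysis modules take).
#' @export
simulate_trio <- function(config = trio_config()) {
  set.seed(config$seed)
  L <- config$ancestor_length
  gc <- config$gc
  strains <- config$strains
  outgroup <- strains[1]
  sisters <- strains[2:3]

  ## ---- component sequences -------------------------------------------
  marker_nt <- vapply(seq_len(config$n_markers), function(i)
    random_orf(config$marker_len, gc), character(1))
  transposase_nt <- random_orf(900, gc)
  surf_len_nt <- config$chimera$surface_len_aa * 3L + 3L
  surface_nt <- random_orf(surf_len_nt, gc)
  dnaa_nt <- random_orf(1200, gc)
  dnan_nt <- random_orf(900, gc)
  gyrb_nt <- random_orf(1200, gc)
  sp_len <- config$crispr$spacer_len
  n_spacers_total <- config$crispr$n_shared_all + config$crispr$n_pair_shared +
    sum(config$crispr$n_unique)
  spacer_pool <- unique(vapply(seq_len(n_spacers_total + 20L), function(i)
    random_dna(sp_len, gc), character(1)))[seq_len(n_spacers_total)]
  rep_seq <- config$crispr$repeat_seq
  leader <- config$crispr$leader

  ## ---- assemble the ancestor -----------------------------------------
  parts <- character(0)
  feats <- list()
  pos <- 0L # length so far
  tagn <- 0L
  add_seq <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add_gap <- function(n) {
    sign <- if (pos < L / 2) 1 else -1
    add_seq(skewed_dna(n, gc, config$skew, sign))
  }
  add_gene <- function(s, product, type = "CDS", tag = NULL) {
    tagn <<- tagn + 1L
    tag <- tag %||% sprintf("%05d", tagn * 10L)
    feats[[length(feats) + 1L]] <<- data.frame(
      locus_tag = tag, type = type, start = pos + 1L,
      end = pos + nchar(s), strand = "+", product = product,
      part = NA_integer_, stringsAsFactors = FALSE)
    add_seq(s)
    tag
  }

  add_gap(100L)
  dnaa_tag <- add_gene(dnaa_nt, "chromosomal replication initiator protein DnaA")
  ori_pos <- 101L
  add_gap(150L)
  add_gene(dnan_nt, "DNA polymerase III subunit beta (dnaN)")
  add_gap(200L)
  add_gene(gyrb_nt, "DNA gyrase subunit B (gyrB)")
  add_gap(3000L)

  marker_tags <- character(config$n_markers)
  marker_pos <- integer(config$n_markers)
  add_markers <- function(ix) {
    for (i in ix) {
      marker_pos[i] <<- pos + 1L
      marker_tags[i] <<- add_gene(marker_nt[i],
                                  sprintf("conserved marker protein %02d", i))
      add_gap(700L)
    }
  }
  cassette_iv <- list()
  add_cassette <- function() {
    iv <- c(start = pos + 1L, end = pos + nchar(transposase_nt))
    add_gene(transposase_nt, "IS family transposase")
    add_gap(400L) # intergenic room so breakpoints never split a gene
    cassette_iv[[length(cassette_iv) + 1L]] <<- iv
    invisible(iv)
  }

  add_markers(1:10)
  add_gap(4000L)
  add_cassette()           # 1: inversion A start
  add_markers(11:15)
  add_cassette()           # 2: inversion A end
  add_gap(12000L)
  add_cassette()           # 3: inversion B start
  add_markers(16:20)
  add_cassette()           # 4: inversion B end
  add_gap(9000L)
  surface_pos <- pos + 1L
  surface_tag <- add_gene(surface_nt, "surface layer (S-layer) protein")
  chimera_site <- pos + 500L # insertion point of the hybrid copy
  add_gap(8000L)
  add_markers(21:30)
  add_gap(4000L)
  # CRISPR locus: leader | (repeat spacer) x n_shared_all | repeat
  ancestral_spacers <- spacer_pool[seq_len(config$crispr$n_shared_all)]
  spacer_next <- config$crispr$n_shared_all
  leader_pos <- pos + 1L
  add_seq(leader)
  array_start <- pos + 1L
  array_seq <- paste0(paste0(rep_seq, ancestral_spacers, collapse = ""), rep_seq)
  feats[[length(feats) + 1L]] <- data.frame(
    locus_tag = "CRISPR1", type = "repeat", start = array_start,
    end = array_start + nchar(array_seq) - 1L, strand = "+",
    product = "CRISPR array (type I-B locus)", part = NA_integer_,
    stringsAsFactors = FALSE)
  add_seq(array_seq)
  insert_at <- array_start + nchar(rep_seq) # leader-end insertion point
  add_gap(4000L)
  add_markers(31:35)
  add_gap(6000L)
  add_cassette()           # 5: inversion C start
  add_markers(36:40)
  add_cassette()           # 6: inversion C end
  add_gap(12000L)
  add_cassette()           # 7: inversion D start
  add_markers(41:45)
  add_cassette()           # 8: inversion D end
  add_gap(5000L)
  add_markers(46:50)
  pad <- L - pos
  if (pad < 1000L) stop("infeasible config: ancestor_length too small for content")
  add_gap(pad)
  ancestor_seq <- paste(parts, collapse = "")
  feats <- do.call(rbind, feats)

  # spurious overlapping ORF annotations (features only)
  if (config$n_spurious > 0) {
    host <- feats[feats$type == "CDS" &
                    grepl("marker", feats$product), , drop = FALSE]
    host <- host[seq(nrow(host) - config$n_spurious + 1L, nrow(host)), ,
                 drop = FALSE]
    # 220 bp of a 300-bp spurious ORF overlap its host marker: too deep
    # for a start-codon-misprediction rescue (truncation would keep under
    # half the gene), so the refinement rule must remove it
    sp <- data.frame(locus_tag = sprintf("SPUR%02d", seq_len(nrow(host))),
                     type = "CDS",
                     start = host$end - 219L,
                     end = pmin(host$end + 80L, L),
                     strand = "+", product = "hypothetical protein",
                     part = NA_integer_, stringsAsFactors = FALSE)
    feats <- rbind(feats, sp)
  }

  ancestor <- annotated_genome("ancestor", ancestor_seq, "circular", feats,
                               source = "simulated")

  ## ---- intergenic (free) intervals for background substitutions ------
  occ <- feats[order(feats$start), c("start", "end")]
  occ <- rbind(occ, data.frame(start = leader_pos, end = leader_pos + nchar(leader) - 1L))
  free_pos <- setdiff(seq_len(L), unlist(mapply(seq, occ$start, occ$end,
                                                SIMPLIFY = FALSE)))
  # keep substitutions clear of block-anchor context at cassette flanks
  total_bg <- sum(config$bg_subs)
  bg_all <- sample(free_pos, total_bg)
  bg_per_strain <- split(bg_all, rep(strains, config$bg_subs[strains]))

  ## ---- marker substitution planning ----------------------------------
  plan <- plan_marker_subs(marker_nt, marker_pos, config$branch_subs[strains],
                           config$aa_changes[strains], strains)

  ## ---- inversion planning --------------------------------------------
  # each inversion runs from just downstream of one cassette to the end
  # of the next, so both breakpoints sit immediately at transposase genes
  # without splitting any feature
  stopifnot(length(cassette_iv) == 8L)
  inv_all <- lapply(c(1L, 3L, 5L, 7L), function(i)
    c(cassette_iv[[i]]["end"] + 200L, cassette_iv[[i + 1L]]["end"]))
  inv_all <- lapply(inv_all, unname)
  inv_by_strain <- setNames(vector("list", 3), strains)
  take <- 1L
  for (s in strains) {
    k <- config$n_inversions[[s]]
    if (k > 0) {
      inv_by_strain[[s]] <- inv_all[seq(take, take + k - 1L)]
      take <- take + k
    } else inv_by_strain[[s]] <- list()
  }

  ## ---- spacer assignment ---------------------------------------------
  pair_spacers <- spacer_pool[spacer_next + seq_len(config$crispr$n_pair_shared)]
  spacer_next <- spacer_next + config$crispr$n_pair_shared
  uniq_spacers <- list()
  for (s in strains) {
    k <- config$crispr$n_unique[[s]]
    uniq_spacers[[s]] <- spacer_pool[spacer_next + seq_len(k)]
    spacer_next <- spacer_next + k
  }

  ## ---- diverged + chimeric surface variants --------------------------
  surf_div <- diverge_orf(surface_nt, config$chimera$parent_divergence)
  surf_minor <- diverge_orf(surface_nt, config$chimera$minor_divergence)
  bp_nt <- config$chimera$breakpoint_aa * 3L
  hybrid_nt <- paste0(substring(surface_nt, 1L, bp_nt),
                      substring(surf_div, bp_nt + 1L, nchar(surf_div)))
  # the diverged variant goes to sister 2, the minor variant to sister 1,
  # the hybrid copy into the outgroup (next to its native surface gene)
  surf_variant_of <- setNames(c(NA, "minor", "diverged"), strains)

  ## ---- derive strains -------------------------------------------------
  genomes <- list()
  events <- list()
  for (s in strains) {
    g <- ancestor
    g$id <- s
    g$features$locus_tag <- paste0(s, "_", g$features$locus_tag)
    ev <- list()
    log_ev <- function(e) ev[[length(ev) + 1L]] <<- e
    # 1. marker substitutions (batch-applied; logged individually)
    if (length(plan[[s]])) {
      pos <- vapply(plan[[s]], `[[`, numeric(1), "pos")
      base <- vapply(plan[[s]], `[[`, character(1), "base")
      for (row in plan[[s]]) {
        log_ev(list(op = "substitute", pos = row$pos, base = row$base,
                    context = "marker", marker = row$marker,
                    synonymous = row$synonymous))
      }
      g$sequence <- batch_substitute(g$sequence, pos, base)
    }
    # 2. surface variant replacement
    if (!is.na(surf_variant_of[[s]])) {
      newseq <- if (surf_variant_of[[s]] == "diverged") surf_div else surf_minor
      g <- edit_replace(g, surface_pos, surface_pos + nchar(surface_nt) - 1L,
                        newseq)
      log_ev(list(op = "replace", start = surface_pos,
                  end = surface_pos + nchar(surface_nt) - 1L, seq = newseq,
                  context = paste0("surface_", surf_variant_of[[s]])))
    }
    # 3. background substitutions (batch-applied; logged individually)
    bgp <- bg_per_strain[[s]]
    if (length(bgp)) {
      old <- substring(g$sequence, bgp, bgp)
      base <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
      for (t in seq_along(bgp)) {
        log_ev(list(op = "substitute", pos = bgp[t], base = base[t],
                    context = "background"))
      }
      g$sequence <- batch_substitute(g$sequence, bgp, base)
    }
    # 4. inversions
    for (iv in inv_by_strain[[s]]) {
      g <- edit_invert(g, iv[1], iv[2])
      log_ev(list(op = "invert", start = iv[1], end = iv[2],
                  context = "inversion"))
    }
    # 5. CRISPR leader-end insertions, oldest first (pair-shared before
    #    strain-unique) so the youngest spacer ends nearest the leader
    for (sp in if (s %in% sisters) c(rev(pair_spacers), rev(uniq_spacers[[s]]))
         else rev(uniq_spacers[[s]])) {
      piece <- paste0(sp, rep_seq)
      g <- edit_insert(g, insert_at, piece)
      log_ev(list(op = "insert", pos = insert_at, seq = piece,
                  context = "spacer_insertion"))
    }
    # 6. internal spacer losses
    n_loss <- config$crispr$internal_losses[[s]]
    if (n_loss > 0) {
      arr <- find_array(g, rep_seq, max_mismatch = 0)
      arr <- arr[[which.max(vapply(arr, function(a) length(a$spacers), integer(1)))]]
      n_sp <- length(arr$spacers)
      # internal: not the first or last five
      loss_idx <- sort(sample(6:(n_sp - 5L), n_loss))
      for (li in rev(loss_idx)) {
        rl <- nchar(rep_seq)
        del_pos <- arr$locus_start + rl +
          (li - 1L) * (sp_len + rl)
        g <- edit_delete(g, del_pos, sp_len + rl)
        log_ev(list(op = "delete", pos = del_pos, n = sp_len + rl,
                    context = "spacer_loss", spacer_index = li))
      }
    }
    # 7. chimeric surface gene copy in the outgroup
    if (s == outgroup) {
      site <- chimera_site
      feat <- data.frame(locus_tag = paste0(s, "_SLAYB"), type = "CDS",
                         start = 1L, end = nchar(hybrid_nt), strand = "+",
                         product = "surface layer (S-layer) protein, variant",
                         part = NA_integer_, stringsAsFactors = FALSE)
      g <- edit_insert(g, site, hybrid_nt, feature = feat)
      log_ev(list(op = "insert", pos = site, seq = hybrid_nt,
                  context = "chimera_insertion"))
    }
    genomes[[s]] <- g
    events[[s]] <- ev
  }

  marker_aa <- sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAStringSet(marker_nt),
    genetic.code = Biostrings::getGeneticCode("11"))))
  names(marker_aa) <- sprintf("marker%02d", seq_along(marker_aa))

  truth <- structure(list(
    seed = config$seed,
    ancestor_seq = ancestor_seq,
    strains = strains,
    events = events,
    strain_md5 = lapply(genomes, function(g) md5_string(g$sequence)),
    planted = list(
      ori_pos = ori_pos,
      # ancestor-frame intervals substitutions must avoid
      protected = {
        pr <- feats[feats$type == "repeat" |
                      grepl("transposase", feats$product), c("start", "end")]
        pr <- rbind(pr, data.frame(start = leader_pos,
                                   end = leader_pos + nchar(leader) - 1L))
        rownames(pr) <- NULL
        pr
      },
      topology = list(outgroup = outgroup, sisters = sisters),
      marker_subs = lapply(plan, function(rows)
        do.call(rbind, lapply(rows, as.data.frame))),
      inversions = inv_by_strain,
      n_inversions_between = pairwise_inversion_counts(config$n_inversions, strains),
      spacer_counts = list(shared_all = config$crispr$n_shared_all,
                           pair_shared = config$crispr$n_pair_shared,
                           unique = as.list(config$crispr$n_unique)),
      spurious = if (config$n_spurious > 0)
        sprintf("SPUR%02d", seq_len(config$n_spurious)) else character(0),
      chimera = list(host = outgroup, locus_tag = paste0(outgroup, "_SLAYB"),
                     breakpoint_aa = config$chimera$breakpoint_aa,
                     parents = c(paste0(outgroup, "_", surface_tag),
                                 paste0(strains[3], "_", surface_tag))))),
    class = "trio_truth")
  truth$checksum <- truth_checksum(truth)

  refs <- list(marker_aa = marker_aa,
               crispr_repeat = rep_seq,
               crispr_leader = leader,
               surface_tags = setNames(paste0(strains, "_", surface_tag), strains),
               chimera_tag = paste0(outgroup, "_SLAYB"),
               dnaa_tags = setNames(paste0(strains, "_", dnaa_tag), strains),
               expressed_ids = as.vector(outer(strains, marker_tags[1:25],
                                               function(a, b) paste0(a, "_", b))))
  list(genomes = genomes, truth = truth, refs = refs)
}

pairwise_inversion_counts <- function(n_inv, strains) {
  pairs <- utils::combn(strains, 2)
  setNames(apply(pairs, 2, function(p) sum(n_inv[p])),
           apply(pairs, 2, paste, collapse = "_"))
}

# mutate an ORF so that roughly `frac` of its amino acids change,
# keeping start/stop intact and introducing no internal stops
diverge_orf <- function(orf, frac) {
  n_codon <- nchar(orf) %/% 3L
  body <- 2:(n_codon - 1L)
  k <- round(frac * length(body))
  if (k == 0) return(orf)
  targets <- sort(sample(body, k))
  for (ci in targets) {
    at <- (ci - 1L) * 3L + 1L
    old <- substring(orf, at, at + 2L)
    old_aa <- translate_dna(old)
    repeat {
      cd <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS && translate_dna(cd) != old_aa) break
    }
    substr(orf, at, at + 2L) <- cd
  }
  orf
}

# choose substitution positions inside markers: distinct codons across
# all branches, synonymous via 4-fold third positions, non-synonymous via
# second positions
plan_marker_subs <- function(marker_nt, marker_pos, branch_subs, aa_changes,
                             strains) {
  fourfold_first2 <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  n_codon <- nchar(marker_nt[1]) %/% 3L
  pool <- expand.grid(marker = seq_along(marker_nt), codon = 2:(n_codon - 1L))
  pool <- pool[sample(nrow(pool)), ]
  used <- 0L
  plan <- setNames(vector("list", length(strains)), strains)
  for (s in strains) {
    n_sub <- branch_subs[[s]]
    n_aa <- aa_changes[[s]]
    rows <- list()
    while (length(rows) < n_sub) {
      used <- used + 1L
      if (used > nrow(pool)) stop("not enough marker codons for planned substitutions")
      mk <- pool$marker[used]
      ci <- pool$codon[used]
      at <- (ci - 1L) * 3L
      codon <- substring(marker_nt[mk], at + 1L, at + 3L)
      want_nonsyn <- length(rows) < n_aa
      if (want_nonsyn) {
        old <- substring(codon, 2L, 2L)
        ok <- FALSE
        for (b in sample(setdiff(DNA_BASES, old))) {
          cand <- codon
          substr(cand, 2L, 2L) <- b
          if (!cand %in% STOP_CODONS &&
              translate_dna(cand) != translate_dna(codon)) {
            rows[[length(rows) + 1L]] <- list(
              marker = mk, pos = marker_pos[mk] + at + 1L, base = b,
              synonymous = FALSE)
            ok <- TRUE
            break
          }
        }
        if (!ok) next
      } else {
        if (!substring(codon, 1L, 2L) %in% fourfold_first2) next
        old <- substring(codon, 3L, 3L)
        b <- sample(setdiff(DNA_BASES, old), 1L)
        rows[[length(rows) + 1L]] <- list(
          marker = mk, pos = marker_pos[mk] + at + 2L, base = b,
          synonymous = TRUE)
      }
    }
    plan[[s]] <- rows
  }
  plan
}

batch_substitute <- function(seq, pos, base) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}

md5_string <- function(x) {
  tf <- tempfile()
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

truth_checksum <- function(truth) {
  payload <- paste(truth$ancestor_seq,
                   jsonlite::toJSON(truth$events, auto_unbox = TRUE),
                   paste(truth$strain_md5, collapse = ","), sep = "\n")
  md5_string(payload)
}

#' @export
print.trio_truth <- function(x, ...) {
  cat(sprintf("<trio_truth> %s: %s event(s)\n",
              paste(x$strains, collapse = "/"),
              paste(vapply(x$events, length, integer(1)), collapse = "/")))
  invisible(x)
}

#' Write / read a trio ground-truth log
#'
#' The log is stored as JSON with an embedded checksum over the ancestor,
#' the event log and the strain sequence digests; [read_truth()] refuses
#' a hand-edited log.
#'
#' @param truth a `trio_truth`.
#' @param path file path.
#' @return `path` invisibly; `read_truth` returns the `trio_truth`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  need <- c("seed", "ancestor_seq", "strains", "events", "strain_md5",
            "checksum")
  if (!all(need %in% names(raw))) {
    stop("truth log schema mismatch: missing ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  truth <- structure(raw[setdiff(names(raw), "checksum")], class = "trio_truth")
  truth$strain_md5 <- as.list(unlist(truth$strain_md5))
  if (truth_checksum(truth) != raw$checksum) {
    stop("truth log checksum mismatch: the log was modified")
  }
  truth$checksum <- raw$checksum
  truth
}

#' Replay a truth log on its ancestor
#'
#' Independent, sequence-only replay engine: applies each strain's logged
#' events to the ancestor sequence and checks the result against the
#' stored digests.
#'
#' @param truth a `trio_truth`.
#' @return Named list of reconstructed strain sequences (error if any
#'   digest disagrees).
#' @export
replay_truth <- function(truth) {
  out <- list()
  for (s in truth$strains) {
    seq <- truth$ancestor_seq
    for (ev in truth$events[[s]]) {
      seq <- switch(ev$op,
        substitute = {
          substr(seq, ev$pos, ev$pos) <- ev$base
          seq
        },
        insert = paste0(substring(seq, 1L, ev$pos - 1L), ev$seq,
                        substring(seq, ev$pos, nchar(seq))),
        delete = paste0(substring(seq, 1L, ev$pos - 1L),
                        substring(seq, ev$pos + ev$n, nchar(seq))),
        invert = paste0(substring(seq, 1L, ev$start - 1L),
                        revcomp(substring(seq, ev$start, ev$end)),
                        substring(seq, ev$end + 1L, nchar(seq))),
        replace = {
          substr(seq, ev$start, ev$end) <- ev$seq
          seq
        },
        stop("unknown event op in log: ", ev$op))
    }
    if (md5_string(seq) != truth$strain_md5[[s]]) {
      stop("replay of strain ", s, " does not match its recorded digest")
    }
    out[[s]] <- seq
  }
  out
}

#' Mutate a genome copy at a fixed per-base substitution rate
#'
#' Utility for ANI calibration: returns a copy of the input with i.i.d.
#' substitutions at `rate` (never the original base).
#'
#' @param genome an [annotated_genome()] or string.
#' @param rate per-base substitution probability.
#' @return Object of the same kind as the input.
#' @export
mutate_genome <- function(genome, rate) {
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  n <- nchar(s)
  k <- rbinom(1L, n, rate)
  if (k > 0) {
    posns <- sample.int(n, k)
    chars <- strsplit(s, "")[[1]]
    chars[posns] <- vapply(chars[posns], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    s <- paste(chars, collapse = "")
  }
  if (inherits(genome, "annotated_genome")) {
    genome$sequence <- s
    genome
  } else s
}
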