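#' End-to-end comparison of a genome trio
#'
#' Runs every analysis stage on three genomes and collects a structured
#' report: ori calls and reorientation, pairwise ANI and tetranucleotide
#' correlations, collinear blocks with signed permutation, exact reversal
#' distance, scenario and transposase-flank summary, CRISPR spacer
#' classification and lineage inference, concatenated-marker apomorphy
#' counts, a chimera scan of the surface-gene family, and CDS overlap
#' refinement. A failing stage is recorded as failed while the others
#' proceed.
#'
#' @param genomes named list of three [annotated_genome()] objects.
#' @param marker_refs named vector of marker reference proteins
#'   (see [extract_markers()]); stage skipped when NULL.
#' @param crispr_repeat,crispr_leader CRISPR repeat/leader sequences;
#'   CRISPR stage skipped when the repeat is NULL.
#' @param surface_query,surface_parents locus tags (query and two
#'   candidate parents, as `genome:locus_tag`) for the chimera scan;
#'   skipped when NULL.
#' @param expressed_ids locus tags found in the proteome, for refinement.
#' @param reorient_genomes reorient each genome into the canonical dnaA
#'   frame before comparison (default TRUE).
#' @return A `trio_report` list; see the methods vignette for the schema.
#' @export
compare_trio <- function(genomes,
                         marker_refs = NULL,
                         crispr_repeat = NULL,
                         crispr_leader = NULL,
                         surface_query = NULL,
                         surface_parents = NULL,
                         expressed_ids = character(0),
                         reorient_genomes = TRUE) {
  stopifnot(length(genomes) == 3L, !is.null(names(genomes)))
  ids <- names(genomes)
  report <- list(genomes = ids, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      structure(list(message = conditionMessage(e)), class = "stage_failure"))
    report$stages[[name]] <<- if (inherits(res, "stage_failure"))
      list(status = "failed", error = res$message)
    else c(list(status = "ok"), res)
    invisible(NULL)
  }

  stage("replichore", {
    oris <- lapply(genomes, function(g) find_ori(g))
    if (reorient_genomes) {
      genomes <<- Map(function(g, oc) reorient(g, oc), genomes, oris)
    }
    list(ori = lapply(oris, function(o)
      list(chosen_dnaA = o$chosen_dnaA, ori_position = o$ori_position,
           confidence = o$confidence)),
      reoriented = reorient_genomes)
  })

  pair_idx <- utils::combn(3L, 2L)
  pair_name <- apply(pair_idx, 2, function(p) paste(ids[p], collapse = "_"))

  stage("signatures", {
    sigs <- lapply(genomes, tetra_signature)
    tetra <- setNames(apply(pair_idx, 2, function(p)
      tetra_correlation(sigs[[p[1]]], sigs[[p[2]]])), pair_name)
    anis <- setNames(apply(pair_idx, 2, function(p)
      ani(genomes[[p[1]]], genomes[[p[2]]])$ani), pair_name)
    list(tetra = as.list(tetra), ani = as.list(anis))
  })

  stage("rearrange", {
    out <- list()
    for (j in seq_len(ncol(pair_idx))) {
      p <- pair_idx[, j]
      bm <- find_blocks(genomes[[p[1]]], genomes[[p[2]]])
      if (!nrow(bm$blocks)) {
        out[[pair_name[j]]] <- list(n_blocks = 0L)
        next
      }
      perm <- to_signed_permutation(bm)
      d <- reversal_distance(perm, topology = "circular")
      fl <- flank_transposases(bm, genomes[[p[1]]], genomes[[p[2]]])
      out[[pair_name[j]]] <- list(
        n_blocks = nrow(bm$blocks), permutation = perm,
        reversal_distance = d,
        scenario_length = reversal_scenario(perm, "circular")$distance,
        transposase_flank_fraction = fl$fraction_flanked)
    }
    out
  })

  if (!is.null(crispr_repeat)) {
    stage("crispr", {
      arrays <- lapply(genomes, function(g) {
        arr <- find_array(g, crispr_repeat)
        if (!length(arr)) stop("no CRISPR array found in ", g$id)
        arr <- arr[[which.max(vapply(arr, function(a) length(a$spacers),
                                     integer(1)))]]
        orient_by_leader(arr, crispr_leader)
      })
      arrays <- orient_by_context(arrays)
      cl <- cluster_spacers(arrays)
      aln <- align_arrays(cl$ids)
      cls <- classify_spacers(aln)
      ord <- infer_order(aln)
      list(n_spacers = lapply(arrays, function(a) length(a$spacers)),
           counts = as.list(cls$counts), n_clusters = cls$n_clusters,
           earliest_diverged = ord$earliest_diverged,
           sister_pair = ord$sister_pair,
           support = as.list(ord$support))
    })
  }

  if (!is.null(marker_refs)) {
    stage("divergence", {
      ms <- extract_markers(genomes, marker_refs)
      concat <- align_and_concat(ms)
      nt <- count_apomorphies(concat, "nt")
      aa <- count_apomorphies(concat, "aa")
      list(alignment_nt_length = ncol(concat$nt),
           alignment_aa_length = ncol(concat$aa),
           apomorphies_nt = as.list(nt$counts),
           apomorphies_aa = as.list(aa$counts),
           excluded_markers = concat$excluded)
    })
  }

  if (!is.null(surface_query) && !is.null(surface_parents)) {
    stage("hybridscan", {
      get_prot <- function(spec) {
        parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
        feature_protein(genomes[[parts[1]]], parts[2])
      }
      q <- get_prot(surface_query)
      pa <- get_prot(surface_parents[1])
      pb <- get_prot(surface_parents[2])
      call <- call_chimera(q, pa, pb)
      list(is_hybrid = call$is_hybrid, breakpoints = call$breakpoints,
           identity_query_parent_a = global_identity(q, pa, "protein"),
           identity_query_parent_b = global_identity(q, pb, "protein"),
           identity_parents = global_identity(pa, pb, "protein"))
    })
  }

  stage("refine", {
    out <- lapply(genomes, function(g) {
      dec <- overlap_refine(g, expressed_ids = expressed_ids, genome = g)
      list(kept = length(dec$kept), removed = length(dec$removed),
           removed_tags = names(dec$removed))
    })
    out
  })

  structure(report, class = "trio_report")
}

#' @export
print.trio_report <- function(x, ...) {
  cat(sprintf("<trio_report> %s\n", paste(x$genomes, collapse = " / ")))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s\n", nm,
                if (st$status == "ok") "ok" else paste("FAILED:", st$error)))
  }
  invisible(x)
}
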