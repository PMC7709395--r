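#' Annotated genome container
#'
#' Bundles a nucleotide sequence with its typed features (CDS, rRNA, tRNA,
#' repeats, ...) and topology. Coordinates are 1-based inclusive throughout,
#' matching GenBank, GFF3 and the Bioconductor range conventions.
#'
#' @param id genome identifier (e.g. a strain name or accession).
#' @param sequence nucleotide string over A/C/G/T/N. Ambiguity codes are
#'   normalized to N with a warning.
#' @param topology `"circular"` or `"linear"`.
#' @param features a data frame with columns `locus_tag`, `type`, `start`,
#'   `end`, `strand`, `product` (missing columns are filled). A feature
#'   spanning the origin junction of a circular genome must be stored as two
#'   parts sharing a locus tag, flagged in the `part` column.
#' @param source free-text provenance (file name or accession).
#'
#' @return An object of class `annotated_genome` with elements `id`,
#'   `sequence`, `topology`, `features`, `source`.
#' @export
annotated_genome <- function(id, sequence, topology = c("circular", "linear"),
                             features = NULL, source = "") {
  topology <- match.arg(topology)
  sequence <- normalize_sequence(sequence, paste0("genome ", id))
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  features <- as_feature_table(features)
  len <- nchar(sequence)
  if (nrow(features)) {
    bad <- features$start < 1L | features$end > len | features$start > features$end
    if (any(bad)) {
      stop("feature coordinates outside [1, ", len, "] or inverted: ",
           paste(features$locus_tag[bad], collapse = ", "))
    }
  }
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features, source = source),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp (%s), %d features\n",
              x$id, format(nchar(x$sequence), big.mark = ","), x$topology,
              nrow(x$features)))
  invisible(x)
}

#' @export
genome_length <- function(genome) nchar(genome$sequence)

# canonical empty/filled feature table
as_feature_table <- function(features) {
  cols <- c("locus_tag", "type", "start", "end", "strand", "product", "part")
  if (is.null(features) || (is.data.frame(features) && nrow(features) == 0L)) {
    return(data.frame(locus_tag = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      part = integer(0), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(features))
  if (is.null(features$locus_tag)) stop("features need a locus_tag column")
  if (is.null(features$type)) features$type <- "CDS"
  if (is.null(features$strand)) features$strand <- "+"
  if (is.null(features$product)) features$product <- ""
  if (is.null(features$part)) features$part <- NA_integer_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features <- features[order(features$start, features$locus_tag,
                             features$part, na.last = TRUE), , drop = FALSE]
  rownames(features) <- NULL
  features[, cols]
}

#' Sequence and translation of an annotated feature
#'
#' `feature_seq` returns the strand-aware nucleotide sequence of a
#' feature (junction-spanning parts are joined); `feature_protein`
#' translates a CDS with the bacterial genetic code, dropping the
#' trailing stop.
#'
#' @param genome an [annotated_genome()].
#' @param locus_tag the feature's locus tag.
#' @return A nucleotide or protein string.
#' @export
feature_seq <- function(genome, locus_tag) {
  ft <- genome$features[genome$features$locus_tag == locus_tag, , drop = FALSE]
  if (!nrow(ft)) stop("no feature with locus_tag ", locus_tag)
  ft <- ft[order(ifelse(is.na(ft$part), 1L, ft$part)), , drop = FALSE]
  s <- paste(substring(genome$sequence, ft$start, ft$end), collapse = "")
  if (ft$strand[1] == "-") s <- revcomp(s)
  s
}

#' @rdname feature_seq
#' @export
feature_protein <- function(genome, locus_tag) {
  nt <- feature_seq(genome, locus_tag)
  aa <- translate_dna(nt)
  sub("\\*$", "", aa)
}

# vectorized extraction and translation of all (non-split) CDS
cds_table <- function(genome) {
  cds <- genome$features[genome$features$type == "CDS" &
                           is.na(genome$features$part), , drop = FALSE]
  if (!nrow(cds)) {
    return(data.frame(locus_tag = character(0), nt = character(0),
                      aa = character(0), stringsAsFactors = FALSE))
  }
  nt <- substring(genome$sequence, cds$start, cds$end)
  neg <- cds$strand == "-"
  if (any(neg)) {
    nt[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(nt[neg])))
  }
  trimmed <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(trimmed),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  data.frame(locus_tag = cds$locus_tag, nt = nt, aa = sub("\\*$", "", aa),
             stringsAsFactors = FALSE)
}
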