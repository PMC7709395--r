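#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @return The reverse-complemented string. `revcomp(revcomp(s))` is `s`.
#' @export
revcomp <- function(seq) {
  if (grepl("[^ACGTN]", seq)) {
    stop("illegal character in sequence: revcomp expects A/C/G/T/N")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# codon -> amino acid lookup (transl_table 11), cached
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::getGeneticCode("11")
    tab
  }
})

# bacterial/plastid genetic code (transl_table 11); standard codon->aa map,
# stops rendered '*'
translate_dna <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) stop("sequence too short to translate (< 3 nt)")
  if (n == 3L) { # single codon: plain table lookup
    aa <- codon_table()[seq]
    return(unname(ifelse(is.na(aa), "X", aa)))
  }
  seq <- substr(seq, 1L, n - n %% 3L)
  as.character(Biostrings::translate(
    Biostrings::DNAString(seq),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
}

#' Six-frame translation
#'
#' Translates all six reading frames with the bacterial genetic code
#' (transl_table 11). Stop codons are rendered as `*`; partial trailing
#' codons are dropped.
#'
#' @param seq nucleotide string, length at least 3.
#' @return Named character vector of the six peptides
#'   (`F1`,`F2`,`F3`,`R1`,`R2`,`R3`).
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3L) stop("sequence too short for translation (< 3 nt)")
  rc <- revcomp(seq)
  frames <- c(
    F1 = substring(seq, 1), F2 = substring(seq, 2), F3 = substring(seq, 3),
    R1 = substring(rc, 1), R2 = substring(rc, 2), R3 = substring(rc, 3))
  vapply(frames, function(s) {
    if (nchar(s) < 3L) "" else translate_dna(s)
  }, character(1))
}

#' Rotate a circular genome to a new start position
#'
#' The base at `new_start` becomes position 1. Features are re-coordinated
#' modulo the genome length; a feature that comes to span the origin
#' junction is split into two parts sharing its locus tag (`part` 1 and 2).
#'
#' @param genome an [annotated_genome()]; must be circular.
#' @param new_start 1-based position that becomes position 1.
#' @return The rotated `annotated_genome`.
#' @export
rotate_genome <- function(genome, new_start) {
  if (genome$topology != "circular") stop("cannot rotate a linear genome")
  len <- genome_length(genome)
  new_start <- ((as.integer(new_start) - 1L) %% len) + 1L
  if (new_start == 1L) return(genome)
  seq2 <- paste0(substring(genome$sequence, new_start, len),
                 substring(genome$sequence, 1L, new_start - 1L))
  ft <- genome$features
  if (nrow(ft)) {
    # merge previously split junction features before remapping
    ft <- merge_junction_parts(ft, len)
    ns <- ((ft$start - new_start) %% len) + 1L
    ne <- ((ft$end - new_start) %% len) + 1L
    out <- vector("list", nrow(ft))
    for (i in seq_len(nrow(ft))) {
      row <- ft[i, , drop = FALSE]
      if (ns[i] <= ne[i]) {
        row$start <- ns[i]; row$end <- ne[i]; row$part <- NA_integer_
        out[[i]] <- row
      } else { # wraps the new junction: split
        p1 <- row; p1$start <- ns[i]; p1$end <- len; p1$part <- 1L
        p2 <- row; p2$start <- 1L; p2$end <- ne[i]; p2$part <- 2L
        out[[i]] <- rbind(p1, p2)
      }
    }
    ft <- do.call(rbind, out)
    ft <- ft[order(ft$start, ft$locus_tag), , drop = FALSE]
    rownames(ft) <- NULL
  }
  genome$sequence <- seq2
  genome$features <- ft
  genome
}

# rejoin part-1/part-2 rows into single (possibly junction-spanning,
# coordinate start>end virtualized via start - len) intervals
merge_junction_parts <- function(ft, len) {
  split_tags <- unique(ft$locus_tag[!is.na(ft$part)])
  if (!length(split_tags)) return(ft)
  keep <- ft[is.na(ft$part), , drop = FALSE]
  for (tag in split_tags) {
    parts <- ft[ft$locus_tag == tag & !is.na(ft$part), , drop = FALSE]
    parts <- parts[order(parts$part), , drop = FALSE]
    row <- parts[1, , drop = FALSE]
    # represent wrap as start in (1..len), end = end2 + len, then re-modulo
    row$end <- parts$end[nrow(parts)] + len
    row$part <- NA_integer_
    keep <- rbind(keep, row)
  }
  # normalize virtual ends back into modular arithmetic domain used above:
  # (start - new_start) %% len works for start; for end we let the %% wrap it
  keep
}

#' Reverse-complement a whole annotated genome
#'
#' @param genome an [annotated_genome()].
#' @return The genome with reverse-complemented sequence and remapped
#'   features (strands flipped).
#' @export
revcomp_genome <- function(genome) {
  len <- genome_length(genome)
  genome$sequence <- revcomp(genome$sequence)
  ft <- genome$features
  if (nrow(ft)) {
    s <- len - ft$end + 1L
    e <- len - ft$start + 1L
    ft$start <- s
    ft$end <- e
    ft$strand <- ifelse(ft$strand == "+", "-", "+")
    # split parts swap roles
    ft$part <- ifelse(is.na(ft$part), NA_integer_, 3L - ft$part)
    ft <- ft[order(ft$start, ft$locus_tag), , drop = FALSE]
    rownames(ft) <- NULL
    genome$features <- ft
  }
  genome
}

#' Read a genome with annotations
#'
#' @param path file path.
#' @param format `"fasta"`, `"genbank"`, or `"gff3"` (GFF3 with its
#'   companion FASTA either embedded after `##FASTA` or given via
#'   `fasta_path`).
#' @param fasta_path companion FASTA for `format = "gff3"` when the
#'   sequence is not embedded.
#' @param topology `"circular"` or `"linear"`; for GenBank input the LOCUS
#'   line wins.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(path, format = c("fasta", "genbank", "gff3"),
                        fasta_path = NULL,
                        topology = c("circular", "linear")) {
  format <- match.arg(format)
  topology <- match.arg(topology)
  switch(format,
         fasta = read_genome_fasta(path, topology),
         genbank = read_genome_genbank(path),
         gff3 = read_genome_gff3(path, fasta_path, topology))
}

read_genome_fasta <- function(path, topology) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("no sequence record in ", path)
  if (length(ss) > 1L) {
    warning("multiple records in ", path, "; using the first")
  }
  id <- sub("\\s.*$", "", names(ss)[1])
  annotated_genome(id, as.character(ss[[1]]), topology, source = path)
}

read_genome_gff3 <- function(path, fasta_path, topology) {
  lines <- readLines(path)
  fasta_at <- which(lines == "##FASTA")
  seq <- NULL
  if (length(fasta_at)) {
    tf <- tempfile(fileext = ".fa")
    writeLines(lines[(fasta_at[1] + 1L):length(lines)], tf)
    ss <- Biostrings::readDNAStringSet(tf)
    unlink(tf)
    seq <- as.character(ss[[1]])
    id <- sub("\\s.*$", "", names(ss)[1])
    lines <- lines[seq_len(fasta_at[1] - 1L)]
  } else if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    seq <- as.character(ss[[1]])
    id <- sub("\\s.*$", "", names(ss)[1])
  } else {
    stop("gff3 input needs an embedded ##FASTA section or fasta_path")
  }
  tf <- tempfile(fileext = ".gff3")
  writeLines(lines, tf)
  gr <- rtracklayer::import(tf, format = "gff3")
  unlink(tf)
  md <- S4Vectors::mcols(gr)
  n <- length(gr)
  get_col <- function(nm, default) {
    if (nm %in% colnames(md)) {
      v <- as.character(md[[nm]])
      v[is.na(v)] <- default
      v
    } else rep(default, n)
  }
  ft <- data.frame(
    locus_tag = get_col("locus_tag", NA_character_),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = get_col("product", ""),
    stringsAsFactors = FALSE)
  no_tag <- is.na(ft$locus_tag)
  ft$locus_tag[no_tag] <- get_col("ID", NA_character_)[no_tag]
  ft$strand[!ft$strand %in% c("+", "-")] <- "+"
  ft <- ft[ft$type != "region", , drop = FALSE]
  annotated_genome(id, seq, topology, ft, source = path)
}

#' Write a genome with annotations
#'
#' FASTA output holds the sequence only; GenBank output uses 1-based
#' inclusive coordinates and survives a read/write round trip field-wise;
#' GFF3 output embeds the sequence after a `##FASTA` divider.
#'
#' @param genome an [annotated_genome()].
#' @param path output file path.
#' @param format `"fasta"`, `"genbank"`, or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, format = c("fasta", "genbank", "gff3")) {
  format <- match.arg(format)
  switch(format,
         fasta = {
           ss <- Biostrings::DNAStringSet(genome$sequence)
           names(ss) <- genome$id
           Biostrings::writeXStringSet(ss, path)
         },
         genbank = write_genome_genbank(genome, path),
         gff3 = write_genome_gff3(genome, path))
  invisible(path)
}

write_genome_gff3 <- function(genome, path) {
  ft <- genome$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$id,
                     genome_length(genome)), con)
  if (nrow(ft)) {
    attrs <- sprintf("ID=%s%s;locus_tag=%s%s",
                     ft$locus_tag,
                     ifelse(is.na(ft$part), "", paste0(".part", ft$part)),
                     ft$locus_tag,
                     ifelse(ft$product == "", "",
                            paste0(";product=", gsub("[;=\t]", "_", ft$product))))
    tab <- data.frame(genome$id, "straintrio", ft$type, ft$start, ft$end,
                      ".", ft$strand, ".", attrs)
    write.table(tab, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  writeLines("##FASTA", con)
  writeLines(paste0(">", genome$id), con)
  s <- genome$sequence
  starts <- seq(1L, nchar(s), by = 70L)
  writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
}
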