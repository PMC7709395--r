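# Minimal GenBank flat-file reader/writer: LOCUS, FEATURES (source/CDS/
# rRNA/tRNA/repeat_region/misc_feature with locus_tag and product
# qualifiers, complement() and two-part join() locations), ORIGIN.
# Coordinates stay 1-based inclusive, so a read/write round trip is
# field-wise exact.

read_genome_genbank <- function(path) {
  lines <- readLines(path)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file (no LOCUS line): ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("malformed GenBank record (no ORIGIN) in ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L

  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(seq)) stop("missing sequence in GenBank record ", path)

  features <- list()
  if (length(feat_i) && feat_i[1] + 1L < orig_i[1]) {
    block <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) { # new feature
        if (!is.null(cur)) features[[length(features) + 1L]] <- cur
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(type = parts[1], location = parts[2],
                    locus_tag = NA_character_, product = "")
      } else if (!is.null(cur) && grepl("^ {10,}\\S", ln)) {
        q <- trimws(ln)
        if (startsWith(q, "/locus_tag=")) {
          cur$locus_tag <- gsub("\"", "", sub("/locus_tag=", "", q))
        } else if (startsWith(q, "/product=")) {
          cur$product <- gsub("\"", "", sub("/product=", "", q))
        } else if (!startsWith(q, "/")) { # continuation of a location
          cur$location <- paste0(cur$location, q)
        }
      }
    }
    if (!is.null(cur)) features[[length(features) + 1L]] <- cur
  }

  rows <- list()
  auto <- 0L
  for (f in features) {
    if (f$type == "source") next
    loc <- f$location
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    segs <- if (grepl("^join\\(", loc)) {
      strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
    } else loc
    type <- if (f$type == "repeat_region") "repeat" else f$type
    tag <- f$locus_tag
    if (is.na(tag)) {
      auto <- auto + 1L
      tag <- sprintf("%s_feat%04d", id, auto)
    }
    for (k in seq_along(segs)) {
      m <- regmatches(segs[k], regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", segs[k]))[[1]]
      if (length(m) != 3L) stop("unparsable location '", f$location,
                                "' for feature ", tag, " in ", path)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_tag = tag, type = type,
        start = as.integer(m[2]), end = as.integer(m[3]),
        strand = strand, product = f$product,
        part = if (length(segs) > 1L) k else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  ft <- if (length(rows)) do.call(rbind, rows) else NULL
  annotated_genome(id, seq, topology, ft, source = path)
}

write_genome_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  len <- genome_length(genome)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s BCT",
                     genome$id, len, genome$topology), con)
  writeLines(sprintf("DEFINITION  %s.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  ft <- genome$features
  if (nrow(ft)) {
    # emit split junction features as a single join() location
    tags <- unique(ft$locus_tag)
    for (tag in tags) {
      rows <- ft[ft$locus_tag == tag, , drop = FALSE]
      rows <- rows[order(ifelse(is.na(rows$part), 1L, rows$part)), , drop = FALSE]
      loc <- paste(sprintf("%d..%d", rows$start, rows$end), collapse = ",")
      if (nrow(rows) > 1L) loc <- sprintf("join(%s)", loc)
      if (rows$strand[1] == "-") loc <- sprintf("complement(%s)", loc)
      type <- if (rows$type[1] == "repeat") "repeat_region" else rows$type[1]
      writeLines(sprintf("     %-15s %s", type, loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", tag), con)
      if (nzchar(rows$product[1])) {
        writeLines(sprintf("                     /product=\"%s\"",
                           rows$product[1]), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  for (i in seq(1L, nchar(s), by = 60L)) {
    chunk <- substring(s, i, min(i + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
}
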