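# shared fixture builders

cds_frame <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(locus_tag = r[[1]], type = "CDS", start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = "+", product = "",
               stringsAsFactors = FALSE)))
}
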