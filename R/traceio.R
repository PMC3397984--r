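#' Write a trace to tab-separated text
#'
#' Plain TSV with a commented header carrying provenance metadata
#' (configuration hash, master seed, column units) so that any output file
#' identifies the run that produced it.
#'
#' @param trace A trace data.frame.
#' @param path Output path.
#' @param meta Named list of metadata (e.g. `seed`, `config_hash`,
#'   `kind`); written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    cat("# ", nm, ": ", format(meta[[nm]]), "\n", sep = "", file = con)
  }
  utils::write.table(trace, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path Input path.
#' @return The trace data.frame, with the header metadata attached as
#'   attribute `"meta"` (a named character list).
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 100L)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  out <- utils::read.delim(path, comment.char = "#", sep = "\t")
  attr(out, "meta") <- meta
  out
}
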