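#' @include AllClasses.R
NULL

#' Read / write tab-separated analysis tables
#'
#' Plain TSV with header, no quoting surprises; the schemas are those
#' documented on the stage functions (plate tables, OCR traces, DEG tables,
#' flux records).
#'
#' @param path file path.
#' @param table data.frame to write.
#' @return `readTSV`: a data.frame; `writeTSV`: the path, invisibly.
#' @name tsv
NULL

#' @rdname tsv
#' @export
readTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname tsv
#' @export
writeTSV <- function(table, path) {
  utils::write.table(
    table, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
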