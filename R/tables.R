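# Lossless delimited-table I/O. All exported tables are comma-delimited UTF-8
# with a header row; numeric columns are serialized with %.17g so that a
# write -> read -> write cycle is byte-identical (17 significant digits
# round-trip IEEE doubles exactly).

#' Write a data frame as a lossless CSV
#'
#' @param records data.frame (may have zero rows; a header-only file is then
#'   written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stopf("records must be a data.frame")
  cols <- lapply(records, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else if (is.logical(col) || is.integer(col)) {
      as.character(col)
    } else {
      col <- as.character(col)
      if (any(grepl('[",\n]', col, useBytes = TRUE)))
        col <- paste0('"', gsub('"', '""', col), '"')
      col
    }
  })
  lines <- paste(names(records), collapse = ",")
  if (nrow(records) > 0L)
    lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
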