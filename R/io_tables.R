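## Plain-TSV readers/writers. Every file starts with '#'-prefixed header
## lines recording provenance; grid coordinates are always 0-based (row, col),
## row 0 at image top.

write_tsv_commented <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in c("# coordinates: 0-based (row, col), row 0 at top", header))
    writeLines(paste0("# ", sub("^# ?", "", h)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_commented <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a colony-size table against a plate layout
#'
#' The TSV must have columns `plate_id, row, col, size`. Every layout
#' position becomes a row of the result; positions absent from the file (or
#' with size `NA`) are recorded as absent (`size = NA`, `flag_empty = TRUE`),
#' never as zero: a dead pin and a non-growing strain are different evidence.
#'
#' @param path TSV file path.
#' @param layout a [plate_layout()].
#' @return a `colony_table` data.frame with columns
#'   `plate_id, row, col, strain, is_control, size, flag_empty`.
#' @export
read_colony_table <- function(path, layout) {
  tab <- read_tsv_commented(path)
  assert_cols(tab, c("plate_id", "row", "col", "size"), "colony table")
  key <- paste(tab$plate_id, tab$row, tab$col)
  if (anyDuplicated(key))
    stopf("duplicate (plate, row, col) entries in %s", path)
  dims <- layout_dims(layout)
  bad <- tab$row < 0 | tab$row >= dims["rows"] |
    tab$col < 0 | tab$col >= dims["cols"]
  if (any(bad))
    stopf("%d position(s) outside the %dx%d grid in %s",
          sum(bad), dims["rows"], dims["cols"], path)
  if (any(!is.na(tab$size) & tab$size < 0))
    stopf("negative colony size in %s", path)
  out <- as.data.frame(layout)
  out$size <- tab$size[match(paste(out$plate_id, out$row, out$col), key)]
  out$flag_empty <- is.na(out$size)
  class(out) <- c("colony_table", "data.frame")
  attr(out, "condition") <- attr(layout, "condition")
  out
}

#' Write a colony table to TSV
#' @param table a `colony_table` data.frame.
#' @param path output path.
#' @param header extra header comment lines.
#' @export
write_colony_table <- function(table, path, header = character()) {
  write_tsv_commented(as.data.frame(table), path,
                      c(header, paste0("condition: ",
                                       attr(table, "condition") %||% "NA")))
}

as_colony_table <- function(df, condition = NULL) {
  assert_cols(df, c("plate_id", "row", "col", "strain", "size"))
  if (is.null(df$flag_empty)) df$flag_empty <- is.na(df$size)
  class(df) <- c("colony_table", "data.frame")
  if (!is.null(condition)) attr(df, "condition") <- condition
  df
}
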