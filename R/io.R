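## Plain-text table input/output for the two pipelines. Probe-level input
## is a TSV/CSV with header probe_set_id, PM, MM; bead-level input has
## header bead_type_id, intensity. UTF-8, decimal point; the delimiter is
## sniffed from the header line.

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a probe-level table
#'
#' @param path TSV or CSV file with columns `probe_set_id`, `PM`, `MM`.
#' @return A data frame.
#' @export
read_probe_level <- function(path) {
  tab <- read_delim_auto(path)
  if (!all(c("probe_set_id", "PM", "MM") %in% names(tab)))
    stop("probe-level input needs columns: probe_set_id, PM, MM")
  tab
}

#' Read a bead-level table
#'
#' @param path TSV or CSV file with columns `bead_type_id`, `intensity`.
#' @return A data frame.
#' @export
read_bead_level <- function(path) {
  tab <- read_delim_auto(path)
  if (!all(c("bead_type_id", "intensity") %in% names(tab)))
    stop("bead-level input needs columns: bead_type_id, intensity")
  tab
}

#' Write a result table as TSV
#'
#' Floats are printed with 6 significant digits; the column order of the
#' input is preserved.
#'
#' @param table a data frame (e.g. from [summarize_chip()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(table, path) {
  fmt <- as.data.frame(lapply(table, function(col) {
    if (is.double(col)) signif(col, 6) else col
  }))
  names(fmt) <- names(table)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
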