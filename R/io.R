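#' Read and write the pipeline's plain-text formats
#'
#' Count tables are TSV with samples as rows and taxa as columns (first
#' column `sample_id`); metadata is TSV keyed by `sample_id`; sensor series
#' are CSV with ISO-8601 `timestamp`, `rh`, `temp`; spectra are CSV with
#' `wavelength_nm`, `intensity`; dissimilarity matrices are labeled TSV;
#' trees are Newick (via \pkg{ape}).
#'
#' @param path file path.
#' @param table,dm,series,spec,metadata objects to write.
#' @param ... passed on to the underlying reader/writer.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @name haloscape_io
NULL

#' @rdname haloscape_io
#' @export
read_count_table <- function(path, ...) {
  df <- utils::read.delim(path, check.names = FALSE, ...)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  .check_count_table(m)
  m
}

#' @rdname haloscape_io
#' @export
write_count_table <- function(table, path) {
  .check_count_table(table)
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname haloscape_io
#' @export
read_metadata <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' @rdname haloscape_io
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname haloscape_io
#' @export
read_sensor_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, ...)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  sensor_series(ts, df$rh, df$temp)
}

#' @rdname haloscape_io
#' @export
write_sensor_csv <- function(series, path) {
  series <- .as_sensor_series(series)
  df <- data.frame(timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
                   rh = series$rh, temp = series$temp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname haloscape_io
#' @export
read_spectrum_csv <- function(path, ...) {
  df <- utils::read.csv(path, ...)
  spectrum(df$wavelength_nm, df$intensity)
}

#' @rdname haloscape_io
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(as.data.frame(spec)[c("wavelength_nm", "intensity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname haloscape_io
#' @export
read_dissimilarity_tsv <- function(path, ...) {
  df <- utils::read.delim(path, check.names = FALSE, ...)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  .check_dissimilarity(m)
  m
}

#' @rdname haloscape_io
#' @export
write_dissimilarity_tsv <- function(dm, path) {
  .check_dissimilarity(dm)
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
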