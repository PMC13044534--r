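#' Read a per-cell measurement table
#'
#' Reads a CSV/TSV cell table and translates common cell-detection export
#' dialects (e.g. QuPath column headers such as "Centroid X µm") into the
#' package's canonical columns (`cell_id`, `image_id`, `sample_id`, `site`,
#' `x_um`, `y_um`, marker columns).
#'
#' @param path File path (delimiter inferred from the extension).
#' @param header_map Named character vector mapping source column names to
#'   canonical names; defaults cover the QuPath measurement-export dialect.
#' @return Cell table data frame.
#' @export
read_cell_table <- function(path, header_map = qupath_header_map()) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  hit <- names(df) %in% names(header_map)
  names(df)[hit] <- header_map[names(df)[hit]]
  df
}

#' @rdname read_cell_table
#' @export
qupath_header_map <- function() {
  c("Object ID" = "cell_id",
    "Image" = "image_id",
    "Centroid X µm" = "x_um",
    "Centroid Y µm" = "y_um")
}

#' Write a cell or event table as CSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_cell_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
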