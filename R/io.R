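#' Read and write the pipeline's plain-text interchange formats
#'
#' Long-format growth tables (`row`, `col`, `time_h`, `cells`), plate
#' layouts (`row`, `col`, `is_control`), bedGraph depth tracks (`chrom`,
#' `start`, `end`, `depth`; 0-based half-open, no header), BED6 gene
#' annotations, and qPCR Ct tables are all tab-separated text.
#'
#' @param x The object to write (a tibble in the respective layout; for
#'   `write_plate_set`, a `plate_set`).
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name mtdrift-io
NULL

#' @rdname mtdrift-io
#' @export
read_plate_curves <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    row = readr::col_integer(), col = readr::col_integer(),
    time_h = readr::col_double(), cells = readr::col_double()))
}

#' @rdname mtdrift-io
#' @export
read_plate_layout <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    row = readr::col_integer(), col = readr::col_integer(),
    is_control = readr::col_logical()))
}

#' @rdname mtdrift-io
#' @param dir Directory in which to write the plate files.
#' @param stem File-name stem (default `"plate"`).
#' @export
write_plate_set <- function(x, dir, stem = "plate") {
  stopifnot(inherits(x, "plate_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  curves <- file.path(dir, paste0(stem, "_curves.tsv"))
  layout <- file.path(dir, paste0(stem, "_layout.tsv"))
  truth <- file.path(dir, paste0(stem, "_truth.json"))
  readr::write_tsv(x$curves, curves)
  readr::write_tsv(x$layout, layout)
  jsonlite::write_json(x$truth, truth, digits = NA)
  invisible(c(curves = curves, layout = layout, truth = truth))
}

#' @rdname mtdrift-io
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    depth = readr::col_double()))
}

#' @rdname mtdrift-io
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(x)))
  readr::write_tsv(x[, c("chrom", "start", "end", "depth")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname mtdrift-io
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "name", "score",
                                "strand"),
                  col_types = "ciicic")
}

#' @rdname mtdrift-io
#' @export
write_bed6 <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(x)))
  if (!"score" %in% names(x)) x$score <- 0L
  if (!"strand" %in% names(x)) x$strand <- "+"
  readr::write_tsv(
    x[, c("chrom", "start", "end", "name", "score", "strand")],
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname mtdrift-io
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), timepoint = readr::col_double(),
    replicate = readr::col_integer(), Ct_target = readr::col_double(),
    Ct_reference = readr::col_double()))
}
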