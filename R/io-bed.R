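#' Read a BED3/BED6 file into an interval tibble
#'
#' Coordinates follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. BED files are tab-separated with no header.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\nchr1\t200\t300", tf)
#' read_bed(tf)
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE, comment = "#")
  if (ncol(x) < 3) abort("BED file must have at least 3 columns")
  nms <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- nms[seq_len(min(ncol(x), 6L))]
  x <- x[, seq_len(min(ncol(x), 6L))]
  x$chrom <- as.character(x$chrom)
  validate_intervals(x)
  as_tibble(x)
}

#' Write intervals to a BED file
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`); 0-based half-open coordinates.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: stop at the first absent optional column
  upto <- which(cumsum(!c("chrom", "start", "end", "name", "score",
                          "strand") %in% keep) == 0)
  cols <- c("chrom", "start", "end", "name", "score", "strand")[upto]
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(x)
}

#' Read a bedGraph signal track
#'
#' A signal track is a run-length encoding of per-base non-negative values:
#' one row per run, 0-based half-open intervals with a `value` column.
#'
#' @param path Path to a bedGraph file (4 tab-separated columns, no header).
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  x$chrom <- as.character(x$chrom)
  validate_intervals(x)
  if (any(x$value < 0)) abort("signal track values must be non-negative")
  as_tibble(x)
}

#' Write a signal track as bedGraph
#'
#' @param track Track tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return `track`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(track)
}

#' Read a chromosome-sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length in bp.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       show_col_types = FALSE, progress = FALSE)
  x$chrom <- as.character(x$chrom)
  if (any(x$length <= 0)) abort("chromosome lengths must be positive")
  as_tibble(x)
}

#' Read single-bp cut-site records
#'
#' Expects the BED-like dialect written by [write_cut_sites()]:
#' `chrom`, `start` (= pos), `end` (= pos + 1), `umi`, `sample_id`, `strand`.
#'
#' @param path Input path.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `strand`, `umi`.
#' @export
read_cut_sites <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "umi", "sample_id", "strand"),
    col_types = "ciiccc", progress = FALSE)
  if (any(x$end != x$start + 1L)) {
    abort("cut-site records must be single-bp (end == start + 1)")
  }
  tibble(sample_id = x$sample_id, chrom = x$chrom, pos = x$start,
         strand = x$strand, umi = x$umi)
}

#' Write cut-site records in BED-like form
#'
#' @param records Cut-site tibble (`sample_id`, `chrom`, `pos`, `strand`,
#'   `umi`); `pos` is the 0-based single-bp break end.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_cut_sites <- function(records, path) {
  out <- tibble(chrom = records$chrom, start = records$pos,
                end = records$pos + 1L, umi = records$umi,
                sample_id = records$sample_id, strand = records$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(records)
}
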