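# Interval algebra over 0-based half-open intervals. The heavy lifting
# (merging, base-level coverage, overlap search) is delegated to
# GenomicRanges/IRanges; tibbles in, tibbles out.

validate_intervals <- function(x, what = "interval") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort(paste0(what, " table must have columns chrom, start, end"))
  }
  bad <- which(is.na(x$chrom) | x$chrom == "" | is.na(x$start) |
                 is.na(x$end) | x$start < 0 | x$end <= x$start)
  if (length(bad)) {
    abort(sprintf(
      "malformed %s at row %d: chrom='%s', start=%s, end=%s (need end > start >= 0)",
      what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

# GRanges -> tibble, sorted deterministically
gr_tbl <- function(gr) {
  tb <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  arrange(tb, .data$chrom, .data$start, .data$end)
}

empty_intervals <- function() {
  tibble(chrom = character(), start = integer(), end = integer())
}

#' Merge intervals that lie within a bp gap of each other
#'
#' Any two input intervals on the same chromosome separated by at most `gap`
#' bp end up in one output interval (`gap = 0` merges touching/overlapping
#' intervals only). The union of covered bases is preserved, extended only by
#' the bridged gaps. Mirrors the "peaks within 150 bp were merged" step of
#' CUT&RUN peak post-processing.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param gap Maximum separation in bp that is still merged. Default 0.
#' @return A sorted tibble of non-overlapping intervals.
#' @export
#' @examples
#' merge_intervals(
#'   tibble::tibble(chrom = "c1", start = c(0, 200, 600), end = c(100, 300, 700)),
#'   gap = 150)
merge_intervals <- function(intervals, gap = 0) {
  stopifnot(gap >= 0)
  if (nrow(intervals) == 0) return(empty_intervals())
  validate_intervals(intervals)
  gr <- GenomicRanges::reduce(as_gr(intervals), min.gapwidth = gap + 1L)
  gr_tbl(gr)
}

#' Reproducible peaks: bases covered by at least m of n replicate peak sets
#'
#' Computes the base-level coverage-depth profile of the `n` sets (each set
#' contributing at most depth 1 per base), thresholds it at `m` and segments
#' the result into maximal intervals. Symmetric in replicate order, unlike an
#' anchor-replicate intersection. This is the "peaks found in m out of n
#' replicates" rule used for sBLISS (5/8), NPAS4 CUT&RUN (4/5) and
#' ATAC/H3K27ac (3/3) reproducibility.
#'
#' @param peak_sets List of interval tibbles, one per replicate.
#' @param m Minimum number of replicates that must cover a base.
#' @return A sorted tibble of non-overlapping intervals.
#' @export
reproducible_peaks <- function(peak_sets, m) {
  n <- length(peak_sets)
  if (m < 1 || m > n) {
    abort(sprintf("m must satisfy 1 <= m <= number of sets (%d), got %s",
                  n, format(m)))
  }
  sets <- map(peak_sets, function(s) {
    if (nrow(s) == 0) return(NULL)
    validate_intervals(s)
    GenomicRanges::reduce(as_gr(s))
  })
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (length(sets) < m) return(empty_intervals())
  all_gr <- suppressWarnings(do.call(c, unname(sets)))
  cvg <- GenomicRanges::coverage(all_gr)
  hit <- methods::as(cvg >= m, "GRanges")
  hit <- hit[S4Vectors::mcols(hit)$score]
  if (length(hit) == 0) return(empty_intervals())
  gr_tbl(hit)
}

# signal track tibble -> named RleList of per-base values (runs are summed if
# they overlap; bedGraph runs are normally disjoint)
track_rle <- function(track, chrom_sizes = NULL) {
  validate_intervals(track, "track")
  gr <- as_gr(track)
  if (!is.null(chrom_sizes)) {
    sl <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    GenomeInfoDb_ok <- tryCatch({
      GenomicRanges::seqlengths(gr) <- sl[GenomicRanges::seqlevels(gr)]
      TRUE
    }, error = function(e) FALSE)
    if (!GenomeInfoDb_ok) abort("track extends beyond declared chromosome bounds")
  }
  GenomicRanges::coverage(gr, weight = track$value)
}

#' Summit-centred fixed-width windows
#'
#' For each interval, finds the position of the maximum track value within the
#' interval (ties broken at the smallest coordinate) and returns the window
#' `[summit - half_width, summit + half_width)`, width exactly `2 * half_width`.
#' An all-zero signal falls back to the interval midpoint and is flagged.
#' Windows are clipped at 0 and at the declared chromosome length (when
#' `chrom_sizes` is given) and flagged, not dropped.
#'
#' @param intervals Interval tibble.
#' @param track Signal track tibble (`chrom`, `start`, `end`, `value`).
#' @param half_width Half-width in bp (500 for the regulatory landscape).
#' @param chrom_sizes Optional tibble (`chrom`, `length`) for boundary
#'   clipping.
#' @return A tibble with columns `chrom`, `start`, `end`, `summit`,
#'   `no_signal`, `clipped`.
#' @export
summit_window <- function(intervals, track, half_width, chrom_sizes = NULL) {
  stopifnot(half_width > 0)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer(), no_signal = logical(),
                  clipped = logical()))
  }
  validate_intervals(intervals)
  rle <- track_rle(track)
  out <- intervals
  out$summit <- NA_integer_
  out$no_signal <- FALSE
  for (cm in unique(out$chrom)) {
    idx <- which(out$chrom == cm)
    v <- if (cm %in% names(rle)) rle[[cm]] else S4Vectors::Rle(0, 0)
    for (i in idx) {
      s0 <- out$start[i]; e0 <- out$end[i]
      if (length(v) < e0) v <- c(v, S4Vectors::Rle(0, e0 - length(v)))
      seg <- as.numeric(v[(s0 + 1L):e0])
      # run-length weight arithmetic can leave ~1e-16 residues on zero bases
      seg[abs(seg) < 1e-9] <- 0
      if (all(seg == 0)) {
        out$summit[i] <- as.integer(floor((s0 + e0) / 2))
        out$no_signal[i] <- TRUE
      } else {
        out$summit[i] <- s0 + which.max(seg) - 1L
      }
    }
  }
  start_w <- out$summit - as.integer(half_width)
  end_w <- out$summit + as.integer(half_width)
  clip_lo <- start_w < 0
  start_w[clip_lo] <- 0L
  clip_hi <- rep(FALSE, nrow(out))
  if (!is.null(chrom_sizes)) {
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)[out$chrom]
    clip_hi <- !is.na(len) & end_w > len
    end_w[clip_hi] <- as.integer(len[clip_hi])
  }
  tibble(chrom = out$chrom, start = as.integer(start_w),
         end = as.integer(end_w), summit = out$summit,
         no_signal = out$no_signal, clipped = clip_lo | clip_hi)
}

#' Build the regulatory-element landscape
#'
#' Takes reproducible accessibility (ATAC) and H3K27ac peak sets (already
#' concatenated over time points), forms their union, merges it, optionally
#' subtracts a blacklist, and replaces each merged region with a fixed-width
#' window centred on the maximal accessibility summit. Each element records
#' whether it arose from accessibility peaks, acetylation peaks, or both.
#'
#' @param atac_reproducible,k27_reproducible Interval tibbles of reproducible
#'   peaks per assay.
#' @param atac_track Accessibility signal track used for summit finding.
#' @param half_width Window half-width in bp (default 500, giving 1-kb
#'   elements).
#' @param merge_gap Gap used when merging the union (default 0).
#' @param blacklist Optional interval tibble subtracted from the merged union
#'   before windows are formed. None is shipped.
#' @param chrom_sizes Optional tibble for boundary clipping.
#' @return A tibble of regulatory elements: `element_id`, `chrom`, `start`,
#'   `end`, `summit`, `source` (`"ATAC"`, `"K27ac"` or `"both"`),
#'   `no_signal`, `clipped`.
#' @export
build_landscape <- function(atac_reproducible, k27_reproducible, atac_track,
                            half_width = 500, merge_gap = 0, blacklist = NULL,
                            chrom_sizes = NULL) {
  un <- merge_intervals(bind_rows(atac_reproducible, k27_reproducible),
                        gap = merge_gap)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    validate_intervals(blacklist, "blacklist")
    kept <- GenomicRanges::setdiff(as_gr(un), GenomicRanges::reduce(as_gr(blacklist)))
    un <- gr_tbl(kept)
  }
  if (nrow(un) == 0) {
    return(tibble(element_id = character(), chrom = character(),
                  start = integer(), end = integer(), summit = integer(),
                  source = character(), no_signal = logical(),
                  clipped = logical()))
  }
  from_atac <- overlaps_any(un, atac_reproducible)
  from_k27 <- overlaps_any(un, k27_reproducible)
  src <- dplyr::case_when(from_atac & from_k27 ~ "both",
                          from_atac ~ "ATAC",
                          TRUE ~ "K27ac")
  win <- summit_window(un, atac_track, half_width, chrom_sizes = chrom_sizes)
  mutate(win,
         element_id = sprintf("el_%04d", row_number()),
         source = src) |>
    relocate("element_id")
}

# logical vector: does each row of x share >= min_overlap bases with any of y
overlaps_any <- function(x, y, min_overlap = 1L) {
  if (nrow(x) == 0) return(logical(0))
  if (is.null(y) || nrow(y) == 0) return(rep(FALSE, nrow(x)))
  GenomicRanges::countOverlaps(as_gr(x), as_gr(y),
                               minoverlap = min_overlap) > 0
}

#' Flag elements that overlap a peak set
#'
#' Half-open overlap: an element `[0, 500)` overlaps a peak `[499, 600)` but
#' not `[500, 600)`.
#'
#' @param elements Element tibble (`chrom`, `start`, `end`, ...).
#' @param peaks Interval tibble of peaks (e.g. binding-factor peak calls,
#'   already extended to their final width).
#' @param min_overlap Minimum shared bases (default 1).
#' @return `elements` with a logical `overlaps_peak` column added.
#' @export
overlap_flag <- function(elements, peaks, min_overlap = 1L) {
  validate_intervals(elements, "element")
  mutate(elements, overlaps_peak = overlaps_any(elements, peaks, min_overlap))
}

#' Extend peaks to fixed width around their summit of signal
#'
#' Convenience wrapper reproducing the peak post-processing used before
#' overlap tests: binding-factor peaks are replaced by fixed windows around
#' their maximal-signal position (±500 bp for NPAS4-style 1-kb peaks, ±200 bp
#' for other factors).
#'
#' @param peaks Interval tibble.
#' @param track Signal track for the factor.
#' @param half_width Half-width in bp; 500 for NPAS4-style peaks, 200
#'   otherwise.
#' @param chrom_sizes Optional tibble for clipping.
#' @return Tibble of fixed-width peak windows.
#' @export
extend_peaks <- function(peaks, track, half_width = 200, chrom_sizes = NULL) {
  summit_window(peaks, track, half_width, chrom_sizes = chrom_sizes)
}
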