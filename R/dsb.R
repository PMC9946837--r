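# sBLISS-style cut-site quantification: UMI deduplication, per-element break
# counts, binding-quartile stratification and downsampled genome-wide totals.

validate_cut_sites <- function(records) {
  need <- c("sample_id", "chrom", "pos", "strand", "umi")
  if (!all(need %in% names(records))) {
    abort(paste("cut-site records need columns:", paste(need, collapse = ", ")))
  }
  if (any(records$pos < 0)) abort("cut-site pos must be >= 0")
  if (!all(records$strand %in% c("+", "-"))) {
    abort("cut-site strand must be '+' or '-'")
  }
  invisible(records)
}

#' Deduplicate cut-site records to unique break events
#'
#' A unique event is one `(chrom, pos, strand, umi)` tuple per sample; reads
#' sharing all four keys are PCR duplicates of the same ligation event. The
#' event key includes strand by default (two opposing free ends at one bp are
#' distinct breaks); set `key_strand = FALSE` to collapse strands.
#' Deduplication is idempotent and order-invariant.
#'
#' @param records Cut-site tibble (`sample_id`, `chrom`, `pos`, `strand`,
#'   `umi`).
#' @param key_strand Include strand in the event key (default TRUE).
#' @return Tibble of unique events (same columns), sorted; per-sample input
#'   read and unique event totals are available via [dedup_stats()].
#' @export
dedup_cut_sites <- function(records, key_strand = TRUE) {
  validate_cut_sites(records)
  keys <- c("sample_id", "chrom", "pos", if (key_strand) "strand", "umi")
  events <- records |>
    distinct(across(dplyr::all_of(keys))) |>
    arrange(across(dplyr::all_of(keys)))
  stats <- records |>
    count(.data$sample_id, name = "total_reads") |>
    left_join(count(events, .data$sample_id, name = "unique_events"),
              by = "sample_id")
  attr(events, "dedup_stats") <- stats
  events
}

#' Per-sample read and unique-event totals from a deduplicated set
#'
#' @param events Output of [dedup_cut_sites()].
#' @return Tibble `sample_id`, `total_reads`, `unique_events`.
#' @export
dedup_stats <- function(events) {
  st <- attr(events, "dedup_stats")
  if (is.null(st)) abort("no dedup_stats attribute; run dedup_cut_sites() first")
  st
}

#' Count unique break events per regulatory element
#'
#' Counts unique events whose single-bp cut site falls inside each element
#' (`start <= pos < end`, half-open; only the 1-bp cut end is quantified).
#' Strand is ignored. Events outside every element are dropped. Landscape
#' elements are summit-centred windows and may overlap; an event inside two
#' elements counts in both.
#'
#' @param events Deduplicated events from [dedup_cut_sites()].
#' @param elements Element tibble with `element_id`, `chrom`, `start`, `end`.
#' @return Wide count tibble: one row per element (`element_id` first column),
#'   one integer column per sample. Every element appears, zero-filled.
#' @export
element_counts <- function(events, elements) {
  validate_intervals(elements, "element")
  samples <- sort(unique(events$sample_id))
  ev_gr <- GenomicRanges::GRanges(events$chrom,
                                  IRanges::IRanges(events$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(ev_gr, as_gr(elements))
  tallied <- tibble(
    sample_id = events$sample_id[S4Vectors::queryHits(hits)],
    element_id = elements$element_id[S4Vectors::subjectHits(hits)]) |>
    count(.data$element_id, .data$sample_id)
  out <- tallied |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)
  scaffold <- tibble(element_id = elements$element_id)
  out <- left_join(scaffold, out, by = "element_id")
  for (s in samples) {
    if (!s %in% names(out)) out[[s]] <- 0L
    out[[s]][is.na(out[[s]])] <- 0L
  }
  out[, c("element_id", samples)]
}

#' Stratify elements into binding quartiles with peak-gated extremes
#'
#' Ranks elements by their control-normalized binding ratio (aggregate
#' binding signal over the element divided by aggregate IgG signal plus a
#' floor `eps`), splits the ranking into four equal-count quartiles (Q1
#' lowest ... Q4 highest; ties broken by a stable sort on ratio, chrom,
#' start), and gates the extremes on peak evidence: `q4_high` elements are in
#' Q4 *and* overlap a binding peak; `q1_low` elements are in Q1 *and* do not.
#'
#' @param elements Element tibble (`element_id`, `chrom`, `start`, `end`).
#' @param numerator_track Binding signal track (e.g. factor CUT&RUN).
#' @param denominator_track Control signal track (e.g. IgG).
#' @param peaks Interval tibble of binding peaks (extended to final width).
#' @param eps Denominator floor in read-depth units (default 1); elements
#'   with zero denominator are still ranked (ratio = numerator / eps) and
#'   flagged.
#' @return `elements` with columns `numerator`, `denominator`, `ratio`,
#'   `zero_denominator`, `quartile` (`"Q1"`..`"Q4"`), `overlaps_peak`,
#'   `q4_high`, `q1_low`.
#' @export
quartile_stratify <- function(elements, numerator_track, denominator_track,
                              peaks, eps = 1) {
  if (nrow(elements) == 0) {
    return(mutate(elements, numerator = numeric(), denominator = numeric(),
                  ratio = numeric(), zero_denominator = logical(),
                  quartile = character(), overlaps_peak = logical(),
                  q4_high = logical(), q1_low = logical()))
  }
  num <- track_sums(elements, numerator_track)
  den <- track_sums(elements, denominator_track)
  out <- elements |>
    mutate(numerator = num, denominator = den,
           zero_denominator = den == 0,
           ratio = num / (den + eps),
           overlaps_peak = overlaps_any(elements, peaks))
  ord <- order(out$ratio, out$chrom, out$start)  # stable, deterministic
  n <- nrow(out)
  q <- integer(n)
  q[ord] <- ceiling(seq_len(n) * 4 / n)
  out |>
    mutate(quartile = paste0("Q", q),
           q4_high = .data$quartile == "Q4" & .data$overlaps_peak,
           q1_low = .data$quartile == "Q1" & !.data$overlaps_peak)
}

# aggregate (summed) track signal over each element
track_sums <- function(elements, track) {
  rle <- track_rle(track)
  vapply(seq_len(nrow(elements)), function(i) {
    cm <- elements$chrom[i]
    if (!cm %in% names(rle)) return(0)
    v <- rle[[cm]]
    e0 <- min(elements$end[i], length(v))
    s0 <- elements$start[i]
    if (e0 <= s0) return(0)
    sum(as.numeric(v[(s0 + 1L):e0]))
  }, numeric(1))
}

#' Genome-wide unique-break totals at matched read depth
#'
#' Input reads (pre-dedup records) of every sample are downsampled without
#' replacement to the lowest per-sample read count, then deduplicated, and
#' the unique-event (UMI) total is reported per sample. Identical seed gives
#' identical output. Downsampling operates on reads, not unique events,
#' matching how raw libraries are depth-matched before UMI totals are
#' compared.
#'
#' @param records Cut-site records for two or more samples.
#' @param seed Integer seed for the downsampling draws.
#' @param key_strand Passed to [dedup_cut_sites()].
#' @return Tibble `sample_id`, `total_reads`, `downsampled_reads`,
#'   `unique_events`.
#' @export
genomewide_breaks <- function(records, seed, key_strand = TRUE) {
  validate_cut_sites(records)
  counts <- count(records, .data$sample_id, name = "total_reads")
  if (nrow(counts) < 2) abort("genomewide_breaks needs at least 2 samples")
  if (any(counts$total_reads == 0)) abort("sample with zero reads")
  r_min <- min(counts$total_reads)
  withr::with_seed(seed, {
    sampled <- counts$sample_id |>
      sort() |>
      map(function(s) {
        rows <- which(records$sample_id == s)
        records[sort(sample(rows, r_min)), , drop = FALSE]
      }) |>
      list_rbind()
  })
  ev <- dedup_cut_sites(sampled, key_strand = key_strand)
  dedup_stats(ev) |>
    rename(downsampled_reads = "total_reads") |>
    left_join(select(counts, "sample_id", "total_reads"), by = "sample_id") |>
    select("sample_id", "total_reads", "downsampled_reads", "unique_events")
}
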