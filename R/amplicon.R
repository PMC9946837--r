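# Targeted-amplicon UMI consensus. Reads arrive pre-aligned to the amplicon
# reference and carry their deviations from it in a compact call string; a
# family of reads sharing (amplicon, UMI) contributes to a position only when
# every member makes the identical call there (unanimity) and the family has
# at least `min_depth` members -- the consensus-10 standard.

#' Construct and validate an amplicon panel
#'
#' @param x Tibble with one row per amplicon: `amplicon_id`, `chrom`, `start`,
#'   `end` (0-based half-open target interval), `ref_seq` (reference sequence,
#'   length `end - start`), and optionally `primer_len` (default 22) and
#'   `umi_len` (default 12) and a `bound` label (TRUE for binding-factor-bound
#'   sites).
#' @return The validated panel tibble with `primer_len`/`umi_len` filled in.
#' @export
amplicon_panel <- function(x) {
  need <- c("amplicon_id", "chrom", "start", "end", "ref_seq")
  if (!all(need %in% names(x))) {
    abort(paste("panel needs columns:", paste(need, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (!"primer_len" %in% names(x)) x$primer_len <- 22L
  if (!"umi_len" %in% names(x)) x$umi_len <- 12L
  validate_intervals(x, "amplicon")
  bad <- which(nchar(x$ref_seq) != x$end - x$start)
  if (length(bad)) {
    abort(sprintf("amplicon '%s': reference length %d != interval width %d",
                  x$amplicon_id[bad[1]], nchar(x$ref_seq[bad[1]]),
                  x$end[bad[1]] - x$start[bad[1]]))
  }
  if (any(x$primer_len >= nchar(x$ref_seq))) {
    abort("primer_len must be smaller than the reference length")
  }
  if (anyDuplicated(x$amplicon_id)) abort("duplicated amplicon_id in panel")
  x
}

#' Read a FASTA of amplicon reference sequences
#'
#' Header lines are taken as amplicon ids (first whitespace-delimited token).
#' Returns a tibble suitable for joining into [amplicon_panel()].
#'
#' @param path FASTA path.
#' @return Tibble with `amplicon_id`, `ref_seq`.
#' @export
read_amplicon_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("no FASTA headers found")
  id <- sub("^>", "", lines[hdr])
  id <- vapply(strsplit(id, "\\s+"), `[[`, character(1), 1)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1),
                 collapse = "")
  tibble(amplicon_id = id, ref_seq = toupper(unname(seqs)))
}

# Parse call strings into a long deviation table.
#
# Syntax (documented for the TSV reader): semicolon-separated operations,
# each anchored at a 1-based amplicon position; "" means the read matches the
# reference everywhere.
#   "37G"     substitution: read calls G at position 37
#   "41-"     single-base deletion at position 41
#   "12+ACG"  insertion of ACG anchored immediately right of position 12
parse_calls <- function(calls, read_id) {
  has <- which(!is.na(calls) & calls != "")
  if (!length(has)) {
    return(tibble(read_id = character(), pos = integer(),
                  op = character(), alt = character()))
  }
  parts <- strsplit(calls[has], ";", fixed = TRUE)
  ids <- rep(read_id[has], lengths(parts))
  tok <- unlist(parts, use.names = FALSE)
  m <- regmatches(tok, regexec("^([0-9]+)([ACGT]|-|\\+[ACGT]+)$", tok))
  bad <- lengths(m) == 0
  if (any(bad)) {
    abort(sprintf("malformed call token '%s' (read %s)",
                  tok[bad][1], ids[bad][1]))
  }
  pos <- as.integer(vapply(m, `[[`, character(1), 2))
  body <- vapply(m, `[[`, character(1), 3)
  op <- ifelse(body == "-", "del", ifelse(startsWith(body, "+"), "ins", "sub"))
  alt <- ifelse(op == "ins", substring(body, 2), body)
  alt[op == "del"] <- "-"
  tibble(read_id = ids, pos = pos, op = op, alt = alt)
}

#' Group amplicon reads into exact-match UMI families
#'
#' Reads are partitioned by `(amplicon_id, umi)` with exact UMI matching (no
#' edit-distance collapsing; the 12-nt UMI space is vastly larger than the
#' template count at assay scale). Reads whose UMI contains a character
#' outside A/C/G/T are discarded and tallied.
#'
#' @param reads Tibble with columns `amplicon_id`, `umi`, `calls` (call
#'   string, see [read_amplicon_reads()]).
#' @param umi_qc Also attach the near-duplicate UMI report from
#'   [umi_qc_report()] as attribute `umi_qc` (default FALSE).
#' @return The retained reads with `family_id` and `family_size` columns
#'   added; attribute `n_discarded` counts reads dropped for invalid UMIs.
#' @export
group_umi_families <- function(reads, umi_qc = FALSE) {
  stopifnot(all(c("amplicon_id", "umi", "calls") %in% names(reads)))
  ok <- grepl("^[ACGT]+$", reads$umi)
  n_discarded <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  key <- paste(reads$amplicon_id, reads$umi, sep = "\r")
  fam <- match(key, unique(key))
  size <- tabulate(fam)
  out <- mutate(as_tibble(reads),
                family_id = sprintf("fam_%06d", fam),
                family_size = size[fam])
  attr(out, "n_discarded") <- n_discarded
  if (umi_qc) attr(out, "umi_qc") <- umi_qc_report(out)
  out
}

#' Report near-duplicate UMI pairs per amplicon
#'
#' Counts pairs of distinct UMIs within an amplicon at Hamming distance 1 --
#' the pairs an edit-distance network would have collapsed. Exact-match
#' grouping keeps them separate (the 12-nt UMI space dwarfs the template
#' count); this report quantifies how much that choice could matter.
#'
#' @param reads Read tibble with `amplicon_id`, `umi`.
#' @return Tibble `amplicon_id`, `n_umis`, `n_near_duplicate_pairs`.
#' @export
umi_qc_report <- function(reads) {
  fam <- distinct(reads, .data$amplicon_id, .data$umi)
  fam |>
    group_by(.data$amplicon_id) |>
    summarise(n_umis = dplyr::n(),
              n_near_duplicate_pairs = hamming1_pairs(.data$umi),
              .groups = "drop")
}

# number of unordered pairs at Hamming distance 1: hash each UMI under every
# single-position wildcard; colliding keys mark neighbouring pairs
hamming1_pairs <- function(umis) {
  if (length(umis) < 2) return(0L)
  len <- nchar(umis[1])
  total <- 0L
  for (p in seq_len(len)) {
    masked <- paste0(substr(umis, 1, p - 1), ".", substr(umis, p + 1, len))
    cnt <- table(masked)
    total <- total + sum(choose(cnt, 2))
  }
  as.integer(total)
}

#' Per-position consensus composition at the unanimity standard
#'
#' A family contributes one count at position `p` iff its size is at least
#' `min_depth` and every member read makes the identical call at `p`
#' (reference base, the same substitution, the same deletion, or the same
#' inserted sequence at the same anchor). Families below `min_depth`
#' contribute nowhere; non-unanimous positions receive no count from that
#' family, in either numerator or denominator.
#'
#' @param reads Output of [group_umi_families()] (or a tibble with
#'   `amplicon_id`, `umi`, `calls`, which is grouped on the fly).
#' @param panel Amplicon panel from [amplicon_panel()].
#' @param min_depth Minimum family size (default 10, the consensus-10
#'   standard).
#' @return Consensus table: one row per (amplicon, position) with columns
#'   `amplicon_id`, `pos` (1-based), `ref` (reference base), `n_families`
#'   (unanimous families at that position), base-call counts `n_A`, `n_C`,
#'   `n_G`, `n_T`, `n_del`, `n_ins` (families unanimously carrying an
#'   identical insertion anchored there), and `n_alt` (families whose
#'   unanimous call differs from the reference in any way). The base-call and
#'   deletion counts sum to `n_families`.
#' @export
consensus_composition <- function(reads, panel, min_depth = 10) {
  stopifnot(min_depth >= 1)
  if (!"family_id" %in% names(reads)) reads <- group_umi_families(reads)
  panel <- amplicon_panel(panel)
  reads <- filter(reads, .data$family_size >= min_depth)
  reads$read_id <- sprintf("r%08d", seq_len(nrow(reads)))

  n_qual <- reads |>
    distinct(.data$amplicon_id, .data$family_id, .data$family_size) |>
    count(.data$amplicon_id, name = "n_qual")

  # dense scaffold: every amplicon position starts at n_families = n_qual,
  # all families unanimous-reference; the sparse deviation pass adjusts it
  scaffold <- panel |>
    left_join(n_qual, by = "amplicon_id") |>
    mutate(n_qual = dplyr::coalesce(.data$n_qual, 0L)) |>
    dplyr::reframe(pos = seq_len(nchar(.data$ref_seq)),
                   ref = strsplit(.data$ref_seq, "")[[1]],
                   n_qual = .data$n_qual,
                   .by = "amplicon_id")

  dev <- parse_calls(reads$calls, reads$read_id)
  pos_adjust <- if (nrow(dev) == 0) {
    tibble(amplicon_id = character(), pos = integer(), lost = integer(),
           call = character(), n_call = integer())
  } else {
    ridx <- match(dev$read_id, reads$read_id)
    dev$family_id <- reads$family_id[ridx]
    dev$amplicon_id <- reads$amplicon_id[ridx]
    dev$family_size <- reads$family_size[ridx]
    L <- setNames(nchar(panel$ref_seq), panel$amplicon_id)
    if (any(dev$pos < 1 | dev$pos > L[dev$amplicon_id])) {
      abort("call position outside amplicon reference")
    }
    # a read's call signature at a position = its sorted ops there; almost
    # every (read, pos) carries a single op, so collapse only the rest
    dev$sig <- paste0(dev$op, ":", dev$alt)
    rp_key <- paste(dev$read_id, dev$pos)
    multi <- rp_key %in% rp_key[duplicated(rp_key)]
    sig <- dev[!multi, c("amplicon_id", "family_id", "family_size", "pos",
                         "read_id", "sig")]
    if (any(multi)) {
      dm <- dev[multi, ]
      merged <- dm |>
        group_by(.data$amplicon_id, .data$family_id, .data$family_size,
                 .data$pos, .data$read_id) |>
        summarise(sig = paste(sort(.data$sig), collapse = "|"),
                  .groups = "drop")
      sig <- bind_rows(sig, merged)
    }
    fam_pos <- sig |>
      group_by(.data$amplicon_id, .data$family_id, .data$family_size,
               .data$pos) |>
      summarise(n_dev = dplyr::n(),
                n_sig = dplyr::n_distinct(.data$sig),
                sig1 = .data$sig[1],
                .groups = "drop") |>
      mutate(unanimous_alt = .data$n_dev == .data$family_size &
               .data$n_sig == 1L)
    fam_pos |>
      group_by(.data$amplicon_id, .data$pos) |>
      summarise(lost = sum(!.data$unanimous_alt),
                alt_calls = list(.data$sig1[.data$unanimous_alt]),
                .groups = "drop")
  }

  tab <- scaffold |>
    left_join(pos_adjust, by = c("amplicon_id", "pos")) |>
    mutate(lost = dplyr::coalesce(.data$lost, 0L),
           n_families = .data$n_qual - .data$lost)

  # classify unanimous-alt families into composition counts; families with no
  # deviation at the position are unanimous reference calls
  cls <- function(calls, ref, n_fam) {
    n <- c(A = 0L, C = 0L, G = 0L, T = 0L, del = 0L, ins = 0L, alt = 0L)
    for (cl in calls) {
      ops <- strsplit(cl, "|", fixed = TRUE)[[1]]
      op <- sub(":.*$", "", ops)
      alt <- sub("^[a-z]+:", "", ops)
      base <- if ("del" %in% op) "del"
              else if ("sub" %in% op) alt[op == "sub"][1]
              else ref
      n[base] <- n[base] + 1L
      if ("ins" %in% op) n["ins"] <- n["ins"] + 1L
      n["alt"] <- n["alt"] + 1L  # every unanimous-alt family deviates somehow
    }
    n[ref] <- n[ref] + (n_fam - length(calls))
    n
  }
  if (!"alt_calls" %in% names(tab)) tab$alt_calls <- vector("list", nrow(tab))
  counts <- t(mapply(function(calls, ref, n_fam) {
    cls(if (is.null(calls)) character() else calls, ref, n_fam)
  }, tab$alt_calls, tab$ref, tab$n_families))
  tibble(amplicon_id = tab$amplicon_id, pos = tab$pos, ref = tab$ref,
         n_families = tab$n_families,
         n_A = counts[, "A"], n_C = counts[, "C"],
         n_G = counts[, "G"], n_T = counts[, "T"],
         n_del = counts[, "del"], n_ins = counts[, "ins"],
         n_alt = counts[, "alt"])
}

#' Filter amplicons on mean consensus-family depth
#'
#' An amplicon is kept iff the mean of `n_families` over its non-primer
#' positions strictly exceeds `min_mean_depth` (the published inclusion rule:
#' average consensus-10 family count across bases > 100).
#'
#' @param consensus Consensus table from [consensus_composition()].
#' @param panel Amplicon panel (source of `primer_len`).
#' @param min_mean_depth Strict lower bound on the mean (default 100).
#' @return Tibble with `amplicon_id`, `mean_depth`, `kept`.
#' @export
filter_amplicons <- function(consensus, panel, min_mean_depth = 100) {
  pl <- setNames(panel$primer_len, panel$amplicon_id)
  consensus |>
    filter(.data$pos > pl[.data$amplicon_id]) |>
    group_by(.data$amplicon_id) |>
    summarise(mean_depth = mean(.data$n_families), .groups = "drop") |>
    mutate(kept = .data$mean_depth > min_mean_depth)
}

#' Read pre-parsed amplicon reads from TSV
#'
#' Three tab-separated columns with header: `amplicon_id`, `umi`, `calls`.
#' The `calls` column uses the deviation mini-syntax: semicolon-separated
#' operations anchored at 1-based positions, e.g. `"37G;41-;12+ACG"`
#' (substitution, single-base deletion, insertion); empty string for a read
#' matching the reference everywhere.
#'
#' @param path Input path.
#' @return Tibble with `amplicon_id`, `umi`, `calls`.
#' @export
read_amplicon_reads <- function(path) {
  x <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  stopifnot(all(c("amplicon_id", "umi", "calls") %in% names(x)))
  x$calls[is.na(x$calls)] <- ""
  x
}

#' Write a consensus table as TSV
#'
#' @param consensus Consensus table.
#' @param path Output path.
#' @return `consensus`, invisibly.
#' @export
write_consensus_table <- function(consensus, path) {
  readr::write_tsv(consensus, path, progress = FALSE)
  invisible(consensus)
}
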