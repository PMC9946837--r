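# Mutation-frequency estimation from consensus tables, young-median age
# normalization, and robust (ROUT-style) outlier removal.

assessed_positions <- function(consensus, panel) {
  pl <- setNames(panel$primer_len, panel$amplicon_id)
  filter(consensus, .data$pos > pl[.data$amplicon_id])
}

#' Total mutation frequency per amplicon
#'
#' `f_total` is the number of consensus families carrying any change from the
#' reference (substitution, deletion or insertion, each family counted once)
#' divided by the total number of consensus bases assessed (the sum of
#' unanimous-family counts over positions). The first `primer_len` bases --
#' the primer-annealing region -- are excluded from numerator and denominator.
#' A zero denominator yields a missing (`NA`) frequency, never zero.
#'
#' @param consensus Consensus table from [consensus_composition()], optionally
#'   with a `sample_id` column (frequencies are then computed per sample).
#' @param panel Amplicon panel (source of per-amplicon `primer_len`).
#' @return Tibble with `amplicon_id` (and `sample_id` if present), `n_alt`
#'   (mutated-family count), `denominator_bases`, `f_total`.
#' @export
mutation_frequency <- function(consensus, panel) {
  grp <- intersect(c("sample_id", "amplicon_id"), names(consensus))
  assessed_positions(consensus, panel) |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(n_alt = sum(.data$n_alt),
              denominator_bases = sum(.data$n_families),
              .groups = "drop") |>
    mutate(f_total = if_else(.data$denominator_bases > 0,
                             .data$n_alt / .data$denominator_bases,
                             NA_real_))
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A")

# canonical (pyrimidine-reference) collapsed class for ref -> alt
collapse_class <- function(ref, alt) {
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, complement_base[ref], ref)
  a <- ifelse(flip, complement_base[alt], alt)
  paste0(r, ">", a)
}

#' Class-resolved mutation frequencies with complementary-base collapsing
#'
#' Substitutions are collapsed into six classes because the mutated strand is
#' unknown: C>A|G>T, C>G|G>C, C>T|G>A, T>A|A>T, T>C|A>G, T>G|A>C. The
#' numerator of class X>Y counts families unanimously calling Y at
#' reference-X positions plus the complementary change at complementary
#' positions; the denominator is the total consensus-family count over
#' assessed positions whose reference base is X or its complement. The
#' insertion+deletion frequency uses all assessed positions as denominator.
#' Classes with no eligible reference base are missing, not zero.
#'
#' @inheritParams mutation_frequency
#' @return Tibble with one row per (sample,) amplicon and class (`class` in
#'   `"C>A"`, `"C>G"`, `"C>T"`, `"T>A"`, `"T>C"`, `"T>G"`, `"indel"`), with
#'   `numerator`, `denominator_bases`, `frequency`.
#' @export
class_frequencies <- function(consensus, panel) {
  grp <- intersect(c("sample_id", "amplicon_id"), names(consensus))
  tab <- assessed_positions(consensus, panel)
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

  long <- tab |>
    tidyr::pivot_longer(cols = c("n_A", "n_C", "n_G", "n_T"),
                        names_to = "called", names_prefix = "n_",
                        values_to = "n_fam_call") |>
    filter(.data$called != .data$ref, .data$n_fam_call > 0) |>
    mutate(class = collapse_class(.data$ref, .data$called))

  num <- long |>
    group_by(across(dplyr::all_of(c(grp, "class")))) |>
    summarise(numerator = sum(.data$n_fam_call), .groups = "drop")

  # denominator per pyrimidine-reference pair
  den <- tab |>
    mutate(pyr = if_else(.data$ref %in% c("A", "G"),
                         complement_base[.data$ref], .data$ref)) |>
    group_by(across(dplyr::all_of(c(grp, "pyr")))) |>
    summarise(denominator_bases = sum(.data$n_families), .groups = "drop")

  scaffold <- tab |>
    distinct(across(dplyr::all_of(grp))) |>
    tidyr::crossing(class = classes) |>
    mutate(pyr = substr(.data$class, 1, 1))

  subs <- scaffold |>
    left_join(num, by = c(grp, "class")) |>
    left_join(den, by = c(grp, "pyr")) |>
    mutate(numerator = dplyr::coalesce(.data$numerator, 0L),
           denominator_bases = dplyr::coalesce(.data$denominator_bases, 0L),
           frequency = if_else(.data$denominator_bases > 0,
                               .data$numerator / .data$denominator_bases,
                               NA_real_)) |>
    select(-"pyr")

  indel <- tab |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(numerator = sum(.data$n_del) + sum(.data$n_ins),
              denominator_bases = sum(.data$n_families), .groups = "drop") |>
    mutate(class = "indel",
           frequency = if_else(.data$denominator_bases > 0,
                               .data$numerator / .data$denominator_bases,
                               NA_real_))

  bind_rows(subs, indel) |>
    arrange(across(dplyr::all_of(c(grp, "class"))))
}

#' Normalize per-animal mutation frequencies to the young-group median
#'
#' Within each site (amplicon), every animal's total mutation frequency is
#' divided by the median frequency of that site across young animals, so the
#' young group is centred at 1 per site and age groups become comparable fold
#' changes. Sites with no young animal carrying a defined frequency are
#' dropped with a warning; sites whose young median is zero give missing
#' values. Missing input frequencies stay missing and never enter medians.
#'
#' @param profiles Tibble with columns `amplicon_id`, `animal_id`,
#'   `age_group` (`"young"`, `"middle"`, `"old"`), `f_total`.
#' @return Tibble `amplicon_id`, `animal_id`, `age_group`, `value` (fold
#'   change vs young median).
#' @export
normalize_to_young <- function(profiles) {
  stopifnot(all(c("amplicon_id", "animal_id", "age_group", "f_total")
                %in% names(profiles)))
  med <- profiles |>
    filter(.data$age_group == "young", !is.na(.data$f_total)) |>
    group_by(.data$amplicon_id) |>
    summarise(young_median = median(.data$f_total), .groups = "drop")
  dropped <- setdiff(unique(profiles$amplicon_id), med$amplicon_id)
  if (length(dropped)) {
    warn(sprintf("dropping %d site(s) with no defined young frequency: %s",
                 length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  profiles |>
    dplyr::inner_join(med, by = "amplicon_id") |>
    mutate(value = if_else(.data$young_median > 0,
                           .data$f_total / .data$young_median, NA_real_)) |>
    select("amplicon_id", "animal_id", "age_group", "value")
}

#' ROUT-style robust outlier detection for a univariate sample
#'
#' Robust outlier removal controlling a false-discovery rate Q, specialised
#' to a constant (location) model: the robust centre is the median; the
#' robust scale (RSDR) is the 68.27th percentile of absolute residuals with
#' the small-sample correction `n/(n-1)`; each point's t-ratio
#' `|residual|/RSDR` is converted to a two-tailed p-value on `n-1` degrees of
#' freedom and a Benjamini-Hochberg-style step-up at rate `Q` flags the
#' outliers. Constant input yields no outliers; missing values are passed
#' through untested.
#'
#' @param values Numeric vector, at least 3 non-missing values.
#' @param Q Outlier false-discovery rate (default 0.001, i.e. 0.1 percent
#'   confidence).
#' @return Tibble with `value`, `t_ratio`, `p`, `outlier` (NA rows for
#'   missing inputs).
#' @export
rout_outliers <- function(values, Q = 0.001) {
  ok <- !is.na(values)
  x <- values[ok]
  n <- length(x)
  if (n < 3) abort("rout_outliers needs at least 3 non-missing values")
  centre <- median(x)
  res <- x - centre
  rsdr <- unname(quantile(abs(res), 0.6827, type = 7)) * n / (n - 1)
  if (rsdr == 0) {
    t_ratio <- rep(0, n)
    p <- rep(1, n)
    flag <- rep(FALSE, n)
  } else {
    t_ratio <- abs(res) / rsdr
    p <- 2 * pt(-t_ratio, df = n - 1)
    ord <- order(p)
    thresh <- Q * seq_len(n) / n
    passed <- p[ord] <= thresh
    k <- if (any(passed)) max(which(passed)) else 0L
    flag <- rep(FALSE, n)
    if (k > 0) flag[ord[seq_len(k)]] <- TRUE
  }
  out <- tibble(value = values, t_ratio = NA_real_, p = NA_real_,
                outlier = NA)
  out$t_ratio[ok] <- t_ratio
  out$p[ok] <- p
  out$outlier[ok] <- flag
  out
}

#' Plot normalized mutation rates by age group
#'
#' Points are per-site, per-animal normalized rates; crossbars show group
#' means.
#'
#' @param normalized Output of [normalize_to_young()], optionally with a
#'   `bound` column distinguishing binding-factor-bound and unbound sites.
#' @return A ggplot object.
#' @export
plot_mutation_rates <- function(normalized) {
  p <- ggplot2::ggplot(normalized,
                       ggplot2::aes(x = .data$age_group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "mutation frequency (fold vs young median)") +
    ggplot2::theme_minimal()
  if ("bound" %in% names(normalized)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$bound),
                                 labeller = ggplot2::label_both)
  }
  p
}
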