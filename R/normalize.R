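# Count normalization (median-of-ratios), low-count filtering, additive batch
# adjustment on the log scale, and fold-threshold inducibility classification
# with Benjamini-Hochberg control.

counts_matrix <- function(counts) {
  stopifnot("element_id" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), "element_id"), drop = FALSE])
  rownames(m) <- counts$element_id
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

matrix_tbl <- function(m) {
  dplyr::bind_cols(tibble(element_id = rownames(m)), as_tibble(m))
}

#' Low-count element filter
#'
#' Two conventions: `"at_least_two_nonzero"` keeps elements with non-zero
#' counts in at least two samples (used for accessibility, acetylation and
#' damage-mark counts); `"any_nonzero"` keeps elements with at least one
#' non-zero sample (used for the sparser break-end counts).
#'
#' @param counts Wide count tibble (`element_id` + one column per sample).
#' @param mode Filtering convention.
#' @return Tibble `element_id`, `n_nonzero`, `kept`.
#' @export
filter_low_counts <- function(counts,
                              mode = c("at_least_two_nonzero", "any_nonzero")) {
  mode <- match.arg(mode)
  m <- counts_matrix(counts)
  nz <- rowSums(m > 0)
  tibble(element_id = rownames(m), n_nonzero = as.integer(unname(nz)),
         kept = unname(nz) >= if (mode == "at_least_two_nonzero") 2L else 1L)
}

#' Median-of-ratios size factors
#'
#' For each sample `j`, the size factor is the median over elements `i` (with
#' all-positive counts) of `counts[i, j] / geomean_i`, where `geomean_i` is
#' the geometric mean of row `i` across samples; the factors are then
#' rescaled to unit geometric mean. This is the median-of-ratios
#' normalization used for sequencing-depth correction of count matrices.
#'
#' @param counts Wide count tibble.
#' @param pseudo_reference If no element has all-positive counts, setting
#'   this to `TRUE` computes row geometric means over positive entries only
#'   and takes the median ratio over elements with positive geometric mean
#'   (a pseudo-reference fallback for sparse matrices). Default `FALSE`:
#'   error instead.
#' @return Tibble `sample_id`, `size_factor` (positive, unit geometric mean).
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- counts_matrix(counts)
  if (ncol(m) < 1) abort("need at least one sample")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos) && !pseudo_reference) {
    abort(paste("no element has positive counts in every sample;",
                "set pseudo_reference = TRUE to use a positive-entry",
                "pseudo-reference"))
  }
  logm <- log(m)
  logm[!is.finite(logm)] <- NA
  if (any(all_pos)) {
    loggeo <- rowMeans(log(m[all_pos, , drop = FALSE]))
    ratios <- log(m[all_pos, , drop = FALSE]) - loggeo
  } else {
    loggeo <- rowMeans(logm, na.rm = TRUE)
    use <- is.finite(loggeo) & rowSums(!is.na(logm)) > 0
    ratios <- logm[use, , drop = FALSE] - loggeo[use]
  }
  s <- exp(apply(ratios, 2, median, na.rm = TRUE))
  if (any(!is.finite(s) | s <= 0)) abort("degenerate size factors")
  s <- s / exp(mean(log(s)))
  tibble(sample_id = colnames(m), size_factor = unname(s))
}

#' Apply size factors to a count matrix
#'
#' @param counts Wide count tibble.
#' @param sf Size-factor tibble from [size_factors()].
#' @return Wide tibble of normalized values (`counts[i, j] / s_j`).
#' @export
normalize_counts <- function(counts, sf) {
  m <- counts_matrix(counts)
  s <- setNames(sf$size_factor, sf$sample_id)[colnames(m)]
  if (any(is.na(s))) abort("size factors missing for some samples")
  matrix_tbl(sweep(m, 2, s, "/"))
}

#' Remove additive batch effects from log-scale values
#'
#' Fits, per element, an additive two-factor linear model
#' `value ~ condition + batch` by least squares and subtracts the fitted
#' batch component, centred so that batch effects sum to zero weighted by
#' batch sizes (the grand values are preserved; condition contrasts are
#' untouched in balanced designs). With a single batch the input is returned
#' unchanged; a design in which batch and condition are confounded is an
#' error.
#'
#' @param log_normalized Wide tibble of log-scale normalized values
#'   (`element_id` + sample columns), e.g. `log2(normalized + 1)`.
#' @param samples Sample sheet tibble with `sample_id`, `condition`, `batch`.
#' @return Wide tibble of batch-adjusted values.
#' @export
batch_adjust <- function(log_normalized, samples) {
  m <- counts_matrix(log_normalized)
  meta <- samples[match(colnames(m), samples$sample_id), ]
  if (any(is.na(meta$sample_id))) abort("sample sheet missing some samples")
  batch <- factor(meta$batch)
  if (nlevels(batch) < 2) return(as_tibble(log_normalized))
  cond <- factor(meta$condition)
  X <- model.matrix(~ cond + batch)
  if (qr(X)$rank < ncol(X)) {
    abort("batch and condition are confounded; batch effects are not estimable")
  }
  fit <- lm.fit(X, t(m))
  bcols <- grep("^batch", colnames(X))
  beta_b <- fit$coefficients[bcols, , drop = FALSE]
  f <- X[, bcols, drop = FALSE] %*% beta_b       # samples x elements
  f <- sweep(f, 2, colMeans(f))                  # weighted zero-sum centring
  matrix_tbl(m - t(f))
}

#' Fold-threshold inducibility classification
#'
#' For each element, computes the log2 fold change `L` between post- and
#' pre-stimulation group means of `log2(x + pseudocount)` values and tests
#' the one-sided null `H0: L <= log2(fold_threshold)` -- exceedance of the
#' fold threshold, not of zero. By default the per-element variance is
#' moderated across elements (empirical-Bayes shrinkage of the pooled
#' two-group variance via [limma::squeezeVar()]), which pools information
#' exactly where per-element replication (3 vs 3) is too thin to rank true
#' inducible elements reliably; `moderate_var = FALSE` gives the plain Welch
#' t. P-values are Benjamini-Hochberg adjusted across all tested elements,
#' and an element is called inducible iff its fold change reaches the
#' threshold *and* its adjusted p-value is below `alpha`.
#'
#' @param normalized Wide tibble of size-factor-normalized counts.
#' @param samples Sample sheet with `sample_id`, `condition`.
#' @param pre,post Condition labels of the two groups (e.g. `"0h"`, `"2h"`).
#' @param fold_threshold Fold-change threshold on the natural scale: 2 for
#'   accessibility, 1.5 for acetylation.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param pseudocount Added before logs (default 1).
#' @param moderate_var Moderate per-element variances across elements
#'   (default TRUE).
#' @param var_floor Variance floor applied when a replicate group has zero
#'   variance (default 1e-8; applied with a warning).
#' @return Tibble `element_id`, `log2_fc`, `p`, `p_adj`, `inducible`.
#' @export
classify_inducible <- function(normalized, samples, pre, post,
                               fold_threshold = 2, alpha = 0.05,
                               pseudocount = 1, moderate_var = TRUE,
                               var_floor = 1e-8) {
  m <- counts_matrix(normalized)
  meta <- samples[match(colnames(m), samples$sample_id), ]
  i_pre <- which(meta$condition == pre)
  i_post <- which(meta$condition == post)
  if (length(i_pre) < 2 || length(i_post) < 2) {
    abort("need at least 2 replicates per group")
  }
  y <- log2(m + pseudocount)
  n1 <- length(i_pre); n2 <- length(i_post)
  m1 <- rowMeans(y[, i_pre, drop = FALSE])
  m2 <- rowMeans(y[, i_post, drop = FALSE])
  v1 <- apply(y[, i_pre, drop = FALSE], 1, stats::var)
  v2 <- apply(y[, i_post, drop = FALSE], 1, stats::var)
  L <- m2 - m1
  offset <- log2(fold_threshold)

  if (moderate_var) {
    s2_pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    zerovar <- s2_pool < var_floor
    if (any(zerovar)) {
      warn(sprintf("%d element(s) with ~zero replicate variance; floored",
                   sum(zerovar)))
      s2_pool[zerovar] <- var_floor
    }
    sq <- limma::squeezeVar(s2_pool, df = n1 + n2 - 2)
    se <- sqrt(sq$var.post * (1 / n1 + 1 / n2))
    df <- sq$df.prior + (n1 + n2 - 2)
    tstat <- (L - offset) / se
    p <- pt(tstat, df = df, lower.tail = FALSE)
  } else {
    zerovar <- v1 < var_floor & v2 < var_floor
    if (any(zerovar)) {
      warn(sprintf("%d element(s) with ~zero replicate variance; floored",
                   sum(zerovar)))
      v1[v1 < var_floor] <- var_floor
      v2[v2 < var_floor] <- var_floor
    }
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tstat <- (L - offset) / se
    p <- pt(tstat, df = df, lower.tail = FALSE)
  }
  p_adj <- p.adjust(p, method = "BH")
  tibble(element_id = rownames(m), log2_fc = unname(L), p = unname(p),
         p_adj = unname(p_adj),
         inducible = unname(L >= offset & p_adj < alpha))
}

#' Combine per-assay inducibility calls into landscape calls
#'
#' An element is landscape-inducible if called inducible by accessibility
#' (2-fold convention) or by acetylation (1.5-fold convention). Elements
#' absent from an assay (filtered for low counts there) contribute FALSE for
#' that assay.
#'
#' @param ... Named tibbles from [classify_inducible()], e.g.
#'   `atac = ..., k27 = ...`.
#' @return Tibble `element_id`, one logical column per assay, `inducible`
#'   (the union).
#' @export
combine_inducible <- function(...) {
  calls <- list(...)
  stopifnot(length(calls) >= 1, !is.null(names(calls)), all(names(calls) != ""))
  ids <- sort(unique(unlist(map(calls, ~ .x$element_id))))
  out <- tibble(element_id = ids)
  for (nm in names(calls)) {
    v <- unname(setNames(calls[[nm]]$inducible, calls[[nm]]$element_id)[ids])
    out[[paste0("inducible_", nm)]] <- !is.na(v) & v
  }
  out$inducible <- rowSums(as.matrix(out[, -1, drop = FALSE])) > 0
  out
}

#' Plot normalized break counts across the stimulation time course
#'
#' Boxplots of per-element mean normalized counts by condition, faceted by
#' binding quartile: the repair signature appears as a rise at 2 h and a
#' return toward baseline in transcriptionally less-active 10-h samples,
#' concentrated in the top binding quartile.
#'
#' @param normalized Wide tibble of normalized counts.
#' @param samples Sample sheet with `sample_id`, `condition`.
#' @param quartiles Tibble with `element_id`, `quartile` (e.g. from
#'   [quartile_stratify()]).
#' @param condition_order Display order of conditions.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(normalized, samples, quartiles,
                            condition_order = c("0h", "2h", "10h_less",
                                                "10h_still")) {
  long <- normalized |>
    tidyr::pivot_longer(-"element_id", names_to = "sample_id",
                        values_to = "value") |>
    left_join(select(samples, "sample_id", "condition"), by = "sample_id") |>
    group_by(.data$element_id, .data$condition) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    left_join(select(quartiles, "element_id", "quartile"), by = "element_id") |>
    mutate(condition = factor(.data$condition,
                              levels = intersect(condition_order,
                                                 unique(.data$condition))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quartile), nrow = 1) +
    ggplot2::labs(x = NULL, y = "normalized break count (per-element mean)") +
    ggplot2::theme_minimal()
}
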