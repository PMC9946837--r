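# Single-nucleus resampling null: viral-infection assignment from amplified
# transcript counts, the observed target-gene group difference, and its
# empirical null from resampled highly expressed genes.

#' Assign viral infection status from amplified transcript counts
#'
#' A nucleus is labelled `Cre` when its mCherry transcript count strictly
#' exceeds the threshold and GFP does not, `DeltaCre` for the converse,
#' `uninfected` when neither exceeds, and `ambiguous` (excluded from group
#' comparisons, tallied) when both do. The default threshold of 8 transcripts
#' sits above the background detection rate of the amplified viral features.
#'
#' @param nuclei Tibble with `nucleus_id`, `mCherry`, `GFP` count columns.
#' @param threshold Strict lower bound; a count equal to the threshold does
#'   not qualify (default 8, i.e. "more than eight transcripts").
#' @return `nuclei` with an `infection` column added; the number of ambiguous
#'   nuclei is attached as attribute `n_ambiguous`.
#' @export
assign_infection <- function(nuclei, threshold = 8) {
  stopifnot(all(c("mCherry", "GFP") %in% names(nuclei)))
  cre <- nuclei$mCherry > threshold
  dcre <- nuclei$GFP > threshold
  out <- mutate(nuclei, infection = dplyr::case_when(
    cre & dcre ~ "ambiguous",
    cre ~ "Cre",
    dcre ~ "DeltaCre",
    TRUE ~ "uninfected"))
  attr(out, "n_ambiguous") <- sum(cre & dcre)
  out
}

expr_matrix <- function(expr) {
  stopifnot("gene" %in% names(expr))
  m <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  rownames(m) <- expr$gene
  m
}

# per-gene (DeltaCre mean - Cre mean) within a cell type
group_diff_by_gene <- function(expr, nuclei, cell_type) {
  m <- expr_matrix(expr)
  meta <- nuclei[match(colnames(m), nuclei$nucleus_id), ]
  in_type <- meta$cell_type == cell_type
  i_cre <- which(in_type & meta$infection == "Cre")
  i_dcre <- which(in_type & meta$infection == "DeltaCre")
  if (length(i_cre) == 0 || length(i_dcre) == 0) {
    abort(sprintf("cell type '%s' lacks nuclei in one infection group",
                  cell_type))
  }
  list(diff = rowMeans(m[, i_dcre, drop = FALSE]) -
         rowMeans(m[, i_cre, drop = FALSE]),
       mean_expr = rowMeans(m[, in_type, drop = FALSE]))
}

#' Observed target-gene expression difference between infection groups
#'
#' The statistic is the mean over target genes of the per-gene difference in
#' group-mean normalized expression, `DeltaCre - Cre`, within one cell type.
#' Genes downregulated after Cre-mediated deletion push the statistic
#' positive. Target genes absent from the matrix are dropped with a warning.
#'
#' @param expr Normalized expression tibble: `gene` column plus one column
#'   per nucleus.
#' @param nuclei Nucleus metadata with `nucleus_id`, `cell_type`, `infection`
#'   (from [assign_infection()]).
#' @param target_genes Character vector of target gene ids.
#' @param cell_type Cell type within which to compare.
#' @return The observed statistic (a single number).
#' @export
observed_difference <- function(expr, nuclei, target_genes, cell_type) {
  gd <- group_diff_by_gene(expr, nuclei, cell_type)
  missing <- setdiff(target_genes, names(gd$diff))
  if (length(missing)) {
    warn(sprintf("%d target gene(s) absent from matrix, dropped: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
    target_genes <- setdiff(target_genes, missing)
  }
  if (!length(target_genes)) abort("no target genes present in the matrix")
  mean(gd$diff[target_genes])
}

#' Resampling null for target-gene downregulation
#'
#' Because direct targets are highly expressed overall, the null draws
#' matched random gene sets from the top `top_frac` of genes by mean
#' expression across all nuclei of the cell type (regardless of infection).
#' Each of `n_iter` iterations samples `length(target_genes)` pool genes
#' without replacement and recomputes the group-difference statistic; the
#' +1-corrected empirical p-value `(1 + #{null >= observed}) / (1 + n_iter)`
#' (for `alternative = "greater"`) is never zero and bottoms out at
#' `1 / (n_iter + 1)` when the observed statistic lies outside the whole null
#' distribution.
#'
#' @inheritParams observed_difference
#' @param n_iter Number of resampling iterations (default 10000).
#' @param top_frac Fraction of genes forming the highly expressed pool
#'   (default 0.1); the pool is the top `ceiling(top_frac * G)` genes and
#'   must be at least as large as the target set.
#' @param seed Integer seed; identical seeds give identical null
#'   distributions.
#' @param alternative `"greater"` (default; observed more positive than null,
#'   the downregulated-in-Cre orientation), `"less"`, or `"two.sided"`.
#' @return An object of class `null_distribution` with elements `null`
#'   (numeric, length `n_iter`), `observed`, `p`, `n_iter`, `n_targets`,
#'   `pool_size`, `cell_type`, `alternative`, `seed`. See
#'   [tidy.null_distribution()], [glance.null_distribution()],
#'   [autoplot.null_distribution()].
#' @export
resample_null <- function(expr, nuclei, target_genes, cell_type,
                          n_iter = 10000, top_frac = 0.1, seed,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  gd <- group_diff_by_gene(expr, nuclei, cell_type)
  pool_n <- ceiling(top_frac * length(gd$mean_expr))
  pool <- names(sort(gd$mean_expr, decreasing = TRUE))[seq_len(pool_n)]
  n_targets <- length(intersect(target_genes, names(gd$diff)))
  if (pool_n < n_targets) {
    abort(sprintf("top-%g%% pool (%d genes) smaller than target set (%d)",
                  100 * top_frac, pool_n, n_targets))
  }
  observed <- observed_difference(expr, nuclei, target_genes, cell_type)
  pool_diff <- gd$diff[pool]
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_iter),
           function(i) mean(pool_diff[sample.int(pool_n, n_targets)]),
           numeric(1))
  })
  p <- switch(alternative,
              greater = (1 + sum(null >= observed)) / (1 + n_iter),
              less = (1 + sum(null <= observed)) / (1 + n_iter),
              two.sided = (1 + sum(abs(null - mean(null)) >=
                                     abs(observed - mean(null)))) /
                (1 + n_iter))
  structure(list(null = null, observed = observed, p = p, n_iter = n_iter,
                 n_targets = n_targets, pool_size = pool_n,
                 cell_type = cell_type, alternative = alternative,
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Resampling null (", x$cell_type, "): ", x$n_iter,
      " iterations, ", x$n_targets, " genes from a pool of ", x$pool_size,
      "\n", sep = "")
  cat(sprintf("observed = %.4g, empirical p = %.4g (%s)\n",
              x$observed, x$p, x$alternative))
  invisible(x)
}

#' Tidy a resampling null distribution
#'
#' @param x A `null_distribution` object.
#' @param ... Unused.
#' @return Tibble with `iteration`, `statistic`.
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(iteration = seq_len(x$n_iter), statistic = x$null)
}

#' One-row summary of a resampling null test
#'
#' @inheritParams tidy.null_distribution
#' @return One-row tibble: `cell_type`, `observed`, `p_value`, `n_iter`,
#'   `n_targets`, `pool_size`, `alternative`, `seed`.
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(cell_type = x$cell_type, observed = x$observed, p_value = x$p,
         n_iter = x$n_iter, n_targets = x$n_targets,
         pool_size = x$pool_size, alternative = x$alternative,
         seed = x$seed)
}

#' Plot a resampling null distribution with the observed statistic
#'
#' @param object A `null_distribution` object.
#' @param ... Unused.
#' @return A ggplot object: histogram of null statistics, observed value as a
#'   vertical line.
#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy.null_distribution(object),
                  ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = expression(Delta * "Cre - Cre mean expression difference"),
      y = "resamples",
      subtitle = sprintf("observed = %.3g, empirical p = %.3g",
                         object$observed, object$p)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
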