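# Median-of-ratios size factors, low-count filters, batch adjustment,
# fold-threshold inducibility.

cm <- function(m, ids = paste0("e", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(element_id = ids), tibble::as_tibble(m))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("low-count filter implements both stated conventions", {
  x <- cm(rbind(c(0, 0, 0), c(0, 0, 5), c(1, 1, 0)))
  two <- filter_low_counts(x, "at_least_two_nonzero")
  any1 <- filter_low_counts(x, "any_nonzero")
  expect_equal(two$kept, c(FALSE, FALSE, TRUE))
  expect_equal(any1$kept, c(FALSE, TRUE, TRUE))
})

test_that("size factors match hand computation exactly", {
  expect_equal(size_factors(cm(rbind(c(5, 5), c(9, 9))))$size_factor,
               c(1, 1), tolerance = 1e-12)
  got <- size_factors(cm(rbind(c(2, 4), c(8, 16))))$size_factor
  expect_equal(got, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("size factors are row-permutation invariant and scale equivariant", {
  withr::with_seed(8, {
    m <- matrix(rpois(60, 40) + 1, nrow = 12)
    s0 <- size_factors(cm(m))$size_factor
    s_perm <- size_factors(cm(m[sample(12), ]))$size_factor
    expect_equal(s0, s_perm, tolerance = 1e-12)
    # scaling one sample by c multiplies its factor by c up to the global
    # unit-geometric-mean rescale
    m2 <- m
    m2[, 3] <- m2[, 3] * 4
    s2 <- size_factors(cm(m2))$size_factor
    expect_equal(s2[3] / s0[3] / (s2[1] / s0[1]), 4, tolerance = 1e-10)
  })
})

test_that("size factors agree with DESeq2 up to its scaling convention", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(19, {
    m <- matrix(rpois(200, 60) + 1, nrow = 20)
    colnames(m) <- paste0("s", 1:10)
    dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
      countData = m,
      colData = S4Vectors::DataFrame(row.names = colnames(m),
                                     cond = factor(rep(1:2, 5))),
      design = ~1))
    dds <- DESeq2::estimateSizeFactors(dds)
    ref <- DESeq2::sizeFactors(dds)
    got <- size_factors(cm(m))$size_factor
    # DESeq2 does not rescale to unit geometric mean; ratios must agree
    expect_equal(got / got[1], unname(ref / ref[1]), tolerance = 1e-10)
  })
})

test_that("no all-positive row errors unless the pseudo-reference is enabled", {
  x <- cm(rbind(c(0, 3), c(4, 0)))
  expect_error(size_factors(x), "pseudo_reference")
  s <- size_factors(x, pseudo_reference = TRUE)
  expect_true(all(s$size_factor > 0))
})

test_that("normalize_counts divides by factors and round-trips", {
  x <- cm(rbind(c(10, 20), c(30, 40)))
  sf <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(1, 2))
  norm <- normalize_counts(x, sf)
  expect_equal(norm$s2, c(10, 20))
  expect_equal(norm$s1, c(10, 30))
  back <- sweep(as.matrix(norm[, -1]), 2, sf$size_factor, "*")
  expect_equal(unname(back), unname(as.matrix(x[, -1])))
})

test_that("batch adjustment removes a planted offset, preserves contrasts", {
  withr::with_seed(4, {
    n_el <- 50
    samples <- tibble::tibble(
      sample_id = paste0("s", 1:8),
      condition = rep(c("pre", "post"), 4),
      batch = rep(c("A", "B"), each = 4))
    y <- matrix(rnorm(n_el * 8, mean = 8), nrow = n_el)
    colnames(y) <- samples$sample_id
    delta <- 1.7
    y[, samples$batch == "B"] <- y[, samples$batch == "B"] + delta
    cond_diff_before <- rowMeans(y[, samples$condition == "post"]) -
      rowMeans(y[, samples$condition == "pre"])
    adj <- batch_adjust(cm(y), samples)
    madj <- as.matrix(adj[, -1])
    batch_diff <- rowMeans(madj[, samples$batch == "B"]) -
      rowMeans(madj[, samples$batch == "A"])
    expect_true(all(abs(batch_diff) <= 1e-8))
    cond_diff_after <- rowMeans(madj[, samples$condition == "post"]) -
      rowMeans(madj[, samples$condition == "pre"])
    expect_equal(cond_diff_after, cond_diff_before, tolerance = 1e-10)

    # idempotent
    adj2 <- batch_adjust(adj, samples)
    expect_equal(as.data.frame(adj2), as.data.frame(adj), tolerance = 1e-10)

    # single batch: identity
    one <- dplyr::mutate(samples, batch = "A")
    expect_equal(as.data.frame(batch_adjust(cm(y), one)),
                 as.data.frame(cm(y)))

    # confounded design: error
    conf <- dplyr::mutate(samples, batch = ifelse(condition == "pre",
                                                  "A", "B"))
    expect_error(batch_adjust(cm(y), conf), "confounded")
  })
})

test_that("batch adjustment matches limma::removeBatchEffect up to centring", {
  withr::with_seed(14, {
    samples <- tibble::tibble(sample_id = paste0("s", 1:6),
                              condition = rep(c("pre", "post"), 3),
                              batch = rep(c("A", "B"), each = 3))
    y <- matrix(rnorm(120, 6), nrow = 20)
    colnames(y) <- samples$sample_id
    got <- as.matrix(batch_adjust(cm(y), samples)[, -1])
    ref <- limma::removeBatchEffect(
      y, batch = samples$batch,
      design = stats::model.matrix(~condition, samples))
    # both remove the same batch component; they may differ by a per-element
    # constant, so compare after row-centring
    expect_equal(got - rowMeans(got), ref - rowMeans(ref),
                 tolerance = 1e-10, ignore_attr = TRUE)
  })
})

test_that("inducibility needs strict exceedance of the fold threshold", {
  withr::with_seed(23, {
    samples <- tibble::tibble(sample_id = paste0("s", 1:6),
                              condition = rep(c("pre", "post"), each = 3))
    # identical groups: never inducible
    flat <- matrix(50 + rnorm(300, sd = 2), nrow = 50)
    colnames(flat) <- samples$sample_id
    got <- classify_inducible(cm(flat), samples, "pre", "post")
    expect_true(all(!got$inducible))

    # exactly 2-fold with tight replicates: offset null not exceeded
    two <- matrix(rep(c(50, 50, 50, 101, 101, 101), 40), nrow = 40,
                  byrow = TRUE) * matrix(exp(rnorm(240, sd = 0.01)), nrow = 40)
    colnames(two) <- samples$sample_id
    got2 <- classify_inducible(cm(two), samples, "pre", "post",
                               fold_threshold = 2)
    expect_true(all(!got2$inducible))

    # clear 4-fold planted increase among nulls is recovered
    base <- matrix(rpois(200 * 6, 50), nrow = 200)
    base[1:20, 4:6] <- rpois(60, 200)
    colnames(base) <- samples$sample_id
    got3 <- classify_inducible(cm(base), samples, "pre", "post",
                               fold_threshold = 2)
    expect_gte(mean(got3$inducible[1:20]), 0.8)
    expect_lte(mean(got3$inducible[-(1:20)]), 0.02)
  })
})

test_that("BH adjustment is monotone and never below the raw p", {
  withr::with_seed(31, {
    samples <- tibble::tibble(sample_id = paste0("s", 1:6),
                              condition = rep(c("pre", "post"), each = 3))
    m <- matrix(rpois(600, 30) * exp(rnorm(600, sd = 0.2)), nrow = 100)
    colnames(m) <- samples$sample_id
    got <- classify_inducible(cm(m), samples, "pre", "post")
    expect_true(all(got$p_adj >= got$p - 1e-12))
    ord <- order(got$p)
    expect_true(all(diff(got$p_adj[ord]) >= -1e-12))
  })
})

test_that("assay calls combine as a union over the landscape", {
  a <- tibble::tibble(element_id = c("e1", "e2"), log2_fc = 1, p = 0.01,
                      p_adj = 0.01, inducible = c(TRUE, FALSE))
  k <- tibble::tibble(element_id = c("e2", "e3"), log2_fc = 1, p = 0.01,
                      p_adj = 0.01, inducible = c(TRUE, FALSE))
  u <- combine_inducible(atac = a, k27 = k)
  expect_equal(u$inducible, c(TRUE, TRUE, FALSE))
  expect_equal(u$inducible_atac, c(TRUE, FALSE, FALSE))
})
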