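# Interval algebra: merging, m-of-n reproducibility, summit windows,
# landscape construction, overlap flags.

test_that("merge_intervals bridges gaps up to the threshold and no further", {
  expect_equal(nrow(merge_intervals(iv(character(), integer(), integer()),
                                    gap = 150)), 0)

  got <- merge_intervals(iv("c1", c(0, 200, 600), c(100, 300, 700)), gap = 150)
  expect_equal(got, iv("c1", c(0, 600), c(300, 700)),
               ignore_attr = TRUE)

  # strict threshold: 151-bp separation survives a 150-bp merge
  apart <- iv("c1", c(0, 251), c(100, 400))
  expect_equal(nrow(merge_intervals(apart, gap = 150)), 2)
  expect_equal(nrow(merge_intervals(iv("c1", c(0, 250), c(100, 400)),
                                    gap = 150)), 1)
})

test_that("merge_intervals rejects malformed intervals and identifies them", {
  expect_error(merge_intervals(iv("c1", 10, 10), gap = 0), "row 1")
  expect_error(merge_intervals(iv(c("c1", "c2"), c(0, 50), c(10, 40)),
                               gap = 0), "row 2")
})

test_that("merge_intervals is idempotent and respects chromosomes", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      x <- dplyr::bind_rows(random_interval_set(5000),
                            dplyr::mutate(random_interval_set(5000),
                                          chrom = "c2"))
      gap <- sample(c(0, 1, 150), 1)
      m1 <- merge_intervals(x, gap)
      expect_equal(merge_intervals(m1, gap), m1)
      # merging never mixes chromosomes
      expect_setequal(unique(m1$chrom), unique(x$chrom))
    }
  })
})

test_that("reproducible_peaks matches the hand-computed depth profile", {
  sets <- list(iv("c1", 10, 20), iv("c1", 15, 25), iv("c1", 40, 50))
  expect_equal(reproducible_peaks(sets, m = 2), iv("c1", 15, 20),
               ignore_attr = TRUE)
  expect_error(reproducible_peaks(sets, m = 4), "1 <= m")
  expect_error(reproducible_peaks(sets, m = 0), "1 <= m")
  one <- list(iv("c1", c(5, 8), c(10, 12)))
  expect_equal(reproducible_peaks(one, m = 1), iv("c1", 5, 12),
               ignore_attr = TRUE)
})

test_that("a region present in exactly 5 of 8 replicates survives 5-of-8; 4 does not", {
  region_a <- iv("c1", 100, 600)   # in 5 replicates
  region_b <- iv("c1", 2000, 2400) # in 4 replicates
  sets <- lapply(1:8, function(i) {
    dplyr::bind_rows(if (i <= 5) region_a,
                     if (i <= 4) region_b)
  })
  got <- reproducible_peaks(sets, m = 5)
  expect_equal(got, region_a, ignore_attr = TRUE)
})

test_that("reproducible_peaks is monotone in m and reduces to merge at m=1", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      sets <- lapply(1:5, function(i) random_interval_set(8000))
      prev <- reproducible_peaks(sets, 1)
      expect_equal(prev,
                   merge_intervals(dplyr::bind_rows(sets), gap = 0))
      for (m in 2:5) {
        cur <- reproducible_peaks(sets, m)
        # base set at m is a subset of the base set at m-1
        if (nrow(cur)) {
          d_prev <- depth_array(prev, 8000) > 0
          d_cur <- depth_array(cur, 8000) > 0
          expect_true(all(d_prev[d_cur]))
        }
        prev <- cur
      }
    }
  })
})

test_that("summit_window centres on the leftmost argmax and has exact width", {
  # flat nonzero signal: tie broken at interval start
  flat <- tibble::tibble(chrom = "c1", start = 0, end = 5000, value = 2)
  got <- summit_window(iv("c1", 1000, 2000), flat, half_width = 500)
  expect_equal(got$summit, 1000)
  expect_equal(c(got$start, got$end), c(500, 1500))

  # peaked signal
  tr <- tibble::tibble(chrom = "c1", start = c(0, 1234, 1235),
                       end = c(1234, 1235, 5000), value = c(1, 9, 1))
  got <- summit_window(iv("c1", 1000, 2000), tr, half_width = 500)
  expect_equal(got$summit, 1234)
  expect_equal(c(got$start, got$end), c(734, 1734))
  expect_false(got$no_signal)

  # all-zero signal: midpoint, flagged
  got <- summit_window(iv("c1", 100, 200),
                       tibble::tibble(chrom = "c1", start = 0, end = 1000,
                                      value = 0), half_width = 500)
  expect_equal(got$summit, 150)
  expect_true(got$no_signal)
  # clipped at chromosome start, flagged
  expect_equal(got$start, 0)
  expect_true(got$clipped)
})

test_that("summit windows are clipped at declared chromosome ends", {
  sizes <- tibble::tibble(chrom = "c1", length = 1000L)
  tr <- tibble::tibble(chrom = "c1", start = 900, end = 910, value = 5)
  got <- summit_window(iv("c1", 880, 940), tr, half_width = 500,
                       chrom_sizes = sizes)
  expect_equal(got$end, 1000)
  expect_true(got$clipped)
})

test_that("interval ops agree with the per-base brute-force oracle", {
  withr::with_seed(101, {
    for (rep in 1:60) {
      len <- sample(500:10000, 1)
      x <- random_interval_set(len)
      gap <- sample(0:200, 1)
      expect_equal(merge_intervals(x, gap), brute_merge(x, gap, len),
                   ignore_attr = TRUE)

      n_sets <- sample(2:5, 1)
      sets <- lapply(seq_len(n_sets), function(i) random_interval_set(len))
      m <- sample(n_sets, 1)
      expect_equal(reproducible_peaks(sets, m),
                   brute_reproducible(sets, m, len), ignore_attr = TRUE)

      tr <- random_interval_set(len)
      tr$value <- stats::runif(nrow(tr), 0, 10)
      intr <- random_interval_set(len)[1, ]
      got <- summit_window(intr, tr, half_width = 100)
      want <- brute_summit(intr, tr, 100, len)
      expect_equal(got$summit, unname(want["summit"]))
      expect_equal(got$end - got$start,
                   200 - max(0, -unname(want["start"])))
      expect_true(got$summit >= intr$start && got$summit < intr$end)
    }
  })
})

test_that("build_landscape records sources and keeps one element per region", {
  tr <- tibble::tibble(chrom = "c1", start = 0, end = 10000, value = 1)
  atac <- iv("c1", 1000, 1400)
  k27 <- iv("c1", 5000, 5600)
  ls <- build_landscape(atac, k27, tr, half_width = 500)
  expect_equal(nrow(ls), 2)
  expect_equal(ls$source, c("ATAC", "K27ac"))
  expect_true(all(ls$end - ls$start == 1000))

  # overlapping regions from both assays collapse to one element, source both
  ls2 <- build_landscape(iv("c1", 1000, 1400), iv("c1", 1300, 1800), tr,
                         half_width = 500)
  expect_equal(nrow(ls2), 1)
  expect_equal(ls2$source, "both")
})

test_that("landscape from synthetic tracks recovers every planted region", {
  cfg <- sim_config(list(dsb = list(n_elements = 60L)))
  sig <- simulate_signal_tracks(cfg, seed = 5)
  atac_rep <- reproducible_peaks(sig$peak_sets$atac, m = 3)
  k27_rep <- reproducible_peaks(sig$peak_sets$k27, m = 3)
  ls <- build_landscape(atac_rep, k27_rep, sig$atac_track, half_width = 500)
  expect_equal(nrow(ls), 60)
  expect_true(all(ls$end - ls$start == 1000))
  # each planted summit is recovered exactly (tracks carry a 1-bp boost)
  expect_equal(ls$summit, sig$elements$summit)
})

test_that("overlap_flag uses half-open semantics", {
  el <- iv("c1", 0, 500)
  expect_true(overlap_flag(el, iv("c1", 499, 600))$overlaps_peak)
  expect_false(overlap_flag(el, iv("c1", 500, 600))$overlaps_peak)
  expect_false(overlap_flag(el, iv(character(), integer(),
                                   integer()))$overlaps_peak)
})

test_that("blacklisted bases are excluded from the landscape", {
  tr <- tibble::tibble(chrom = "c1", start = 0, end = 10000, value = 1)
  ls <- build_landscape(iv("c1", c(1000, 5000), c(1400, 5400)),
                        iv(character(), integer(), integer()), tr,
                        half_width = 100,
                        blacklist = iv("c1", 4900, 5500))
  expect_equal(nrow(ls), 1)
  expect_true(ls$start >= 900 && ls$end <= 1500)
})
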