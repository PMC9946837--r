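# Mutation frequencies, complementary-class collapsing, young-median
# normalization, ROUT outlier removal.

# consensus-table row builder
cons_row <- function(amplicon_id, pos, ref, n_families, n_alt = 0L,
                     n_del = 0L, n_ins = 0L, sub = NULL) {
  row <- tibble::tibble(amplicon_id = amplicon_id, pos = pos, ref = ref,
                        n_families = n_families, n_A = 0L, n_C = 0L,
                        n_G = 0L, n_T = 0L, n_del = n_del, n_ins = n_ins,
                        n_alt = n_alt)
  if (!is.null(sub)) for (b in names(sub)) row[[paste0("n_", b)]] <- sub[[b]]
  # reference calls fill the remainder of the base-call identity
  base_cols <- paste0("n_", c("A", "C", "G", "T"))
  used <- rowSums(row[base_cols]) + row$n_del
  row[[paste0("n_", ref)]] <- row[[paste0("n_", ref)]] + n_families - used
  row
}

test_that("f_total is alt families over assessed consensus bases", {
  panel <- amplicon_panel(tibble::tibble(
    amplicon_id = "a", chrom = "c1", start = 0L, end = 25L,
    ref_seq = strrep("ACGTA", 5), primer_len = 22L))
  tab <- dplyr::bind_rows(
    cons_row("a", 23L, "G", 200L, n_alt = 1L, sub = list(T = 1L)),
    cons_row("a", 24L, "T", 200L),
    cons_row("a", 25L, "A", 100L, n_alt = 1L, sub = list(G = 1L)))
  got <- mutation_frequency(tab, panel)
  expect_equal(got$f_total, 2 / 500)
  expect_equal(got$n_alt, 2L)
  expect_equal(got$denominator_bases, 500L)

  # alt family at position 22 only: inside the primer, ignored
  tab2 <- dplyr::bind_rows(
    cons_row("a", 22L, "T", 100L, n_alt = 5L, sub = list(G = 5L)),
    cons_row("a", 23L, "G", 100L), cons_row("a", 24L, "T", 100L),
    cons_row("a", 25L, "A", 100L))
  expect_equal(mutation_frequency(tab2, panel)$f_total, 0)

  # zero denominator -> missing, not zero
  tab3 <- dplyr::bind_rows(cons_row("a", 23L, "G", 0L),
                           cons_row("a", 24L, "T", 0L),
                           cons_row("a", 25L, "A", 0L))
  expect_true(is.na(mutation_frequency(tab3, panel)$f_total))
})

test_that("no alt families anywhere gives f_total zero", {
  cfg <- sim_config(list(amplicon = list(
    n_amplicons = 2L, templates_per_site = 30L, read_error = 0,
    mu = list(young = c(unbound = 0, bound = 0)),
    animals = tibble::tibble(animal_id = "a1", age_group = "young"))))
  sim <- simulate_amplicon_reads(cfg, seed = 2)
  cc <- consensus_composition(group_umi_families(sim$reads), sim$panel)
  expect_true(all(mutation_frequency(cc, sim$panel)$f_total == 0))
})

test_that("collapsed substitution classes pool complementary changes", {
  # 50 C and 50 G assessed positions at depth 100; one C>T family at a C
  # position, one G>A family at a G position -> f(C>T|G>A) = 2/10,000
  panel <- amplicon_panel(tibble::tibble(
    amplicon_id = "a", chrom = "c1", start = 0L, end = 102L,
    ref_seq = paste0("AA", strrep("CG", 50)), primer_len = 2L))
  rows <- list()
  for (p in 3:102) {
    ref <- if (p %% 2 == 1) "C" else "G"
    rows[[p]] <- cons_row("a", as.integer(p), ref, 100L)
  }
  rows[[3]] <- cons_row("a", 3L, "C", 100L, n_alt = 1L, sub = list(T = 1L))
  rows[[4]] <- cons_row("a", 4L, "G", 100L, n_alt = 1L, sub = list(A = 1L))
  tab <- dplyr::bind_rows(rows)
  cf <- class_frequencies(tab, panel)
  expect_equal(cf$frequency[cf$class == "C>T"], 2 / 10000)
  expect_equal(cf$frequency[cf$class == "C>A"], 0)
  # no T or A reference bases assessed -> T>* classes missing
  expect_true(all(is.na(cf$frequency[startsWith(cf$class, "T>")])))
})

test_that("indel frequency uses all assessed positions as denominator", {
  panel <- amplicon_panel(tibble::tibble(
    amplicon_id = "a", chrom = "c1", start = 0L, end = 502L,
    ref_seq = paste0("AA", strrep("ACGTT", 100)), primer_len = 2L))
  rows <- lapply(3:502, function(p) {
    ref <- substr(panel$ref_seq, p, p)
    cons_row("a", as.integer(p), ref, 100L)
  })
  rows[[1]] <- cons_row("a", 3L, "A", 100L, n_alt = 3L, n_del = 3L)
  tab <- dplyr::bind_rows(rows)
  cf <- class_frequencies(tab, panel)
  expect_equal(cf$frequency[cf$class == "indel"], 3 / 50000)
})

test_that("class and indel numerators jointly account for every alt family", {
  cfg <- sim_config(list(amplicon = list(
    n_amplicons = 4L, templates_per_site = 60L, read_error = 1e-3,
    mu = list(young = c(unbound = 3e-3, bound = 3e-3)),
    animals = tibble::tibble(animal_id = "a1", age_group = "young"))))
  sim <- simulate_amplicon_reads(cfg, seed = 31)
  cc <- consensus_composition(group_umi_families(sim$reads), sim$panel)
  mf <- mutation_frequency(cc, sim$panel)
  cf <- class_frequencies(cc, sim$panel)
  per_amp <- cf |>
    dplyr::group_by(amplicon_id) |>
    dplyr::summarise(total = sum(numerator), .groups = "drop")
  joined <- dplyr::left_join(mf, per_amp, by = "amplicon_id")
  # a family with both a substitution and an insertion is counted once in
  # n_alt but appears in both class numerators; at these rates none occur
  expect_equal(joined$total, joined$n_alt)
})

test_that("mutation_frequency is invariant to read order and batch splits", {
  cfg <- sim_config(list(amplicon = list(
    n_amplicons = 2L, templates_per_site = 40L, read_error = 1e-3,
    mu = list(young = c(unbound = 2e-3, bound = 2e-3)),
    animals = tibble::tibble(animal_id = "a1", age_group = "young"))))
  sim <- simulate_amplicon_reads(cfg, seed = 13)
  reads <- sim$reads
  f1 <- mutation_frequency(
    consensus_composition(group_umi_families(reads), sim$panel), sim$panel)
  shuffled <- reads[withr::with_seed(1, sample(nrow(reads))), ]
  f2 <- mutation_frequency(
    consensus_composition(group_umi_families(shuffled), sim$panel),
    sim$panel)
  expect_equal(f1, f2)
})

test_that("young-median normalization is exact for odd young counts", {
  prof <- tidyr::crossing(amplicon_id = c("s1", "s2"),
                          animal_id = paste0("y", 1:3)) |>
    dplyr::mutate(age_group = "young",
                  f_total = c(1e-3, 2e-3, 3e-3, 2e-3, 4e-3, 8e-3))
  old <- tibble::tibble(amplicon_id = "s1", animal_id = "o1",
                        age_group = "old", f_total = 4e-3)
  norm <- normalize_to_young(dplyr::bind_rows(prof, old))
  young_med <- norm |>
    dplyr::filter(age_group == "young") |>
    dplyr::group_by(amplicon_id) |>
    dplyr::summarise(med = median(value))
  expect_true(all(young_med$med == 1))
  expect_equal(norm$value[norm$animal_id == "o1"], 4e-3 / 2e-3)
})

test_that("sites without young data are dropped; zero young median gives NA", {
  prof <- tibble::tibble(
    amplicon_id = c("s1", "s1", "s2", "s2", "s2"),
    animal_id = c("o1", "o2", "y1", "y2", "y3"),
    age_group = c("old", "old", "young", "young", "young"),
    f_total = c(1e-3, 2e-3, 0, 0, 0))
  expect_warning(norm <- normalize_to_young(prof), "no defined young")
  expect_false("s1" %in% norm$amplicon_id)
  expect_true(all(is.na(norm$value[norm$amplicon_id == "s2"])))
})

test_that("ROUT flags the gross outlier and nothing in constant data", {
  expect_true(all(!rout_outliers(rep(1, 10))$outlier))
  got <- rout_outliers(c(1, 1.1, 0.9, 1.05, 0.95, 25), Q = 0.001)
  expect_equal(which(got$outlier), 6)
  # direct evaluation of the frozen recipe for the flagged point
  x <- c(1, 1.1, 0.9, 1.05, 0.95, 25)
  res <- x - median(x)
  rsdr <- unname(quantile(abs(res), 0.6827, type = 7)) * 6 / 5
  expect_equal(got$t_ratio[6], abs(res[6]) / rsdr)
  expect_equal(got$p[6], 2 * pt(-abs(res[6]) / rsdr, df = 5))
  # missing values pass through untested
  got_na <- rout_outliers(c(1, NA, 1.1, 0.9, 30))
  expect_true(is.na(got_na$outlier[2]))
  expect_error(rout_outliers(c(1, 2)), "at least 3")
})

test_that("parameter recovery: estimator tracks the planted frequency", {
  # pooled estimate across the panel approximates mu within binomial error
  mu <- 2e-3
  cfg <- sim_config(list(amplicon = list(
    n_amplicons = 5L, templates_per_site = 100L, read_error = 5e-4,
    mu = list(young = c(unbound = mu, bound = mu)),
    animals = tibble::tibble(animal_id = "a1", age_group = "young"))))
  sim <- simulate_amplicon_reads(cfg, seed = 99)
  cc <- consensus_composition(group_umi_families(sim$reads), sim$panel)
  mf <- mutation_frequency(cc, sim$panel)
  est <- sum(mf$n_alt) / sum(mf$denominator_bases)
  ci <- stats::binom.test(sum(mf$n_alt), sum(mf$denominator_bases))$conf.int
  expect_true(mu >= ci[1] && mu <= ci[2])
})
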