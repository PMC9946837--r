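# Stage wiring: end-to-end mutation and DSB pipelines driven by a config
# list or YAML file, with a run manifest and optional persisted TSV outputs.

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  config
}

run_manifest <- function(config, seed, stage_counts) {
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  tibble(key = c("config_hash", "seed", "package_version",
                 names(stage_counts)),
         value = c(rlang::hash(cfg_for_hash), as.character(seed),
                   as.character(utils::packageVersion("dsbmut")),
                   as.character(unlist(stage_counts))))
}

write_stage <- function(x, out_dir, name) {
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")),
                     progress = FALSE)
  }
  invisible(x)
}

#' Run the amplicon mutation pipeline end to end
#'
#' Wires UMI-family grouping, consensus composition, amplicon depth
#' filtering, per-animal mutation frequencies, young-median normalization and
#' ROUT outlier flagging. Inputs are either simulated (default) or read from
#' files named in the config.
#'
#' Config keys: `seed` (required for simulation), `sim` (overrides for
#' [sim_config()]), or `reads_file` + `panel_file` (TSVs) to run on real
#' tables; `min_depth` (default 10), `min_mean_depth` (default 100),
#' `rout_q` (default 0.001), `out_dir` (optional; stage TSVs are written
#' there).
#'
#' @param config List or YAML path.
#' @return List with `panel`, `consensus`, `amplicon_filter`, `profiles`,
#'   `normalized`, `outliers`, `manifest` (and `truth` when simulated).
#' @export
run_mutation_pipeline <- function(config = list()) {
  config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  min_depth <- config$min_depth %||% 10
  min_mean_depth <- config$min_mean_depth %||% 100
  rout_q <- config$rout_q %||% 0.001

  if (!is.null(config$reads_file)) {
    reads <- read_amplicon_reads(config$reads_file)
    panel <- amplicon_panel(readr::read_tsv(config$panel_file,
                                            show_col_types = FALSE,
                                            progress = FALSE))
    truth <- NULL
  } else {
    seed <- config$seed %||% abort("config$seed is required for simulation")
    sim <- simulate_amplicon_reads(sim_config(config$sim %||% list()), seed)
    reads <- sim$reads
    panel <- sim$panel
    truth <- sim$truth
  }
  if (nrow(reads) == 0 || nrow(panel) == 0) abort("empty panel or read set")

  by_sample <- if ("sample_id" %in% names(reads)) {
    split(reads, reads$sample_id)
  } else list(s1 = reads)
  consensus <- imap(by_sample, function(r, s) {
    grouped <- group_umi_families(r)
    mutate(consensus_composition(grouped, panel, min_depth = min_depth),
           sample_id = s, .before = 1)
  }) |> list_rbind()

  keep <- consensus |>
    group_by(.data$sample_id) |>
    dplyr::group_map(~ mutate(filter_amplicons(.x, panel, min_mean_depth),
                              sample_id = .y$sample_id, .before = 1)) |>
    list_rbind()
  consensus_kept <- consensus |>
    semi_join(filter(keep, .data$kept), by = c("sample_id", "amplicon_id"))

  profiles <- mutation_frequency(consensus_kept, panel)
  classes <- class_frequencies(consensus_kept, panel)

  ages <- if (!is.null(truth)) {
    cfg_animals <- sim_config(config$sim %||% list())$amplicon$animals
    setNames(cfg_animals$age_group, cfg_animals$animal_id)
  } else {
    setNames(config$age_groups$age_group, config$age_groups$animal_id)
  }
  profiles$age_group <- unname(ages[profiles$sample_id])
  prof_in <- rename(profiles, animal_id = "sample_id")
  normalized <- normalize_to_young(prof_in)
  outliers <- normalized |>
    filter(!is.na(.data$value)) |>
    mutate(rout_outliers(.data$value, Q = rout_q)[, c("t_ratio", "p",
                                                      "outlier")])

  manifest <- run_manifest(config, config$seed %||% NA, list(
    n_reads = nrow(reads), n_amplicons = nrow(panel),
    n_amplicons_kept = sum(keep$kept), n_profiles = nrow(profiles),
    n_outliers = sum(outliers$outlier, na.rm = TRUE)))

  write_stage(consensus, out_dir, "consensus")
  write_stage(keep, out_dir, "amplicon_filter")
  write_stage(profiles, out_dir, "profiles")
  write_stage(classes, out_dir, "class_frequencies")
  write_stage(normalized, out_dir, "normalized_rates")
  write_stage(outliers, out_dir, "outliers")
  write_stage(manifest, out_dir, "manifest")

  list(panel = panel, consensus = consensus, amplicon_filter = keep,
       profiles = profiles, class_frequencies = classes,
       normalized = normalized, outliers = outliers, truth = truth,
       manifest = manifest)
}

#' Run the DSB quantification pipeline end to end
#'
#' Wires landscape construction (reproducible peaks, summit windows), cut-site
#' deduplication, per-element counting, low-count filtering, median-of-ratios
#' normalization, batch adjustment, inducibility classification (0 h vs 2 h),
#' binding-quartile stratification and downsampled genome-wide break totals.
#'
#' Config keys: `seed` (required), `sim` (overrides for [sim_config()]),
#' `fold_threshold` (default 2), `alpha` (default 0.05), `half_width`
#' (default 500), `eps` (IgG floor, default 1), `out_dir` (optional).
#'
#' @param config List or YAML path.
#' @return List with `landscape`, `quartiles`, `counts`, `size_factors`,
#'   `normalized`, `adjusted` (log2 batch-adjusted), `inducible`,
#'   `genomewide`, `samples`, `truth`, `manifest`.
#' @export
run_dsb_pipeline <- function(config = list()) {
  config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  seed <- config$seed %||% abort("config$seed is required")
  cfg <- sim_config(config$sim %||% list())
  fold_threshold <- config$fold_threshold %||% 2
  alpha <- config$alpha %||% 0.05
  half_width <- config$half_width %||% 500
  eps <- config$eps %||% 1

  sig <- simulate_signal_tracks(cfg, seed)
  cuts <- simulate_cut_sites(cfg, seed)
  chrom_sizes <- tibble(chrom = names(cfg$genome$chroms),
                        length = unname(cfg$genome$chroms))

  atac_rep <- reproducible_peaks(sig$peak_sets$atac,
                                 m = length(sig$peak_sets$atac))
  k27_rep <- reproducible_peaks(sig$peak_sets$k27,
                                m = length(sig$peak_sets$k27))
  landscape <- build_landscape(atac_rep, k27_rep, sig$atac_track,
                               half_width = half_width,
                               chrom_sizes = chrom_sizes)

  quartiles <- quartile_stratify(landscape, sig$binding_track,
                                 sig$igg_track, sig$peak_sets$binding,
                                 eps = eps)

  events <- dedup_cut_sites(cuts$records)
  counts <- element_counts(events, landscape)
  lowmask <- filter_low_counts(counts, mode = "any_nonzero")
  counts_kept <- semi_join(counts, filter(lowmask, .data$kept),
                           by = "element_id")
  sf <- size_factors(counts_kept)
  normalized <- normalize_counts(counts_kept, sf)
  logn <- normalized
  logn[, -1] <- log2(normalized[, -1] + 1)
  adjusted <- batch_adjust(logn, cuts$samples)
  adj_linear <- adjusted
  adj_linear[, -1] <- 2^adjusted[, -1] - 1
  inducible <- classify_inducible(adj_linear, cuts$samples, pre = "0h",
                                  post = "2h",
                                  fold_threshold = fold_threshold,
                                  alpha = alpha)
  genomewide <- genomewide_breaks(cuts$records, seed = seed)

  manifest <- run_manifest(config, seed, list(
    n_records = nrow(cuts$records), n_unique_events = nrow(events),
    n_landscape_elements = nrow(landscape),
    n_elements_kept = sum(lowmask$kept),
    n_inducible = sum(inducible$inducible),
    n_samples = nrow(cuts$samples)))

  write_stage(landscape, out_dir, "landscape")
  write_stage(quartiles, out_dir, "quartiles")
  write_stage(counts, out_dir, "element_counts")
  write_stage(sf, out_dir, "size_factors")
  write_stage(adjusted, out_dir, "log2_adjusted_counts")
  write_stage(inducible, out_dir, "inducible_calls")
  write_stage(genomewide, out_dir, "genomewide_breaks")
  write_stage(manifest, out_dir, "manifest")

  list(landscape = landscape, quartiles = quartiles, counts = counts,
       size_factors = sf, normalized = normalized, adjusted = adjusted,
       inducible = inducible, genomewide = genomewide,
       samples = cuts$samples, elements_truth = cuts$elements,
       truth = cuts$truth, manifest = manifest)
}
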