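# Seeded generators for every input the pipeline consumes, with ground-truth
# labels. Each generator is a pure function of (cfg, seed): identical inputs
# give identical output. Defaults are desk-scale (2 chromosomes x 1 Mb,
# 200 elements, 30 amplicons) with the study's design frozen in where it is
# known: replicate numbers per stimulation time point, the 12-nt UMI, the
# consensus-10 depth standard, the Q4 fold profile across the time course.

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.data.frame(override[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Simulation configuration with frozen defaults
#'
#' Returns the default simulation configuration, optionally overridden by a
#' nested list (only supplied fields are replaced). See the methods vignette
#' for what each block emulates and why the defaults were chosen.
#'
#' @param overrides Nested list of overrides, e.g.
#'   `list(amplicon = list(read_error = 0.005))`.
#' @return A `sim_config` list with blocks `genome`, `amplicon`, `dsb`,
#'   `signal`, `expr`.
#' @export
sim_config <- function(overrides = list()) {
  cfg <- list(
    genome = list(chroms = c(chr1 = 1e6, chr2 = 1e6)),
    amplicon = list(
      n_amplicons = 30L,
      amplicon_length = 122L,   # 22-bp primer + 100 assessed bases
      primer_len = 22L,
      umi_len = 12L,
      gc = 0.45,
      templates_per_site = 250L,
      family_law = "ztpois",    # zero-truncated Poisson; "nbinom" alternative
      family_lambda = 12,
      nb_size = 4,
      read_error = 5e-4,
      sub_frac = 0.9, del_frac = 0.05, ins_frac = 0.05,
      bound_frac = 0.5,
      # per-base true mutation frequency by age group and binding status:
      # unbound sites double by middle age; bound sites start higher and
      # stay flat until old age
      mu = list(young = c(unbound = 5e-4, bound = 8e-4),
                middle = c(unbound = 1e-3, bound = 8e-4),
                old = c(unbound = 1e-3, bound = 1.1e-3)),
      animals = tibble(
        animal_id = c(paste0("y", 1:4), paste0("m", 1:4), paste0("o", 1:3)),
        age_group = rep(c("young", "middle", "old"), c(4, 4, 3)))),
    dsb = list(
      n_elements = 200L,
      element_width = 1000L,
      baseline_rate = 0.03,     # unique events per bp per sample at fold 1
      conditions = tibble(
        condition = c("0h", "2h", "10h_less", "10h_still"),
        n_reps = c(8L, 8L, 4L, 6L),
        fold_q4 = c(1, 3, 1.5, 3)),
      quartile_weight = c(Q1 = 0, Q2 = 1 / 3, Q3 = 2 / 3, Q4 = 1),
      # probability an element is activity-inducible, by binding quartile;
      # most of the landscape stays flat, as in real stimulation data
      inducible_prob = c(Q1 = 0.05, Q2 = 0.10, Q3 = 0.20, Q4 = 0.50),
      dup_p = 0.75,             # read count per event = 1 + Geometric(p)
      umi_len = 8L,
      background_events = 2000L,
      batch_effect = 1.5,       # multiplier on batch-B counts
      batch_frac_elements = 0.5),
    signal = list(
      intensity_meanlog = 0, intensity_sdlog = 1,
      summit_boost = 3,
      igg_shape = 50,  # aggregate control signal over 1-kb windows: low CV
      source_probs = c(both = 0.5, ATAC = 0.3, K27ac = 0.2),
      replicates = list(atac = list(n = 3L, p = 1.0),
                        k27 = list(n = 3L, p = 1.0),
                        bliss = list(n = 8L, p = 0.7)),
      peak_jitter = 50L),
    expr = list(
      n_genes = 2000L,
      n_nuclei = c(Cre = 250L, DeltaCre = 250L, uninfected = 80L),
      cell_type = "CA1",
      n_targets = 25L,
      effect = 0.5,             # Cre target expression multiplied by 1-effect
      gene_meanlog = 1, gene_sdlog = 1,
      noise_sdlog = 0.4,
      viral_rate = 40, viral_background = 0.3, viral_detect = 0.9))
  structure(deep_merge(cfg, overrides), class = c("sim_config", "list"))
}

random_seqs <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m))
}

rztpois <- function(n, lambda) {
  x <- rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- rpois(sum(x == 0), lambda)
  x
}

other_bases <- function(base) {
  lapply(base, function(b) setdiff(c("A", "C", "G", "T"), b))
}

#' Simulate targeted-amplicon UMI reads with planted mutations
#'
#' Templates (alleles) are drawn per site; each template acquires true
#' mutations at the site's per-base frequency (a mutation is fixed across the
#' whole UMI family); family sizes follow a zero-truncated Poisson (default
#' lambda 12) or negative binomial; every read then receives independent
#' per-base sequencing errors at rate `read_error`, substitutions uniform
#' over the three alternatives. The truth table records every planted
#' mutation.
#'
#' @param cfg A [sim_config()] (its `amplicon` and `genome` blocks are used).
#' @param seed Integer seed.
#' @return List with `panel` (an [amplicon_panel()] with `bound` labels),
#'   `reads` (tibble `sample_id`, `amplicon_id`, `umi`, `calls`), and `truth`
#'   (list: `mutations` per planted template mutation, `families` with true
#'   family sizes, `site_mu` with the per-site per-age true frequency).
#' @export
simulate_amplicon_reads <- function(cfg = sim_config(), seed) {
  ac <- cfg$amplicon
  if (ac$n_amplicons < 1) abort("amplicon simulation needs n_amplicons >= 1")
  if (nrow(ac$animals) < 1) abort("amplicon simulation needs >= 1 animal")
  withr::with_seed(seed, {
    chroms <- cfg$genome$chroms
    L <- ac$amplicon_length
    panel <- tibble(
      amplicon_id = sprintf("amp_%02d", seq_len(ac$n_amplicons)),
      chrom = sample(names(chroms), ac$n_amplicons, replace = TRUE),
      bound = seq_len(ac$n_amplicons) <= round(ac$bound_frac * ac$n_amplicons))
    panel$start <- vapply(panel$chrom,
                          function(cm) sample.int(chroms[[cm]] - L, 1) - 1L,
                          integer(1))
    panel$end <- panel$start + L
    probs <- c((1 - ac$gc) / 2, ac$gc / 2, ac$gc / 2, (1 - ac$gc) / 2)
    panel$ref_seq <- vapply(seq_len(ac$n_amplicons), function(i) {
      paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
             collapse = "")
    }, character(1))
    panel <- amplicon_panel(panel)

    site_mu <- tidyr::crossing(
      panel[, c("amplicon_id", "bound")],
      tibble(age_group = names(ac$mu)))
    site_mu$mu <- mapply(function(age, b) {
      ac$mu[[age]][[if (b) "bound" else "unbound"]]
    }, site_mu$age_group, site_mu$bound)

    all_reads <- list(); all_mut <- list(); all_fam <- list()
    for (a in seq_len(nrow(ac$animals))) {
      animal <- ac$animals$animal_id[a]
      age <- ac$animals$age_group[a]
      sim <- sim_amplicon_sample(panel, ac, age)
      all_reads[[a]] <- mutate(sim$reads, sample_id = animal, .before = 1)
      all_mut[[a]] <- mutate(sim$mutations, sample_id = animal, .before = 1)
      all_fam[[a]] <- mutate(sim$families, sample_id = animal, .before = 1)
    }
    list(panel = panel,
         reads = list_rbind(all_reads),
         truth = list(mutations = list_rbind(all_mut),
                      families = list_rbind(all_fam),
                      site_mu = site_mu))
  })
}

# one animal's reads across the whole panel (runs inside the caller's seed)
sim_amplicon_sample <- function(panel, ac, age_group) {
  L <- ac$amplicon_length
  Tn <- ac$templates_per_site
  n_amp <- nrow(panel)
  n_templates <- n_amp * Tn
  tmpl <- tibble(
    template = seq_len(n_templates),
    amplicon_id = rep(panel$amplicon_id, each = Tn),
    bound = rep(panel$bound, each = Tn),
    umi = random_seqs(n_templates, ac$umi_len))
  refs <- strsplit(panel$ref_seq, "")
  names(refs) <- panel$amplicon_id

  # planted template mutations: Bernoulli(mu) per (template, position)
  mu_t <- vapply(tmpl$bound, function(b) {
    ac$mu[[age_group]][[if (b) "bound" else "unbound"]]
  }, numeric(1))
  mu_max <- max(mu_t)
  n_mut <- if (mu_max > 0) rbinom(1, n_templates * L, mu_max) else 0L
  mut <- if (n_mut > 0) {
    cell <- sample.int(n_templates * L, n_mut)  # uniform over template x pos
    ti <- ((cell - 1L) %/% L) + 1L
    po <- ((cell - 1L) %% L) + 1L
    # thin to each template's own rate (bound/unbound sites may differ)
    keep <- runif(n_mut) < mu_t[ti] / mu_max
    ti <- ti[keep]; po <- po[keep]
    op <- sample(c("sub", "del", "ins"), length(ti), replace = TRUE,
                 prob = c(ac$sub_frac, ac$del_frac, ac$ins_frac))
    ref_base <- vapply(seq_along(ti), function(k) {
      refs[[tmpl$amplicon_id[ti[k]]]][po[k]]
    }, character(1))
    alt <- character(length(ti))
    is_sub <- op == "sub"
    alt[is_sub] <- vapply(which(is_sub), function(k) {
      sample(setdiff(c("A", "C", "G", "T"), ref_base[k]), 1)
    }, character(1))
    alt[op == "del"] <- "-"
    is_ins <- op == "ins"
    alt[is_ins] <- random_seqs(sum(is_ins), 2)
    tibble(template = ti, amplicon_id = tmpl$amplicon_id[ti], pos = po,
           op = op, alt = alt)
  } else {
    tibble(template = integer(), amplicon_id = character(), pos = integer(),
           op = character(), alt = character())
  }

  sizes <- switch(ac$family_law,
                  ztpois = rztpois(n_templates, ac$family_lambda),
                  nbinom = 1L + stats::rnbinom(n_templates, size = ac$nb_size,
                                               mu = ac$family_lambda - 1),
                  abort("unknown family_law"))
  n_reads <- sum(sizes)
  read_tmpl <- rep.int(tmpl$template, sizes)

  # per-read sequencing errors, substitutions only, uniform over alternatives
  err_n <- rbinom(n_reads, L, ac$read_error)
  tot_err <- sum(err_n)
  err <- if (tot_err > 0) {
    er <- tibble(read = rep.int(seq_len(n_reads), err_n),
                 pos = sample.int(L, tot_err, replace = TRUE))
    er <- distinct(er, .data$read, .data$pos)  # one error call per read-pos
    er$template <- read_tmpl[er$read]
    # template's own call at the error position (sub alt or reference)
    tkey <- paste(er$template, er$pos)
    mkey <- paste(mut$template, mut$pos)
    midx <- match(tkey, mkey)
    t_op <- ifelse(is.na(midx), "ref", mut$op[midx])
    er <- er[t_op != "del", , drop = FALSE]   # no base to miscall
    midx <- midx[t_op != "del"]; t_op <- t_op[t_op != "del"]
    t_base <- ifelse(t_op == "sub", mut$alt[midx], NA)
    need_ref <- is.na(t_base)
    amp_of <- tmpl$amplicon_id[er$template]
    t_base[need_ref] <- vapply(which(need_ref), function(k) {
      refs[[amp_of[k]]][er$pos[k]]
    }, character(1))
    er$alt <- vapply(t_base, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    er
  } else {
    tibble(read = integer(), pos = integer(), template = integer(),
           alt = character())
  }

  # compose call strings: template ops inherited by every read, overridden by
  # that read's own errors at the same position
  tmpl_ops <- if (nrow(mut) > 0) {
    body <- ifelse(mut$op == "del", "-",
                   ifelse(mut$op == "ins", paste0("+", mut$alt), mut$alt))
    tibble(template = mut$template, pos = mut$pos, body = body,
           from_template = TRUE)
  } else tibble(template = integer(), pos = integer(), body = character(),
                from_template = logical())
  read_ops <- bind_rows(
    if (nrow(tmpl_ops) > 0) {
      fam_sizes <- sizes[tmpl_ops$template]
      reads_of <- split(seq_len(n_reads), read_tmpl)
      tibble(read = unlist(reads_of[as.character(tmpl_ops$template)],
                           use.names = FALSE),
             pos = rep.int(tmpl_ops$pos, fam_sizes),
             body = rep.int(tmpl_ops$body, fam_sizes),
             priority = 1L)
    },
    if (nrow(err) > 0) {
      tibble(read = err$read, pos = err$pos, body = err$alt, priority = 2L)
    })
  calls <- rep("", n_reads)
  if (nrow(read_ops) > 0) {
    read_ops <- read_ops |>
      arrange(.data$read, .data$pos, dplyr::desc(.data$priority)) |>
      distinct(.data$read, .data$pos, .keep_all = TRUE) |>
      mutate(tok = paste0(.data$pos, .data$body))
    collapsed <- read_ops |>
      group_by(.data$read) |>
      summarise(calls = paste(.data$tok, collapse = ";"), .groups = "drop")
    calls[collapsed$read] <- collapsed$calls
  }
  reads <- tibble(amplicon_id = tmpl$amplicon_id[read_tmpl],
                  umi = tmpl$umi[read_tmpl],
                  calls = calls)
  mut_out <- mutate(mut, umi = tmpl$umi[.data$template])
  fam <- tibble(amplicon_id = tmpl$amplicon_id, umi = tmpl$umi, size = sizes)
  list(reads = reads, mutations = mut_out, families = fam)
}

# element layout + binding truth shared by the cut-site and signal-track
# generators: same (cfg, seed) => same elements
sim_elements <- function(cfg, seed) {
  withr::with_seed(seed, {
    dc <- cfg$dsb; sc <- cfg$signal
    chroms <- cfg$genome$chroms
    w <- dc$element_width
    slot <- w + 2L * sc$peak_jitter + 100L
    slots <- imap(as.list(chroms), function(len, cm) {
      tibble(chrom = cm, slot_start = seq(0L, len - slot, by = slot))
    }) |> list_rbind()
    if (nrow(slots) < dc$n_elements) abort("genome too small for n_elements")
    pick <- sort(sample.int(nrow(slots), dc$n_elements))
    el <- slots[pick, ]
    el$start <- el$slot_start + sc$peak_jitter + 50L
    el$end <- el$start + w
    el$element_id <- sprintf("el_%04d", seq_len(nrow(el)))
    el$summit <- el$start + sample.int(w - 200L, nrow(el)) + 100L
    el$binding <- stats::rlnorm(nrow(el), sc$intensity_meanlog,
                                sc$intensity_sdlog)
    el$atac_intensity <- stats::rlnorm(nrow(el), sc$intensity_meanlog,
                                       sc$intensity_sdlog / 2)
    ordb <- order(el$binding, el$chrom, el$start)
    q <- integer(nrow(el))
    q[ordb] <- ceiling(seq_len(nrow(el)) * 4 / nrow(el))
    el$quartile <- paste0("Q", q)
    el$has_binding_peak <- el$quartile == "Q4"
    el$inducible <- runif(nrow(el)) < dc$inducible_prob[el$quartile]
    el$source <- sample(names(sc$source_probs), nrow(el), replace = TRUE,
                        prob = sc$source_probs)
    el$batch_affected <- runif(nrow(el)) < dc$batch_frac_elements
    select(el, "element_id", "chrom", "start", "end", "summit", "binding",
           "atac_intensity", "quartile", "has_binding_peak", "inducible",
           "source", "batch_affected")
  })
}

#' Simulate sBLISS-style cut-site records across a stimulation time course
#'
#' Unique break events per element and sample are Poisson with rate
#' `baseline_rate * width * fold(condition, quartile) * batch multiplier`.
#' Only elements carrying the `inducible` truth label (drawn with
#' quartile-dependent probability, so inducibility concentrates where
#' binding is strongest while most of the landscape stays flat) are
#' enriched; for those, the condition fold profile applies fully in the top
#' binding quartile and is scaled down by the quartile weight below it. Each unique event is
#' re-read `1 + Geometric(dup_p)` times to model PCR duplicates, and
#' background events are scattered uniformly over the genome. Samples
#' alternate between two processing batches (all conditions present in each
#' batch); in batch B, a fixed random subset of elements has its rate
#' multiplied by `batch_effect`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed. The element layout is derived from the same
#'   seed, so it matches [simulate_signal_tracks()] called with equal
#'   `(cfg, seed)`.
#' @return List with `records` (cut-site tibble), `elements` (truth layout
#'   with quartiles), `samples` (sample sheet: `sample_id`, `condition`,
#'   `batch`), and `truth` (per element x sample planted unique-event counts
#'   and fold).
#' @export
simulate_cut_sites <- function(cfg = sim_config(), seed) {
  el <- sim_elements(cfg, seed)
  dc <- cfg$dsb
  withr::with_seed(seed + 1L, {
    cond <- cfg$dsb$conditions
    samples <- cond |>
      dplyr::reframe(sample_id = sprintf("%s_r%d", .data$condition,
                                         seq_len(.data$n_reps)),
                     fold_q4 = .data$fold_q4, .by = "condition")
    samples$batch <- rep(c("A", "B"), length.out = nrow(samples))
    qw <- dc$quartile_weight[el$quartile]
    w <- dc$element_width
    recs <- list(); truth <- list()
    for (i in seq_len(nrow(samples))) {
      fold <- 1 + (samples$fold_q4[i] - 1) * qw * el$inducible
      bmult <- if (samples$batch[i] == "B") {
        ifelse(el$batch_affected, dc$batch_effect, 1)
      } else rep(1, nrow(el))
      lam <- dc$baseline_rate * w * fold * bmult
      n_ev <- rpois(nrow(el), lam)
      ev_el <- rep.int(seq_len(nrow(el)), n_ev)
      pos <- el$start[ev_el] + sample.int(w, length(ev_el), replace = TRUE) - 1L
      chrom <- el$chrom[ev_el]
      # background scattered genome-wide
      nbg <- dc$background_events
      bg_chrom <- sample(names(cfg$genome$chroms), nbg, replace = TRUE)
      bg_pos <- vapply(bg_chrom, function(cm) {
        sample.int(cfg$genome$chroms[[cm]], 1) - 1L
      }, integer(1))
      n_tot <- length(chrom) + nbg
      ev <- tibble(chrom = c(chrom, bg_chrom), pos = c(pos, bg_pos),
                   strand = sample(c("+", "-"), n_tot, replace = TRUE),
                   umi = random_seqs(n_tot, dc$umi_len))
      times <- 1L + rgeom(nrow(ev), dc$dup_p)
      rec <- ev[rep.int(seq_len(nrow(ev)), times), ]
      rec$sample_id <- samples$sample_id[i]
      recs[[i]] <- rec
      truth[[i]] <- tibble(element_id = el$element_id,
                           sample_id = samples$sample_id[i],
                           fold = fold, planted_events = n_ev)
    }
    list(records = select(list_rbind(recs), "sample_id", "chrom", "pos",
                          "strand", "umi"),
         elements = el,
         samples = select(samples, "sample_id", "condition", "batch"),
         truth = list_rbind(truth))
  })
}

#' Simulate binding and control signal tracks with replicate peak sets
#'
#' Per-element binding intensities are heavy-tailed (log-normal); the binding
#' track carries each element's intensity with a 1-bp summit boost at the
#' true summit, the IgG control is flat noise over elements, and the
#' accessibility track has an independent intensity with the same summit
#' boost (for summit-window recovery). Replicate peak sets per assay include
#' each true region independently with the configured reproducibility
#' probability, with jittered boundaries.
#'
#' @inheritParams simulate_cut_sites
#' @return List with `elements` (truth), `binding_track`, `igg_track`,
#'   `atac_track` (run tibbles), and `peak_sets`: `atac`/`k27`/`bliss` lists
#'   of replicate interval tibbles and `binding` (true binding-peak windows).
#' @export
simulate_signal_tracks <- function(cfg = sim_config(), seed) {
  el <- sim_elements(cfg, seed)
  sc <- cfg$signal
  withr::with_seed(seed + 2L, {
    triangle <- function(value) {
      bind_rows(
        tibble(chrom = el$chrom, start = el$start, end = el$summit,
               value = value),
        tibble(chrom = el$chrom, start = el$summit, end = el$summit + 1L,
               value = value * sc$summit_boost),
        tibble(chrom = el$chrom, start = el$summit + 1L, end = el$end,
               value = value)) |>
        filter(.data$end > .data$start) |>
        arrange(.data$chrom, .data$start)
    }
    binding_track <- triangle(el$binding)
    atac_track <- triangle(el$atac_intensity)
    igg_track <- tibble(chrom = el$chrom, start = el$start, end = el$end,
                        value = stats::rgamma(nrow(el), sc$igg_shape,
                                              sc$igg_shape)) |>
      arrange(.data$chrom, .data$start)

    jitter_set <- function(rows, p) {
      keep <- runif(nrow(rows)) < p
      out <- rows[keep, c("chrom", "start", "end")]
      n <- nrow(out)
      out$start <- pmax(0L, out$start - sample.int(sc$peak_jitter, n,
                                                   replace = TRUE))
      out$end <- out$end + sample.int(sc$peak_jitter, n, replace = TRUE)
      arrange(out, .data$chrom, .data$start)
    }
    atac_truth <- el[el$source %in% c("ATAC", "both"), ]
    k27_truth <- el[el$source %in% c("K27ac", "both"), ]
    peak_sets <- list(
      atac = map(seq_len(sc$replicates$atac$n),
                 ~ jitter_set(atac_truth, sc$replicates$atac$p)),
      k27 = map(seq_len(sc$replicates$k27$n),
                ~ jitter_set(k27_truth, sc$replicates$k27$p)),
      bliss = map(seq_len(sc$replicates$bliss$n),
                  ~ jitter_set(el, sc$replicates$bliss$p)),
      binding = tibble(chrom = el$chrom[el$has_binding_peak],
                       start = el$summit[el$has_binding_peak] - 500L,
                       end = el$summit[el$has_binding_peak] + 500L))
    list(elements = el, binding_track = binding_track,
         igg_track = igg_track, atac_track = atac_track,
         peak_sets = peak_sets)
  })
}

#' Simulate a normalized single-nucleus expression matrix
#'
#' Gene baselines are log-normal; expression values are baseline times
#' multiplicative log-normal noise (an already-normalized matrix; raw-count
#' modelling and normalization are upstream of this package). Target genes
#' are drawn from the top expression decile and multiplied by `1 - effect` in
#' Cre-infected nuclei. Viral transcript counts follow the infection truth
#' with detection dropout.
#'
#' @inheritParams simulate_cut_sites
#' @return List with `expr` (tibble: `gene` + nucleus columns), `nuclei`
#'   (tibble: `nucleus_id`, `cell_type`, `mCherry`, `GFP`), and `truth`
#'   (list: `infection` per nucleus, `targets`, `effect`).
#' @export
simulate_expression <- function(cfg = sim_config(), seed) {
  ec <- cfg$expr
  withr::with_seed(seed, {
    G <- ec$n_genes
    genes <- sprintf("gene_%04d", seq_len(G))
    base <- stats::rlnorm(G, ec$gene_meanlog, ec$gene_sdlog)
    grp <- rep(names(ec$n_nuclei), ec$n_nuclei)
    N <- length(grp)
    ids <- sprintf("nuc_%04d", seq_len(N))
    top_decile <- genes[order(base, decreasing = TRUE)][seq_len(ceiling(G / 10))]
    targets <- sample(top_decile, ec$n_targets)
    eff <- rep(1, G); names(eff) <- genes
    m <- matrix(stats::rlnorm(G * N, 0, ec$noise_sdlog), nrow = G) * base
    cre_cols <- which(grp == "Cre")
    m[match(targets, genes), cre_cols] <-
      m[match(targets, genes), cre_cols] * (1 - ec$effect)
    colnames(m) <- ids; rownames(m) <- genes

    detect <- function(n, rate) {
      rpois(n, rate) * rbinom(n, 1, ec$viral_detect)
    }
    mch <- ifelse(grp == "Cre", detect(N, ec$viral_rate),
                  detect(N, ec$viral_background))
    gfp <- ifelse(grp == "DeltaCre", detect(N, ec$viral_rate),
                  detect(N, ec$viral_background))
    nuclei <- tibble(nucleus_id = ids, cell_type = ec$cell_type,
                     mCherry = as.integer(mch), GFP = as.integer(gfp))
    list(expr = dplyr::bind_cols(tibble(gene = genes), as_tibble(m)),
         nuclei = nuclei,
         truth = list(infection = tibble(nucleus_id = ids,
                                         true_infection = grp),
                      targets = targets, effect = ec$effect))
  })
}
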