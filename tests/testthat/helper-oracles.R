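# Brute-force per-base oracles for the interval operations, and small fixture
# builders. The oracles materialise explicit depth arrays and stay independent
# of the coverage-based implementation they check.

iv <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start,
                                                 end = end)

# per-base depth array oracle over one chromosome of length len
depth_array <- function(intervals, len) {
  d <- integer(len)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i] + 1L
    e <- intervals$end[i]
    d[s:e] <- d[s:e] + 1L
  }
  d
}

# segment a logical per-base mask into 0-based half-open intervals
segments_from_mask <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
}

brute_merge <- function(intervals, gap, len) {
  out <- lapply(sort(unique(intervals$chrom)), function(cm) {
    x <- intervals[intervals$chrom == cm, ]
    covered <- depth_array(x, len) > 0
    # bridge gaps of <= gap uncovered bases between covered runs
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (!r$values[k] && k > 1 && k < length(r$values) &&
          r$lengths[k] <= gap) {
        covered[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
      }
    }
    segments_from_mask(covered, cm)
  })
  dplyr::bind_rows(out)
}

brute_reproducible <- function(peak_sets, m, len) {
  chroms <- sort(unique(unlist(lapply(peak_sets, function(s) s$chrom))))
  out <- lapply(chroms, function(cm) {
    depth <- integer(len)
    for (s in peak_sets) {
      x <- s[s$chrom == cm, ]
      if (nrow(x)) depth <- depth + (depth_array(x, len) > 0)
    }
    segments_from_mask(depth >= m, cm)
  })
  dplyr::bind_rows(out)
}

brute_summit <- function(interval, track, half_width, len) {
  vals <- numeric(len)
  tr <- track[track$chrom == interval$chrom, ]
  for (i in seq_len(nrow(tr))) {
    vals[(tr$start[i] + 1):tr$end[i]] <- vals[(tr$start[i] + 1):tr$end[i]] +
      tr$value[i]
  }
  seg <- vals[(interval$start + 1):interval$end]
  if (all(seg == 0)) {
    summit <- floor((interval$start + interval$end) / 2)
  } else {
    summit <- interval$start + which.max(seg) - 1L
  }
  c(start = summit - half_width, end = summit + half_width, summit = summit)
}

# brute-force consensus oracle: enumerate every (family, position) pair
brute_consensus <- function(reads, panel, min_depth = 10) {
  refs <- strsplit(panel$ref_seq, "")
  names(refs) <- panel$amplicon_id
  out <- list()
  for (amp in panel$amplicon_id) {
    r <- reads[reads$amplicon_id == amp, ]
    L <- length(refs[[amp]])
    fams <- split(r$calls, r$umi)
    fams <- fams[vapply(fams, length, 1L) >= min_depth]
    n_fam <- matrix(0L, nrow = L, ncol = 8,
                    dimnames = list(NULL, c("n_families", "A", "C", "G", "T",
                                            "del", "ins", "alt")))
    for (fam in fams) {
      # decode each read into per-position calls
      decoded <- lapply(fam, function(cs) {
        base <- refs[[amp]]
        insv <- rep("", L)
        if (!is.na(cs) && cs != "") {
          for (tok in strsplit(cs, ";")[[1]]) {
            m <- regmatches(tok, regexec("^([0-9]+)(.*)$", tok))[[1]]
            p <- as.integer(m[2]); body <- m[3]
            if (body == "-") base[p] <- "-"
            else if (startsWith(body, "+")) insv[p] <- substring(body, 2)
            else base[p] <- body
          }
        }
        list(base = base, ins = insv)
      })
      for (p in seq_len(L)) {
        bcalls <- vapply(decoded, function(d) d$base[p], character(1))
        icalls <- vapply(decoded, function(d) d$ins[p], character(1))
        if (length(unique(bcalls)) == 1 && length(unique(icalls)) == 1) {
          n_fam[p, "n_families"] <- n_fam[p, "n_families"] + 1L
          b <- bcalls[1]
          col <- if (b == "-") "del" else b
          n_fam[p, col] <- n_fam[p, col] + 1L
          if (icalls[1] != "") n_fam[p, "ins"] <- n_fam[p, "ins"] + 1L
          if (b != refs[[amp]][p] || icalls[1] != "") {
            n_fam[p, "alt"] <- n_fam[p, "alt"] + 1L
          }
        }
      }
    }
    out[[amp]] <- tibble::tibble(
      amplicon_id = amp, pos = seq_len(L), ref = refs[[amp]],
      n_families = n_fam[, "n_families"], n_A = n_fam[, "A"],
      n_C = n_fam[, "C"], n_G = n_fam[, "G"], n_T = n_fam[, "T"],
      n_del = n_fam[, "del"], n_ins = n_fam[, "ins"], n_alt = n_fam[, "alt"])
  }
  dplyr::bind_rows(out)
}

# random interval set on one chromosome for property tests
random_interval_set <- function(len, n_max = 20) {
  n <- sample.int(n_max, 1)
  start <- sample.int(len - 50, n, replace = TRUE) - 1L
  width <- sample.int(200, n, replace = TRUE)
  tibble::tibble(chrom = "c1", start = start,
                 end = pmin(start + width, len))
}

random_umis <- function(n, len = 8) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m))
}

# minimal panel fixture
toy_panel <- function(ref_seq = "ACGTACGTAC", primer_len = 2L,
                      id = "amp1") {
  dsbmut::amplicon_panel(tibble::tibble(
    amplicon_id = id, chrom = "chr1", start = 0L,
    end = nchar(ref_seq), ref_seq = ref_seq, primer_len = primer_len,
    umi_len = 12L))
}

# n reads with identical calls for each of the given UMIs
reads_for <- function(umis, sizes, calls = "", amplicon_id = "amp1") {
  calls <- rep(calls, length.out = length(umis))
  tibble::tibble(
    amplicon_id = amplicon_id,
    umi = rep(umis, sizes),
    calls = rep(calls, sizes))
}
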