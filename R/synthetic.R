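#' Simulation configuration
#'
#' Study-condition defaults: 3 culture days x 3 biological replicates,
#' Gaussian chromatographic peaks of 12 s FWHM sampled every 2 s (typical
#' nanoLC), additive Gaussian intensity noise truncated at zero with
#' SNR = apex/sigma defined per trace, and a 10% log-normal run-to-run
#' variation of total analyte signal (which is common to the light and heavy
#' trace of an analyte, so it perturbs abundances but cancels in the heavy
#' fraction). Default SNR is 50, reflecting the strong XIC signals of
#' abundant histone peptides; recovery stress tests use SNR 20.
#'
#' @param seed Integer seed; a fixed seed makes every generator byte-stable.
#' @param days Labeling days simulated.
#' @param replicates Biological replicates per day and condition.
#' @param peak_fwhm Chromatographic peak full width at half maximum, s.
#' @param dt Sampling interval, s.
#' @param snr Apex signal-to-noise ratio (> 0).
#' @param area_cv Log-normal sdlog of per-analyte total-signal variation.
#' @param n_frag_pairs Distinguishing fragment pairs simulated per
#'   positional-isomer pair.
#' @param rt_center Retention-time apex, s.
#' @param total_area Total XIC area of a backbone family, arbitrary units.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, days = 1:3, replicates = 3L,
                       peak_fwhm = 12, dt = 2, snr = 50, area_cv = 0.10,
                       n_frag_pairs = 4L, rt_center = 600,
                       total_area = 1e6) {
  if (snr <= 0) stop("snr must be > 0")
  if (peak_fwhm <= 0 || dt <= 0) stop("peak_fwhm and dt must be > 0")
  structure(list(seed = as.integer(seed), days = days,
                 replicates = as.integer(replicates), peak_fwhm = peak_fwhm,
                 dt = dt, snr = snr, area_cv = area_cv,
                 n_frag_pairs = as.integer(n_frag_pairs),
                 rt_center = rt_center, total_area = total_area),
            class = "sim_config")
}

# One noisy Gaussian trace with the given area; sigma_noise = apex/snr,
# truncated at zero. noise = FALSE gives the exact profile.
.gauss_trace <- function(area, apex_rt, config, noise = TRUE) {
  sigma <- config$peak_fwhm / (2 * sqrt(2 * log(2)))
  rt <- seq(apex_rt - 3 * config$peak_fwhm, apex_rt + 3 * config$peak_fwhm,
            by = config$dt)
  y <- area * stats::dnorm(rt, apex_rt, sigma)
  if (noise && area > 0) {
    apex <- area / (sigma * sqrt(2 * pi))
    y <- pmax(0, y + stats::rnorm(length(y), 0, apex / config$snr))
  }
  data.frame(rt = rt, intensity = y)
}

#' Simulate a co-eluting light/heavy XIC pair
#'
#' Both traces share the retention apex (non-deuterated isotope labels
#' co-elute) and, before noise, the heavy share of the total area equals
#' `true_f`.
#'
#' @param true_f True heavy fraction in \[0, 1\].
#' @param config A [sim_config()]. Uses the current RNG state; call
#'   `set.seed()` (or use [simulate_run()]) for reproducibility.
#' @param total_area Combined light + heavy area.
#' @param apex_rt Retention apex, s.
#' @param noise Add intensity noise? Default TRUE.
#' @return A list with data.frames `light` and `heavy` (columns `rt`,
#'   `intensity`).
#' @export
simulate_xic_pair <- function(true_f, config = sim_config(),
                              total_area = config$total_area,
                              apex_rt = config$rt_center, noise = TRUE) {
  if (true_f < 0 || true_f > 1) stop("true_f must be in [0, 1]")
  list(light = .gauss_trace((1 - true_f) * total_area, apex_rt, config, noise),
       heavy = .gauss_trace(true_f * total_area, apex_rt, config, noise))
}

#' Shipped bottom-up ground truth
#'
#' Per-proteoform true relative abundances (summing to 1 within each backbone
#' family) and true heavy fractions for the built-in H3/H4 panel, for each
#' day and condition. Day-2 reference fractions encode the field's
#' qualitative expectations: acetylated forms label faster than
#' trimethylated ones, K9me1 > K9me2 > K9me3, bivalent
#' K27me3K36me2 tracks the repressive mark, and the five reference marks
#' carry fractions 0.665 (K27ac), 0.582 (K36me2), 0.484 (K9ac), 0.436
#' (K4me3) and 0.235 (K27me3). Fractions follow the replication-dilution
#' time course f(d) = 1 - (1 - f2)^(d/2), so they are monotone in day and
#' hit the reference at day 2.
#'
#' The second condition `"TRT"` perturbs, relative to `"WT"`: the day-2
#' abundances of K4me3/K4ac by 2^-8 / 2^+8 (a 16-unit spread of abundance
#' log2 fold changes) and the heavy fractions of K9me2/K27me1 by
#' 2^+0.25 / 2^-0.25 (a 0.5-unit spread of labeling log2 fold changes),
#' a constructed 32x dynamic-range contrast on orthogonal proteoform sets.
#'
#' @param days Days to include, default 1:3.
#' @param conditions Conditions to include, default `c("WT", "TRT")`.
#' @param panel Peptide panel, default [default_panel()].
#' @return A data.frame of class `"ground_truth"` with columns
#'   `proteoform_id`, `family`, `day`, `condition`, `rel_abundance`,
#'   `heavy_fraction`.
#' @export
default_truth <- function(days = 1:3, conditions = c("WT", "TRT"),
                          panel = default_panel()) {
  base <- data.frame(
    proteoform_id = c(
      "H3_3_8_unmod", "H3_3_8_K4me3", "H3_3_8_K4ac",
      "H3_9_17_unmod", "H3_9_17_K9me1", "H3_9_17_K9me2", "H3_9_17_K9me3",
      "H3_9_17_K9ac", "H3_9_17_K14ac",
      "H3_18_26_unmod", "H3_18_26_K18ac", "H3_18_26_K23ac",
      "H3_18_26_K18acK23ac",
      "H3_27_40_unmod", "H3_27_40_K27me1", "H3_27_40_K27me3",
      "H3_27_40_K36me2", "H3_27_40_K27me3K36me2", "H3_27_40_K27ac",
      "H4_4_17_unmod", "H4_4_17_K5ac", "H4_4_17_K16ac",
      "H4_4_17_K5acK8acK12acK16ac"),
    ab = c(0.3575, 0.64, 0.0025,
           0.40, 0.10, 0.16, 0.20, 0.06, 0.08,
           0.55, 0.15, 0.20, 0.10,
           0.18, 0.20, 0.30, 0.12, 0.17, 0.03,
           0.40, 0.20, 0.25, 0.15),
    f2 = c(0.50, 0.436, 0.60,
           0.50, 0.40, 0.28, 0.15, 0.484, 0.52,
           0.50, 0.55, 0.52, 0.62,
           0.50, 0.42, 0.235, 0.582, 0.27, 0.665,
           0.50, 0.60, 0.58, 0.68),
    stringsAsFactors = FALSE)
  stopifnot(setequal(base$proteoform_id, panel$proteoform_id))
  base$family <- panel$family[match(base$proteoform_id, panel$proteoform_id)]
  out <- do.call(rbind, lapply(conditions, function(cond) {
    b <- base
    if (cond == "TRT") {
      b$ab[b$proteoform_id == "H3_3_8_K4me3"] <- 0.64 * 2^-8
      b$ab[b$proteoform_id == "H3_3_8_K4ac"] <- 0.0025 * 2^8
      b$ab[b$proteoform_id == "H3_3_8_unmod"] <-
        1 - sum(b$ab[b$family == "H3_3_8" & b$proteoform_id != "H3_3_8_unmod"])
      b$f2[b$proteoform_id == "H3_9_17_K9me2"] <- 0.28 * 2^0.25
      b$f2[b$proteoform_id == "H3_27_40_K27me1"] <- 0.42 * 2^-0.25
    }
    do.call(rbind, lapply(days, function(d) {
      data.frame(proteoform_id = b$proteoform_id, family = b$family,
                 day = d, condition = cond, rel_abundance = b$ab,
                 heavy_fraction = 1 - (1 - b$f2)^(d / 2),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Simulate a full bottom-up run
#'
#' Generates one light/heavy XIC pair per proteoform x replicate x day x
#' condition, with independent replicate noise, and (optionally) a DIA
#' fragment table for every positional-isomer group in the panel. The ground
#' truth and configuration ride along as attributes so recovery can be
#' checked row by row.
#'
#' @param truth A `"ground_truth"` data.frame (see [default_truth()]).
#' @param config A [sim_config()]; `config$seed` is set at entry, so output
#'   is byte-identical for identical inputs.
#' @param panel Peptide panel.
#' @param fragments Also simulate fragment tables for isomer groups?
#' @param noise Add noise? `FALSE` gives exact signals for round-trip tests.
#' @return A list of class `"signal_set"` with elements `signals` (long
#'   data.frame: `proteoform_id`, `family`, `label_state`, `replicate`,
#'   `day`, `condition`, `rt`, `intensity`), `fragments` (data.frame or
#'   NULL), `truth`, `config`, and `isomer_map`.
#' @export
simulate_run <- function(truth, config = sim_config(), panel = default_panel(),
                         fragments = TRUE, noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth") || is.data.frame(truth))
  set.seed(config$seed)
  truth <- truth[order(truth$condition, truth$day, truth$proteoform_id), ]
  key <- unique(truth[, c("day", "condition")])
  sig <- list(); frg <- list()
  imap <- .isomer_pairs(panel)
  for (r in seq_len(nrow(key))) {
    d <- key$day[r]; cond <- key$condition[r]
    tt <- truth[truth$day == d & truth$condition == cond, ]
    for (rep_i in seq_len(config$replicates)) {
      for (i in seq_len(nrow(tt))) {
        area <- config$total_area * tt$rel_abundance[i] *
          if (noise) exp(stats::rnorm(1, 0, config$area_cv)) else 1
        pair <- simulate_xic_pair(tt$heavy_fraction[i], config,
                                  total_area = area, noise = noise)
        for (st in c("light", "heavy")) {
          tr <- pair[[st]]
          sig[[length(sig) + 1L]] <- data.frame(
            proteoform_id = tt$proteoform_id[i], family = tt$family[i],
            label_state = st, replicate = rep_i, day = d, condition = cond,
            rt = tr$rt, intensity = tr$intensity, stringsAsFactors = FALSE)
        }
      }
      if (fragments && nrow(imap)) {
        for (g in seq_len(nrow(imap))) {
          ta <- tt[tt$proteoform_id == imap$proteoform_a[g], ]
          tb <- tt[tt$proteoform_id == imap$proteoform_b[g], ]
          if (!nrow(ta) || !nrow(tb)) next
          for (win in c("light", "heavy")) {
            wa <- ta$rel_abundance *
              if (win == "heavy") ta$heavy_fraction else 1 - ta$heavy_fraction
            wb <- tb$rel_abundance *
              if (win == "heavy") tb$heavy_fraction else 1 - tb$heavy_fraction
            ft <- simulate_isobaric_fragments(wa / (wa + wb), config,
                                              noise = noise)
            ft$group <- imap$group[g]; ft$window <- win
            ft$replicate <- rep_i; ft$day <- d; ft$condition <- cond
            frg[[length(frg) + 1L]] <- ft
          }
        }
      }
    }
  }
  structure(list(
    signals = do.call(rbind, sig),
    fragments = if (length(frg)) do.call(rbind, frg) else NULL,
    truth = truth, config = config, isomer_map = imap),
    class = "signal_set")
}

# Pairwise isomer groups from the panel; groups with > 2 members are
# returned with resolvable = FALSE (pairwise fragment resolution only).
.isomer_pairs <- function(panel) {
  gr <- panel$isomer_group[!is.na(panel$isomer_group)]
  out <- lapply(unique(gr), function(g) {
    ids <- panel$proteoform_id[!is.na(panel$isomer_group) &
                                 panel$isomer_group == g]
    data.frame(group = g,
               proteoform_a = ids[1],
               proteoform_b = ids[min(2, length(ids))],
               n_members = length(ids),
               resolvable = length(ids) == 2L,
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(group = character(), proteoform_a = character(),
                      proteoform_b = character(), n_members = integer(),
                      resolvable = logical()))
  do.call(rbind, out)
}

#' Simulate DIA fragments for a positional-isomer pair
#'
#' Distinguishing fragment pairs split a common precursor intensity in
#' proportion `mix : (1 - mix)` with per-fragment multiplicative log-normal
#' noise (sdlog = 1/snr) plus an additive noise floor; shared fragments carry
#' the summed intensity.
#'
#' @param mix True fraction of the first isomer (form A) in \[0, 1\].
#' @param config A [sim_config()]. Uses the current RNG state.
#' @param total Precursor-level intensity scale.
#' @param noise Add noise?
#' @return A data.frame with columns `fragment_id`, `species` (`"A"`, `"B"`
#'   or `"shared"`), `intensity`.
#' @export
simulate_isobaric_fragments <- function(mix, config = sim_config(),
                                        total = 1e4, noise = TRUE) {
  if (mix < 0 || mix > 1) stop("mix must be in [0, 1]")
  n <- config$n_frag_pairs
  base <- total * exp(stats::rnorm(n, 0, if (noise) 0.4 else 0))
  mult <- function(k) if (noise) exp(stats::rnorm(k, 0, 1 / config$snr)) else 1
  floor_sd <- total / (50 * config$snr)
  addf <- function(k) if (noise) abs(stats::rnorm(k, 0, floor_sd)) else 0
  rbind(
    data.frame(fragment_id = paste0("pair", seq_len(n)), species = "A",
               intensity = mix * base * mult(n) + addf(n)),
    data.frame(fragment_id = paste0("pair", seq_len(n)), species = "B",
               intensity = (1 - mix) * base * mult(n) + addf(n)),
    data.frame(fragment_id = paste0("shared", 1:2), species = "shared",
               intensity = total * mult(2) + addf(2))
  )
}

#' Shipped middle-down ground truth
#'
#' True abundance distribution and heavy fractions over 0..15 methyl
#' equivalents of the H3 1-50 tail. Equivalents divisible by 3 (acetyl-rich
#' combinations, an acetyl weighing ~3 methyl equivalents nominally) carry
#' the highest labeling; the fully unmodified tail and hypermethylated
#' states (n >= 10 not acetyl-rich) the lowest, mirroring the expectation
#' that hyperacetylated tails turn over fastest.
#'
#' @return A data.frame with columns `n_equiv`, `abundance` (sums to 1),
#'   `heavy_fraction`, `group`.
#' @export
default_md_truth <- function() {
  n <- 0:15
  ab <- stats::dpois(n, 4); ab <- ab / sum(ab)
  f <- c(0.25, 0.40, 0.45, 0.62, 0.50, 0.52, 0.64, 0.48,
         0.46, 0.66, 0.35, 0.32, 0.68, 0.28, 0.25, 0.22)
  grp <- ifelse(n == 0, "unmod",
                ifelse(n %in% c(3, 6, 9, 12), "ac-rich",
                       ifelse(n >= 10, "me-rich", "mixed")))
  data.frame(n_equiv = n, abundance = ab, heavy_fraction = f, group = grp)
}

#' Simulate a middle-down precursor trace table
#'
#' One light and one heavy Gaussian trace per methyl-equivalent state at the
#' ladder's target m/z (jittered within a couple of ppm, as real calibration
#' would), with areas proportional to abundance x (1 - f) and abundance x f.
#'
#' @param truth_md Middle-down truth, see [default_md_truth()].
#' @param config A [sim_config()]; `config$seed` is set at entry.
#' @param backbone Tail backbone, default H3.1 residues 1-50.
#' @param z Charge state, default 8.
#' @param label Isotope label, default heavy histidine.
#' @param mz_jitter_ppm SD of the m/z calibration jitter, ppm.
#' @param noise Add intensity noise?
#' @return A list with `traces` (data.frame `mz`, `rt`, `intensity`),
#'   `ladder`, `truth`, `config`.
#' @export
simulate_ladder_run <- function(truth_md = default_md_truth(),
                                config = sim_config(),
                                backbone = h3_tail_1_50(), z = 8L,
                                label = get_label("H-heavy"),
                                mz_jitter_ppm = 2, noise = TRUE) {
  set.seed(config$seed)
  lad <- methyl_ladder(backbone, max_equiv = max(truth_md$n_equiv), z = z,
                       label = label)
  rows <- list()
  for (i in seq_len(nrow(truth_md))) {
    ab <- truth_md$abundance[i]; f <- truth_md$heavy_fraction[i]
    for (st in c("light", "heavy")) {
      target <- if (st == "light") lad$light_mz[i] else lad$heavy_mz[i]
      obs_mz <- target * (1 + if (noise)
        stats::rnorm(1, 0, mz_jitter_ppm * 1e-6) else 0)
      area <- config$total_area * ab * if (st == "heavy") f else 1 - f
      tr <- .gauss_trace(area, config$rt_center, config, noise)
      rows[[length(rows) + 1L]] <- data.frame(mz = obs_mz, rt = tr$rt,
                                              intensity = tr$intensity)
    }
  }
  list(traces = do.call(rbind, rows), ladder = lad, truth = truth_md,
       config = config)
}

#' Simulate two interval sets with a controlled overlap fraction
#'
#' Construction: the genome is cut into equal slots, one per B interval and
#' one per non-overlapping A interval; `round(target * n_a)` A intervals are
#' placed inside randomly chosen B intervals (guaranteeing >= 1 bp overlap)
#' and the rest in their own slots (guaranteeing none), so the realized
#' fraction of A intervals overlapping B equals the target to within
#' rounding (1/n_a). A uniform random read set is also returned.
#'
#' @param genome_len Genome length in bp (single chromosome `"chr1"`).
#' @param n_a,n_b Interval counts.
#' @param target Target fraction of A intervals overlapping B, in \[0, 1\].
#' @param seed Integer seed.
#' @param n_reads Number of reads, default 200.
#' @param read_len Read length, bp.
#' @return A list with `GRanges` elements `a`, `b`, `reads` and the realized
#'   `fraction`.
#' @export
simulate_intervals <- function(genome_len, n_a, n_b, target, seed = 1L,
                               n_reads = 200L, read_len = 50L) {
  if (target < 0 || target > 1) stop("target must be in [0, 1]")
  set.seed(seed)
  k <- round(target * n_a)
  n_slots <- n_b + (n_a - k)
  slot <- floor(genome_len / n_slots)
  if (slot < 8) stop("infeasible packing: ", n_slots, " slots of < 8 bp in ",
                     genome_len, " bp")
  starts <- (seq_len(n_slots) - 1L) * slot
  starts <- sample(starts)                       # shuffle slot order
  w <- max(2L, floor(slot * 0.6))
  mk <- function(s0) {                           # interval within its slot
    off <- sample.int(slot - w - 1L, 1L)
    c(s0 + off, s0 + off + w)                    # 0-based half-open
  }
  b_iv <- t(vapply(starts[seq_len(n_b)], mk, numeric(2)))
  a_free <- if (n_a - k > 0)
    t(vapply(starts[n_b + seq_len(n_a - k)], mk, numeric(2))) else
      matrix(numeric(0), 0, 2)
  a_ovl <- if (k > 0) t(vapply(sample(seq_len(n_b), k, replace = TRUE),
    function(j) {
      lo <- b_iv[j, 1]; hi <- b_iv[j, 2]
      s <- lo + sample.int(hi - lo, 1L) - 1L
      c(s, s + max(1L, sample.int(hi - s, 1L)))
    }, numeric(2))) else matrix(numeric(0), 0, 2)
  a_iv <- rbind(a_ovl, a_free)
  to_gr <- function(m) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2]))
  rs <- sample.int(genome_len - read_len, n_reads, replace = TRUE) - 1L
  list(a = to_gr(a_iv), b = to_gr(b_iv),
       reads = to_gr(cbind(rs, rs + read_len)),
       fraction = k / n_a)
}
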