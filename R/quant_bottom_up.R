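#' Trapezoidal area of an extracted ion chromatogram
#'
#' @param trace A data.frame with strictly increasing `rt` (s) and
#'   non-negative `intensity`, at least 3 points.
#' @param rt_window Optional `c(lo, hi)` restricting integration; must
#'   overlap at least 3 trace points.
#' @return The (non-negative) area.
#' @export
integrate_trace <- function(trace, rt_window = NULL) {
  stopifnot(is.data.frame(trace), all(c("rt", "intensity") %in% names(trace)))
  rt <- trace$rt; y <- trace$intensity
  if (length(rt) < 3) stop("need at least 3 points to integrate")
  if (any(diff(rt) <= 0)) stop("rt must be strictly increasing")
  if (any(y < 0)) stop("intensities must be >= 0")
  if (!is.null(rt_window)) {
    keep <- rt >= rt_window[1] & rt <= rt_window[2]
    if (sum(keep) < 3) stop("rt window overlaps fewer than 3 trace points")
    rt <- rt[keep]; y <- y[keep]
  }
  pracma::trapz(rt, y)
}

#' Heavy-label fraction of a light/heavy area pair
#'
#' heavy / (light + heavy). Both areas zero is an undefined-signal error
#' (condition class `"histurnover_undefined_signal"`), which
#' [quantify_run()] converts into a flagged record rather than a silent 0.
#'
#' @param light_area,heavy_area Non-negative areas.
#' @return A fraction in \[0, 1\].
#' @export
heavy_fraction <- function(light_area, heavy_area) {
  if (light_area < 0 || heavy_area < 0) stop("areas must be >= 0")
  if (light_area + heavy_area == 0)
    stop(structure(class = c("histurnover_undefined_signal",
                             "error", "condition"),
                   list(message = "light and heavy areas are both zero",
                        call = sys.call())))
  heavy_area / (light_area + heavy_area)
}

#' Relative abundance within a backbone family
#'
#' Each proteoform's total area (its light + heavy areas already summed)
#' divided by the family total, so the family sums to 1 — the convention of
#' treating all peptides with the same amino-acid sequence, including all
#' modified forms, as 100%.
#'
#' @param areas Named non-negative numeric vector of per-proteoform total
#'   areas; at least one must be positive.
#' @return Named fractions summing to 1.
#' @export
relative_abundance <- function(areas) {
  if (any(areas < 0)) stop("areas must be >= 0")
  tot <- sum(areas)
  if (tot == 0) stop("zero family total area")
  areas / tot
}

#' Resolve a positional-isomer pair from distinguishing fragments
#'
#' For every distinguishing fragment pair, the share of form A is
#' a / (a + b); the returned mix is the arithmetic (unweighted) mean of
#' those per-fragment shares — "averaging the ratio for each fragment ion
#' with different mass between the two species". With a single
#' distinguishing pair this reduces to that pair's ratio. No distinguishing
#' fragments gives an unresolved result (mix NA, `resolved = FALSE`), in
#' which case only family-level quantification is possible.
#'
#' @param frags A fragment data.frame with columns `fragment_id`, `species`
#'   (`"A"`, `"B"`, `"shared"`), `intensity`.
#' @return A list with `mix_a`, `per_fragment`, `n_fragments`, `resolved`.
#' @export
resolve_isobaric <- function(frags) {
  stopifnot(all(c("fragment_id", "species", "intensity") %in% names(frags)))
  d <- frags[frags$species %in% c("A", "B"), ]
  ids <- intersect(d$fragment_id[d$species == "A"],
                   d$fragment_id[d$species == "B"])
  if (!length(ids))
    return(list(mix_a = NA_real_, per_fragment = numeric(0),
                n_fragments = 0L, resolved = FALSE))
  per <- vapply(ids, function(id) {
    a <- sum(d$intensity[d$fragment_id == id & d$species == "A"])
    b <- sum(d$intensity[d$fragment_id == id & d$species == "B"])
    if (a + b == 0) return(NA_real_)
    a / (a + b)
  }, numeric(1))
  per <- per[!is.na(per)]
  if (!length(per))
    return(list(mix_a = NA_real_, per_fragment = numeric(0),
                n_fragments = 0L, resolved = FALSE))
  list(mix_a = mean(per), per_fragment = per, n_fragments = length(per),
       resolved = TRUE)
}

# Integrate the light/heavy pair of one analyte run. The shared window is
# +/- window_widths peak widths around the apex of the stronger trace
# (co-elution assumed: the labels are non-deuterated).
.quant_pair <- function(light, heavy, peak_fwhm, window_widths = 3) {
  ref <- if (max(light$intensity) >= max(heavy$intensity)) light else heavy
  apex <- ref$rt[which.max(ref$intensity)]
  win <- c(apex - window_widths * peak_fwhm, apex + window_widths * peak_fwhm)
  c(light = integrate_trace(light, win), heavy = integrate_trace(heavy, win))
}

#' Quantify a bottom-up run
#'
#' Turns a signal set (simulated or read from TSV) into one QuantRecord per
#' proteoform x replicate x day x condition: integrated light/heavy areas
#' over a shared window of +/- 3 peak widths around the apex, the heavy
#' fraction, and the relative abundance within the backbone family.
#' Positional-isomer pairs are re-apportioned from their fragment tables
#' when present (independently in the light and heavy precursor windows, so
#' each isomer keeps its own heavy fraction); pairs without fragment data,
#' or isomer groups of 3+ members, are flagged `"unresolved_isomer"`.
#' Families whose total area falls below `area_floor` are reported missing
#' (`"low_signal"`, NA fractions), not zero. Signals for analytes absent
#' from the panel are skipped with a warning.
#'
#' @param run A `"signal_set"` from [simulate_run()], or a list with
#'   elements `signals` (and optionally `fragments`, `isomer_map`).
#' @param panel Peptide panel.
#' @param config A [sim_config()] supplying `peak_fwhm`; defaults to the
#'   run's own config.
#' @param area_floor Minimum family total area for quantification.
#' @param apex_mode Use apex height instead of integrated area? Default
#'   FALSE (area, consistent with total-area relative ratios).
#' @return A data.frame of class `"quant_table"`: `proteoform_id`, `family`,
#'   `replicate`, `day`, `condition`, `light_area`, `heavy_area`,
#'   `relative_abundance`, `heavy_fraction`, `resolved`, `flag`.
#' @export
quantify_run <- function(run, panel = default_panel(), config = run$config,
                         area_floor = 0, apex_mode = FALSE) {
  signals <- run$signals
  frags <- run$fragments
  imap <- run$isomer_map
  if (is.null(imap)) imap <- .isomer_pairs(panel)
  orphan <- setdiff(unique(signals$proteoform_id), panel$proteoform_id)
  if (length(orphan)) {
    warning("skipping analytes not in panel: ", paste(orphan, collapse = ", "))
    signals <- signals[!signals$proteoform_id %in% orphan, ]
  }
  key <- unique(signals[, c("proteoform_id", "family", "replicate",
                            "day", "condition")])
  rec <- key
  rec$light_area <- rec$heavy_area <- NA_real_
  for (i in seq_len(nrow(key))) {
    sel <- signals$proteoform_id == key$proteoform_id[i] &
      signals$replicate == key$replicate[i] & signals$day == key$day[i] &
      signals$condition == key$condition[i]
    li <- signals[sel & signals$label_state == "light", c("rt", "intensity")]
    he <- signals[sel & signals$label_state == "heavy", c("rt", "intensity")]
    if (apex_mode) {
      rec$light_area[i] <- max(li$intensity); rec$heavy_area[i] <- max(he$intensity)
    } else {
      ar <- .quant_pair(li, he, config$peak_fwhm)
      rec$light_area[i] <- ar["light"]; rec$heavy_area[i] <- ar["heavy"]
    }
  }
  rec$resolved <- TRUE
  rec$flag <- "ok"

  # fragment-level re-apportioning of positional-isomer pairs
  if (nrow(imap)) for (g in seq_len(nrow(imap))) {
    members <- c(imap$proteoform_a[g], imap$proteoform_b[g])
    runs <- unique(rec[rec$proteoform_id %in% members,
                       c("replicate", "day", "condition")])
    for (r in seq_len(nrow(runs))) {
      sel <- rec$proteoform_id %in% members &
        rec$replicate == runs$replicate[r] & rec$day == runs$day[r] &
        rec$condition == runs$condition[r]
      ia <- which(sel & rec$proteoform_id == members[1])
      ib <- which(sel & rec$proteoform_id == members[2])
      if (!length(ia) || !length(ib)) next
      fsel <- if (is.null(frags)) logical(0) else
        frags$group == imap$group[g] & frags$replicate == runs$replicate[r] &
        frags$day == runs$day[r] & frags$condition == runs$condition[r]
      if (!imap$resolvable[g] || is.null(frags) || !any(fsel)) {
        rec$resolved[c(ia, ib)] <- FALSE
        rec$flag[c(ia, ib)] <- "unresolved_isomer"
        next
      }
      for (win in c("light", "heavy")) {
        res <- resolve_isobaric(frags[fsel & frags$window == win, ])
        if (!res$resolved) {
          rec$resolved[c(ia, ib)] <- FALSE
          rec$flag[c(ia, ib)] <- "unresolved_isomer"
          next
        }
        col <- paste0(win, "_area")
        tot <- rec[[col]][ia] + rec[[col]][ib]
        rec[[col]][ia] <- tot * res$mix_a
        rec[[col]][ib] <- tot * (1 - res$mix_a)
      }
    }
  }

  rec$total_area <- rec$light_area + rec$heavy_area
  rec$heavy_fraction <- NA_real_
  for (i in seq_len(nrow(rec))) {
    rec$heavy_fraction[i] <- tryCatch(
      heavy_fraction(rec$light_area[i], rec$heavy_area[i]),
      histurnover_undefined_signal = function(e) {
        rec$flag[i] <<- "undefined_signal"; NA_real_
      })
  }
  rec$relative_abundance <- NA_real_
  fam_key <- unique(rec[, c("family", "replicate", "day", "condition")])
  for (i in seq_len(nrow(fam_key))) {
    sel <- rec$family == fam_key$family[i] &
      rec$replicate == fam_key$replicate[i] & rec$day == fam_key$day[i] &
      rec$condition == fam_key$condition[i]
    tot <- sum(rec$total_area[sel])
    if (tot < area_floor || tot == 0) {
      rec$flag[sel] <- "low_signal"
    } else {
      rec$relative_abundance[sel] <- relative_abundance(
        stats::setNames(rec$total_area[sel], rec$proteoform_id[sel]))
    }
  }
  rec$total_area <- NULL
  rownames(rec) <- NULL
  class(rec) <- c("quant_table", "data.frame")
  rec
}

#' @export
print.quant_table <- function(x, ...) {
  cat("<quant_table> ", nrow(x), " records, ",
      length(unique(x$proteoform_id)), " proteoforms, ",
      length(unique(x$day)), " day(s), ",
      length(unique(x$condition)), " condition(s); flags: ",
      paste(names(table(x$flag)), table(x$flag), sep = "=", collapse = ", "),
      "\n", sep = "")
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
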