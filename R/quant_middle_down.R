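#' Extract a methyl-equivalent ladder from m/z-keyed traces
#'
#' Matches every ladder target (light and heavy, 0..max equivalents) to the
#' traces whose m/z lies within +/- `ppm` parts per million of the target and
#' integrates the matched signal. Construction asserts that no two ladder
#' windows overlap at the requested tolerance (at 10 ppm the 8+ H3 1-50
#' ladder spacing of ~1.75 m/z is two orders of magnitude wider).
#' Unmatched targets get area 0 and `matched = FALSE`.
#'
#' @param traces A data.frame with columns `mz`, `rt`, `intensity`; rows
#'   sharing an `mz` value form one trace.
#' @param ladder A [methyl_ladder()] data.frame.
#' @param ppm Mass tolerance in ppm (> 0), default 10.
#' @return A data.frame of class `"ladder_xic"`: `n_equiv`, `label_state`,
#'   `target_mz`, `area`, `matched`, with the tolerance in attribute `ppm`.
#' @export
extract_ladder <- function(traces, ladder, ppm = 10) {
  if (ppm <= 0) stop("ppm tolerance must be > 0")
  targets <- data.frame(
    n_equiv = rep(ladder$n_equiv, 2),
    label_state = rep(c("light", "heavy"), each = nrow(ladder)),
    target_mz = c(ladder$light_mz, ladder$heavy_mz))
  tol <- targets$target_mz * ppm * 1e-6
  o <- order(targets$target_mz)
  lo <- targets$target_mz[o] - tol[o]; hi <- targets$target_mz[o] + tol[o]
  if (any(hi[-length(hi)] > lo[-1]))
    stop("ladder windows overlap at ", ppm,
         " ppm: tolerance too wide for this ladder")
  mzs <- unique(traces$mz)
  targets$area <- 0
  targets$matched <- FALSE
  for (i in seq_len(nrow(targets))) {
    hit <- mzs[abs(mzs - targets$target_mz[i]) <= tol[i]]
    if (!length(hit)) next
    targets$matched[i] <- TRUE
    targets$area[i] <- sum(vapply(hit, function(m) {
      tr <- traces[traces$mz == m, c("rt", "intensity")]
      integrate_trace(tr[order(tr$rt), ])
    }, numeric(1)))
  }
  structure(targets, ppm = ppm, class = c("ladder_xic", "data.frame"))
}

#' Per-equivalent heavy fractions of a ladder
#'
#' heavy / (light + heavy) for each methyl-equivalent state, as in the
#' bottom-up analysis; states with no signal in either channel are NA with
#' `missing = TRUE`.
#'
#' @param lx A `"ladder_xic"` from [extract_ladder()].
#' @return A data.frame with `n_equiv`, `heavy_fraction`, `missing`.
#' @export
ladder_heavy_fractions <- function(lx) {
  n <- sort(unique(lx$n_equiv))
  out <- data.frame(n_equiv = n, heavy_fraction = NA_real_, missing = FALSE)
  for (i in seq_along(n)) {
    l <- lx$area[lx$n_equiv == n[i] & lx$label_state == "light"]
    h <- lx$area[lx$n_equiv == n[i] & lx$label_state == "heavy"]
    if (l + h == 0) out$missing[i] <- TRUE
    else out$heavy_fraction[i] <- heavy_fraction(l, h)
  }
  out
}

#' Relative abundance distribution over methyl equivalents
#'
#' (light + heavy) area per equivalent state, normalized to sum to 1.
#'
#' @param lx A `"ladder_xic"` from [extract_ladder()].
#' @return A data.frame with `n_equiv`, `fraction`.
#' @export
equiv_distribution <- function(lx) {
  n <- sort(unique(lx$n_equiv))
  tot <- vapply(n, function(k) sum(lx$area[lx$n_equiv == k]), numeric(1))
  if (sum(tot) == 0) stop("zero total ladder area")
  data.frame(n_equiv = n, fraction = tot / sum(tot))
}
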