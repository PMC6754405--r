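#' Significance stars for a p-value
#'
#' Strict thresholds as conventionally printed alongside the heteroscedastic
#' t-test: `*` p < 0.05, `**` p < 0.005, `***` p < 0.0005, else `ns`.
#'
#' @param p A p-value (or vector).
#' @return Character vector in `c("ns", "*", "**", "***")`.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.0005, "***", ifelse(p < 0.005, "**",
                                   ifelse(p < 0.05, "*", "ns")))
}

#' Two-tailed heteroscedastic (Welch) t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p-value, plus the star representation. `paired = TRUE`
#' gives the paired t-test used for day-paired comparisons.
#'
#' @param x,y Numeric samples, each of length >= 2, with nonzero variance in
#'   at least one.
#' @param paired Pair observations instead of Welch? Default FALSE.
#' @return A list of class `"welch_test"`: `t`, `df`, `p`, `stars`.
#' @export
welch_t <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (paired && stats::var(x - y) == 0) {
    if (isTRUE(all.equal(mean(x - y), 0)))
      return(structure(list(t = 0, df = length(x) - 1, p = 1, stars = "ns"),
                       class = "welch_test"))
    stop("paired differences are constant and nonzero")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0 && !paired) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                            stars = "ns"), class = "welch_test"))
    stop("both samples have zero variance")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, paired = paired,
                      alternative = "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, stars = p_stars(ht$p.value)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.2f, p = %.4g %s\n",
              x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with positive variance.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  stats::cor(x, y, method = "pearson")
}

# Replicate-mean metric per proteoform (optionally per day).
.metric_means <- function(records, metric, by_day = TRUE) {
  f <- if (by_day) list(proteoform_id = records$proteoform_id,
                        day = records$day)
       else list(proteoform_id = records$proteoform_id)
  stats::aggregate(records[[metric]], f, mean, na.rm = TRUE)
}

#' Abundance vs labeling fold-change comparison between two conditions
#'
#' For each proteoform present in both conditions, computes the log2 fold
#' change of replicate-mean relative abundance and of replicate-mean heavy
#' fraction (per day, then averaged over days), the dynamic-range ratio
#' (abundance log2-FC span over labeling log2-FC span) and the Pearson
#' correlation between the two fold-change columns. Zero means are floored
#' at `eps` and flagged.
#'
#' @param records_a,records_b `"quant_table"` records for the two conditions.
#' @param eps Floor applied to zero fractions before log2.
#' @return A data.frame of class `"fc_scatter"` with columns
#'   `proteoform_id`, `log2fc_abundance`, `log2fc_heavy`, `flagged`;
#'   attributes `dynamic_range_ratio` and `fc_correlation`.
#' @export
fc_scatter <- function(records_a, records_b, eps = 1e-9) {
  fc_of <- function(metric) {
    ma <- .metric_means(records_a, metric)
    mb <- .metric_means(records_b, metric)
    m <- merge(ma, mb, by = c("proteoform_id", "day"),
               suffixes = c("_a", "_b"))
    m$flag <- m$x_a <= 0 | m$x_b <= 0 | is.na(m$x_a) | is.na(m$x_b)
    m$fc <- log2(pmax(m$x_b, eps) / pmax(m$x_a, eps))
    ag <- stats::aggregate(list(fc = m$fc, flag = m$flag),
                           list(proteoform_id = m$proteoform_id),
                           function(v) mean(v, na.rm = TRUE))
    ag
  }
  ab <- fc_of("relative_abundance")
  hv <- fc_of("heavy_fraction")
  out <- merge(ab, hv, by = "proteoform_id", suffixes = c("_ab", "_hv"))
  res <- data.frame(proteoform_id = out$proteoform_id,
                    log2fc_abundance = out$fc_ab,
                    log2fc_heavy = out$fc_hv,
                    flagged = out$flag_ab > 0 | out$flag_hv > 0)
  span <- function(v) diff(range(v[is.finite(v)]))
  ratio <- if (span(res$log2fc_heavy) == 0) NA_real_ else
    span(res$log2fc_abundance) / span(res$log2fc_heavy)
  structure(res,
            dynamic_range_ratio = ratio,
            fc_correlation = tryCatch(
              pearson_r(res$log2fc_abundance, res$log2fc_heavy),
              error = function(e) NA_real_),
            class = c("fc_scatter", "data.frame"))
}

#' Replicate precision of abundance vs labeling
#'
#' Coefficient of variation (sd/mean over replicates) per proteoform x day x
#' condition for relative abundance and for heavy fraction, averaged per
#' proteoform, plus a paired t-test across proteoforms comparing the two CV
#' populations. Labeling incorporation is expected to be the more precise
#' metric (it divides two quantities instead of four or five).
#'
#' @param records A `"quant_table"` with >= 3 replicates.
#' @return A list with `cv` (data.frame `proteoform_id`, `cv_abundance`,
#'   `cv_heavy`) and `test` (a `"welch_test"`, paired).
#' @export
replicate_precision <- function(records) {
  if (max(records$replicate) < 3) stop("need >= 3 replicates")
  cv <- function(v) if (all(is.na(v)) || mean(v, na.rm = TRUE) == 0)
    NA_real_ else stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
  g <- list(proteoform_id = records$proteoform_id, day = records$day,
            condition = records$condition)
  a <- stats::aggregate(records$relative_abundance, g, cv)
  h <- stats::aggregate(records$heavy_fraction, g, cv)
  m <- merge(a, h, by = c("proteoform_id", "day", "condition"),
             suffixes = c("_ab", "_hv"))
  per <- stats::aggregate(list(cv_abundance = m$x_ab, cv_heavy = m$x_hv),
                          list(proteoform_id = m$proteoform_id),
                          mean, na.rm = TRUE)
  ok <- stats::complete.cases(per)
  list(cv = per,
       test = welch_t(per$cv_abundance[ok], per$cv_heavy[ok], paired = TRUE))
}

#' Correlation of labeling (or abundance) between two days
#'
#' Pearson correlation across proteoforms of replicate-mean values at two
#' days, the day-to-day consistency check for labeling incorporation.
#'
#' @param records A `"quant_table"`.
#' @param day_i,day_j The two days to compare.
#' @param metric `"heavy_fraction"` (default) or `"relative_abundance"`.
#' @param condition Optional condition filter.
#' @return Pearson r.
#' @export
day_correlation <- function(records, day_i, day_j,
                            metric = "heavy_fraction", condition = NULL) {
  if (!is.null(condition)) records <- records[records$condition %in% condition, ]
  mm <- .metric_means(records, metric)
  xi <- mm[mm$day == day_i, c("proteoform_id", "x")]
  xj <- mm[mm$day == day_j, c("proteoform_id", "x")]
  m <- merge(xi, xj, by = "proteoform_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stop("fewer than 3 matched proteoforms")
  pearson_r(m$x.x, m$x.y)
}
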