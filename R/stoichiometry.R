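#' Media labeling-stoichiometry parameters
#'
#' Defaults reproduce the published culture conditions: a maximum of 4e6
#' cells at harvest, ~300 pg protein per cell, arginine at 5.78% of cellular
#' amino acids, heavy arginine spiked to 5.75 mM into 1 mL RPMI 1640
#' containing ~0.2 mg/mL light arginine.
#'
#' @param cells_final Cell count at the end of culture (>= 0).
#' @param protein_per_cell Protein mass per cell, pg.
#' @param arg_fraction Fraction of proteome amino acids that are the labeled
#'   amino acid (dimensionless).
#' @param heavy_conc Heavy amino-acid concentration in the medium, mM.
#' @param light_conc Light amino-acid concentration in the medium, mg/mL.
#' @param volume Culture volume, mL.
#' @param light_aa_mw,heavy_aa_mw Molar masses of the light and heavy amino
#'   acid, g/mol (arginine 174.20; R10 arginine 184.21).
#' @return A list of class `"media_params"`.
#' @export
media_params <- function(cells_final = 4e6, protein_per_cell = 300,
                         arg_fraction = 0.0578, heavy_conc = 5.75,
                         light_conc = 0.2, volume = 1,
                         light_aa_mw = 174.20, heavy_aa_mw = 184.21) {
  p <- list(cells_final = cells_final, protein_per_cell = protein_per_cell,
            arg_fraction = arg_fraction, heavy_conc = heavy_conc,
            light_conc = light_conc, volume = volume,
            light_aa_mw = light_aa_mw, heavy_aa_mw = heavy_aa_mw)
  if (cells_final < 0) stop("cells_final must be >= 0")
  pos <- p[setdiff(names(p), "cells_final")]
  bad <- names(pos)[vapply(pos, function(x) !is.numeric(x) || x <= 0, TRUE)]
  if (length(bad)) stop("media parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  structure(p, class = "media_params")
}

#' Labeled vs unlabeled amino-acid budget of a labeling culture
#'
#' Computes the unlabeled amino acid locked in the harvested proteome
#' (cells x pg/cell x amino-acid fraction), the unlabeled amino acid in the
#' medium, their total, the heavy amino acid added, and the molar excess of
#' heavy over light in the medium. Proteome and total masses are additionally
#' reported rounded to the nearest 10 ug, the convention used for the
#' published "~70 ug" / "270 ug" figures.
#'
#' @param params A [media_params()] object.
#' @return A list of class `"stoich_report"` with elements
#'   `proteome_unlabeled_ug`, `media_unlabeled_ug`, `total_unlabeled_ug`
#'   (rounded report values), their `_exact` counterparts, `labeled_mg`,
#'   `heavy_conc_mg_ml`, `media_molar_ratio` and `mass_ratio`.
#' @examples
#' media_stoichiometry(media_params())  # ~70 + 200 = 270 ug vs ~1 mg, ~5x
#' @export
media_stoichiometry <- function(params = media_params()) {
  stopifnot(inherits(params, "media_params"))
  round10 <- function(x) round(x / 10) * 10
  proteome <- params$cells_final * params$protein_per_cell *
    params$arg_fraction * 1e-6                    # pg -> ug
  media <- params$light_conc * params$volume * 1e3 # mg -> ug
  labeled_mg <- params$heavy_conc * 1e-3 * params$heavy_aa_mw * params$volume
  molar_light_mM <- params$light_conc / params$light_aa_mw * 1e3
  rep <- list(
    proteome_unlabeled_ug = round10(proteome),
    media_unlabeled_ug = round10(media),
    total_unlabeled_ug = round10(proteome) + round10(media),
    proteome_unlabeled_ug_exact = proteome,
    media_unlabeled_ug_exact = media,
    total_unlabeled_ug_exact = proteome + media,
    labeled_mg = labeled_mg,
    heavy_conc_mg_ml = params$heavy_conc * 1e-3 * params$heavy_aa_mw,
    media_molar_ratio = params$heavy_conc / molar_light_mM,
    mass_ratio = labeled_mg * 1e3 / (round10(proteome) + round10(media))
  )
  structure(rep, class = "stoich_report")
}

#' @export
print.stoich_report <- function(x, ...) {
  cat(sprintf(
    paste0("Labeling stoichiometry\n",
           "  unlabeled in proteome : %6.0f ug\n",
           "  unlabeled in medium   : %6.0f ug\n",
           "  total unlabeled       : %6.0f ug\n",
           "  heavy label added     : %6.2f mg (%.2f mg/mL)\n",
           "  heavy/light molar     : %6.2fx\n"),
    x$proteome_unlabeled_ug, x$media_unlabeled_ug, x$total_unlabeled_ug,
    x$labeled_mg, x$heavy_conc_mg_ml, x$media_molar_ratio))
  invisible(x)
}

#' Expected newly synthesized fraction under replication dilution
#'
#' Idealized labeling model: with a fully labeled precursor pool, every
#' chromatin duplication halves the share of old (light) histones, so the
#' expected labeled fraction after `cycles` cell cycles is 1 - 2^(-cycles).
#' One cycle gives 50%; real cultures fall short of this because the medium
#' still contains light amino acid and cells recycle amino acids internally.
#'
#' @param cycles Non-negative number of cell cycles (may be fractional).
#' @return The expected new-histone fraction in \[0, 1).
#' @examples
#' expected_new_fraction(1)  # 0.5
#' @export
expected_new_fraction <- function(cycles) {
  if (any(cycles < 0)) stop("cycles must be >= 0")
  1 - 2^(-cycles)
}
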