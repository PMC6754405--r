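#' Construct a proteoform
#'
#' A proteoform is a peptide backbone plus positioned modifications — the unit
#' of quantification. Positions are 1-based within the peptide; `offset` holds
#' the first residue's number in the full protein so reported names can use
#' protein coordinates (e.g. K9 within the H3 9-17 peptide).
#'
#' @param backbone Uppercase amino-acid string.
#' @param mods Optional data.frame with columns `pos` (1-based peptide
#'   position) and `code` (registry code). At most one modification per
#'   position; the target residue must match.
#' @param offset 1-based protein position of the first backbone residue.
#' @param id Optional identifier; defaults to a protein-numbered name.
#' @param registry Modification registry.
#' @return An object of class `"proteoform"`.
#' @examples
#' p <- proteoform("KSTGGKAPR", data.frame(pos = 1, code = "ac"), offset = 9)
#' proteoform_mass(apply_derivatization(p))
#' @export
proteoform <- function(backbone, mods = NULL, offset = 1L, id = NULL,
                       registry = default_mods()) {
  stopifnot(is.character(backbone), length(backbone) == 1L, nchar(backbone) > 0)
  res <- strsplit(backbone, "")[[1]]
  if (!all(res %in% names(.AA_MONO)))
    stop("unknown residue letter(s): ",
         paste(unique(res[!res %in% names(.AA_MONO)]), collapse = ", "))
  if (is.null(mods)) mods <- data.frame(pos = integer(), code = character())
  mods <- data.frame(pos = as.integer(mods$pos), code = as.character(mods$code))
  if (nrow(mods)) {
    if (any(mods$pos < 1L | mods$pos > nchar(backbone)))
      stop("modification position outside backbone")
    if (anyDuplicated(mods$pos))
      stop("at most one modification per position")
    i <- match(mods$code, registry$code)
    if (anyNA(i)) stop("unknown modification code(s): ",
                       paste(mods$code[is.na(i)], collapse = ", "))
    tgt <- registry$targets[i]
    ok <- mapply(function(p, t) grepl(res[p], t, fixed = TRUE), mods$pos, tgt)
    if (!all(ok))
      stop("modification target mismatch at position(s) ",
           paste(mods$pos[!ok], collapse = ", "))
    mods <- mods[order(mods$pos), , drop = FALSE]
  }
  p <- structure(
    list(backbone = backbone, mods = mods, derivatized = FALSE,
         n_prop = 0L, prop_sites = character(), offset = as.integer(offset)),
    class = "proteoform")
  p$id <- if (is.null(id)) proteoform_name(p) else id
  p
}

#' Protein-numbered name of a proteoform
#'
#' @param p A proteoform.
#' @return E.g. `"K9me3K14ac"`, or `"unmod"` when no modification is present.
#' @export
proteoform_name <- function(p) {
  m <- p$mods[p$mods$code != "unmod", , drop = FALSE]
  if (!nrow(m)) return("unmod")
  res <- strsplit(p$backbone, "")[[1]]
  paste0(res[m$pos], m$pos + p$offset - 1L, m$code, collapse = "")
}

#' @export
print.proteoform <- function(x, ...) {
  cat("<proteoform> ", x$backbone, " (aa ", x$offset, "-",
      x$offset + nchar(x$backbone) - 1L, ") ", proteoform_name(x),
      if (x$derivatized) paste0(" +", x$n_prop, "prop [derivatized]"),
      "\n", sep = "")
  invisible(x)
}

#' Propionyl-derivatize a proteoform
#'
#' Emulates two rounds of propionic anhydride treatment before and after
#' trypsin digestion: one propionyl group is added at every lysine whose side
#' chain is free (unmodified) or monomethylated, plus one at the peptide
#' N-terminus. Acetylated, di- and trimethylated lysines are chemically
#' blocked and untouched. Calling it on an already derivatized proteoform is
#' an error (the chemistry is single-shot per analyte).
#'
#' @param p A proteoform with `derivatized = FALSE`.
#' @param registry Modification registry (supplies `blocks_propionylation`).
#' @return The proteoform with `n_prop`/`prop_sites` filled and
#'   `derivatized = TRUE`.
#' @export
apply_derivatization <- function(p, registry = default_mods()) {
  stopifnot(inherits(p, "proteoform"))
  if (p$derivatized) stop("proteoform is already derivatized")
  res <- strsplit(p$backbone, "")[[1]]
  kpos <- which(res == "K")
  blocked <- integer()
  if (nrow(p$mods)) {
    i <- match(p$mods$code, registry$code)
    blocked <- p$mods$pos[registry$blocks_propionylation[i]]
  }
  free_k <- setdiff(kpos, blocked)
  p$n_prop <- length(free_k) + 1L
  p$prop_sites <- c("Nterm", if (length(free_k)) paste0("K", free_k + p$offset - 1L))
  p$derivatized <- TRUE
  p
}

#' Monoisotopic mass of a proteoform
#'
#' Residue masses + water + modification deltas (+ 56.026215 Da per propionyl
#' group when derivatized).
#'
#' @param p A proteoform.
#' @param registry Modification registry.
#' @return Neutral monoisotopic mass in Da.
#' @export
proteoform_mass <- function(p, registry = default_mods()) {
  stopifnot(inherits(p, "proteoform"))
  res <- strsplit(p$backbone, "")[[1]]
  m <- sum(.AA_MONO[res]) + .WATER_MASS
  if (nrow(p$mods)) m <- m + sum(mod_delta(p$mods$code, registry))
  m + p$n_prop * .PROP_MASS
}

#' Mass shift contributed by an isotope label
#'
#' One `label$delta` per occurrence of the labeled residue in the backbone.
#' Zero occurrences give 0 (no error): the bottom-up workflow assumes
#' ArgC-like peptides with a single C-terminal arginine, and
#' [quantify_run()]/[methyl_ladder()] check the residue count where a single
#' label copy matters.
#'
#' @param p A proteoform or a backbone string.
#' @param label A label list from [get_label()].
#' @return Mass shift in Da.
#' @export
label_delta <- function(p, label = get_label("R10")) {
  backbone <- if (inherits(p, "proteoform")) p$backbone else p
  n <- sum(strsplit(backbone, "")[[1]] == label$residue)
  n * label$delta
}

#' Classify the mass relationship of two proteoforms
#'
#' Same-backbone proteoforms are `positional_isomer` when their masses are
#' equal and their modification codes match but sit at different positions
#' (e.g. K9ac vs K14ac), `near_isobaric` when 0 < |dm| <= `resolving_tol`
#' (e.g. ac vs me3, dm ~ 0.0364 Da), `identical` when mods and positions all
#' match, and `distinct` otherwise.
#'
#' @param p1,p2 Proteoforms sharing a backbone.
#' @param resolving_tol Mass tolerance (Da) below which two distinct masses
#'   are considered unresolved. Default 0.05.
#' @param registry Modification registry.
#' @return One of `"identical"`, `"positional_isomer"`, `"near_isobaric"`,
#'   `"distinct"`.
#' @export
isobaric_class <- function(p1, p2, resolving_tol = 0.05,
                           registry = default_mods()) {
  stopifnot(inherits(p1, "proteoform"), inherits(p2, "proteoform"))
  if (p1$backbone != p2$backbone) stop("proteoforms have different backbones")
  dm <- abs(proteoform_mass(p1, registry) - proteoform_mass(p2, registry))
  same_codes <- identical(sort(p1$mods$code), sort(p2$mods$code))
  same_pos <- identical(p1$mods[order(p1$mods$pos), c("pos", "code")],
                        p2$mods[order(p2$mods$pos), c("pos", "code")])
  if (same_pos && same_codes) return("identical")
  if (dm < 1e-9 && same_codes) return("positional_isomer")
  if (dm > 0 && dm <= resolving_tol) return("near_isobaric")
  "distinct"
}

#' Methyl-equivalent m/z ladder for an intact tail
#'
#' For the middle-down workflow: target m/z values for a backbone carrying
#' 0..`max_equiv` methyl equivalents (+14.015650 Da each) at charge `z`, with
#' the matching heavy-label m/z offset by `label_delta/z`. Consecutive light
#' entries are spaced by 14.015650/z.
#'
#' @param backbone Amino-acid string (e.g. histone H3.1 residues 1-50).
#' @param max_equiv Highest methyl-equivalent count (>= 0), default 15.
#' @param z Charge state, default 8.
#' @param label Isotope label list, default heavy histidine.
#' @return A data.frame with columns `n_equiv`, `light_mz`, `heavy_mz`.
#' @export
methyl_ladder <- function(backbone, max_equiv = 15L, z = 8L,
                          label = get_label("H-heavy")) {
  stopifnot(max_equiv >= 0, z >= 1)
  base <- proteoform_mass(proteoform(backbone))
  n <- 0:max_equiv
  light <- mz(base + n * .METHYL_MASS, z)
  ld <- label_delta(backbone, label)
  data.frame(n_equiv = n, light_mz = light, heavy_mz = light + ld / z)
}

#' Histone H3.1 N-terminal tail, residues 1-50
#'
#' The GluC-generated intact tail analyzed in the middle-down workflow. It
#' carries a single histidine (H39), which is why heavy histidine gives a
#' clean two-state light/heavy pair.
#'
#' @return The 50-residue backbone string.
#' @export
h3_tail_1_50 <- function() "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALRE"
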