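#' @keywords internal
#' @importFrom stats rnorm dnorm sd var cor aggregate setNames
#' @importFrom utils read.delim write.table head
#' @importFrom methods is
"_PACKAGE"

# Monoisotopic residue masses (Da), standard 20 amino acids.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.PROTON_MASS <- 1.007276
.WATER_MASS  <- 18.010565
.METHYL_MASS <- 14.015650   # CH2
.PROP_MASS   <- 56.026215   # C3H4O, propionyl

#' Default histone PTM registry
#'
#' The modification table used throughout the package: short code, residue
#' letters the modification targets, monoisotopic mass shift (Da), and whether
#' the modification chemically blocks propionylation of a lysine side chain.
#' Deltas are elemental-composition monoisotopic masses: ac = C2H2O
#' (42.010565), me1 = CH2 (14.015650), me2 = C2H4, me3 = C3H6 (42.046950),
#' prop = C3H4O (56.026215). Free and monomethylated lysines remain reactive
#' to propionic anhydride; ac/me2/me3 (and prop itself) block the side chain.
#'
#' @return A data.frame with columns `code`, `targets`, `delta`,
#'   `blocks_propionylation`.
#' @export
default_mods <- function() {
  data.frame(
    code = c("unmod", "me1", "me2", "me3", "ac", "prop"),
    targets = c("K", "K", "K", "K", "K", "K"),
    delta = c(0, .METHYL_MASS, 2 * .METHYL_MASS, 3 * .METHYL_MASS,
              42.010565, .PROP_MASS),
    blocks_propionylation = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Load a modification registry from TSV
#'
#' Columns: `code`, `targets` (residue letters, e.g. "K"), `delta` (Da),
#' `blocks_propionylation` (TRUE/FALSE).
#'
#' @param path Path to a tab-separated registry file.
#' @return A registry data.frame as [default_mods()].
#' @export
read_mod_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("code", "targets", "delta", "blocks_propionylation")
  missing <- setdiff(need, names(reg))
  if (length(missing))
    stop("modification registry ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  reg$blocks_propionylation <- as.logical(reg$blocks_propionylation)
  if (any(!is.finite(reg$delta)))
    stop("non-finite delta in modification registry")
  reg
}

#' Monoisotopic mass shift of a registered modification
#'
#' @param code Modification short code (e.g. `"ac"`, `"me3"`).
#' @param registry Modification registry, see [default_mods()].
#' @return Mass shift in Da.
#' @examples
#' mod_delta("ac")   # 42.010565, the near-isobaric partner of me3 (42.046950)
#' @export
mod_delta <- function(code, registry = default_mods()) {
  i <- match(code, registry$code)
  if (anyNA(i))
    stop("unknown modification code(s): ",
         paste(code[is.na(i)], collapse = ", "),
         "; registered: ", paste(registry$code, collapse = ", "))
  registry$delta[i]
}

#' Default isotope label registry
#'
#' `R10` is fully labeled arginine (13C6 15N4), delta = 6*(13.003355 - 12) +
#' 4*(15.000109 - 14.003074) = 10.008269 Da per arginine. `H-heavy` is the
#' heavy histidine used for intact-tail work; its exact isotopologue is a
#' user-configurable choice and the shipped default is 13C6 (6.020129 Da).
#' The label delta in force is always echoed in run manifests.
#'
#' @return A data.frame with columns `name`, `residue`, `delta`.
#' @export
default_labels <- function() {
  data.frame(
    name = c("R10", "H-heavy"),
    residue = c("R", "H"),
    delta = c(6 * (13.003355 - 12) + 4 * (15.000109 - 14.003074),
              6 * (13.003355 - 12)),
    stringsAsFactors = FALSE
  )
}

#' Look up an isotope label by name
#'
#' @param name Label name (e.g. `"R10"`).
#' @param registry Label registry, see [default_labels()].
#' @return A one-row list with `name`, `residue`, `delta`.
#' @export
get_label <- function(name, registry = default_labels()) {
  i <- match(name, registry$name)
  if (is.na(i))
    stop("unknown label '", name, "'; registered: ",
         paste(registry$name, collapse = ", "))
  as.list(registry[i, ])
}

#' m/z of an ion
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge.
#' @return (mass + z * 1.007276) / z.
#' @export
mz <- function(mass, z) {
  if (any(z <= 0) || any(z != round(z))) stop("charge z must be a positive integer")
  (mass + z * .PROTON_MASS) / z
}
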