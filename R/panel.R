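#' Parse a protein-numbered modification string
#'
#' Turns strings such as `"K9me3K14ac"` (the Supplementary-Table naming
#' convention) into peptide-local positions using the peptide's protein
#' offset. `""`, `"unmod"` or NA mean no modification.
#'
#' @param s Modification string.
#' @param offset Protein position of the peptide's first residue.
#' @param backbone Peptide backbone (used to check the residue letter).
#' @return A data.frame with columns `pos` (1-based peptide) and `code`.
#' @export
parse_mod_string <- function(s, offset, backbone) {
  if (is.na(s) || s == "" || s == "unmod")
    return(data.frame(pos = integer(), code = character()))
  m <- gregexpr("([A-Z])(\\d+)(me1|me2|me3|ac|prop)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse modification string '", s, "'")
  res <- strsplit(backbone, "")[[1]]
  out <- do.call(rbind, lapply(toks, function(tk) {
    letter <- substr(tk, 1, 1)
    num <- as.integer(sub("^[A-Z](\\d+).*$", "\\1", tk))
    code <- sub("^[A-Z]\\d+", "", tk)
    pos <- num - offset + 1L
    if (pos < 1L || pos > length(res) || res[pos] != letter)
      stop("modification '", tk, "' does not match backbone ", backbone,
           " at offset ", offset)
    data.frame(pos = pos, code = code)
  }))
  out
}

#' Read a peptide panel from TSV
#'
#' Columns: `protein`, `start`, `end`, `backbone`, `mods` (protein-numbered
#' string, `"unmod"` for the unmodified form). An optional `isomer_group`
#' column marks sets of positional isomers that require fragment-level
#' resolution.
#'
#' @param path Path to a tab-separated panel file.
#' @param registry Modification registry.
#' @return A panel data.frame with an added `proteoform_id` column
#'   (`protein_mods`) and a `proteoforms` attribute holding the parsed
#'   [proteoform()] objects.
#' @export
read_panel <- function(path, registry = default_mods()) {
  pan <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("protein", "start", "end", "backbone", "mods")
  missing <- setdiff(need, names(pan))
  if (length(missing))
    stop("panel ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  if (!"isomer_group" %in% names(pan)) pan$isomer_group <- NA_character_
  build_panel(pan, registry)
}

# Finalize a panel data.frame: validate backbones/mods, attach proteoforms.
build_panel <- function(pan, registry = default_mods()) {
  if (any(nchar(pan$backbone) != pan$end - pan$start + 1L))
    stop("backbone length inconsistent with start/end coordinates")
  pf <- lapply(seq_len(nrow(pan)), function(i) {
    proteoform(pan$backbone[i],
               parse_mod_string(pan$mods[i], pan$start[i], pan$backbone[i]),
               offset = pan$start[i], registry = registry)
  })
  pan$family <- paste(pan$protein, pan$start, pan$end, sep = "_")
  pan$proteoform_id <- paste(pan$family, pan$mods, sep = "_")
  if (anyDuplicated(pan$proteoform_id))
    stop("duplicated proteoform ids in panel")
  attr(pan, "proteoforms") <- stats::setNames(pf, pan$proteoform_id)
  pan
}

#' Built-in histone H3/H4 peptide panel
#'
#' A ~20-proteoform panel covering the classic H3 ArgC-like peptides
#' (TKQTAR 3-8, KSTGGKAPR 9-17, KQLATKAAR 18-26, KSAPATGGVKKPHR 27-40) and
#' the H4 4-17 polyacetyl peptide, in the forms carried by the shipped
#' synthetic ground truth. K9ac/K14ac and K18ac/K23ac are marked as
#' positional-isomer groups.
#'
#' @param registry Modification registry.
#' @return A panel data.frame as returned by [read_panel()].
#' @export
default_panel <- function(registry = default_mods()) {
  pan <- read_panel(system.file("extdata", "panel_h3_h4.tsv",
                                package = "histurnover", mustWork = TRUE),
                    registry)
  pan
}
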