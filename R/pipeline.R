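# Polynomial rolling hash of the canonicalized config (manifest identity).
.config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
             collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# TSV writer/reader with a '# config_hash: ...' comment header.
write_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Validate a run configuration
#'
#' Reads a YAML run configuration (or takes a list), checks every field and
#' fails fast with all violations listed at once: referenced files must
#' exist, tolerances (`ppm`, `integration window widths`, `area_floor`)
#' must be positive, and the selected label must be registered.
#'
#' @param cfg Path to a YAML file or a configuration list. Recognized
#'   fields: `seed`, `days`, `replicates`, `snr`, `label`, `ppm`,
#'   `area_floor`, `panel` (path, optional), `mod_registry` (path,
#'   optional), `signals`/`fragments` (TSV paths, optional), `peaks_a`,
#'   `peaks_b`, `reads`, `tss` (BED paths, optional), `simulate` (logical),
#'   `middle_down` (logical), `outdir`.
#' @return The validated configuration list, class `"run_config"`.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg)) stop("config must be a YAML file path or a list")
  defaults <- list(seed = 1L, days = 1:3, replicates = 3L, snr = 50,
                   label = "R10", ppm = 10, area_floor = 0,
                   simulate = TRUE, middle_down = FALSE, outdir = tempdir())
  cfg <- utils::modifyList(defaults, cfg)
  cfg$seed <- as.integer(cfg$seed)
  problems <- character()
  num_pos <- c(ppm = cfg$ppm, snr = cfg$snr, replicates = cfg$replicates)
  for (nm in names(num_pos))
    if (!is.numeric(num_pos[[nm]]) || num_pos[[nm]] <= 0)
      problems <- c(problems, paste0("field '", nm, "' must be > 0"))
  if (!is.numeric(cfg$area_floor) || cfg$area_floor < 0)
    problems <- c(problems, "field 'area_floor' must be >= 0")
  labels <- default_labels()
  if (!cfg$label %in% labels$name)
    problems <- c(problems, paste0("unknown label '", cfg$label,
                                   "'; registered: ",
                                   paste(labels$name, collapse = ", ")))
  for (f in c("panel", "mod_registry", "signals", "fragments",
              "peaks_a", "peaks_b", "reads", "tss"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      problems <- c(problems, paste0("field '", f, "': file not found: ",
                                     cfg[[f]]))
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the end-to-end analysis
#'
#' Executes the configured stages in order — simulate (optional), bottom-up
#' quantification, middle-down quantification (optional), statistics, and
#' genomic overlap (optional, when BED inputs are configured) — writing TSV
#' outputs (each tagged with the config hash in a header comment) and a JSON
#' run manifest recording the seed, label delta in force, per-stage row
#' counts and warnings. Deterministic given an identical configuration.
#' A missing fragment table is not an error: positional-isomer families are
#' flagged unresolved and the run proceeds.
#'
#' @param cfg A validated `"run_config"` (or something [validate_config()]
#'   accepts).
#' @param outdir Output directory, created if needed; overrides
#'   `cfg$outdir`.
#' @return Invisibly, a list with `quant`, `stats`, `overlap` (or NULL),
#'   `middle_down` (or NULL), `manifest`, and the output `files`.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  if (is.null(outdir)) outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(unclass(cfg))
  label <- get_label(cfg$label)
  warnings <- character()
  note <- function(...) warnings <<- c(warnings, paste0(...))
  registry <- if (is.null(cfg$mod_registry)) default_mods() else
    read_mod_registry(cfg$mod_registry)
  panel <- if (is.null(cfg$panel)) default_panel(registry) else
    read_panel(cfg$panel, registry)
  config <- sim_config(seed = cfg$seed, days = cfg$days,
                       replicates = cfg$replicates, snr = cfg$snr)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv(df, path, hash)
    files <<- c(files, path)
  }

  # --- signals: simulate or load -------------------------------------------
  if (isTRUE(cfg$simulate)) {
    run <- simulate_run(default_truth(days = cfg$days, panel = panel),
                        config, panel)
    emit(run$signals, "signals.tsv")
    if (!is.null(run$fragments)) emit(run$fragments, "fragments.tsv")
  } else {
    if (is.null(cfg$signals)) stop("simulate is FALSE and no signals file given")
    run <- list(signals = read_tsv(cfg$signals),
                fragments = if (!is.null(cfg$fragments))
                  read_tsv(cfg$fragments) else NULL,
                config = config, isomer_map = .isomer_pairs(panel))
  }
  if (is.null(run$fragments))
    note("no fragment table: positional-isomer families left unresolved")

  # --- bottom-up quantification --------------------------------------------
  quant <- quantify_run(run, panel, config, area_floor = cfg$area_floor)
  emit(as.data.frame(quant), "quant_records.tsv")

  # --- middle-down (optional) ----------------------------------------------
  md <- NULL
  if (isTRUE(cfg$middle_down)) {
    lr <- simulate_ladder_run(default_md_truth(), config, label =
                                get_label("H-heavy"))
    lx <- extract_ladder(lr$traces, lr$ladder, ppm = cfg$ppm)
    md <- merge(ladder_heavy_fractions(lx), equiv_distribution(lx),
                by = "n_equiv")
    emit(md, "middle_down.tsv")
  }

  # --- statistics ----------------------------------------------------------
  stats_out <- list()
  days <- sort(unique(quant$day))
  conds <- unique(quant$condition)
  if (length(days) >= 2) {
    dc <- do.call(rbind, lapply(utils::combn(days, 2, simplify = FALSE),
      function(pr) data.frame(day_i = pr[1], day_j = pr[2],
        r = day_correlation(quant, pr[1], pr[2], condition = conds[1]))))
    stats_out$day_correlations <- dc
    emit(dc, "day_correlations.tsv")
  }
  if (max(quant$replicate) >= 3) {
    rp <- replicate_precision(quant[quant$condition == conds[1], ])
    stats_out$replicate_precision <- rp
    emit(rp$cv, "replicate_cv.tsv")
  }
  if (length(conds) >= 2) {
    fc <- fc_scatter(quant[quant$condition == conds[1], ],
                     quant[quant$condition == conds[2], ])
    stats_out$fc <- fc
    emit(as.data.frame(fc), "fold_changes.tsv")
  }

  # --- genomic overlap (optional) ------------------------------------------
  overlap <- NULL
  if (!is.null(cfg$peaks_a) && (!is.null(cfg$peaks_b) || !is.null(cfg$reads))) {
    a <- read_bed(cfg$peaks_a, drop_chroms = cfg$drop_chroms)
    overlap <- list()
    if (!is.null(cfg$peaks_b)) {
      b <- read_bed(cfg$peaks_b, drop_chroms = cfg$drop_chroms)
      overlap$peak_intersect_pct <- peak_intersect_fraction(a, b)
      overlap$bp_coverage_pct_peaks <- bp_coverage_fraction(a, b)
    }
    if (!is.null(cfg$reads)) {
      rd <- read_bed(cfg$reads, drop_chroms = cfg$drop_chroms)
      overlap$bp_coverage_pct_reads <- bp_coverage_fraction(a, rd)
      overlap$reads_per_100bp_mean <- mean(reads_per_100bp(a, rd))
    }
    emit(as.data.frame(overlap), "overlap_metrics.tsv")
  }

  manifest <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("histurnover")),
    seed = cfg$seed,
    label = list(name = label$name, residue = label$residue,
                 delta = label$delta),
    rows = list(signals = nrow(run$signals),
                fragments = if (is.null(run$fragments)) 0L else
                  nrow(run$fragments),
                quant_records = nrow(quant)),
    warnings = warnings)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mpath)
  invisible(list(quant = quant, stats = stats_out, overlap = overlap,
                 middle_down = md, manifest = manifest, files = files))
}
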