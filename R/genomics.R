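#' Read a BED3/BED6 file
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' closed convention of `GRanges` on input and back on output, so a
#' read/write round trip is byte-stable. Malformed lines (fewer than 3
#' fields, non-numeric or negative coordinates, start >= end) raise an error
#' naming the offending line.
#'
#' @param path Path to a BED file.
#' @param drop_chroms Optional chromosome names to discard at read time
#'   (e.g. `c("chrM", "chrX", "chrY")`). Off by default.
#' @return A `GRanges` (strand and score kept when present).
#' @export
read_bed <- function(path, drop_chroms = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no intervals in ", path)
  fields <- strsplit(lines[idx], "\t")
  parsed <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    ln <- idx[i]
    if (length(f) < 3) stop("BED line ", ln, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("BED line ", ln, ": non-numeric coordinates")
    if (s < 0) stop("BED line ", ln, ": negative start")
    if (s >= e) stop("BED line ", ln, ": start >= end")
    list(chrom = f[1], start = s, end = e,
         name = if (length(f) >= 4) f[4] else NA_character_,
         score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5]))
                 else NA_real_,
         strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*")
  })
  df <- do.call(rbind, lapply(parsed, as.data.frame))
  if (!is.null(drop_chroms)) df <- df[!df$chrom %in% drop_chroms, ]
  if (!nrow(df)) stop("no intervals left in ", path, " after chrom filter")
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  if (any(!is.na(df$name))) gr$name <- df$name
  if (any(!is.na(df$score))) gr$score <- df$score
  gr
}

#' @rdname read_bed
#' @param gr A `GRanges` to write.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  has_name <- !is.null(gr$name); has_score <- !is.null(gr$score)
  strands <- as.character(GenomicRanges::strand(gr))
  has_strand <- any(strands != "*")
  if (has_name || has_score || has_strand) {
    df$name <- if (has_name) gr$name else "."
    df$score <- if (has_score) gr$score else 0
    if (has_strand) df$strand <- ifelse(strands == "*", ".", strands)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# put two GRanges on a common seqlevel set (unstranded ops)
.harmonize <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Merge two interval sets
#'
#' Union of the two sets with overlapping and directly adjacent (0-gap)
#' intervals coalesced — the operation used to merge peak calls from
#' technical replicates. Strand is ignored.
#'
#' @param a A `GRanges`.
#' @param b Optional second `GRanges`.
#' @return A sorted, disjoint `GRanges`.
#' @export
merge_set <- function(a, b = NULL) {
  g <- if (is.null(b)) a else {
    h <- .harmonize(a, b)
    c(GenomicRanges::granges(h$a), GenomicRanges::granges(h$b))
  }
  GenomicRanges::reduce(g, ignore.strand = TRUE)
}

#' Percent of peaks with >= 1 bp intersection
#'
#' 100 x (number of `a` intervals overlapping at least one `b` interval by
#' >= 1 bp) / (number of `a` intervals). Adjacency is not overlap; strand is
#' ignored.
#'
#' @param a Query peak set (non-empty `GRanges`).
#' @param b Subject peak set.
#' @return A percentage.
#' @export
peak_intersect_fraction <- function(a, b) {
  if (!length(a)) stop("empty query set")
  h <- .harmonize(a, b)
  hits <- GenomicRanges::countOverlaps(h$a, h$b, minoverlap = 1L,
                                       ignore.strand = TRUE)
  100 * sum(hits > 0) / length(a)
}

#' Percent of peak base pairs covered by reads
#'
#' 100 x (bp of `a` covered by >= 1 interval of `reads`) / (total bp of
#' `a`), with `a` reduced first so overlapping peaks are not double-counted.
#'
#' @param a Peak set (non-empty `GRanges`).
#' @param reads Read/coverage set.
#' @return A percentage.
#' @export
bp_coverage_fraction <- function(a, reads) {
  if (!length(a)) stop("empty query set")
  h <- .harmonize(GenomicRanges::reduce(GenomicRanges::granges(a),
                                        ignore.strand = TRUE),
                  GenomicRanges::reduce(GenomicRanges::granges(reads),
                                        ignore.strand = TRUE))
  ov <- GenomicRanges::intersect(h$a, h$b, ignore.strand = TRUE)
  100 * sum(GenomicRanges::width(ov)) / sum(GenomicRanges::width(h$a))
}

#' Reads per 100 bp of each peak
#'
#' For each `a` interval: (number of reads overlapping it by >= 1 bp) x 100
#' / interval length — read counts normalized for peak length. Reads are
#' counted as the intervals provided (fragments or mates, as supplied).
#'
#' @param a Peak set (non-empty `GRanges`).
#' @param reads Read set.
#' @return Numeric vector, one value per `a` interval.
#' @export
reads_per_100bp <- function(a, reads) {
  if (!length(a)) stop("empty query set")
  h <- .harmonize(a, reads)
  cnt <- GenomicRanges::countOverlaps(h$a, h$b, minoverlap = 1L,
                                      ignore.strand = TRUE)
  cnt * 100 / GenomicRanges::width(a)
}

#' Promoter windows around transcription start sites
#'
#' Each TSS is extended 3 kb upstream and 2 kb downstream in its strand's
#' reading direction: `+` gives \[pos-3000, pos+2000) and `-` gives
#' \[pos-2000, pos+3000) in 0-based half-open coordinates, clipped at 0.
#'
#' @param tss A data.frame with columns `chrom`, `pos` (0-based TSS
#'   position) and `strand` (`"+"`/`"-"`), or a `GRanges` of width-1 sites.
#' @param upstream,downstream Extension sizes in bp.
#' @param allow_unstranded Treat missing/`"."` strand as `+`? Default FALSE
#'   (error).
#' @return A `GRanges` of promoter windows.
#' @export
promoter_windows <- function(tss, upstream = 3000, downstream = 2000,
                             allow_unstranded = FALSE) {
  if (inherits(tss, "GRanges"))
    tss <- data.frame(chrom = as.character(GenomicRanges::seqnames(tss)),
                      pos = GenomicRanges::start(tss) - 1L,
                      strand = as.character(GenomicRanges::strand(tss)))
  if (any(tss$pos < 0)) stop("TSS positions must be >= 0")
  st <- as.character(tss$strand)
  unk <- !st %in% c("+", "-")
  if (any(unk)) {
    if (!allow_unstranded)
      stop("unknown strand for ", sum(unk), " TSS entr",
           if (sum(unk) == 1) "y" else "ies",
           "; set allow_unstranded = TRUE to treat as '+'")
    st[unk] <- "+"
  }
  start0 <- ifelse(st == "+", tss$pos - upstream, tss$pos - downstream)
  end0 <- ifelse(st == "+", tss$pos + downstream, tss$pos + upstream)
  start0 <- pmax(start0, 0)
  GenomicRanges::GRanges(tss$chrom,
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         strand = st)
}
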