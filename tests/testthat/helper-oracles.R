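# Independent oracles used across the test suite. Each one is deliberately
# implemented from first principles (elemental compositions, density
# integration, per-bp coverage vectors) so it never shares code with the
# implementation path it checks.

# --- residue masses from elemental compositions --------------------------
.ORACLE_ATOM <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)

.ORACLE_COMP <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

comp_mass <- function(comp) sum(.ORACLE_ATOM[names(comp)] * comp)

# peptide mass by summing elemental compositions + H2O + n_prop * C3H4O
oracle_peptide_mass <- function(seq, n_prop = 0) {
  res <- strsplit(seq, "")[[1]]
  sum(vapply(.ORACLE_COMP[res], comp_mass, numeric(1))) +
    comp_mass(c(H = 2, O = 1)) + n_prop * comp_mass(c(C = 3, H = 4, O = 1))
}

# --- Welch test recomputed from scratch, p by density integration --------
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1); vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  dens <- function(u) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + u^2 / df)^(-(df + 1) / 2)
  tail_p <- integrate(dens, abs(tt), Inf, rel.tol = 1e-13)$value
  list(t = tt, df = df, p = 2 * tail_p)
}

oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# --- per-bp brute-force interval oracles (genome <= 10 kb) ---------------
# 0-based half-open intervals as a 2-column matrix from a GRanges on chr1
gr_to_mat <- function(gr) {
  cbind(GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

cov_vector <- function(m, genome_len) {
  v <- logical(genome_len)
  for (i in seq_len(nrow(m))) v[(m[i, 1] + 1):m[i, 2]] <- TRUE
  v
}

oracle_merge <- function(m_list, genome_len) {
  v <- Reduce(`|`, lapply(m_list, cov_vector, genome_len))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], ends[r$values])  # 0-based half-open
}

oracle_peak_frac <- function(a, b, genome_len) {
  vb <- cov_vector(b, genome_len)
  hit <- vapply(seq_len(nrow(a)),
                function(i) any(vb[(a[i, 1] + 1):a[i, 2]]), logical(1))
  100 * sum(hit) / nrow(a)
}

oracle_bp_frac <- function(a, reads, genome_len) {
  va <- cov_vector(a, genome_len); vr <- cov_vector(reads, genome_len)
  100 * sum(va & vr) / sum(va)
}

oracle_reads_per_100bp <- function(a, reads) {
  vapply(seq_len(nrow(a)), function(i) {
    n <- sum(reads[, 1] < a[i, 2] & reads[, 2] > a[i, 1])
    n * 100 / (a[i, 2] - a[i, 1])
  }, numeric(1))
}

# random 0-based half-open interval set on a small genome
random_intervals <- function(n, genome_len, max_w = 60) {
  s <- sample.int(genome_len - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  m <- cbind(s, pmin(s + w, genome_len))
  m
}

mat_to_gr <- function(m) GenomicRanges::GRanges(
  "chr1", IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2]))

# --- least-squares oracle for isomer-mix recovery ------------------------
oracle_ls_mix <- function(frags) {
  d <- frags[frags$species %in% c("A", "B"), ]
  ids <- unique(d$fragment_id)
  a <- vapply(ids, function(i)
    sum(d$intensity[d$fragment_id == i & d$species == "A"]), numeric(1))
  b <- vapply(ids, function(i)
    sum(d$intensity[d$fragment_id == i & d$species == "B"]), numeric(1))
  sum(a * (a + b)) / sum((a + b)^2)
}
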