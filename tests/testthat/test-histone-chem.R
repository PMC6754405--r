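test_that("registered modification deltas match their printed values and compositions", {
  # acetyl (C2H2O) and trimethyl (C3H6) are the classic near-isobaric pair
  expect_equal(mod_delta("ac"), 42.010, tolerance = 1e-3)
  expect_equal(mod_delta("me3"), 42.047, tolerance = 1e-3)
  expect_equal(mod_delta("ac"), comp_mass(c(C = 2, H = 2, O = 1)),
               tolerance = 1e-5)
  expect_equal(mod_delta("me3"), comp_mass(c(C = 3, H = 6)), tolerance = 1e-5)
  expect_equal(mod_delta("me1"), comp_mass(c(C = 1, H = 2)), tolerance = 1e-5)
  expect_equal(mod_delta("prop"), comp_mass(c(C = 3, H = 4, O = 1)),
               tolerance = 1e-5)
  expect_identical(mod_delta("unmod"), 0)
  expect_error(mod_delta("phospho"), "unknown modification")
  # ac - me3 gap: the resolution-defining 36 mDa (within 1e-4 Da absolute)
  expect_lt(abs((mod_delta("ac") - mod_delta("me3")) - (42.0106 - 42.0470)),
            1e-4)
})

test_that("modification registry round-trips through TSV", {
  path <- tempfile(fileext = ".tsv")
  write.table(default_mods(), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  reg <- read_mod_registry(path)
  expect_equal(reg$delta, default_mods()$delta)
  expect_equal(reg$blocks_propionylation, default_mods()$blocks_propionylation)
})

test_that("derivatization propionylates free and me1 lysines plus the N-terminus", {
  d <- apply_derivatization(proteoform("KSTGGKAPR", offset = 9))
  expect_identical(d$n_prop, 3L)          # N-term, K9, K14
  expect_setequal(d$prop_sites, c("Nterm", "K9", "K14"))

  dk9ac <- apply_derivatization(
    proteoform("KSTGGKAPR", data.frame(pos = 1, code = "ac"), offset = 9))
  expect_identical(dk9ac$n_prop, 2L)      # ac blocks K9
  expect_setequal(dk9ac$prop_sites, c("Nterm", "K14"))

  dme1 <- apply_derivatization(
    proteoform("KSTGGKAPR", data.frame(pos = 1, code = "me1"), offset = 9))
  expect_identical(dme1$n_prop, 3L)       # me1 lysines stay reactive

  no_k <- apply_derivatization(proteoform("STGGAPR"))
  expect_identical(no_k$n_prop, 1L)       # N-terminus only

  expect_error(apply_derivatization(d), "already derivatized")
})

test_that("proteoform masses agree with an elemental-composition oracle", {
  expect_equal(proteoform_mass(proteoform("G")), 75.03203, tolerance = 1e-5)
  d <- apply_derivatization(proteoform("KSTGGKAPR", offset = 9))
  expect_equal(proteoform_mass(d), oracle_peptide_mass("KSTGGKAPR", 3),
               tolerance = 1e-6)
  expect_equal(proteoform_mass(d), 1068.593, tolerance = 1e-3)
  # a random selection of panel proteoforms vs the oracle
  pan <- default_panel()
  pfs <- attr(pan, "proteoforms")
  for (p in pfs[c(2, 8, 18, 23)]) {
    dd <- apply_derivatization(p)
    expect_equal(proteoform_mass(dd),
                 oracle_peptide_mass(p$backbone, dd$n_prop) +
                   sum(mod_delta(p$mods$code)),
                 tolerance = 1e-6)
  }
  expect_error(proteoform("KSTZ"), "unknown residue")
})

test_that("ac vs me3 at the same site differ by the registered delta gap", {
  for (bb in c("KSTGGKAPR", "KQLATKAAR")) {
    pac <- proteoform(bb, data.frame(pos = 1, code = "ac"))
    pme <- proteoform(bb, data.frame(pos = 1, code = "me3"))
    expect_lt(abs((proteoform_mass(pac) - proteoform_mass(pme)) -
                    (42.0106 - 42.0470)), 1e-4)
  }
})

test_that("mz follows the proton convention and inverts cleanly", {
  expect_equal(mz(1000, 1), 1001.007276)
  expect_error(mz(1000, 0), "positive integer")
  # heavy-light delta of ~10 Da appears as ~5 m/z at 2+
  expect_equal(mz(1010.008, 2) - mz(1000, 2), 5.004, tolerance = 1e-3)
  for (z in 1:6) expect_equal(mz(1234.5, z) * z - z * 1.007276, 1234.5,
                              tolerance = 1e-9)
  m <- 800
  zz <- sapply(1:5, function(z) mz(m, z))
  expect_true(all(diff(zz) < 0))
})

test_that("label deltas count labeled residues", {
  r10 <- get_label("R10")
  expect_equal(r10$delta, 10.008, tolerance = 1e-3)
  expect_equal(label_delta("KSTGGKAPR", r10), r10$delta)
  expect_equal(label_delta("KSTGGKAPP", r10), 0)
  hh <- get_label("H-heavy")
  expect_equal(label_delta(h3_tail_1_50(), hh), hh$delta)  # single H39
  expect_error(get_label("K8"), "unknown label")
})

test_that("isobaric classification separates isomers, near-isobars and distinct forms", {
  k9ac <- proteoform("KSTGGKAPR", data.frame(pos = 1, code = "ac"), offset = 9)
  k14ac <- proteoform("KSTGGKAPR", data.frame(pos = 6, code = "ac"), offset = 9)
  k9me3 <- proteoform("KSTGGKAPR", data.frame(pos = 1, code = "me3"), offset = 9)
  un <- proteoform("KSTGGKAPR", offset = 9)
  expect_identical(isobaric_class(k9ac, k14ac), "positional_isomer")
  expect_identical(isobaric_class(k9ac, k9me3, resolving_tol = 0.05),
                   "near_isobaric")
  expect_identical(isobaric_class(un, k9ac), "distinct")
  expect_identical(isobaric_class(k9ac, k9ac), "identical")
  expect_error(isobaric_class(k9ac, proteoform("KQLATKAAR")),
               "different backbones")
})

test_that("the H3 tail methyl ladder has the expected spacing, offset and window", {
  lad <- methyl_ladder(h3_tail_1_50(), max_equiv = 15, z = 8)
  expect_equal(nrow(lad), 16L)
  expect_equal(unique(round(diff(lad$light_mz), 4)), 1.7520)
  # heavy - light offset constant across the ladder
  expect_equal(unique(round(lad$heavy_mz - lad$light_mz, 9)),
               round(get_label("H-heavy")$delta / 8, 9))
  # the full 8+ ladder sits inside the 665-710 acquisition window
  expect_true(all(lad$light_mz > 665 & lad$light_mz < 710))
  expect_true(all(lad$heavy_mz > 665 & lad$heavy_mz < 710))
  # cross-check the base mass against the elemental oracle
  expect_equal(lad$light_mz[1],
               (oracle_peptide_mass(h3_tail_1_50()) + 8 * 1.0078250319 -
                  8 * 0.0005485799) / 8,
               tolerance = 1e-4)
})

test_that("panel parsing maps protein-numbered mods onto peptide positions", {
  pan <- default_panel()
  expect_identical(nrow(pan), 23L)
  pfs <- attr(pan, "proteoforms")
  p <- pfs[["H3_27_40_K27me3K36me2"]]
  expect_equal(p$mods$pos, c(1L, 10L))
  expect_equal(p$mods$code, c("me3", "me2"))
  expect_identical(proteoform_name(p), "K27me3K36me2")
  expect_error(parse_mod_string("K9ac", 18, "KQLATKAAR"), "does not match")
  expect_error(proteoform("KSTGGKAPR", data.frame(pos = 2, code = "ac")),
               "target mismatch")
  expect_error(proteoform("KSTGGKAPR",
                          data.frame(pos = c(1, 1), code = c("ac", "me1"))),
               "one modification per position")
})
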