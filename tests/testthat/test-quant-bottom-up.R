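test_that("trace integration matches analytic areas", {
  rt <- seq(0, 100, by = 0.1)
  zero <- data.frame(rt = rt, intensity = rep(0, length(rt)))
  expect_equal(integrate_trace(zero), 0)
  # rectangular pulse: height 5 over width 20
  pulse <- data.frame(rt = rt, intensity = ifelse(rt >= 40 & rt < 60, 5, 0))
  expect_equal(integrate_trace(pulse), 100, tolerance = 1e-3)
  # Gaussian at 2 s sampling vs closed form apex * sigma * sqrt(2*pi)
  sigma <- 12 / (2 * sqrt(2 * log(2)))
  rt2 <- seq(540, 660, by = 2)
  g <- data.frame(rt = rt2, intensity = 1000 * exp(-(rt2 - 600)^2 / (2 * sigma^2)))
  expect_equal(integrate_trace(g), 1000 * sigma * sqrt(2 * pi),
               tolerance = 5e-3)
  expect_error(integrate_trace(g, c(900, 950)), "fewer than 3")
  expect_error(integrate_trace(g[1:2, ]), "at least 3")
  expect_error(integrate_trace(data.frame(rt = c(1, 1, 2), intensity = 0:2)),
               "strictly increasing")
})

test_that("heavy fraction is a guarded, scale-invariant ratio", {
  expect_equal(heavy_fraction(100, 100), 0.5)
  expect_equal(heavy_fraction(0, 42), 1)
  expect_equal(heavy_fraction(42, 0), 0)
  expect_error(heavy_fraction(0, 0), class = "histurnover_undefined_signal")
  expect_error(heavy_fraction(-1, 5), ">= 0")
  set.seed(1)
  for (i in 1:20) {
    l <- runif(1, 0, 100); h <- runif(1, 0, 100); c <- runif(1, 0.01, 1e6)
    expect_equal(heavy_fraction(l, h), heavy_fraction(c * l, c * h))
  }
})

test_that("relative abundance normalizes a backbone family to 1", {
  expect_equal(unname(relative_abundance(c(a = 7))), 1)
  expect_equal(unname(relative_abundance(c(a = 3, b = 3))), c(0.5, 0.5))
  set.seed(2)
  for (i in 1:10) {
    v <- setNames(runif(5, 0, 10), letters[1:5])
    expect_equal(sum(relative_abundance(v)), 1, tolerance = 1e-12)
  }
  expect_error(relative_abundance(c(a = 0, b = 0)), "zero family total")
})

test_that("isomer resolution averages per-fragment ratios", {
  fr <- data.frame(fragment_id = c("f1", "f1", "f2", "f2"),
                   species = c("A", "B", "A", "B"),
                   intensity = c(40, 60, 60, 40))
  expect_equal(resolve_isobaric(fr)$mix_a, 0.5)   # mean of 0.4 and 0.6
  one <- fr[1:2, ]
  expect_equal(resolve_isobaric(one)$mix_a, 0.4)  # single pair = its ratio
  pure <- data.frame(fragment_id = c("f1", "f1"), species = c("A", "B"),
                     intensity = c(100, 0))
  expect_equal(resolve_isobaric(pure)$mix_a, 1)
  shared_only <- data.frame(fragment_id = "s1", species = "shared",
                            intensity = 10)
  expect_false(resolve_isobaric(shared_only)$resolved)
})

test_that("resolved mixes track a least-squares oracle under noise", {
  cfg <- sim_config(snr = 20)
  set.seed(314)
  d <- replicate(60, {
    mix <- runif(1)
    fr <- simulate_isobaric_fragments(mix, cfg)
    r <- resolve_isobaric(fr)
    c(abs(r$mix_a - oracle_ls_mix(fr)), abs(r$mix_a - mix))
  })
  expect_lt(mean(d[1, ]), 0.05)   # agreement with the LS estimator
  expect_lt(mean(d[2, ]), 0.05)   # and with the truth
})

test_that("noiseless runs quantify to the ground truth exactly", {
  pan <- default_panel()
  cfg <- sim_config(seed = 8, days = 2)
  tr <- default_truth(days = 2, conditions = "WT", panel = pan)
  run <- simulate_run(tr, cfg, pan, noise = FALSE)
  q <- quantify_run(run, pan, cfg)
  expect_identical(nrow(q), nrow(pan) * 3L)  # panel x replicates x 1 day
  m <- merge(as.data.frame(q), tr, by = c("proteoform_id", "day", "condition"))
  expect_equal(m$heavy_fraction.x, m$heavy_fraction.y, tolerance = 1e-9)
  expect_equal(m$relative_abundance, m$rel_abundance, tolerance = 1e-9)
  expect_true(all(q$flag == "ok"))
  # per-family normalization holds on every run
  sums <- aggregate(relative_abundance ~ family + replicate, as.data.frame(q),
                    sum)
  expect_true(all(abs(sums$relative_abundance - 1) < 1e-6))
})

test_that("noisy runs recover per-proteoform means within tolerance", {
  pan <- default_panel()
  cfg <- sim_config(seed = 19, days = 2)
  tr <- default_truth(days = 2, conditions = "WT", panel = pan)
  q <- quantify_run(simulate_run(tr, cfg, pan), pan, cfg)
  mm <- aggregate(heavy_fraction ~ proteoform_id, as.data.frame(q), mean)
  m <- merge(mm, tr, by = "proteoform_id")
  expect_lt(max(abs(m$heavy_fraction.x - m$heavy_fraction.y)), 0.02)
})

test_that("missing fragments, orphans and weak families degrade with flags", {
  pan <- default_panel()
  cfg <- sim_config(seed = 4, days = 1)
  tr <- default_truth(days = 1, conditions = "WT", panel = pan)
  run <- simulate_run(tr, cfg, pan, fragments = FALSE)
  q <- quantify_run(run, pan, cfg)
  iso <- q$proteoform_id %in% c("H3_9_17_K9ac", "H3_9_17_K14ac",
                                "H3_18_26_K18ac", "H3_18_26_K23ac",
                                "H4_4_17_K5ac", "H4_4_17_K16ac")
  expect_true(all(q$flag[iso] == "unresolved_isomer"))
  expect_true(all(!q$resolved[iso]))
  expect_true(all(q$flag[!iso] == "ok"))
  # orphan analytes: warn and skip
  run2 <- run
  extra <- run2$signals[run2$signals$proteoform_id == "H3_3_8_unmod", ]
  extra$proteoform_id <- "H9_1_6_unmod"
  run2$signals <- rbind(run2$signals, extra)
  expect_warning(q2 <- quantify_run(run2, pan, cfg), "not in panel")
  expect_false("H9_1_6_unmod" %in% q2$proteoform_id)
  # an absurd area floor marks families missing, not zero
  q3 <- quantify_run(run, pan, cfg, area_floor = 1e12)
  expect_true(all(q3$flag == "low_signal"))
  expect_true(all(is.na(q3$relative_abundance)))
})
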