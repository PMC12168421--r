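test_that("generated cosinor series follow the closed form", {
  expect_equal(generate_rhythmic_series(10, 3, 14, 14), 13)
  expect_equal(generate_rhythmic_series(10, 3, 14, 2), 7)
  expect_equal(generate_rhythmic_series(5, 0, 0, c(0, 6, 12, 18)),
               rep(5, 4))
  expect_error(generate_rhythmic_series(1, -1, 0, 1), "amplitude")
  expect_error(generate_rhythmic_series(1, 1, 0, 1, noise_sd = -1),
               "noise_sd")
})

test_that("studies are a pure function of the seed", {
  d <- study_design(n_cows = 4, groups = c("DF", "NF"), n_taxa = 10,
                    seed = 61)
  mix <- c(FTR = 4, MFR = 2, ARRHYTHMIC = 4)
  expect_identical(generate_study(d, mix), generate_study(d, mix))
  d2 <- d
  d2$seed <- 62
  st1 <- generate_study(d, mix)
  st2 <- generate_study(d2, mix)
  expect_false(identical(st1$abundance, st2$abundance))
})

test_that("generated abundances close to 1 and align with metadata", {
  d <- study_design(n_cows = 3, groups = c("ALF", "DF", "NF"), n_taxa = 12,
                    kingdoms = c("bacteria", "archaea"), seed = 63)
  st <- generate_study(d, c(FTR = 6, ARRHYTHMIC = 6))
  for (kd in names(st$abundance)) {
    expect_equal(rowSums(st$abundance[[kd]]),
                 stats::setNames(rep(1, nrow(st$metadata)),
                                 st$metadata$sample_id),
                 tolerance = 1e-9)
    expect_identical(rownames(st$abundance[[kd]]), st$metadata$sample_id)
  }
  expect_false(anyDuplicated(st$metadata$sample_id) > 0)
  expect_true(all(st$qpcr$total_copies > 0))
})

test_that("class-mix bookkeeping is validated", {
  d <- study_design(n_cows = 3, groups = c("DF", "NF"), n_taxa = 10,
                    seed = 64)
  expect_error(generate_study(d, c(FTR = 4)), "sum to n_taxa")
  expect_error(generate_study(d, c(BAD = 10)), "class labels")
  st <- generate_study(d, c(ARRHYTHMIC = 10))
  expect_true(all(st$truth$amplitude == 0))
  expect_true(all(!st$truth$rhythmic))
})

test_that("truth amplitude is zero exactly when a group is arrhythmic", {
  d <- study_design(n_cows = 3, groups = c("RFT2d", "RFT7d"), n_taxa = 12,
                    seed = 65)
  st <- generate_study(d, c(GCR = 4, LCR = 4, CCR = 4))
  tr <- st$truth
  expect_true(all((tr$amplitude == 0) == (!tr$rhythmic)))
  expect_true(all(tr$peak_time >= 0 & tr$peak_time < 24))
  gcr2d <- tr[tr$class == "GCR" & tr$group == "RFT2d", ]
  expect_true(all(!gcr2d$rhythmic))
  gcr7d <- tr[tr$class == "GCR" & tr$group == "RFT7d", ]
  expect_true(all(gcr7d$rhythmic))
})

test_that("noiseless latent series round-trip through the cosinor fit", {
  d <- study_design(n_cows = 3, groups = c("DF", "NF"), n_taxa = 8,
                    noise_sd = 0, cow_effect_sd = 0, seed = 66)
  st <- generate_study(d, c(FTR = 4, MFR = 4))
  md <- st$metadata
  for (g in c("DF", "NF")) {
    sel <- md[md$group == g, ]
    for (tx in colnames(st$latent$bacteria)[c(1, 5)]) {
      fit <- fit_cosinor(st$latent$bacteria[sel$sample_id, tx],
                         sel$clock_time)
      tr <- st$truth[st$truth$taxon_id == tx & st$truth$group == g, ]
      expect_equal(fit$mesor, tr$mesor, tolerance = 1e-6)
      expect_equal(fit$amplitude, tr$amplitude, tolerance = 1e-6)
      expect_equal(fit$peak_time, tr$peak_time, tolerance = 1e-6)
    }
  }
})

test_that("FTR truth peaks shift by exactly 12 h between DF and NF", {
  d <- study_design(n_cows = 3, groups = c("DF", "NF"), n_taxa = 10,
                    seed = 67)
  st <- generate_study(d, c(FTR = 6, MFR = 4))
  tr <- st$truth
  for (tx in unique(tr$taxon_id)) {
    pk <- tr[tr$taxon_id == tx, ]
    shift <- abs(circular_peak_diff(pk$peak_time[pk$group == "DF"],
                                    pk$peak_time[pk$group == "NF"]))
    if (pk$class[1] == "FTR") expect_equal(shift, 12, tolerance = 1e-9)
    else expect_true(shift >= 3 - 1e-9 && shift <= 6 + 1e-9)
  }
})

test_that("fermentation series have evening VFA peaks and consistent TVFA", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:24),
                   clock_time = rep(c(2, 8, 14, 20), 6))
  f <- generate_fermentation_series(md, noise_frac = 0)
  expect_equal(f$tvfa, rowSums(f[, c("acetate", "propionate", "butyrate",
                                     "isobutyrate", "valerate",
                                     "isovalerate")]),
               tolerance = 1e-9)
  # no-noise series refit by the cosinor recovers the default peaks
  fit <- fit_cosinor(f$acetate, md$clock_time)
  expect_equal(fit$peak_time, 18, tolerance = 0.1)
  fit_ph <- fit_cosinor(f$ph, md$clock_time)
  expect_equal(fit_ph$peak_time, 6, tolerance = 0.1)
  # peak override and max-at-peak property
  f2 <- generate_fermentation_series(md, peak_map = c(acetate = 20),
                                     noise_frac = 0)
  expect_equal(max(f2$acetate), f2$acetate[md$clock_time == 20][1])
  # zero amplitudes give constant records
  amps <- stats::setNames(rep(0, 8),
                          c("acetate", "propionate", "butyrate",
                            "isobutyrate", "valerate", "isovalerate",
                            "ph", "nh3n"))
  f3 <- generate_fermentation_series(md, amplitude_map = amps,
                                     noise_frac = 0)
  expect_equal(length(unique(f3$acetate)), 1)
  expect_error(generate_fermentation_series(md, peak_map = c(acetate = 25)),
               "\\[0, 24\\)")
})
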