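fake_fit <- function(p, peak, period = 24) {
  structure(list(rhythm_p = p, peak_time = peak, period = period,
                 mesor = 1, amplitude = 1), class = "cosinor_fit")
}

fake_cmp <- function(p_mesor, p_amplitude, p_peak) {
  structure(list(p_mesor = p_mesor, p_amplitude = p_amplitude,
                 p_peak = p_peak), class = "rhythm_comparison")
}

test_that("feeding-response rules reproduce the figure-legend cases", {
  expect_equal(classify_feeding_response(fake_fit(.01, 19), fake_fit(.01, 7)),
               "FTR")
  expect_equal(classify_feeding_response(fake_fit(.01, 19), fake_fit(.01, 22)),
               "MFR")
  expect_equal(classify_feeding_response(fake_fit(.20, 19), fake_fit(.01, 7)),
               "RHYTHMIC_UNCLASSIFIED")
  expect_equal(classify_feeding_response(fake_fit(.20, 19), fake_fit(.30, 7)),
               "ARRHYTHMIC")
})

test_that("the 12 +/- 3 h window is inclusive at both endpoints", {
  # shifts of exactly 9 and 15 h classify FTR
  expect_equal(classify_feeding_response(fake_fit(.01, 0), fake_fit(.01, 9)),
               "FTR")
  expect_equal(classify_feeding_response(fake_fit(.01, 0), fake_fit(.01, 15)),
               "FTR")
  expect_equal(classify_feeding_response(fake_fit(.01, 0), fake_fit(.01, 8.99)),
               "MFR")
  expect_equal(classify_feeding_response(fake_fit(.01, 0), fake_fit(.01, 15.01)),
               "MFR")
})

test_that("transplantation-response rules reproduce the figure-legend cases", {
  expect_equal(classify_rft_response(fake_fit(.3, 1), fake_fit(.01, 1)), "GCR")
  expect_equal(classify_rft_response(fake_fit(.01, 1), fake_fit(.3, 1)), "LCR")
  expect_equal(classify_rft_response(fake_fit(.3, 1), fake_fit(.4, 1)),
               "NEVER_RHYTHMIC")
  expect_equal(classify_rft_response(fake_fit(.01, 1), fake_fit(.01, 1),
                                     fake_cmp(.6, .4, .9)), "CCR")
  expect_equal(classify_rft_response(fake_fit(.01, 1), fake_fit(.01, 1),
                                     fake_cmp(.6, .4, .01)), "InCCR")
  expect_error(classify_rft_response(fake_fit(.01, 1), fake_fit(.01, 1)),
               "comparison")
})

test_that("class summaries report counts and abundance percent", {
  ab <- matrix(c(0.40, 0.22, 0.38), nrow = 1,
               dimnames = list("s1", c("A", "B", "C")))
  ab <- ab[rep(1, 4), ]
  rownames(ab) <- paste0("s", 1:4)
  cls <- data.frame(taxon_id = c("A", "B", "C"),
                    label = c("FTR", "FTR", "ARRHYTHMIC"))
  s <- summarize_classes(cls, ab)
  expect_equal(s$n_taxa[s$label == "FTR"], 2)
  expect_equal(s$mean_abundance_pct[s$label == "FTR"], 62)
  expect_equal(s$mean_abundance_pct[s$label == "ARRHYTHMIC"], 38)
  # empty label set -> all-zero summary
  s0 <- summarize_classes(cls[0, ], ab, label_set = c("FTR", "MFR"))
  expect_true(all(s0$n_taxa == 0))
  expect_true(all(s0$mean_abundance_pct == 0))
  # missing taxon -> consistency error
  expect_error(summarize_classes(data.frame(taxon_id = "Z", label = "FTR"),
                                 ab), "missing")
})

test_that("labels partition the taxa for each contrast", {
  d <- study_design(n_cows = 6, groups = c("DF", "NF"), n_taxa = 30, seed = 21)
  st <- generate_study(d, c(FTR = 10, MFR = 6, ARRHYTHMIC = 10,
                            RHYTHMIC_UNCLASSIFIED = 4))
  cls <- classify_taxa(st$abundance$bacteria, st$metadata, "DF_vs_NF",
                       mixed = FALSE)
  expect_equal(nrow(cls), 30)
  expect_false(anyNA(cls$label))
  expect_true(all(cls$label %in% c("FTR", "MFR", "RHYTHMIC_UNCLASSIFIED",
                                   "ARRHYTHMIC")))
})

test_that("noiseless studies reproduce intended classes exactly", {
  # feeding contrast with arrhythmic taxa present
  d1 <- study_design(n_cows = 4, groups = c("DF", "NF"), n_taxa = 20,
                     noise_sd = 0, cow_effect_sd = 0, seed = 22)
  st1 <- generate_study(d1, c(FTR = 8, MFR = 6, ARRHYTHMIC = 6))
  cls1 <- classify_taxa(st1$abundance$bacteria, st1$metadata, "DF_vs_NF",
                        mixed = FALSE)
  truth1 <- unique(st1$truth[, c("taxon_id", "class")])
  expect_equal(cls1$label,
               truth1$class[match(cls1$taxon_id, truth1$taxon_id)])
  # transplantation contrast, gain/loss mix
  d2 <- study_design(n_cows = 4, groups = c("RFT2d", "RFT7d"), n_taxa = 20,
                     noise_sd = 0, cow_effect_sd = 0, seed = 23)
  st2 <- generate_study(d2, c(GCR = 8, LCR = 6, NEVER_RHYTHMIC = 6))
  cls2 <- classify_taxa(st2$abundance$bacteria, st2$metadata,
                        "RFT2d_vs_RFT7d", mixed = FALSE)
  truth2 <- unique(st2$truth[, c("taxon_id", "class")])
  expect_equal(cls2$label,
               truth2$class[match(cls2$taxon_id, truth2$taxon_id)])
  # consistent-rhythm mix: both groups share one rhythmic cohort, so the
  # closed-scale truth is exact (see the vignette on closure and the
  # noiseless limit)
  d3 <- study_design(n_cows = 4, groups = c("RFT2d", "RFT7d"), n_taxa = 16,
                     noise_sd = 0, cow_effect_sd = 0, seed = 25)
  st3 <- generate_study(d3, c(CCR = 10, NEVER_RHYTHMIC = 6))
  cls3 <- classify_taxa(st3$abundance$bacteria, st3$metadata,
                        "RFT2d_vs_RFT7d", mixed = FALSE)
  truth3 <- unique(st3$truth[, c("taxon_id", "class")])
  expect_equal(cls3$label,
               truth3$class[match(cls3$taxon_id, truth3$taxon_id)])
})

test_that("noisy ground-truth labels are recovered at >= 90%", {
  d <- study_design(n_cows = 12, groups = c("DF", "NF"), n_taxa = 60,
                    seed = 24)
  st <- generate_study(d, c(FTR = 25, MFR = 10, ARRHYTHMIC = 25))
  cls <- classify_taxa(st$abundance$bacteria, st$metadata, "DF_vs_NF")
  truth <- unique(st$truth[, c("taxon_id", "class")])
  acc <- mean(cls$label == truth$class[match(cls$taxon_id, truth$taxon_id)])
  expect_gte(acc, 0.9)
})
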