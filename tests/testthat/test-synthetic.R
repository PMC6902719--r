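test_that("identical seed and configuration give a bit-identical dataset", {
  cfg <- quick_config(11)
  s1 <- generate_study(cfg, example_supplement_effects("epidermis"))
  s2 <- generate_study(cfg, example_supplement_effects("epidermis"))
  expect_identical(s1$concentrations, s2$concentrations)
  expect_identical(s1$design, s2$design)
  s3 <- generate_study(quick_config(12), example_supplement_effects("epidermis"))
  expect_false(identical(s1$concentrations, s3$concentrations))
})

test_that("the noise-free limit reproduces the baseline medians exactly", {
  cfg <- quick_config(1, subject_sd = 0, mult_noise_sd = 0, add_noise_sd = 0,
                      lod_quantile = 0)
  st <- generate_study(cfg)
  med <- default_baseline_medians(default_panel())
  med <- med[med$tissue == "epidermis", ]
  x <- as.matrix(st$concentrations$epidermis[, med$species])
  expect_false(anyNA(x))
  for (s in med$species) {
    expect_equal(unname(x[, s]), rep(med$median[med$species == s], nrow(x)))
  }
})

test_that("every subject is fully paired across phase and timepoint", {
  cfg <- study_config(n_subjects = c(EPA = 3, DHA = 2), seed = 5)
  st <- generate_study(cfg)
  counts <- dplyr::count(st$design, subject)
  expect_true(all(counts$n == 2 * 3 * 3)) # phase x tissue x uvr_time
  per_cell <- dplyr::count(st$design, subject, phase, tissue, uvr_time)
  expect_true(all(per_cell$n == 1))
})

test_that("LOD censoring produces the configured missingness fraction", {
  cfg <- study_config(n_subjects = c(EPA = 60), tissues = "epidermis",
                      uvr_timepoints = "unirradiated", add_noise_sd = 0,
                      lod_quantile = 0.3, seed = 202)
  st <- generate_study(cfg)
  x <- as.matrix(st$concentrations$epidermis[, panel_species(st$panel, "epidermis")])
  frac <- colMeans(is.na(x))
  # per species: 120 cells from 60 independent subjects; the subject effect
  # correlates the two phases, so use the subject count for the binomial SE
  se <- sqrt(0.3 * 0.7 / 60)
  expect_true(all(abs(frac - 0.3) < 3 * se))
  expect_lt(abs(mean(frac) - 0.3), 0.03)
})

test_that("epidermal DHA-derived totals exceed EPA-derived totals about 10-fold", {
  st <- generate_study(quick_config(31))
  data <- st$concentrations$epidermis
  lod <- dplyr::filter(st$lod, tissue == "epidermis")
  complete <- substitute_lod(suppressMessages(filter_missing(data)), lod)
  tot_epa <- precursor_totals(complete, st$panel, "EPA")$total
  tot_dha <- precursor_totals(complete, st$panel, "DHA")$total
  ratio <- mean(tot_dha) / mean(tot_epa)
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("unresolvable effect targets are named in the error", {
  expect_error(
    generate_study(quick_config(1), list(effect_spec("resolvins", 2))),
    "resolvins"
  )
  expect_error(effect_spec("HEPEs", -1), "positive")
})

test_that("noise-free RBC profiles move the n-3 index from 4.86 to 7.67", {
  prof <- generate_rbc_profiles(
    n_subjects = 5,
    pre_means = c("20:5n-3" = 1.0, "22:6n-3" = 3.86, "20:4n-6" = 13),
    post_shift = c("20:5n-3" = 2.81),
    between_sd = 0, within_sd = 0, seed = 3
  )
  idx <- n3_index(prof)
  expect_equal(idx$n3_index[idx$phase == "pre"], rep(4.86, 5))
  expect_equal(idx$n3_index[idx$phase == "post"], rep(7.67, 5))
})

test_that("a single-subject RBC table is valid and paired", {
  prof <- generate_rbc_profiles(n_subjects = 1, seed = 9)
  expect_equal(dplyr::n_distinct(prof$subject), 1)
  expect_setequal(unique(prof$phase), c("pre", "post"))
  expect_true(all(prof$pct >= 0))
})

test_that("invalid RBC templates are rejected", {
  expect_error(generate_rbc_profiles(
    pre_means = c("20:5n-3" = 1, "22:6n-3" = 3.86),
    post_shift = c("20:5n-3" = -2)
  ), "negative")
  expect_error(generate_rbc_profiles(
    pre_means = c("16:0" = 80, "18:0" = 30)
  ), "100")
  expect_error(generate_rbc_profiles(
    pre_means = c("20:5n-3" = 1, "22:6n-3" = 3.86),
    post_shift = c("20:3n-3" = 1)
  ), "20:3n-3")
})

test_that("with no shift the paired test on the n-3 index is calibrated", {
  reps <- 400
  pvals <- vapply(seq_len(reps), function(i) {
    prof <- generate_rbc_profiles(
      n_subjects = 12,
      pre_means = c("20:5n-3" = 1.0, "22:6n-3" = 3.86),
      post_shift = c("20:5n-3" = 0),
      seed = 5000 + i
    )
    idx <- tidyr::pivot_wider(n3_index(prof), names_from = "phase",
                              values_from = "n3_index")
    paired_t_test(idx$post - idx$pre)$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
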