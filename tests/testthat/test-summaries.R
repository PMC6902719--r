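profile_of <- function(epa, dha, extra = c("16:0" = 20)) {
  fa <- c("20:5n-3" = epa, "22:6n-3" = dha, extra)
  tibble::tibble(subject = "S1", phase = "pre", fatty_acid = names(fa),
                 pct = unname(fa))
}

test_that("the n-3 index is the sum of EPA% and DHA% and ignores the rest", {
  expect_equal(n3_index(profile_of(2, 3))$n3_index, 5)
  expect_equal(n3_index(profile_of(0, 0))$n3_index, 0)
  # permutation/other-entry invariance
  base <- n3_index(profile_of(1.2, 3.4, c("16:0" = 20, "18:0" = 15)))
  alt <- n3_index(profile_of(1.2, 3.4, c("18:1n-9" = 40)))
  expect_equal(base$n3_index, alt$n3_index)
  expect_error(
    n3_index(dplyr::filter(profile_of(1, 2), fatty_acid != "22:6n-3")),
    "22:6n-3"
  )
})

test_that("a simulated EPA-arm cohort has mean baseline index near 4.86", {
  prof <- generate_rbc_profiles(n_subjects = 200, seed = 44)
  idx <- n3_index(prof)
  pre <- idx$n3_index[idx$phase == "pre"]
  se <- sd(pre) / sqrt(length(pre))
  expect_lt(abs(mean(pre) - 4.86), 3 * se + 0.05)
})

test_that("per-fatty-acid paired tests follow the t-test conventions", {
  prof <- generate_rbc_profiles(n_subjects = 10, seed = 2)
  res <- fatty_acid_paired_tests(prof)
  expect_setequal(res$fatty_acid, names(rbc_template("EPA")$pre_means))
  expect_true(all(res$n == 10))

  # identical pre/post gives the p = 1 convention
  flat <- dplyr::bind_rows(
    tibble::tibble(subject = c("S1", "S2", "S3"), phase = "pre",
                   fatty_acid = "20:5n-3", pct = c(1, 2, 3)),
    tibble::tibble(subject = c("S1", "S2", "S3"), phase = "post",
                   fatty_acid = "20:5n-3", pct = c(1, 2, 3))
  )
  expect_equal(fatty_acid_paired_tests(flat)$p, 1)

  # unpaired subject excluded with warning
  expect_warning(res2 <- fatty_acid_paired_tests(flat[-4, ]), "S1")
  expect_equal(res2$n, 2)
})

test_that("an EPA-arm shift is detected and sign flips leave p unchanged", {
  hits <- vapply(1:12, function(i) {
    prof <- generate_rbc_profiles(n_subjects = 12, seed = 900 + i)
    res <- fatty_acid_paired_tests(prof)
    res$p[res$fatty_acid == "20:5n-3"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  prof <- generate_rbc_profiles(n_subjects = 8, seed = 77)
  flipped <- prof
  wide <- tidyr::pivot_wider(prof, names_from = "phase", values_from = "pct")
  flipped <- dplyr::bind_rows(
    dplyr::transmute(wide, subject, phase = "pre", fatty_acid, pct = pre),
    dplyr::transmute(wide, subject, phase = "post", fatty_acid,
                     pct = 2 * pre - post) # mirror the shift
  )
  a <- fatty_acid_paired_tests(prof)
  b <- fatty_acid_paired_tests(flipped)
  expect_equal(a$p, b$p[match(a$fatty_acid, b$fatty_acid)])
})

test_that("precursor totals sum the right species and ignore column order", {
  panel <- tiny_panel()
  d <- tibble::tibble(
    sample_id = "s1", subject = "S1", phase = "pre",
    `12-HEPE` = 100, `18-HEPE` = 219, `12-HETE` = 50, PGE2 = 10
  )
  tot <- precursor_totals(d, panel, "EPA")
  expect_equal(tot$total, 319)

  shuffled <- d[, c("sample_id", "subject", "phase", "18-HEPE", "PGE2",
                    "12-HETE", "12-HEPE")]
  expect_equal(precursor_totals(shuffled, panel, "EPA")$total, 319)

  expect_error(precursor_totals(d, panel, "ALA"), "No ALA-derived")
})

test_that("percent change has the stated arithmetic and scale invariance", {
  expect_equal(percent_change(rep(100, 5), rep(208, 5)), 108)
  expect_equal(percent_change(c(50, 150), c(50, 150)), 0)
  expect_equal(percent_change(rep(100, 3), rep(50, 3)), -50)
  set.seed(3)
  pre <- runif(10, 50, 150); post <- runif(10, 50, 300)
  expect_equal(percent_change(pre * 7, post * 7), percent_change(pre, post))
  expect_error(percent_change(c(0, 0), c(1, 2)), "positive")
})

test_that("precursor_change reports pre/post means and a paired log-scale test", {
  st <- generate_study(quick_config(55, lod_quantile = 0),
                       example_supplement_effects("epidermis"))
  d <- st$concentrations$epidermis
  out <- precursor_change(d, st$panel, "EPA",
                          pairwise_comparison("EPA", "epidermis"))
  expect_equal(out$n, 12)
  expect_gt(out$percent_change, 0) # HEPEs doubled
  expect_lt(out$p, 0.05)
})

test_that("monotone pairs give rho = 1 and reversed pairs rho = -1", {
  up <- spearman_test(c(1, 5, 9, 13, 20), c(2, 4, 11, 30, 50))
  expect_equal(up$rho, 1)
  down <- spearman_test(1:6, 6:1)
  expect_equal(down$rho, -1)
})

test_that("the 5-pair example matches the exhaustive permutation oracle", {
  res <- spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 0.8)
  # 16 of the 120 permutations reach |rho| >= 0.8
  expect_equal(res$p, 16 / 120, tolerance = 1e-12)
  ct <- cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), method = "spearman",
                 exact = TRUE)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
})

test_that("exact permutation p agrees with cor.test for all n <= 7", {
  set.seed(12)
  for (n in 4:7) {
    for (i in 1:5) {
      x <- rnorm(n); y <- rnorm(n) # continuous, no ties
      res <- spearman_test(x, y)
      ct <- cor.test(x, y, method = "spearman", exact = TRUE)
      expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    }
  }
})

test_that("constant vectors are reported as missing with a note", {
  res <- spearman_test(c(3, 3, 3, 3), 1:4)
  expect_true(is.na(res$rho))
  expect_equal(res$note, "constant vector")
})

test_that("the cross-compartment screen pairs subject-phase observations", {
  st <- generate_study(study_config(n_subjects = c(EPA = 8),
                                    tissues = c("epidermis", "plasma"),
                                    uvr_timepoints = "unirradiated",
                                    lod_quantile = 0, seed = 21))
  skin <- st$concentrations$epidermis
  plasma <- st$concentrations$plasma
  out <- spearman_cross_compartment(skin, plasma)
  shared <- intersect(panel_species(st$panel, "epidermis"),
                      panel_species(st$panel, "plasma"))
  expect_setequal(out$species, shared)
  expect_true(all(out$n == 16)) # 8 subjects x 2 phases
  expect_true(all(out$p >= 0 & out$p <= 1, na.rm = TRUE))

  # a species made perfectly concordant across compartments
  skin2 <- skin; plasma2 <- plasma
  key <- paste(skin$subject, skin$phase)
  plasma2[["12-HETE"]] <- skin2[["12-HETE"]][match(paste(plasma$subject, plasma$phase), key)] * 2
  out2 <- spearman_cross_compartment(skin2, plasma2)
  expect_equal(out2$rho[out2$species == "12-HETE"], 1)
})
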