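# small concentration table builder: species columns A, B with controlled
# missingness over n samples
toy_table <- function(A, B) {
  n <- length(A)
  tibble::tibble(
    sample_id = sprintf("s%d", seq_len(n)),
    subject = sprintf("S%d", seq_len(n)),
    A = A, B = B
  )
}

test_that("species missing in strictly more than half the samples are dropped", {
  d5 <- toy_table(A = c(NA, NA, NA, 4, 5), B = 1:5)
  expect_message(out <- filter_missing(d5), "A")
  expect_false("A" %in% names(out))
  expect_true("B" %in% names(out))
  expect_equal(removed_species(out)$species, "A")
  expect_equal(removed_species(out)$n_missing, 3L)
})

test_that("a species missing in exactly half the samples is retained", {
  d4 <- toy_table(A = c(NA, NA, 3, 4), B = 1:4)
  out <- filter_missing(d4)
  expect_true(all(c("A", "B") %in% names(out)))
  expect_equal(nrow(removed_species(out)), 0)
})

test_that("a fully observed table passes through unchanged and zeros count as missing", {
  d <- toy_table(A = 1:4, B = 5:8)
  out <- filter_missing(d)
  expect_equal(out$A, as.numeric(1:4))
  expect_equal(nrow(removed_species(out)), 0)

  dz <- toy_table(A = c(0, 0, 0, 4), B = 1:4)
  expect_message(outz <- filter_missing(dz), "A")
  expect_false("A" %in% names(outz))

  expect_error(filter_missing(d[0, ]), "No samples")
})

test_that("LOD substitution fills exactly the missing cells", {
  d <- toy_table(A = c(NA, 2, 3, 4), B = 1:4)
  out <- substitute_lod(d, c(A = 0.5, B = 9))
  expect_equal(out$A, c(0.5, 2, 3, 4))
  expect_equal(out$B, as.numeric(1:4)) # observed values untouched

  complete <- toy_table(A = 1:4, B = 5:8)
  expect_equal(substitute_lod(complete, c(A = 1, B = 1))$A, as.numeric(1:4))

  expect_error(substitute_lod(d, c(B = 9)), "no positive LOD for: A")
  all_na <- toy_table(A = c(NA, NA, NA, NA), B = 1:4)
  expect_error(substitute_lod(all_na, c(A = 1, B = 1)), "filtered")
})

test_that("the arsinh transform has the analytic log2 limit and inverts", {
  # a = 0, b = 1: h(1000) = log2(2000) in the high-intensity limit
  expect_lt(abs(asinh(1000) / log(2) - log2(2000)), 1e-4)
  expect_equal(asinh(0) / log(2), 0)
  # numeric inversion round-trip
  for (x in c(0.01, 1, 50, 1e4)) {
    h <- asinh(0.3 + 2 * x) / log(2)
    expect_lt(abs(glog_inverse(h, 0.3, 2) - x) / x, 1e-9)
  }
})

test_that("fitting requires a complete matrix", {
  d <- toy_table(A = c(NA, 2, 3, 4), B = 1:4)
  expect_error(fit_glog(d), "substitute_lod")
})

test_that("near-identical samples get near-identical calibrations", {
  set.seed(42)
  base <- rlnorm(30, log(50), 1.5)
  d <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    !!!setNames(
      purrr::map(1:30, function(i) {
        v <- base[i] * exp(rnorm(4, 0, 0.2)) + rnorm(4, 0, 0.5)
        pmax(v, 0.01)
      }),
      sprintf("sp%02d", 1:30)
    )
  )
  # make s1 and s2 identical
  for (s in sprintf("sp%02d", 1:30)) d[[s]][2] <- d[[s]][1]
  fit <- fit_glog(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$a[["s1"]] - fit$a[["s2"]]), 1e-3 + 0.01 * abs(fit$a[["s1"]]))
  expect_lt(abs(log(fit$b[["s1"]]) - log(fit$b[["s2"]])), 1e-3)
})

test_that("the fitted transform is strictly monotone per sample", {
  res <- run_epidermis_comparison(13)
  fit <- res$fit
  grid <- sort(c(0, 10^seq(-2, 4, length.out = 50)))
  for (s in names(fit$a)) {
    h <- asinh(fit$a[[s]] + fit$b[[s]] * grid) / log(2)
    expect_true(all(diff(h) > 0))
  }
  expect_true(all(fit$b > 0))
})

test_that("on purely multiplicative noise the fit reduces to a log2 scale", {
  # medians spanning the assay's dynamic range identify the transition
  # point of the transform; without an additive noise component the fitted
  # curve must then be log2-like at the top of the observed range
  panel <- default_panel()
  spp <- panel$name[panel$skin]
  med <- tibble::tibble(species = spp, tissue = "epidermis",
                        median = 10^seq(log10(0.05), log10(3000),
                                        length.out = length(spp)))
  cfg <- quick_config(77, baseline_medians = med, add_noise_sd = 0,
                      lod_quantile = 0)
  st <- generate_study(cfg)
  d <- st$concentrations$epidermis
  fit <- fit_glog(d)
  expect_true(fit$converged)
  xmax <- max(as.matrix(d[, fit$species]))
  gaps <- (asinh(fit$a + fit$b * 2 * xmax) -
             asinh(fit$a + fit$b * xmax)) / log(2)
  expect_lt(max(abs(gaps - 1)), 1e-4)
})

test_that("transformed replicate SD is flat across the intensity range", {
  st <- generate_study(quick_config(88))
  data <- st$concentrations$epidermis
  lod <- dplyr::filter(st$lod, tissue == "epidermis")
  complete <- substitute_lod(suppressMessages(filter_missing(data)), lod)
  fit <- fit_glog(complete)
  tr <- apply_glog(complete, fit)
  x <- as.matrix(tr[, fit$species])
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  ter <- cut(rank(mu, ties.method = "first"), 3)
  ratio <- mean(sds[ter == levels(ter)[3]]) / mean(sds[ter == levels(ter)[1]])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("apply_glog rejects mismatched samples or species", {
  st <- generate_study(quick_config(5, lod_quantile = 0))
  d <- st$concentrations$epidermis
  fit <- fit_glog(d)
  expect_error(apply_glog(dplyr::select(d, -`12-HETE`), fit), "Species")
  expect_error(apply_glog(d[1:5, ], fit), "Samples")
})

test_that("the fallback transform is monotone and LOD-aware", {
  d <- toy_table(A = c(0.5, 2, 3, 4), B = 1:4)
  out <- log_lod_transform(d, c(A = 0.5, B = 1))
  expect_equal(out$A, log2(c(0.5, 2, 3, 4) + 0.25))
  expect_equal(attr(out, "transform"), "log2_half_lod")
  expect_error(log_lod_transform(d, c(A = 0.5)), "B")
})
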