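#' Volcano plot of per-species paired tests
#'
#' @param object A `species_test_result` from [diff_test()].
#' @param ... Unused.
#' @return A ggplot object: log2 fold change vs -log10 q, significant
#'   species highlighted.
#' @export
autoplot.species_test_result <- function(object, ...) {
  df <- tidy(object)
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$q),
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (glog scale)",
                  y = expression(-log[10] ~ q),
                  colour = paste0("q < ", alpha),
                  title = attr(object, "comparison")$label) +
    ggplot2::theme_minimal()
}

#' Group enrichment plot
#'
#' @param object An `iga_result` from [run_iga()].
#' @param ... Unused.
#' @return A ggplot object: -log10 corrected PC per group, faceted by
#'   direction, with the significance threshold marked.
#' @export
autoplot.iga_result <- function(object, ...) {
  thr <- attr(object, "correction")$threshold %||% 5e-4
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = -log10(.data$pc_corrected),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "purple3")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ PC[corrected]),
                  fill = paste0("PC < ", format(thr))) +
    ggplot2::theme_minimal()
}

#' Calibration curves of a glog fit
#'
#' @param object A `glog_fit` from [fit_glog()].
#' @param ... Unused.
#' @return A ggplot object showing each sample's arsinh transform over the
#'   fitted intensity range.
#' @export
autoplot.glog_fit <- function(object, ...) {
  xmax <- max(sinh(max(object$mu) * log(2)) / min(object$b), 1)
  grid <- exp(seq(log(xmax * 1e-4 + 1e-9), log(xmax), length.out = 200))
  df <- purrr::map_dfr(names(object$a), function(s) {
    tibble::tibble(sample_id = s, x = grid,
                   h = asinh(object$a[[s]] + object$b[[s]] * grid) / log(2))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$h,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "glog2 transform",
                  title = "Per-sample variance-stabilizing calibration") +
    ggplot2::theme_minimal()
}

#' Mean-SD plot of transformed data
#'
#' Diagnostic for variance stabilization: per-species standard deviation
#' against the rank of the per-species mean. A flat trend indicates the
#' transformed data are homoscedastic across the intensity range.
#'
#' @param data Transformed concentration tibble (see [apply_glog()]).
#' @param species Optional subset of species columns.
#' @return A ggplot object.
#' @export
plot_mean_sd <- function(data, species = NULL) {
  sp <- species_cols(data, species)
  x <- conc_matrix(data, sp)
  df <- tibble::tibble(
    species = sp,
    mean = colMeans(x, na.rm = TRUE),
    sd = apply(x, 2, sd, na.rm = TRUE)
  )
  df$rank <- rank(df$mean, ties.method = "first")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$sd)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "rank of per-species mean", y = "per-species SD") +
    ggplot2::theme_minimal()
}

#' Tidy and summarize a glog fit
#'
#' `tidy()` returns the per-sample calibration parameters; `glance()` the
#' fit-level summary.
#'
#' @param x A `glog_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.glog_fit <- function(x, ...) {
  tibble::tibble(sample_id = names(x$a), a = unname(x$a), b = unname(x$b))
}

#' @rdname tidy.glog_fit
#' @export
glance.glog_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$a), n_species = length(x$species),
    n_trimmed = length(x$trimmed), sigma = x$sigma,
    converged = x$converged, iterations = x$iterations
  )
}

#' Serialize a glog fit to JSON for audit
#'
#' @param fit A `glog_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_glog_fit <- function(fit, path) {
  stopifnot(inherits(fit, "glog_fit"))
  jsonlite::write_json(
    list(a = as.list(fit$a), b = as.list(fit$b), sigma = fit$sigma,
         converged = fit$converged, iterations = fit$iterations,
         trimmed = fit$trimmed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
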