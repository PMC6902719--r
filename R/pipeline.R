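#' Analyze one pairwise comparison end to end
#'
#' Runs the full per-comparison pipeline on a study dataset: selects the
#' comparison's samples from the tissue's concentration table, removes
#' species missing in more than half of those samples, substitutes the
#' remaining missing cells with the species LOD, fits and applies the glog
#' variance-stabilizing normalization (falling back to `log2(x + lod/2)`
#' if the calibration does not converge), performs the paired species
#' tests with BH correction, and scores every mediator group in both
#' directions by iterative group analysis.
#'
#' @param study A `study_dataset` from [generate_study()], or a list with
#'   `concentrations` (named list of tibbles per tissue), `lod`
#'   (tibble `tissue, species, lod`) and `scheme`.
#' @param comparison A [pairwise_comparison()].
#' @param scheme Group scheme; defaults to the study's.
#' @param rank_by Ranking statistic for iGA (see [rank_species()]).
#' @param alpha FDR threshold for per-species significance.
#' @param pc_threshold Corrected-PC threshold for group significance.
#' @return A `comparison_analysis` list: `species` (the
#'   `species_test_result`), `groups` (the `iga_result`), `fit` (the
#'   `glog_fit`), `transform` (`"glog"` or the fallback), `removed`,
#'   `comparison`.
#' @export
run_comparison <- function(study, comparison, scheme = NULL,
                           rank_by = c("log2fc", "t"), alpha = 0.05,
                           pc_threshold = 5e-4) {
  rank_by <- match.arg(rank_by)
  scheme <- scheme %||% study$scheme
  data <- study$concentrations[[comparison$tissue]]
  if (is.null(data)) {
    abort(paste0("Study has no concentration table for tissue: ",
                 comparison$tissue))
  }
  lod <- dplyr::filter(study$lod, .data$tissue == comparison$tissue)

  sel <- comparison_samples(data, comparison)
  sel$.side <- NULL
  filtered <- filter_missing(sel)
  complete <- substitute_lod(filtered, lod)

  fit <- fit_glog(complete)
  if (fit$converged) {
    transformed <- apply_glog(complete, fit)
  } else {
    warn("glog calibration did not converge; using log2(x + lod/2) fallback.")
    transformed <- log_lod_transform(complete, lod)
    attr(transformed, "removed_species") <- removed_species(filtered)
  }

  species <- diff_test(transformed, comparison, alpha = alpha)
  groups <- run_iga(species, scheme, rank_by = rank_by,
                    threshold = pc_threshold)
  structure(
    list(species = species, groups = groups, fit = fit,
         transform = attr(transformed, "transform"),
         removed = removed_species(filtered), comparison = comparison),
    class = "comparison_analysis"
  )
}

#' @export
print.comparison_analysis <- function(x, ...) {
  cat("Comparison analysis:", x$comparison$label, "\n")
  cat(sprintf("  transform: %s; %d species tested (%d removed), %d significant\n",
              x$transform, nrow(x$species), nrow(x$removed),
              sum(x$species$significant)))
  sig <- x$groups[x$groups$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("  significant groups:",
        paste(sprintf("%s (%s, PC = %.2g)", sig$group, sig$direction,
                      sig$pc_corrected), collapse = "; "), "\n")
  } else {
    cat("  no significant group changes\n")
  }
  invisible(x)
}
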