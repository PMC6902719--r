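#' Define a pairwise within-subject comparison
#'
#' A comparison contrasts two conditions of the same subjects in one arm
#' and tissue — e.g. pre- vs post-supplementation of unirradiated
#' epidermis, or unirradiated vs 24 h post-UVR skin. Conditions are named
#' lists over `phase` and/or `uvr_time`; side B minus side A is the
#' reported direction, with the subject as the pairing key.
#'
#' @param arm Study arm (e.g. `"EPA"`).
#' @param tissue Compartment (`"epidermis"`, `"dermis"`, `"plasma"`).
#' @param a,b Named lists selecting the two conditions, e.g.
#'   `list(phase = "pre", uvr_time = "unirradiated")`.
#' @param label Optional label used in printed output.
#' @return A `pairwise_comparison` object.
#' @export
pairwise_comparison <- function(arm, tissue,
                                a = list(phase = "pre"),
                                b = list(phase = "post"),
                                label = NULL) {
  allowed <- c("phase", "uvr_time")
  for (side in list(a, b)) {
    if (length(side) == 0 || !all(names(side) %in% allowed)) {
      abort("Conditions may only restrict `phase` and `uvr_time`.")
    }
  }
  if (identical(a[order(names(a))], b[order(names(b))])) {
    abort("The two conditions of a comparison must differ.")
  }
  fmt <- function(s) paste(unlist(s), collapse = "/")
  structure(
    list(arm = arm, tissue = tissue, a = a, b = b,
         label = label %||% paste0(arm, " ", tissue, ": ", fmt(a), " vs ", fmt(b))),
    class = "pairwise_comparison"
  )
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat("Pairwise comparison (paired by subject):", x$label, "\n")
  invisible(x)
}

match_condition <- function(data, cond, arm, tissue) {
  hit <- rep(TRUE, nrow(data))
  if (!is.null(arm) && "arm" %in% names(data)) hit <- hit & data$arm %in% arm
  if (!is.null(tissue) && "tissue" %in% names(data)) {
    hit <- hit & data$tissue %in% tissue
  }
  for (nm in names(cond)) {
    if (!nm %in% names(data)) {
      abort(paste0("Comparison conditions need column `", nm, "` in the data."))
    }
    hit <- hit & data[[nm]] %in% cond[[nm]]
  }
  hit
}

#' Select the samples a comparison uses
#'
#' @param data Concentration tibble with design columns.
#' @param comparison A [pairwise_comparison()].
#' @return The selected rows with an additional `.side` column
#'   (`"A"`/`"B"`).
#' @export
comparison_samples <- function(data, comparison) {
  stopifnot(inherits(comparison, "pairwise_comparison"))
  in_a <- match_condition(data, comparison$a, comparison$arm, comparison$tissue)
  in_b <- match_condition(data, comparison$b, comparison$arm, comparison$tissue)
  if (any(in_a & in_b)) {
    abort("Comparison conditions overlap: a sample matches both sides.")
  }
  if (!any(in_a) || !any(in_b)) {
    abort(paste0("Comparison selects no samples on side ",
                 if (!any(in_a)) "A" else "B", ": ", comparison$label))
  }
  out <- data[in_a | in_b, , drop = FALSE]
  out$.side <- ifelse(in_a[in_a | in_b], "A", "B")
  out
}

#' Per-subject paired differences on the transformed scale
#'
#' For every species, `difference = B - A` per subject. Because the
#' transformed scale is log2-like, these differences are per-subject log2
#' fold changes. Subjects present on only one side are excluded with a
#' warning.
#'
#' @param data Transformed concentration tibble (see [apply_glog()]).
#' @param comparison A [pairwise_comparison()].
#' @return Long tibble `(subject, species, difference)`.
#' @export
paired_differences <- function(data, comparison) {
  sel <- comparison_samples(data, comparison)
  sp <- species_cols(sel)
  ab <- split(sel, sel$.side)
  subj <- intersect(ab$A$subject, ab$B$subject)
  lost <- setdiff(union(ab$A$subject, ab$B$subject), subj)
  if (length(lost) > 0) {
    warn(paste0("Excluding subject(s) without both conditions: ",
                paste(lost, collapse = ", ")))
  }
  if (length(subj) == 0) abort("No subject has samples on both sides.")
  dup <- c(ab$A$subject[duplicated(ab$A$subject)],
           ab$B$subject[duplicated(ab$B$subject)])
  if (length(dup) > 0) {
    abort(paste0("Subject(s) contribute more than one sample per side: ",
                 paste(unique(dup), collapse = ", ")))
  }
  xa <- conc_matrix(ab$A[match(subj, ab$A$subject), , drop = FALSE], sp)
  xb <- conc_matrix(ab$B[match(subj, ab$B$subject), , drop = FALSE], sp)
  d <- xb - xa
  tibble::tibble(
    subject = rep(subj, times = length(sp)),
    species = rep(sp, each = length(subj)),
    difference = as.vector(d)
  )
}

#' Two-tailed paired Student's t test on a difference vector
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p value. Degenerate inputs follow fixed conventions: zero
#' variance with zero mean gives `p = 1` (no signal), zero variance with a
#' nonzero mean gives `p = 0` with a warning (infinite evidence under the
#' model).
#'
#' @param d Numeric vector of paired differences (`NA`s dropped).
#' @return One-row tibble `(n, estimate, t, df, p)`.
#' @export
paired_t_test <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) abort("Need at least 2 paired differences.")
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble::tibble(n = n, estimate = 0, t = 0, df = n - 1, p = 1))
    }
    warn("Zero variance with nonzero mean difference; p set to 0.")
    return(tibble::tibble(n = n, estimate = m, t = sign(m) * Inf,
                          df = n - 1, p = 0))
  }
  fit <- t.test(d, mu = 0, alternative = "two.sided")
  tibble::tibble(n = n, estimate = m, t = unname(fit$statistic),
                 df = unname(fit$parameter), p = fit$p.value)
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' Standard BH q values controlling the false discovery rate:
#' `q(i) = min over p(j) >= p(i) of p(j) * m / rank(j)`, capped at 1.
#' Invariant to the input order and monotone in p.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Vector of q values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Paired differential test of every species in a comparison
#'
#' Runs the per-species paired t tests on the transformed data of one
#' pairwise comparison, applies BH correction within the comparison's
#' species set, and reports the mean paired difference on the glog2 scale
#' as the log2 fold change (exact log2 FC in the high-intensity limit).
#' Species with fewer than two complete pairs are skipped and logged.
#'
#' @param data Transformed concentration tibble for the comparison's
#'   samples (see [apply_glog()]).
#' @param comparison A [pairwise_comparison()].
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @return A `species_test_result` tibble: `species`, `n`, `log2fc`, `t`,
#'   `p`, `q`, `significant`, in the input species order, with attributes
#'   `comparison`, `removed_species` (propagated from [filter_missing()])
#'   and `skipped_species`.
#' @export
diff_test <- function(data, comparison, alpha = 0.05) {
  diffs <- paired_differences(data, comparison)
  sp_order <- species_cols(data)
  by_species <- split(diffs$difference, factor(diffs$species, levels = sp_order))
  enough <- purrr::map_lgl(by_species, ~ sum(!is.na(.x)) >= 2)
  if (any(!enough)) {
    inform(paste0("Skipping species with fewer than 2 complete pairs: ",
                  paste(names(by_species)[!enough], collapse = ", ")))
  }
  res <- purrr::map_dfr(by_species[enough], paired_t_test, .id = "species")
  res$q <- bh_adjust(res$p)
  out <- tibble::tibble(
    species = res$species, n = res$n, log2fc = res$estimate,
    t = res$t, p = res$p, q = res$q, significant = res$q < alpha
  )
  class(out) <- c("species_test_result", class(out))
  attr(out, "comparison") <- comparison
  attr(out, "removed_species") <- removed_species(data)
  attr(out, "skipped_species") <- names(by_species)[!enough]
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.species_test_result <- function(x, ...) {
  cmp <- attr(x, "comparison")
  if (!is.null(cmp)) cat("Paired species tests -", cmp$label, "\n")
  cat(sprintf("%d species tested, %d significant at q < %g; %d removed, %d skipped\n",
              nrow(x), sum(x$significant), attr(x, "alpha") %||% 0.05,
              nrow(removed_species(x)), length(attr(x, "skipped_species"))))
  NextMethod()
}

#' @rdname diff_test
#' @param x A `species_test_result`.
#' @param ... Unused.
#' @export
tidy.species_test_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "species_test_result")
  for (nm in c("comparison", "removed_species", "skipped_species", "alpha")) {
    attr(out, nm) <- NULL
  }
  out
}

#' @rdname diff_test
#' @export
glance.species_test_result <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x),
    n_significant = sum(x$significant),
    n_removed = nrow(removed_species(x)),
    n_skipped = length(attr(x, "skipped_species")),
    alpha = attr(x, "alpha") %||% 0.05
  )
}
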