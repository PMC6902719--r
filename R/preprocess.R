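#' Concentration tables
#'
#' Throughout the package a concentration table is a tibble with one row
#' per sample: metadata columns (`sample_id`, `subject`, `arm`, `phase`,
#' `tissue`, `uvr_time` — whichever are present) followed by one numeric
#' column per species. `NA` means "not detected" (below the analytical
#' LOD); zeros in input files are treated the same way.
#'
#' @name concentration-table
#' @keywords internal
NULL

design_cols <- c("sample_id", "subject", "arm", "phase", "tissue", "uvr_time")

species_cols <- function(data, species = NULL) {
  sp <- setdiff(names(data), c(design_cols, ".side"))
  if (!is.null(species)) sp <- intersect(sp, species)
  if (length(sp) == 0) abort("No species columns found in `data`.")
  sp
}

conc_matrix <- function(data, species) {
  m <- as.matrix(data[species])
  storage.mode(m) <- "double"
  rownames(m) <- data$sample_id %||% as.character(seq_len(nrow(data)))
  m
}

#' Read a concentration CSV
#'
#' Expects sample metadata columns followed by species columns; blank cells
#' and zeros become `NA` (below LOD).
#'
#' @param path CSV path.
#' @param panel Optional panel; if given, species columns are checked
#'   against it.
#' @return A concentration tibble (see [species_cols] conventions).
#' @export
read_concentrations <- function(path, panel = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sp <- species_cols(data, panel$name)
  if (!is.null(panel)) {
    unknown <- setdiff(setdiff(names(data), design_cols), panel$name)
    if (length(unknown) > 0) {
      warn(paste0("Columns not in panel, ignored as species: ",
                  paste(unknown, collapse = ", ")))
    }
  }
  data[sp] <- purrr::map(data[sp], function(x) {
    x <- as.numeric(x)
    x[!is.na(x) & x <= 0] <- NA_real_
    x
  })
  data
}

#' Remove species missing in more than half of the samples
#'
#' For the samples at hand (a single pairwise comparison's samples —
#' filtering is per comparison, not global), a species whose missing count
#' strictly exceeds half the number of samples is dropped; a species
#' missing in exactly half is retained. Zeros count as missing. The removed
#' species are recorded in the `"removed_species"` attribute (a tibble with
#' the missing counts) and reported via a message.
#'
#' @param data Concentration tibble, already restricted to the comparison's
#'   samples.
#' @param species Optional subset of species columns to consider.
#' @return The tibble without the dropped species columns.
#' @export
filter_missing <- function(data, species = NULL) {
  if (nrow(data) == 0) abort("No samples selected; cannot filter species.")
  sp <- species_cols(data, species)
  x <- conc_matrix(data, sp)
  x[!is.na(x) & x <= 0] <- NA_real_
  n_missing <- colSums(is.na(x))
  drop <- n_missing > nrow(x) / 2
  removed <- tibble::tibble(species = sp[drop],
                            n_missing = unname(n_missing[drop]),
                            n_samples = nrow(x))
  if (any(drop)) {
    inform(paste0("Removed ", sum(drop), " species missing in more than half of ",
                  nrow(x), " samples: ", paste(sp[drop], collapse = ", ")))
  }
  out <- dplyr::select(data, -dplyr::all_of(sp[drop]))
  out[sp[!drop]] <- tibble::as_tibble(x[, !drop, drop = FALSE])
  attr(out, "removed_species") <- removed
  out
}

#' Removal log of a filtered table
#'
#' @param data A tibble returned by [filter_missing()].
#' @return Tibble of removed species with missing counts.
#' @export
removed_species <- function(data) {
  attr(data, "removed_species") %||%
    tibble::tibble(species = character(), n_missing = integer(),
                   n_samples = integer())
}

#' Substitute remaining missing values with the limit of detection
#'
#' After [filter_missing()], every surviving species is missing in at most
#' half of the samples; each remaining missing cell is replaced by that
#' species' analytical LOD. Observed values are never altered.
#'
#' @param data Concentration tibble (post-filter).
#' @param lod Named numeric vector of per-species LODs, or a tibble with
#'   columns `species` and `lod`.
#' @return A complete concentration tibble.
#' @export
substitute_lod <- function(data, lod) {
  if (is.data.frame(lod)) lod <- setNames(lod$lod, lod$species)
  sp <- species_cols(data)
  x <- conc_matrix(data, sp)
  all_missing <- colSums(is.na(x)) == nrow(x)
  if (any(all_missing)) {
    abort(paste0("Species missing in all samples should have been filtered: ",
                 paste(sp[all_missing], collapse = ", ")))
  }
  has_na <- sp[colSums(is.na(x)) > 0]
  no_lod <- has_na[!(has_na %in% names(lod)) |
                     !is.finite(lod[has_na]) | lod[has_na] <= 0]
  if (length(no_lod) > 0) {
    abort(paste0("Missing values but no positive LOD for: ",
                 paste(no_lod, collapse = ", ")))
  }
  for (s in has_na) {
    x[is.na(x[, s]), s] <- lod[[s]]
  }
  data[sp] <- tibble::as_tibble(x)
  attr(data, "removed_species") <- attr(data, "removed_species")
  data
}

# Negative trimmed profile log-likelihood of the per-sample affine arsinh
# calibration, plus its analytic gradient. theta = (a_1..a_S, log b_1..log b_S).
# When every kept cell sits in the logarithmic regime of arsinh, a common
# shift of all log b_s is an exact flat direction (it moves every
# transformed value by the same constant, which the species means absorb);
# a weak quadratic anchor on mean(log b) pins that gauge so the optimum is
# unique. The anchor does not affect any identified direction and cancels
# from every downstream statistic.
glog_nll <- function(theta, x, keep, anchor = 0, lambda = 0.1) {
  S <- nrow(x)
  a <- theta[seq_len(S)]
  b <- exp(theta[S + seq_len(S)])
  w <- a + x * b
  h <- asinh(w)
  hk <- h[, keep, drop = FALSE]
  r <- hk - rep(colMeans(hk), each = S)
  rss <- sum(r * r)
  n_tot <- length(hk)
  jac <- sum(log(b)) * sum(keep) - 0.5 * sum(log1p(w[, keep, drop = FALSE]^2))
  n_tot / 2 * log(rss) - jac +
    lambda * (mean(theta[S + seq_len(S)]) - anchor)^2
}

glog_grad <- function(theta, x, keep, anchor = 0, lambda = 0.1) {
  S <- nrow(x)
  a <- theta[seq_len(S)]
  b <- exp(theta[S + seq_len(S)])
  w <- a + x * b
  h <- asinh(w)
  hk <- h[, keep, drop = FALSE]
  r <- hk - rep(colMeans(hk), each = S)
  rss <- sum(r * r)
  n_tot <- length(hk)
  wk <- w[, keep, drop = FALSE]
  xbk <- (x * b)[, keep, drop = FALSE]
  invs <- 1 / sqrt(1 + wk^2)
  common <- (n_tot / rss) * r * invs
  ga <- rowSums(common) + rowSums(wk / (1 + wk^2))
  gb <- rowSums(common * xbk) - rowSums(1 - wk * xbk / (1 + wk^2)) +
    2 * lambda * (mean(theta[S + seq_len(S)]) - anchor) / S
  c(ga, gb)
}

#' Fit a glog (arsinh) variance-stabilizing normalization
#'
#' Calibrates, per sample, an affine-arsinh transform
#' \deqn{h_s(x) = \operatorname{arsinh}(a_s + b_s x) / \ln 2}
#' so that transformed values are, per species, homoscedastic around a
#' species mean. Under the additive-plus-multiplicative error model this
#' transform stabilizes the variance and approaches `log2` (up to an
#' offset) at high intensity. Parameters are estimated by profile maximum
#' likelihood with least-trimmed-squares robustness: the fit iterates
#' between parameter optimization (BFGS with analytic gradients) and
#' re-selecting the `1 - trim` fraction of species with the smallest
#' residual sums of squares, until the parameter change drops below `tol`
#' or `maxit` iterations are reached.
#'
#' @param data A complete concentration tibble (after [substitute_lod()]);
#'   at least 2 samples and 2 species.
#' @param species Optional subset of species columns.
#' @param trim Fraction of species excluded from the likelihood as
#'   potential outliers (default 0.1, i.e. a 90% least-trimmed fit).
#' @param tol Convergence tolerance on the maximum absolute parameter
#'   change (default 1e-8).
#' @param maxit Maximum number of trimming iterations (default 100).
#' @return A `glog_fit` object: per-sample offsets `a` and scales `b`
#'   (named by `sample_id`), per-species transformed means `mu`, residual
#'   spread `sigma`, `converged` flag, `iterations`, and the trimmed
#'   species set.
#' @seealso [apply_glog()], [glog_inverse()], [tidy.glog_fit()]
#' @export
fit_glog <- function(data, species = NULL, trim = 0.1, tol = 1e-8,
                     maxit = 100) {
  sp <- species_cols(data, species)
  x <- conc_matrix(data, sp)
  if (anyNA(x)) abort("`data` must be complete; run substitute_lod() first.")
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort("Need at least 2 samples and 2 species to fit the normalization.")
  }
  S <- nrow(x); P <- ncol(x)
  n_keep <- max(2L, ceiling((1 - trim) * P))

  scale0 <- pmax(apply(x, 1, median), .Machine$double.eps)
  theta <- c(rep(0, S), -log(scale0))
  keep <- rep(TRUE, P)
  converged <- FALSE
  it <- 0L
  # offsets are constrained non-negative: concentrations are non-negative,
  # so the calibration must stay on the non-saturating arsinh branch
  # (otherwise the trimmed likelihood is unbounded along a -> -Inf).
  lower <- c(rep(0, S), rep(-Inf, S))
  anchor <- mean(-log(scale0))
  # warm start: one coarse pass before the trimmed iterations
  warm <- optim(theta, glog_nll, glog_grad, x = x, keep = keep,
                anchor = anchor, method = "L-BFGS-B", lower = lower,
                control = list(maxit = 300))
  theta <- warm$par
  while (it < maxit) {
    it <- it + 1L
    f_old <- glog_nll(theta, x, keep, anchor)
    opt <- optim(theta, glog_nll, glog_grad, x = x, keep = keep,
                 anchor = anchor, method = "L-BFGS-B", lower = lower,
                 control = list(maxit = 500, factr = 10))
    # monotone acceptance: reject moves that do not improve the objective
    # beyond numerical noise, so a converged fit has zero parameter change
    if (opt$value < f_old - max(1e-10, abs(f_old) * 1e-12)) {
      delta <- max(abs(opt$par - theta))
      theta <- opt$par
    } else {
      delta <- 0
    }
    # re-select the trimmed species set under the new calibration
    a <- theta[seq_len(S)]; b <- exp(theta[S + seq_len(S)])
    h <- asinh(a + x * b)
    r2 <- colSums((h - rep(colMeans(h), each = S))^2)
    keep_new <- rank(r2, ties.method = "first") <= n_keep
    if (delta < tol && identical(keep_new, keep)) {
      converged <- TRUE
      break
    }
    keep <- keep_new
  }

  a <- theta[seq_len(S)]
  b <- exp(theta[S + seq_len(S)])
  h <- asinh(a + x * b) / log(2)
  mu <- colMeans(h)
  resid <- h - rep(mu, each = S)
  sample_ids <- rownames(x)
  structure(
    list(a = setNames(a, sample_ids), b = setNames(b, sample_ids),
         mu = setNames(mu, sp), sigma = sd(as.vector(resid[, keep])),
         species = sp, trimmed = sp[!keep], trim = trim,
         converged = converged, iterations = it),
    class = "glog_fit"
  )
}

#' @export
print.glog_fit <- function(x, ...) {
  cat("glog variance-stabilizing calibration\n")
  cat(sprintf("  %d samples, %d species (%d trimmed), sigma = %.4g\n",
              length(x$a), length(x$species), length(x$trimmed), x$sigma))
  cat(sprintf("  %s after %d iteration(s)\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Apply a fitted glog transform
#'
#' Transforms each sample with its calibrated `arsinh(a + b x)/ln 2`; the
#' result is on a log2-like scale (doubling an abundant species raises its
#' value by about 1) and strictly increasing in concentration for every
#' sample.
#'
#' @param data Complete concentration tibble whose samples and species
#'   match the fit.
#' @param fit A [fit_glog()] result.
#' @return The tibble with species columns transformed.
#' @export
apply_glog <- function(data, fit) {
  stopifnot(inherits(fit, "glog_fit"))
  sp <- species_cols(data, fit$species)
  if (!setequal(sp, fit$species)) {
    abort("Species columns do not match the fitted normalization.")
  }
  sp <- fit$species
  x <- conc_matrix(data, sp)
  ids <- rownames(x)
  if (!setequal(ids, names(fit$a))) {
    abort("Samples do not match the fitted normalization.")
  }
  a <- fit$a[ids]; b <- fit$b[ids]
  h <- asinh(a + x * b) / log(2)
  data[sp] <- tibble::as_tibble(h)
  attr(data, "removed_species") <- attr(data, "removed_species")
  attr(data, "transform") <- "glog"
  data
}

#' Invert a glog transform
#'
#' @param h Transformed values (log2-like scale).
#' @param a,b Offset and scale of the sample's calibration.
#' @return Concentrations `x` with `asinh(a + b x)/ln 2 = h`.
#' @export
glog_inverse <- function(h, a, b) {
  (sinh(h * log(2)) - a) / b
}

#' Fallback log transform with half-LOD offset
#'
#' Deterministic, strictly monotone per-species transform
#' `log2(x + lod/2)` used when the glog calibration fails to converge.
#'
#' @param data Complete concentration tibble.
#' @param lod Named LOD vector or `(species, lod)` tibble.
#' @return Transformed tibble, `transform` attribute `"log2_half_lod"`.
#' @export
log_lod_transform <- function(data, lod) {
  if (is.data.frame(lod)) lod <- setNames(lod$lod, lod$species)
  sp <- species_cols(data)
  missing_lod <- sp[!sp %in% names(lod)]
  if (length(missing_lod) > 0) {
    abort(paste0("No LOD for: ", paste(missing_lod, collapse = ", ")))
  }
  x <- conc_matrix(data, sp)
  h <- log2(x + rep(pmax(lod[sp], .Machine$double.eps) / 2, each = nrow(x)))
  data[sp] <- tibble::as_tibble(h)
  attr(data, "transform") <- "log2_half_lod"
  data
}
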