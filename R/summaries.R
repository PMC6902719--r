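#' Omega-3 index of erythrocyte fatty-acid profiles
#'
#' The n-3 index is the sum of the EPA (20:5n-3) and DHA (22:6n-3) weight
#' percentages of total RBC fatty acids, a standard biomarker of long-chain
#' omega-3 status and supplement compliance. It is linear in the two
#' entries and ignores every other fatty acid.
#'
#' @param profiles Long tibble `(subject, phase, fatty_acid, pct)` as
#'   produced by [generate_rbc_profiles()], or any tibble with those
#'   columns.
#' @return Tibble `(subject, phase, n3_index)` in percent.
#' @export
n3_index <- function(profiles) {
  needed <- c("20:5n-3", "22:6n-3")
  absent <- setdiff(needed, unique(profiles$fatty_acid))
  if (length(absent) > 0) {
    abort(paste0("Profiles lack required fatty acid(s): ",
                 paste(absent, collapse = ", ")))
  }
  profiles |>
    dplyr::filter(.data$fatty_acid %in% needed) |>
    dplyr::summarise(n3_index = sum(.data$pct),
                     n_fa = dplyr::n(),
                     .by = c("subject", "phase")) |>
    (\(d) {
      if (any(d$n_fa != 2)) {
        abort("Each subject/phase needs exactly one 20:5n-3 and one 22:6n-3 entry.")
      }
      dplyr::select(d, -"n_fa")
    })()
}

#' Paired pre/post tests of each fatty acid
#'
#' One two-tailed paired Student's t test per fatty acid on the per-subject
#' post minus pre weight-% differences. No multiplicity correction is
#' applied (each fatty acid is reported at its raw p, mirroring standard
#' compliance reporting). Unpaired subjects are excluded with a warning.
#'
#' @param profiles Long tibble `(subject, phase, fatty_acid, pct)` with
#'   phases `"pre"` and `"post"`.
#' @return Tibble `(fatty_acid, n, mean_pre, mean_post, t, p)`.
#' @export
fatty_acid_paired_tests <- function(profiles) {
  wide <- tidyr::pivot_wider(profiles, names_from = "phase",
                             values_from = "pct")
  if (!all(c("pre", "post") %in% names(wide))) {
    abort("Profiles must contain both `pre` and `post` phases.")
  }
  unpaired <- unique(wide$subject[is.na(wide$pre) | is.na(wide$post)])
  if (length(unpaired) > 0) {
    warn(paste0("Excluding unpaired subject(s): ",
                paste(unpaired, collapse = ", ")))
    wide <- wide[!wide$subject %in% unpaired, , drop = FALSE]
  }
  wide |>
    dplyr::summarise(
      res = list(paired_t_test(.data$post - .data$pre)),
      mean_pre = mean(.data$pre), mean_post = mean(.data$post),
      .by = "fatty_acid"
    ) |>
    tidyr::unnest("res") |>
    dplyr::select("fatty_acid", "n", "mean_pre", "mean_post", "t", "p")
}

#' Per-sample totals of a precursor's metabolites
#'
#' Sums, within each sample, the raw concentrations of every panel species
#' derived from the given precursor PUFA (e.g. all EPA-derived mediators).
#' Totals are computed on the concentration scale in the tissue's unit,
#' not on the transformed scale; after [substitute_lod()], censored cells
#' contribute the LOD.
#'
#' @param data Concentration tibble (raw scale, ideally complete).
#' @param panel Panel tibble.
#' @param precursor One of [mediator_precursors()].
#' @return The design columns of `data` plus `precursor` and `total`.
#' @export
precursor_totals <- function(data, panel, precursor) {
  validate_panel(panel)
  precursor <- match.arg(precursor, mediator_precursors())
  sp <- intersect(species_cols(data), panel$name[panel$precursor == precursor])
  if (length(sp) == 0) {
    abort(paste0("No ", precursor, "-derived species present in `data`."))
  }
  x <- conc_matrix(data, sp)
  meta <- dplyr::select(data, dplyr::any_of(design_cols))
  dplyr::bind_cols(meta, tibble::tibble(precursor = precursor,
                                        total = unname(rowSums(x, na.rm = TRUE))))
}

#' Percent change of mean totals
#'
#' `100 * (mean(post) - mean(pre)) / mean(pre)`, on the raw concentration
#' scale. Scale-invariant: multiplying every concentration by the same
#' positive constant leaves it unchanged.
#'
#' @param pre_totals,post_totals Numeric vectors of per-subject totals.
#' @return Percent change (a single number; 108 means +108%).
#' @export
percent_change <- function(pre_totals, post_totals) {
  m_pre <- mean(pre_totals)
  if (!is.finite(m_pre) || m_pre <= 0) {
    abort("Mean pre-total must be positive to express a percent change.")
  }
  100 * (mean(post_totals) - m_pre) / m_pre
}

#' Supplementation effect on a precursor's metabolite pool
#'
#' Combines [precursor_totals()], [percent_change()] and a paired t test:
#' per-subject pre and post totals of the precursor's metabolites in one
#' arm and tissue, the mean percent change on the raw scale, and a paired
#' two-tailed t test on the log-transformed totals (totals are strictly
#' positive sums, tested on the log scale like all concentration data).
#'
#' @param data Complete concentration tibble (raw scale) containing both
#'   phases of one tissue.
#' @param panel Panel tibble.
#' @param precursor One of [mediator_precursors()].
#' @param comparison A [pairwise_comparison()] (typically pre vs post).
#' @return One-row tibble `(arm, tissue, precursor, n, mean_pre, mean_post,
#'   percent_change, t, p)`.
#' @export
precursor_change <- function(data, panel, precursor, comparison) {
  totals <- precursor_totals(data, panel, precursor)
  sel <- comparison_samples(totals, comparison)
  wide <- tidyr::pivot_wider(
    dplyr::select(sel, "subject", ".side", "total"),
    names_from = ".side", values_from = "total"
  )
  wide <- wide[!is.na(wide$A) & !is.na(wide$B), , drop = FALSE]
  if (nrow(wide) < 2) abort("Fewer than 2 paired totals.")
  tt <- paired_t_test(log(wide$B) - log(wide$A))
  tibble::tibble(
    arm = comparison$arm, tissue = comparison$tissue, precursor = precursor,
    n = nrow(wide), mean_pre = mean(wide$A), mean_post = mean(wide$B),
    percent_change = percent_change(wide$A, wide$B), t = tt$t, p = tt$p
  )
}

# all permutations of 1..n as an (n!) x n matrix, lexicographic
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

spearman_rho <- function(rx, ry) {
  suppressWarnings(cor(rx, ry))
}

#' Spearman correlation screen between skin and plasma mediators
#'
#' For every species measured in both compartments, pairs the skin and
#' plasma concentrations of the same subject and phase and computes the
#' Spearman rank correlation. For n <= 9 pairs the two-sided p value is
#' exact, from the full permutation distribution of the rank vectors
#' (which remains valid under ties); for larger n the large-sample t
#' approximation is used. Species with a constant vector in either
#' compartment have an undefined rho and are reported as missing with a
#' note.
#'
#' @param skin,plasma Concentration tibbles with `subject` and `phase`
#'   columns (raw scale).
#' @param pairing Metadata columns used to pair observations (default
#'   subject and phase).
#' @param min_pairs Minimum complete pairs per species (default 3).
#' @return Tibble `(species, n, rho, p, note)`.
#' @export
spearman_cross_compartment <- function(skin, plasma,
                                       pairing = c("subject", "phase"),
                                       min_pairs = 3) {
  if (!all(pairing %in% names(skin)) || !all(pairing %in% names(plasma))) {
    abort(paste0("Both tables need the pairing column(s): ",
                 paste(pairing, collapse = ", ")))
  }
  shared <- intersect(species_cols(skin), species_cols(plasma))
  if (length(shared) == 0) {
    abort("No species measured in both compartments.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(skin, dplyr::all_of(c(pairing, shared))),
    dplyr::select(plasma, dplyr::all_of(c(pairing, shared))),
    by = pairing, suffix = c("_skin", "_plasma")
  )
  purrr::map_dfr(shared, function(s) {
    x <- joined[[paste0(s, "_skin")]]
    y <- joined[[paste0(s, "_plasma")]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs) {
      return(tibble::tibble(species = s, n = n, rho = NA_real_, p = NA_real_,
                            note = "too few pairs"))
    }
    res <- spearman_test(x[ok], y[ok])
    tibble::tibble(species = s, n = n, rho = res$rho, p = res$p,
                   note = res$note)
  })
}

#' Spearman rank correlation with exact small-sample p value
#'
#' @param x,y Paired numeric vectors (no missing values).
#' @param exact_n_max Largest n for which the exact permutation p is
#'   computed (default 9).
#' @return List with `rho`, `p`, `note`.
#' @export
spearman_test <- function(x, y, exact_n_max = 9) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, note = "constant vector"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- spearman_rho(rx, ry)
  if (n <= exact_n_max) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(pp) spearman_rho(rx, ry[pp]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, note = "exact permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- min(1, 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE))
    list(rho = rho, p = p, note = "t approximation")
  }
}
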