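#' Study configuration for the synthetic-data generator
#'
#' Encodes the paired supplementation-study design the generator emulates:
#' two independent arms (EPA, n = 12; DHA, n = 9), up to three compartments
#' (epidermis, dermis in pg/mg protein; plasma in pg/ml), UVR challenge
#' timepoints, and pre/post-supplementation sampling for every subject so
#' the design is fully paired.
#'
#' Concentrations follow an additive-plus-multiplicative error model on top
#' of a species- and tissue-specific baseline median `m`:
#' \deqn{x = m \exp(u) \cdot f \cdot \exp(\epsilon) + \delta}
#' with `u` a between-subject log-scale effect (SD `subject_sd`, constant
#' across phases and timepoints so paired contrasts cancel it), `f` the
#' product of any applicable effect multipliers, `\epsilon` log-scale
#' measurement noise (SD `mult_noise_sd`) and `\delta` additive noise in
#' concentration units (SD `add_noise_sd`). Values are truncated at zero
#' and left-censored at the species LOD: anything below the LOD is recorded
#' as missing. The LOD is placed at the `lod_quantile` quantile of each
#' species' baseline log-normal distribution, so `lod_quantile` is
#' (approximately) the per-species missingness fraction.
#'
#' @param n_subjects Named integer vector of subjects per arm.
#' @param tissues Compartments to simulate.
#' @param uvr_timepoints UVR challenge timepoints to simulate.
#' @param baseline_medians Optional tibble `(species, tissue, median)`;
#'   defaults to [default_baseline_medians()] of the panel in use.
#' @param subject_sd Between-subject log-scale SD (default 0.5, i.e. about
#'   a 65% coefficient of variation between volunteers).
#' @param mult_noise_sd Log-scale measurement SD (default 0.25, about a 29%
#'   analytical CV).
#' @param add_noise_sd Additive noise SD in concentration units (default 1;
#'   negligible for abundant species, dominant near the LOD, which is what
#'   makes the glog transform non-trivial).
#' @param lod_quantile Fraction of the baseline distribution censored
#'   (default 0.1). `0` disables censoring.
#' @param seed Integer seed; identical seed and configuration give a
#'   bit-identical dataset.
#' @return A `study_config` list.
#' @seealso [generate_study()], [effect_spec()]
#' @export
study_config <- function(n_subjects = c(EPA = 12, DHA = 9),
                         tissues = c("epidermis", "dermis", "plasma"),
                         uvr_timepoints = c("unirradiated", "24h", "72h"),
                         baseline_medians = NULL,
                         subject_sd = 0.5,
                         mult_noise_sd = 0.25,
                         add_noise_sd = 1,
                         lod_quantile = 0.1,
                         seed = 1L) {
  if (is.null(names(n_subjects)) || any(names(n_subjects) == "")) {
    abort("`n_subjects` must be a named vector, e.g. c(EPA = 12, DHA = 9).")
  }
  if (any(n_subjects < 1)) abort("Each arm needs at least one subject.")
  tissues <- match.arg(tissues, several.ok = TRUE)
  uvr_timepoints <- match.arg(uvr_timepoints, several.ok = TRUE)
  for (nm in c("subject_sd", "mult_noise_sd", "add_noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      abort(paste0("`", nm, "` must be a single non-negative number."))
    }
  }
  if (!is.numeric(lod_quantile) || lod_quantile < 0 || lod_quantile >= 1) {
    abort("`lod_quantile` must lie in [0, 1).")
  }
  structure(
    list(n_subjects = n_subjects, tissues = tissues,
         uvr_timepoints = uvr_timepoints, baseline_medians = baseline_medians,
         subject_sd = subject_sd, mult_noise_sd = mult_noise_sd,
         add_noise_sd = add_noise_sd, lod_quantile = lod_quantile,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Default baseline median concentrations
#'
#' Plausible species/tissue medians assembled from class-level rules:
#' epidermal 12-HETE, 2-AG and 13-HODE are the dominant skin species; total
#' epidermal EPA-derived mediator mass is roughly an order of magnitude
#' below the DHA-derived mass (about 320 vs 3100 pg/mg protein); dermis
#' runs at a quarter of epidermal levels; in plasma the CYP450 epoxides and
#' diols are among the most abundant species, PEA is the dominant NAE and
#' 2-AG is a minor species below AEA. These are simulation anchors, not
#' measured values.
#'
#' @param panel A panel tibble.
#' @return A tibble `(species, tissue, median)` in the tissue's unit
#'   (pg/mg protein for epidermis/dermis, pg/ml for plasma).
#' @export
default_baseline_medians <- function(panel) {
  validate_panel(panel)
  epi <- dplyr::case_when(
    panel$name == "12-HETE" ~ 2000,
    panel$name == "13-HODE" ~ 1500,
    panel$name == "9-HODE" ~ 800,
    panel$name == "2-AG" ~ 3000,
    panel$name == "AEA" ~ 30,
    panel$name == "OEA" ~ 800,
    panel$name == "PEA" ~ 600,
    panel$name == "EPEA" ~ 30,
    panel$name == "DHEA" ~ 300,
    panel$name == "PGE2" ~ 150,
    panel$name == "PGD2" ~ 120,
    panel$name == "TXB2" ~ 80,
    panel$name == "LTB4" ~ 20,
    panel$name == "t-EKODE" ~ 100,
    panel$precursor == "AA" & panel$pathway == "COX" ~ 40,
    panel$precursor == "AA" & panel$pathway %in% hydroxy_pathways ~ 80,
    panel$precursor == "EPA" & panel$pathway %in% hydroxy_pathways ~ 30,
    panel$precursor == "EPA" & panel$pathway == "COX" ~ 5,
    panel$precursor == "DHA" & panel$pathway %in% hydroxy_pathways ~ 250,
    panel$precursor %in% c("LA", "ALA", "DGLA") &
      panel$pathway %in% hydroxy_pathways ~ 60,
    panel$pathway == "CYP450-epoxide" & panel$precursor == "LA" ~ 300,
    panel$pathway == "CYP450-epoxide" & panel$precursor == "AA" ~ 60,
    panel$pathway == "CYP450-epoxide" & panel$precursor == "DHA" ~ 40,
    panel$pathway == "CYP450-epoxide" ~ 20,
    panel$pathway == "CYP450-diol" & panel$precursor == "LA" ~ 200,
    panel$pathway == "CYP450-diol" & panel$precursor == "AA" ~ 40,
    panel$pathway == "CYP450-diol" & panel$precursor == "DHA" ~ 30,
    panel$pathway == "CYP450-diol" ~ 15,
    panel$pathway == "NAE" ~ 80,
    .default = 20
  )
  plasma <- dplyr::case_when(
    panel$name == "2-AG" ~ 20,
    panel$name == "AEA" ~ 50,
    panel$name == "PEA" ~ 1500,
    panel$name == "OEA" ~ 500,
    panel$name == "12-HETE" ~ 300,
    panel$pathway %in% c("CYP450-epoxide", "CYP450-diol") ~ epi * 4,
    panel$precursor == "AA" & panel$pathway %in% hydroxy_pathways ~ 100,
    panel$precursor == "DHA" & panel$pathway %in% hydroxy_pathways ~ 100,
    panel$precursor == "EPA" & panel$pathway %in% hydroxy_pathways ~ 20,
    .default = epi
  )
  dplyr::bind_rows(
    tibble::tibble(species = panel$name, tissue = "epidermis", median = epi,
                   measured = panel$skin),
    tibble::tibble(species = panel$name, tissue = "dermis", median = epi / 4,
                   measured = panel$skin),
    tibble::tibble(species = panel$name, tissue = "plasma", median = plasma,
                   measured = panel$plasma)
  ) |>
    dplyr::filter(.data$measured) |>
    dplyr::select(-"measured")
}

#' Specify a simulation ground-truth effect
#'
#' A multiplicative fold-effect applied to a species or to every member of
#' a named group, restricted to an arm, tissue, phase and/or UVR timepoint.
#' `NULL` restrictions mean "all". A list of these is the generator's truth,
#' e.g. EPA supplementation doubling the HEPEs post-supplementation.
#'
#' @param target A group label (resolved against the scheme) or species name.
#' @param multiplier Positive fold-effect.
#' @param arm,tissue,phase,uvr_time Optional restrictions.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(target, multiplier, arm = NULL, tissue = NULL,
                        phase = "post", uvr_time = NULL) {
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0) {
    abort("`multiplier` must be a single positive number.")
  }
  structure(list(target = target, multiplier = multiplier, arm = arm,
                 tissue = tissue, phase = phase, uvr_time = uvr_time),
            class = "effect_spec")
}

resolve_effect_targets <- function(effects, panel, scheme) {
  purrr::map(effects, function(e) {
    if (!inherits(e, "effect_spec")) abort("Effects must be `effect_spec` objects.")
    members <- if (e$target %in% names(scheme)) {
      scheme[[e$target]]
    } else if (e$target %in% panel$name) {
      e$target
    } else {
      abort(paste0("Effect target not resolvable against panel or scheme: ",
                   e$target))
    }
    e$species <- members
    e
  })
}

#' Example supplementation ground truth
#'
#' The canonical effect set used throughout the package's simulations: in
#' the EPA arm the HEPE group doubles and the HETE group falls to 0.7-fold
#' post-supplementation; in the DHA arm the HDHA group rises 1.5-fold.
#'
#' @param tissue Tissues the effects act in (default epidermis and plasma).
#' @return A list of [effect_spec()] objects.
#' @export
example_supplement_effects <- function(tissue = c("epidermis", "plasma")) {
  list(
    effect_spec("HEPEs", 2.0, arm = "EPA", tissue = tissue, phase = "post"),
    effect_spec("HETEs", 0.7, arm = "EPA", tissue = tissue, phase = "post"),
    effect_spec("HDHAs", 1.5, arm = "DHA", tissue = tissue, phase = "post")
  )
}

#' Generate a fully paired synthetic study dataset
#'
#' Draws one dataset under the design and noise model described in
#' [study_config()]. Every subject contributes a pre- and a
#' post-supplementation sample for every tissue and UVR timepoint, so all
#' pairwise contrasts the pipeline tests are available. The effect list is
#' the dataset's ground truth and is returned with it.
#'
#' @param config A [study_config()].
#' @param effects List of [effect_spec()] ground-truth effects.
#' @param panel,scheme Panel and group scheme the dataset is generated for.
#' @return A `study_dataset`: list with `design` (tibble: sample_id,
#'   subject, arm, phase, tissue, uvr_time), `concentrations` (named list,
#'   one samples-by-species tibble per tissue, design columns included,
#'   `NA` = below LOD), `lod` (tibble: tissue, species, lod), plus the
#'   `panel`, `scheme`, `truth` and `config` used.
#' @export
generate_study <- function(config = study_config(), effects = list(),
                           panel = default_panel(),
                           scheme = default_group_scheme(panel)) {
  stopifnot(inherits(config, "study_config"))
  validate_panel(panel)
  validate_scheme(scheme, panel)
  effects <- resolve_effect_targets(effects, panel, scheme)

  medians <- config$baseline_medians %||% default_baseline_medians(panel)
  if (!all(c("species", "tissue", "median") %in% names(medians))) {
    abort("`baseline_medians` needs columns species, tissue, median.")
  }
  if (any(medians$median <= 0)) abort("Baseline medians must be positive.")

  arms <- names(config$n_subjects)
  subjects <- unlist(purrr::map(arms, function(a) {
    sprintf("%s%02d", a, seq_len(config$n_subjects[[a]]))
  }))
  arm_of <- setNames(rep(arms, config$n_subjects), subjects)

  design <- tidyr::expand_grid(
    subject = subjects,
    phase = c("pre", "post"),
    tissue = config$tissues,
    uvr_time = config$uvr_timepoints
  ) |>
    dplyr::mutate(
      arm = unname(arm_of[.data$subject]),
      sample_id = paste(.data$subject, .data$phase, .data$tissue,
                        .data$uvr_time, sep = "_")
    ) |>
    dplyr::select("sample_id", "subject", "arm", "phase", "tissue", "uvr_time")

  total_sd <- sqrt(config$subject_sd^2 + config$mult_noise_sd^2)
  lod_tbl <- medians |>
    dplyr::mutate(lod = if (config$lod_quantile > 0) {
      .data$median * exp(qnorm(config$lod_quantile) * total_sd)
    } else 0) |>
    dplyr::select("tissue", "species", "lod")

  out <- withr::with_seed(config$seed, {
    purrr::map(setNames(config$tissues, config$tissues), function(tis) {
      spp <- if (tis == "plasma") panel$name[panel$plasma] else panel$name[panel$skin]
      med_tbl <- dplyr::filter(medians, .data$tissue == tis)
      med <- setNames(med_tbl$median, med_tbl$species)[spp]
      if (anyNA(med)) {
        abort(paste0("No baseline median for: ",
                     paste(spp[is.na(med)], collapse = ", "), " in ", tis))
      }
      lodv <- dplyr::filter(lod_tbl, .data$tissue == tis)
      lodv <- setNames(lodv$lod, lodv$species)[spp]

      des <- dplyr::filter(design, .data$tissue == tis)
      ns <- length(subjects); np <- length(spp); nr <- nrow(des)

      # between-subject effect, constant across phase and uvr_time
      u <- matrix(rnorm(ns * np, 0, config$subject_sd), ns, np,
                  dimnames = list(subjects, spp))
      fold <- matrix(1, nr, np, dimnames = list(des$sample_id, spp))
      for (e in effects) {
        hit <- rep(TRUE, nr)
        if (!is.null(e$arm)) hit <- hit & des$arm %in% e$arm
        if (!is.null(e$tissue)) hit <- hit & tis %in% e$tissue
        if (!is.null(e$phase)) hit <- hit & des$phase %in% e$phase
        if (!is.null(e$uvr_time)) hit <- hit & des$uvr_time %in% e$uvr_time
        cols <- intersect(e$species, spp)
        if (any(hit) && length(cols) > 0) {
          fold[hit, cols] <- fold[hit, cols] * e$multiplier
        }
      }
      emult <- matrix(rnorm(nr * np, 0, config$mult_noise_sd), nr, np)
      eadd <- matrix(rnorm(nr * np, 0, config$add_noise_sd), nr, np)
      x <- rep(med, each = nr) * exp(u[des$subject, , drop = FALSE]) *
        fold * exp(emult) + eadd
      x <- pmax(x, 0)
      x[x < rep(lodv, each = nr)] <- NA_real_
      dplyr::bind_cols(des, tibble::as_tibble(x))
    })
  })

  structure(
    list(design = design, concentrations = out, lod = lod_tbl, panel = panel,
         scheme = scheme,
         truth = purrr::map_dfr(effects, function(e) tibble::tibble(
           target = e$target, multiplier = e$multiplier,
           arm = e$arm %||% NA_character_,
           tissue = paste(e$tissue %||% "all", collapse = "+"),
           phase = paste(e$phase %||% "all", collapse = "+"),
           uvr_time = paste(e$uvr_time %||% "all", collapse = "+")
         )),
         config = config),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Synthetic paired lipid-mediator study\n")
  cat("  arms:    ", paste(sprintf("%s (n=%d)", names(x$config$n_subjects),
                                   x$config$n_subjects), collapse = ", "), "\n")
  cat("  tissues: ", paste(names(x$concentrations), collapse = ", "), "\n")
  cat("  species: ", paste(purrr::map_int(x$concentrations,
                                          ~ sum(names(.x) %in% x$panel$name)),
                           collapse = "/"), "\n")
  cat("  samples: ", nrow(x$design), "; effects:", nrow(x$truth), "\n")
  invisible(x)
}

#' Default erythrocyte fatty-acid composition template
#'
#' Mean pre-supplementation RBC fatty-acid weight percentages and the
#' post-supplementation shifts for each arm. The EPA arm template moves the
#' omega-3 index (EPA% + DHA%) from 4.86 to 7.67; the DHA arm from 4.39 to
#' 8.25, with a modest AA decrease in the EPA arm.
#'
#' @param arm `"EPA"` or `"DHA"`.
#' @return List with numeric named vectors `pre_means` and `post_shift`.
#' @export
rbc_template <- function(arm = c("EPA", "DHA")) {
  arm <- match.arg(arm)
  if (arm == "EPA") {
    list(
      pre_means = c("16:0" = 21.5, "18:0" = 15.8, "18:1n-9" = 14.2,
                    "18:2n-6" = 11.1, "20:4n-6" = 13.0, "22:4n-6" = 3.1,
                    "20:5n-3" = 1.00, "22:5n-3" = 2.5, "22:6n-3" = 3.86),
      post_shift = c("20:5n-3" = 2.81, "20:4n-6" = -1.0, "22:5n-3" = 0.7)
    )
  } else {
    list(
      pre_means = c("16:0" = 21.5, "18:0" = 15.8, "18:1n-9" = 14.2,
                    "18:2n-6" = 11.1, "20:4n-6" = 13.2, "22:4n-6" = 3.1,
                    "20:5n-3" = 0.95, "22:5n-3" = 2.5, "22:6n-3" = 3.44),
      post_shift = c("22:6n-3" = 3.46, "20:5n-3" = 0.40)
    )
  }
}

#' Generate paired erythrocyte fatty-acid profiles
#'
#' Simulates per-subject RBC fatty-acid weight-% profiles before and after
#' supplementation: subject baselines scatter around `pre_means` with SD
#' `between_sd`, the arm's `post_shift` is added post-supplementation, and
#' Gaussian within-subject noise with SD `within_sd` is added to every
#' measurement (all in weight-% units, floored at 0).
#'
#' @param n_subjects Number of subjects.
#' @param pre_means Named vector of mean pre-supplementation weight-%.
#' @param post_shift Named vector of post-supplementation deltas (names must
#'   be a subset of `pre_means`; missing entries shift by 0).
#' @param between_sd,within_sd Gaussian SDs in weight-% units.
#' @param seed Integer seed.
#' @return Long tibble `(subject, phase, fatty_acid, pct)`, fully paired.
#' @seealso [n3_index()], [rbc_template()]
#' @export
generate_rbc_profiles <- function(n_subjects = 12,
                                  pre_means = rbc_template("EPA")$pre_means,
                                  post_shift = rbc_template("EPA")$post_shift,
                                  between_sd = 0.5, within_sd = 0.25,
                                  seed = 1L) {
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  if (any(pre_means <= 0)) abort("All `pre_means` must be positive.")
  if (sum(pre_means) > 100) abort("`pre_means` must sum to at most 100.")
  shift <- setNames(rep(0, length(pre_means)), names(pre_means))
  extra <- setdiff(names(post_shift), names(pre_means))
  if (length(extra) > 0) {
    abort(paste0("`post_shift` names absent from `pre_means`: ",
                 paste(extra, collapse = ", ")))
  }
  shift[names(post_shift)] <- post_shift
  if (any(pre_means + shift < 0)) {
    bad <- names(pre_means)[pre_means + shift < 0]
    abort(paste0("Shift produces negative weight-% for: ",
                 paste(bad, collapse = ", ")))
  }
  if (sum(pre_means + shift) > 100) {
    abort("Post-shift means must sum to at most 100.")
  }
  fa <- names(pre_means)
  nf <- length(fa)
  withr::with_seed(as.integer(seed), {
    base <- matrix(rnorm(n_subjects * nf, 0, between_sd), n_subjects, nf)
    pre <- rep(pre_means, each = n_subjects) + base +
      matrix(rnorm(n_subjects * nf, 0, within_sd), n_subjects, nf)
    post <- rep(pre_means + shift, each = n_subjects) + base +
      matrix(rnorm(n_subjects * nf, 0, within_sd), n_subjects, nf)
    subj <- sprintf("S%02d", seq_len(n_subjects))
    dplyr::bind_rows(
      tibble::tibble(subject = rep(subj, nf), phase = "pre",
                     fatty_acid = rep(fa, each = n_subjects),
                     pct = pmax(as.vector(pre), 0)),
      tibble::tibble(subject = rep(subj, nf), phase = "post",
                     fatty_acid = rep(fa, each = n_subjects),
                     pct = pmax(as.vector(post), 0))
    ) |>
      dplyr::arrange(.data$subject, dplyr::desc(.data$phase), .data$fatty_acid)
  })
}
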