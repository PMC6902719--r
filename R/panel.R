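#' Lipid mediator panels
#'
#' A mediator panel is the registry of lipid species a targeted LC-MS/MS
#' assay quantifies: for every species its precursor polyunsaturated fatty
#' acid (PUFA), the enzymatic pathway that produces it, the reporting unit
#' and the analytical limit of detection (LOD). Panels are plain tibbles
#' (one row per species) so they compose with dplyr verbs; [load_panel()]
#' validates a CSV into one.
#'
#' @name lipid-panel
#' @keywords internal
NULL

#' Recognised precursor PUFAs and biosynthetic pathways
#'
#' `mediator_precursors()` lists the parent fatty acids a species may derive
#' from; `mediator_pathways()` the pathway labels. `"hybrid-monohydroxy"`
#' marks monohydroxy fatty acids that can arise from LOX, COX or CYP450
#' activity (or any combination), which therefore cannot be attributed to a
#' single enzyme class.
#'
#' @return Character vector of valid labels.
#' @export
mediator_precursors <- function() {
  c("AA", "EPA", "DHA", "LA", "DGLA", "ALA", "SFA-MUFA", "other")
}

#' @rdname mediator_precursors
#' @export
mediator_pathways <- function() {
  c("COX", "LOX", "CYP450-epoxide", "CYP450-diol", "eCB", "NAE",
    "nonenzymatic", "hybrid-monohydroxy")
}

panel_required_cols <- c("name", "precursor", "pathway", "unit", "lod")

validate_panel <- function(panel, call = rlang::caller_env()) {
  if (!is.data.frame(panel) || nrow(panel) == 0) {
    abort("A mediator panel must be a data frame with at least one species.",
          call = call)
  }
  missing_cols <- setdiff(panel_required_cols, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("Panel is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  dup <- unique(panel$name[duplicated(panel$name)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated species name(s) in panel: ",
                 paste(dup, collapse = ", ")), call = call)
  }
  bad_prec <- unique(setdiff(panel$precursor, mediator_precursors()))
  if (length(bad_prec) > 0) {
    abort(paste0("Unknown precursor label(s): ",
                 paste(bad_prec, collapse = ", ")), call = call)
  }
  bad_path <- unique(setdiff(panel$pathway, mediator_pathways()))
  if (length(bad_path) > 0) {
    abort(paste0("Unknown pathway label(s): ",
                 paste(bad_path, collapse = ", ")), call = call)
  }
  if (any(!is.finite(panel$lod) | panel$lod <= 0)) {
    bad <- panel$name[!is.finite(panel$lod) | panel$lod <= 0]
    abort(paste0("LOD must be a positive number; offending species: ",
                 paste(bad, collapse = ", ")), call = call)
  }
  invisible(panel)
}

#' Read a mediator panel from CSV
#'
#' The CSV must have columns `name`, `precursor`, `pathway`, `unit`, `lod`
#' and may carry logical `skin` / `plasma` columns flagging in which
#' compartments the species is measured (both default to `TRUE` when
#' absent). Row order is preserved; it defines the canonical species order
#' used by all downstream result tables.
#'
#' @param path Path to a panel CSV file.
#' @return A tibble with one row per species, in file order.
#' @seealso [write_panel()], [default_panel()], [default_group_scheme()]
#' @export
load_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"skin" %in% names(panel)) panel$skin <- TRUE
  if (!"plasma" %in% names(panel)) panel$plasma <- TRUE
  panel <- dplyr::select(panel, dplyr::all_of(c(panel_required_cols, "skin", "plasma")))
  validate_panel(panel)
  panel
}

#' Write a mediator panel to CSV
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(panel, f))` reproduces
#' `panel` field for field.
#'
#' @param panel A panel tibble as returned by [load_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' The packaged fixture panel
#'
#' A synthetic but realistically sized panel: 89 species measured in skin
#' (epidermis/dermis) of which 66 are also measured in plasma, covering
#' prostanoids, monohydroxy fatty acids from AA/EPA/DHA and 18-carbon PUFAs,
#' CYP450 epoxides and diols, endocannabinoids and N-acyl ethanolamines.
#' Species names follow common lipidomics shorthand; LODs are plausible
#' assay magnitudes, not measured values.
#'
#' @return A panel tibble (see [load_panel()]).
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "mediator_panel.csv", package = "oxylipr",
                         mustWork = TRUE))
}

#' Species measured in a given compartment
#'
#' @param panel A panel tibble.
#' @param tissue One of `"epidermis"`, `"dermis"`, `"plasma"`.
#' @return Character vector of species names, in panel order.
#' @export
panel_species <- function(panel, tissue = c("epidermis", "dermis", "plasma")) {
  tissue <- match.arg(tissue)
  validate_panel(panel)
  if (tissue == "plasma") panel$name[panel$plasma] else panel$name[panel$skin]
}

# Monohydroxy/ketone fatty-acid pathways grouped by precursor: a
# nonenzymatically formed HETE is still reported with the HETEs.
hydroxy_pathways <- c("LOX", "hybrid-monohydroxy", "nonenzymatic")

#' Default 8-group enrichment scheme
#'
#' Assembles the eight lipid-mediator classes used for group-level (iGA)
#' analysis from each species' precursor and pathway: (1) AA-derived COX
#' prostanoids and thromboxanes; (2) AA-derived hydroxy acids (HETEs,
#' hepoxilins, leukotrienes, oxo-ETEs); (3) EPA-derived species (HEPEs plus
#' 3-series prostanoids); (4) DHA-derived hydroxy acids (HDHAs);
#' (5) octadecanoid and other-PUFA hydroxy acids (HODEs, HOTrEs, HETrEs,
#' oxo-ODEs, t-EKODE); (6) CYP450 epoxides; (7) CYP450 diols; (8)
#' endocannabinoids and N-acyl ethanolamines. Groups are disjoint; hybrid
#' and nonenzymatic monohydroxy species are assigned by precursor.
#'
#' Species matching no rule are left out of every group, with a warning
#' naming the orphans. The scheme is data, not code: any named list of
#' species-name vectors works wherever a scheme is accepted (see
#' [read_group_scheme()]).
#'
#' @param panel A panel tibble.
#' @return A named list of 8 character vectors of species names.
#' @export
default_group_scheme <- function(panel) {
  validate_panel(panel)
  rules <- list(
    prostanoids  = function(p) p$precursor == "AA" & p$pathway == "COX",
    HETEs        = function(p) p$precursor == "AA" & p$pathway %in% hydroxy_pathways,
    HEPEs        = function(p) p$precursor == "EPA" &
      p$pathway %in% c(hydroxy_pathways, "COX"),
    HDHAs        = function(p) p$precursor == "DHA" & p$pathway %in% hydroxy_pathways,
    octadecanoids = function(p) p$precursor %in% c("LA", "ALA", "DGLA") &
      p$pathway %in% hydroxy_pathways,
    CYP450_epoxides = function(p) p$pathway == "CYP450-epoxide",
    CYP450_diols    = function(p) p$pathway == "CYP450-diol",
    eCBs_NAEs       = function(p) p$pathway %in% c("eCB", "NAE")
  )
  scheme <- purrr::map(rules, function(rule) panel$name[rule(panel)])
  assigned <- unlist(scheme, use.names = FALSE)
  orphans <- setdiff(panel$name, assigned)
  if (length(orphans) > 0) {
    warn(paste0("Species assigned to no group: ",
                paste(orphans, collapse = ", ")))
  }
  scheme <- scheme[lengths(scheme) > 0]
  if (length(scheme) == 0) {
    abort("No groups could be constructed from this panel.")
  }
  scheme
}

validate_scheme <- function(scheme, panel = NULL, call = rlang::caller_env()) {
  if (!is.list(scheme) || length(scheme) == 0 || is.null(names(scheme)) ||
      any(names(scheme) == "")) {
    abort("A group scheme must be a non-empty named list of species names.",
          call = call)
  }
  if (any(lengths(scheme) == 0)) {
    abort(paste0("Empty group(s): ",
                 paste(names(scheme)[lengths(scheme) == 0], collapse = ", ")),
          call = call)
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unlist(scheme, use.names = FALSE), panel$name)
    if (length(unknown) > 0) {
      abort(paste0("Group member(s) absent from panel: ",
                   paste(unknown, collapse = ", ")), call = call)
    }
  }
  invisible(scheme)
}

#' Read or write a group scheme (YAML or JSON)
#'
#' A scheme file maps group labels to lists of species names. The format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @param scheme A named list of character vectors.
#' @param panel Optional panel to validate membership against.
#' @return `read_group_scheme()` returns the named list;
#'   `write_group_scheme()` returns `path` invisibly.
#' @export
read_group_scheme <- function(path, panel = NULL) {
  scheme <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  scheme <- purrr::map(scheme, as.character)
  validate_scheme(scheme, panel)
  scheme
}

#' @rdname read_group_scheme
#' @export
write_group_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(scheme, path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    yaml::write_yaml(purrr::map(scheme, as.list), path)
  }
  invisible(path)
}
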