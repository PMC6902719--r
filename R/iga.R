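#' Rank species for iterative group analysis
#'
#' Orders the tested species by signed log2 fold change: descending for
#' direction `"up"` (rank 1 = strongest increase), ascending for `"down"`.
#' Ties are broken by the smaller p value, then lexicographically by name,
#' so the ranking is deterministic. Ranking by the t statistic instead is
#' available via `rank_by`.
#'
#' @param results A `species_test_result` tibble (see [diff_test()]), or
#'   any tibble with `species`, `log2fc`, `p` (and `t`) columns.
#' @param direction `"up"` or `"down"`.
#' @param rank_by Ranking statistic: `"log2fc"` (default) or `"t"`.
#' @return Tibble `(rank, species, stat, p)` with attribute `direction`.
#' @export
rank_species <- function(results, direction = c("up", "down"),
                         rank_by = c("log2fc", "t")) {
  direction <- match.arg(direction)
  rank_by <- match.arg(rank_by)
  if (nrow(results) == 0) abort("`results` is empty; nothing to rank.")
  stat <- results[[rank_by]]
  key <- if (direction == "up") -stat else stat
  ord <- order(key, results$p, results$species)
  out <- tibble::tibble(
    rank = seq_len(nrow(results)),
    species = results$species[ord],
    stat = stat[ord],
    p = results$p[ord]
  )
  attr(out, "direction") <- direction
  attr(out, "rank_by") <- rank_by
  out
}

#' Minimum hypergeometric tail PC value of one group
#'
#' The iterative group analysis enrichment score: walking down the ranked
#' list, for each group-member count `x = 1..G` with `r_x` the rank of the
#' x-th member, compute the hypergeometric upper tail
#' \deqn{p(x) = P(X \ge x) = \sum_{k=x}^{\min(G, r_x)}
#'   \binom{G}{k}\binom{N-G}{r_x-k} \big/ \binom{N}{r_x},}
#' the probability that at least `x` of the `G` members land in the top
#' `r_x` of `N` species by chance. The PC ("probability of change") value
#' is the minimum of `p(x)` over `x`; the member count and rank attaining
#' it are returned.
#'
#' @param member_ranks Integer ranks of the group members within the ranked
#'   list (need not be sorted).
#' @param n_total Length `N` of the ranked list.
#' @return List with `pc_raw`, `x_star`, `r_star`.
#' @seealso [run_iga()]
#' @export
iga_pc_value <- function(member_ranks, n_total) {
  g <- length(member_ranks)
  if (g < 1) abort("The group must have at least one member in the list.")
  r <- sort(as.integer(member_ranks))
  if (any(r < 1) || any(r > n_total) || anyDuplicated(r)) {
    abort("Member ranks must be distinct integers in 1..n_total.")
  }
  x <- seq_len(g)
  p <- phyper(x - 1, m = g, n = n_total - g, k = r, lower.tail = FALSE)
  i <- which.min(p)
  list(pc_raw = p[i], x_star = x[i], r_star = r[i])
}

#' Bonferroni correction of PC values
#'
#' The PC scores of all groups and both directions are corrected together:
#' `pc_corrected = min(1, pc_raw * n_tests)` with `n_tests` the number of
#' group-direction scores, and significance declared at
#' `pc_corrected < 5e-4`.
#'
#' @param results Tibble with a `pc_raw` column (one row per group and
#'   direction).
#' @param n_tests Number of tests corrected for; defaults to `nrow(results)`.
#' @param threshold Significance threshold on the corrected PC
#'   (default `5e-4`).
#' @return `results` with `pc_corrected` and `significant` columns.
#' @export
correct_pc <- function(results, n_tests = nrow(results), threshold = 5e-4) {
  results$pc_corrected <- pmin(1, results$pc_raw * n_tests)
  results$significant <- results$pc_corrected < threshold
  attr(results, "correction") <- list(method = "bonferroni",
                                      n_tests = n_tests,
                                      threshold = threshold)
  results
}

#' Iterative group analysis of a comparison's species results
#'
#' Scores every group of the scheme in both directions: members are
#' intersected with the tested (post-filter) species universe, the list is
#' ranked by signed log2 fold change ([rank_species()]), each group's
#' minimum hypergeometric tail PC is computed ([iga_pc_value()]) and all
#' scores are Bonferroni-corrected together over groups x directions
#' ([correct_pc()]). Groups with no surviving member are skipped and
#' logged.
#'
#' @param results A `species_test_result` tibble from [diff_test()].
#' @param scheme Named list of species-name vectors (e.g.
#'   [default_group_scheme()]).
#' @param rank_by Ranking statistic passed to [rank_species()].
#' @param threshold Corrected-PC significance threshold (default `5e-4`).
#' @return An `iga_result` tibble: `group`, `direction`, `n_members`,
#'   `pc_raw`, `pc_corrected`, `x_star`, `r_star`, `significant`, with the
#'   correction rule and skipped groups recorded as attributes.
#' @export
run_iga <- function(results, scheme, rank_by = c("log2fc", "t"),
                    threshold = 5e-4) {
  rank_by <- match.arg(rank_by)
  validate_scheme(scheme)
  universe <- results$species
  members <- purrr::map(scheme, intersect, universe)
  skipped <- names(members)[lengths(members) == 0]
  members <- members[lengths(members) > 0]
  if (length(members) == 0) {
    abort("No group of the scheme intersects the tested species.")
  }
  if (length(skipped) > 0) {
    inform(paste0("Skipping group(s) with no surviving member: ",
                  paste(skipped, collapse = ", ")))
  }
  out <- purrr::map_dfr(c(up = "up", down = "down"), function(dir) {
    ranked <- rank_species(results, dir, rank_by)
    pos <- setNames(ranked$rank, ranked$species)
    purrr::map_dfr(names(members), function(grp) {
      pc <- iga_pc_value(unname(pos[members[[grp]]]), nrow(ranked))
      tibble::tibble(group = grp, direction = dir,
                     n_members = length(members[[grp]]),
                     pc_raw = pc$pc_raw, x_star = pc$x_star,
                     r_star = pc$r_star)
    })
  })
  out <- correct_pc(out, n_tests = nrow(out), threshold = threshold)
  out <- out[, c("group", "direction", "n_members", "pc_raw", "pc_corrected",
                 "x_star", "r_star", "significant")]
  class(out) <- c("iga_result", class(out))
  attr(out, "skipped_groups") <- skipped
  attr(out, "rank_by") <- rank_by
  attr(out, "correction") <- list(method = "bonferroni",
                                  n_tests = 2 * length(members),
                                  threshold = threshold)
  out
}

#' @export
print.iga_result <- function(x, ...) {
  corr <- attr(x, "correction")
  cat(sprintf(
    "Iterative group analysis: %d group-direction scores, %s-corrected, PC < %g significant\n",
    nrow(x), corr$method, corr$threshold))
  if (length(attr(x, "skipped_groups")) > 0) {
    cat("  skipped groups:", paste(attr(x, "skipped_groups"), collapse = ", "), "\n")
  }
  NextMethod()
}
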