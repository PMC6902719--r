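# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the hypergeometric tails come from exhaustive
# enumeration or Monte-Carlo permutation, never from phyper().

# P(at least x of the G group members fall in the top r) by enumerating
# every C(N, G) placement of the member ranks.
enum_tail_oracle <- function(N, G, r, x) {
  cmb <- utils::combn(N, G)
  mean(apply(cmb, 2, function(s) sum(s <= r) >= x))
}

# Full iGA PC by enumeration: min over x of the enumerated tail.
enum_pc_oracle <- function(N, ranks) {
  G <- length(ranks)
  r <- sort(ranks)
  p <- vapply(seq_len(G), function(x) enum_tail_oracle(N, G, r[x], x),
              numeric(1))
  list(pc = min(p), x_star = which.min(p))
}

# Monte-Carlo permutation estimate of P(at least x members in top r) for a
# random G-subset of 1..N, by direct urn simulation (vectorized over draws:
# the G member positions are drawn sequentially without replacement, and we
# track how many land in the top r). Returns the estimate and its SE.
mc_tail_oracle <- function(N, G, r, x, ndraw = 1e6) {
  in_top <- integer(ndraw)
  for (j in seq_len(G)) {
    p_top <- (r - in_top) / (N - j + 1)
    in_top <- in_top + (stats::runif(ndraw) < p_top)
  }
  est <- mean(in_top >= x)
  list(est = est, se = sqrt(max(est * (1 - est), 1 / ndraw) / ndraw))
}

# Tiny panel used across unit tests.
tiny_panel <- function() {
  tibble::tibble(
    name = c("PGE2", "12-HETE", "12-HEPE", "18-HEPE", "14-HDHA", "13-HODE",
             "11,12-EET", "11,12-DHET", "2-AG", "OEA"),
    precursor = c("AA", "AA", "EPA", "EPA", "DHA", "LA", "AA", "AA", "AA",
                  "SFA-MUFA"),
    pathway = c("COX", "LOX", "LOX", "hybrid-monohydroxy", "LOX",
                "hybrid-monohydroxy", "CYP450-epoxide", "CYP450-diol",
                "eCB", "NAE"),
    unit = "pg/mg-protein",
    lod = c(1, 2, 0.5, 0.5, 1, 2, 1, 0.5, 5, 2),
    skin = TRUE,
    plasma = TRUE
  )
}

# Small, fast study configuration for unit tests.
quick_config <- function(seed, ...) {
  study_config(n_subjects = c(EPA = 12), tissues = "epidermis",
               uvr_timepoints = "unirradiated", seed = seed, ...)
}

run_epidermis_comparison <- function(seed, effects = list(), ...) {
  st <- generate_study(quick_config(seed, ...), effects)
  suppressMessages(suppressWarnings(
    run_comparison(st, pairwise_comparison("EPA", "epidermis"))
  ))
}
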