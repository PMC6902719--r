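---
title: "Statistical methods for paired lipid-mediator panel studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for paired lipid-mediator panel studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxylipr)
```

## Scope and data model

`oxylipr` analyzes targeted lipidomics panels — oxylipins,
endocannabinoids and N-acyl ethanolamines quantified by LC-MS/MS — from
paired human intervention studies. The design it assumes is a within-subject
contrast: every subject is measured under two conditions (before and after
supplementation, or unirradiated versus a fixed time after a UVR
challenge), in one or more compartments (epidermis and dermis in pg/mg
protein, plasma in pg/ml). Concentrations below the analytical limit of
detection (LOD) arrive as blanks; zeros in input files are treated the
same way, since a reported zero from a targeted assay means "not
detected", not "absent".

Three tables describe a study: a *panel* (one row per species: precursor
PUFA, pathway, unit, LOD), a *sample design* (subject, arm, phase, tissue,
UVR timepoint) and per-tissue *concentration tables* (samples × species).
All are plain tibbles, so they compose with dplyr.

## Missing values

For each pairwise comparison — never globally — species missing in
strictly more than half of the comparison's samples are removed, and the
remaining missing cells of surviving species are substituted with the
species' LOD. Per-comparison filtering matters: a species wiped out in
post-UVR skin may be perfectly quantifiable at baseline, and a global
filter would either drag it through comparisons where it is mostly
imputed or discard it where it is informative. The boundary is strict:
missing in exactly half keeps the species. Substitution by the LOD (rather
than LOD/2 or zero) is the natural companion of left-censoring: the only
thing known about a censored cell is that it lies below the LOD, and the
LOD is the least extreme value consistent with that, which keeps imputed
differences conservative.

The synthetic-data generator produces missingness *only* by LOD
left-censoring, matching this remedy. It does not model values missing at
random (lost injections, chromatography failures); with such data the
filter still applies but the LOD substitution would be biased low for
cells that are missing for non-censoring reasons.

## Variance-stabilizing normalization

Targeted panel intensities follow an additive-plus-multiplicative error
model: abundant species vary proportionally (a roughly constant CV), while
near the detection limit a constant additive noise floor dominates. A
plain log transform therefore explodes the variance of low-intensity
species. The package fits, per sample $s$, the generalized-log
calibration

$$h_s(x) = \operatorname{arsinh}(a_s + b_s x) / \ln 2,$$

with $b_s > 0$ and, in this implementation, $a_s \ge 0$. The model for the
transformed data is species mean plus homoscedastic Gaussian error; the
parameters maximize the profile likelihood (which includes the Jacobian of
the transform), with least-trimmed-squares robustness: only the 90% of
species with the smallest residual sums of squares enter the objective,
and the trimmed set is re-selected after each optimization pass until both
the parameters (change < 1e-8) and the trimmed set are stable, up to 100
iterations. Optimization is quasi-Newton (L-BFGS-B) with analytic
gradients.

Three numerical choices deserve a note, because the likelihood surface has
two genuinely degenerate directions:

* **Offsets are constrained non-negative.** When every kept species sits
  in the logarithmic regime of arsinh, the trimmed likelihood is unbounded
  along $a_s \to -\infty$ (the Jacobian term keeps improving while the fit
  term is flat), which drags the calibration onto the saturating branch
  where low-intensity species are annihilated. For non-negative
  concentrations the meaningful branch has $a_s \ge 0$, and the constraint
  removes the escape route.
* **The overall scale is anchored.** A common shift of all $\log b_s$
  moves every transformed value by the same constant in the log regime,
  which the species means absorb exactly — an exact flat direction. A weak
  quadratic anchor on $\mathrm{mean}(\log b_s)$ (weight 0.1, centred at
  the median-based initialization) pins this gauge. The anchored mode
  cancels from every downstream statistic (paired differences, per-species
  SDs, ranks), so the anchor affects reporting convention only.
* **Monotone acceptance.** An optimizer restart at the optimum can wander
  by ~1e-7 along near-flat directions without changing the objective
  beyond machine resolution. The trim loop therefore accepts a new iterate
  only if it improves the objective beyond numerical noise; a converged
  fit then shows an exactly zero parameter change and the convergence
  criterion is meaningful.

If the fit still fails to converge, the pipeline falls back to the
deterministic, strictly monotone `log2(x + LOD/2)` per species and records
that in the result's `transform` field.

The transform is fitted per tissue × comparison dataset, not jointly
across tissues, because skin and plasma are on different units; and per
comparison rather than per arm, mirroring the per-comparison filtering
(the choice is recorded in the fit object). Its two diagnostics are the
mean-SD plot (`plot_mean_sd()`), which should be flat, and the doubling
gap $h(2x) - h(x)$, which must approach 1 at high intensity: the fitted
transform is exactly log2-like where $a_s + b_s x \gg 1$. The tests check
the flatness as a top-vs-bottom intensity-tertile SD ratio within
$[0.5, 2]$ under the generator's additive+multiplicative defaults, and the
log2 limit (to 1e-4 at the observed maximum) on purely multiplicative data
whose baseline medians span the assay's dynamic range — with only one or
two species near the noise floor the transition point $a_s/b_s$ is weakly
identified and its sampling noise, not the transform family, dominates the
comparison.

## Paired testing and FDR control

Each surviving species is tested with a two-tailed paired Student's
$t$ test on the per-subject transformed differences (post − pre). The mean
paired difference on the glog2 scale is reported as the log2 fold change;
in the high-intensity limit it is exactly that, and near the LOD it is a
shrunken version, which is the price of variance stabilization. Subjects
missing either side of a pair are dropped with a warning; species with
fewer than two complete pairs are skipped and logged. Degenerate cases
follow fixed conventions: zero variance with zero mean difference gives
$p = 1$, zero variance with nonzero mean gives $p = 0$ with a warning.
Benjamini-Hochberg correction is applied within each comparison's species
set (each pairwise comparison is the analysis unit), with significance at
$q < 0.05$.

## Iterative group analysis

Class-level shifts are scored by rank-based iterative group analysis. For
a direction (up or down), species are ranked by signed log2 fold change —
the fold change, not the $t$ statistic, is the default ranking statistic,
matching the method's original formulation; ranking by $t$ is available by
argument and recorded in the result's metadata. Ties are broken by the
smaller $p$, then by name, making ranks deterministic. For a class with
$G$ members among $N$ tested species, with $r_x$ the rank of its $x$-th
member, the PC score is

$$\mathrm{PC} = \min_{x = 1..G} \; P(X \ge x), \qquad
  X \sim \mathrm{Hypergeom}(N, G, r_x).$$

Classes are evaluated against the post-filter species universe (PC is
defined relative to the tested list); classes with no surviving member are
skipped and logged. Because the paper trail for the correction of PC
scores is thin, the package uses the conservative, deterministic choice:
Bonferroni over classes × two directions, capped at 1, with significance
below $5 \times 10^{-4}$; the rule is stored in the result's attributes.
Note the raw PC is a minimum over $G$ dependent tail probabilities and is
therefore not a uniform p value under the null — the calibration tests
below treat it accordingly (union bound), and the stringent threshold
absorbs the difference in practice.

The implementation is verified against two independent oracles: exhaustive
enumeration of all $\binom{N}{G}$ member placements for $N \le 12$, and a
$10^6$-draw urn-simulation Monte-Carlo for $N \le 30$. Two structural
properties are also tested: promoting a member to a better rank never
increases PC, and reversing the ranked list swaps the up/down results
exactly.

## Summaries

Precursor-metabolite pools (e.g. "all EPA-derived species") are summed on
the raw concentration scale in the tissue's unit — totals are reported in
pg/mg protein or pg/ml, so transforming first would wreck their meaning —
with LOD-substituted cells contributing the LOD. Percent change is
$100\,(\bar{x}_\text{post} - \bar{x}_\text{pre})/\bar{x}_\text{pre}$ on
that raw scale (scale-invariant), while the paired test on totals runs on
log totals, consistent with testing concentration data on a log scale. The
erythrocyte omega-3 index is EPA% + DHA% of total RBC fatty acids;
per-fatty-acid paired tests are reported at raw $p$ without multiplicity
correction, as is conventional for compliance panels. Skin–plasma
concordance is screened per species by Spearman rank correlation on
subject × phase pairs; with $n \le 9$ pairs the two-sided $p$ is exact
from the full permutation distribution of the rank vectors (valid under
ties), otherwise the large-sample $t$ approximation is used. Pairing by
subject × phase (rather than subject only) doubles the usable pairs while
keeping pre and post measurements of the same subject aligned; the choice
is recorded in the output.

## The synthetic-data generator

The generator is the package's substitute for undeposited clinical data
and the ground truth for every calibration claim. Its defaults encode the
emulated study design: two independent arms (EPA $n = 12$, DHA $n = 9$),
three compartments, three UVR timepoints, and fully paired pre/post
sampling. Concentrations are

$$x = m\,e^{u} \cdot f \cdot e^{\varepsilon} + \delta,$$

with $m$ the species × tissue baseline median, $u \sim N(0, 0.5^2)$ a
between-subject log effect held constant across phases and timepoints (so
paired contrasts cancel it), $f$ the product of applicable ground-truth
multipliers, $\varepsilon \sim N(0, 0.25^2)$ multiplicative measurement
noise and $\delta \sim N(0, 1)$ additive noise in concentration units,
truncated at zero and left-censored at the LOD. The LOD sits at the 10%
quantile of each species' baseline distribution, giving roughly 10%
missingness. The between-subject SD of 0.5 (~65% CV) and measurement SD of
0.25 (~29% CV) are plausible magnitudes for inter-individual lipid
mediator variation and targeted LC-MS/MS repeatability; the study they
emulate reports no per-species variances, so these are the package's own
choices, fixed once.

Baseline medians are likewise class-level anchors, not measurements: the
epidermal DHA-derived pool is set roughly an order of magnitude above the
EPA-derived pool (≈3100 vs ≈320 pg/mg protein), dermis runs at a quarter
of epidermal levels, and in plasma the CYP450 species are among the most
abundant while 2-AG is minor and PEA dominates the NAEs. The canonical
effect set (`example_supplement_effects()`) doubles the HEPEs and reduces
the HETEs to 0.7-fold in the EPA arm and raises the HDHAs 1.5-fold in the
DHA arm, post-supplementation.

What passing tests on these data do and do not show: they establish that
the pipeline is correctly calibrated under its own model (type-I error of
the paired test within Monte-Carlo error of nominal at $n = 12$ over
10,000 replicates; essentially zero BH discoveries and corrected-PC calls
within the Bonferroni-implied rate over 500 null pipelines; ≥90% recovery
of 2-fold group effects over 200 replicates with no direction inversions)
and that the estimators compute what they claim. They cannot establish
robustness to features the generator does not produce: heavy-tailed or
correlated measurement error across species, batch effects and
chromatographic drift, missingness that is not left-censoring, or isomer
misannotation. The generator also draws the subject effect independently
per species, so it does not emulate subject-level correlation structure
across the panel.

## Problem sizes and reproducibility

The simulation-based checks use one comparison of the emulated design (12
subjects, 89 species, 24 samples): 500 replicates for null calibration,
200 for effect recovery, 10,000 for the $t$ calibration, 200 + 50
instances for the enrichment oracles. Every stochastic step flows from an
explicit integer seed (`study_config(seed = )`, `generate_rbc_profiles(seed = )`),
and identical seed plus configuration reproduces a dataset bit for bit.
The analysis entry points are pure functions of their inputs.

## Known limitations

* The per-comparison filter means a species' presence in one comparison's
  results says nothing about another's; cross-comparison syntheses must
  join on species explicitly.
* The glog fold-change estimate is shrunken near the LOD, so ranks at the
  bottom of the intensity range are compressed; iGA inherits this.
* The raw PC score is not a uniform p value (see above); treat `pc_raw`
  comparatively and rely on `pc_corrected` against its threshold.
* With very small panels (a handful of species) the 90% trimmed fit can
  be driven by two or three species; `fit_glog(trim = 0)` is then the
  safer call.
* The default 8-class scheme is a reconstruction from precursor × pathway
  structure; studies with their own class definitions should supply a
  scheme (`read_group_scheme()`) rather than rely on the default.
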