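---
title: "Models and methods behind spatepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spatepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spatepi analyses counts of rare point events (homicides, disease cases)
over a partition of a city or region into areal units. This vignette is
the package's own account of the statistical machinery: the models, their
assumptions, the tunable parameters and their defaults, the numerical
choices, and what the synthetic test-bed does and does not establish.

## Data model

An **area table** holds one row per areal unit: a projected planar polygon
(metres — the package refuses coordinates that look like lon/lat degrees,
because every bandwidth and distance below is metric), a population at
risk, and numeric covariates. A **count panel** is the areas-by-years
integer matrix of event counts produced by point-in-polygon aggregation;
boundary points are assigned deterministically to the first containing
area in stable input order, and events falling in no polygon are kept in
an explicit `unassigned` bucket so event totals always reconcile.

Contiguity weights default to **queen** adjacency (shared boundary
vertex), row-standardized. Rationale: row standardization makes the
spatial lag an average of neighbours and yields the exact identity
`mean(local Moran) = global Moran`, which the test suite checks to 1e-10.
Contiguity is decided from shared ring vertices (tolerance 1e-6 m); this
is exact for lattices and for polygon layers whose shared borders carry
matching vertices, the normal case for administrative boundary files.

## Rate smoothing and classification

Raw rates `O_i / n_i` are noisy where populations are small. The
empirical Bayes smoother is the classic global method-of-moments
estimator: prior mean `m = sum(O)/sum(n)`, between-area variance
`A = max(0, sum(n_i (r_i - m)^2)/sum(n) - m/mean(n))`, weight
`w_i = A/(A + m/n_i)`, smoothed rate `w_i r_i + (1 - w_i) m`. Two
consequences worth knowing: `A` is floored at zero, so a panel whose
between-area variation is entirely Poisson sampling noise shrinks *every*
area exactly to `m` (the package then refuses to cut the constant vector
into Jenks classes — this is the statistically correct degenerate case,
not a defect); and shrinkage is monotone in population, so small areas
move furthest.

Jenks natural breaks are computed by the exact Fisher dynamic programme
(O(k·n²)), not a heuristic; a brute-force enumeration oracle confirms
optimality for n ≤ 10. Default `k = 5`, the conventional choropleth class
count; the class count used by the source maps is not stated anywhere, so
this is a documented package choice.

## Kernel density surfaces

`kde_surface()` evaluates `f(x,y) = 1/(n h²) Σ K(d_i/h)` at cell centres
of a raster whose extent is the event bounding box padded by one
bandwidth (so the full kernel mass of every event is on the grid — the
mass-conservation tests depend on this). The kernel is **quartic**,
`K(u) = (3/π)(1-u²)²` for `u < 1`: the density formulation leaves `K`
unspecified, and the quartic is the convention of desktop GIS density
tools, with compact support that keeps evaluation fast. Two
normalizations are exposed because the probability form integrates to 1
while maps conventionally show incident density: `scale = "count"`
(default) reports events per km² and integrates to `n`;
`scale = "probability"` reports per m² and integrates to 1. A Gaussian
kernel (truncated at 4h) is available for comparison.

## Moran statistics

Global Moran's I uses the cross-product form with expectation
`-1/(n-1)`; the default inference is the two-sided analytic test under
the randomization assumption (the form behind z-scores like 5.8 in
applied reports), with a seeded permutation test always available.
Permutation p-values are `(1 + #extreme)/(n_perm + 1)` and can never be
zero.

Local Moran `I_i = z_i/m2 · Σ_j w_ij z_j` (with `m2 = Σz²/n`) is tested
by **conditional permutation**: `x_i` stays fixed while the remaining
values are drawn without replacement into the neighbour slots; the
pseudo-p is two-sided (`2·min(p_low, p_high)`, capped at 1), which keeps
the false-positive fraction near alpha under spatial randomness (checked
by Monte Carlo). Cluster labels HH/LL/HL/LH come from the signs of `z_i`
and its spatial lag, masked to `not-significant` above alpha; optional
Benjamini–Hochberg adjustment across areas is off by default, since the
conventional LISA map is unadjusted and both behaviours should be
reproducible.

## Scan statistics

Both scans use the discrete Poisson likelihood ratio
`LLR = O ln(O/E) + (C-O) ln((C-O)/(C-E))` with the `0·ln 0 = 0`
convention, expected counts by indirect standardization on person-time
only (no covariate adjustment — the scans deliberately test raw
incidence against population at risk), and Monte Carlo inference that
redistributes the conditional total `C` multinomially over cells with
probabilities proportional to expectations. Window caps default to 50% of
person-time (temporal) and 50% of population × 50% of the period
(space-time); candidate spatial windows are circles grown over
nearest-centroid areas. Secondary clusters are reported greedily with no
shared areas with any better-ranked cluster. The vectorized
implementation is verified against a brute-force enumeration of every
(centre, radius, window) cylinder.

Two properties of the max-LLR cylinder worth knowing when reading
results: the reported RR always dominates O/E for high clusters, and the
most likely cluster tends to *over-extend* — absorbing neighbouring
noise, particularly when populations are heterogeneous. In our recovery
experiments (RR = 3 disc of 9 areas over 3 of 10 years, ~720 events,
populations uniform on 5,000–35,000), the primary cluster achieves
Jaccard ≥ 0.5 with the implanted truth in roughly three quarters of
replicates; most misses still contain the truth but are diluted.

## The variable-selection cascade

The funnel mirrors a common applied workflow and assigns every candidate
variable exactly one removal stage: (1) Pearson screen at alpha = 0.05;
(2) iterative collinearity gate — while any VIF in the surviving set
exceeds 7.5, drop the worst and recompute (largest-first iteration makes
the result deterministic); (3) exhaustive subset search up to `max_size`
(default 6), keeping models whose every coefficient is significant and
every VIF admissible, ranked by adjusted R² with AICc then lexicographic
tie-breaks; (4) OLS backward pruning of the best subset. All regressions
run on z-standardized variables, which is what makes near-zero intercepts
and comparable coefficient magnitudes meaningful. Note that backward
pruning at alpha = 0.05 retains a spuriously significant noise column in
roughly one replicate in five (selection inflation of 1 − 0.95⁴); the
funnel is a reproduction of practice, not an oracle, and the pipeline
will fall back to the best-ranked exploratory model when no subset meets
every gate, logging that it did so.

Areas with zero events over the whole period are excluded before the
regression stages (with the removal list logged), matching the treatment
of such areas as outliers in the motivating workflow.

## GWR and MGWR

GWR solves a weighted least-squares problem at every site with
**adaptive bisquare** weights `(1 - (d/b_i)²)²`, where `b_i` is the
distance to the k-th nearest site (self included). The single `k` is
chosen by golden-section search over integers in `[p+2, n]` minimizing
`AICc = 2n ln σ̂ + n ln 2π + n(n + tr S)/(n - 2 - tr S)` with
`σ̂² = RSS/n`; the integer search memoizes evaluations and guarantees
bracket shrinkage, finishing by enumerating the final ≤ 3 candidates.
σ̂² inside AICc uses RSS/n (keeping AICc comparable across OLS, GWR and
MGWR, which share one AICc formula in this package), while coefficient
standard errors use RSS/(n − tr S). Local inference is corrected for the
effective number of tests: `adj_alpha = α(p+1)/tr(S)`, and the adjusted
critical t is the two-sided Student quantile at `adj_alpha` with
`n − tr(S)` degrees of freedom. A `kernel = "uniform"` debug switch
reproduces global OLS exactly (coefficients to 1e-10, identical AICc) —
the equivalence the oracle tests rely on.

MGWR relaxes the single-bandwidth assumption: each term (intercept
included) gets its own bandwidth, calibrated by **backfitting**. Terms
are initialized from the GWR fit at its optimal bandwidth (the
convention of the multiscale calibration literature, and faster than OLS
initialization); each sweep re-selects every term's bandwidth by
golden-section AICc on its partial residual and updates the term's
smoother. Convergence uses the term-change score
`SOC_f = sqrt(Σ_j ||Δf_j||²/n)` with tolerance 1e-5 (also stopping when
the score itself stops changing by that amount); non-convergence at
`max_iter = 200` returns the fit flagged `converged = FALSE` with a
warning. Per-term hat matrices are propagated through the backfit
(`R_j ← A_j(I − Σ_{l≠j} R_l)`), so `Σ_j ENP_j = tr(S)` holds exactly and
per-term adjusted alphas (`α/ENP_j`) and pseudo-t surfaces are available.
Per-term standard errors follow the smoother-matrix convention
`var(f_j) = σ² R_j R_j'`, `SE(β_j) = SE(f_j)/|x_j|`. The per-area local
R² is reported at the median per-term bandwidth — a reporting choice,
since no single kernel is canonical for an additive multiscale fit.

One property to be aware of: with every bandwidth frozen to a common
value, the backfit fixed point solves per-term univariate local normal
equations, not the joint local WLS, so it reproduces the single-bandwidth
GWR *approximately* (coefficient-surface correlations around 0.8–0.99 and
nearly coincident fitted values in our experiments), not to machine
precision. This is a property of the backfitting algorithm itself.

The **Monte Carlo variability test** asks whether a coefficient surface's
spatial variation is real: the statistic is the variance of the local
coefficients; each of `n_iter` iterations (default 1000; at least 19 to
resolve p = 0.05) permutes the site locations and recalibrates the term
at its fixed bandwidth on its final partial residuals. Size is honest
when the data-generating surface is truly flat; when another term's
surface is misfit, leaked structure in the partial residual can inflate
rejections for a flat term — the test reads on the fitted decomposition,
not the unknowable truth.

## The synthetic test-bed

The generator emulates the structure of a neighbourhood-scale homicide
study: a 12×12 lattice of 1 km cells (144 areas ≈ the 140-neighbourhood
scale), populations uniform on 5,000–35,000 (mean 20,000, matching the
heterogeneity of urban neighbourhood populations), ten years of counts,
and a base rate of 2.5 per 100,000 person-years (2.3 in the shipped
fixture, calibrated so the expected total *including* two implanted
space-time cylinders is ≈ 700 events). Covariates are zero-mean
unit-variance Gaussian fields with exponential correlation
`exp(-d/range)` realized through the correlation-matrix square root
(default range 3 km). Coefficient surfaces are constants, linear
gradients, or Gaussian hotspot bumps; Poisson counts use
`pop · rate · exp(Σ β_j(u,v) x_j) · RR`, with the log-linear effects
centred so that `base_rate` is the population-average rate for every
seed (covariates act as relative risks). Event points are scattered
uniformly inside their area polygon by rejection sampling, so panels and
point sets agree by construction. Every generator is bit-reproducible
under its seed, and the pipeline derives all stage seeds from one global
integer.

Gaussian-response fits (`sim_response()`) drive the GWR/MGWR recovery
experiments (surface correlation ≥ 0.8 for varying terms, mean absolute
error ≤ 0.1 for constant terms at 144 sites with noise sd 0.25); the
Poisson generator drives the rate/Moran/scan side. What passing tests do
**not** show about real data: real boundaries are irregular (contiguity
richer than a lattice), real covariates are collinear in ways the
exponential-field generator does not produce, real event processes are
over-dispersed relative to Poisson, and real coefficient surfaces need
not belong to the constant/gradient/hotspot family. The test-bed
validates the *machinery*, not any substantive conclusion.

## Problem sizes and runtimes

The shipped test suite runs at deliberately desk-scale sizes: lattices of
16–144 areas, 500-replicate permutation size checks at n = 64,
50-replicate scan-recovery runs at n = 144 with inference disabled
(recovery depends only on the maximum-LLR window), and 20-replicate MGWR
experiments with 99 Monte Carlo iterations per term. The full synthetic
pipeline on the paper-scale fixture with 199 replicates per Monte Carlo
stage completes in well under a minute on one CPU; production analyses
should raise `n_sim`/`n_perm`/`mc_iter` to 999+.
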