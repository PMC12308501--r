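---
title: "Methods: PLI connectivity, small-world metrics and condition-reactivity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity, small-world metrics and condition-reactivity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`plinet` implements a functional-network analysis chain for band-limited,
source-level ROI time series: phase lag index (PLI) connectivity, binary
graph construction, small-world metrics normalized against rewired null
networks, and the three statistical analyses built on top (condition
reactivity, trait association of change scores, baseline dependence). This
vignette is the package's account of the underlying models, the parameters
that matter, and the design decisions taken where conventions genuinely
diverge.

## The measurement model

### Phase lag index

For each epoch, each ROI's instantaneous phase is the angle of its analytic
signal (FFT-based Hilbert transform). For ROIs $i, j$ the PLI is

$$\mathrm{PLI} = \left| \frac{1}{N} \sum_{k=1}^{N}
  \mathrm{sign}\,\Delta\varphi(t_k) \right|,$$

with the phase difference wrapped to $(-\pi, \pi]$ and the three-case sign
convention $+1 / -1 / 0$ for positive / negative / exactly zero differences.
The index quantifies the *asymmetry* of the phase-difference distribution
around zero: consistent nonzero lags give values near 1, while zero-lag
synchrony — the component most inflated by volume conduction and source
leakage — contributes nothing. Two numerical choices are deliberate:

* wrapping is done as the angle of $e^{i(\varphi_i - \varphi_j)}$, so the
  sign is always taken on the wrapped difference; an exact antiphase
  difference wraps to $+\pi$ and counts as positive;
* exact zeros contribute 0 literally — there is no epsilon band. Phase
  differences of continuous signals are almost never exactly zero except in
  the degenerate identical-signal case, which is exactly the case the 0
  convention is meant to capture.

Per-epoch matrices are averaged arithmetically across epochs into one
symmetric, zero-diagonal matrix per participant × condition × band. The
per-epoch kernel is compiled (Rcpp) because it is the pipeline's single hot
loop (2278 pairs × 2500 samples per epoch); a plain-R `pli()` exists and the
test suite cross-checks the two paths against each other.

### Filtering and epoching

Recordings are cut into consecutive non-overlapping 5-s epochs (trailing
remainder dropped), then each epoch is band-passed — that order matches the
upstream convention the pipeline emulates, and a regression test verifies
that samples away from the epoch edges are bit-identical between the two
orders (the FIR convolution is local). The five default bands are delta 2–4,
theta 4–8, alpha 8–13, beta 13–30 and gamma 30–60 Hz.

A recording passes QC only if at least `min_epochs = 10` epochs survive
(≥ 50 s of usable signal at 5-s epochs). QC failures raise a typed condition
naming the participant and condition; the pipeline records them as exclusions
rather than failing.

The filter realization is unspecified in most MEG reports, so the package
fixes a transparent contract: a linear-phase Hamming-window FIR band-pass
with transition width 15% of the lower band edge, applied with exact
group-delay compensation and reflection padding — zero phase by construction,
so downstream phase estimates are unbiased. The order implied by the
transition width is capped at the signal length minus one; for delta-band
filtering of 5-s epochs the cap binds and the realized transition widens to
about 0.7 Hz. Passband gain and stopband attenuation are tested against the
filter's own frequency-response oracle (unit-RMS tone in/out).

The Hilbert transform distorts phases within a few samples of epoch edges.
By default nothing is trimmed (matching common practice, where the effect
dilutes into PLI's average); `instantaneous_phase()` and `pli_matrix()`
accept `trim_s` for analyses that need exactness at the edges, and tests
exercise it. A decimation helper with anti-alias filtering exists for
externally supplied recordings at higher rates; synthetic data are generated
at the working rate (500 Hz), where it is a no-op.

## Graphs

### Proportional threshold

Each weighted matrix is binarized by keeping the `round(κ·M)` largest of the
`M = n(n−1)/2` pair weights (default κ = 0.20; sensitivity sweep κ = 0.10,
0.12, …, 0.30). Rounding is half-away-from-zero and ties at the boundary
break deterministically by descending weight then ascending (row, column)
index. Tie handling in reference toolboxes is an artifact of their sort
order and platform; pinning it makes results reproducible bit-for-bit.

### Metrics and the finite-only path length

The clustering coefficient is the mean local clustering over all nodes, with
degree < 2 nodes contributing 0. The characteristic path length is the mean
of the *finite* off-diagonal BFS distances over unordered pairs: unreachable
pairs are treated as missing, with no extraction of the largest connected
component. At the default density the graphs usually form one large
component, so the finite-only mean approximates a largest-component
restriction, but the two differ when isolated nodes appear at low κ — the
package implements the finite-only convention exactly, and a graph with no
finite distances yields a flagged `NA`, not an error.

### Null networks and small-worldness

`C_rand` and `L_rand` are means over `n_null = 1000` degree-preserving
double-edge-swap randomizations, attempting 5 swaps per edge ("rewiring all
edges five times"; at this strength the alternative reading — five full
passes over the edge list — is equivalent in distribution). Nulls may be
disconnected; `L_rand` uses the identical finite-only averaging. Then
`C_norm = C / C_rand`, `L_norm = L / L_rand`, `SW = C_norm / L_norm`. Each
null draws its own child seed from the recorded master seed, so any single
null network is individually reproducible. Degree sequences are asserted
exactly in tests; an Erdős–Rényi-like graph is its own null (SW within the
Monte-Carlo interval of 1), and Watts–Strogatz graphs at small rewiring
probability give SW > 1 with the characteristic peak at small nonzero
rewiring.

The Watts–Strogatz generator is implemented in-package with pinned
semantics — ring lattice with `k` nearest neighbours, each lattice edge
independently rewired with probability `p`, edge count exactly `nk/2`, no
self-loops or duplicates — because it serves as an *oracle fixture*: its
lattice clustering has the closed form $3(k-2)/(4(k-1))$ against which the
metric code is tested.

## Statistical models

For each metric (SW, C, L) and band, condition reactivity is modelled as

```
value ~ diagnosis * condition + age_months + sex + (1 | participant_id)
```

estimated by maximum likelihood with Wald z inference (z statistics are what
such studies report; ML rather than REML keeps fixed-effect comparisons
coherent). Reference levels are TD, DR and female; diagnosis and condition
enter as 0/1 indicators. The corrected threshold is α = 0.05/5 = 0.01, a
Bonferroni correction across the five bands only — never across metrics,
which measure non-independent aspects of the same graph. All p-values are
two-sided; results with 0.05 ≤ p < 0.10 are labelled "exploratory trend" in
the term tables, distinct from significance.

A significant diagnosis × condition interaction gates the follow-ups
(override available for testing): group-specific condition models, and OLS
regressions of the SRS raw total on the EO−DR change score with diagnosis,
their interaction, age and sex, using HC1 sandwich standard errors (the
robust variant is rarely stated in reports; HC1 is the common default).
These follow-ups use α = 0.05 as separate exploratory hypotheses.

Baseline-dependence regressions `Δ ~ baseline × diagnosis + age + sex` run
for every cell at α = 0.01. Their null expectation is not 0: if DR and EO
values share independent noise, $\mathrm{cov}(X, Y - X)/\mathrm{var}(X) =
-1$, so a negative slope is the regression-to-the-mean artifact and only
departures from −1 are informative. The test suite verifies both closed
forms (slope −1 for iid conditions, slope 0 when EO = DR + independent
noise).

Degenerate inputs are flagged, never silent: singular random-effect fits,
optimizer messages, rank-deficient designs, and covariates with a single
observed level (possible after heavy QC exclusion), which are dropped from
the formula and named in the fit's convergence field. If even the fallback
covariance is unavailable the standard errors are `NA` and the flag says so.

Diagnostics mirror the checks a careful analyst runs: residual skewness and
kurtosis, residuals versus fitted (exactly orthogonal for the OLS models;
mixed models show a benign positive trend from random-effect shrinkage,
reported for reference), an |residual|-versus-fitted trend as a
heteroscedasticity flag, and the random-intercept distribution.

## The synthetic-data module

The generators define the study conditions under which everything is tested.

* **Cohort**: 23 ASD + 31 TD; ages uniform over 60–97 (ASD) and 44–109 (TD)
  months; sex ratios 14/23 and 17/31. SRS raw totals are normal with means
  69.391 / 47.677, truncated at 0. No dispersion is published for those
  means, so the default SD (11.5, both groups) was chosen once so that the
  implied two-sample t statistic at these group sizes is ≈ −6.9, matching the
  reported group contrast.
* **Epoch counts**: recordings are 130 s (DR) and 190 s (EO), capping usable
  5-s epochs at 26 and 38. Post-artifact epoch counts are drawn as the cap
  minus a Poisson loss (defaults: mean 2 for DR, 16 for EO, putting EO counts
  near 22). Published mean epoch counts for the DR condition exceed what a
  130-s recording can contain; the generator treats the stated durations as
  binding and calibrates the loss rates to them.
* **Coupling**: each coupled ROI pair shares a narrowband carrier (centre
  frequency of the band, slow sinusoidal FM so it is quasi-narrowband with a
  stable envelope); the second ROI lags by `lag_radians` plus von Mises
  jitter redrawn in blocks of `1/bandwidth` seconds, matching the natural
  phase-decorrelation scale of a band-limited signal. This model was chosen
  because it admits a closed form: the expected long-run PLI is
  $|p_+ - p_-|$, the signed-probability asymmetry of the wrapped lag-plus-
  jitter distribution, computable by numerical integration of the von Mises
  density and cross-checked by brute-force resampling. Concentration ∞ gives
  single-epoch PLI exactly 1 (tested with edge trimming); concentration 0
  gives the uniform circle and expected PLI 0. Uncoupled ROIs carry
  independent white noise. All amplitudes are irrelevant downstream — the
  pipeline is phase-only, and a scaling-invariance test asserts it.
* **Metric-level simulation** (`simulate_metrics()`): statistical
  parameter-recovery and error-rate studies need hundreds of cohort
  replicates; running the full signal chain for each would add cost without
  adding information about the *models*. The metric table is therefore drawn
  directly from the additive generative model the mixed model assumes
  (participant intercept SD 0.05, residual SD 0.05 around metric-typical
  levels), with injectable diagnosis / condition / interaction effects and an
  optional group-specific Δ–SRS association. Signal-level injection of
  condition effects remains available through per-group × condition coupling
  specs in the pipeline config.

What the generators deliberately do **not** emulate: sensor-space
acquisition, volume conduction and source leakage (synthetic "sources" are
leakage-free, so absolute PLI noise floors are optimistic), 1/f spectral
shape, non-stationarity, artifacts, or spatially structured covariance
between ROIs. Passing tests therefore validate the *estimators and
inference machinery* under known truth, not the empirical distribution of
any clinical dataset — headline coefficients from real cohorts are not
reproducible from synthetic data, and the package makes no attempt to tune
toward them.

## Problem sizes and seeds

The test suite runs the full chain at reduced but non-trivial sizes chosen to
keep the complete run in the low minutes on one core: demo pipelines of 4–12
participants with 10–50 nulls; null ensembles of 1000 for the degree-sequence
invariant; 100–500 cohort replicates for coverage and type-I studies at the
study's own n = 23 + 31; 200 random graphs (n ≤ 12) for brute-force metric
equivalence. Every random stage takes an explicit seed; the pipeline spawns
per-stage and per-null child seeds from one master seed and records them in
the run manifest, so any number in any output table is reproducible from the
manifest alone.

## Known limitations

* The PLI noise floor for independent narrowband signals scales like
  $\sqrt{2/(\pi\,T\,\Delta f)}$ per epoch; for delta-band 5-s epochs this is
  substantial, so between-band comparisons of raw PLI levels are not
  meaningful — which is precisely why the graph stage normalizes against
  degree-preserving nulls.
* Wald z inference in small samples is mildly anticonservative (the measured
  type-I rate at α = 0.01 sits near 0.015 at n = 54); the acceptance suite
  checks it stays within binomial bounds rather than pretending exactness.
* The finite-only path length convention makes L slightly optimistic when
  graphs fragment at low κ; the sweep exists to make such sensitivity
  visible rather than hidden.
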