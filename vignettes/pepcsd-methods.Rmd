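---
title: "Measuring and modelling peptide charge state distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling peptide charge state distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcsd)
```

## The measurement problem

Electrospray ionization deposits a variable number of protons on each
peptide, so one peptide appears in an MS1 scan as several co-eluting
isotope envelopes, one per charge state. The charge state distribution
(CSD) — the relative summed intensity of those envelopes over charges
1+ to 5+ — is the object this package measures and models. The naive
expectation is that a peptide takes as many protons as it has basic
sites (the N-terminal amine plus arginine, lysine and histidine side
chains); the interesting biology and physics live in the deviations,
which `pepcsd` classifies as *undercharging* (mean charge below the
basic-site count) and *overcharging* (mean charge above it).

This vignette documents the models and procedures, the tunable
parameters with their defaults and units, the numerical choices, what
the bundled synthetic generator does and does not emulate, and the
package's known limitations.

## Peptide chemistry

Residue monoisotopic masses and CHNOS compositions ship as plain-text
tables (`inst/extdata`); modifications follow MaxQuant naming. Supported
modifications are fixed cysteine carbamidomethylation (+57.02146 Da) or
N-ethylmaleimidation (+125.04768 Da), variable methionine oxidation
(+15.99491 Da) and N-terminal acetylation (+42.01057 Da). Theoretical
isotope envelopes are computed by convolving the natural isotope
distributions of C, H, N, O and S according to the peptide's elemental
composition, collapsing isotope fine structure onto integer offsets
(binary-exponentiation convolution with a 1e-12 relative tail cut), then
truncating at a cumulative coverage of 0.999 and renormalizing. All
isotope peaks are spaced by the ^13^C–^12^C mass difference
(1.0033548 Da), the dominant contributor in peptides; this
single-spacing approximation is well within centroided-data precision.

The basic-site count is defined as 1 (N-terminus) + #R + #K + #H. By
default the N-terminus still counts when acetylated; whether an
acetylated amine should count is genuinely ambiguous (it can no longer
be protonated, but acetylated peptides are rare and are excluded from
the basicity regressions anyway, which consider unmodified peptides
only), so the choice is exposed as
`count_nterm_when_acetylated` on `peptide()`.

## The extraction scheme

For each MS2-identified peptide, `extract_peptide()` scans the MS1
spectra around the identification and estimates one intensity per
charge state per scan. The scheme is deliberately stringent: it prefers
returning nothing over returning a contaminated reading.

A charge state in a scan is called **present** only if all three filters
pass:

1. *m/z offset* — every compared theoretical isotope position has an
   observed centroid within `mz_tolerance_ppm` (default 10 ppm);
2. *envelope shape* — the cosine similarity between the matched
   intensities and the theoretical abundances exceeds
   `cosine_threshold` (default 0.98);
3. *no chimeric peaks* — no unmatched peak inside the envelope's m/z
   span exceeds `chimeric_intensity_fraction` (default 0.2) of the
   matched base peak.

It is called **absent**, with extracted intensity exactly 0, only when
no peak lies within `absence_vicinity_ppm` (default 20 ppm) of any
compared position. Anything else is **unconfident**, and a scan yields a
CSD only when *every* charge state is present or absent and at least one
is present — so a single ambiguous envelope discards the whole scan
rather than biasing the reading. The compared positions are the envelope
prefix covering ≥ 95% of abundance (`compared_coverage`), with at least
`min_isotope_peaks` (default 2) peaks.

Two structural rules complete the scheme. Charges whose monoisotopic
m/z falls outside the acquisition window (default 300–1800) are
*unobservable*: they are excluded from the every-charge requirement
(otherwise no high-mass peptide could ever yield a reading) and carry
probability zero in the emitted CSD. And the scan set is the
identification's retention time ± `rt_window` (default 30 s), greedily
extended outward while the identified charge stays present — a
peak-shape-free operationalization of "across the elution". Per-scan
CSDs are averaged with per-scan total intensity as weight; duplicate
identifications of one peptide merge the same way. A peptide needs
`min_scans` (default 1) valid scans, else it is skipped and logged.

The exact vicinity and chimeric thresholds are package choices, exposed
in `extraction_config()`; they are set so that a noise-free rendered
envelope is recovered exactly and the simulator's injected contaminants
are rejected. Because normalization divides by the summed matched
intensity and the compared envelope prefix is identical across charge
states of one peptide, the missing envelope tail cancels exactly in the
CSD — the noiseless round trip is exact to floating-point precision,
which the test suite asserts at TV ≤ 1e-9.

Profile-mode spectra are centroided by splitting contiguous above-zero
runs at strict local intensity minima and collapsing each cluster to its
intensity-weighted mean m/z with summed intensity; vendor-centroided
mzML input bypasses this.

## Comparing CSDs and batch correction

Errors between readings of the same peptide are measured by total
variation, ½ Σ |p_k − q_k| ∈ [0, 1]. Systematic charging offsets between
runs (e.g. different flow rates) are modelled by a single parameter
β > 0 scaling each charge-state probability by β^k before
renormalization — an additive shift on the log-probability scale, linear
in charge, under which adjacent log-odds shift by exactly −log β and
zero probabilities stay zero (batch corrections therefore form a group:
β = 1 is the identity and 1/β the inverse). `fit_batch_correction()`
minimizes the summed total variation over shared peptides by
golden-section search on log β ∈ [−2, 2] (tolerance 1e-4); the objective
is piecewise-smooth, so a derivative-free bracketing search is the
appropriate tool, and since β = 1 lies in the search set the corrected
error never exceeds the uncorrected one.

## Charging regimes and monotone trends

`classify_regime()` calls a peptide *matched* when the probability at
its basic-site count is ≥ 1 − tol (tol default 1e-6, exposed),
*undercharged*/*overcharged* by the sign of mean charge minus basic-site
count otherwise; the measure-zero case of a non-concentrated CSD with
mean charge exactly equal to the count is assigned to *matched*, so the
three regimes partition any dataset. Basic-site counts above 5 are
clamped to 5 with a warning (charges above 5+ are outside the measured
axis).

Mean-charge-versus-mass trends per basic-site count use a 20-function
cubic P-spline basis with a second-order difference penalty (smoothing
weight default 5) and a hard non-decreasing constraint. Monotonicity is
enforced through non-negativity of the first differences of the spline
coefficients — a sufficient condition for monotone B-spline expansions —
and the penalized constrained least-squares problem is solved with
`mgcv::pcls()`. The smoothing-weight semantics of the original
spline-fitting conventions vary between libraries, so the parameter is
exposed; equivalence across implementations is qualitative, not
bit-level. `regime_transition_mass()` reports the smallest mass at which
the fitted curve reaches the basic-site count (the under-to-overcharging
switch), on a 512-point grid over the fitted domain, and
`observable_charges()` masks charges whose monoisotopic m/z leaves the
acquisition window.

## Intrinsic basicity

Each charging region fixes a basic-site count `b` and an adjacent
charge pair (k, k+1); the canonical regions are #2O (2, 2+/3+), #3O
(3, 3+/4+), #3U (3, 2+/3+) and #4U (4, 3+/4+), where O/U marks whether
the pair sits on the overcharging or undercharging side of `b`. Within
a region, unmodified peptides with p_k + p_{k+1} > 0 enter a regression
of the fractional target y = p_{k+1}/(p_k + p_{k+1}) on 20 residue
counts and 20 N-terminal identity indicators.

The fit minimizes Σ BCE(y_i, σ(x_i·w + w₀)) + λ‖w‖² with λ = 0.01 and
the intercept unpenalized (penalizing it would bias the charge-pair
baseline; the regularization is meant to be mild and on the features
only). Fractional targets are handled natively in the binary
cross-entropy — no expansion into pseudo-observations — which matches
the target's definition and keeps the coefficients interpretable as
log-odds contributions. The objective is convex; it is solved by damped
Newton iterations with step halving to a gradient max-norm of 1e-8.
Because the 20 N-terminal indicators sum to one, the design is exactly
collinear with the intercept: the ridge penalty resolves this at any
λ > 0, and the λ = 0 path deliberately errors on rank-deficient designs
instead of silently picking a solution. Features are not standardized
(counts and indicators share a natural unit; standardization would make
the published λ scale-dependent). No observation weighting by intensity
or abundance is applied.

A run enters cross-run comparisons only if every canonical region holds
strictly more than 100 eligible peptides with nonzero probability on
both charge states (`min_region_peptides`). Mass-adjusted basicities
are the residuals of a Huber-loss line fit (δ = 0.01) of coefficient
versus residue mass over the 17 non-basic amino acids, computed by
iteratively reweighted least squares to 1e-8; with coefficients of
order 0.1–1, δ = 0.01 makes the loss effectively L1 with a smooth core,
so the fit tracks the median mass trend and outlying amino acids keep
their full residual. Cysteine's mass includes its fixed modification by
default (`use_modified_cys_mass`), since that is the species actually
present in the data. Region-run profiles are compared by Pearson
correlation over the 17 non-basic count coefficients and clustered by
average-linkage hierarchical clustering on 1 − r with a two-cluster
cut — average linkage on correlation distance being the conventional
heatmap default; the algorithm choice is exposed.

## The synthetic generator

`generate_peptides()` draws tryptic-like sequences (C-terminal K/R, at
most two internal K/R as missed cleavages, length ≥ 7, residues at
roughly proteome-like frequencies) with masses in 700–4600 Da.
`charging_model()` defines ground-truth CSDs through adjacent log-odds:

    log(p_{k+1}/p_k) = intercept_k + mass_slope·M
                       + basic_site_effect[b]·[k+1 ≤ b]
                       + Σ residue_coefficients·counts
                       + nterm_coefficient[first residue]

normalized over charges 1–5. This generative family was chosen over,
say, a Gaussian mean-charge model so that the package's logistic
regression is *correctly specified* on synthetic data: the regression's
target is exactly σ of the model's linear predictor, making parameter
recovery a meaningful end-to-end test rather than an approximation. Two
consequences are worth noting. First, the basic-site effect applies
only on the undercharging side (k+1 ≤ b), so simulated trend curves for
different basic-site counts converge beyond their transitions — the
overcharging regime depends on mass but not on basic sites. Second,
residue and N-terminal coefficient sets differ between the two sides
(defaults: glutamine up and aspartate down on the overcharging side;
proline up and N-terminal R/K/H strongly down on the undercharging
side), so basicity profiles fitted on O-regions and U-regions form two
distinct clusters. Because peptide mass is itself linear in residue
counts, the ground-truth coefficient vector in feature space is
`residue_coefficient + mass_slope × residue_mass`; recovery tests
compare against this implied vector.

Softmax probabilities are never exactly zero, but measured CSDs are:
states below the instrument's sensitivity simply do not register. The
model therefore truncates probabilities below `min_probability`
(default 1e-3) to exact zeros and renormalizes. This both emulates that
detection reality and makes the noiseless round trip well-posed — with
strictly positive tails, a charge state whose m/z leaves the 300–1800
window would carry truth mass that no extractor could ever see.

`render_ms_run()` gives each peptide a Gaussian elution profile (FWHM
default 10 scans, apex uniform over the run, log-normal amplitude) and
writes isotope peaks per scan, charge and offset, with log-normal
intensity noise (given CV), Gaussian m/z jitter (given ppm), a hard
detection floor, window clipping and optional chimeric contaminants
(one uniform peak within the envelope span at 10–100% of the base
peak — the minimal structure that exercises the chimeric filter). The
hard floor mirrors the known limitation that intensities below the
instrument threshold are unmeasurable. Ground truth records two flags:
`observable` (every supported charge state's compared isotope peaks lie
inside the window — the peptides whose full CSD is recoverable even in
principle) and `clean` (no foreign peak, from another peptide or an
injected contaminant, intrudes into any envelope span while the peptide
elutes). Readings for observable-but-unclean peptides are legitimately
vetoed by the chimeric filter; round-trip oracles therefore assert
exactness on the observable-and-clean set.

What the simulator does **not** emulate: chromatographic tailing or
peak-shape asymmetry, ion mobility, MS2 fragmentation, correlated
(non-independent) noise across isotope peaks, electronic baseline, and
realistic peptide-abundance structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated noise model,
not performance on any particular instrument's data.

## Problem sizes and determinism

All stochastic functions accept a `seed` and are deterministic given
it; seeds are applied through an isolated RNG scope, leaving the
caller's stream untouched. The test suite exercises extraction round
trips at 30–100 peptides per run, batch-correction recovery at 150–200
peptides, coefficient recovery at 2,500–5,000 peptides per charging
region, and trend fitting at 3,000 peptides — sizes at which every
statistical check has comfortable margin while a full run of the suite
stays fast on a single CPU.

## Known limitations

- The extraction thresholds are package defaults tuned to the bundled
  simulator's noise model, not community-standard constants; real data
  may warrant different tolerances (all are exposed).
- Batch correction is global and one-parameter; per-peptide or
  multi-run joint normalization is out of scope.
- The basicity model is first-order in composition: no pairwise or
  positional interactions beyond the N-terminal indicator, so effects
  like internal proline kinks are only captured through the count term.
- CSDs conflate everything from ionization through ion transport;
  coefficients are descriptive associations, not gas-phase basicities.
- Only the four modifications listed above are supported, and charges
  above 5+ are outside the measured axis.
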