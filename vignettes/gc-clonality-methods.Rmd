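---
title: "Quantifying clonal dynamics of single germinal centers"
author: "gcClonality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clonal dynamics of single germinal centers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcClonality)
library(SummarizedExperiment)
```

# The measurement problem

Germinal centers (GCs) are transient structures in lymph nodes where B cells
proliferate, mutate their receptors and undergo affinity-based selection.
With a Confetti reporter driven from the *Aicda* promoter, each GC B cell is
stochastically and heritably committed to one of four fluorescent proteins
(mCFP, nGFP, cYFP, cRFP) or, when both alleles recombine, an unordered pair
of two distinct ones — ten observable color states in all. Because color is
heritable, the color composition of a GC tracks its clonal composition
(with the caveat that one color does not imply one clone), and repeated
imaging of the same GC turns clonal evolution into a compositional time
series.

This package implements the quantitative side of that experiment: the color
model, the per-GC clonality statistics, exponential fits of early GC
seeding, regression checks of measurement fidelity, and a PCA-based test of
synchrony between GCs of the same animal. A stochastic simulator generates
data with the same statistical structure so that every stage can be
validated against known truth.

# The color model

`enumerateColorStates()` fixes the canonical order of the ten states: the
four single-XFP states in declaration order, then the six pairs sorted
lexicographically (e.g. `"cYFP+mCFP"`). Every frequency vector, CSV column
layout and loading matrix in the package uses this order.

`RecombinationModel` collapses the biallelic biology to the cell level:
a cell is labeled with probability equal to the recombination efficiency
(default 0.475, the midpoint of the 45–50% measured for a single tamoxifen
gavage); conditional on labeling, a configurable fraction (default 0.1)
carries two distinct XFPs drawn as two independent allele draws conditioned
on distinctness. The in vivo double-label proportion is not precisely
quantified — only that it is the rarer outcome — so it is an explicit
parameter rather than an estimate. `colorStateDistribution()` gives the
induced analytic distribution over `unlabeled` plus the ten states; it is
the reference law for simulator founders and for Monte-Carlo checks.

The divergence score needs the *expected* composition under random
recombination. Empirically this is estimated from observations taken early
in the response, before selection has had any effect
(`expectedFrequenciesFromReference()`, pooling labeled counts); a uniform
fallback (`uniformExpectedFrequencies()`) and the analytic model law
(`expectedFrequenciesFromModel()`) are also available.

# Clonality statistics

All statistics operate on relative frequencies over *labeled* cells only.
Unlabeled ("dark") cells never enter the ten-vector; they act through the
occupation fraction, and observations with occupation below 50% are
discarded (`filterSparse()`, strict inequality) because such GCs are
considered to contain at least one expanded dark clone.

* **Clonal dominance** — the maximum entry of the composition; the
  frequency of the currently winning color.
* **Top-two dominance** — the sum of the two largest entries.
* **Clonal divergence score** — the L1 distance
  $D(t) = \sum_{i=1}^{10} |f_i(t) - e_i|$ between observed and expected
  compositions; 0 for a perfectly random-recombination-like GC, at most 2.
* **Meander index** — the cumulative path length of the composition
  through frequency space,
  $M(t_j) = \sum_{l \le j} \lVert f(t_l) - f(t_{l-1}) \rVert$.

The meander step norm deserves a note. Verbal descriptions of this
statistic mix three readings: a sum of squared per-color changes, the
absolute change of the divergence index, and the "integral of relative
velocities" / "distance traveled". These disagree in units and value. We
default to the Euclidean norm of the per-step frequency-change vector: it
is a true path length, consistent with both the velocity and the
distance-traveled readings, and is additive over concatenated segments.
The other readings remain available (`norm = "sq"`, `"ddiv"`, `"l1"`),
and none is asserted to be the uniquely correct historical formula. The
meander deliberately ignores the spacing of time points (observations are
taken daily or on alternating days without normalization); it is a
distance, not a rate.

**Clonal inversion events** (`detectInversions()`) formalize the
qualitative phenomenon of a winning color being supplanted by another. An
event requires (i) a change of dominant-color identity between consecutive
retained observations, (ii) the outgoing color to have reached dominance
$\ge d_{\min}$ at or before the change, and (iii) the incoming color to
reach $\ge d_{\min}$ at or after it. Consecutive changes with distinct
incoming colors are separate events, so a "double inversion" counts twice.
The threshold $d_{\min} = 0.4$ is a declared convention of this package —
the phenomenon has no numeric definition in the literature — and is
reported with every event. Ties in the dominant color are broken by
canonical state order for attribution only; the dominance *value* is
tie-free.

# Exponential seeding fits

Early GC seeding is modeled as $y(t) = y_0 e^{kt}$, fitted by nonlinear
least squares on the raw count scale (`fitExponential()`), which tolerates
zeros at early times; a log-linear regression on positive counts serves
only as the initializer. The time constant $\tau = 1/k$ and the doubling
time $\ln 2 \cdot \tau$ are derived quantities, never independently
fitted; their confidence intervals are monotone transformations of the
interval for $k$, so a growth-rate interval reaching zero yields an
infinite upper doubling-time bound. Intervals use t quantiles on $n - 2$
degrees of freedom. Residuals are unweighted by default (the conventional
homoscedastic assumption); for genuinely Poisson counts the
`weights = "poisson"` option provides variance-matched inference, and the
simulation-based recovery checks in the test suite use it, because
homoscedastic intervals undercover badly when counts span many orders of
magnitude.

Follicles are classified three ways (`classifyFollicle()`): *conforming*
(doubling time $\le$ 12 h with $R^2 \ge 0.95$), *slow* (12–15 h,
inclusive upper bound), and *non-conforming* (beyond 15 h, or a poor fit).
The 15 h boundary reconciles a verbal ">12 h" rule with reference fits
around 13 h that are explicitly regarded as reasonable; all three
thresholds are configurable and are reported with every label. Applied to
the bundled reference fits of eight longitudinally imaged follicles
(`follicleGrowthReference()`), the rule labels exactly Fo3, Fo5 and Fo8
non-conforming (3/8 = 37.5%).

# Fidelity and synchrony

`fidelityRegression()` checks that chronically window-imaged GCs measure
the same clonality as conventional explants: ordinary least squares of the
in vivo metric on the paired ex vivo metric, with a "fidelity pass" flag
when the slope's confidence interval contains 1.

For synchrony, `buildFeatureMatrix()` lays out one row per (GC × time)
observation — each observation is its own point, matching how such data
are plotted — and `runPCA()` performs column-centered, unscaled PCA (all
columns are frequencies in the same units, so variance scaling would only
inflate rare colors). Component signs follow a deterministic convention
(largest-magnitude loading positive). `testMouseAssociation()` then fits,
per component, a linear model of scores on the mouse factor plus time (and
treatment when present) and reports the mouse-factor F test and per-mouse
contrasts. Color frequencies are *not* added as covariates: they are the
features from which the components are built, so adjusting for them would
be circular; time and treatment are the confounders adjusted for. Note the
caveat that (GC × time) rows are repeated measures of the same GC, so the
test is exploratory — it detects structure, it does not assign mechanism.

# The simulator

`simulateGCTrajectory()` generates the clone-resolved process the analysis
assumes observationally:

1. **Founding.** `nFounders` cells (default 100, the scale of the few
   hundred naïve B cells known to start a GC response; the exact number is
   a fixture, not an estimate) receive heritable colors from the
   recombination model and log-fitness values from
   $\mathcal N(0, \sigma_f)$.
2. **Growth.** Fitness-weighted Poisson branching with mean factor-2
   growth per generation until the population cap (default 1500 cells).
3. **Mature phase.** Fitness-weighted multinomial resampling at exactly
   the cap each generation — a Wright–Fisher model with selection acting
   through differential survival, consistent with the evidence that death,
   not division rate, is the primary effector of GC selection. Population
   size is conserved exactly.
4. **Mutation.** Each generation, a binomial share (`mutationRate`,
   default 0.01/cell) of each clone founds a new clone with log-fitness
   perturbed by $\mathcal N(0, \sigma_m)$ — the source of late clonal
   bursts.

The generation is 6 h (the fastest fitted seeding doubling time), so the
default recording grid — alternating days from day 7 to day 19 — spans 76
generations. $\sigma_f = 0.1$ (pairwise selective differences of roughly
5–25% per generation) was chosen because it reproduces the qualitative
dynamics the statistics were designed for: heterogeneous day-7 dominance,
homogenization toward pauciclonality at widely varying rates, occasional
inversion, and occasional take-over by an unlabeled clone (the "black-out"
route to low occupation). Much stronger selection makes every GC
monochrome before the first observation; much weaker selection makes drift
at $N = 1500$ negligible on a three-week scale.

`simulateMouse()` runs several GCs in generation lockstep. With
`reentryRate > 0`, each GC each generation exports, with that probability,
its fittest clone through a shared mouse-level pool into another random GC
of the same mouse at 1% of the cap — a deliberately simple generator of
the hypothesized memory-B-cell reentry coupling. It is a hypothesis
generator, not a claim: all its parameters are exposed, and
`reentryRate = 0` yields exactly independent GCs (and, with one GC,
bit-identical output to `simulateGCTrajectory()` under the same seed).

`sampleObservation()` is the observation model: a multinomial draw of
`samplingDepth` cells (default 250, the typical manual count per GC and
time point) from the labeled composition, partitioned into `nZplanes`
(default 3) independent sub-draws mirroring counting on well-separated
z-planes with no double counting. The labeled occupation fraction is
carried along for the sparsity filter.

What the simulator does *not* emulate: spatial structure and dark/light
zone cycling, antigen-specific affinity landscapes, T-cell help, GC birth
and death, and measurement artifacts other than multinomial sampling
(e.g. color misclassification, depth-dependent signal loss). Tests passing
on synthetic data therefore validate the statistical machinery and its
contracts, not the biological fidelity of any particular parameter value.

# Numerical conventions and degenerate inputs

* Frequency vectors must sum to 1 within 1e-9; the analytic recombination
  distribution conserves mass to 1e-12.
* An observation with zero labeled counts is an error for frequency
  conversion (and is skipped with a record by the samplers).
* A constant seeding series has an exactly singular gradient for the
  nonlinear fit; the fit falls back to the log-linear solution and reports
  $k \approx 0$ with an infinite doubling time rather than failing.
* A non-positive finite $\tau$ is rejected; $k \le 0$ maps to
  $\tau = \infty$ and an infinite doubling time.
* PCA on a zero-variance matrix, association testing with one mouse, and
  fidelity regression with a constant predictor are errors, not silent
  results.
* All simulator randomness flows from the single seed argument; functions
  restore the caller's RNG state.

# Problem sizes used in validation

The test suite and the reproduction script use: 1000 random composition
pairs/series for the metric oracles; 2000 neutral Wright–Fisher replicates
at $N = 50$ over 20 generations for the heterozygosity law
$H_t = H_0 (1 - 1/N)^t$; 200 Poisson replicates of an 11-point seeding
series for growth-rate recovery ($k = 0.11\,\mathrm{h}^{-1}$); and 200
replicates of a 6-mouse, 48-observation design for association power and
permutation size. These sizes give Monte-Carlo standard errors comfortably
below the tolerances asserted, while keeping a full run in the order of a
minute.

# Known limitations

* Color clonality is a lower bound on clonal structure: distinct clones
  sharing a color are indistinguishable, so dominance overstates and
  divergence understates true clonality shifts.
* The inversion rule depends on the declared threshold $d_{\min}$;
  trajectories hovering near it can gain or lose events under small
  perturbations.
* The mouse-association model treats (GC × time) rows as exchangeable
  given covariates; with strong within-GC autocorrelation its p-values
  are anticonservative, which is acceptable for an exploratory screen but
  not for confirmatory claims.
* The simulator's reentry mechanism is one of many couplings that produce
  synchrony; detecting association does not identify the mechanism.
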