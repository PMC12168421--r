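---
title: "Methods: cosinor rhythmometry, rhythm classification and network ecology for rumen microbiome time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cosinor rhythmometry, rhythm classification and network ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenrhythm)
```

This vignette documents the models behind `rumenrhythm`, the assumptions
they make, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the methodology left them open.

## The cosinor model

Every rhythm analysis in the package rests on the fixed-period cosinor
model for a measurement $y$ observed at clock times $t$ (hours):

$$y(t) = M + A \cos\!\left(\frac{2\pi (t - \phi)}{24}\right) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2).$$

$M$ (mesor) is the rhythm-adjusted mean; $A \ge 0$ (amplitude) is half the
predictable peak-to-trough change within a cycle; $\phi \in [0, 24)$ (peak
time, acrophase) is the clock time at which the fitted rhythm attains its
maximum. The period is fixed at 24 h — the feeding cycle of the study
design — and is deliberately not estimated; period scanning
(e.g. Lomb–Scargle) is out of scope.

`fit_cosinor` estimates the model through its exact linearization
$y = M + \beta\cos\omega t + \gamma\sin\omega t$, so the least-squares
problem is linear and the optimum is global; $A = \sqrt{\beta^2+\gamma^2}$
and $\phi = (24/2\pi)\,\mathrm{atan2}(\gamma,\beta) \bmod 24$. Because the
model space is identical, the linear fit coincides with nonlinear least
squares on $(M, A, \phi)$; the test suite verifies agreement with an
independent grid-refined nonlinear optimizer to $10^{-6}$ on noiseless and
noisy fixtures.

Rhythmicity is the 2-degree-of-freedom F test of
$H_0\!: \beta = \gamma = 0$ against the intercept-only model. Two
degenerate cases are defined explicitly rather than left to 0/0
arithmetic:

* a **constant series** has no evidence of rhythm: `rhythm_p = 1`,
  amplitude 0;
* an **exactly fitted series** with non-zero amplitude (zero residual
  variance, e.g. noiseless simulations) returns `rhythm_p = 0` with
  `degenerate = TRUE`.

Sampling over multiple days is pooled modulo 24 h (the harmonic regressors
only see $t \bmod 24$), treating the two recorded days as repeated cycles.
Whether the original analyses pooled or averaged days is not stated in the
methodology this package follows; pooling retains the replicate
information and is assumed throughout. Preconditions: at least 4
observations and at least 3 distinct times modulo the period (otherwise
the design matrix is rank deficient and an error is raised).

## Mixed model and group comparison

`fit_cosinor_mixed` adds a Gaussian per-subject (cow) random intercept,
estimated by REML via `lme4`. The random structure is intercept-only — no
cow-specific amplitude or phase — the smallest structure consistent with
how the mixed comparison is used downstream, and it keeps the model at two
variance components. With balanced designs the fixed-effect estimates
coincide with OLS; when the estimated intercept variance is zero the fit
reduces to `fit_cosinor` exactly. Noiseless inputs take a deterministic
exact-fit path (sum-coded fixed-effect subjects), so the mesor is the mean
of the per-subject mesors and `subject_var` the variance of their
intercepts.

`compare_rhythms` fits one joint model in which a group indicator
interacts with the intercept and both harmonics, then tests the group
difference on the $(M, A, \phi)$ scale by the delta method on the
coefficient covariance (Wald z tests; with subjects, an `lme4` random
intercept is included and its fixed-effect covariance is used). The
peak-time difference is mapped circularly into $(-12, 12]$, with $-12$
reported as $+12$. Two numerical guards:

* when either group's amplitude is estimated at fewer than 2 standard
  errors, the acrophase is unidentifiable; `p_peak` is set to 1 and
  flagged, rather than reporting a meaningless circular test;
* when a standard error is exactly zero (noiseless limits), the p-value is
  1 for a zero estimate and 0 otherwise.

These Wald/delta-method tests are a documented substitute for the mixed
comparison tests of the original tooling, whose internal statistics are
not described in the methodology; no bit-compatibility is claimed.

### Which test screens for rhythmicity

`classify_taxa` screens each taxon's rhythmicity per group with the
*single-group* cosinor F test on the pooled cow series
(`detection = "single"`, the default), and reserves the mixed model for
the between-group parameter comparison — the same division of labour as
the methodology this package reimplements. The choice is also statistical:
the random-intercept Wald chi-square screen is anti-conservative at this
design's size (12 cows × 8 samples), rejecting more than its nominal 5% of
true nulls, while the single-group F test is exact under independent noise
and conservative when cow heterogeneity inflates the residual. A
`detection = "mixed"` option is retained.

## Classification rules

For the daytime- vs nighttime-feeding contrast (DF vs NF), with
$\alpha = 0.05$ on raw p-values (no multiplicity correction by default;
Benjamini–Hochberg is available as an option):

* **ARRHYTHMIC** — rhythmic in neither group;
* **RHYTHMIC_UNCLASSIFIED** — rhythmic in exactly one group (kept as an
  explicit label rather than silently dropped);
* **FTR** — rhythmic in both, absolute circular peak shift within
  $12 \pm 3$ h; the window endpoints 9 h and 15 h are *inclusive* ("12 ± 3"
  does not specify openness; inclusivity is the documented choice and is
  pinned by tests);
* **MFR** — rhythmic in both, shift outside that window.

For the transplantation contrast (RFT2d vs RFT7d):

* **GCR** — arrhythmic at 48 h, rhythmic at 7 days; **LCR** the reverse;
  **NEVER_RHYTHMIC** — neither;
* **CCR** — rhythmic in both and none of the mesor, amplitude, peak-time
  comparison tests significant; **InCCR** otherwise. "Pattern parameters"
  is interpreted as exactly the three reported rhythm parameters.

The rules are generic over any feature table (relative abundance,
estimated absolute abundance, pathway abundance). `summarize_classes`
reports per label the taxon count and the summed mean relative abundance
across the contrast's samples in percent of total reads.

## Quantification and fermentation

The qPCR formulas are implemented exactly as printed: standard copies
$(N_L \cdot A \cdot 10^{-9})/(660\,n)$ and total copies per mL
$(M_Q \cdot C \cdot V_D)/(S \cdot V)$; estimated absolute abundance is
total copies × relative abundance, so EAA tables conserve the per-sample
totals by construction. Standards are treated in copies/µl (a published
"mol/µl" standard concentration is dimensionally implausible and read as
copies/µl). Shannon diversity uses base 2 by default (configurable);
Chao1 uses the classic $S_{obs} + F_1^2/(2F_2)$ with the bias-corrected
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ only when $F_2 = 0$. The conventional
"Shannon = richness / Chao1 = evenness" glosses are treated as a
transposition slip; standard definitions apply. Rarefaction is provided as
a seeded utility but diversity operates on whatever counts are supplied.

$ECH_4 = 2\,\mathrm{Ac}\% - \mathrm{Pr}\% + 2\,\mathrm{Bu}\% -
\mathrm{Va}\%$ is computed from molar percentages of TVFA with the
iso-acids included in the denominator (their inclusion is not specified;
including them is the documented choice, and ECH₄ itself never involves
them).

## SparCC and the network layer

`sparcc` implements the log-ratio variance estimator for compositional
data: $T_{ij} = \mathrm{var}\log(x_i/x_j)$, basis variances solved from
$\sum_{j\ne i} T_{ij} = (D-1)\omega_i + \sum_{j\ne i}\omega_j$ under the
sparsity assumption, correlations
$r_{ij} = (\omega_i + \omega_j - T_{ij})/(2\sqrt{\omega_i\omega_j})$
clipped to $[-1, 1]$, and up to 10 rounds of excluding the most correlated
pair above 0.1 from the equations and re-solving (exclusion stops before
any taxon would drop below two included partners, which would make the
system unsolvable). Zeros are handled with a fixed pseudocount
($10^{-6}$) on relative abundances instead of Dirichlet count resampling —
a deliberate dialect, since the pipeline's inputs are relative abundances;
it makes the estimator deterministic, so the `inner_iterations` argument
(kept for interface parity with resampling variants) does not change the
result.

Bootstrap significance resamples, per replicate, **each taxon's column
independently** across samples — preserving marginals while breaking
inter-taxon association — and re-runs the estimator;
$p = (1 + \#\{|r^*| \ge |r|\})/(n_{boot}+1)$, two-sided with a
$1/(n_{boot}+1)$ floor. (Resampling whole samples jointly would preserve
the very associations being tested and could never rank an observed
correlation against a null.) Networks keep edges with $|r| > 0.3$
*strictly* and $p < 0.05$ strictly; isolated nodes are retained.

Node features use unweighted shortest paths: betweenness excludes
endpoints, closeness is computed within each connected component as
$(n_{comp}-1)/\sum d$ with closeness 0 for isolated nodes, and weighted
degree is $\sum |r|$ over incident edges. Module detection is greedy
modularity maximization on absolute weights (deterministic); when the
greedy partition has $Q \le 0$ (e.g. complete graphs) the trivial
single-module partition is returned instead. Zi/Pi follow their standard
definitions with degenerate guards ($Z_i = 0$ when the module's
within-degree spread is zero, $P_i = 0$ for isolated nodes), and role
thresholds are strict inequalities (network hub: $Z_i > 2.5, P_i > 0.62$;
module hub: $Z_i > 2.5$ only; connector: $P_i > 0.62$ only; peripheral
otherwise) so boundary values fall on the non-hub side.

Levins' niche breadth $B_j = 1/\sum_i P_{ij}^2$ uses as $P_{ij}$ the share
of taxon $j$'s abundance (mean over each community's samples) found in
community $i$, so $1 \le B_j \le N$. The Mantel test correlates
off-diagonal distances (Spearman by default, Bray–Curtis distances by
default — both configurable, as the original choices are unstated) and
permutes sample labels of one matrix; the p-value is two-sided on $|r|$
with the $(1+\#)/(n+1)$ convention. Whether networks are built from
relative or estimated absolute abundance is configurable; relative
abundance is the default input.

## The synthetic-study generator

`generate_study` emulates the study design: cows sampled every 6 h at
clock times {2, 8, 14, 20} on 2 consecutive days (8 samples per cow per
group), 12 cows, groups among ALF/DF/NF/RFT2d/RFT7d, one or more kingdoms.
Per taxon and group, a latent log-abundance cosinor signal plus a per-cow
Gaussian random intercept plus i.i.d. Gaussian noise is generated, and
relative abundances are produced by softmax-style closure within each
sample. Class semantics are imposed on the latent parameters: FTR taxa
shift their peak by exactly +12 h from DF to NF; MFR taxa by a 3–6 h draw
(outside the 12 ± 3 h window); GCR/LCR taxa switch rhythmicity between
RFT2d and RFT7d; InCCR taxa change amplitude (×1.6) and peak (+6 h).
The study is a pure function of the design's seed.

Default magnitudes, chosen once as realistic for rumen relative-abundance
rhythms and used by all recovery tests: latent amplitude
$\sim U(0.3, 0.5)$ on the log scale (about 1.8–2.7× peak-to-trough fold
change), mesor spread $N(0, 0.75)$ across taxa (roughly 1.5 orders of
magnitude of abundance), cow-intercept sd 0.3, observation noise sd 0.1 —
one quarter of the mean amplitude, the noise condition under which
classification recovery is assessed. The within-taxon noise model is not
stated by the methodology this package follows; Gaussian noise on the log
scale is a modeling choice, flagged as such.

**Phase balancing and compositional closure.** Rhythmic taxa are generated
in anti-phase pairs of matched mesor and amplitude (peaks 12 h apart), so
the latent community total carries no 24-h harmonic. This matters because
closure divides every taxon by the community total: an unbalanced
community would impose an apparent anti-phase rhythm on every
ground-truth-arrhythmic taxon — with an induced-signal-to-noise ratio that
is *independent of the amplitude scale* — and the recorded truth labels
would simply be false for the generated relative abundances. With balanced
phases the denominator retains only even harmonics, which are orthogonal
to the 24-h fit on the equispaced 6-h grid, so arrhythmic truth survives
closure. The diurnal rhythm of total microbial load is carried separately
and explicitly by the qPCR layer (a log-scale cosinor peaking at 19:00,
matching rhythmic population observations). Setting
`balance_phases = FALSE` deliberately exposes the closure artifact, which
is worth simulating in its own right.

One residual closure effect remains even with balanced phases: in the
exact noiseless limit, if the *set* of rhythmic taxa differs between two
groups (say a GCR + CCR mix between RFT2d and RFT7d), the closed-scale
mesor of a CCR taxon differs between groups by a small but exact amount,
so "no parameter difference" is literally false on the relative scale and
the comparison correctly flags InCCR. Exact-recovery tests therefore use
mixes whose closed-scale truth is well-defined; at the default noise level
this effect is far below the comparison's resolution and mixed CCR/InCCR
cohorts are recovered in full.

What the generator does **not** emulate: sequencing (no reads, ASVs,
rarefaction depths or taxonomy), phylogeny, overdispersed count noise,
cow-specific phases or amplitudes, day-to-day parameter drift, and any
dependence structure among taxa beyond closure. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimators and
rules under the stated model, not robustness to every feature of real
amplicon data.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to run on
a single CPU in a few minutes: 1000 null series for type-I calibration, 50
fixtures for the nonlinear-oracle comparison, 200 Monte-Carlo replicates
for mixed-model recovery and comparison power, 100-taxon studies for
classification recovery, 5 taxa × 500 samples for SparCC checks, and a
reduced end-to-end pipeline (16 taxa, 2 kingdoms, 30 bootstrap replicates,
99 Mantel permutations) for the determinism check. One master seed drives
every stochastic stage through derived substreams; re-running the pipeline
with the same configuration reproduces byte-identical outputs, which the
manifest's checksums make easy to verify.

## Known limitations

* Single-harmonic, fixed-period cosinor only; no autocorrelated-error
  variants (the original nested autoregressive mixed models are out of
  scope).
* Wald/delta-method comparison inference is asymptotic; with 8 distinct
  design points per group and small amplitude-to-noise ratios the
  peak-time test relies on the amplitude-identifiability guard.
* SparCC assumes a sparse basis correlation structure; with few taxa
  (the minimum is 5) estimates are approximate, which is why recovery is
  validated against planted correlations rather than asserted exactly.
* The bootstrap p floor means no pair can be reported below
  $1/(n_{boot}+1)$; with the conventional 100 replicates that floor is
  ~0.0099, which is adequate for the 0.05 edge filter but not for
  multiplicity-corrected inference.
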