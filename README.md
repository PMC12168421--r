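# rumenrhythm

Circadian rhythm analysis of rumen microbiome time series.

The rumen microbiome oscillates through the daily feeding cycle: the
populations and relative abundances of bacteria, archaea and protozoa, the
fermentation end products (VFAs, pH, ammonia), and even community assembly
rise and fall over 24 h. `rumenrhythm` implements, as a tested and reusable
R pipeline, the analysis framework used to characterise these oscillations
in dairy-cow time-series studies where rumen fluid is sampled every 6 h over
48-h cycles under different feeding regimes (ad libitum, daytime-restricted,
nighttime-restricted) and after rumen fluid transplantation. It is aimed at
rumen/gut microbiome researchers who have taxon abundance tables, qPCR
loads and fermentation measurements on a within-day sampling grid and want
rhythm detection, rhythm-response classification and network ecology in one
place — together with a synthetic-study generator with known ground truth,
so that every stage can be validated without any sequencing data.

## What it computes

**Cosinor rhythmometry.** Each series is fit to the fixed-period cosinor
model

    y(t) = M + A·cos(2π(t − φ)/24) + ε

by OLS on its linearization `y = M + β·cos(ωt) + γ·sin(ωt)` with
`A = √(β² + γ²)` and peak time `φ = (24/2π)·atan2(γ, β) mod 24`. The mesor
`M` is the rhythm-adjusted mean, the amplitude `A` half the predictable
peak-to-trough change, and `φ` the clock time of the fitted maximum.
Rhythmicity is the 2-df F test of `β = γ = 0` (`fit_cosinor`); a per-cow
random intercept version is available via REML (`fit_cosinor_mixed`), and
`compare_rhythms` tests between-group differences in (mesor, amplitude,
peak) with delta-method Wald tests on a joint interaction model.

**Rhythm-response classification.** For the daytime- vs nighttime-feeding
contrast, taxa rhythmic in both groups (p < 0.05) are *feeding-time
responsive* (FTR) when the peak shift lies within 12 ± 3 h and
*multi-factor responsive* (MFR) otherwise. For the 48-h vs 7-day
post-transplantation contrast, taxa are classified as *consistent* (CCR),
*inconsistent* (InCCR), *gained* (GCR) or *lost* (LCR) circadian rhythm
(`classify_taxa`, `summarize_classes`).

**Quantification.** qPCR standard-curve copies `(N_L·A·10⁻⁹)/(660·n)`,
total copies per mL `(M_Q·C·V_D)/(S·V)`, estimated absolute abundance
(total copies × relative abundance), Shannon and Chao1 diversity.

**Fermentation.** VFA molar percentages of TVFA, the acetate:propionate
ratio, and the estimated methane statistic
`ECH₄ = 2·Acetate% − Propionate% + 2·Butyrate% − Valerate%`.

**Network ecology.** A from-scratch SparCC estimator (log-ratio variances,
basis-variance system, iterative exclusion of strongly correlated pairs)
with bootstrap significance; signed networks thresholded at |r| > 0.3 and
p < 0.05; degree/weighted degree/closeness/betweenness; greedy-modularity
modules; within-module (Zi) and among-module (Pi) connectivity with the
peripheral/connector/module-hub/network-hub roles (thresholds 2.5 / 0.62);
Levins' niche breadth `B_j = 1/Σᵢ P²ᵢⱼ`; Bray–Curtis distances and a
permutation Mantel test.

**Synthetic studies.** `generate_study` simulates the full design (cows ×
clock times × days × groups × kingdoms) with cosinor-structured latent
log-abundances, per-cow intercepts, compositional closure, rhythmic qPCR
loads and cosinor-structured fermentation series, recording the exact
ground-truth parameters and class of every taxon.

## Worked example

```r
library(rumenrhythm)

## a rhythmic series: 12 cows sampled every 6 h over 2 days
t <- rep(seq(0, 42, by = 6), 12)
set.seed(42)
y <- 8.2 + 1.9 * cos(2 * pi * (t - 18) / 24) + rnorm(length(t), 0, 0.6)
fit_cosinor(y, t)
#> Cosinor fit (period 24 h)
#>   mesor 8.232  amplitude 1.978  peak 18.33 h  rhythm p 8.1e-38
#>   n = 96  residual sd 0.6187  subject var 0
```

The fit recovers the simulated rhythm: mean level ≈ 8.2, about ±2 units of
predictable daily change, peaking shortly after 18:00, with overwhelming
evidence of rhythmicity.

```r
## a synthetic feeding-restriction study with known truth
design <- study_design(n_cows = 12, groups = c("DF", "NF"),
                       n_taxa = 40, seed = 1)
study  <- generate_study(design, c(FTR = 20, MFR = 6, ARRHYTHMIC = 14))
classes <- classify_taxa(study$abundance$bacteria, study$metadata,
                         contrast = "DF_vs_NF")
summarize_classes(classes, study$abundance$bacteria)
#>                   label n_taxa mean_abundance_pct
#> 1                   FTR     20           50.36681
#> 2                   MFR      6           17.33463
#> 3 RHYTHMIC_UNCLASSIFIED      0            0.00000
#> 4            ARRHYTHMIC     14           32.29857
```

All 40 planted labels are recovered; the summary reports, per class, the
taxon count and the summed mean relative abundance in percent of total
reads — the same currency in which class proportions are reported in rumen
rhythm studies.

`run_pipeline(default_pipeline_config(seed = 1))` runs every stage
end-to-end (simulate → classify → quantify → ferment → network → Mantel)
and writes all stage TSVs plus a manifest with output checksums.

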