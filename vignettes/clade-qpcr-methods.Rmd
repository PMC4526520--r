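---
title: "Methods: clade-resolved qRT-PCR quantification of photosynthetic gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade-resolved qRT-PCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeqpcr)
```

## The problem this package addresses

*Prochlorococcus*, the most abundant photosynthetic organism in the
oligotrophic oceans, comprises high-light (HL) and low-light (LL)
adapted ecotypes that stratify vertically in the water column. A
clade-resolved qRT-PCR assay targets three genes per ecotype with
separate HL and LL primer sets: *rnpB* (RNase P RNA, the stable
reference), *rbcL* (RuBisCO large subunit, a proxy for carbon-fixation
capacity) and *psbA* (photosystem II D1 protein, a proxy for PSII
content). From crossing points (Cp) and amplicon melting temperatures
(Tm), the pipeline quantifies relative expression by depth, the HL/LL
composition of a community, *Synechococcus* cross-amplification, and
treatment effects in pollutant-exposure experiments.

This vignette documents the models, the numerical choices and the
reasoning behind the defaults. Every empirical statement here is also
computed by the test suite or by `scripts/acceptance.R`; nothing is
asserted that the code does not reproduce.

## Quantification model

Cp values relate to initial template copies through
$N_0 = k\,(1+E)^{-Cp}$, with $E$ the amplification efficiency and $k$
an instrument detection constant. Since $k$ never cancels out of an
absolute quantity, the package emits only relative measures, where $k$
cancels exactly:

* **delta-Cp**: $\Delta Cp = Cp_{ref} - Cp_{tg}$, with *rnpB* as
  reference; relative expression is $2^{\Delta Cp}$.
* **fold change** between conditions $a$ and $b$:
  $2^{\Delta Cp_a - \Delta Cp_b}$. A 10-cycle offset is a ~1000-fold
  copy difference ($2^{10} = 1024$), a 5-cycle offset ~30-fold
  ($2^5 = 32$).
* **rbcL/psbA ratio**: $2^{\Delta Cp_{rbcL} - \Delta Cp_{psbA}}$.
* **HL clade fraction**: treating the per-clade *rnpB* signal as a
  census of metabolically active cells,
  $r = 2^{\,Cp_{LL} - Cp_{HL}}$ and $f_{HL} = r/(1+r)$. This assumes
  equal per-cell *rnpB* expression and equal primer efficiency across
  clades; both assumptions are surfaced as flags on the output, and a
  generalized $(1+E)^{\Delta Cp}$ form is available for unequal
  efficiencies.

Base-2 exponentiation is the default throughout because assays are
accepted only within the 95--105% efficiency window, where the error
from assuming perfect doubling is smaller than replicate noise.

Applied to the packaged survey Cp summary table (six primer sets at
three depth classes across a 62-station, three-ocean survey), these
identities give the headline figures: HL fractions of 97% at 3 m, 6%
at the deep chlorophyll maximum (DCM) and 2% at DCM+40 m; HL *rbcL*
and *psbA* roughly 5x and 3x more abundant at the surface than at
DCM+40; LL *rbcL* about 3x more abundant at depth than at the surface:

```{r report}
tab <- read_cp_summary(system.file("extdata", "survey_cp_summary.csv",
                                   package = "cladeqpcr"))
survey_report(tab)
```

A note on the clade fractions: they are computed from the per-depth
*mean* Cp values, not as the mean of per-sample fractions. The former
is what a summary table permits and is what the headline percentages
correspond to; with per-sample data the package computes per-sample
fractions too (`quantify_samples()`).

## Cp calling by second-derivative maximum

Instrument firmware reports Cp as the cycle at which the second
derivative of the amplification curve peaks, but does not document its
numerics. The package's caller is:

1. **Baseline**: linear fit over early cycles (default 3--12),
   subtracted.
2. **Smoothing**: Savitzky--Golay local least-squares polynomial,
   window 7 cycles, degree 4. Degree 3 was rejected after measurement:
   on noiseless model curves a cubic window-7 smoother biases the
   called Cp by ~0.4 cycles because the sigmoid toe has strong
   fourth-derivative content, while degree 4 preserves it (bias
   < 0.08 cycles).
3. **Differentiation**: fourth-order five-point central stencil
   $(-f_{i-2} + 16 f_{i-1} - 30 f_i + 16 f_{i+1} - f_{i+2})/12$. The
   plain three-point second difference leaves a phase-dependent
   argmax shift of ~0.06 cycles; the higher-order stencil reduces the
   total error below 0.04 cycles before smoothing.
4. **Sub-cycle refinement**: the discrete second-derivative sequence
   is interpolated with a cubic spline and the maximum located on a
   0.001-cycle grid within two cycles of the discrete maximum. This
   outperformed a three-point quadratic refinement, whose bias varies
   with the fractional phase of the true crossing and breaks the
   0.05-cycle template-spacing check at non-integer log2 ratios.

Curves whose baseline-corrected signal never exceeds `min_signal`
(default 1 RFU; RFU scales are instrument-arbitrary) are censored as
`no_amplification`. Calls at cycle 40 or later are flagged `late_cp`
but retained, because weak LL signals in surface samples are still
quantified rather than discarded. All window/threshold choices are
arguments of `call_cp()`.

**Replicate QC**: all samples run in duplicate; `merge_replicates()`
keeps the arithmetic mean Cp when the duplicates differ by less than
0.25 cycles, and otherwise reports no merged value with a
`replicate_disagreement` flag. (At sub-0.25-cycle agreement the
difference between averaging Cp and averaging copies is negligible.)

**Efficiency**: the cited firmware method is not reproducible, so the
standard-curve formulation is used --- the least-squares slope of Cp on
log10 dilution gives $E = 10^{-1/slope} - 1$, the scale on which the
95--105% acceptance window is expressed. Because the window is stated
in whole percent, the acceptance comparison is made at whole-percent
resolution.

## The synthetic signal generator

The generator exists so that every downstream stage can be tested
against known ground truth without instrument exports.

**Amplification** follows logistic growth sampled at integer cycles,
$N(c) = K/(1 + A e^{-c\,\ln(1+E_0)})$ with $A = (K-N_0)/N_0$: a
sigmoid whose exponential phase is exactly $N_0 (1+E_0)^c$. The closed
form was chosen over iterating the discrete logistic recurrence
because it is exactly shift-equivariant in $\log N_0$ --- a $d$-fold
template change shifts the whole curve by $\log_2 d / \log_2(1+E_0)$
cycles --- and its second-derivative maximum has a closed form (at
copy fraction $N/K = (3-\sqrt3)/6$, exposed as `analytic_cp()`). The
iterated map is not time-shift invariant and misses the spacing law by
up to 0.09 cycles at $E_0 = 1$, which would confound caller validation
with generator artefacts. Defaults (plateau $10^{12}$ copies,
$10^{-11}$ RFU/copy, baseline 0.4 + 0.002c RFU, noise sd 0.005 RFU)
put plateaus near 10 RFU and Cp values in the observed 15--32 range.

**Melt curves** sum two-state duplex-fraction sigmoids
$1/(1+e^{(T-Tm)/w})$ per amplicon species over a 65--95 °C grid
(0.1 °C default spacing) plus a monotone linear background; the
noiseless $-dF/dT$ peaks exactly at each Tm with height
amplitude$/(4w)$. The default transition half-width is **0.5 °C**, not
wider: with $w = 0.7$ two equal components 2.0 °C apart sum to a
single maximum (the sech² bumps fuse), whereas melt analysis of this
assay must resolve the *Prochlorococcus*-vs-*Synechococcus* Tm gap
down to ~2 °C; $w = 0.5$ leaves a ~22% relative dip at that
separation and gives derivative peaks of ~1.8 °C full width at half
maximum, typical of dye-based amplicon melts.

**Survey simulation** draws per-sample latent Cp values from the
per-depth summary Normals (truncated to (0, 45]), adds duplicate
technical replicates (sd 0.06 cycles, so duplicates essentially always
pass the 0.25-cycle rule), and draws rbcL-LL melt identities from
*Prochlorococcus*-like (81--86 °C) or *Synechococcus*-like (88--89 °C)
Tm windows with a per-depth mixture fraction (default: half the
surface samples *Synechococcus*-like, none at depth, mirroring the
observed surface predominance of cross-amplification). Cp-level
simulation is the default for speed; full curve-level signals are
available through `simulate_amplification()`.

**Exposure simulation** generates the 2 strains x 2 pollutant
mixtures x 2 times x 3 replicate-pairs factorial: control
$\Delta Cp$ per gene (between-flask sd 0.3 cycles), treatment
$\Delta Cp$ = control + log2(true fold) + noise (sd 0.7 cycles,
consistent with a ~0.4 sd on fold ratios near 0.8). Default true
effects are 0.82 for *rbcL* and 1.09 for *psbA* --- the effect sizes
the assay is designed to detect. Cell-specific effects (for injecting
interactions) are supplied as a data frame.

What the generator deliberately does **not** emulate: sequence-level
thermodynamics (no primers, no Tm-from-sequence), inhibitor kinetics,
probe chemistries other than intercalating dye, heteroscedastic
instrument noise, or inter-run batch effects. Passing tests therefore
demonstrate correctness of the *algorithms* under a clean mechanistic
signal model, not robustness to every artefact of real exports.

## Melt peak calling and taxon classification

`derivative_profile()` returns the Savitzky--Golay smoothed
$-dF/dT$ (window 7 points, degree 3) with half-window endpoints
trimmed. `call_peaks()` keeps local maxima whose topographic
prominence is at least 10% of the tallest peak's height and merges
maxima closer than 1.0 °C (keeping the taller, ties toward lower Tm);
the tallest surviving peak is the *major* peak. The 10% relative
prominence rule and the tie-break are declared choices --- no published
peak-acceptance rule exists for this assay. Profiles with negligible
dynamic range are classed `none`.

With the defaults, equal-amplitude components are resolved as `double`
whenever their separation is >= 2.0 °C and merged to a `single` call at
<= 0.3 °C; single-component Tm is recovered within 0.2 °C (noiseless)
across 70--94 °C and widths 0.4--1.2 °C.

Only the rbcL-LL primer set discriminates genera by Tm.
`tm_windows()` assigns *Prochlorococcus* in [81, 86] °C and
*Synechococcus* in [87.5, 90] °C, leaving 86--87.5 °C as an explicit
ambiguous buffer: the source ranges (81--86 vs 88--89 °C) are
observations, not decision boundaries, so the *Synechococcus* window
is widened symmetrically while keeping the windows disjoint. A double
profile with one peak in each window is reported as `ambiguous` with
both taxon flags --- mixed presence --- rather than forced to the major
peak. HL primer sets are non-discriminative by default: their Tm
variation reflects within-genus strain variation, not genus identity.
The single-peak-only quantification rule is enforced downstream by
`apply_quant_filters()` as an `included` flag with a recorded reason;
records are never silently dropped.

`heterogeneity_summary()` reports, per target and group, the
major-peak Tm mean ± sd, the percentage of profiles with >= 2 peaks,
and the percentage of major peaks further than 2 group-sd from the
group mean (e.g. 16 double-peaked profiles among 61 surface samples =
26.2%).

## Statistical contrasts

* **Depth contrasts** (`depth_anova()`): one-way ANOVA of relative
  expression across depth classes per gene x clade, with
  Lilliefors-corrected Kolmogorov--Smirnov normality checks (the
  estimated-parameter form of the KS test), Tukey HSD post-hoc
  comparisons, and a compact letter display assigned by greedy
  insertion over the sorted means --- deterministic, ties toward the
  lower mean; groups share a letter iff their adjusted p exceeds 0.05.
  The response is the raw relative expression by default with a log2
  option.
* **Paired tests** (`paired_ratio_test()`): paired t-test on
  treatment-minus-control $\Delta Cp$ differences; reported with the
  arithmetic mean ± sd of per-pair fold ratios (the conventional
  tabulated quantity) *and* the geometric mean fold
  $2^{\overline{\Delta\Delta Cp}}$ with its t-based 95% CI. The
  geometric form is the unbiased estimator of a multiplicative effect
  under log-normal noise --- with noise sd 0.7 cycles the arithmetic
  mean of ratios overshoots a true 0.82 effect by ~10%, which is an
  estimator property, not an implementation error.
* **Factorial GLM** (`exposure_glm()`): three-way fixed-effects ANOVA
  of the fold-change response on Treatment, Strain and Time with all
  interactions (1 df each on the two-level balanced design, where term
  F values are invariant to factor ordering). The raw fold change is
  the default response to match the conventional table semantics; a
  log2 option provides the variance-stabilized alternative. With
  unbalanced data the sequential (type I) sums-of-squares convention
  is recorded in the result's metadata.
* **Nonparametric** (`paired_wilcoxon()`): paired signed-rank test;
  an all-tied input returns p = 1 by convention (no evidence of a
  shift in either direction).

Under seeded nulls (500 replicates), the paired t, the depth ANOVA
and the GLM terms all reject at rates within [0.03, 0.07] at
$\alpha = 0.05$ --- checked by the test suite at these exact settings.
No multiple-testing correction is applied beyond Tukey HSD, matching
the analysis design the package reproduces.

## Problem sizes and degenerate inputs

The test suite and acceptance script run entirely on synthetic data:
caller validation over a 3 x 6 grid of efficiency x template, 500-rep
null calibrations with 24 observations per replicate, power checks at
50 pairs per design cell, and a 200-pair effect-recovery check. These
sizes were chosen so each statistical property is measured with
adequate Monte-Carlo precision (a calibrated 5% rate estimated from
500 reps has a standard error of ~1%).

Degenerate inputs are handled explicitly rather than by crashing:
no-template curves censor; constant ANOVA/GLM responses return zero F
statistics flagged degenerate; empty design cells raise an error
naming the cell; groups too small for a sd are skipped with a message;
censored Cp values propagate as undefined quantities with flags.

## Known limitations

* Absolute copy numbers are out of reach by design ($k$ is never
  resolved); all outputs are relative.
* Clade fractions inherit the equal-efficiency and equal-per-cell
  reference-expression assumptions; they are flags, not corrections.
* The Tm windows are fixed decision boundaries fitted to one assay;
  other primer systems need their own `tm_windows()` configuration.
* The generator's homoscedastic Gaussian noise and two-state melt
  model are idealizations; saturating-dye artefacts and
  high-resolution-melt clustering are explicitly out of scope.
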