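---
title: "Models and methods: somatic variation and ageing endophenotypes from blood WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: somatic variation and ageing endophenotypes from blood WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgsage)
```

This vignette is the package's own account of the science it implements:
the statistical models, their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-data generators do
and do not emulate, and the numerical choices made where the design was
genuinely open. No empirical claim here goes beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## 1. Dynamic-threshold somatic SNV detection

At a reference-homozygous locus sequenced to depth $n$, alternate reads
arise from machine error at rate $\varepsilon$ per read. At a
heterozygous locus the alternate-read probability is
$\tfrac12 + \tfrac{\varepsilon}{3}$ (half the reads come from the
alternate chromatid; errors redistribute a small excess toward it). A
somatic clone at variant allele fraction $f$ yields alternate reads with
probability $p_A = (1 - \tfrac43\varepsilon) f + \varepsilon$. A locus is
called somatic when $c_E \le n_A \le c_H$: enough alternate reads that
error is implausible, few enough that a poorly sampled heterozygote is
implausible.

The thresholds are chosen *per depth* to maximise the somatic detection
sensitivity
$$p_n = r_{RR} \sum_{n_A = c_E}^{c_H} \binom{n}{n_A} p_A^{n_A} (1 - p_A)^{n - n_A},
\qquad r_{RR} = \tfrac12\!\left(1 - r_H + \sqrt{1 - 2 r_H}\right),$$
subject to the signal-to-noise constraint
$$\frac{r_C}{1 - r_C}\,\frac{p_n}{r_{RR}\,\alpha_E + r_H\,\alpha_H} \ge g_r,$$
with $\alpha_E = \Pr(\text{err} \ge c_E)$ (upper binomial tail at
$\varepsilon$) and $\alpha_H = \Pr(\text{het} \le c_H)$ (lower tail at
$\tfrac12 + \tfrac{\varepsilon}{3}$). Defaults: $g_r = 5$, $f = 0.2$,
$\varepsilon = 2\times10^{-3}$, $r_H = 10^{-4}$, $r_C = 5\times10^{-7}$ —
a parameterisation tuned for sensitivity at standard ~38x depth. The
"$\binom{n}{n_A}$" terms are binomial coefficients; all tails are
evaluated in log space through `pbinom`. `optimal_thresholds()`
enumerates every integer pair $0 \le c_E \le c_H \le n$ exhaustively
(there are at most 5253 at the 101-read pileup depth cap), so the
reported optimum is exact; ties in $p_n$ break to the smallest $c_E$,
then the largest $c_H$, making the output deterministic. The search
order is otherwise immaterial because the optimum is found by complete
enumeration.

```{r thresholds}
threshold_table(somatic_params(), max_depth = 45L)[38:45, ]
```

Depths too shallow for any pair to meet the constraint (here $n < 14$)
are *infeasible*: $p_n = 0$ and no call is ever made. This is the
designed behaviour, not a failure mode — sensitivity is simply zero
where noise cannot be controlled.

**Sensitivity normalisation.** Burden in each of the 96 trinucleotide
substitution classes (pyrimidine-reference convention,
`mutation_classes96()`) is the call count divided by $\sum p_n$ over all
loci of that class, making samples with different depth profiles
comparable. The $r_{RR}$ prefactor is kept inside $p_n$ as printed; a
`drop_prefactor` switch divides it out for users who want sensitivity
conditional on a reference-homozygous locus — at $r_H = 10^{-4}$ the
difference is 0.01%, so the choice is cosmetic, and the default follows
the printed formula. Classes whose total sensitivity is zero are
returned as `NA` (flagged missing) and imputed as zero burden by the
factorisation step, a conservative choice for a burden measure.

## 2. Signature factorisation and cardinality selection

The class-by-sample burden matrix is denoised by non-negative matrix
factorisation under Frobenius loss with Lee–Seung multiplicative
updates, best of 100 random restarts. Explained variance is defined as
$1 - \|M - WH\|_F^2 / \|M - \bar M\|_F^2$ with a grand-mean-centred
denominator (a raw-denominator switch exists); the definition is stated
here because reasonable alternatives differ and the cardinality scan
depends on it.

Cardinality is selected on a reduced matrix: samples sorted by age,
groups of 16 consecutive samples summed per class (a remainder group
smaller than 16 merges into the last group). Age-grouping is what makes
the scan work: signature activities vary systematically with age, so
summing age-neighbours suppresses Poisson noise while preserving the
rank structure. "The lowest cardinality giving an inflection point" is
operationalised as the smallest $k$ (scanned over 2–10, with $k = 1$
fitted to anchor the curve) at which the curve has flattened: the next
marginal gain collapses to less than a fifth of the gain that reached
$k$, or the curve is already flat there; a constant matrix degenerates
to the scan floor $k = 2$, and a curve with no collapse falls back to
the largest second difference. The relative rule matters: an
absolute-drop (second-difference) rule fires at whatever single step is
largest, which on curves that are still steep before the elbow
systematically lands one short of the true rank — on planted rank-3
cohorts it identifies the first split rather than the flattening point
whenever the first component dominates. The fivefold margin sits far
from both regimes observed on such curves (pre-elbow gain ratios around
0.4, post-elbow around 0.03). A manual override (`k_override`) is
available. The iteration budget (500, tolerance $10^{-7}$
relative per 10 iterations) matters: multiplicative updates plateau, so
per-sample scores are only determined up to the plateau; matched
signature profiles and reconstructions are stable, and the tests assert
exactly those.

## 3. Subclonal copy-number model

One genetically homogeneous aneuploid subclone at cell fraction $f$ on a
diploid background gives chromatid mean ploidies $p_j = f k_j + (1-f)$.
With unphased reference/alternate depths the chromatid identity of each
allele is unknown, so each het locus contributes a phase-symmetric
mixture
$$\tfrac12\,\mathrm{NB}(d_R; c_i p_1, s)\,\mathrm{NB}(d_A; c_i p_2, s) +
  \tfrac12\,\mathrm{NB}(d_R; c_i p_2, s)\,\mathrm{NB}(d_A; c_i p_1, s),$$
negative binomial with mean–size parameterisation ($q = s/(s+\mu)$) and
a per-sample dispersion $s$. The half-depth normaliser is
$c_i = b_i e^{h(g_i)} \bar d/2$: a cohort baseline $b_i$, a
sample-specific GC correction $h$ (penalised smooths of the five
principal components of the GC-fraction matrix over 100–800 bp windows,
fitted by `mgcv::gam`; estimated on at most 10,000 evenly spaced loci
for speed and evaluated everywhere — the smooth is low-dimensional so
this changes nothing material), and the sample mean depth.

**Numerical choices.**

* *Normaliser robustness.* The sample-mean normalisation is itself
  biased by any aneuploid segment (a deleted chromosome lowers the mean
  it is normalised against). Two corrections are applied: $c$ is
  pre-scaled by the median observed/expected depth ratio (robust to an
  aneuploid minority of loci), and after the best fit a recalibration
  pass rescales $c$ by the likelihood-weighted observed/expected ratio
  and re-polishes $(f, s)$, accepted only if the log-likelihood does not
  decrease. Without these, a few percent of global scale error lets a
  compensating "pseudo-split" solution (diploid segments assigned
  $(1,2)$ at a small spurious $f$) overtake the truth — a real
  identifiability cliff of this model family that users analysing
  samples with very large aneuploid fractions should know about. The
  corrections hold the estimator accurate up to roughly 12–15% of loci
  being aneuploid, i.e. beyond a chromosome-arm-scale event.
* *Segmentation.* Initial blocks of 100 het loci (a sub-50 remainder
  joins the previous block; a contig with fewer than 100 loci is one
  segment); adjacent segments merge greedily while any phase-symmetric
  two-sample KS p-value is $\ge 0.01$, never across contigs. The KS
  comparison of the unordered pair $(d_R/c, d_A/c)$ is not defined by a
  standard bivariate test, so it is implemented as two 1-D rank-based KS
  tests — on the per-locus minima and maxima — combined by taking twice
  the smaller p-value (Bonferroni), which is phase-symmetric and
  well-defined with integer ties. Note that the 0.01 stop threshold
  implies a few hundred boundary tests per genome, so one or two
  spurious ~100-locus segments per sample are *expected*; they carry a
  selection bias (retained precisely for looking unusual) and are
  occasionally assigned a non-diploid pair. They do not move $f$
  materially and cannot create a CHIP flag on a null sample, but
  segment lists should be read with this in mind.
* *Optimisation.* $f$ on a grid $0, 0.01, \ldots, 0.5$ with local
  polish; $f \le 0.5$ because the model assumes a diploid majority. $s$
  starts from a median-of-segments moment estimate (segment-level mean
  correction keeps aneuploid segments from deflating it) and is polished
  on a log scale in $[1, 1000]$; if the polished $s$ moves more than 10%
  from its start, the $f$ grid is re-scanned at the new dispersion —
  the location of the global basin in $f$ can depend on $s$.
* *BIC over the ploidy cap.* Parameters are counted as $f$, $s$, plus 2
  per pre-merge segment. That count is identical for every candidate
  $k_{\max}$, so BIC minimisation reduces to comparing profile
  log-likelihoods, with ties (smaller caps reaching the same optimum)
  resolved to the smallest $k_{\max}$; only the winner is polished.
  After fitting, adjacent segments with identical ploidies merge, and a
  fully diploid fit reports $f = 0$ by convention ($f$ is
  unidentifiable without an aneuploid segment).

The CHIP-by-CNV flag requires at least one non-diploid segment *and*
$f \ge 0.10$.

## 4. Mitochondrial and Y metrics

Copies per nucleus: $2\,(R_T/S_T)/(R_A/S_A)$ for target contig set $T$
against autosomes, from mapped read counts as reported (no duplicate
correction; patch contigs excluded by the reader's contig filter). The
heteroplasmy quality score is
$q = -10\log_{10}(1 - F(n; p, N))$ with $F$ the binomial CDF and a fixed,
deliberately conservative error estimate $p = 0.0025$; "$1 - F(n)$" is
read literally as $\Pr(X > n)$ (an `inclusive` switch gives
$\Pr(X \ge n)$), the tail is evaluated in log space, and underflow is
capped at the documented sentinel $q = 990$. The burden filter cascade —
$n_{alt} \ge 10$, allele fraction $\ge 0.001$, $q \ge 30$, strand bias
$> 0.9$ discarded only for $n_{alt} > 15$, hypervariable windows
MT:302–319 and MT:3105–3109 excluded — counts surviving variants with
allele fraction below 0.01. Strand bias is computed on alternate reads
only (the natural reading; flagged as an interpretation). One structural
consequence worth knowing: at 3000x mitochondrial depth, a variant with
$n_{alt} \le 15$ cannot reach $q \ge 30$, so the strand-bias exemption
matters only at lower depths.

## 5. Locus confidence tiers

Per-sample depth bounds are the 0.001/0.999 Poisson quantiles (left
quantile: smallest $k$ with CDF $\ge p$ — the paper-level description
does not fix a convention, and this matches common practice) at the
modal nonzero autosomal coverage, the lower bound floored at 15 reads;
modal ties break to the smaller depth. Loci whose cohort out-of-bound
rate *strictly* exceeds 5% ("exceeded") are marked, then smoothed by
morphological closing (131 bp centred element) and opening (11 bp),
implemented exactly on intervals over the integer line — no raster
approximation, with genome coordinates clamped only at output. Closing
then opening is idempotent, which the tests assert. Tier 3 is
non-canonical contigs, pseudoautosomal regions (GRCh37 defaults,
overridable), and anything within 5 bp of the union of the five
poor-quality sets; remaining loci are tier 1 inside the high-confidence
set, else tier 2 — a partition, also asserted. BED files are 0-based
half-open on disk and 1-based inclusive in memory via `rtracklayer`.

## 6. Cohort comparison

`carrier_fisher()` reports the cross-product odds ratio
$(ad)/(bc)$ — which is what reproduces the published point estimates —
with a Haldane 0.5 correction only when a cell is zero (reported), and
takes p-value and CI from the exact conditional test
(`stats::fisher.test`, i.e. the noncentral hypergeometric inversion; the
CI method is stated because "Fisher's exact test" alone does not fix
one). The direction-of-effect test cross-tabulates
enrichment/depletion against risk/protective alleles and applies the
same exact machinery; zero-difference variants are dropped and counted.

Polygenic scores are $S_i = \sum_j \beta_j d_{ij}$ over autosomal score
loci with call rate $\ge 97\%$; remaining missing dosages are imputed as
$2 f_j$ from the score definition's reference frequency.

**Drift bootstrap.** Expected cohort scores
$s = \tfrac{2}{n}\sum_j f_j \beta_j$ differ between closely related
cohorts through genetic drift alone. The pool of standardised
differences $d_{2,i} = (f_{1,i} - f_{2,i})/\sqrt{f_{2,i}(1-f_{2,i})}$ is
built from *all* well-genotyped loci (call rate $\ge 97\%$ in both
cohorts, absolute frequency difference $< 4\%$; score loci included —
the frequency-difference filter applies to both the pool and the score
loci by default, switchable, as the wording leaves the pool's filters
open). Each round resamples $d_2$ per score locus, forms a simulated
reference cohort $f_{ref} = f_2 + d_2\sqrt{f_2(1-f_2)}$ clipped to
$[0,1]$ (clip events counted), and records $s_1 - s_{ref}$. The
two-sided p-value is the printed Iverson-bracket formula
$p = \tfrac{2}{B+1}\left(\tfrac12 + \min(\#[s_1 < s_{ref}], \#[s_1 > s_{ref}])\right)$,
implemented exactly: ties count on neither side, so with identical
cohorts (an all-zero pool) every round ties and the formula *forces its
floor* $1/(B+1)$ — a degenerate case that cannot arise with real
finite-sample frequencies but is worth knowing when testing with
constructed inputs. Normalisation rescales all score quantities so the
bootstrap reference-cohort scores have mean 0 and SD 1; with one
comparator per run the simulated reference derived from that comparator
plays this role (in a multi-cohort analysis one would designate a single
reference run and reuse its scale). CIs are the 0.025/0.975 quantiles of
the normalised depletion.

Power curves use `stats::power.t.test` (root-finding on the relevant
noncentral $t$ distributions) over a sample-size grid with the pooled
unit-sample SD, inverted to sample-size-versus-power by piecewise linear
interpolation.

## 7. Ageing statistics

Measure transformations: identity, $\log_{10}$, or a power transform
with exponent 0.7 (grip strength in kg), applied before modelling and
inverted for effective-age reporting. Trends are OLS slopes rescaled to
change per decade with Wald CIs; inter-cohort trend differences use a
likelihood-ratio test of shared-slope vs per-group-slope linear models,
Holm-corrected across measures.

**Permutation test.** The deviance of the Gaussian additive model
`frailty ~ s(age) + s(weight) + s(BMI) + s(abdocirc) + s(somatic)`
(GCV-penalised thin-plate smooths) is compared to `n_perm` refits with
the somatic column permuted;
$\hat p = (\sum_i [d_{(i)} \le d] + 0.5)/(n_{perm}+1)$, which is bounded
away from 0 and 1 by construction. Permutation refits reuse the
smoothing parameters selected on the observed fit — refitting is then a
penalised least-squares solve, and the implementation exploits that the
somatic block's Gram matrix is invariant under row permutation, so each
round costs a few small matrix products. The observed deviance is
computed through the same fixed-smoothing solver (it equals the `mgcv`
fit's deviance), keeping the comparison exchangeable under the null; a
`refit_smoothing` switch re-selects smoothness every round for users
who want the fully adaptive variant at ~100x the cost. Type-I error of
the fast path is verified empirically by the acceptance study.

The two-stage screen runs all candidate tests on a seed-deterministic
25% subset, passes those with $\hat p < 0.2$ to the complementary 75%,
and Holm-corrects the validation p-values.

Age-local quantiles use integer-rounded ages and a ±1-year
neighbourhood, self-inclusive (so values lie in $(0, 1]$ and all-equal
values sit at 1); the quantile is invariant to monotone transformation
of the measure. Effective-age curves fit `frailty ~ age + s(q)`, convert
predictions at a reference age to an age excess by inverting through the
linear age coefficient relative to $q = 0.5$ — with a linear age term
the inversion is always well-defined unless the age coefficient is
near zero, which is warned about — and attach 95% shortest-interval
(HPD) bands from bootstrap resampling of individuals. The bootstrap
default here is 1000 replicates; the acceptance studies use a few
hundred, and users reproducing publication-grade bands should raise it
(the original analyses of this kind used $10^5$). Cohort intercept
correction fits `measure ~ s(age, by = sex) + sex + cohort` (the sex
main effect is required for identifiability of the by-sex smooths) and
shifts each cohort to the reference intercept, an additive shift that
preserves within-cohort variance.

## 8. What the synthetic cohorts do and do not emulate

The generators produce every input with the statistical structure the
models assume: binomial allele sampling at ref-hom/het/somatic loci with
the same error model the thresholds use; negative-binomial depths
(size 100 by default — near-Poisson, matching the CNV model's
overdispersion scale); planted clones with chosen VAF and signature
mixture; planted aneuploid segments with GC-dependent depth bias (a
gentle unimodal log-bias peaking near 45% GC, amplitude 0.3, observed
through five tightly correlated nested windows — deliberately
recoverable, as real GC bias is smooth and gentle; a steeper or
non-smooth bias field would defeat any GC model of this form); drifted
cohort frequencies (base Beta(2,2), drift scale 0.03 ≈ fixation index
$10^{-3}$, typical of closely related European-ancestry cohorts);
and elderly phenotypes with a male-only mtDNA-quantile effect on grip
strength plantable in kg. Depth-bias realism, linkage disequilibrium,
read-level artefacts, haplotype structure and population stratification
are *not* emulated, so green recovery tests demonstrate correctness of
the estimators under their own assumptions — not robustness to
misspecified real data. The mitochondrial null generator uses a
per-site error rate of 0.001, below the q-score's fixed 0.0025: that
parameter is an upper error estimate by design, and a null simulated
exactly at the decision threshold would not represent a usable assay.

Reference study sizes (chosen once as desk-scale conditions; also the
problem sizes the acceptance studies use): SNV samples of $2\times10^4$
to $10^5$ loci; CNV genomes of 8 contigs × 5000 het loci with one
planted whole-contig deletion (5000 affected loci at depth ≈ 38); NMF
cohorts of 200 samples with three age-structured signature activities;
drift pools of $2\times10^4$ loci with 100-locus scores, bootstrap
$B = 10^4$; permutation studies of 500 individuals at
$n_{perm} = 1000$. The planted score depletion for power studies is
0.005 score units — several times the drift SD under the default scale,
the regime the strongest published longevity-score depletions occupy.

## 9. Known limitations

* The CNV model assumes one clone; mixtures of subclones bias $f$
  toward an average and can split segments. Gonosomes are not modelled.
* The sample-mean normalisation limits trustworthy fits to samples with
  at most roughly 15% of het loci aneuploid (see §3).
* NMF scores inherit the multiplicative-update plateau; compare
  signatures by cosine, not by raw score equality.
* The drift bootstrap treats loci as independent (no LD) and conditions
  on observed frequencies, ignoring their sampling error — adequate for
  large cohorts, anticonservative for very small ones.
* Permutation p-values with fixed smoothing are exchangeable-valid
  under the null but slightly conservative against alternatives
  compared to full re-selection.
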