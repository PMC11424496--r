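---
title: "Screening epigenetic-regulator mutations for ligand-receptor dysregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening epigenetic-regulator mutations for ligand-receptor dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbLR)
```

## The problem

Ligand-receptor (LR) interactions -- PDL1 (CD274) binding PD1 (PDCD1), chemokines
binding their receptors -- mediate the crosstalk between tumour, immune and
stromal cells. Epigenetic-regulator (ER) genes (histone writers, readers and
erasers, DNA methylators) sit upstream of the expression programs feeding these
interactions, and their somatic mutations can perturb them, with consequences for
anti-tumour immunity and immunotherapy response. `perturbLR` screens a tumour
cohort for ER mutations whose carriers coincide, more often than chance allows,
with samples in which a particular LR interaction looks dysregulated.

Inputs are a TPM-scale expression matrix (genes x samples), a binary somatic
mutation matrix (or a MAF file, binarized over protein-coding-altering variant
classes), a list of LR pairs, and a list of ER genes.

## Step 1: per-sample interaction dysregulation

For an LR pair $(G_i, G_j)$, sample $m$ has the two-gene expression vector
$E_m = (e_{im}, e_{jm})$. Its distance to the cohort is the Mahalanobis distance

$$d_m = \sqrt{(E_m - \mu)^\top S^{-1} (E_m - \mu)},$$

with $\mu$ the per-gene mean and $S$ the unbiased sample covariance. A sample far
from the cohort cloud *relative to the pair's own correlation structure* -- e.g. a
high ligand with an unexpectedly low receptor -- gets a large $d_m$ even when both
marginal values are unremarkable.

The distances are then screened for outliers with a one-sided Grubbs' test,

$$G = \frac{\max_m d_m - \bar d}{s},$$

compared against the $t$-based critical value
$G_{crit}(n, \alpha) = \frac{n-1}{\sqrt n}\sqrt{t^2 / (n - 2 + t^2)}$ with $t$ the
upper $\alpha/n$ point of Student's $t$ on $n-2$ degrees of freedom. Because
Grubbs tests a single extreme at a time, the test is *iterated*: the maximal
sample is flagged, removed, and the remainder retested, stopping at the first
non-significant step or when a fraction `max_outlier_fraction` of samples has
been flagged. The cap (default 0.2) prevents degenerate mass removal on
heavy-tailed pairs. Only the upper tail is tested: small distances mean a sample
close to the cohort mean, which is not dysregulation.

Numerical choices:

* **Rooted vs squared distance.** The default is the rooted distance because the
  Grubbs screen assumes approximate normality of the scored values and rooted
  distances are much closer to normal than squared ones; `squared = TRUE`
  reproduces the raw quadratic form (the flagged sets need not coincide).
* **Covariance.** Unbiased ($n-1$) estimator. A pair is "not testable" when
  $\det S < 10^{-12}\,(\mathrm{tr}\,S/2)^2$ -- e.g. two perfectly correlated
  genes -- and lands in the skipped-pair report instead of producing unstable
  distances.
* **Scale.** Expression is used on the TPM scale as given; `log_transform`
  applies $\log_2(x+1)$ first. On raw TPM (log-normal-like data) the distance
  distribution is right-skewed, so the iterated screen flags somewhat more than
  the nominal $\alpha$ fraction per pair (about 5--6% of samples at
  $\alpha = 0.05$ in our simulations); on Gaussian inputs the per-set
  family-wise flagging rate is calibrated at $\alpha$. Dysregulated-set sizes
  should therefore be read as a ranking device, not as a calibrated prevalence
  estimate.
* **$\alpha$** defaults to 0.05 and is a free parameter.

## Step 2: associating ER mutations with dysregulation

For every ER gene with at least `min_mut_samples` carriers (default 3; the same
floor is applied to the wild-type group so the rank test is meaningful) and every
pair with at least one dysregulated sample:

1. **Differential-expression gate.** A two-sided Wilcoxon rank-sum test compares
   each interacting gene's expression in carriers vs. wild type over all aligned
   samples. The candidate survives when at least one of the two genes has
   $p <$ `de_alpha` (default 0.05, either direction). The exact null
   distribution is used for tie-free data when either group has fewer than 8
   samples; otherwise the tie-corrected normal approximation.
2. **Overlap permutation test.** With $n_{obser}$ the number of samples both
   mutated and dysregulated, the carrier set is redrawn `n_perm` times (default
   1000) as a uniform random subset of the same size -- a marginal-preserving
   label shuffle whose null overlap distribution is exactly hypergeometric,
   which is what the test suite exploits as an independent oracle. The default
   p-value is the add-one estimator
   $p = (1 + \#\{n_{permu} \ge n_{obser}\})/(N+1)$, which stays in $(0,1]$;
   `p_mode = "as_printed"` gives the strict-inequality form
   $p = \#\{n_{permu} > n_{obser}\}/N$, which degenerates to 0 when no
   permutation beats the observation (hence not the default). Candidates with
   $p <$ `assoc_alpha` (default 0.05) are marked selected; the full candidate
   table is always returned, with optional Benjamini-Hochberg correction across
   the tested candidates (`fdr = TRUE`, off by default).

Because the permutation p-value is discrete, very small dysregulated sets make
it conservative at any fixed threshold (with $n_{dys} = 1$ the smallest
attainable p is about $n_{mut}/n$); it is never anti-conservative. Each
(ER, pair) test draws its permutations from a seed derived deterministically
from the master seed and the test's identity, so results are byte-identical
across reruns and across `workers` counts, and independent of evaluation order.
Permutations are drawn independently per (ER, pair) test rather than once per
ER across all pairs; under the marginal-preserving null the two schemes give
the same per-test distribution.

## Downstream summaries

* **Mutation signature** (`build_signature()`): samples are stratified by the
  integrated status of a chosen ER set -- 0 (wild type, no ER mutated),
  1 (exactly one), 2 (two or more) -- the grouping used to compare immune
  characteristics and survival between patient strata.
* **Immune scores** (`immune_scores()`): MHC-I expression is the arithmetic
  mean of HLA-A, HLA-B, HLA-C and B2M; the cytotoxic-T-lymphocyte (CTL) level
  is the arithmetic mean of CD8A, CD8B, GZMA, GZMB and PRF1; cytolytic activity
  (CYT) is the geometric mean of GZMA and PRF1. All are computed on the
  provided TPM scale, no log transform. CYT uses the TPM+1 pseudocount
  convention of the cytolytic-activity literature by default
  (`cyt_pseudocount = FALSE` for the raw geometric mean).
* **Enrichment** (`hypergeometric_enrichment()`): upper-tail hypergeometric
  tests of a query set (e.g. the dysregulated LR genes) against a GMT
  collection such as the MSigDB hallmark sets, BH-corrected. The universe
  defaults naturally to the expression matrix's post-filter gene set, passed
  explicitly by the caller.

## Input filtering rules

Genes are kept when expressed (TPM strictly above `min_tpm`, default 0) in
strictly more than `min_fraction` (default 0.7) of samples. MAF variants are
retained when their classification affects protein-coding capacity
(`coding_variant_classes()`: missense, nonsense, nonstop, frameshifts, in-frame
indels, splice site, translation start site); a gene-sample entry is 1 iff at
least one retained variant exists. Gene symbols are uppercased at parse time;
duplicate expression rows collapse by mean, duplicate mutation rows by OR.
No alias/ID mapping is attempted.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts with exactly the structure the screen
assumes, plus ground truth, so sensitivity and calibration are testable without
any external data:

* pair genes are bivariate normal on the log2 scale (unit SD around
  $\log_2 10$, so TPM values are right-skewed with median near 10) with
  correlation `pair_correlation` (default 0.6);
* each causal pair has a `dysregulated_fraction` (default 0.05) subset of
  samples whose *ligand* is displaced by `outlier_shift` (default 6) log-scale
  SDs -- a displacement of one gene, breaking the pair correlation, which is
  the geometry the Mahalanobis screen detects;
* the causal ER's carriers cover an `overlap_enrichment` fraction (default
  0.8) of those dysregulated samples and are filled to `carrier_fraction`
  (default 0.1) with random others; null ERs get uniform random carrier sets;
* carriers additionally get a `de_shift` (default 1) log2-unit ligand shift so
  the differential-expression gate is satisfiable;
* background genes are independent log-normal noise.

Defaults describe a 200-sample cohort. All draws flow from one seed through
named per-component streams, so changing the number of pairs does not perturb
the mutation draws. What the generator does *not* emulate: copy-number and
purity effects, batch structure, correlated mutation co-occurrence, realistic
mutation frequency spectra, or single-cell resolution -- so passing tests
demonstrate the method's statistical behaviour under its own model
assumptions, not performance on real tumours.

## Validation study sizes

The test suite and `scripts/acceptance.R` run, among others:

* permutation vs. exact hypergeometric tail on 50 random mask configurations
  at 10,000 permutations (agreement within 3 binomial SEs using the unbiased
  $\#\{\ge\}/N$ tail estimate);
* Grubbs calibration on 500 null Gaussian sets of 100 values, and recovery of
  a single planted 6-SD outlier in 500 sets;
* distance agreement with an explicit-2x2-inverse brute force on 100 random
  datasets (tolerance $10^{-8}$), plus affine invariance under random
  invertible maps;
* full-screen null calibration on one 200-sample cohort with 20 ERs, 20 pairs
  and no causal ER;
* planted-signal recovery over 100 replicate cohorts (200 samples, 5 pairs,
  10 ERs, 6-SD outlier shift, 5% dysregulated, 0.8 overlap enrichment,
  1 log2-unit expression shift) -- the causal (ER, pair) must be selected in
  at least 90;
* byte-determinism of the association table across reruns and worker counts.

These sizes were chosen so the whole suite runs in about a minute on a laptop
while leaving each check enough replicates for its stated tolerance.

## Known limitations

Grubbs' test on raw-TPM distances is anti-conservative on heavy-tailed pairs
(see above); use `log_transform = TRUE` when calibrated per-pair flagging rates
matter. The screen tests each (ER, pair) marginally -- co-mutated ERs can both
be selected for the same pair without any causal claim. No covariate adjustment
(tumour purity, subtype) is performed; run the pipeline per cohort/cancer type
and compare across runs instead.
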