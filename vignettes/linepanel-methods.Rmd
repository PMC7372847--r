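---
title: "Models and methods behind linepanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind linepanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`linepanel` analyses genome reference panels built from iso-female inbred
lines of haplodiploid insects: panels in which each line descends from a
single mated female, within-line genetic variance is nearly exhausted by
inbreeding, and among-line variance therefore estimates broad-sense genetic
variance.  This vignette explains the statistical models, the synthetic-data
generator that provides ground truth for them, the numerical choices, and
the known limitations.  It states no empirical result that the package's
tests do not themselves compute.

## The phenotype model

The focal trait is the brood sex ratio, expressed throughout as the
proportion of male offspring.  In haplodiploids the mother controls sex
allocation by fertilising (daughters) or not fertilising (sons) each egg,
and under local mate competition strongly female-biased ratios are
expected; the package's defaults centre the proportion male at 0.25.

A brood from line $i$ with clutch size $n$ contributes a male count
$m \sim \mathrm{Binomial}(n, p_i)$ with
$$\operatorname{logit} p_i = \beta_0 + \textstyle\sum_j \beta_j x_{ij} + u_i,
  \qquad u_i \sim N(0, \sigma^2_L),$$
where $x_{ij} \in \{0, \tfrac12, 1\}$ is the line's allele dose at causal
SNP $j$ and $u_i$ is the residual line effect.  Clutch size is modelled as
a rounded truncated-at-1 Normal with its own line effect; a linear model on
the untransformed scale is the field's convention for clutch size, and the
rounded Normal keeps that convention in the generator.

### Broad-sense heritability

`broad_sense_h2()` fits the one-way random-effects model
$y_{ik} = \mu + u_i + e_{ik}$ by REML (`lme4::lmer`) and reports
$H^2 = V_L / (V_L + V_E)$, with the arcsine-square-root transform applied
to brood proportions (the classical variance-stabilising choice: the
binomial sampling variance of $\arcsin\sqrt{m/n}$ is approximately
$1/(4n)$ regardless of $p$).  The likelihood-ratio statistic against the
no-line-effect model is referred to $\chi^2_1$.  Because the null value
$\sigma^2_L = 0$ sits on the boundary of the parameter space, this
reference is conservative; the test suite asserts the conservatism rather
than correcting it, since no mixture correction is applied by the
conventional line-panel analyses this package follows.

The generator solves the inverse problem: given a target $H^2$ on the
transformed scale, `calibrate_line_variance()` computes
$V_L(\sigma^2_L) = \operatorname{Var}\,\arcsin\sqrt{\operatorname{logit}^{-1}(\beta_0+u)}$
by Gauss–Hermite integration and
$V_E = E[1/(4n)]$ over the discretised clutch distribution, then solves
$V_L/(V_L+V_E) = H^2$ for $\sigma^2_L$ with `uniroot`.  The default target
is $H^2 = 0.106$; an acceptance test checks that the mean REML estimate
over 200 simulated phenotype replicates of a 25-line, 38-brood panel
recovers the target within $\pm 0.02$.

### Among-line variation

`among_line_ftest()` is the quasi-binomial GLM of brood male/female counts
on line identity, tested with an F test so that over-dispersion (absorbed
by the quasi-likelihood dispersion) does not inflate the test.  With $L$
lines and $B$ broods the test has $(L-1, B-L)$ degrees of freedom.

## The single-marker association scan

Genotype is a line-level covariate: every brood of a line shares its
genotype, so broods pool exactly into per-line sufficient statistics
($m_i$ males of $N_i$ offspring).  The association model for sex ratio is
the binomial random-intercept model
$$m_i \sim \mathrm{Binomial}(N_i,\ \operatorname{logit}^{-1}(b_0 + b_1 g_i + u_i)),
  \qquad u_i \sim N(0, \sigma^2_u),$$
with $g_i \in \{0, 1\}$ the homozygous allele code; heterozygous
(within-line segregating) and missing calls drop the line for that SNP's
test only.

Two fitters implement the model:

* **`method = "quadrature"`** maximises the marginal likelihood with
  adaptive Gauss–Hermite quadrature (nodes recentred and rescaled at each
  line's conditional mode) — the same approximation class as
  `lme4::glmer(nAGQ = 9)`, against which it is cross-checked in the test
  suite.  Adaptivity matters here: at pooled denominators of thousands of
  offspring per line the conditional posterior of $u_i$ is far narrower
  than the prior, and fixed-node quadrature visibly biases both the
  estimate and its standard error.
* **`method = "elogit"`** (the scan default) exploits those same large
  denominators: the per-line empirical logit
  $y_i = \log\{(m_i + \tfrac12)/(N_i - m_i + \tfrac12)\}$ is very nearly
  Gaussian with known sampling variance
  $c_i = (m_i+\tfrac12)^{-1} + (N_i-m_i+\tfrac12)^{-1}$, so the GLMM
  collapses to the line-level weighted linear mixed model
  $y_i \sim N(b_0 + b_1 g_i,\ \sigma^2_u + c_i)$, solved in closed form
  per SNP with weights from a single null-model moment estimate of
  $\sigma^2_u$ and a per-SNP rescaling by the weighted residual mean
  square.  In the balanced case this is exactly the line-means regression.

Inference for $b_1$ uses a $t$ reference with (lines used $-\,2$) degrees
of freedom — the between-line degrees of freedom appropriate for a
line-level covariate; a normal or $\chi^2_1$ reference would be
anti-conservative at 25 lines.  The clutch-size scan is the Gaussian
analogue through per-line means and the one-way ANOVA variance-component
estimates.

The fast route is the default for genome scans because the empirical
significance threshold is permutation-based: the same fitter produces the
observed and the null p-values, so conclusions are insulated from fitter
differences, and a full 2,000-SNP scan takes milliseconds, which is what
makes hundreds of permutation scans affordable.  The test suite verifies
that the two routes agree closely on the same data and that the fast
route's null p-values are uniform (a pooled Kolmogorov–Smirnov check over
many simulated panels).

### Permutation-based empirical threshold

`permutation_null()` permutes iso-female line identity against the
genotype columns — equivalently, the genotype vector is reassigned across
lines while each line keeps its own broods — which breaks
genotype–phenotype linkage while preserving the brood structure.  Both
framings of "permuting line identity" (shuffling genotype labels across
lines, or phenotype blocks across lines) produce the same null here,
because only the pairing of genotype with line phenotype matters.
`empirical_threshold()` estimates, for every candidate threshold $t$
(each observed p-value in ascending order),
$$\hat q(t) = \frac{\text{mean per-permutation count of null } p \le t}
                    {\text{observed count of } p \le t},$$
enforces monotonicity by a running minimum from the largest candidate
downwards (step-up), and reports the largest $t$ with $\hat q(t) \le q$.
When no candidate qualifies, the minimum attainable $\hat q$ is reported
and no SNP is called significant.  The number of permutations defaults to
100 for analysis runs; the calibration experiments in the test suite use
20 (documented there), which bounds the per-scan probability of any false
declaration near $1/21$.

### No relatedness correction

Single-marker scans on line panels often require a kinship correction.
The package instead provides the structure check used for panels of this
kind: `structure_check()` correlates pairwise line $F_{ST}$ with pairwise
absolute differences in line phenotype means (Spearman).  A null result
justifies the uncorrected scan; a material positive correlation warns
that stratification is confounded with the phenotype.

## Population-genetic summaries

`window_diversity()` computes the classical estimators on
coverage-standardised pooled counts at fixed sample size $n$ (the
subsampling target): per site $\pi = \frac{n}{n-1}(1 - \sum_i f_i^2)$,
$\theta_W = S/(a_1 L)$ with $a_1 = \sum_{i<n} 1/i$, and Tajima's $D$ with
the standard constants, reported missing (not zero) when a window has no
segregating site.  Alleles seen fewer than `min_count` times do not count
as segregating.  The pooled-sequencing bias corrections applied by the
dedicated pool-seq windowing tools are deliberately not replicated: this
package implements the classical statistics on subsampled counts, so its
absolute $\pi/\theta$ values are not numerically comparable to corrected
pool-seq estimates of the same data.

`subsample_coverage()` resamples each usable site to exactly the target
number of draws, with replacement by default, flagging sites outside the
`[min_cov, max_cov]` raw-coverage band as unusable.

`pairwise_fst()` uses the Hudson-style estimator with each line treated as
a population of two chromosomes (homozygote = frequency 0 or 1,
heterozygote = 0.5), combined across sites variable within the pair as a
ratio of averages.  One caveat worth stating plainly: on a deeply inbred panel with
hard genotype calls, almost every site variable within a pair of lines is
a fixed difference, so this estimator sits near 1 by construction.
Intermediate panel-wide values (such as the ~0.3 reported for real panels
from pooled sequencing) arise only when per-line allele frequencies are
estimated from many pooled individuals, which is outside the
genotype-matrix contract; the estimator here is the appropriate one for
hard calls, and its identities ($F_{ST}=0$ for shared polymorphism,
1 for fixed differences) are what the tests assert.

## Linkage disequilibrium decay

`pairwise_r2()` computes squared Pearson correlations of homozygous allele
codes across lines (pairwise-complete over missing and heterozygous
calls), capped at 1 Mb by default.  `fit_decay()` fits the hyperbola
$r^2 = 1/(1 + p x)$ by nonlinear least squares (PORT algorithm, starting
value $p_0 = 1/\mathrm{median}(x)$, lower bound $10^{-14}$); the model
forces $r^2(0) = 1$ and any empirical shortfall near zero distance is
absorbed by the fit, with no intercept parameter.  The half-decay
distance is $1/p$ exactly, and `distance_at_r2()` inverts the curve:
$x(r^2) = (1/r^2 - 1)/p$.  `decay_landscape()` repeats the fit per focal
SNP over its 1 Mb flanks and reports $\log_{10}$ half-decay distances;
SNPs with fewer than 10 usable flanking pairs are reported missing.
Whether a panel's single headline half-decay should come from one pooled
fit or from the mean of per-SNP fits is a reporting choice; both are
available, and the pooled fit is the default headline.

## The synthetic panel generator

The generator is first-class, tested code; every downstream stage is
exercised against its known truth.

**Founder haplotypes.** A Markov copying process runs along each
chromosome: a latent founder-lineage indicator is copied from SNP to SNP
and refreshed with probability $1 - e^{-\rho d}$ over distance $d$.  Within
segments of `rate_segment_bp` the switch rate $\rho$ is constant, and
$2\rho$ is drawn from an exponential distribution with mean `p_sim`.
Because the exponential mixture is the Laplace transform of the
hyperbola, the expected squared allelic correlation at distance $x$ is
exactly $1/(1 + p_{\mathrm{sim}} x)$ — the decay law the LD module fits —
while individual segments decay exponentially fast or slow, reproducing
the strong within-genome LD heterogeneity of real panels.  Two
implementation details matter:

* the segment rates are a *stratified* exponential sample (inverse CDF on
  a jittered, permuted grid), so that the realised mixture matches its
  target distribution even with on the order of a hundred segments; with
  iid draws the binned mean $r^2$ curve can miss the hyperbola by well
  over 10% through mixture sampling noise alone;
* `rate_mixture = FALSE` replaces the mixture by the constant rate
  $p_{\mathrm{sim}}/2$, giving uniform exponential pair decay
  $e^{-p_{\mathrm{sim}} d}$ and a flat decay landscape — the right
  background for calibration experiments, where duplicated SNP columns
  from low-recombination segments would otherwise create dependence among
  tests.

Founder allele frequencies are constant within `freq_block_bp` blocks and
drawn from a rescaled Beta spectrum; the refresh process is restarted at
block boundaries so marginal frequencies are exact.  The blockwise
spectrum is a simplification: real site-frequency spectra vary
continuously along the genome.

**Inbreeding.** Lines descend from *distinct* foundress females (founder
haplotypes are drawn without replacement across lines — sharing founders
would make line pairs partially identical, which both misrepresents the
design and induces spurious genome-wide dependence).  The pedigree is
explicitly haplodiploid: the foundress is crossed to one of her sons (a
haploid male carrying one recombinant maternal gamete), then the line is
propagated by full-sib mating; daughters receive a maternal gamete plus
the father's whole haploid genome, sons a maternal gamete only.  Meioses
recombine with a Poisson number of crossovers per chromosome (default
mean 1).  The classical diploid full-sib recursion
$F_t = (1 + 2F_{t-1} + F_{t-2})/4$ is kept as the analytic reference
(`inbreeding_coefficient()`), with expected segregating fraction $1 - F$;
the explicit haplodiploid pedigree loses heterozygosity faster than this
diploid reference, which is why simulated panels sit well below the
$1 - F(9) \approx 14\%$ expectation, as real panels do.

**Causal architecture.** Sex-ratio effects enter on the logit scale at
named positions; pleiotropy windows place `n_causal` shared SNPs that
affect both traits.  Three deliberate choices make the injected truth
recoverable rather than self-obscuring: shared causal SNPs are restricted
to common variants (`causal_maf_min`, default 0.25 — a rare causal allele
in a 25–34 line panel carries almost no detectable signal), are spread
evenly through their window and mutually decorrelated across lines (so
each contributes an independent association rather than a redundant or
cancelling one), and carry mixed effect-direction patterns across the two
traits.  The sign structure matters for the overlap test specifically:
the SNP-identity permutation preserves each SNP's pair of p-values, so a
shared basis that also creates a genome-wide correlation between the two
traits' line effects contaminates the permutation null itself;
sign-balanced local effects leave the global coupling near zero while the
|t|-based within-window rankings still coincide.

**What the generator does not emulate.** No demographic history,
selection, or mutation accumulation; no cytoplasmic-incompatibility
dynamics (the infection-status outlier is a flagged metadata entry only);
read-level sequencing error and genotype-calling uncertainty are absent,
so the genotype matrix is clean apart from residual heterozygosity.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated models, not robustness to the full error
structure of real sequencing data.

## Windowed cross-trait overlap

`window_scan()` asks, per window and window size (25–400 kb), whether the
most-associated SNPs for the two traits coincide.  SNPs are ranked by
p-value within the window separately per trait (ties broken by position);
for each cutoff $r$ the top-$r$ sets are intersected and the overlap $k$
is tested exactly against the hypergeometric null with the window's SNP
count as universe; the window summary is the minimum exact p over
cutoffs, with no multiplicity correction — the selection over cutoffs is
absorbed by the permutation null, which applies the same minimum.
Ranking and universe are within-window (not genome-wide ranks intersected
with windows) because the exact test's universe must equal the window's
SNP count for the SNP-identity permutation to be exchangeable.

`overlap_permutation()` reassigns the (p$_A$, p$_B$) pairs to random
positions — preserving both traits' p-value multisets, their genome-wide
coupling, and every window's SNP count — and flags a window when its
observed summary p is strictly below all (default 100) permuted summary
p's of that window.  Two behaviours of this rule are worth knowing.  At
low SNP density the discrete support of the summary p is so coarse that
observed values tie, rather than beat, the permutation minima: sparse
null genomes flag essentially no windows.  At high SNP density every
window's flag probability approaches the exchangeability baseline
$1/(n_{\mathrm{perm}}+1)$, so a dense genome-wide scan flags about 1% of
windows under the null — the rule controls the per-window error, not a
genome-wide rate.  The acceptance experiments use each regime for what it
is: detection power on a dense fixture, false-flag behaviour on a
genome-scale sparse one.

## Variant-effect classification

`classify_variant()` is a deliberately small classifier over a validated
annotation model (exons non-overlapping per transcript, CDS within exons,
CDS length divisible by 3 after phase adjustment).  Within CDS the
reference and alternate codons are translated strand- and phase-aware
(stop-introducing → `stop_gained`, amino-acid change →
`missense_variant`, silent → `synonymous_variant`, with `p.Xxx123Xxx`
notation); exonic non-CDS positions become 5'/3' UTR variants by
transcription direction, intronic positions `intron_variant`, positions
within 5 kb of a gene up/downstream variants, everything else
`intergenic_variant`.  A splice-region flag (1–3 bp into an exon at an
exon/intron junction, 3–8 bp into the intron — the common convention of
the standard annotation tools, both configurable) rides along with the
primary term, as in `splice_region_variant & synonymous_variant`.
Severity order for picking one primary call per SNP:
stop_gained > missense > splice_region > synonymous > UTR > intron >
up/downstream > intergenic.  The headline `pn_ps` is the raw
nonsynonymous/synonymous *count* ratio — a constraint proxy, not a
rate-normalised dN/dS; the field name says so.  Indels, multi-nucleotide
variants and regulatory-motif prediction are out of scope.

## Numerical and reproducibility choices

* Coordinates are 1-based internally, matching VCF.
* Heterozygote masking happens inside `apply_gwas_filters()`, not at read
  time, so the population-genetic modules still see residual
  heterozygosity; the filter cascade order (line exclusion →
  heterozygote masking → fixed-SNP removal → call-count filter → MAF
  filter) is logged step by step and is idempotent.
* Every stochastic function takes a seed; `run_pipeline()` derives
  per-stage seeds from one master seed by stage-name hashing so stages
  can be re-run in isolation; fixture files are byte-identical under a
  fixed configuration.
* The LD fit and the quadrature GLMM are deterministic given their
  inputs (fixed starting values, bounds, and tolerances, stated in the
  function documentation).
* Tajima's D is reported missing when $S = 0$; q-value thresholds report
  the minimum attainable $\hat q$ when nothing passes; boundary fits
  (LD decay at the lower bound, $V_L = 0$) are flagged, not hidden.

## Problem sizes used by the test suite

The simulation experiments in the tests are sized to be statistically
decisive while remaining routine to run: LD calibration uses a
200-haplotype pool over five 24 Mb chromosomes (≥10⁴ pairs per distance
bin); null-scan calibration uses 100 panels of 25 lines × 2,000 SNPs ×
38 broods/line with 20-permutation thresholds; heritability recovery uses
200 phenotype replicates of a 25-line panel; overlap detection uses 12
phenotype replicates of a 34-line, 6,250-SNP panel with 100-permutation
nulls, plus genome-scale sparse null scans.  These are the package's own
choices of experiment size; all seeds are fixed in the tests.

## Known limitations

* The empirical-logit scan assumes large per-line offspring totals; for
  panels with small broods or few broods per line, use
  `method = "quadrature"` (or `lme4::glmer` directly) — the elogit
  Gaussian approximation degrades as totals shrink.
* Absolute $\pi$/$\theta$ levels are not comparable to corrected pool-seq
  pipeline output (see above); comparisons should be within-package.
* Pairwise $F_{ST}$ on hard calls saturates near 1 for deeply inbred
  panels; it ranks pairs usefully but its absolute level is not
  comparable to pooled-frequency estimates.
* The per-window overlap rule's genome-wide false-flag count scales with
  the number of testable windows (≈1% of dense windows); interpret
  flagged windows jointly, across sizes and chromosomes, not singly.
* The classifier handles single-nucleotide substitutions only, and one
  annotation release at a time; overlapping genes produce one call per
  (SNP, transcript), with severity selection left explicit.
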