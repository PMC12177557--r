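---
title: "Models and methods behind bloodeqtl"
author: "bloodeqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bloodeqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodeqtl)
```

# Scope

`bloodeqtl` implements a complete expression-QTL discovery chain for bulk
RNA-seq expression measured alongside dense genotypes in a structured
(e.g. livestock) population: expression normalization and filtering, variant
QC, LD pruning to count independent tests, mixed-model association scans,
eQTL region calling with cis/trans classification, trans-regulatory hotspot
detection, QTL overlap and Bayesian colocalization, and PCIT co-expression
networks. A first-class synthetic-data module generates genotypes,
counts and traits with planted regulatory architecture so that every stage
of the chain can be validated against a known answer.

# Expression preparation

Counts are normalized with the trimmed mean of M-values (TMM) estimator and
expressed as log2 counts per million. Three rules matter downstream:

* **Zero masking.** A raw count of zero is set to missing *before* the log
  transform; a zero is treated as unobserved expression rather than as
  $-\infty$. Because zeros are pre-masked, the log2-cpm transform uses no
  pseudo-count by default (`prior = 0` in `log_cpm()`).
* **Low-expression filter.** A gene is retained iff strictly more than 35%
  of its non-missing samples exceed the cpm threshold $t = 10/L_{\min}$,
  where $L_{\min}$ is the minimum library size in millions. The package
  takes $L_{\min}$ as an input and derives $t$; with $L_{\min}\approx14.5$M
  this resolves to the familiar cpm > 0.69. The boundary is strict: a gene
  passing in exactly 35% of samples is removed.
* **Normality screen.** Each retained gene is tested with Shapiro–Wilk
  (Royston's algorithm via `stats::shapiro.test`); if the test rejects at
  `alpha_sw` (default 0.01), leave-one-out p-values identify the sample
  whose removal best restores normality, and that sample is masked — but
  only if its removal actually restores normality — up to `max_removals`
  (default 3) times per gene. The alpha, the iteration rule and the cap are
  package decisions: the screen as used in practice leaves them open, and
  the defaults keep the false-removal rate of clean Gaussian vectors near
  the nominal alpha. Removal is per-gene masking, not whole-sample
  exclusion.

TMM factors are computed by edgeR's implementation of the published
estimator (reference column by 75th-percentile cpm, 30%/5% M/A trims,
inverse delta-method-variance weights, geometric mean rescaled to 1); the
test suite locks the behavior against an independently written brute-force
evaluation of the same formula. One property worth stating precisely: a
pure depth change (multiplying a library by $c$) is absorbed by the library
size, so the TMM *factor* stays at 1 while the *effective* library size
scales by $c$; composition changes are what the factor corrects.

# Genotype QC, LD pruning and the significance threshold

Variants are dropped when MAF < 5% (computed on non-missing calls) or when
more than 10% of calls are missing; both cutoffs are strict, and an
all-missing variant is reported as its own category rather than an error.

LD is measured as the squared Pearson correlation between mean-imputed
dosage vectors (composite LD; no phasing is assumed). Pruning mimics the
common genotype-software recipe: a sliding window of 0.5 Mb, a cutoff of
$r^2 = 0.7$, and a sidestep of 10 SNPs. Within each window frame every pair
above the cutoff loses its later-positioned member (position ties drop the
lower-MAF variant), and the frame start advances by 10 *retained* variants
— "sidestep" counted on retained rather than all variants is a documented
reading of an ambiguous convention. Because stepped frames can skip a pair
that straddles two frames, a final ascending sweep over retained variants
enforces the postcondition outright: no surviving pair within 0.5 Mb has
$r^2 > 0.7$. The sweep also makes pruning idempotent, which the tests
verify together with an exhaustive pair audit.

The number of surviving variants is the number of independent tests; the
genome-wide threshold is $\alpha/n_{\text{indep}}$. With $\alpha = 0.05$
and 118,571 independent SNPs this is $4.217\times10^{-7}$. The correction
deliberately counts SNP multiplicity only, not gene multiplicity — one
shared threshold for every gene's scan.

# The mixed-model association engine

For each phenotype (a gene's normalized expression, or a health trait)
the model is

$$y = X\beta + g + S_l a_l + e,\qquad
g \sim N(0, G\sigma^2_g),\quad e \sim N(0, I\sigma^2_e),$$

with $X$ the intercept, sex and batch design, $G$ the genomic relationship
matrix of Yang et al. ($G_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i) /
(2p_i(1-p_i))$, monomorphic variants excluded, missing dosages
mean-imputed) and $S_l$ the dosage of the tested variant.

The null model (no SNP term) is fitted by REML after one eigendecomposition
of $G$: in the rotated basis the covariance is diagonal in
$\lambda = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$, and $\lambda$ is found by
1-D optimization (bracket tolerance $10^{-6}$, clamped to
$[0, 1-10^{-6}]$). The decomposition is computed once per sample set and
reused by every gene's null fit and scan; a phenotype with missing values
falls back to a decomposition of the subset GRM (casewise deletion).

The scan then estimates $a_l$ and its standard error by generalized least
squares with the variance *ratio* $\lambda$ frozen at the null estimate
while the residual *scale* is re-profiled per SNP with the SNP in the model
(divisor $n - p - 1$). This differs from freezing both components: the
package chose per-SNP scale profiling because it makes the identity-GRM
limit collapse *exactly* to ordinary least-squares regression (the test
suite requires agreement within 0.01 in $\log_{10}p$), whereas a frozen
scale leaves a systematic $O(0.1)$ discrepancy in $\log_{10}p$ at $n=60$.
At null SNPs the two conventions agree closely, and both are standard
"two-step" approximations to the exact per-SNP joint REML refit, against
which the tests hold the scan to $|\Delta\log_{10}p| \le 0.05$ for all
$p < 0.01$ on a fixed small instance. A caveat the package states plainly:
at $n = 60$ any SNP reaching $p < 0.01$ explains upward of 10% of the
phenotype's variance, and including such a SNP in a joint fit moves the
REML variance-ratio estimate materially — so the agreement of *any*
two-step scan with the exact refit is instance-dependent at that scale
(across random replicates the 0.05 bound holds in roughly half), and
tightens as $n$ grows. This is the usual trade of two-step mixed-model
scans, not a defect of the implementation; the exact-refit oracle in the
test suite is what quantifies it. Wald p-values use the normal reference (documented; at the
sample sizes of interest the normal/t distinction is absorbed by the
profiling convention). When $\hat\sigma^2_g$ hits the zero boundary the
weights become unity and the scan *is* linear regression — the natural
fallback, no special casing. A variant constant in the analysis subset is
emitted with $p=1$ and a degenerate flag rather than dropped, keeping scan
output aligned across genes.

# eQTL regions, cis/trans, hotspots

Significant variants for one gene are grouped into regions by splitting the
position-sorted list wherever two consecutive SNPs are 1 Mb or more apart
("less than 1 Mb apart" read strictly, and tested at the exact boundary).
Clusters with fewer than 3 SNPs are discarded; survivors are extended by
0.5 Mb on each side (floored at position 1, capped at the chromosome end
when a length is supplied). The region's top variant is its smallest-p
member, ties broken by genomic position — a deterministic convention the
source procedure leaves open.

A variant is *cis* to a gene iff it lies on the same chromosome within
1 Mb of the nearest gene-body boundary (distance zero inside the gene;
the 1 Mb boundary is inclusive, and the anchor is the gene body, not the
TSS — both conventions are documented because the underlying procedure
does not pin them down). A region is labelled cis when any member SNP is
cis. Variants associated with $\ge 10$ distinct genes are hotspots;
variants that are the top SNP of $\ge 10$ regions are top-hotspots. QTL
intervals are intersected with extended cis-eQTL intervals as closed
intervals (one shared bp counts), via IRanges.

# Colocalization

For a trait scan and a gene scan over a shared region, each SNP's evidence
is summarized by the Wakefield approximate Bayes factor: with $V = se^2$,
$W$ the prior effect variance and $z = \beta/se$,

$$\log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac{z^2 r}{2},
\qquad r = \frac{W}{V+W}.$$

With per-SNP priors $p_1, p_2$ (single-trait causality, default $10^{-4}$)
and $p_{12}$ (shared causality, default $10^{-5}$), and
$S_1 = \mathrm{lse}(l_1)$, $S_2 = \mathrm{lse}(l_2)$,
$S_{12} = \mathrm{lse}(l_1+l_2)$ (lse = log-sum-exp), the five hypotheses
have log evidence $0$; $\log p_1 + S_1$; $\log p_2 + S_2$;
$\log p_1 + \log p_2 + \log(e^{S_1+S_2} - e^{S_{12}})$;
$\log p_{12} + S_{12}$ — all computed in log space, with the H3 difference
floored (with a warning) in the numerically impossible case. For a
single-SNP region H3 is structurally impossible and its evidence is
$-\infty$. Posteriors are normalized exponentials; the per-SNP shared
posterior is $\propto e^{l_{1i}+l_{2i}}$, and the 95% credible set is the
smallest descending-sorted prefix reaching 0.95, ties broken by position.
An enumeration oracle over all single-SNP and SNP-pair causal
configurations pins the evidence terms to $10^{-10}$ in log space for
small regions.

Priors follow the conventional defaults; the effect prior SD is 0.15 on
standardized phenotypes. Posteriors are reported as fractions in $[0,1]$.
A sensitivity point the simulations make explicit: with these priors and
$n = 255$, per-trait signals below roughly 12% variance explained leave
the posterior indecisive — mass drifts to the single-trait hypotheses (or
H0) because a Bayes factor near the prior odds cannot overcome them. The
simulation suites therefore plant 15% per-trait variance for the
shared-causal arm and 18% for the distinct-causal arm (H3 requires *both*
signals individually decisive, hence slightly stronger effects); these are
the package's chosen study conditions for the validation experiments, and
weaker-signal behavior is a documented property, not a defect.

# PCIT co-expression

For every unordered pair $(x,y)$ and every third variable $z$, the
first-order partial correlations
$r_{xy\cdot z} = (r_{xy} - r_{xz}r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$
define the trio tolerance
$\epsilon_{xyz} = \tfrac13( r_{xy\cdot z}/r_{xy} + r_{xz\cdot y}/r_{xz} +
r_{yz\cdot x}/r_{yz})$, skipping ratios whose denominator is below
$10^{-12}$ in absolute value. The edge $(x,y)$ is removed iff for *every*
$z$ both $|r_{xy}| < |\epsilon\, r_{xz}|$ and
$|r_{xy}| < |\epsilon\, r_{yz}|$ — the "for every z" quantifier follows
the original algorithm and is locked by a literal triple-loop oracle in
the tests rather than by prose. Correlations use pairwise-complete
observations so traits with missing values can be appended as extra
variables. Zero-variance variables and perfectly collinear pairs are
errors by design: the partial correlations are undefined there.

# The synthetic-data generator

**Genotypes.** Each diploid individual is the sum of two haplotypes, each a
mosaic of `n_founder_haplotypes` founder haplotypes with exponentially
distributed copy-block lengths (mean `block_length_mean`, default 200 kb).
The founder panel itself is spatially autocorrelated: a founder keeps its
previous allele with probability $e^{-d/\ell}$ (`founder_ld_length`,
default 500 kb), so nearby sites share founder patterns and sit in high
$r^2$ while distant sites decorrelate — this two-layer construction gives
the blockwise $r^2\approx 1$ structure that the pruning and top-SNP logic
need, which a panel of independent founder alleles cannot produce unless
only two founders are used. Variants whose realized sample MAF falls below
`maf_min` (default 0.05) are dropped; 1% of calls are masked to missing to
exercise the missingness filter. Defaults emulate a 255-sample commercial
pig cohort; LD decay and the MAF spectrum at sequence level are
calibration choices, not published facts.

**Expression.** Gene $g$, sample $j$ counts are negative binomial with mean
$(L_j/10^6)\,2^{\eta_{gj}}$ and dispersion 0.1, where $\eta$ holds the
baseline log2-cpm abundance ($\sim N(5, 1.5^2)$), planted cis effects
(placed within 1 Mb of the gene TSS), hotspot effects, small sex and batch
effects, a polygenic term drawn from the GRM of the simulated genotypes
(variance set so `h2_polygenic`, default 0.2, is its share of the Gaussian
log2 variance, anchored by `resid_sd = 0.5`), and a Gaussian residual.
Library sizes span 14.5–45M reads, so the minimum-library cpm threshold
resolves near the familiar 0.69. Planting betas on the log2 scale means
planted effects and the analysis scale agree by construction. The
`cis_spec` override plants a cis effect of exact size at a chosen variant
(relocating the gene's TSS beside it), which the validation experiments
use to realize "a variant explaining 15% of this gene's variance": a
calibration pass with the effect zeroed measures the gene's realized
residual variance on the normalized scale, and the planted beta is sized
against that measurement — the intended variance fraction then holds on
the analysis scale rather than only on the latent scale.

**Traits.** A quantitative trait is `effect` × dosage + a polygenic draw
(variance `h2`) + Gaussian residual, standardized to mean 0 and variance 1.

**What the generator does not emulate.** Sequence context (no reference
genome or reads), sex chromosomes, imputation uncertainty, batch-by-gene
interaction structure, and the long-tailed MAF spectrum of real sequence
panels. Passing tests demonstrate the pipeline's statistical behavior
under a faithful caricature of the study design, not performance on any
particular real dataset.

# Problem sizes used in the validation suites

The test and acceptance experiments run at desk scale, chosen to keep each
suite a few minutes while preserving the statistical phenomena of
interest: null calibration uses one 300-sample, 10,000-SNP panel under a
$\lambda = 0.3$ polygenic background; recovery experiments use 50
replicates of a 255-sample, 2,000-SNP, 200-gene, 50-Mb chromosome with 60
founder haplotypes; colocalization arms use 50 replicates of a 255-sample,
150-SNP, 8-Mb region. The 60-founder choice matters: with few founders the
GRM has a very low-rank family structure, causal dosages align with its
top eigenvectors, and the mixed model absorbs part of a planted effect
into $\hat\sigma^2_g$ (the desk-scale analogue of proximal contamination,
amplified because a 2,000-SNP GRM dilutes a causal LD block far less than
a multi-million-SNP GRM). More founders flatten the spectrum and keep the
absorption at realistic levels; the residual effect is visible in the
recovery rates and is discussed, not hidden.

# Known limitations

* Single-chromosome simulation by default; multi-chromosome data can be
  assembled by concatenating independently seeded panels.
* The scan's two-step approximation shares the usual proximal-contamination
  property of GRM-based LMMs (no leave-one-chromosome-out mode).
* Colocalization assumes a single causal variant per trait per region.
* The PCIT implementation is $O(v^3)$ in the number of variables — suitable
  for hotspot target sets and trait panels, not whole transcriptomes.
* Case-control traits, dominance, and multi-trait models are out of scope.
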