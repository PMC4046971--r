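---
title: "Dissecting transcriptional heterogeneity in iPSC panels: models and methods"
author: "ipscvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting transcriptional heterogeneity in iPSC panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipscvar)
```

# The problem

Induced pluripotent stem cell (iPSC) lines differ transcriptionally, and the
candidate explanations are confounded in most study designs: donor genetic
background, the somatic tissue a line was reprogrammed from ("epigenetic
memory"), intrinsic iPSC-vs-ESC differences, and technical batch. A design
that derives multiple tissues from the *same* donors, reprograms each tissue
into several independent lines, and profiles everything by RNA-seq alongside
embryonic stem cell (ESC) controls can separate these factors. `ipscvar`
implements the statistical machinery for such a panel:

1. a pooled linear mixed model that decomposes log2 FPKM variation into
   named variance components and reports each as an intraclass correlation
   (percent variance explained, %VE);
2. a five-hypothesis negative-binomial classification of per-gene
   reprogramming outcomes, with permutation FDR and a threshold-free
   hierarchical mixture for category proportions;
3. a beta-binomial analogue for the ratio of each gene's top two isoforms;
4. phased allele-specific expression (ASE), imprinting classification and
   adult-to-iPSC imprinting concordance;
5. replication statistics for externally ascertained eQTLs;
6. a synthetic-study generator that emulates the full design with known
   ground truth, so every stage is testable without controlled-access data.

The default design has 47 samples from four donors (three male, one female):
18 adult samples (6 fibroblast, 3 keratinocyte, 9 endothelial progenitor
cell (EPC) passages), 25 iPSC lines (9 F-iPSC, 6 K-iPSC, 10 E-iPSC), 4 ESC
samples from two lines, and two sequencing batches. The donor-to-sample
assignment within each tissue (which the totals only partially determine) is
fixed in `default_study_design()`.

# The variance-component model

For gene $j$, the vector of log2 FPKM values across samples is modeled as

$$ y_j = Z_1 b_{1j} + Z_2 b_{2j} + Z_3 b_{3j} + Z_4 b_{4j} + Z_5 b_{5j}
   + \varepsilon_j, \qquad b_{kj} \sim N(0, D_k), $$

where $Z_1$ is the intercept; $Z_2$ indicates the five-level cell class
(fibroblast, keratinocyte, EPC, iPSC, ESC), with one variance
$\delta^2_{21}$ shared by the three adult levels and another
$\delta^2_{22}$ by the two pluripotent levels (the latter is what separates
iPSCs from ESCs); $Z_3$ indicates the iPSC tissue of origin (F/K/E,
variance $\delta^2_{32}$), zero for non-iPSC samples; $Z_4$ indicates donor
within cell class, with separate variances for adult ($\delta^2_{41}$) and
iPSC ($\delta^2_{42}$) donor levels and zero rows for ESC samples (whose
donors are not study donors); and $Z_5$ indicates sequencing batch
($\delta^2_5$). The residual is homoscedastic ($\sigma^2$), or
heteroscedastic with per-cell-class terms ("model 1": adult/iPSC/ESC) or
per-tissue terms ("model 2": three adult tissues, three iPSC origins, ESC —
seven groups).

Each component is summarized as an intraclass correlation,
$\mathrm{VE}_k = \delta^2_k / (\delta^2_k + \sigma^2_{\mathrm{rel}})$, where
$\sigma^2_{\mathrm{rel}}$ is the residual variance of the samples the
component acts on (a sample-weighted mean across groups for heteroscedastic
fits). VEs are fractions *holding other components fixed* and do not sum to
one.

## Pooling, standardization and why the scale matters

Genes are pooled into a single likelihood: with $\tilde y_j$ gene $j$'s
standardized expression, the model says $K^\top \tilde y_j \sim
N(0, K^\top V(\theta) K)$ where $V(\theta) = \sum_k Z_k D_k Z_k^\top + R$
and $K$ is an orthonormal basis of the orthogonal complement of the ones
vector — working in this contrast space removes the per-gene intercept
exactly (a REML-style treatment). Writing $S = \frac1J \sum_j (K^\top
\tilde y_j)(K^\top \tilde y_j)^\top$, the pooled log-likelihood is

$$ \ell(\theta) = -\tfrac{J}{2}\left[(n-1)\log 2\pi + \log\det V^*(\theta)
   + \operatorname{tr}\{V^*(\theta)^{-1} S\}\right], $$

so each evaluation costs one $O(n^3)$ factorization regardless of the
number of genes.

Standardization is a genuine design choice. Genes differ in scale (the
per-gene precision $\tau_j$ of replicate measurements spans orders of
magnitude), so some per-gene scaling is needed before pooling. Scaling each
gene by its **total** sample standard deviation, however, couples the scale
to the gene's own realized random-effect draws: a gene that drew a large
donor effect gets a large total variance and is shrunk, which systematically
deflates the estimated share of components with few effective levels (donor
most of all — we measured a bias of about $-0.04$ on donor VE in
simulations). `ipscvar` therefore centers each gene and divides by its
**moderated within-replicate-group** standard deviation, where replicate
groups are samples sharing every design level (donor x cell class x tissue
x batch) and the moderation shrinks the per-gene variance toward the mean
with a prior weight of 4 degrees of freedom. This scale adapts to $\tau_j$
but is statistically independent of the gene's random-effect draws;
parameter recovery in simulation is then unbiased to within ~0.01 per
component. For a design with no replicate groups at all the code falls back
to total-variance scaling.

## Estimation and numerical choices

The likelihood is maximized by L-BFGS-B on log-variance parameters
(enforcing positivity) from five deterministic starting points, keeping the
best converged run; non-convergence of all restarts raises an error rather
than returning silently (degenerate inputs, e.g. a dozen mitochondrial
genes, are expected to fail this way). A Cholesky failure triggers a single
ridge repair (1e-8 on the diagonal). Components whose design columns are
identically zero in a given metadata table (e.g. adult terms in an
iPSC-only design) are dropped from the parameter vector. Genes with zero
variance are dropped with a message. `mixed_model_loglik()` exposes the
pooled likelihood at arbitrary parameter values; the test suite checks it
against a dense per-gene multivariate-normal evaluation to 1e-8 and
verifies that constraining model 2's seven residual terms to equality in
triples reproduces model 1's likelihood exactly.

Dropping a component and refitting (`refit_excluding()`) quantifies
confounding: in a design where donors are nested in tissue of origin,
removing the donor component reattributes donor variance to origin, which is
the signature by which apparent "memory" can arise from genetic background.

# Classifying reprogramming outcomes

For each somatic tissue, counts from the (adult, derived-iPSC, ESC) triple
are compared per gene under five NB mean constraints: invariant
($q_A=q_I=q_E$), correctly reprogrammed (CR: $q_I=q_E$), transcriptional
memory (TM: $q_A=q_I$), aberrant (AR: $q_A=q_E$), complex (CX: all free).
Counts are NB with mean $s_i\mu$ (median-of-ratios size factors $s_i$) and
variance $\mu + \alpha\mu^2$. Group means are fitted by damped Fisher
scoring, vectorized across all genes simultaneously — this is what makes
hundreds of permutations over ten thousand genes affordable.

**Dispersion.** A per-gene method-of-moments estimate (computed under the
full-means model, so true group differences do not inflate it) informs a
fitted trend $\alpha(\mu)=a_0/\mu+a_1$; the classifier evaluates the trend
at each gene's mean rather than using the noisy per-gene value, because at
a dozen samples per triple the per-gene deviations are noise-dominated and
measurably degrade likelihood-ratio calibration. The dispersion is held
fixed across the five fits of a gene so the LRs are comparable.

**The min-p rule.** CX nests every other alternative, so its raw LR always
wins; selecting "the best alternative" is only non-degenerate with a
degrees-of-freedom penalty. Genes are therefore classified by the minimum
p-value among the four alternatives (LR against chi-square with 1, 1, 1, 2
df), with ties broken toward the larger LR. CX genes are sub-classified as
partial memory (PTM) when the fitted iPSC mean lies strictly between the
adult and ESC means, else partial aberrant (PAR).

**Permutation FDR.** Class labels are permuted across the triple's samples
(size factors stay attached to samples); FDR(t) = mean permuted count of
min-p ≤ t over the observed count, clipped to [0,1] and monotonized into
q-values; the operating threshold is the largest t with FDR ≤ 5%. On fully
null data the FDR proper is 1 wherever any discovery exists, so the
meaningful calibration check — which the test suite runs over 20 seeds — is
that the permutation-estimated false-positive *rate* at the 5% operating
point matches the realized fraction of genes called (within ±0.03).
Reported gene lists additionally require a 1.5-fold or greater change
between the fitted iPSC and ESC means (inclusive bound, either direction),
and counts are tabulated by category and direction (activation iff
$q_I > q_E$).

**Category proportions without a threshold.** A hierarchical mixture
estimates the true proportions $\pi$ of genes per hypothesis by EM on
$\sum_g \log \sum_k \pi_k \Lambda_{gk}$. The weights $\Lambda_{gk}$ are
approximate marginal likelihoods: each merged group's log2 mean offset from
the pooled mean carries a normal prior integrated out by the Wakefield
approximation, averaged over a prior-sd grid of (1, 2, 4) on the log2 scale
— i.e. effects from two- to sixteen-fold, the plausible magnitude range for
reprogramming failures. A proper Bayes factor has expectation one under the
null, so null genes do not leak mass into the alternatives; with plain BIC
weights (also available, `method = "bic"`) the null leak is roughly three
times larger. In simulation at 10,000 genes the EM recovers proportions of
(0.97, 0.01, 0.01, 0.005, 0.005) to within ±0.01 per component; the EM
objective is checked to be non-decreasing at every iteration, and
convergence requires the change to fall below 1e-8.

# Isoform-ratio memory

The same five constraint patterns apply to the fraction of a gene's most
abundant isoform among its top two, modeled beta-binomially with a per-gene
overdispersion $\rho$ (moment-estimated within classes under the full-means
model and held fixed across fits; fractions are fitted by 1-D likelihood
optimization per merged class). Only genes where two independent
quantifiers agree on the identity and order of the top two isoforms are
tested; disagreeing genes are excluded and counted. Permutation FDR is
shared with the expression classifier.

# Allele-specific expression and imprinting

Phased heterozygous-SNP counts are summed per (sample, gene) to haplotype
totals; entries below 20 reads total coverage (a declared default — the
source analyses state only that low-coverage genes were excluded) or below
the minimum SNP count are excluded and counted. Imbalance is tested by the
exact two-sided binomial test against 0.5. Imprinting status uses declared,
configurable cutoffs: mono-allelic iff the allelic fraction is ≥ 0.9 or
≤ 0.1 *and* the 95% CI excludes 0.5; bi-allelic iff the CI lies within
(0.2, 0.8); else ambiguous. Loss of imprinting is flagged when the adult
sample is mono-allelic and a strict majority of the donor's derived lines
are bi-allelic. Adult-to-iPSC concordance is the Pearson $r^2$ of allelic
fractions over genes testable in both compartments, with iPSC lines
averaged using coverage weights. Binomial counting noise attenuates this
$r^2$ below the true concordance of the underlying fractions; the test
suite checks the measured value against the analytic attenuation
$\left(\frac{V_p}{V_p + \overline{p(1-p)}/d}\right)^2$ at depth $d$.
Reference-mapping bias correction is out of scope; counts are taken as
given.

# eQTL replication

With four donors, per-gene inference is hopeless and deliberately not
offered — all statistics are pooled. iPSC expression is averaged within
donor (genotype is a donor property), standardized per gene along with the
dosage of the ascertained high-expression allele, and pooled into one
Pearson correlation; flipping the recorded high-expression allele flips the
sign exactly. Allelic imbalance at heterozygous eSNPs is a one-sample
t-test of per-gene high-haplotype fractions against 0.5. Variance explained
by lead-eSNP dosage needs care at $n=4$: the raw per-gene OLS $R^2$ has
null expectation $1/(n-1)=1/3$, so the headline figure pools unbiased
variance components across genes,
$1 - \overline{\mathrm{RSS}/(n-2)} \, / \, \overline{\mathrm{TSS}/(n-1)}$,
which recovers a planted 17% fraction to within ±0.02 in simulation; the
raw mean and a permutation-derived null mean are reported alongside.
`stratified_donor_ve()` reruns the variance decomposition on the most- and
least-strongly ascertained gene strata and contrasts donor VE.

# The synthetic-data generator

`simulate_study()` draws per-gene latent log2 means from the mixed model
itself (intercepts N(4, 1.5^2), effects from the configured variance
parameters), then counts from NB with mean $2^{\mathrm{latent}} \times$
gene length (kb) $\times$ library size (millions) and dispersion
$\alpha(\mu)=a_0/\mu+a_1$ (defaults $a_0=1$, $a_1=0.01$, a DESeq-like
trend); FPKM then recovers $2^{\mathrm{latent}}$ in expectation. Size
factors are log-normal(0, 0.1) to exercise normalization; gene lengths
log-normal around 1.5 kb. Default variance parameters put the components in
the regime the analyses are designed for: donor VE 0.38 among iPSCs and
0.42 among adult samples, origin 0.04, iPSC-vs-ESC 0.01, batch 0.02, and
adult-tissue differences at 0.30 (no reference value is stated for the last;
large between-tissue differences are what any adult panel shows). One
global seed fans out deterministically to per-component child seeds, so
sub-simulations are independently reproducible and a fixed seed reproduces
every matrix bit-for-bit.

`simulate_three_way_counts()` assigns DE categories in exact proportions
and shifts class means by ±(effect) in log2: CR shifts adult, TM shifts
ESC, AR shifts iPSC; CX places all three apart with the iPSC mean strictly
between (PTM truth) for half the CX genes and outside (PAR truth) for the
rest. `simulate_allelic_counts()` draws per-SNP totals Poisson and paternal
counts binomial at the class's true paternal fraction, with a matching
phased VCF. `simulate_eqtl()` scales each gene's effect to its realized
donor genotype variance so the planted variance fraction is exact per gene.

What the generator does **not** emulate: GC-content bias (the GC module is
exercised with its own planted bias instead), reference-mapping bias in
allelic counts, correlated genes (co-expression), outlier samples, or
library-preparation artifacts. Passing tests therefore demonstrate
correctness of the estimators under the declared generative model, not
robustness to every artifact of real RNA-seq.

# Normalization details

FPKM is counts / (length in kb x mapped fragments in millions); the log
transform uses a pseudocount of 1 (configurable). GC correction bins genes
into 25 equal-occupancy GC bins, computes per-sample relative enrichments
$F_{il}$ against the pooled profile, fits a cubic smoothing spline
(df = 5) of log2 enrichment against bin-mean GC, divides counts by the
predicted enrichment and rescales to preserve sample totals; empty bins
merge into a neighbor with a message; with a single bin the correction
degenerates to a global scalar. Bin count and spline df are declared
defaults, not inferred from any source. The active/repressed expression
dichotomy is a two-component Gaussian mixture fitted by EM in log space
(convergence 1e-8, monotone likelihood asserted); the correlation heatmap
order comes from complete-linkage clustering of 1 − r with samples
pre-sorted lexicographically for deterministic tie-breaking; per-gene
precision $\tau_j$ is the inverse pooled within-replicate variance, capped
at the 99th percentile of finite values to avoid infinite weights.

# Problem sizes used by the test suite

The packaged tests run the variance-component recovery at 2,000 genes x 20
seeds on the 47-sample design, the confounded-design contrast at 1,000
genes x 20 seeds, null classification calibration at 10,000 genes, planted
classification power at 500 genes per category inside a 10,000-gene
invariant background, permutation-FDR calibration at 2,000 null genes x 100
permutations x 20 seeds, EM proportion recovery at 10,000 genes, and eQTL
recovery at 3,000 genes. These sizes give Monte-Carlo error comfortably
below each check's tolerance while keeping a full run of the suite to a few
minutes on one core.

# Known limitations

- The pooled likelihood treats genes as independent; co-expression makes
  the effective gene count smaller than J, so standard errors (not
  reported) would be optimistic. Point estimates are unaffected.
- Variance parameters are shared across genes by construction; the
  precision scaling absorbs per-gene scale but not per-gene *structure*
  differences.
- The min-p classification inherits chi-square asymptotics; at very low
  counts the permutation FDR, not the nominal p-value, carries the error
  control.
- ASE takes phased counts as given: phasing errors and mapping bias
  propagate directly.
- With four donors, eQTL statistics are pooled only, and the
  variance-explained estimator, while unbiased, has a wide sampling
  distribution per gene.
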