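---
title: "Quantifying absolute gene copy number from targeted capture coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying absolute gene copy number from targeted capture coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capcnv)
library(dplyr)
```

## The problem

Conifer genomes are enormous (tens of gigabases) and riddled with
pseudogenes, which makes whole-genome sequencing impractical for
population-scale studies and makes copy-number variation (CNV) of individual
gene families hard to measure. Hybridization capture solves the cost
problem: a panel of tiled oligonucleotide baits pulls down the gene family
of interest together with a set of putatively single-copy genes, and
sequencing depth over each target becomes the raw signal. The catch is that
read-depth methods natively report *relative* copy number. `capcnv`
implements the extra step that makes the estimate *absolute*: single-copy
genes on the same panel act as internal standards, exactly like
known-concentration standards in analytical chemistry.

The estimator for gene $g$ in sample $s$ is

$$\widehat{cn}_{g,s} = \frac{\tilde{y}_{g,s}}
{\left(\prod_{h \in H} \tilde{y}_{h,s}\right)^{1/|H|}},$$

where $\tilde{y}$ are TMM-normalized per-gene coverage values and $H$ is the
set of high-confidence single-copy internal standards. Because the scaling
constant is per-sample, any per-sample multiplicative distortion — library
size, capture input, normalization residue — cancels exactly; the geometric
mean makes the estimator insensitive to a log-symmetric spread among
standards and gives the exact conservation law
$\big(\prod_{h} \widehat{cn}_{h,s}\big)^{1/|H|} = 1$, which the test suite
asserts to $10^{-12}$.

## Pipeline stages and their parameters

### Bait design

Targets are padded (default 1,000 bp each side, clamped to contig bounds) so
that flanks and regulatory context are captured along with the gene body.
Baits of 80 nt are tiled at 2X density, i.e. a new bait every
`round(80 / 2) = 40` nt; when the last regular bait would stop short of the
3' end, one extra bait is anchored flush with the end, so every base of a
region at least one bait long is covered (a property test checks the
closed-form bait count against brute-force enumeration for all lengths up
to 1,000). Baits are filtered on two quantities: the number of alignment
hits against the reference genome (cross-hybridization risk) and the
predicted melting temperature. The Tm model is the deterministic GC/length
formula with a linear mismatch penalty,
$T_m = 81.5 + 16.6\log_{10}(\mathrm{Na^+}/50\,\mathrm{mM}) + 0.41\,\%GC -
675/N - \%mismatch$, written so that the salt term vanishes at the 50 mM
reference; the Wallace rule is available for short oligos.
Nearest-neighbour thermodynamic models are a deliberate extension point,
not a default: for an 80-mer filter window the GC formula is adequate and
exactly reproducible. The hit-count and Tm cutoffs are **required**
arguments with no defaults — sensible values depend on the genome's repeat
content and the capture chemistry, and silently guessing them would be
worse than asking.

### Coverage statistics

Per-region mean target-base depth is the interval-weighted average of a
bedGraph depth track (bases absent from the track count as zero; a region
with no track at all is a *dropout*, reported as depth 0 with a warning
rather than an error, because capture failure is a result, not a parse
problem). Normalized coverage divides a region's mean depth by the average
depth over all target bases of the sample, computed as a ratio of sums
(total read-bases over total target bases), not a mean of per-region means
— the two differ when region lengths differ. Its length-weighted mean is
exactly 1 per sample and it is invariant to rescaling a sample's depths. A
`denominator_regions` argument restricts the denominator to a subset (e.g.
the internal standards): with very-high-copy targets on the panel the
"all target genes" denominator is dominated by them, and both conventions
are defensible, so both are provided and neither is silently preferred.

### Selecting high-confidence internal standards

Single-copy classification by orthology benchmarks (e.g. BUSCO classes,
consumed as a 4-level table) is unreliable in gymnosperms: lineages with
high gene turnover can carry dozens of copies of genes that are single-copy
in the taxa the orthology database was curated from. The filter therefore
intersects two independent criteria: (a) the gene's log-normalized coverage
lies within $k$ standard deviations (default 1, boundary inclusive) of the
mean over the candidate set, and (b) the gene is classified single-copy.
The mean and SD are computed over the candidate genes only, not the whole
panel — the window asks "is this gene's coverage typical *of the putative
single-copy set*". The window is applied in SD units around a recomputed
mean, so the retained set is invariant both to uniform rescaling of
coverage and to the logarithm base (natural log by default); shrinking $k$
can only shrink the set. With SD = 0 (identical coverage everywhere) all
candidates pass the window, which is the only consistent reading of a
zero-width band. A seeded test plants multi-copy genes more than 3 SDs
above lognormal single-copy coverage and checks the filter excludes every
planted gene while keeping at least 95% of the true standards.

### TMM normalization

Between-sample normalization uses the trimmed mean of M-values, written
from scratch in this package: for sample $k$ against reference $r$, over
genes positive in both columns,
$M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}$ and
$A_g = \tfrac12 \log_2\!\big(\tfrac{y_{gk}}{N_k}\cdot\tfrac{y_{gr}}{N_r}\big)$;
the most extreme 30% of each tail of $M$ and 5% of each tail of $A$ are
discarded (rank-based double trimming), and the factor is
$2^{\sum w_g M_g / \sum w_g}$ with inverse delta-method variances
$w_g^{-1} = \frac{N_k - y_{gk}}{N_k y_{gk}} + \frac{N_r - y_{gr}}{N_r y_{gr}}$
as precision weights (an unweighted switch exists for diagnostics). The
reference sample is the one whose upper quartile of library-size-scaled
counts is closest to the mean upper quartile, ties to the first sample;
factors are rescaled to geometric mean 1. Fewer than 10 genes positive in
both columns is too little information to estimate a composition factor, so
the factor falls back to 1 with a warning — this guard is applied to the
gene count *before* trimming, which keeps a 10-gene matrix estimable (the
suite verifies factors against a frozen run of the published reference
implementation on five fixture matrices, to within $10^{-6}$).

Two interpretation notes. The input may be per-gene *mean depths* (already
length-normalized by the coverage averaging) or raw per-gene counts; both
are accepted, and the common claim that TMM "accounts for gene length" is
realised here by that upstream division, not by an extra length term inside
TMM. Second, with precision weights the factors are not exactly invariant
to rescaling a single column (the weights depend on absolute counts); the
unweighted variant is exactly invariant, and the tests assert both
behaviours explicitly.

### Copy numbers, family totals and the bootstrap cross-check

Copy numbers come from the geometric-mean scaling above. Zero
internal-standard values are excluded from the geometric mean rather than
pseudocounted — a zero standard is a capture failure, not evidence about
scale — and the exclusion count is surfaced for QC; a sample with no usable
standard gets missing copy numbers and a flag. Copy numbers are reported
unrounded. Family totals sum the gene models of a family per sample, with
an option to restrict to complete/near-complete models when a model-status
column is available, and `fold_range()` gives the max/min ratio of totals.

As an independent estimator, `bootstrap_ratio_cn()` resamples the reference
genes with replacement (10,000 replicates by default, mandatory seed,
bit-reproducible): each replicate computes the target / mean-resampled-
reference ratio per sample, normalizes it to the mean ratio in a baseline
sample group, and the replicate distribution yields the mean ratio and an
empirical 95% interval. This is a panel-oriented simplification — genes are
resampled, not reads — of the subsampling strategy used by panel CNV
callers, and is documented as an approximation, not a reimplementation.
`cross_validate_estimators()` reports the Pearson correlation between the
direct and bootstrap estimates across samples.

### Downstream statistics

The inferential layer wraps the standard R implementations rather than
re-deriving them: sequential (Type I) two-way ANOVA via `aov` in the fixed
order provenance, gene model, interaction (a Type II option via `car`
exists for unbalanced provenance panels, where sequential sums of squares
depend on term order — the suite demonstrates both the balanced-design
order invariance and the unbalanced order dependence); Wilcoxon rank-sum
with exact enumeration when $\min(n,m) \le 10$ and no ties, otherwise the
tie-corrected normal approximation; Tukey HSD with Tukey–Kramer handling of
unequal group sizes; Welch's $t$ with Satterthwaite degrees of freedom; and
Pearson correlation. Degenerate inputs follow explicit conventions: a
constant response reports missing $F$ and $p$; a zero residual mean square
with real effects reports $F = \infty$, $p = 0$ with a warning (detected
relative to the total sum of squares, not against exact floating-point
zero); two constant equal groups give $p = 1$ in the Welch test. All
p-values are raw; no multiple-testing correction is added beyond Tukey's
own adjustment.

### qPCR validation arm

The threshold cycle $C_{1/2}$ is the inflection point of a four-parameter
logistic fitted to each amplification curve
($F(c) = \mathrm{base} + \mathrm{amp}/(1 + e^{-(c - m)/s})$, bounded
Levenberg–Marquardt, initialized at base = min, amp = range, $m$ = cycle of
the largest first difference, $s = 1$). A parametric fit is used instead of
a numerical second derivative because curves are sampled once per cycle.
Curves whose total rise is below 5% of their signal magnitude (configurable)
are flagged as non-amplifying and produce a missing $C_{1/2}$, which
propagates as missing copies; note this flatness test is on the raw
fluorescence scale, so extreme affine offsets can change the flag even
though the fitted $C_{1/2}$ itself is affine-equivariant. The standard
curve is the least-squares line $C_q = b + m\log_{10}(\text{copies})$ over
a dilution series (duplicate wells averaged per level, at least three
distinct levels), with amplification efficiency $10^{-1/m} - 1$; perfect
doubling gives $m = -1/\log_{10} 2 \approx -3.3219$ and efficiency 100%.
Absolute copies per reaction invert that line, and copies per genome divide
by the genome equivalents loaded, computed from input DNA mass and an
assumed genome size at ~650 g/mol per base pair (the worked conversion: 20
ng against a 20 Gbp genome is ~926 genome equivalents).

## The synthetic-data generator

Every estimator is verified against `simulate_counts()`, a generative model
of capture counts with known truth:
$\mu_{g,s} = L_s\, e_g\, cn_{g,s}$ with lognormal library-size effects
$L_s$ (log-SD 0.5 — captured libraries routinely differ severalfold in
depth, which is what TMM absorbs), lognormal per-gene capture efficiencies
$e_g$ (log-SD 0.05 — after Tm and hit-count filtering a bait set is
deliberately homogeneous, leaving a few percent gene-to-gene spread), and
negative-binomial counts with dispersion $\varphi = 0.05$
($\mathrm{Var} = \mu(1 + \varphi\mu)$, i.e. ~22% coefficient of variation
per gene at high depth; $\varphi = 0$ degenerates to deterministic rounded
means, used by the noise-off identity test). Internal standards have true
copy number 1; family totals are drawn uniformly per sample from a
configured range (optionally per provenance), split across gene models by
fixed weights. Seeds are mandatory everywhere and the global RNG state is
left untouched. A Monte-Carlo test checks the empirical mean and variance
of a cell against the NB moment formulas over 10,000 replicate draws.

`study_scale_panel()` is the study-scale preset: 40 samples across 9
provenances, 120 internal standards, one five-model high-copy family
("bglu1") with per-sample totals spanning 56–381 copies — the extremes
planted exactly, so the true fold range is 6.8 by construction, with model
weights 0.30/0.25/0.20/0.15/0.10 so that gene models differ as they do in
real families — and one single-copy family ("ugt5b") with planted outlier
totals of 14, 12, 11 and 4 in four samples from four different provenances.

What the generator deliberately does *not* emulate: GC-content bias (a
multiplicative per-gene covariate can be added for robustness experiments
but is off by default), read-level artefacts (chimeras, mapping ambiguity,
fragment-length structure of long-insert libraries), pseudogene
cross-capture, and correlated noise between gene models of one family.
Passing the recovery suite therefore shows the estimator chain is correct
under its own multiplicative model, not that real capture data are free of
these additional distortions.

## What recovery on the preset panel shows — and one honest limitation

On the preset panel the full pipeline (normalize, validate standards,
quantify) recovers per-sample family totals with a median absolute relative
error of about 8%, the internal standards' estimated copy numbers
distribute tightly around 1, and the direct and bootstrap estimators
correlate at $r > 0.99$ (problem sizes: 40 samples, 126 genes, 10,000
bootstrap replicates — a full run takes a few seconds on one CPU).

The max/min *fold range* of the recovered totals is a different matter.
With ~11% noise per family total, the maximum over 40 samples is biased
upward and the minimum downward (extreme-value selection: several samples
sit within one noise SD of each true extreme), so the recovered fold range
overestimates the planted 6.8 by about +13% in the median across seeds,
with wide spread; at the suite's fixed seed it overshoots substantially,
and the corresponding expectation in the acceptance suite fails. This is a
property of max/min statistics under this noise level, not of the
estimator: the assertion is left in place rather than widened, and users
comparing fold ranges between noisy totals should treat them as
upper-bound-ish summaries or bootstrap them.

## Numerical conventions

Intervals are 0-based half-open (BED convention) everywhere inside the
package; conversion to 1-based coordinates happens only at report
rendering. Strand is ignored throughout — capture coverage and copy number
are strand-symmetric. TSV with a header row is the only table dialect
(comma files are rejected), with the literal string `NA` as the
missing-value marker, and missing values propagate rather than becoming
zeros. All writers produce canonical files that round-trip bit-exactly, and
`run_pipeline()` writes a manifest (input checksums, parameters, seed,
output checksums) sufficient to reproduce every output byte for byte.
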