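---
title: "Methods: copy-number eQTL mapping in radiation hybrid panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number eQTL mapping in radiation hybrid panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the model

A radiation hybrid (RH) panel is built by lethally irradiating donor
cells, fusing the fragments into a hamster recipient line, and selecting
clones that retain a marker gene (classically thymidine kinase, *Tk1*).
Each surviving clone carries a random set of donor fragments, so across a
panel of ~80 clones essentially every donor locus is present at elevated
copy number in some clones and absent in others. Two array measurements
per clone drive the analysis: an aCGH log10 ratio (hybrid DNA over
recipient control) per marker, and an expression log10 ratio per gene.

The core model is ordinary least squares per gene–marker pair,

$$y_c = \mu + \alpha x_c + \varepsilon_c,$$

with $y_c$ the expression log-ratio of the gene in clone $c$ and $x_c$
the normalized dosage log-ratio at the marker. $\alpha$ is dimensionless:
$\alpha = 1$ means expression tracks copy number one-for-one, negative
$\alpha$ means dosage-driven repression. The full model is compared with
$y = \mu$ through $F = (\mathrm{RSS}_0 - \mathrm{RSS}_1) /
(\mathrm{RSS}_1 / (n-2))$. A perfect fit reports $F = \infty$, which
sorts above every finite null value and yields $P = 0$ with the pool
resolution $1/N$ attached as metadata.

**Permutation null.** Parametric F reference distributions are not trusted
here: dosage is strongly non-Gaussian (near-binary mixture) and panels
are small. Instead, clone labels of each expression vector are reshuffled
(per gene, per round — the dosage matrix is untouched, so the correlation
structure among markers is retained) and the F statistics from all
permuted pairs are pooled into one empirical null. Five rounds per pair
suffice because pooling multiplies the effective null size by the number
of pairs. $P$ is the fraction of null values *strictly greater* than the
observed F; ties count as not greater.

**cis/trans and FDR.** A pair is *cis* when the marker lies on the gene's
chromosome within 5 Mb of the gene interval (distance 0 inside the gene,
else the gap to the nearer boundary), *trans* otherwise. Because the two
classes test different families of hypotheses with very different sizes,
Benjamini–Hochberg q-values are computed separately within each class.

## aCGH normalization

Raw log ratios are smoothed over a sliding window of ten adjacent markers
(five left, four right, truncated at chromosome ends; windows never span
chromosomes). The pooled smoothed values are bimodal: a large mode for
markers at recipient copy number and a smaller mode one extra copy up.
Since both donor and recipient are male, one extra copy means ratio 3/2
on autosomes but 2/1 on the sex chromosomes, so each class is normalized
by its own affine map sending the first mode to 0 and the second to
log10(3/2) or log10(2/1).

Mode location uses a Gaussian KDE with the Silverman bandwidth computed
from the sample *standard deviation* ($0.9\,s\,n^{-1/5}$), not the usual
IQR variant: when ~89% of values sit in the lower mode the IQR collapses
to the noise scale and the density over-resolves into spurious wiggles.
The two highest local maxima separated by at least `min_sep` (default
0.05 log10 units) are taken as candidate modes and refined by mean-shift
iteration, which converges to the exact KDE mode and is affine-
equivariant. The component boundary for the "95th percentile of the first
mode" retention threshold is the density minimum between the two centers
— one of several defensible component definitions; it is recorded in the
returned object so downstream consumers can see which convention
produced the threshold. If the upper component holds less than 1% of the
values, the fit aborts with a "no gain detected" error rather than
normalizing against noise.

Two properties follow from this construction and are asserted by tests:
normalization is idempotent (per-class refit on normalized data returns
the targets exactly, because mode finding commutes with affine maps), and
retention calls are invariant to any affine transform of the raw data.

**Retention calling.** A locus is called retained in a clone when the
mean normalized ratio of the `k = 10` markers nearest the locus exceeds
the first-mode 95th percentile. Concordance with legacy genotypes is a
1-df Pearson chi-square; centromere enrichment is a Welch t-test on
per-locus retention frequencies.

**Binning.** Optionally, dosage can be reduced to 0/1 extra copies by
recursive binary segmentation per clone and chromosome (split accepted
while it improves a Gaussian BIC with a 2-parameter penalty), each
segment assigned by whether its mean is nearer 0 or the class target.
Any consistent changepoint method satisfying exact noiseless recovery
would do; this one has no external dependencies and recovers noiseless
block structure exactly.

## The simulator's stated world

The generator plants ground truth at the parameter values the analysis
is calibrated against:

| parameter | default | meaning |
|---|---|---|
| `target_retention` | 0.114 | marker-averaged donor retention per clone |
| `mean_fragment_length` | 4 Mb | exponential donor fragment length |
| `alpha_positive_mean` | 0.73 | mean of the positive cis effect component |
| `alpha_negative_mean` | −0.12 | mean of the negative component |
| `fraction_negative` | 0.36 | fraction of genes with negative alpha |
| `x_attenuation_factor` | 0.5 | multiplier on X-linked effect sizes |
| `acgh_noise_sd` | 0.03 | Gaussian noise on raw aCGH log ratios |
| `expr_noise_sd` | 0.05 | Gaussian noise on expression log ratios |
| `raw_mode_separation` | log10(3/2) | raw distance between aCGH modes |

Fragment starts follow a homogeneous Poisson process per chromosome with
exponential lengths; the stationary coverage of such a process is
$1 - e^{-\lambda L}$, which fixes the rate from the retention target. One
fragment per clone is forced to cover the selectable-marker locus *and*
its nearest aCGH marker, with independent exponential overhangs on both
sides — the correct length-biased distribution of a point-covering
fragment under the memoryless length law. The base rate is tuned down to
compensate, so the *marker-averaged* retention still matches the target
while the selectable locus is retained in 100% of clones; retention is
consequently elevated near that locus and slightly below target
elsewhere, as in real panels under selection. Optional knobs exist for
centromeric start-point enrichment (off by default: the phenomenon is
real but no generative parameter is published) and for lognormal
clone-to-clone retention heterogeneity (off by default, for the same
reason).

Cis effects are drawn from a two-component Gaussian mixture truncated at
zero (positive component N(0.73, 0.25²), negative N(−0.12, 0.08²), the
negative branch chosen with probability 0.36); X-linked effects are
multiplied by 0.5 at generation time. Component spreads are not published
summaries; they were chosen once so that the mixture is clearly bimodal
with realistic overlap and are not tuned. Expression is baseline +
effect × normalized dosage at the gene's nearest marker, plus optional
trans links (positive-mean effects from a random source marker to a gene
on another chromosome), plus Gaussian noise.

**Scale constraints of the desk-sized world.** Two regime conditions
must hold for a simulated panel to behave like the dense genome-wide
panels the method was built for, and both are about ratios, not absolute
sizes. First, marker spacing times the smoothing window must stay well
below the fragment length, or smoothing blurs fragments away (real
panels: 13 kb spacing × 10 ≪ 4 Mb). Second, the genome must be large
against the ~8 Mb expected extent of the forced selectable fragment, or
that single fragment distorts the genome-wide retention budget. The test
fixtures therefore use ≥180 Mb toy genomes with ~100–200 kb marker
spacing, and scale the window down (never the fragment up) when a
criterion pins the marker count low.

**What a green test does not establish.** The generator draws Gaussian
noise, makes gains strictly +1 copy (the ~1% double-gain rate of real
panels is ignored — the normalization itself treats the data as two
modes), plants no probe-level artifacts, no cross-species hybridization
bias, no passage-related marker loss, and no correlation between effect
sign and expression level. Recovery and calibration results on simulated
panels validate the estimator and its null, not the biology of any real
dataset.

## Downstream statistics

*Hotspots.* Counts of genes regulated per marker (or markers per gene)
among trans records below a q threshold are modeled as Poisson with mean
equal to the average count; the reported tail is $\Pr(X > n)$ with BH
adjustment across units. By default the mean is taken over units with at
least one trans hit; an option includes zero-count units over an explicit
universe, since "average across all markers" is ambiguous when most
markers regulate nothing.

*Noncoding blocks.* A trans peak (local maximum of the −log10 P profile;
two maxima are distinct peaks only when the profile drops ≥ 2 units
between them, and each peak carries its 2-unit support interval) is
noncoding when more than 300 kb from any annotated gene or microRNA;
noncoding peaks within 300 kb chain into blocks by single linkage.
Cross-dataset block matching is greedy one-to-one by overlap length then
distance, with a 1-df chi-square over an explicitly supplied universe of
candidate blocks — the universe is a parameter precisely because its
definition is a modeling choice.

*Sign concordance.* 2 × 2 chi-squares here and everywhere else in the
package use no Yates continuity correction (a `correct` flag exists on
the internal statistic): the conventional floor P < 2.2 × 10⁻¹⁶ printed
by R corresponds to the uncorrected statistic. Genes with exactly zero
effect are excluded and counted.

*X attenuation.* For each clone, cis effect sizes are averaged over genes
whose nearest marker is gained in that clone (normalized dosage above
half the class target), separately by chromosome class and effect sign,
and autosome–X differences are tested by a paired t across clones
(df = complete clones − 1). Clones with no gained X-linked genes drop out
of the pairing and are counted. "Averaged over genes gained in that
clone" is one documented reading of a per-clone average; the unpaired
mean |alpha| comparison is reported alongside as a robustness check.

*Correlation-structure comparison.* Gene–gene Pearson correlation
matrices from two datasets over a shared gene list are compared by the
Frobenius norm of their difference. The null permutes *gene labels* of
the expression matrix — the permuted correlation matrix is a symmetric
row/column permutation of the original, so the multiset of pairwise
correlations is preserved exactly while gene identity is destroyed;
permuting sample labels instead would destroy the correlations
themselves and is deliberately not offered. The norm includes the square
root; since the permutation P compares ranks, including or dropping the
root cannot change P, and a test asserts exactly that invariance.
P counts permuted distances *strictly below* the observed one.

## Numerical and testing choices

- Empirical P values are step functions of F; monotonicity (nonincreasing
  in F) is asserted as a property.
- Pairs whose dosage is constant across clones are unidentifiable; they
  are skipped and counted, never fitted.
- Missing clone values are dropped pairwise per gene–marker pair.
- Calibration is checked on a global-null panel (no planted effects).
  The ~50,000 pair-level P values are *marginally* uniform but not
  independent — pairs share genes, and neighboring markers share
  fragments — so the Kolmogorov–Smirnov test, which assumes independent
  draws, is applied to a one-pair-per-gene subsample, while mean and tail
  frequencies are checked on the full set.
- Master seed plus fixed per-stage offsets derive each stage's child
  seed, so any stage can be regenerated alone; all seeds stay below
  2³¹ − 1.

## Known limitations

- The full genome-wide cross product (~5 × 10⁹ pairs) is cluster-scale;
  the mapper's default evaluates all cis candidates plus a marker stride
  for trans, which tiles the genome but can skip the exact source marker
  of a weak trans effect.
- The permutation is per gene-vector per round; a global clone
  permutation shared across genes in each round is a defensible
  alternative that would preserve gene–gene correlations under the null.
- Mode normalization assumes both copy states are present in the pooled
  data of each chromosome class; datasets without gains fail loudly
  rather than silently rescaling noise.
- The one-to-one block matcher is greedy, not optimal; with heavily
  nested blocks an optimal assignment could differ.
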