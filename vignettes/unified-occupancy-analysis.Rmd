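---
title: "Unified multi-sample peak calling and occupancy analysis"
author: "UniPeakR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified multi-sample peak calling and occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Motivation

Most ChIP-seq peak callers analyze one sample at a time and report a
binary list of peaks per sample. When the question is *quantitative
co-occupancy* — how strongly do dozens of transcription factors bind the
same loci, and what does that predict about transcription — per-sample
peak lists are awkward: the coordinates disagree between samples,
thresholds discard intensity information, and weak-but-real signal at a
site defined by another factor is lost. UniPeakR instead calls **one
consistent set of enriched regions across all samples** and reports a
regions × samples matrix of read counts, which is then normalized to
continuous occupancy scores. Negative controls (input, IgG,
reverse-crosslinked chromatin) and histone-mark libraries never shape
the regions, but their reads are counted inside them, so they are
available as covariates rather than being consumed by pre-filtering.

# The density model

Each aligned read contributes a single *hit* at the 5'-most reference
base of its alignment, on the alignment's strand (for a reverse-strand
alignment this is the rightmost aligned base). With $C(j)$ the number of
5' hits at base $j$, the smoothed density at base $i$ on one strand is

$$
H(i) \;=\; \frac{\sum_{j=i-h}^{i+h} K\!\left(\frac{i-j}{h}\right) C(j)}
               {\sum_{k=-h}^{h} K\!\left(\frac{k}{h}\right)},
\qquad
K(x) = \tfrac{3}{4}(1 - x^2)\,\mathbf{1}\{|x| \le 1\},
$$

an Epanechnikov-kernel weighted average with a **fixed,
position-independent denominator**. Because the denominator does not
adapt at chromosome ends, every hit at least $h$ bp from an end
contributes exactly unit mass to the profile; edge hits lose the mass
that falls off-chromosome. This is deliberate: it keeps the profile
linear in the hits (smoothing a merged track equals summing smoothed
tracks) and makes the fold-enrichment threshold interpretable as a read
density. The kernel is evaluated at integer offsets only, matching the
discrete formula; smoothing is direct sparse convolution (no FFT — at
these bandwidths a compiled moving weighted sum is exact and fast
enough).

# Strand shift

Sequencing reads 5' ends of both strands of sheared fragments, so
forward- and reverse-strand pileups flank a binding site at a
displacement of about one fragment length; each strand must be shifted
toward the center by $s \approx F/2$ before the strands can be summed.
The shift is estimated per sample:

1. Preliminary regions are called from the sample's own unshifted
   forward-plus-reverse profile at bandwidth 50 nt, fold threshold 25×,
   kurtosis threshold 50, and the 1000 regions with the most reads are
   kept.
2. For each region and each integer shift $s \in [25, 150]$ nt, the
   Pearson correlation between the forward profile translated $+s$ and
   the reverse profile translated $-s$ is computed over the region's
   span **extended by the maximum shift on both sides**. The extension
   is a deliberate convention: without it, shifted profiles are
   truncated at the region border, which biases the correlation for
   regions whose strand pileups were split into separate preliminary
   regions (this genuinely happens when the fragment length exceeds
   twice the preliminary bandwidth).
3. Each region's correlation-maximizing shift votes; votes from regions
   whose best correlation falls below 0.3 are discarded. The vote
   distribution is smoothed on the shift grid with an Epanechnikov
   kernel of bandwidth 5 nt, and the global maximum is the sample-wide
   shift. Ties — both in the per-region argmax and at the smoothed
   maximum — break toward the smaller shift, a documented convention.

Negative controls rarely have enough enriched regions for their own
estimate and receive the median of the ChIP samples' shifts (midpoint
for an even count). Histone-mark samples are treated the same way: they
are excluded from region calling, and a diffuse mark would make its own
preliminary-region estimate unreliable.

# Region calling and filters

After shifting, each ChIP sample's strand profiles are re-smoothed at
bandwidth 100 nt (wider, to capture adjacent binding sites as one
region), combined, and summed across samples. Enriched regions are
maximal runs of bases where this pooled density strictly exceeds
`fold` × b, with the uniform background b = total retained ChIP reads /
effective genome size. The defaults repeat the preliminary-pass settings
(fold 25, kurtosis 50, minimum strand correlation 0.3); the final pass
adds structural filters: regions on chrX/chrY/chrM, regions overlapping
a blacklist interval by at least 1 bp, and regions longer than 500 bp
(strictly; exactly 500 bp survives) are removed. Applied conventions
worth naming:

* **Kurtosis** is excess (Fisher) kurtosis of the multiset of shifted
  5'-start positions inside the region; a raw-kurtosis flag is provided
  since either variant is defensible. Zero positional variance (a
  single-base read stack, the canonical artifact) is defined as $+\infty$
  and always fails.
* **Peak position** is the leftmost argmax of the pooled density.
* **Strand correlation** in the final pass uses the pooled shifted
  strand profiles, not per-sample profiles — with many samples a
  per-sample rule would multiply marginal failures.
* The 500 bp size filter applies only to the final pass, not to the
  shift-estimation regions.

Counting then places each sample's shifted hits (forward $+s$, reverse
$-s$) into the surviving regions — closed 1-based intervals, the
GenomicRanges convention used throughout the package — for **all**
samples including controls and histone marks.

# Normalization

Counts are made comparable across samples by median-of-ratios size
factors and variance-stabilized with
$\tau(q) = \int_0^q dv / \sqrt{v + \alpha(v)\,v^2}$, where $\alpha(q)$
is a fitted dispersion–mean relationship. The dispersion is estimated
by pooling, across every replicate class with at least two samples, the
per-region mean and variance of factor-normalized counts, and fitting a
fixed-span (0.3) local linear regression of log variance on log mean.
Two numerical points: the log of a sample variance is debiased
analytically before fitting (its expectation under normal-theory
scaling is $\log\sigma^2 + \psi(\tfrac{m-1}{2}) - \log\tfrac{m-1}{2}$
for $m$ replicates — without this the fitted variance, and hence the
dispersion, is systematically low for small $m$); and the integral is
evaluated after substituting $v = t^2$, which removes the square-root
singularity at zero so a cumulative trapezoid on a uniform grid of
4096 points is accurate (the Poisson limit $\tau(q) \to 2\sqrt{q}$ is
reproduced to well under 1%). Zero-variance region/class points are
floored rather than dropped, so identical replicates correctly drive
the fit to the dispersion floor ($10^{-8}$). We read "a single
empirical dispersion per analysis" as one pooled dispersion–mean
*relationship* rather than one scalar — only fitted values are ever
used — and expose a scalar-dispersion option for the other reading.
No numeric parity with any particular reference implementation is
promised; the contract (monotone, variance-flattening, size-factor
aware) is what the tests pin down.

# Downstream analyses

* **Clustering**: sample–sample distances are $1 - r$ (Pearson) over
  region occupancy vectors; rooted ultrametric trees come from UPGMA
  (average-linkage `hclust`, heights halved) and unrooted trees from
  Saitou–Nei neighbor joining (`ape::nj`). Ties in the minimal pair
  merge in index order.
* **Motif-conditioned tests**: per TF, replicate occupancy columns are
  averaged; occupancy at consensus promoters with versus without a
  motif set is compared by a two-sided Welch t-test (a Student option
  exists; Welch is the default because group variances have no reason
  to match). The reported statistic is the signed log10 p-value,
  positive for enrichment at motif-bearing promoters; base 10 is a
  convention flag.
* **Motif scanning**: windows of 201 bp centered on region peaks are
  scored on both strands with log2-odds against a uniform 0.25
  background; per-window p-values come from the exact null distribution
  of the discretized score (dynamic programming over PWM columns,
  granularity 1/1000 bit), and E = best p × total windows scanned in
  the run. The search-space convention makes E run-relative, as in
  database search tools; with very few regions E < 10 is permissive by
  construction, so the per-motif E-values are also exported. This
  scanner is a documented approximation of MAST's statistics;
  pre-computed MAST tables can be ingested instead and are the fidelity
  route.
* **Regulation model**: for each cell type one two-block PLS model (our
  SIMPLS implementation; CRAN's pls package is not a dependency)
  regresses the replicate-level response matrix (PIC, histone marks,
  Pol II, CAGE, RNA) on control plus TF occupancy, both blocks
  column-centered and autoscaled (a flag disables scaling). The
  latent-variable count is the first component plus every subsequent
  one that lowers the leave-one-out RMSEP, averaged over response
  columns, by at least 0.01 — applied greedily in component order.
  Leave-one-out is literal (n refits; no algebraic shortcut), and
  per-response $R^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$ with TSS about
  the overall column mean; a constant response is assigned 0. The
  input-only "null" variant quantifies how much predictability is
  generic rather than TF-specific; one multivariate-Y model per variant
  is fitted, matching the matrix form of the model rather than
  per-response fits.

# What the simulators emulate — and what they do not

`simulateChipseq` plants point sources: per site and sample a Poisson
read count, uniform strand assignment, 5' starts at site $\mp F/2$ plus
rounded normal jitter (sd $F/10$ — a modeling convention, not a claim
about sonication physics), uniform background, and background-only
controls. `simulateNBCounts` generates NB counts with log-uniform
region means and planted size factors; `simulateRegulation` generates a
rank-k latent factor structure (factor sds decreasing 3 → 1) shared
between TF occupancy and responses, with independent-noise controls.
All generators are pure functions of their seed.

Real data differ in ways the simulators deliberately omit: PCR
duplicates, mappability and GC structure in the background, fragment
length heterogeneity, copy-number variation, and motif-driven sequence
at sites. Passing tests therefore demonstrate algorithmic correctness
and calibration under the stated model, not end-to-end performance on
ENCODE-scale data: the published analyses this design follows used
billions of reads, which is why the test suite pins properties
(recovery rates, exactness against brute-force oracles, monotonicity)
rather than dataset-specific region counts.

Problem sizes used by the tests and the acceptance script — chromosomes
of 0.2–1 Mb, 10–50 sites, 100 reads per site, 1–3 samples, count
matrices up to 4000 × 8, PLS at n = 150–200 — were chosen as the
smallest scales at which the estimators' sampling noise is comfortably
inside the tested tolerances.

# Known limitations

* Single-end logic only: each read contributes its own 5' end; mate
  information is ignored.
* The fold threshold is relative to a global uniform background;
  locally elevated background (e.g. copy-number gains) is not modeled —
  the blacklist and kurtosis/strand-correlation filters are the only
  artifact defenses.
* Read-length truncation to a common length is upstream responsibility
  when consuming aligned data; duplicate collapsing is off by default
  (a flag exists) because the method's quantitative premise is that
  stack heights carry signal.
* The E-value of the built-in scanner is exact for the discretized
  per-window score but run-relative in its search-space factor;
  cross-run comparisons should use p-values.
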