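# UniPeakR

Multi-sample ChIP-seq peak calling with a single consistent region set,
and quantitative occupancy analysis on top of it.

## The problem

Classical peak callers process one ChIP-seq sample at a time and emit
per-sample peak lists whose coordinates and thresholds disagree across
samples. For regulatory-genomics questions about *co-occupancy* — how
strongly do many transcription factors (TFs) bind the same loci, which
of those loci are promoters, and what does graded occupancy predict
about transcription — that representation throws away exactly the
information needed. UniPeakR calls **one region set from all ChIP
samples jointly** and reports a regions × samples matrix of read
counts, normalized to continuous occupancy scores. Negative controls
and histone-mark libraries never shape the regions but are counted
within them, so they enter later analyses as covariates.

## The model

Each aligned read is one hit at the 5' end of its alignment,
strand-specifically. With C(j) hits at base j, the per-strand density
is the Epanechnikov-kernel weighted average

    H(i) = Σ_{j=i-h..i+h} K((i-j)/h) C(j) / Σ_{k=-h..h} K(k/h),
    K(x) = (3/4)(1-x²) 1{|x|≤1}

with a fixed denominator, so each interior hit carries unit mass.
Per sample, the forward/reverse strand displacement s ≈ fragment/2 is
estimated from the correlation-maximizing shifts of the strongest
preliminary regions (bandwidth 50 nt, fold 25×, kurtosis ≤ 50, top
1000 regions; shift grid 25–150 nt, vote curve smoothed at 5 nt).
Shifted strand profiles are re-smoothed at 100 nt, summed over samples,
and enriched regions are maximal runs where the pooled density exceeds
25× the uniform background (total reads / genome size). Leptokurtic
regions, regions with strand correlation < 0.3, regions on
chrX/chrY/chrM, blacklist overlaps, and regions > 500 bp are removed;
every sample's shifted hits are then counted in the survivors.
Downstream modules cover median-of-ratios size factors with a
negative-binomial variance-stabilizing transformation, promoter
annotation (consensus promoters = density peak within 500 bp of a
Pol II-S5P peak, a CAGE peak, and a TSS), Pearson-distance UPGMA and
neighbor-joining trees, motif-set scanning with exact DP p-values,
Welch tests of motif-conditioned occupancy, and a SIMPLS partial
least-squares model of gene-regulation readouts with leave-one-out
cross-validation.

## Worked example

Simulate 30 binding sites with shared lognormal strengths on a 500 kb
chromosome (3 ChIP replicates + 1 input control, fragment length 150,
100 reads/site), then run the full pipeline:

```r
library(UniPeakR)
layout <- GenomeLayout(c(chr1 = 500000L))
sites  <- as.integer(seq(10000, 490000, length.out = 30))
set.seed(7)
intensity <- exp(rnorm(30, sd = 0.8))
sim <- simulateChipseq(layout, sites, fragmentLength = 150,
                       readsPerSite = 100, backgroundRate = 0.001,
                       nSamples = 3, nControls = 1, seed = 7,
                       intensities = matrix(intensity, 30, 3))
se <- runUniPeak(sim$tracks, layout)
metadata(se)$shifts
#>  chip_01  chip_02  chip_03 input_01
#>       75       75       75       75
head(assay(se), 3)
#>              chip_01 chip_02 chip_03 input_01
#> region_00001     680     618     649        0
#> region_00002      67      56      58        0
#> region_00003      54      70      72        0
```

Every sample's estimated shift is 75 bp — half the simulated fragment
length — and 28 of the 30 sites are called (the two weakest fall below
the 25× threshold, as they should). Normalization and clustering:

```r
occ <- normalizeOccupancy(se)
round(head(assay(occ, "occupancy")[, 1:3], 3), 2)
#>              chip_01 chip_02 chip_03
#> region_00001   25.52   24.08   25.87
#> region_00002    8.81    8.03    8.53
#> region_00003    7.96    8.91    9.42
d <- pearsonDistance(assay(occ, "occupancy")[, 1:3])
round(d, 3)
#>         chip_01 chip_02 chip_03
#> chip_01   0.000   0.010   0.004
#> chip_02   0.010   0.000   0.007
#> chip_03   0.004   0.007   0.000
ape::write.tree(upgmaTree(d))
#> (chip_02:0.0043,(chip_01:0.0021,chip_03:0.0021):0.0022);
```

The occupancy scores are on a variance-stabilized scale (a 10× count
range becomes ~3× in score), and the replicates cluster at Pearson
distances of about 0.01. A thin command-line front end over the same
functions lives in `exec/unipeak` (`call`, `normalize`, `simulate`
subcommands with a YAML config mirroring `unipeakDefaults()`).

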