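# methylCTCF

An R package for the integrative analysis of differential CTCF binding,
DNA methylation and nucleosome dynamics between two cellular conditions —
the motivating system being wild-type (WT) mouse embryonic stem cells
versus *Tet1/Tet2* double-knockout (DKO) cells, in which the loss of 5mC
oxidation reshapes the methylome, repositions nucleosomes and evicts CTCF
from a subset of its sites.

The package is aimed at computational epigenomics researchers who want to
(a) predict CTCF binding from sequence with a biophysical model, (b) call
differential methylation, differential nucleosome occupancy and
replicate-consensus differential CTCF binding from standard file formats
(FASTA, BED, BEDPE, bedGraph, methratio-style TSV), and (c) quantify how
well sequence and chromatin features predict CTCF loss and how CTCF loss
at domain boundaries propagates to gene expression. A synthetic epigenome
generator with a machine-readable truth manifest makes every step testable
end to end.

## The core model

CTCF-DNA binding affinity is predicted from sequence with a TRAP-style
occupancy model. A motif of width *w* (19 bp for CTCF) is a position
probability matrix *p(j,b)*; every sequence window *S* gets a mismatch
energy relative to the per-column consensus,

    βE(S) = (1/λ) Σ_j ln[ p(j, b_max) / p(j, S_j) ],

and a binding probability

    p(S) = R₀ e^(−βE) / (1 + R₀ e^(−βE)),

with defaults R₀ = 10⁹ and λ = 1.5. Probabilities are computed on both
strands, summed and capped at 1, and assigned to window centres; this
per-bp affinity landscape is the basis for region affinities, metaplots
around CpG classes, periodicity analysis (the affinity landscape
oscillates with the nucleosome repeat length) and k-means clustering of
per-site profiles.

Around it sit the standard analyses: CpG classification (common
methylated ≥ 0.8 in both; gained < 0.2 → > 0.5; lost > 0.5 → < 0.2;
unmethylated < 0.2 in both), 1-kb sliding-window DMR calling at > 10%
deviation, per-bp nucleosome occupancy with 100-bp differential windows,
fragment-overlap shift classes (95% / 70% cut-offs), NRL estimation from
dyad autocorrelation, replicate-consensus CTCF site categories (present in
all replicates of one condition and none of the other), Mann–Whitney
ROC/AUC predictor comparison, element-level fold enrichment, and an
eight-category expression-linkage table with chi-square tests.

## Worked example

Simulate a 1-Mb two-condition epigenome with planted truth (180 CTCF
sites in two affinity tiers, CpG islands, planted DMRs, methylation
spreading around lost sites, phased nucleosomes at NRL 176 bp, two
replicates per condition), then run the core analyses:

```r
library(methylCTCF)
library(S4Vectors)

cfg <- syntheticConfig()        # defaults: 1 Mb, seed 1
sim <- simulateEpigenome(cfg)

## replicate-consensus CTCF site categories
sites <- consensusSites(sim$peaks$wt, sim$peaks$dko)
table(mcols(sites)$category)
#>        common          lost        gained uncategorized
#>           123            57             4             0

## nucleosome repeat length from WT dyads (planted: 176 bp)
estimateNRL(sim$fragments$wt[[1]])$nrl
#> [1] 175.7775

## DMRs: the 20 planted blocks plus the spreading regions that the
## generator creates around the 57 lost CTCF sites
dmrs <- callDMRs(sim$meth$wt, sim$meth$dko)
length(dmrs)
#> [1] 134

## which predictor of CTCF loss wins?
occW <- occupancyTrack(sim$fragments$wt)
occD <- occupancyTrack(sim$fragments$dko)
ms   <- scanMotifs(sites, sim$bundle$genome, sim$bundle$motif)
tab  <- buildPredictorTable(ms, occW, occD, sim$meth$wt, sim$bundle$genome)
rocAUC(tab$flankCpgDensity, tab$label, direction = "<")$auc  # 1-kb CpG density
#> [1] 0.7754956
rocAUC(tab$motifScore, tab$label, direction = "<")$auc       # motif strength
#> [1] 0.621452
```

The consensus table recovers the planted common/lost/gained partition
exactly (peak false-negative rate is 0 by default). The NRL estimate is
within half a base pair of the planted 176 bp. The AUCs reproduce the
qualitative ordering built into the generator's site-loss model — local
CpG density protects CTCF binding more strongly than motif strength does,
and both beat chance.

`runPipeline(config, outdir)` runs everything (simulation, affinity
landscape, CpG classes, smoothing, DMRs, occupancy, differential
occupancy, NRL, consensus sites, motif scan, composition, normalised
profiles, enrichment, predictor AUCs, expression linkage) from one JSON
config and writes inputs, results and a provenance record; a packaged demo
config is at `system.file("extdata", "demo_config.json", package =
"methylCTCF")` and completes in well under a minute.

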