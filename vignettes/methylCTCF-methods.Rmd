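---
title: "Models and methods in methylCTCF"
author: "methylCTCF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in methylCTCF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

methylCTCF implements an integrative analysis of how DNA methylation and
nucleosome repositioning shape differential CTCF binding between two
cellular conditions — the motivating system is wild-type (WT) mouse
embryonic stem cells versus Tet1/Tet2 double-knockout (DKO) cells, where
loss of 5mC oxidation globally remodels the methylome. The package covers:

* a biophysical (TRAP-style) model predicting CTCF binding affinity
  landscapes from genome sequence;
* per-CpG methylation classification, smoothed methylation landscapes and
  sliding-window DMR calling;
* nucleosome occupancy from mononucleosome fragments, differential
  occupancy regions, fragment-overlap shift classes and nucleosome repeat
  length (NRL) estimation;
* replicate-consensus classification of common / lost / gained CTCF sites
  with motif scanning and CpG composition;
* anchor-centred average profiles with replicate averaging, cross-condition
  normalisation, periodicity estimation and profile clustering;
* fold enrichment, ROC/AUC comparison of predictors of CTCF loss, and
  linkage of expression changes to lost domain boundaries;
* a synthetic epigenome generator that plants known ground truth so that
  every analysis step can be validated end to end.

# The TRAP binding model

A motif is a position probability matrix $p(j,b)$ of width $w$ (19 bp for
CTCF), normalised from integer counts after adding a pseudocount of 1 to
every cell so that all probabilities are strictly positive and energies
stay finite. Each sequence window $S$ is scored by its mismatch energy
relative to the per-column-best consensus,

$$\beta E(S) \;=\; \frac{1}{\lambda}\sum_{j=1}^{w}
\ln\frac{p(j,b_{\max})}{p(j,S_j)},$$

which is zero exactly for the consensus, and converted to a binding
probability with a concentration-like constant $R_0$:

$$p(S) \;=\; \frac{R_0\,e^{-\beta E}}{1 + R_0\,e^{-\beta E}}.$$

Defaults are $R_0 = 10^9$ and $\lambda = 1.5$, the parameterisation used in
the CTCF literature for this model family. The occupancy form above is the
published TRAP form; the package adopts it as the natural reading of a
"TRAP constant plus energy mismatch scale" parameterisation and documents
it here as an interpretation rather than a transcription.

Numerical and design choices:

* **Strands.** $p$ is computed independently on the forward and
  reverse-complement readings of each window and the two are **summed,
  capped at 1** (`strandMode = "sum"`). CTCF binds one orientation per
  site, but either strand can carry the motif; max-pooling is available via
  `strandMode = "max"` because the choice is not fixed by first principles.
* **Coordinates.** A window's probability is assigned to its centre
  position, `floor(start + w/2)` in 0-based terms. Positions within half a
  motif width of a contig end are missing (NA), never zero.
* **Ambiguous bases.** Windows containing non-ACGT characters are missing,
  not zero — a zero would carve artificial affinity valleys into assembly
  gaps.
* **Region affinity** is the sum of per-position window probabilities over
  a region (missing positions contribute nothing), which makes it additive
  over disjoint sub-regions.

The implementation is vectorised per motif column; the test suite holds it
to within $10^{-9}$ relative error of an independent brute-force
double-loop scan.

## The packaged motif

`loadCtcfMotif()` returns a **constructed, synthetic** 19-bp CTCF-like
matrix (`inst/extdata/ctcf_synthetic.pfm`, JASPAR text dialect): 19 sharp
columns (counts 199 vs 1) whose consensus carries one central CpG, mirroring
the width, information content and CpG placement of the canonical CTCF
motif. It is a labelled stand-in, not the empirical JASPAR matrix; any real
PFM in JASPAR dialect can be supplied through `loadPFM()`. Column sharpness
matters for this model class: with $R_0 = 10^9$, soft columns would let
random sequence saturate the occupancy form, while counts of ~200:1 put a
random window ~14 mismatches (~$\beta E \approx 43$) below the consensus.

# Methylome analysis

**CpG classes.** `classifyCpG()` applies the standard WT/DKO thresholds:
common methylated ($\ge 0.8$ in both), gained ($< 0.2$ WT, $> 0.5$ DKO),
lost ($> 0.5$ WT, $< 0.2$ DKO), unmethylated ($< 0.2$ both), otherwise
"other". The 0.8 bound is inclusive and the 0.2/0.5 bounds strict, exactly
as printed in the definitions the package follows; the classes partition
the unit square (property-tested on a grid).

**Strand collapsing.** Bisulfite calls on the two strands of a CpG are
merged coverage-weighted into one dinucleotide record at the plus-strand C
position when reading methratio-style TSVs — CpG methylation is symmetric
and halving the records doubles effective coverage.

**Smoothing.** `smoothMethylation()` computes the unweighted mean ratio of
covered CpGs per sliding window (default 500 bp), the representation in
which methylation landscapes and their CTCF bifurcation points are read.

**DMR calling.** `callDMRs()` implements the deviation rule: 1000-bp
windows (step 100 bp; the step is a package choice, as "sliding" does not
fix one), qualified when they contain at least `minCpgs = 4` CpGs covered
at `minCov = 4` or more in both conditions and the window means deviate by
strictly more than `delta = 0.10`. Only CpGs adequately covered in *both*
conditions enter the means, so the two conditions are compared over the
same positions. Overlapping or adjacent qualified windows of one direction
merge; where a gain run and a loss run overlap across a sharp transition,
the overlap is split at its midpoint so output DMRs are disjoint; merged
intervals are re-verified against the deviation criterion after their means
are recomputed. Two numerical notes: the strict inequality carries a
$10^{-9}$ float guard so a deviation of exactly `delta` is never called,
and `minCpgs`/`minCov` defaults are deliberately conservative guards
against single-CpG windows. The package implements the stated deviation
rule only — no beta-binomial significance testing is layered on top, and
no attempt is made to reproduce any particular external caller's extra
filters.

# Nucleosome analysis

**Occupancy.** `occupancyTrack()` counts fragments covering each base pair;
replicates merge additively before scaling. Normalisations: raw counts,
per-million fragments (default), or mean-scaled. Raw tracks conserve mass
(sum of values equals sum of fragment lengths).

**Differential occupancy.** Non-overlapping 100-bp tiles (a sliding step
can be set, but tiles make region counts well defined), calling windows
with $|\log_2(\mathrm{DKO}/\mathrm{WT})| \ge 1$ and a signal floor of half
the pooled genome-mean occupancy. Both thresholds are package defaults —
no canonical values exist for them — and both are exposed. The operation is
antisymmetric: swapping inputs swaps gained and lost labels.

**Fragment shift classes.** For each WT fragment the DKO partner maximising
the reciprocal overlap $f = |{\rm intersection}| / \max(|{\rm WT}|, |{\rm
partner}|)$ is found; classes use the published cut-offs ($f > 0.95$
stable, $f < 0.95$ shifted by more than 5%, $f < 0.70$ shifted by more
than 30%, no partner unmatched). The longer-fragment denominator is the
conservative reading of "overlap between the bodies", which does not fix a
denominator.

**NRL estimation.** `estimateNRL()` tabulates dyads (fragment midpoints)
per base pair, computes the autocovariance by FFT, and searches lags
100–400 bp for the dominant interior local maximum. Significance compares
the peak against a noise floor estimated from the *local roughness* of the
autocorrelation (median absolute successive difference), not its overall
spread — a genuine smooth oscillation would otherwise count as its own
noise. The peak position is refined with a local quadratic fit that
includes a linear baseline term over ±12 lags; a plain 3-point parabola is
biased by the sloping autocorrelation baseline (we measured ~2–3 bp of
bias at short repeat lengths, removed by the baseline term). Uniform dyads
return an explicit "no periodicity" result, never a number. The reported
uncertainty is a curvature-based heuristic (residual scatter over peak
curvature, floored at 0.5 bp).

# Profiles

`anchorProfile()` averages a signal at each offset in $[-\mathrm{flank},
+\mathrm{flank}]$ from anchor centres, per replicate, then reports the
cross-replicate mean and **sample** standard deviation ($n-1$), matching
the convention of shading the standard deviation of replicate averaging.
Minus-strand anchors are mirrored. Default flanks follow the field's
plotting conventions (±2000 bp for CTCF/affinity, ±1000 bp for
methylation around nucleosomes) and are arguments everywhere.

`normalizeToCommon()` multiplies both DKO profiles by
$s = \overline{\mathrm{WT\,common}} / \overline{\mathrm{DKO\,common}}$, so
after scaling the common-site means agree exactly while the lost-site
contrast is untouched; the operation is idempotent.

`estimateProfilePeriodicity()` detrends the profile with a running mean
(default window, twice the upper period bound), then scans a fine grid of
candidate periods (0.25 bp) with a least-squares sine fit; missing
positions are simply dropped, which is what masked contig edges need.
Significance is a permutation test: 199 shuffles of the detrended values,
comparing the observed peak $R^2$ over a coarse grid against the permuted
maxima ($\alpha = 0.01$). The uncertainty is the half-width of the $R^2$
peak at half prominence. Flat or white-noise profiles are reported as not
periodic.

`clusterProfiles()` is k-means (default $k = 6$, seed 1 — $k$ is not fixed
by the problem and both are arguments) after optional subsampling to
200,000 rows, with a per-cluster asymmetry score
$|\bar{L} - \bar{R}| / s_p$, where $\bar{L}, \bar{R}$ are members' mean
left/right flank values and $s_p$ the pooled SD of those means. A control
matrix (e.g. 50,000 random-region profiles) is clustered with identical
settings when supplied.

# Association statistics

**Fold enrichment** counts query *elements* overlapping a feature by at
least 1 bp (the element, not the base pair, is the unit, matching
"percentage overlap of sites" phrasing). The analytic expectation is
$n_q \cdot \mathrm{feature\ bp} / \mathrm{genome\ bp}$; the permutation
method re-places elements uniformly (length-preserving, chromosome-matched)
and reports the empirical expectation and p-value.

**ROC/AUC.** `rocAUC()` is the Mann–Whitney form with average ranks, i.e.
ties counted half — exactly the probability a random positive outscores a
random negative with ties split. Orientation is an explicit argument and
no AUC ≥ 0.5 convention is forced. The suite holds it equal to all-pairs
brute force (including ties) and to pROC.

**Predictors of CTCF loss.** One row per motif site: motif log-odds score,
nucleosome occupancy change (DKO − WT over the site ±100 bp), WT
methylation level, and flank CpG density over the 1000-bp region centred
on the site (±500 bp). Missing values are masked, not imputed.

**Expression linkage.** Transcripts are tabulated in eight (overlapping)
categories: genome-wide; inside TADs; within 10 kb of any loop boundary;
within 10 kb of any TAD boundary; inside TADs that lost a boundary (a
boundary is lost when a lost CTCF site lies within 10 kb of it); within
10 kb of a lost loop boundary; within 10 kb of a lost TAD boundary; lost
CTCF in the promoter (±1 kb around the TSS — the promoter window is a
package default, exposed as an argument). Each category's (up, down)
counts are compared with the genome-wide category by a 2×2 chi-square
without continuity correction (intended use has large counts); comparing
against genome-wide rather than each category's complement is the
package's documented choice.

# The synthetic epigenome generator

No generative model exists for the real data, so every generator parameter
is an artifact choice; this section states the defaults and why they were
chosen. The generator's purpose is to produce data with the statistical
structure the analysis assumes, together with a truth manifest that is
written as separate JSON and never encoded in the analysis inputs.

**Genome.** One 1-Mb chromosome by default — large enough that windows,
profiles and replicate peak sets behave as they do on real chromosomes,
small enough that the full pipeline runs in seconds. The base sequence is
made CpG-free first, then CG dinucleotides are planted at 0.10/bp inside
20 islands of 2 kb and 0.01/bp outside — island-like versus
mammalian-background densities. 180 CTCF motifs (60 inside islands, 120
outside, plus 4 DKO-only "gained" sites) are planted on random strands in
two tiers: strong (exact consensus) and weak (one random substitution; one
is enough to separate the tiers' scores cleanly while keeping weak sites
above the default 80% scan threshold).

**Site loss.** Each site's loss probability is
$\mathrm{logit}^{-1}(0.2 + 1.4\,[\mathrm{weak}] - 0.08\,d)$ with $d$ the
local CpG density per kb over ±500 bp. Island sites ($d \approx 80$–100)
essentially never lose CTCF; background sites lose it at ~0.35 (strong) to
~0.7 (weak). This builds in the two qualitative facts the analysis should
recover: CpG-dense flanks protect binding (density is the best predictor),
and weaker motifs lose binding more often (motif score is a weaker but
real predictor). Loss flags are drawn in `generateGenome()` so that
methylomes, peaks and expression all see one consistent truth under one
seed.

**Methylomes.** Island CpGs at 0.05 in both conditions; background CpGs at
0.30 in both by default, so that all WT/DKO differences come from planted
structure: 20 DMR blocks of 2 kb at ±0.35 (placed in background sequence
clear of islands and sites, ≥5 kb apart — beyond one caller window plus
merging reach), and methylation spreading around each lost CTCF site,
$\Delta(d) = 0.3\,e^{-d/500\,\mathrm{bp}}$ on a per-site side (left, right
or both, recorded in the manifest). Observed ratios are
$\mathrm{Binomial}(c, p)/c$ with Poisson coverage (mean 20, floored at 1)
— bisulfite counting noise and nothing else.

**Nucleosomes.** Half of 120,000 fragments per replicate come from phased
arrays: dyads at site centre $+ k \cdot \mathrm{NRL}$, $k = \pm1..\pm5$,
Gaussian jitter SD 20 bp, with the $k = 0$ position excluded at sites
bound in that condition (the CTCF-bound motif is nucleosome-depleted) and
included where the site is unbound — so occupancy over lost motifs is
restored in DKO. The rest is uniform background. Fragment lengths are
Normal(150, 10) clipped to [100, 200] bp. Default NRL 176 bp, the repeat
length characteristic of the regions this analysis targets.

**Peaks.** Every bound site yields a peak (centre ±150 bp, edges jittered
SD 10 bp) in every replicate of its condition, minus false negatives at
rate `pFn` (default 0). With `pFn = 0` the consensus rule must recover the
planted partition exactly, and the tests require that.

**Expression.** TADs tile the chromosome (100 kb); loops connect random
boundary pairs. Baseline up/down probabilities are 0.15/0.10 (genome-wide
excess of up-regulation). Transcripts inside TADs with a lost boundary
gain down-regulation probability $0.4 \cdot (0.2 + 0.8w)$ where $w$ decays
linearly to zero at twice the 10-kb boundary distance, and transcripts
with a lost CTCF site in their promoter receive the full boost — giving
the monotone ordering genome-wide < near lost boundary ≤ lost promoter.

**Determinism.** Every simulation step seeds the RNG from the config seed
plus a fixed per-step offset, so identical configs give byte-identical
output files, and individual steps can be re-run in isolation.

**What the generator does not emulate.** Read-level sequencing (no FASTQ,
no error model), MNase digestion bias, replicate batch effects,
chromosome-scale heterogeneity, non-CpG methylation, 5hmC/5fC as separate
base-resolution tracks, and the true genomic correlation structure of CpG
density, motif strength and chromatin state. Tests passing on this
generator therefore demonstrate that the estimators recover what they are
designed to recover under their stated noise models — binomial counting
noise, Poisson coverage, Gaussian positioning jitter — not that the
biological effect sizes of any real dataset will match.

# Validation scales and the acceptance benchmarks

The package's benchmark problem sizes are chosen as the smallest at which
each estimator's noise floor is comfortably below its tolerance: the DMR
benchmark uses a 2-Mb genome with 50 planted DMRs at Δ = 0.35, coverage
20×, and background CpG density 0.04/bp (≈40 CpGs per 1-kb window, putting
the 0.10 calling threshold five standard errors above baseline noise, so
"zero off-target calls" is a fair requirement); NRL recovery uses 80,000
fragments per replicate over 0.5 Mb; the predictor comparison uses the
default 1-Mb genome with 180 sites; and the expression-linkage benchmark
uses a 2-Mb genome with deliberately sparse lost sites so that only some
TAD boundaries are lost. One interpretation choice: the null
expression-linkage calibration ("all categories indistinguishable without
a boost") is scored as the fraction of run × category chi-square tests
with p > 0.01 across 100 seeded replications, because the per-run "all
categories simultaneously" event has no controlled level when the
categories share most of their transcripts.

# Known limitations

* The TRAP strand combination (sum versus max) is an exposed choice, not a
  derived one; results near saturation are insensitive to it, but
  region-affinity magnitudes differ by up to 2×.
* The DMR caller implements the deviation rule only; windows with
  systematic coverage differences between conditions are handled by the
  shared-CpG restriction, not by a count-based test.
* `differentialOccupancy()` thresholds are not calibrated to reproduce any
  published absolute region counts; those depend on normalisation details
  that are not in scope.
* The NRL uncertainty and the periodicity peak half-width are heuristics;
  for formal intervals, bootstrap over anchors.
* Chi-square against the genome-wide category double-counts transcripts
  that are in both sets; with the intended large-n use this biases towards
  conservatism, but exact independence does not hold.
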