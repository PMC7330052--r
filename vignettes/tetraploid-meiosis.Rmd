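---
title: "Tetraploid meiosis from triploid progeny: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetraploid meiosis from triploid progeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetragamete)
```

## The cross and the data

An allotetraploid (doubled-diploid) parent carries two copies of each of
two divergent subgenomes.  At SNPs diagnostic of one ancestral species it
is duplex, AAMM, in known coupling phase: both M alleles sit on the two
chromosomes of M-subgenome origin.  Crossed to a diploid parent that is
nulliplex (AA), every triploid offspring receives one A allele from the
diploid side, so its M-allele dose (0/1/2, called from two-channel
fluorescence or supplied directly) identifies the tetraploid's diploid
gamete: AA, AM or MM.  A markers x hybrids dose matrix is therefore a
direct read-out of a gamete cohort, and everything in this package is an
analysis of that cohort.

## The single-locus inheritance model

Meioses are a mixture of two pairing regimes.  With probability `PP`
(preferential pairing) the four chromosomes form strictly homologous
bivalents (M with M, A with A); each bivalent transmits one chromatid, so
the gamete is always AM — disomic inheritance transmits the parent's full
interspecific heterozygosity.  With probability `τ = 1 − PP` pairing is
random: the three pairing configurations are equally likely, the
homologous one again gives AM, and either heterologous configuration gives
AA : AM : MM as 1/4 : 1/2 : 1/4, which marginalises to the classic
1 : 4 : 1 (2/3 ≈ 66% heterozygous).  Double reduction — both copies of the
same parental chromosome region ending up in one gamete, requiring a
quadrivalent and a crossover between centromere and locus — occurs only
within the tetrasomic fraction, at relative frequency `β ≤ 1/6`, and
produces AA or MM with probability 1/2 each.  Assembled:

$$p_{AM} = PP + \tau\,\tfrac{2}{3}(1-\beta), \qquad
  p_{AA} = p_{MM} = \tau\left[\tfrac{1-\beta}{6} + \tfrac{\beta}{2}\right].$$

The cited likelihood framework behind this decomposition is not printed in
the source literature we follow; the parameterization above is stated
explicitly so it can be audited, and the test suite verifies it against an
independent enumeration of pairing configurations and double-reduction
classes, plus the three analytic anchors (all-AM at `PP = 1`; 1:4:1 at
`τ = 1`; `β` at most 1/6).

### Estimators

At a centromeric locus no crossover separates locus from centromere, so
`β = 0` and homozygous gametes arise only from the tetrasomic fraction:
`p_hom = τ/3`.  The multinomial ML estimate is the closed form
`τ̂ = 3(n_AA + n_MM)/n`, clipped to [0, 1].  At a telomeric locus with the
chromosome's `τ` held fixed, `p_hom = τ(1 + 2β)/3` gives
`β̂ = (3 f_hom/τ − 1)/2`, clipped to [0, 1/6]; `β` is unidentifiable when
`τ = 0` (an error by design).  Both closed forms are required, in tests,
to equal a brute-force grid maximisation of the likelihood (step `1e-4`)
within `1e-3` on a thousand random count vectors.

A chromosome's `τ` is the *mean of the per-marker* `τ̂` over its
designated centromeric markers (four in the emulated design), not a
pooled-count ML — matching the averaging convention of the study design we
follow — with the sd across markers reported as dispersion.  `β` is
likewise the mean over the designated telomeric markers.  Standard errors
use the binomial delta method (`se(τ̂) = 3·sqrt(f(1−f)/n)`); a seeded
gamete-resampling bootstrap is available because the ± semantics of the
published per-chromosome tables are ambiguous.  Marker roles
(centromeric/telomeric/other) are configuration: centromere coordinates
are metadata the dose data cannot reveal.

PHR (parental heterozygosity restitution) is simply the heterozygous
fraction — per marker over observed gametes, per gamete over observed
markers, per chromosome as the mean of its markers.  At a centromeric
locus `PHR = 1 − τ/3` in expectation, which the tests verify against
simulation within three binomial standard errors.

## Segregation tests

Three Pearson χ² tests per marker, no continuity correction, no
multiple-testing adjustment in the headline classification (a Bonferroni
column is emitted alongside): allele counts `2n_MM + n_AM` vs 1:1 (df 1);
`n_AA` vs `n_MM` among homozygous gametes only (df 1, flagged untestable
when there are none); genotype counts vs 1:4:1 (df 2, flagged when an
expected class is below 5).  One property deserves note: the allele-level
test treats the `2n` alleles as independent, but heterozygous gametes
contribute *zero* variance to the allele-count difference (their two
alleles cancel), so at the high heterozygosity typical of preferential
pairing the test is conservative — its type-I rate is below α, which is
why real panels show "no distortion" at the allele level while the
homozygote-conditional test (exactly binomial(1/2) under the symmetric
null) finds plenty.  The tests assert conservatism for the allele test
and calibration for the homozygote test; a blanket claim that the
allele test itself is calibrated at any (PP, β) is not attainable for
this statistic, so the provable property is what is asserted.

## Crossovers and graphical genotypes

A gamete's sequence of locus states along a chromosome is run-length
encoded; crossovers between adjacent observed markers are counted as the
minimal number of chromosome-origin switches explaining the transition:
AM↔AA or AM↔MM is 1, AA↔MM is 2 (both chromatid origins must switch),
missing markers are bridged between observed flanks.  The counting
software used in the source study does not document its convention;
minimal-switch is the parsimony choice, and the identity
`crossovers = (runs − 1) + (#AA↔MM adjacencies)` is asserted as a test.

## Two-locus model and the simplified linkage map

For two coupling-phase duplex loci under fully random pairing, exhaustive
enumeration over the three configurations and the chromatid haplotypes of
the two heterologous M/A bivalents (haplotype probabilities
`a = (1−r)/2` non-recombinant, `b = r/2` recombinant) gives a 3x3 joint
genotype table with corners `(2/3)a²`, anti-corners `(2/3)b²`, edges
`(2/3)2ab` and centre `1/3 + (2/3)(2a² + 2b²)`.  Its marginals are the
1:4:1 single-locus distribution for every `r`, and the table is checked
against a million-draw chromosome-wise simulation at
`r ∈ {0, 0.1, 0.25, 0.5}`.  `r̂` is the bounded ML over [0, 0.5]
(tolerance `1e-6`), `LOD = log10 L(r̂) − log10 L(0.5)`.

The map is deliberately built under the tetrasomic hypothesis even though
the data are predominantly disomic — this reproduces the compressed-map
behaviour of the original analysis by design: preferentially paired
meioses contribute no observable interspecific recombination, so apparent
`r̂` shrinks with `τ` and linkage groups with near-complete disomy span
only a few cM.

Grouping is plain connected components above a LOD threshold (the
threshold is data-size dependent: 14 suits a ~250-gamete real panel;
simulations should scale it down), with an average-linkage dendrogram
emitted as a cross-check; the manual split/merge of problem groups done in
the original study is not automated.  **Ordering** deviates from the
design sketch we started from (classical MDS on Kosambi-transformed
distances): near-saturated pairs (`r̂` approaching 0.5) map to huge,
noisy Kosambi distances that dominate a classical embedding, and at the
stated validation size (250 gametes, τ = 0.3, 15 markers) classical MDS
failed its own |ρ| ≥ 0.95 bar on roughly a fifth of seeds.  The shipped
ordering is spectral seriation — the Fiedler vector of the graph
Laplacian weighted by `LOD·(0.5 − r̂)`, a similarity that vanishes
exactly where the distance transform explodes — followed by local
polishing (2-opt reversals and single-marker insertions minimising total
adjacent distance); classical MDS on shortest-path-completed distances
remains as the degenerate-weight fallback.  Positions are cumulative
Kosambi distances (`d = 25 ln[(1+2r)/(1−2r)]` cM) of adjacent `r̂`;
orientation follows physical bp.  Marey diagnostics report per-group
majority-chromosome synteny and Spearman colinearity of cM vs bp.

## Dose calling from fluorescence

The theta angle `atan2(y, x)` in degrees places a sample between pure-A
(0°) and pure-M (90°) signal.  Anchors are per-marker means of control
classes: homozygous A, 1:1 heterozygous, homozygous M.  Expected theta for
an M-allele fraction f interpolates piecewise-linearly through (0, θ_AA),
(1/2, θ_het), (1, θ_MM) — monotone and anchor-exact; a tan-space transform
can be swapped in by the user.  Triploids are assigned the nearest of
f ∈ {0, 1/3, 2/3, 1}, with f = 1 (MMM) flagged invalid for this cross and
low radial intensity (default threshold: 10% of the median control norm)
set to missing.  The original cluster assignment was manual; nearest
expected theta is the deterministic, reproducible replacement, and the
diploid mode (f ∈ {0, 1/2, 1}) exists so that the controls themselves
round-trip to their own genotypes — a 1:1 diploid control sits exactly
between the two triploid heterozygous clusters, so the triploid rule
cannot and should not recover it.

## The simulator: a stated world

The generator's defaults are fixed once, from the emulated study design,
and are not tuned to test outcomes:

- 9 chromosomes; per-chromosome `PP` (0.751, 0.82, 0.749, 0.781, 0.633,
  0.669, 0.733, 0.995, 0.945) and telomeric `β` (0.136, 0.118, 1/6,
  0.084, 0.109, 0.007, 0.132, 1/6, 1/6 — printed 0.167 values are the
  rounded admissible maximum) from the published per-chromosome table;
- marker counts per chromosome (19, 19, 25, 19, 14, 13, 14, 15, 20 = 158)
  and physical spans (26.3–50.8 Mb) from the published panel; 269
  gametes; preset seed 20200625;
- choices the sources do not state, set once to field-realistic values:
  bivalent genetic length 100 cM per chromosome (a typical plant
  chromosome; only ratios of marker spacing to length matter for the
  validated properties), centromere at 40% of the length, markers evenly
  spaced, β ramping linearly from 0 at the centromere to the telomeric
  value at each end, 2% missing cells.

Locus-wise mode draws each marker independently from the single-locus
model — it realises the stated β profile exactly and is the default for
estimator validation.  Chromosome-wise mode simulates whole meioses:
pairing regime per the mixture, Haldane crossovers (Poisson at 1
event/Morgan, no interference — mapping uses Kosambi, a deliberate,
documented mismatch that only matters at large distances), genotypes read
at marker positions.  Its double reduction is an approximate forcing
(probability 6β among random-pairing meioses, shared chromatid origin
distal to the first crossover), calibrated to the telomeric β only; exact
β is guaranteed only locus-wise.  Fluorescence simulation maps doses to
expected theta, adds Gaussian angular noise and a ±10% radial jitter, and
emits control records.

What a green test does **not** establish: the simulator draws from the
same model family the estimators assume, so recovery tests validate the
estimation machinery, not the model's adequacy for real meioses.  Real
data add features the generator omits — per-locus PP variation along a
chromosome (observed in the source system on chromosome 3 and exposed
here only as a per-marker τ̂ diagnostic), selection on gametes, crossover
interference, assay-specific cluster distortions, and non-random
missingness.

## Numerical conventions and degenerate inputs

Estimates are clipped to their admissible ranges ([0,1] for τ̂,
[0, 1/6] for β̂) with a `clipped` flag; `r̂` within `1e-6` of 0.5 is
snapped to 0.5 with LOD 0; Kosambi is infinite at `r = 0.5` (error by
default, `Inf` on request); NJ branch lengths that come out negative on
non-additive input are clipped to zero with the deficit moved to the
sister branch, preserving the joined pair's path length; zero-intensity
fluorescence points, markers with no observed gametes, and
gamete-chromosomes with fewer than two observed markers are flagged
rather than guessed.  QC removes markers first, then samples on the
remaining cells, at missing fraction ≥ threshold (retention means
strictly less than 10% by default); duplicate removal uses exact vector
equality (missing cells must coincide — the redundancy criterion of the
original pipeline's software is unstated, exactness is our choice) and
keeps the first occurrence.  All randomness flows from a single integer
seed; pipelines re-run byte-identically.

## Known limitations

No quadrivalent cytology, chromatid interference, or unreduced-gamete
(FDR/SDR) mechanisms; no along-chromosome PP model; no bit compatibility
with the polyploid mapping packages the original study used; two-parent
duplex x nulliplex designs only, with coupling phase fixed by
construction of the diagnostic markers.
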