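---
title: "Models and methods behind tnseq5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tnseq5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why:
the models behind each stage, the parameters that matter, the numerical
conventions, what the synthetic-data generator does and does not emulate,
and the design choices made where the design was genuinely open.

## 1. The experiment being modelled

A pooled Tn5 mutant library is grown, transposon–genome junctions are
amplified and sequenced out of the transposon *O* end, and per-mutant
abundances are read off from the read counts at each unique insertion
site. The transposon carries an outward-facing constitutive promoter at
its *I* end, so each insertion has an orientation relative to the
disrupted gene: *sense* insertions can drive read-through transcription of
downstream operon members (no polar effect), *antisense* insertions
disrupt transcription. Essentiality is inferred from where insertions are
*absent* in a saturating library; conditional fitness from how read counts
shift between growth conditions.

## 2. Coordinate conventions (readproc)

All coordinates are 1-based inclusive; the chromosome is treated as
circular by default (linear mode by flag). The aligner demands a perfect
match of the first 15 bases of each trimmed fragment (`seed_len = 15`) and
extends ungapped; the best hit is chosen by coverage, then identity, and
exact ties are discarded as ambiguous rather than assigned arbitrarily.

Site correction: Tn5 duplicates `d = 9` bp of target DNA. The first read
base (O-end adjacent) and the reported site (I-end adjacent, the promoter
side) are the two outer bases of the duplicated target, `d − 1` bp apart,
and the orientation flips to the promoter's direction:
hit(+, c) → site(c + d − 1, −); hit(−, c) → site(c − d + 1, +). In the
degenerate `d = 0` limit the coordinate shift is 0 (not −1): the
convention is pinned by the simulator round trip, which must recover every
error-free site exactly.

Rounding of all printed densities and percentages is *half away from
zero* (`round_half_up()`), the commercial rounding used in sequencing
summary tables; base R's round-half-to-even would print some densities
one unit off.

Quality trimming is reduced to a minimal length/N-content screen because
upstream adapter/quality trimming belongs to dedicated external tools and
simulated reads need none.

## 3. Essentiality rules (essentiality)

Pre-filters on intragenic insertions, protein-coding genes only unless
noted (defaults in `filter_policy()`):

* **+1 frame, sense** (`offset mod 3 == 0`): the transposon-borne
  promoter, Shine–Dalgarno and ATG can express the remaining 3′ portion of
  the ORF in frame, so such insertions do not prove dispensability. The
  register arithmetic is not uniquely determined by the construct
  description, so the residue class is a parameter
  (`plus1_frame_offset_mod3`, default 0).
* **Stop codon** (last 3 bp), both orientations. Whether the original
  filter was orientation-specific is unknowable from its wording; removing
  both is the conservative reading.
* **Edges**: sense insertions in the last 9 bp, antisense in the first
  9 bp (`edge_window = 9`, respective pairing; a both-ends/both-
  orientations variant is a switch).
* RNA genes have no frame or stop codon; only the edge filters apply.

Classification, in precedence order: `essential_non_hit` (zero surviving
insertions), `essential_last10` (all offsets ≥ 0.9 × length),
`essential_gap80` (largest insertion-free stretch ≥ 0.8 × length), else
nonessential. Gap computation includes the flanks from the gene start to
the first insertion and from the last insertion to the gene end — the
non-hit and last-10% rules are the boundary cases of exactly that
definition. The 5′ offset convention on minus-strand genes
(`offset = end − position`) is asserted by round-trip tests rather than
inherited from any reference implementation. Genes overlapping other genes
receive sites independently (double-counting is conservative for
essentiality).

## 4. Cluster permutation test (clusterperm)

Maximal runs of consecutive essential protein-coding genes are compared
with a null in which the observed label multiset is uniformly shuffled.
`p(n)` estimates the probability that a random arrangement contains at
least one run of ≥ n essential genes, with the add-one estimator
`(count + 1)/(N + 1)` so p is never 0. Internally a shuffle is drawn as a
uniform random subset of label positions; the maximal run length follows
from the gaps between sorted positions — exactly equivalent to permuting
the labels, but O(k) instead of O(n) per draw.

One hypothesis is tested per *distinct observed run length*, not per run
instance: with per-instance testing the Holm denominator grows with the
number of clusters and the study-scale behaviour (smallest significant
length 6 at 4,054 genes / 616 essential / 100,000 permutations) is not
reproduced. Gene order is linear by default; the chromosome is circular,
but a wrap-around run is a measure-zero concern the `circular` flag can
switch on.

## 5. Differential abundance (diffabund)

The stage reimplements the documented count-based pipeline in simplified
form rather than wrapping an existing package: median-of-ratios size
factors; per-gene NB GLM (log link, size-factor offsets) fitted by IRLS;
two-sided Wald test on the group log2 fold change with the standard error
from the expected information; Benjamini–Hochberg at α = 0.1. Deliberately
absent: empirical-Bayes dispersion priors, LFC shrinkage, Cook's-distance
outlier handling and independent filtering — those belong to the reference
implementation's internals, not to the documented contract. The reference
implementation is used in the test suite as an independent cross-check for
size factors, and a fixed-theta GLM fit cross-checks the IRLS.

Dispersions: gene-wise method-of-moments `α = max(0, (v − μ)/μ²)` with
variances pooled within conditions; a trend `α(μ) = a₁/μ + a₀` fitted by
robust regression (`MASS::rlm`); final dispersion is the log-scale
combination `exp(w·log α_trend + (1 − w)·log α_gw)` with `w = 0.5`.
Gene-wise estimates *below* the trend are raised to the trend before
combining: at three replicates the method-of-moments estimate has huge
downward noise, and letting it pull the final dispersion under the trend
inflates Wald statistics and measurably breaks FDR calibration in null
simulations. Only above-trend (outlier-like) dispersion survives, at
weight 1 − w. Genes with zero counts throughout one group get a 0.5-count
continuity correction and a `pseudo` flag; non-converged IRLS fits are
flagged and their p-values set missing.

With this choice, null simulations at 3 + 3 replicates keep the fraction
of significant genes below ~2% and mixed simulations keep the realized
false-discovery proportion near the nominal 0.1 while detecting ≥ 4-fold
depletions with well over 80% power — the residual excess over 0.1 is the
small-sample liberality of the Wald test itself.

## 6. The synthetic-data generator

Defaults emulate the study system: a high-GC chromosome (GC 0.68), genes
in one-strand operons of 1–6 members with short spacers, ~15% essential
genes placed both as whole essential operons and singly, Tn5 geometry
(9-bp duplication, junction reads beginning with a configurable O-end
marker — the real marker sequence is construct-specific and not public,
so it is a documented parameter), 150-bp reads, triplicate libraries, and
selection modelled as discrete Wright–Fisher resampling with
multiplicative per-generation weights `exp(s)` through a bottleneck
(default 10⁵; `Inf` gives the deterministic limit). Initial mutant
abundances are log-normal (σ = 1), reproducing the heavy-tailed read-count
distribution of real pools; passage and selection then lose a tunable
fraction of sites, qualitatively matching the observed pool contraction.

Viability rule: disrupting an essential gene is lethal for either
orientation; an optional rescue switch (`sense_rescue`, off by default)
keeps sense insertions whose offset falls in the +1 codon register. The
biological mechanism that lets some sense insertions in essential-gene
operons survive (promoter read-through vs a functional truncated protein)
is not settled, so neither is asserted as ground truth; the default keeps
truth labels simple and exactly checkable.

Not modelled, hence not demonstrated by passing tests: PCR and GC bias,
chimeric reads, paired-end sequencing, realistic quality profiles,
transposition cold spots, and reads from the delivery plasmid (a decoy
screen hook exists via `primer_set`/marker filtering). Recovery statistics
on synthetic data are therefore upper bounds on real-data performance.

## 7. Problem sizes and tolerances

The test suite and acceptance script run at desk scale, chosen so each
check is decisive yet fast: round-trip and recovery simulations use
30–150 kb genomes with thousands of sites; exhaustive run-length
enumeration backs the Monte-Carlo test up to 20 genes (±3 standard
errors); the study-scale permutation run uses the full 4,054/616/100,000
configuration (Monte-Carlo SE on p(6) ≈ 6 × 10⁻⁴, far from the 0.05
boundary); IRLS convergence tolerance is 1e-8 with 50 iterations.
Degenerate inputs are defined, not crashed on: empty pools yield empty
FASTQs and valid manifests, empty site tables yield NA densities,
single-site genomes yield one circular gap of length L − 1.

## 8. Known limitations

* The exact-seed aligner is exact-match-seeded and ungapped by design; it
  does not handle indels inside the junction fragment.
* The Wald test at three replicates is mildly liberal; the conservative
  dispersion floor compensates but does not remove this.
* Essentiality is gene-level; domain-level dissection is available only
  indirectly through per-gene largest-gap coordinates.
* Multi-contig genomes are processed per contig; no scaffolding.
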