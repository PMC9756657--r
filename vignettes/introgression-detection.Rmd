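---
title: "Detecting introgression from split reads, window topologies, and allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgression from split reads, window topologies, and allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

# Scope and model

`introscan` locates donor-genome introgression blocks in a focal assembly
and anchors assembly scaffolds to linkage groups. The biological setting
is a farmed tilapia strain whose breeding history mixed several
*Oreochromis* species, leaving *mossambicus*- and *aureus*-derived tracts
in a predominantly *niloticus*-like genome. Three detectors operate on
three data types — long-read alignments, per-window phylogenies, and
population allele frequencies — and deliberately measure different things:

* the **split-read scan** finds tract *boundaries*: a read sampled across
  a boundary aligns fully to the focal assembly but cannot align
  contiguously to either donor, so it splits between them;
* **topology weighting** finds tract *interiors*: inside a donor tract the
  focal haplotype is genealogically sister to the donor, and with enough
  tips per taxon every sampled combination agrees (weighting 1.0);
* **D / f4 / f-branch** quantify the *genome-wide admixture fraction* and
  assign it to branches of the species tree, without localizing tracts.

All three assume the focal/donor divergence is small enough for
homologous coordinates to be comparable and large enough for windows of a
few hundred bp to carry phylogenetic signal; none of them distinguishes
introgression from incomplete lineage sorting (ILS) at a single locus —
only the genome-wide excess and its spatial clustering do.

Internally every coordinate is 0-based half-open; GFF3 and VCF are
converted at the I/O boundary (`read_gff3`, `read_vcf`) and nowhere else.
Alignments are interchanged as PAF so the pipeline has no binary-format
dependency.

# Split-read detector

`trim_scaffold_ends` removes alignments within `trim_bp` (default 10 kb)
of a scaffold end on *all three* references; reads spanning the end of one
reference scaffold and the start of another would otherwise mimic splits.
`classify_split_reads` then requires, per read: focal coverage of at
least `min_focal_fraction` (default 0.95 — "fully aligned" needs a
quantitative form, and 95% tolerates soft-clipped tails), at least one
alignment to each donor of at least `min_donor_len` (default 200 bp;
shorter fragments carry no signal at a few percent divergence), and
pairwise-disjoint donor spans on the read (no base aligned to both
donors).

`call_intervals` bins the focal coverage **of the split reads** in 1 kb
intervals. Merged runs of occupied bins holding at least one split read
are *candidates*; candidates whose best bin holds at least
`min_reads_per_interval` (default 10) split reads, outside the excluded
linkage groups (default LG0, unplaced scaffolds), are *reported* — the
two-tier funnel mirrors a first pass that admits everything sharing one
split read and a reporting pass at 10 reads per 1 kb interval.
`min_count` (default 30, the mean read coverage) merges the *all-read*
coverage for context annotation and the donor-side intervals used for
partner pairing; partners are chosen by the highest read-name
intersection, ties broken by coordinate (first wins, logged in the
output ordering).

Thresholds are monotone by construction: raising `trim_bp`,
`min_count`, or `min_reads_per_interval` never expands the reported
coverage (a property test asserts this).

# Topology weighting

`enumerate_topologies` enumerates all unrooted bifurcating topologies on
the k taxon groups by leaf insertion — (2k−5)!! trees, 15 for the five
groups used here — and canonicalizes each as its sorted set of
non-trivial splits. `weight_window` iterates **all** combinations of one
tip per group (the exhaustive "complete" strategy, not sampling),
restricts the window tree's splits to the chosen tips, and matches the
induced topology by split-set identity. A pruned polytomy contributes
equal weight to every compatible topology (the `distribute` policy;
`discard` is available). Weights therefore sum to exactly 1 per resolved
window; an independent test oracle re-derives them via `ape::keep.tip`
and Robinson–Foulds matching.

Window trees come from `infer_window_trees`: 200 bp windows advancing by
160 bp, pairwise Hamming distance on genotype codes, `ape::nj`.
Neighbour joining replaces likelihood tree inference deliberately: at
200 bp a handful of sites determines the topology and NJ is exact on the
additive distances those sites induce, while being orders of magnitude
faster. Windows without variant sites are skipped and counted; a sample
with no called genotype in a window is dropped for that window.

Region extraction (`extract_regions`) operates on **raw** weights at
threshold 1.0: only raw per-window weights can reach 1.0, so a smoothed
series would make the threshold unattainable. Loess smoothing
(`smooth_weights`, local linear, tricube kernel, span 0.05 as a fraction
of the windows per seqid) is for reporting and plots only. The span is
floored at 3/n so every local fit has at least two points; a single-window
seqid is returned unchanged with a warning. Runs of qualifying windows
also break across genomic gaps — a qualifying window that does not touch
its predecessor starts a new region.

# Admixture statistics

`filter_sites` applies the quality funnel — biallelic SNPs with total
depth in [90, 900], minor allele count ≥ 3, at most one individual
missing, no SNP overlapping or within 3 bp of an indel, repeat-rich LG3
excluded — and reports per-criterion removal counts. `ld_prune` is a
greedy left-to-right scan dropping sites with genotype r² > 0.6 against
any retained site within 20 kb; a post-hoc all-pairs test verifies the
survivors.

`d_statistic` polarizes derived alleles by the outgroup's major allele
(sites where the outgroup is exactly 50/50 are dropped and counted) and
uses the frequency form of ABBA/BABA; significance comes from a
delete-one jackknife over 20 contiguous equal-site blocks (|Z| > 3 is the
conventional cutoff). `f4_ratio` uses the within-P3 denominator
(`p3` in both donor slots): with one to three samples per population,
per-site donor subsampling halves are noisier than the f-hom form, so the
latter is the default and the raw (unclipped) estimate is retained as an
attribute. `f_branch` takes the rooted species tree and computes
`f_b(C) = median over A in sister(b) of [min over B in desc(b) of
f_G(A,B,C)]`, clipped at zero; cells where no valid trio exists are NA,
not zero.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuned. `sim_params()` encodes: a 1 Mb focal genome in 2 scaffolds; 2%
donor–donor divergence (1% per branch from their common ancestor, in the
range of congeneric cichlid genome divergence); admixture proportion
f = 0.1 in exponential tracts of mean 20 kb (no empirical tract-length
distribution is available for these strains — exponential is the
simplest tract model with a tunable mean); error-free 15 kb reads
(sd 1.5 kb) at 30× (HiFi accuracy justifies error-free as the default;
a uniform error rate is available); five populations of two diploids;
ILS rate 0.1; per-site depth Poisson(300); a 22-LG map with 4 scaffolds
per LG and 10 probes per scaffold. Tracts keep a 25 kb margin from
scaffold ends so that both flanks of each boundary remain alignable after
the 10 kb end trim — a condition of the planted-truth design, since a
boundary inside the trim zone is undetectable by construction.

Genotypes are simulated site-wise: inside a tract the focal lineage joins
the donor; outside, the species genealogy applies with probability
1 − `ils_rate`, otherwise a uniformly drawn discordant topology. One
derived mutation is placed on a single edge of the rooted genealogy with
probability proportional to a coalescent-consistent branch length
(species splits at relative depths 1, 2, 3 with the root at 4; under
introgression the focal lineage coalesces with the donor at depth 0.5).
The branch-length weighting matters: with equal edge lengths the
introgression genealogy's (niloticus, aureus) edge would generate an f4
signal as large as the true (focal, donor) signal, and f-branch could not
localize the flow; with coalescent-consistent lengths the true signal
exceeds the artifact roughly three-fold, which is also what real
genealogies produce (the donor-sister branch is long because the
admixture is recent). Discordant ILS genealogies keep uniform edges:
they are symmetric in the focal/niloticus pair, so they add noise, not
bias. A `per_site = TRUE` mode draws introgression independently per
site, used for genome-wide admixture-fraction calibration.

Under this model the within-P3 f4-ratio estimator has expectation
slightly below the simulated f (about 0.087–0.091 at f = 0.10: the
denominator picks up a 2f term from the introgressed class plus an ILS
inflation), comfortably inside the ±0.03 recovery band the calibration
tests assert. This bias is a property of the estimator, not the
simulator, and the clipped estimate is reported as-is.

What the generator does **not** emulate: recombination within tracts (an
external coalescent simulator can be wrapped where that matters),
sequencing error and base quality, structural variation, reference bias,
and mapping ambiguity in repeats. Passing tests therefore demonstrate
the correctness of the *procedures* under their stated assumptions, not
detector performance on real repeat-rich chromosomes — on real data the
split-read scan in particular is expected to accumulate signal in
repeat-dense regions regardless of introgression, which is why reported
intervals carry coverage-context annotation and per-LG ranking rather
than a significance claim.

# Linkage anchoring

Probe best-hits (highest score; cross-scaffold ties dropped and counted)
joined with the genetic map assign each scaffold the LG of its probes;
probe-less scaffolds go to LG0 and multi-LG scaffolds are chimera
candidates. Breaking requires the per-LG probe ranges to be disjoint
blocks; the cut falls at the **midpoint** between the last probe of one
block and the first of the next. The distal probes only bound the
breakpoint, and the midpoint is the minimax choice inside that interval;
cut-at-left/right-probe variants would systematically donate the
uncertain interval to one side. Scaffolds with interleaved LG probes are
left unbroken and reported — cutting them would require evidence the map
cannot supply.

Ordering uses the median probe cM per scaffold (robust to stray hits;
ties by name), orientation the sign of the Spearman bp–cM correlation,
with single-probe or zero-correlation scaffolds oriented '+' and flagged
orientation-unknown — a convention, since the map genuinely cannot orient
them. Building concatenates with exactly 100 N between neighbours and
emits AGP rows that reconstruct the FASTA byte-for-byte (a round-trip
test asserts this, as does base conservation across breaking). The Marey
table reports, per LG, the fraction of adjacent probe pairs whose cM
order matches their bp order; 1.0 on a clean fixture, and any forced
mis-orientation drops it below 1.0.

# Numerical choices and degenerate inputs

* Coverage bins are half-open and the final partial bin at a scaffold end
  is kept (dropping it would silently delete terminal signal).
* Gene intersection counts any overlap ≥ 1 bp, matching the default
  behaviour of interval-intersection tools; a gene overlapping two
  regions is reported once per region.
* `f = 0` and `f = 1` produce the exact degenerate outputs (focal equals
  donorA, respectively donorB); a total tract target below the minimum
  tract length warns and emits a single minimal tract.
* D is flagged undefined when ΣABBA + ΣBABA = 0; f4 when its denominator
  vanishes; both are NA-flagged rather than zero-filled.
* All generators are deterministic given `seed`; each stage derives its
  own sub-seed so regenerating one stage does not perturb another.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen as the smallest
sizes at which every statistic is comfortably away from its decision
boundary: a 1 Mb genome at 30× for the split-read recovery, 20 000–50 000
sites for the D/f4/f-branch calibrations (100 null seeds, 20 recovery
seeds, 10 localization seeds), 200 bp × 625–1250 windows for the
weighting runs, and an 88-scaffold 22-LG map. The operations are linear
sweeps or small exhaustive enumerations throughout; genome-scale inputs
are a matter of runtime, not algorithm.

# Known limitations

* The split-read scan cannot see boundaries within `trim_bp` of a
  scaffold end, nor tracts shorter than the donor-fragment floor.
* Weighting-1.0 region extraction is conservative: a single discordant
  tip combination (one ILS-affected sample) removes a window, so
  reported regions under-cover true tracts near their edges.
* The f4-ratio estimator is mildly conservative under the within-P3
  denominator, and f-branch inherits any error in the supplied species
  tree — with heavy admixture, distance-based trees can mis-place the
  recipient (stage 4 of the analysis detects and reports this).
* PSL probe hits are not parsed; probe hits are consumed as TSV.
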