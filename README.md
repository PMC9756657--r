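# introscan

Detecting interspecific introgression in a focal fish genome from long
reads, window topologies, and allele frequencies — with a ground-truthed
synthetic-data module so every stage is verifiable offline.

## The problem

Farmed tilapia strains carry genomic material from several *Oreochromis*
species: blocks of donor genome introduced by hybridization and
backcrossing during breeding. Given a focal assembly and two donor
references (an *O. niloticus*-like reference and an *O. mossambicus*-like
donor), the package locates these introgressed blocks with three
complementary lines of evidence, and anchors assembly scaffolds into
linkage groups from a genetic map:

1. **Split-read scan** (`classify_split_reads`, `call_intervals`). HiFi
   reads that align *fully* to the focal assembly but *split, without
   overlap on the read,* between the two donor references mark tract
   boundaries. Alignments within 10 kb of scaffold ends are discarded,
   coverage is binned in 1 kb intervals, and intervals sharing at least 10
   split reads per bin (outside the unplaced-scaffold pool LG0) are
   reported, with donor partner intervals chosen by the highest
   intersection of read names.
2. **Topology weighting** (`infer_window_trees`, `weight_window`,
   `extract_regions`). Neighbour-joining trees inferred in sliding 200 bp
   windows (40 bp overlap) are weighted over all 15 unrooted topologies on
   the five taxon groups (focal, *niloticus*, *aureus*, *mossambicus*,
   *urolepis*) by exhaustively iterating every one-tip-per-group
   combination (the "complete" method). Regions where the donor-sister
   topology has weighting 1.0 are extracted and intersected with the gene
   annotation; loess smoothing (span 0.05) is applied for plotting.
3. **Admixture statistics** (`d_statistic`, `f4_ratio`, `f_branch`).
   Frequency-based Patterson's D over derived-allele frequencies
   (`ABBA = (1-p1) p2 p3 (1-pO)`, `BABA = p1 (1-p2) p3 (1-pO)`,
   `D = Σ(ABBA-BABA)/Σ(ABBA+BABA)`) with delete-one block-jackknife Z
   scores; the f4-admixture ratio
   `f_G = Σ(p2-p1)p3(1-pO) / Σ(p3-p1)p3(1-pO)` as an admixture-proportion
   estimator; and the branch-resolved f-branch summary
   `f_b(C) = median_{A∈sister(b)} min_{B∈desc(b)} f_G(A,B,C)` that
   assigns gene flow to specific branches of the species tree. Sites pass
   a quality funnel (total depth in [90, 900], minor allele count ≥ 3, at
   most one missing individual, no SNP within 3 bp of an indel, repeat-rich
   LG3 excluded) and can be LD-pruned (r² > 0.6 in 20 kb windows).
4. **Linkage anchoring** (`assign_scaffolds`, `break_chimeras`,
   `order_and_orient`, `build_lg_sequences`, `marey_table`). SNP-array
   probe hits plus a genetic map assign scaffolds to 22 linkage groups;
   scaffolds with probes from two LGs in disjoint blocks are cut at the
   midpoint between the distal probes; scaffolds are ordered by median cM,
   oriented by the sign of the bp–cM rank correlation, concatenated with
   100 Ns (AGP emitted), and checked with Marey-map monotonicity scores.

Because the original sequencing data are external, a first-class
synthetic-data module (`simulate_genomes`, `simulate_reads`,
`simulate_alignments`, `simulate_genotypes`, `simulate_probe_map`)
generates genomes with planted introgression tracts, reads spanning tract
boundaries, split alignments, coalescent-flavoured genotypes with tunable
incomplete lineage sorting, and a 22-LG map with injected chimeric
scaffolds — all with machine-readable truth.

## Worked example

```r
library(introscan)

p <- sim_params(seed = 1, genome_length = 1e6, f = 0.1,
                read_depth = 30, read_length = 15000)
g <- simulate_genomes(p)                    # focal + two donors + truth
reads <- simulate_reads(g$focal, p)
al <- simulate_alignments(reads, g)

tf <- trim_scaffold_ends(al$focal)
sr <- classify_split_reads(tf, trim_scaffold_ends(al$donorA),
                           trim_scaffold_ends(al$donorB))
calls <- call_intervals(sr, tf)
calls
#> split-read calls: 8 candidate interval(s), 8 reported
head(rank_groups(calls), 2)
#>   linkage_group n_intervals n_reads combined_bp
#> 1    scaffold_2           5     373      281181
#> 2    scaffold_1           3     120      110582
```

Every reported interval brackets a boundary of a planted donor tract
(there are 11 tracts, hence 22 boundaries, covered by 8 merged intervals);
the ranking table mirrors the per-linkage-group interval/read/combined-bp
ranking used to flag the most introgression-dense chromosomes.

The numbered drivers under `analysis/` run the full workflow on the
synthetic study data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R           # fixtures + truth (scratch/simdata)
Rscript analysis/02_split_reads.R        # intervals, LG ranking, precision/recall
Rscript analysis/03_topology_weighting.R # weights, weighting-1.0 regions, genes
Rscript analysis/04_admixture_stats.R    # site funnel, D/Z, f4, f-branch
Rscript analysis/05_anchoring.R          # chimera breaks, AGP, Marey QC
```

On the default conditions stage 2 prints `boundary precision 1.000,
recall 1.000`, stage 3 finds donor-sister regions with Jaccard ≈ 0.87
against the planted tracts, and stage 4's strongest f-branch entry is
`focal <- mossambicus` (0.157 at a realized tract fraction of 0.2).

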