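#!/usr/bin/env Rscript
# Stage 3: topology weighting along the genome.
#
# Neighbour-joining trees are inferred in sliding 200 bp windows (40 bp
# overlap) from the genotype panel; each window tree is weighted over the
# 15 possible 5-taxon topologies by exhaustive one-tip-per-group
# enumeration.  Regions where the donor-sister topology has weighting 1.0
# are extracted and intersected with the gene annotation; loess-smoothed
# (span 0.05) weights are written for plotting.

suppressPackageStartupMessages(library(introscan))
sd <- "scratch/simdata"
if (!file.exists(file.path(sd, "panel.vcf")))
  stop("run analysis/01_simulate.R first")

pops_tab <- utils::read.table(file.path(sd, "populations.tsv"), sep = "\t",
                              col.names = c("sample", "population"))
gm <- read_vcf(file.path(sd, "panel.vcf"),
               stats::setNames(pops_tab$population, pops_tab$sample))

pop_order <- c("focal", "niloticus", "aureus", "mossambicus", "urolepis")
groups <- do.call(taxon_groups, stats::setNames(
  lapply(pop_order, function(p) pops_tab$sample[pops_tab$population == p]),
  pop_order))
topo <- enumerate_topologies(groups)

wt <- infer_window_trees(gm, window = 200, overlap = 40)
cat(sprintf("%d windows with trees (%d skipped, no variant sites)\n",
            nrow(wt$windows), attr(wt, "n_skipped")))
W <- weight_windows(wt, groups, topo)
S <- suppressWarnings(smooth_weights(W, span = 0.05))
utils::write.table(S, file.path(sd, "weights_smoothed.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

avg <- colMeans(as.matrix(W[, grep("^w_", names(W))]))
topo_summary <- data.frame(topology = topo$newick, mean_weight = avg,
                           is_species = seq_along(avg) == topo$species_index)
topo_summary <- topo_summary[order(-topo_summary$mean_weight), ]
utils::write.table(topo_summary, "results/03_topology_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("mean weight of species topology:",
    round(avg[topo$species_index], 3), "\n")

# donor-sister topology: focal sister to the mossambicus-like donor
donor_key <- topology_key(
  ape::read.tree(text = "(((niloticus,aureus),(focal,mossambicus)),urolepis);"),
  pop_order)
regions <- extract_regions(W, donor_key, threshold = 1.0)
write_bed(regions, "results/03_intro_regions.bed")
cat(sprintf("%d donor-sister regions at weighting 1.0, %d bp total\n",
            nrow(regions), sum(regions$end - regions$start)))

genes <- read_gff3(file.path(sd, "genes.gff3"), feature_types = "gene")
hits <- intersect_genes(regions, genes)
utils::write.table(hits, "results/03_intro_genes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("%d gene overlaps (%d unique genes)\n", nrow(hits),
            length(unique(hits$gene_id))))

truth <- read_bed(file.path(sd, "truth_geno_blocks.bed"))
cover <- function(df, L) {
  v <- rep(FALSE, L)
  for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}
L <- max(truth$end, regions$end)
va <- cover(regions, L); vb <- cover(truth, L)
cat(sprintf("Jaccard overlap with truth tracts: %.3f\n",
            sum(va & vb) / sum(va | vb)))
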