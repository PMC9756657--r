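#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with known ground truth.
#
# Emits, under scratch/simdata/ (large, regenerable):
#   focal/donorA/donorB genomes (FASTA), HiFi-like reads (FASTA),
#   alignments to the three references (PAF), truth tracts (BED),
#   genotypes for the five-population panel (VCF), a toy gene annotation
#   (GFF3), and the 22-LG probe/map fixture (TSV + FASTA).
# Small summary tables go to results/.

suppressPackageStartupMessages(library(introscan))

out <- "scratch/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

## 1. Genomes, reads, alignments (split-read detector input) --------------
p <- sim_params(seed = 1, genome_length = 1e6, f = 0.1, read_depth = 30,
                read_length = 15000)
g <- simulate_genomes(p)
write_fasta(g$focal, file.path(out, "focal.fa"))
write_fasta(g$donorA, file.path(out, "donorA.fa"))
write_fasta(g$donorB, file.path(out, "donorB.fa"))
write_bed(g$truth$blocks, file.path(out, "truth_blocks.bed"))

reads <- simulate_reads(g$focal, p)
write_fasta(reads, file.path(out, "reads.fa"))
al <- simulate_alignments(reads, g)
write_paf(al$focal, file.path(out, "reads_vs_focal.paf"))
write_paf(al$donorA, file.path(out, "reads_vs_donorA.paf"))
write_paf(al$donorB, file.path(out, "reads_vs_donorB.paf"))

## 2. Genotype panel with tract-structured introgression ------------------
pg <- sim_params(seed = 11, f = 0.2, ils_rate = 0.1, n_sites = 10000,
                 geno_length = 1e5, block_mean_length = 5000)
sim <- simulate_genotypes(pg)
write_vcf(sim$matrix, file.path(out, "panel.vcf"))
write_bed(sim$truth$blocks, file.path(out, "truth_geno_blocks.bed"))
writeLines(paste(sim$matrix$samples$sample_id,
                 sim$matrix$samples$population, sep = "\t"),
           file.path(out, "populations.tsv"))

# toy gene annotation tiling the genotype coordinate space (2 kb genes
# every 3 kb) so introgressed regions can be intersected with genes
gene_start <- seq(0, pg$geno_length - 3000, by = 3000)
gff <- c("##gff-version 3",
         sprintf("geno_1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=gene%03d",
                 gene_start + 1, gene_start + 2000, seq_along(gene_start)))
writeLines(gff, file.path(out, "genes.gff3"))

## 3. Probe map / anchoring fixture ---------------------------------------
pm_par <- sim_params(seed = 21, n_lgs = 22, scaffolds_per_lg = 4,
                     chimera_fraction = 0.1)
pm <- simulate_probe_map(pm_par)
write_fasta(pm$scaffolds, file.path(out, "asm_scaffolds.fa"))
utils::write.table(pm$hits, file.path(out, "probe_hits.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(pm$map, file.path(out, "genetic_map.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
chim <- data.frame(
  name = vapply(pm$truth$chimeras, `[[`, character(1), "name"),
  join = vapply(pm$truth$chimeras, `[[`, numeric(1), "join"))
utils::write.table(chim, file.path(out, "truth_chimeras.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(pm$truth$assignments, file.path(out, "truth_anchoring.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

summary <- data.frame(
  dataset = c("genome", "reads", "genotypes", "map"),
  detail = c(
    sprintf("%d scaffolds, %d bp, %d introgressed tracts (%d bp)",
            length(g$focal), sum(nchar(g$focal)), nrow(g$truth$blocks),
            sum(g$truth$blocks$end - g$truth$blocks$start)),
    sprintf("%d reads, %.1fx depth", length(reads),
            sum(nchar(reads)) / sum(nchar(g$focal))),
    sprintf("%d sites x %d samples, %d tracts", nrow(sim$matrix$sites),
            nrow(sim$matrix$samples), nrow(sim$truth$blocks)),
    sprintf("%d scaffolds in %d LGs, %d chimeras", length(pm$scaffolds),
            pm_par$n_lgs, nrow(chim))))
utils::write.table(summary, "results/01_simulation_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Simulated inputs written to", out, "\n")
print(summary, right = FALSE)
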