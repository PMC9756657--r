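#!/usr/bin/env Rscript
# Stage 2: split-read introgression scan.
#
# Reads that map fully to the focal assembly but split cleanly between the
# two donor references mark putative introgression-block boundaries.  This
# driver trims 10 kb scaffold ends, classifies split reads, calls candidate
# and reported intervals (>= 10 split reads per 1 kb bin, LG0 excluded),
# ranks linkage groups, and scores the calls against the planted truth.

suppressPackageStartupMessages(library(introscan))
sd <- "scratch/simdata"
if (!file.exists(file.path(sd, "reads_vs_focal.paf")))
  stop("run analysis/01_simulate.R first")

focal <- read_paf(file.path(sd, "reads_vs_focal.paf"), "focal")
donorA <- read_paf(file.path(sd, "reads_vs_donorA.paf"), "donorA")
donorB <- read_paf(file.path(sd, "reads_vs_donorB.paf"), "donorB")

tf <- trim_scaffold_ends(focal)
ta <- trim_scaffold_ends(donorA)
tb <- trim_scaffold_ends(donorB)
split_reads <- classify_split_reads(tf, ta, tb)
calls <- call_intervals(split_reads, tf, ta, tb)

cat(sprintf("%d of %d reads satisfy the split criterion\n",
            length(split_reads), length(unique(focal$read_id))))
print(calls)

rep_out <- calls$reported
write_bed(calls$candidates[, c("seqid", "start", "end", "n_reads")],
          "results/02_candidate_intervals.bed")
write_bed(rep_out[, c("seqid", "start", "end", "n_reads")],
          "results/02_reported_intervals.bed")
utils::write.table(rank_groups(calls), "results/02_lg_ranking.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# score against truth: a call is correct when it overlaps a tract boundary
# within one mean read length
truth <- read_bed(file.path(sd, "truth_blocks.bed"))
bnd <- data.frame(seqid = rep(truth$seqid, 2),
                  pos = c(truth$start, truth$end))
tol <- 15000
prec <- mean(vapply(seq_len(nrow(rep_out)), function(i)
  any(bnd$seqid == rep_out$seqid[i] & bnd$pos + tol > rep_out$start[i] &
        bnd$pos - tol < rep_out$end[i]), logical(1)))
rec <- mean(vapply(seq_len(nrow(bnd)), function(j)
  any(rep_out$seqid == bnd$seqid[j] & bnd$pos[j] + tol > rep_out$start &
        bnd$pos[j] - tol < rep_out$end), logical(1)))
cat(sprintf("boundary precision %.3f, recall %.3f (tolerance %d bp)\n",
            prec, rec, tol))
utils::write.table(
  data.frame(metric = c("n_split_reads", "n_candidates", "n_reported",
                        "precision", "recall"),
             value = c(length(split_reads), nrow(calls$candidates),
                       nrow(rep_out), prec, rec)),
  "results/02_split_read_summary.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
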