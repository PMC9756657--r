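# Shared fixture builders and independent brute-force oracles.

aln <- function(read_id, read_len, read_start, read_end, target,
                target_start, target_end, strand = "+", target_len = 1e6,
                ref_label = "focal", mapq = 60L) {
  data.frame(read_id = read_id, read_len = as.integer(read_len),
             read_start = as.integer(read_start),
             read_end = as.integer(read_end), strand = strand,
             target = target, target_len = as.integer(target_len),
             target_start = as.integer(target_start),
             target_end = as.integer(target_end),
             n_match = as.integer(read_end - read_start),
             block_len = as.integer(read_end - read_start),
             mapq = as.integer(mapq), ref_label = ref_label,
             stringsAsFactors = FALSE)
}

five_groups <- function(n_per = 2) {
  pops <- c("focal", "niloticus", "aureus", "mossambicus", "urolepis")
  do.call(taxon_groups,
          stats::setNames(lapply(pops, function(p) paste0(p, "_", seq_len(n_per))),
                          pops))
}

# O(reads x bins) overlap scan, independent of bin_coverage's grouping path
oracle_bin_counts <- function(records, bin_size) {
  out <- list()
  for (sq in sort(unique(records$target))) {
    r <- records[records$target == sq, ]
    maxe <- max(r$target_end)
    for (b in 0:((maxe - 1) %/% bin_size)) {
      bs <- b * bin_size; be <- min(bs + bin_size, maxe)
      ov <- r$target_start < be & r$target_end > bs
      if (any(ov))
        out[[length(out) + 1]] <- data.frame(
          seqid = sq, start = bs, end = be,
          count = length(unique(r$read_id[ov])), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# O(n x m) pair scan for region x gene overlap
oracle_intersect <- function(regions, genes) {
  pairs <- list()
  for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(genes))) {
    if (regions$seqid[i] == genes$seqid[j] &&
        regions$start[i] < genes$end[j] && regions$end[i] > genes$start[j])
      pairs[[length(pairs) + 1]] <- c(i, j)
  }
  pairs
}

# independent topology-weighting oracle: prune with ape::keep.tip and match
# by Robinson-Foulds distance against each enumerated topology tree
oracle_weight <- function(tree, groups, topo) {
  combos <- expand.grid(groups, stringsAsFactors = FALSE)
  w <- numeric(length(topo$key))
  for (i in seq_len(nrow(combos))) {
    tips <- as.character(combos[i, ])
    pr <- ape::keep.tip(tree, tips)
    for (g in names(groups))
      pr$tip.label[pr$tip.label %in% groups[[g]]] <- g
    pr <- ape::unroot(pr)
    hit <- which(vapply(topo$trees,
                        function(tt) ape::dist.topo(pr, tt) == 0, logical(1)))
    w[hit] <- w[hit] + 1 / length(hit)
  }
  w / nrow(combos)
}

# genotype matrix built directly from a site table and genotype code matrix
make_gm <- function(geno, populations, pos = NULL, seqid = "chr1",
                    depth = 300, is_indel = FALSE, biallelic = TRUE,
                    dist_indel = NA_real_) {
  n <- nrow(geno)
  samples <- data.frame(sample_id = colnames(geno), population = populations,
                        stringsAsFactors = FALSE)
  sites <- data.frame(
    seqid = rep_len(seqid, n),
    pos = if (is.null(pos)) seq_len(n) * 10L else pos,
    ref_allele = "A", alt_allele = "T",
    total_depth = rep_len(depth, n), is_indel = rep_len(is_indel, n),
    biallelic = rep_len(biallelic, n),
    dist_indel = rep_len(dist_indel, n), stringsAsFactors = FALSE)
  gm <- list(sites = sites, geno = geno, samples = samples)
  class(gm) <- "genotype_matrix"
  gm
}

# one-sample-per-population matrix from per-population "allele patterns":
# rows of 0/1 per population are expanded to hom genotypes 0/2
pattern_gm <- function(patterns, pops) {
  geno <- 2L * patterns
  colnames(geno) <- pops
  make_gm(geno, pops)
}
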