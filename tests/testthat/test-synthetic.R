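test_that("admixture limits: f=0 copies donorA, f=1 copies donorB", {
  p0 <- sim_params(seed = 3, genome_length = 50000, n_scaffolds = 1, f = 0,
                   block_margin = 1000)
  g0 <- simulate_genomes(p0)
  expect_identical(g0$focal, g0$donorA)
  expect_equal(nrow(g0$truth$blocks), 0)

  p1 <- sim_params(seed = 3, genome_length = 50000, n_scaffolds = 1, f = 1,
                   block_margin = 1000)
  g1 <- simulate_genomes(p1)
  expect_identical(unname(g1$focal), unname(g1$donorB))
})

test_that("planted tract total tracks f * genome_length within 20%", {
  p <- sim_params(seed = 9, genome_length = 1e6, f = 0.1)
  g <- simulate_genomes(p)
  tot <- sum(g$truth$blocks$end - g$truth$blocks$start)
  expect_gt(tot, 0.8 * 1e5)
  expect_lt(tot, 1.2 * 1e5)
  # focal differs from donorA exactly inside tracts (where donorB differs)
  b <- g$truth$blocks[1, ]
  expect_false(identical(substr(g$focal[[b$seqid]], b$start + 1, b$end),
                         substr(g$donorA[[b$seqid]], b$start + 1, b$end)))
  out_start <- b$end + 1000
  expect_identical(substr(g$focal[[b$seqid]], out_start, out_start + 5000),
                   substr(g$donorA[[b$seqid]], out_start, out_start + 5000))
})

test_that("read simulation hits target depth, is deterministic, handles zero depth", {
  p <- sim_params(seed = 5, genome_length = 2e5, n_scaffolds = 1, f = 0,
                  read_depth = 10, read_length = 5000, read_length_sd = 500,
                  block_margin = 1000)
  g <- simulate_genomes(p)
  reads <- simulate_reads(g$focal, p)
  expect_gt(sum(nchar(reads)), 0.9 * 10 * 2e5)
  expect_lt(sum(nchar(reads)), 1.1 * 10 * 2e5)
  expect_identical(reads, simulate_reads(g$focal, p))

  p0 <- sim_params(seed = 5, genome_length = 2e5, n_scaffolds = 1,
                   read_depth = 0, block_margin = 1000)
  expect_length(simulate_reads(g$focal, p0), 0)
})

test_that("alignment emulation splits reads at tract boundaries, disjoint on the read", {
  p <- sim_params(seed = 7, genome_length = 2e5, n_scaffolds = 1, f = 0.15,
                  read_depth = 8, read_length = 8000, read_length_sd = 400,
                  block_margin = 10000, block_mean_length = 15000)
  g <- simulate_genomes(p)
  reads <- simulate_reads(g$focal, p)
  al <- simulate_alignments(reads, g)
  expect_equal(nrow(al$focal), length(reads))
  expect_true(all(al$focal$read_start == 0 &
                    al$focal$read_end == al$focal$read_len))

  origin <- introscan:::parse_read_origin(names(reads))
  blocks <- g$truth$blocks
  for (i in seq_len(nrow(origin))) {
    rid <- origin$read_id[i]
    a <- al$donorA[al$donorA$read_id == rid, ]
    b <- al$donorB[al$donorB$read_id == rid, ]
    inside <- any(blocks$start <= origin$start[i] & blocks$end >= origin$end[i])
    outside <- !any(blocks$start < origin$end[i] & blocks$end > origin$start[i])
    if (outside) {      # entirely donorA ancestry: one full-length A record
      expect_equal(nrow(a), 1)
      expect_equal(nrow(b), 0)
    }
    if (inside) expect_equal(nrow(a), 0)
    if (nrow(a) && nrow(b)) {   # boundary-spanning: spans must be disjoint
      expect_false(any(outer(a$read_start, b$read_end, `<`) &
                         outer(a$read_end, b$read_start, `>`)))
    }
  }
})

test_that("emulated alignments are realizable: substrings match the references", {
  p <- sim_params(seed = 8, genome_length = 1e5, n_scaffolds = 1, f = 0.2,
                  read_depth = 3, read_length = 6000, read_length_sd = 300,
                  block_margin = 8000)
  g <- simulate_genomes(p)
  reads <- simulate_reads(g$focal, p)
  al <- simulate_alignments(reads, g)
  check <- function(rec, ref) {
    for (i in seq_len(min(nrow(rec), 30))) {
      # PAF semantics: query[start,end) (rev-complemented for '-') matches
      # the target interval on the forward strand
      seg <- substr(reads[[rec$read_id[i]]], rec$read_start[i] + 1,
                    rec$read_end[i])
      if (rec$strand[i] == "-") seg <- revcomp(seg)
      expect_identical(
        seg, substr(ref[[rec$target[i]]], rec$target_start[i] + 1,
                    rec$target_end[i]))
    }
  }
  check(al$focal, g$focal)
  check(al$donorA, g$donorA)
  check(al$donorB, g$donorB)
})

test_that("f=0 genomes yield no donorB alignment records", {
  p <- sim_params(seed = 4, genome_length = 1e5, n_scaffolds = 1, f = 0,
                  read_depth = 5, read_length = 5000, block_margin = 1000)
  g <- simulate_genomes(p)
  al <- simulate_alignments(simulate_reads(g$focal, p), g)
  expect_equal(nrow(al$donorB), 0)
})

test_that("genotype simulation is deterministic and respects the null", {
  p <- sim_params(seed = 6, f = 0, ils_rate = 0, n_sites = 500,
                  geno_length = 50000)
  s1 <- simulate_genotypes(p)
  s2 <- simulate_genotypes(p)
  expect_identical(s1$matrix$geno, s2$matrix$geno)
  expect_true(all(s1$truth$genealogy == "species"))
  expect_equal(length(unique(s1$truth$topology)), 1)
})

test_that("tract sites show elevated focal-donorB allele sharing", {
  p <- sim_params(seed = 10, f = 0.2, ils_rate = 0.1, n_sites = 5000,
                  geno_length = 1e5)
  sim <- simulate_genotypes(p)
  gm <- sim$matrix
  foc <- gm$samples$population == "focal"
  mos <- gm$samples$population == "mossambicus"
  nil <- gm$samples$population == "niloticus"
  share_fm <- rowMeans(gm$geno[, foc, drop = FALSE]) == 2 &
    rowMeans(gm$geno[, mos, drop = FALSE]) == 2 &
    rowMeans(gm$geno[, nil, drop = FALSE]) == 0
  inb <- sim$truth$genealogy == "intro"
  expect_gt(mean(share_fm[inb]), 5 * mean(share_fm[!inb]))
})

test_that("probe-map fixture: clean scaffolds are single-LG, '-' scaffolds decrease in cM", {
  p <- sim_params(seed = 2, n_lgs = 4, scaffolds_per_lg = 3,
                  chimera_fraction = 0)
  pm <- simulate_probe_map(p)
  pr <- merge_probes(pm$hits, pm$map)
  per_sc <- tapply(pr$lg, pr$scaffold, function(x) length(unique(x)))
  expect_true(all(per_sc == 1))

  minus <- pm$truth$assignments$scaffold[pm$truth$assignments$orientation == "-"]
  for (sc in minus) {
    d <- pr[pr$scaffold == sc, ]
    expect_true(all(diff(d$cm[order(d$bp)]) < 0))
  }
})

test_that("injected chimera join points are recorded in truth", {
  p <- sim_params(seed = 12, n_lgs = 6, scaffolds_per_lg = 3,
                  chimera_fraction = 0.2)
  pm <- simulate_probe_map(p)
  expect_gt(length(pm$truth$chimeras), 0)
  ch <- pm$truth$chimeras[[1]]
  expect_equal(nchar(pm$scaffolds[[ch$name]]),
               sum(pm$truth$assignments$length[
                 pm$truth$assignments$scaffold %in% ch$components]))
  expect_equal(ch$join,
               pm$truth$assignments$length[
                 pm$truth$assignments$scaffold == ch$components[1]])
})
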