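pops5 <- c("focal", "niloticus", "aureus", "mossambicus", "urolepis")

test_that("filter_sites applies each exclusion rule at its exact boundary", {
  base <- function(n) matrix(rep(c(2L, 2L, 0L, 0L, 0L), n), nrow = n,
                             byrow = TRUE,
                             dimnames = list(NULL, paste0("s", 1:5)))
  gm <- make_gm(base(8), pops5)
  gm$sites$total_depth <- c(300L, 80L, 89L, 90L, 900L, 901L, 950L, 300L)
  out <- filter_sites(gm, site_filter_params(exclude_seqids = "none"))
  expect_equal(out$sites$total_depth, c(300L, 90L, 900L, 300L))

  gm2 <- make_gm(base(2), pops5)
  gm2$geno[1, ] <- c(1L, 1L, 0L, 0L, 0L)   # MAC 2: removed
  gm2$geno[2, ] <- c(2L, 1L, 0L, 0L, 0L)   # MAC 3: kept
  out2 <- filter_sites(gm2, site_filter_params(exclude_seqids = "none"))
  expect_equal(nrow(out2$sites), 1)
  expect_equal(unname(out2$geno[1, 1]), 2L)

  gm3 <- make_gm(matrix(rep(c(2L, 2L, 2L, 0L, 0L), 3), nrow = 3,
                        byrow = TRUE,
                        dimnames = list(NULL, paste0("s", 1:5))), pops5)
  gm3$geno[1, 1:2] <- NA                   # 2 missing: removed
  gm3$geno[2, 1] <- NA                     # 1 missing: kept (MAC still 4)
  out3 <- filter_sites(gm3, site_filter_params(exclude_seqids = "none"))
  expect_equal(nrow(out3$sites), 2)

  gm4 <- make_gm(base(3), pops5)
  gm4$sites$dist_indel <- c(3, 4, 0)       # <=3 bp from an indel: removed
  out4 <- filter_sites(gm4, site_filter_params(exclude_seqids = "none"))
  expect_equal(out4$sites$dist_indel, 4)

  gm5 <- make_gm(base(2), pops5, seqid = c("LG3", "LG5"))
  out5 <- filter_sites(gm5, site_filter_params())
  expect_equal(out5$sites$seqid, "LG5")
  expect_equal(unname(attr(out5, "funnel")["excluded_seqid"]), 1L)
})

test_that("ld_prune drops correlated neighbours and the survivors verify post hoc", {
  set.seed(55)
  n_samp <- 20
  g1 <- sample(0:2, n_samp, replace = TRUE)
  geno <- rbind(g1, g1, sample(0:2, n_samp, replace = TRUE))
  storage.mode(geno) <- "integer"
  colnames(geno) <- paste0("s", seq_len(n_samp))
  gm <- make_gm(geno, rep("p1", n_samp), pos = c(1000L, 2000L, 3000L))
  out <- ld_prune(gm)
  expect_equal(out$sites$pos, c(1000L, 3000L))

  # independent sites are all retained
  geno2 <- matrix(sample(0:2, 10 * n_samp, replace = TRUE), nrow = 10)
  storage.mode(geno2) <- "integer"
  colnames(geno2) <- paste0("s", seq_len(n_samp))
  gm2 <- make_gm(geno2, rep("p1", n_samp), pos = seq(1000L, 10000L, 1000L))
  out2 <- ld_prune(gm2, r2_max = 0.99)
  expect_equal(nrow(out2$sites), 10)

  # exhaustive all-pairs recheck of the pruned set within the window
  geno3 <- matrix(sample(0:2, 40 * n_samp, replace = TRUE), nrow = 40)
  storage.mode(geno3) <- "integer"
  colnames(geno3) <- paste0("s", seq_len(n_samp))
  gm3 <- make_gm(geno3, rep("p1", n_samp),
                 pos = sort(sample.int(30000L, 40)))
  out3 <- ld_prune(gm3, r2_max = 0.6, window = 20000)
  s <- out3$sites$pos
  for (i in seq_along(s)) for (j in seq_len(i - 1)) {
    if (s[i] - s[j] <= 20000) {
      r <- suppressWarnings(stats::cor(out3$geno[i, ], out3$geno[j, ]))
      if (!is.na(r)) expect_lte(r^2, 0.6 + 1e-12)
    }
  }
})

test_that("D statistic reproduces pattern counts and is antisymmetric in P1/P2", {
  # 3 ABBA sites + 1 BABA site as fixed homozygous patterns -> D = 0.5
  pat <- rbind(c(0, 1, 1, 0), c(0, 1, 1, 0), c(0, 1, 1, 0), c(1, 0, 1, 0))
  pops <- c("p1", "p2", "p3", "out")
  gm <- pattern_gm(pat, pops)
  d <- d_statistic(gm, "p1", "p2", "p3", "out", n_jackknife_blocks = 4)
  expect_equal(d$D, 0.5)
  expect_equal(d$abba_sum, 3)
  expect_equal(d$baba_sum, 1)

  d_swapped <- d_statistic(gm, "p2", "p1", "p3", "out",
                           n_jackknife_blocks = 4)
  expect_equal(d_swapped$D, -d$D)
  expect_true(abs(d$D) <= 1)

  # no informative sites -> flagged undefined
  mono <- pattern_gm(rbind(c(0, 0, 0, 0), c(1, 1, 0, 0)), pops)
  expect_true(d_statistic(mono, "p1", "p2", "p3", "out")$undefined)
})

test_that("f4 ratio hits its algebraic limits", {
  set.seed(77)
  pops <- c("p1", "p2", "p3", "out")
  p3pat <- sample(0:1, 50, replace = TRUE)
  p1pat <- sample(0:1, 50, replace = TRUE)
  # P2 identical to P3 -> numerator equals denominator -> 1
  gm1 <- pattern_gm(cbind(p1pat, p3pat, p3pat, 0), pops)
  expect_equal(as.numeric(f4_ratio(gm1, "p1", "p2", "p3", "out")), 1)
  # P2 identical to P1 -> 0
  gm0 <- pattern_gm(cbind(p1pat, p1pat, p3pat, 0), pops)
  expect_equal(as.numeric(f4_ratio(gm0, "p1", "p2", "p3", "out")), 0)
})

test_that("f4 ratio is invariant under sample duplication", {
  p <- sim_params(seed = 61, f = 0.1, n_sites = 2000, geno_length = 40000)
  gm <- simulate_genotypes(p, per_site = TRUE)$matrix
  f1 <- as.numeric(f4_ratio(gm, "niloticus", "focal", "mossambicus",
                            "urolepis"))
  gm2 <- gm
  gm2$geno <- cbind(gm$geno, gm$geno)
  colnames(gm2$geno) <- c(colnames(gm$geno), paste0(colnames(gm$geno), "_dup"))
  gm2$samples <- rbind(gm$samples,
                       transform(gm$samples,
                                 sample_id = paste0(sample_id, "_dup")))
  f2 <- as.numeric(f4_ratio(gm2, "niloticus", "focal", "mossambicus",
                            "urolepis"))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("f-branch marks undefined cells NA and is invariant to sample order", {
  sp_tree <- ape::read.tree(
    text = "((((focal,niloticus),aureus),mossambicus),urolepis);")
  p <- sim_params(seed = 62, f = 0.15, n_sites = 4000, geno_length = 40000)
  gm <- simulate_genotypes(p, per_site = TRUE)$matrix
  fb <- f_branch(gm, sp_tree, "urolepis")
  # taxa under a branch or its parent have no defined entry
  expect_true(all(is.na(fb$matrix[fb$branches == "mossambicus", ])))
  expect_true(all(fb$matrix[!is.na(fb$matrix)] >= 0))

  perm <- sample(ncol(gm$geno))
  gm_perm <- gm
  gm_perm$geno <- gm$geno[, perm]
  gm_perm$samples <- gm$samples[perm, ]
  fb2 <- f_branch(gm_perm, sp_tree, "urolepis")
  expect_equal(fb$matrix, fb2$matrix, tolerance = 1e-12)
})

test_that("jackknife SE shrinks with the number of informative sites", {
  ses <- vapply(c(2000, 20000), function(ns) {
    p <- sim_params(seed = 63, f = 0, ils_rate = 0.3, n_sites = ns,
                    geno_length = ns * 10)
    d <- d_statistic(simulate_genotypes(p)$matrix, "niloticus", "focal",
                     "mossambicus", "urolepis")
    d$se
  }, numeric(1))
  expect_lt(ses[2], ses[1])
})
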