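test_that("topology enumeration counts follow (2k-5)!! and keys are canonical", {
  expect_length(enumerate_topologies(letters[1:4])$key, 3)
  t5 <- enumerate_topologies(c("focal", "niloticus", "aureus",
                               "mossambicus", "urolepis"))
  expect_length(t5$key, 15)
  expect_false(anyDuplicated(t5$key) > 0)
  expect_length(enumerate_topologies(letters[1:6])$key, 105)
  expect_error(enumerate_topologies(letters[1:3]), "at least 4")

  # the species topology is found and matches the ladder newick
  ladder <- ape::read.tree(
    text = "((((focal,niloticus),aureus),mossambicus),urolepis);")
  expect_equal(topology_key(ladder, t5$groups), t5$species_key)
  # every enumerated tree reproduces its own key
  for (i in seq_along(t5$key))
    expect_equal(topology_key(t5$trees[[i]], t5$groups), t5$key[i])
})

test_that("weight_window handles single combinations and split focal tips", {
  groups1 <- taxon_groups(A = "a1", B = "b1", C = "c1", D = "d1", E = "e1")
  topo <- enumerate_topologies(groups1)
  tr <- topo$trees[[3]]
  tr$tip.label <- paste0(tolower(tr$tip.label), "1")
  w <- weight_window(tr, groups1, topo)
  expect_equal(w[3], 1)
  expect_equal(sum(w), 1)

  # two A tips on opposite sides -> weight split 0.5 / 0.5
  tr2 <- ape::read.tree(text = "((a1,b1),(c1,(d1,(e1,a2))));")
  groups2 <- taxon_groups(A = c("a1", "a2"), B = "b1", C = "c1", D = "d1",
                          E = "e1")
  w2 <- weight_window(tr2, groups2, topo)
  expect_equal(sum(w2 > 0), 2)
  expect_equal(unname(w2[w2 > 0]), c(0.5, 0.5))
  expect_equal(sum(w2), 1)

  expect_error(weight_window(tr, taxon_groups(A = "zz", B = "b1", C = "c1",
                                              D = "d1", E = "e1"), topo),
               "absent")
})

test_that("weight_window equals the keep.tip/Robinson-Foulds oracle on random trees", {
  set.seed(99)
  groups_of <- function(sizes) {
    nm <- c("A", "B", "C", "D", "E")
    tips <- unlist(lapply(seq_along(sizes), function(i)
      paste0(tolower(nm[i]), seq_len(sizes[i]))))
    do.call(taxon_groups, stats::setNames(
      lapply(seq_along(sizes), function(i)
        paste0(tolower(nm[i]), seq_len(sizes[i]))), nm))
  }
  topo <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  for (rep in 1:25) {
    sizes <- pmin(1 + stats::rpois(5, 0.8), 3)
    groups <- groups_of(sizes)
    tips <- unlist(groups, use.names = FALSE)
    tr <- ape::rtree(length(tips), tip.label = sample(tips))
    expect_equal(weight_window(tr, groups, topo),
                 oracle_weight(tr, groups, topo), tolerance = 1e-12)
  }
})

test_that("weights always sum to one and averages partition species vs discordant", {
  p <- sim_params(seed = 23, f = 0.1, ils_rate = 0.2, n_sites = 3000,
                  geno_length = 30000)
  sim <- simulate_genotypes(p)
  groups <- five_groups()
  topo <- enumerate_topologies(groups)
  wt <- infer_window_trees(sim$matrix)
  W <- weight_windows(wt, groups, topo)
  wm <- as.matrix(W[, grep("^w_", names(W))])
  expect_true(all(abs(rowSums(wm) - 1) < 1e-9))
  avg <- colMeans(wm)
  sp <- avg[topo$species_index]
  expect_equal(unname(sp + sum(avg[-topo$species_index])), 1, tolerance = 1e-9)
})

test_that("loess smoothing preserves constants and stays within the step range", {
  n <- 200
  series <- data.frame(seqid = "c1", start = (0:(n - 1)) * 160,
                       end = (0:(n - 1)) * 160 + 200,
                       w_1 = rep(0.4, n),
                       w_2 = c(rep(0, n / 2), rep(1, n / 2)))
  sm <- suppressWarnings(smooth_weights(series, span = 0.05))
  expect_equal(sm$w_1, rep(0.4, n), tolerance = 1e-8)
  expect_gte(min(sm$w_2), 0 - 1e-8)
  expect_lte(max(sm$w_2), 1 + 1e-8)
  # tight span approaches the raw series (near-singular local fits warn)
  sm2 <- suppressWarnings(smooth_weights(series, span = 3 / n))
  expect_lt(mean(abs(sm2$w_2 - series$w_2)), 0.05)
})

test_that("region extraction merges consecutive full-weight windows", {
  series <- data.frame(seqid = "c1",
                       start = c(0, 160, 320, 800),
                       end = c(200, 360, 520, 1000),
                       w_1 = c(1, 1, 1, 0.5))
  r <- extract_regions(series, 1, threshold = 1.0)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 0)
  expect_equal(r$end, 520)       # 200 + 2 * 160

  gap <- series; gap$w_1 <- c(1, 1, 1, 1)   # non-adjacent run -> two regions
  expect_equal(nrow(extract_regions(gap, 1, 1.0)), 2)
  none <- series; none$w_1 <- 0.9
  expect_equal(nrow(extract_regions(none, 1, 1.0)), 0)
  expect_error(extract_regions(series, 1, threshold = 1.5), "0, 1")
})

test_that("donor-sister regions recover planted tracts (Jaccard >= 0.5)", {
  p <- sim_params(seed = 41, f = 0.2, ils_rate = 0.1, n_sites = 8000,
                  geno_length = 8e4)
  sim <- simulate_genotypes(p)
  groups <- five_groups()
  topo <- enumerate_topologies(groups)
  W <- weight_windows(infer_window_trees(sim$matrix), groups, topo)
  ik <- introscan:::introgression_key(topo, names(groups))
  regions <- extract_regions(W, ik, threshold = 1.0)
  cover <- function(df, L) {
    v <- rep(FALSE, L)
    for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
    v
  }
  va <- cover(regions, 8e4); vb <- cover(sim$truth$blocks, 8e4)
  expect_gte(sum(va & vb) / sum(va | vb), 0.5)
})

test_that("NJ window trees join identical samples and are deterministic", {
  geno <- matrix(c(0L, 0L, 2L, 2L, 2L, 2L, 0L, 2L,
                   0L, 0L, 2L, 2L, 2L, 2L, 2L, 0L,
                   0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L,
                   2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L), nrow = 4, byrow = TRUE)
  colnames(geno) <- c("x1", "x2", "y1", "y2", "z1", "z2", "q1", "q2")
  gm <- make_gm(geno, rep(c("X", "Y", "Z", "Q"), each = 2),
                pos = c(10L, 50L, 90L, 130L))
  wt <- infer_window_trees(gm, window = 200, overlap = 40)
  expect_equal(nrow(wt$windows), 1)
  tr <- wt$trees[[1]]
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["x1", "x2"], 0, tolerance = 1e-9)
  # identical samples sit as adjacent tips (cherry)
  pair_mrca <- ape::getMRCA(tr, c("x1", "x2"))
  expect_length(introscan:::descendant_tips(tr, pair_mrca), 2)
  wt2 <- infer_window_trees(gm, window = 200, overlap = 40)
  expect_identical(ape::write.tree(tr), ape::write.tree(wt2$trees[[1]]))
})

test_that("NJ recovers the generating topology from an additive distance matrix", {
  # ((a,b),(c,d)) with internal branch 2 and terminal branches 1
  dm <- matrix(c(0, 2, 4, 4,
                 2, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4, 4,
               dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  tr <- ape::nj(stats::as.dist(dm))
  expect_equal(topology_key(tr, c("a", "b", "c", "d")),
               topology_key(ape::read.tree(text = "((a,b),(c,d));"),
                            c("a", "b", "c", "d")))
})
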