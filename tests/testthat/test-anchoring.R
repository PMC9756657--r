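toy_probes <- function(scaffold, bp, lg, cm, score = 100L) {
  n <- length(bp)
  data.frame(probe_id = sprintf("%s_p%02d", scaffold, seq_len(n)),
             scaffold = scaffold, bp = as.integer(bp), strand = "+",
             score = score, lg = lg, cm = cm, stringsAsFactors = FALSE)
}

test_that("scaffold assignment: single LG assigned, probe-less to LG0, chimeras flagged", {
  pr <- rbind(toy_probes("scA", c(100, 5000), "LG5", c(1, 2)),
              toy_probes("scB", c(100, 900000, 2000000, 2900000),
                         c("LG1", "LG1", "LG2", "LG2"), c(1, 2, 10, 11)))
  a <- assign_scaffolds(pr, scaffold_names = c("scA", "scB", "scC"))
  expect_equal(a$lg[a$scaffold == "scA"], "LG5")
  expect_equal(a$lg[a$scaffold == "scC"], "LG0")
  expect_true(a$chimera[a$scaffold == "scB"])
  expect_false(any(a$chimera[a$scaffold != "scB"]))
})

test_that("merge_probes keeps the best hit and drops cross-scaffold ties", {
  hits <- data.frame(probe_id = c("p1", "p1", "p2", "p2"),
                     scaffold = c("scA", "scB", "scA", "scB"),
                     bp = c(10L, 20L, 30L, 40L),
                     strand = "+", score = c(100L, 90L, 80L, 80L))
  map <- data.frame(probe_id = c("p1", "p2"), lg = "LG1", cm = c(1, 2))
  m <- merge_probes(hits, map)
  expect_equal(m$probe_id, "p1")          # p2 tied across scaffolds: dropped
  expect_equal(m$scaffold, "scA")
  expect_equal(attr(m, "n_dropped_ties"), 1L)
})

test_that("chimera break falls at the midpoint between distal probes", {
  pr <- toy_probes("scB", c(0, 1000000, 2000000, 3000000),
                   c("LG1", "LG1", "LG2", "LG2"), c(1, 2, 10, 11))
  a <- assign_scaffolds(pr)
  res <- break_chimeras(a, pr, scaffold_lengths = c(scB = 4000000))
  expect_equal(res$breaks$cut, 1500000)
  expect_equal(sort(unique(res$probes$scaffold)), c("scB.1", "scB.2"))
  expect_equal(res$assignments$lg[res$assignments$scaffold == "scB.1"], "LG1")
  expect_equal(res$assignments$lg[res$assignments$scaffold == "scB.2"], "LG2")
  # piece-local probe coordinates are rebased
  expect_equal(res$probes$bp[res$probes$scaffold == "scB.2"],
               c(2000000, 3000000) - 1500000)
})

test_that("overlapping LG blocks leave the scaffold unbroken with a warning", {
  pr <- toy_probes("scX", c(0, 2000000, 1000000, 3000000),
                   c("LG1", "LG1", "LG2", "LG2"), c(1, 2, 10, 11))
  a <- assign_scaffolds(pr)
  expect_warning(res <- break_chimeras(a, pr,
                                       scaffold_lengths = c(scX = 4000000)),
                 "overlap")
  expect_equal(res$unresolved, "scX")
  expect_equal(nrow(res$breaks), 0)
})

test_that("orientation follows the bp-cM rank correlation", {
  pr_plus <- toy_probes("sc1", c(100, 2000), "LG1", c(0.5, 1.5))
  pr_minus <- toy_probes("sc2", c(100, 2000), "LG1", c(1.5, 0.5))
  pr_single <- toy_probes("sc3", 500, "LG1", 3)
  pr <- rbind(pr_plus, pr_minus, pr_single)
  oo <- order_and_orient(assign_scaffolds(pr), pr)
  expect_equal(oo$orientation[oo$scaffold == "sc1"], "+")
  expect_equal(oo$orientation[oo$scaffold == "sc2"], "-")
  expect_equal(oo$orientation[oo$scaffold == "sc3"], "+")
  expect_false(oo$orientation_known[oo$scaffold == "sc3"])
  expect_equal(oo$scaffold, c("sc1", "sc2", "sc3"))   # by median cM
})

test_that("LG building inserts exactly 100 Ns, reverse-complements, and round-trips via AGP", {
  scaffolds <- c(s1 = strrep("A", 10), s2 = paste0(strrep("G", 15), "ACGTA"))
  oo <- data.frame(lg = "LG1", position = 1:2, scaffold = c("s1", "s2"),
                   orientation = c("+", "-"), orientation_known = TRUE,
                   median_cm = c(1, 2), n_probes = 2L)
  b <- build_lg_sequences(oo, scaffolds)
  expect_equal(nchar(b$sequences[["LG1"]]), 10 + 100 + 20)
  expect_equal(substr(b$sequences[["LG1"]], 11, 110), strrep("N", 100))
  expect_equal(substr(b$sequences[["LG1"]], 111, 130), revcomp(scaffolds[["s2"]]))

  # AGP rows reconstruct the FASTA exactly
  reconstructed <- ""
  for (i in seq_len(nrow(b$agp))) {
    row <- b$agp[i, ]
    piece <- if (row$component_type == "U") strrep("N", as.integer(row$component_id))
    else {
      s <- scaffolds[[row$component_id]]
      if (row$orientation == "-") s <- revcomp(s)
      substr(s, row$component_beg, row$component_end)
    }
    reconstructed <- paste0(reconstructed, piece)
  }
  expect_identical(reconstructed, b$sequences[["LG1"]])

  single <- build_lg_sequences(oo[1, ], scaffolds)
  expect_false(grepl("N", single$sequences[["LG1"]]))
  expect_error(build_lg_sequences(transform(oo, scaffold = c("s1", "zz")),
                                  scaffolds), "absent")
})

test_that("Marey monotonicity is 1.0 when anchored correctly and below when inverted", {
  p <- sim_params(seed = 19, n_lgs = 3, scaffolds_per_lg = 3,
                  chimera_fraction = 0)
  pm <- simulate_probe_map(p)
  pr <- merge_probes(pm$hits, pm$map)
  oo <- order_and_orient(assign_scaffolds(pr), pr)
  mt <- marey_table(oo, pr, nchar(pm$scaffolds))
  expect_true(all(mt$monotonicity$score == 1))

  flip <- oo
  minus <- which(flip$orientation == "-")[1]
  if (!is.na(minus)) {
    flip$orientation[minus] <- "+"
    mt2 <- marey_table(flip, pr, nchar(pm$scaffolds))
    lg_flipped <- flip$lg[minus]
    expect_lt(mt2$monotonicity$score[mt2$monotonicity$lg == lg_flipped], 1)
  }
})

test_that("breaking and building conserve every input base", {
  p <- sim_params(seed = 29, n_lgs = 5, scaffolds_per_lg = 3,
                  chimera_fraction = 0.2, map_scaffold_length = 5000)
  pm <- simulate_probe_map(p)
  pr <- merge_probes(pm$hits, pm$map)
  asg <- assign_scaffolds(pr, names(pm$scaffolds))
  bk <- break_chimeras(asg, pr, scaffolds = pm$scaffolds)
  oo <- order_and_orient(bk$assignments, bk$probes)
  build <- build_lg_sequences(oo, bk$scaffolds)
  lg0 <- bk$assignments$scaffold[bk$assignments$lg == "LG0"]
  n_gap <- sum(vapply(split(oo$scaffold, oo$lg), length, integer(1)) - 1) * 100
  total_built <- sum(nchar(build$sequences)) + sum(nchar(bk$scaffolds[lg0]))
  expect_equal(total_built - n_gap, sum(nchar(pm$scaffolds)))
})
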