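# Frequency-based admixture statistics: site filtering, LD pruning,
# Patterson's D with block-jackknife significance, the f4-admixture ratio,
# and branch-resolved f-branch localization on the species tree.

#' Site-filter parameters
#'
#' Defaults follow the SNP quality funnel used for the admixture analysis:
#' total depth in [90, 900], minor allele count at least 3, at most one
#' individual missing, no SNP overlapping or within 3 bp of an indel, and
#' the repeat-rich LG3 excluded.
#'
#' @param min_total_depth,max_total_depth Total-depth bounds (inclusive).
#' @param min_minor_allele_count Minimum minor allele count.
#' @param max_missing_individuals Maximum samples with missing genotype.
#' @param indel_exclusion_distance SNPs at most this many bp from an indel
#'   are removed.
#' @param exclude_seqids Seqids dropped entirely (default \code{"LG3"}).
#' @return Named parameter list.
#' @export
site_filter_params <- function(min_total_depth = 90, max_total_depth = 900,
                               min_minor_allele_count = 3,
                               max_missing_individuals = 1,
                               indel_exclusion_distance = 3,
                               exclude_seqids = "LG3") {
  stopifnot(min_total_depth > 0, min_total_depth < max_total_depth,
            min_minor_allele_count >= 0, max_missing_individuals >= 0)
  list(min_total_depth = min_total_depth, max_total_depth = max_total_depth,
       min_minor_allele_count = min_minor_allele_count,
       max_missing_individuals = max_missing_individuals,
       indel_exclusion_distance = indel_exclusion_distance,
       exclude_seqids = exclude_seqids)
}

#' Filter genotype sites for the admixture statistics
#'
#' Retains biallelic SNPs passing every criterion of
#' \code{\link{site_filter_params}}; removal counts per criterion are
#' attached as \code{attr(, "funnel")}.
#'
#' @param gm A \code{genotype_matrix}.
#' @param params Parameters from \code{\link{site_filter_params}}.
#' @return Filtered \code{genotype_matrix}.
#' @export
filter_sites <- function(gm, params = site_filter_params()) {
  s <- gm$sites
  n_missing <- rowSums(is.na(gm$geno))
  alt <- rowSums(gm$geno, na.rm = TRUE)
  tot <- 2L * rowSums(!is.na(gm$geno))
  mac <- pmin(alt, tot - alt)
  crit <- list(
    non_biallelic_or_indel = s$biallelic & !s$is_indel,
    depth = !is.na(s$total_depth) &
      s$total_depth >= params$min_total_depth &
      s$total_depth <= params$max_total_depth,
    minor_allele_count = mac >= params$min_minor_allele_count,
    missingness = n_missing <= params$max_missing_individuals,
    indel_proximity = is.na(s$dist_indel) |
      s$dist_indel > params$indel_exclusion_distance,
    excluded_seqid = !(s$seqid %in% params$exclude_seqids)
  )
  keep <- Reduce(`&`, crit)
  funnel <- vapply(crit, function(x) sum(!x), integer(1))
  out <- list(sites = s[keep, , drop = FALSE],
              geno = gm$geno[keep, , drop = FALSE],
              samples = gm$samples)
  rownames(out$sites) <- NULL
  class(out) <- "genotype_matrix"
  attr(out, "funnel") <- c(funnel, retained = sum(keep))
  out
}

#' Prune sites in linkage disequilibrium
#'
#' Greedy left-to-right scan per seqid: a site is dropped when its genotype
#' r-squared with any already-retained site within the window exceeds
#' \code{r2_max}.
#'
#' @param gm A \code{genotype_matrix} (sites sorted by position).
#' @param r2_max Maximum tolerated r-squared (default 0.6).
#' @param window Window size in bp (default 20000).
#' @return Pruned \code{genotype_matrix}.
#' @export
ld_prune <- function(gm, r2_max = 0.6, window = 20000) {
  s <- gm$sites
  keep <- logical(nrow(s))
  for (sq in unique(s$seqid)) {
    idx <- which(s$seqid == sq)
    retained <- integer(0)
    for (i in idx) {
      near <- retained[s$pos[i] - s$pos[retained] <= window]
      ok <- TRUE
      for (j in rev(near)) {
        r <- suppressWarnings(stats::cor(gm$geno[i, ], gm$geno[j, ],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
      }
      if (ok) { keep[i] <- TRUE; retained <- c(retained, i) }
    }
  }
  out <- list(sites = s[keep, , drop = FALSE],
              geno = gm$geno[keep, , drop = FALSE],
              samples = gm$samples)
  rownames(out$sites) <- NULL
  class(out) <- "genotype_matrix"
  out
}

# per-population alternate-allele frequencies, polarized so that the
# ancestral allele is the outgroup's major allele; sites where the outgroup
# is exactly 50/50 are dropped (ambiguous polarization)
derived_freqs <- function(gm, pops, outgroup) {
  freq1 <- function(pop) {
    cols <- gm$samples$population == pop
    if (!any(cols)) stop("population '", pop, "' has no samples")
    alt <- rowSums(gm$geno[, cols, drop = FALSE], na.rm = TRUE)
    tot <- 2 * rowSums(!is.na(gm$geno[, cols, drop = FALSE]))
    ifelse(tot > 0, alt / tot, NA_real_)
  }
  p <- vapply(unique(c(pops, outgroup)), freq1, numeric(nrow(gm$sites)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                   dimnames = list(NULL, unique(c(pops, outgroup))))
  po <- p[, outgroup]
  flip <- !is.na(po) & po > 0.5
  p[flip, ] <- 1 - p[flip, ]
  ambiguous <- !is.na(po) & po == 0.5
  usable <- !ambiguous & !apply(p, 1, anyNA)
  list(freqs = p[usable, , drop = FALSE], usable = which(usable),
       n_ambiguous = sum(ambiguous))
}

#' Patterson's D (ABBA-BABA) with block-jackknife significance
#'
#' Frequency-based D over derived-allele frequencies polarized by the
#' outgroup's major allele: per site
#' \code{ABBA = (1-p1) p2 p3 (1-pO)}, \code{BABA = p1 (1-p2) p3 (1-pO)},
#' \code{D = sum(ABBA-BABA) / sum(ABBA+BABA)}.  The standard error comes
#' from a delete-one jackknife over contiguous equal-site blocks.
#'
#' @param gm A filtered \code{genotype_matrix}.
#' @param P1,P2,P3,O Population labels (O is the outgroup).
#' @param n_jackknife_blocks Number of contiguous blocks (default 20).
#' @return list (class \code{trio_result}): populations, \code{n_sites_used},
#'   \code{abba_sum}, \code{baba_sum}, \code{D}, \code{se}, \code{Z},
#'   \code{f_g}.
#' @export
d_statistic <- function(gm, P1, P2, P3, O, n_jackknife_blocks = 20) {
  df <- derived_freqs(gm, c(P1, P2, P3), O)
  p <- df$freqs
  p1 <- p[, P1]; p2 <- p[, P2]; p3 <- p[, P3]; po <- p[, O]
  abba <- (1 - p1) * p2 * p3 * (1 - po)
  baba <- p1 * (1 - p2) * p3 * (1 - po)
  num <- sum(abba - baba); den <- sum(abba + baba)
  n <- length(abba)
  if (den == 0) {
    res <- list(P1 = P1, P2 = P2, P3 = P3, O = O, n_sites_used = n,
                abba_sum = sum(abba), baba_sum = sum(baba),
                D = NA_real_, se = NA_real_, Z = NA_real_, f_g = NA_real_,
                undefined = TRUE)
    class(res) <- "trio_result"
    return(res)
  }
  D <- num / den
  B <- min(n_jackknife_blocks, n)
  blk <- ceiling(seq_len(n) / (n / B))
  dj <- vapply(seq_len(B), function(b) {
    i <- blk != b
    sum(abba[i] - baba[i]) / sum(abba[i] + baba[i])
  }, numeric(1))
  se <- sqrt((B - 1) / B * sum((dj - mean(dj))^2))
  fg <- f4_ratio(gm, P1, P2, P3, O)
  res <- list(P1 = P1, P2 = P2, P3 = P3, O = O, n_sites_used = n,
              abba_sum = sum(abba), baba_sum = sum(baba), D = D, se = se,
              Z = if (se > 0) D / se else NA_real_, f_g = fg,
              undefined = FALSE)
  class(res) <- "trio_result"
  res
}

#' @export
print.trio_result <- function(x, ...) {
  cat(sprintf("D(%s,%s;%s,%s) = %.4f  Z = %.2f  f_G = %.4f  (%d sites)\n",
              x$P1, x$P2, x$P3, x$O, x$D, x$Z, x$f_g, x$n_sites_used))
  invisible(x)
}

#' f4-admixture ratio
#'
#' Estimates the admixture proportion from P3 into P2 relative to P1 as
#' \code{f_G = sum((p2-p1) p3 (1-pO)) / sum((p3-p1) p3 (1-pO))} over
#' polarized derived-allele frequencies (the within-P3 denominator form).
#' The returned value is clipped to [0, 1]; the raw estimate is kept in
#' \code{attr(, "raw")}.
#'
#' @param gm A filtered \code{genotype_matrix}.
#' @param P1,P2,P3,O Population labels.
#' @return Admixture-fraction estimate in [0, 1] (NA when the denominator
#'   vanishes).
#' @export
f4_ratio <- function(gm, P1, P2, P3, O) {
  df <- derived_freqs(gm, c(P1, P2, P3), O)
  p <- df$freqs
  num <- sum((p[, P2] - p[, P1]) * p[, P3] * (1 - p[, O]))
  den <- sum((p[, P3] - p[, P1]) * p[, P3] * (1 - p[, O]))
  if (den == 0) {
    out <- NA_real_
    attr(out, "raw") <- NA_real_
    return(out)
  }
  raw <- num / den
  out <- min(1, max(0, raw))
  attr(out, "raw") <- raw
  out
}

#' Branch-resolved admixture localization (f-branch)
#'
#' Summarizes correlated f4-ratio statistics on a rooted species tree: for
#' each branch b and each taxon C neither descending from b nor from b's
#' parent, \code{f_b(C) = median over A in sister(b)'s descendants of
#' [min over B in b's descendants of f_G(A, B, C)]}, clipped at zero.
#' Large entries localize gene flow from C into the lineage of b.
#'
#' @param gm A filtered \code{genotype_matrix}.
#' @param tree Rooted \code{ape::phylo} over the population labels,
#'   outgroup included.
#' @param outgroup Outgroup label (fixed O of every trio).
#' @return list (class \code{f_branch_matrix}) with \code{matrix}
#'   (branches x taxa; NA marks undefined entries), \code{branches}
#'   (clade label per row) and \code{tree}.
#' @export
f_branch <- function(gm, tree, outgroup) {
  stopifnot(outgroup %in% tree$tip.label)
  ingroup_tree <- ape::drop.tip(tree, outgroup)
  tips <- ingroup_tree$tip.label
  nt <- length(tips)
  root <- nt + 1L
  nodes <- setdiff(unique(as.vector(ingroup_tree$edge)), root)
  clade <- function(nd) tips[descendant_tips(ingroup_tree, nd)]
  parent_of <- function(nd) ingroup_tree$edge[ingroup_tree$edge[, 2] == nd, 1]
  sibling_clade <- function(nd) {
    pa <- parent_of(nd)
    sib <- setdiff(ingroup_tree$edge[ingroup_tree$edge[, 1] == pa, 2], nd)
    unique(unlist(lapply(sib, clade)))
  }
  cache <- new.env(parent = emptyenv())
  fg <- function(A, B, C) {
    key <- paste(A, B, C, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- as.numeric(f4_ratio(gm, A, B, C, outgroup))
    cache[[key]] <- v
    v
  }
  m <- matrix(NA_real_, length(nodes), nt,
              dimnames = list(NULL, tips))
  labels <- character(length(nodes))
  for (r in seq_along(nodes)) {
    nd <- nodes[r]
    db <- clade(nd)
    labels[r] <- paste(sort(db), collapse = "+")
    ds <- sibling_clade(nd)
    pa <- parent_of(nd)
    dparent <- if (pa == root) tips else clade(pa)
    for (C in setdiff(tips, dparent)) {
      if (!length(ds)) next
      vals <- vapply(ds, function(A)
        min(vapply(db, function(B) fg(A, B, C), numeric(1))), numeric(1))
      m[r, C] <- max(0, stats::median(vals))
    }
  }
  out <- list(matrix = m, branches = labels, tree = tree)
  class(out) <- "f_branch_matrix"
  out
}

#' @export
print.f_branch_matrix <- function(x, ...) {
  m <- x$matrix
  rownames(m) <- x$branches
  print(round(m, 4))
  invisible(x)
}
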