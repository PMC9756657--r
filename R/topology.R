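# Topology weighting over taxon groups: exhaustive enumeration of unrooted
# topologies, per-window weighting by iterating all one-tip-per-group
# combinations (the "complete" method), loess smoothing, and extraction of
# donor-sister regions.

#' Define taxon groups
#'
#' @param ... Named character vectors: group name -> tip labels.  Group
#'   order is meaningful (the species topology is the ladder over the given
#'   order, first group innermost, last group outermost).
#' @return Named list of tip-label vectors.
#' @export
taxon_groups <- function(...) {
  g <- list(...)
  if (length(g) < 2) stop("need at least 2 taxon groups")
  if (is.null(names(g)) || any(!nzchar(names(g))))
    stop("all groups must be named")
  if (any(lengths(g) == 0)) stop("every group must contain at least one tip")
  tips <- unlist(g, use.names = FALSE)
  if (anyDuplicated(tips))
    stop("tip(s) occur in more than one group: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  g
}

# canonical key of an unrooted topology given as a set of nontrivial splits;
# each split is represented by the side NOT containing the reference label,
# sorted and comma-joined; splits sorted and pipe-joined.
splits_to_key <- function(splits, labels) {
  ref <- labels[1]
  norm <- vapply(splits, function(s) {
    if (ref %in% s) s <- setdiff(labels, s)
    paste(sort(s), collapse = ",")
  }, character(1))
  paste(sort(unique(norm)), collapse = "|")
}

# nontrivial splits (as tip-name sets) of a phylo tree, treated as unrooted
unrooted_splits <- function(tr) {
  tr <- ape::unroot(tr)
  k <- length(tr$tip.label)
  sides <- lapply(setdiff(unique(tr$edge[, 2]), seq_len(k)), function(nd) {
    tr$tip.label[descendant_tips(tr, nd)]
  })
  sides[vapply(sides, function(s) length(s) >= 2 && length(s) <= k - 2,
               logical(1))]
}

#' Canonical key of a tree's unrooted topology over given labels
#' @param tr \code{ape::phylo} with tip labels drawn from \code{labels}.
#' @param labels Full label set fixing the canonical form.
#' @return Character key; equal keys mean equal unrooted topologies.
#' @export
topology_key <- function(tr, labels) {
  splits_to_key(unrooted_splits(tr), labels)
}

#' Enumerate all unrooted bifurcating topologies on k taxon groups
#'
#' Exhaustive leaf-insertion enumeration; the count is (2k-5)!! (15 for
#' five groups).  The species topology is the ladder over the given group
#' order, e.g. \code{((((focal,niloticus),aureus),mossambicus),urolepis)}.
#'
#' @param groups Character vector of group names (or a
#'   \code{\link{taxon_groups}} list, in which case its names are used).
#' @return A \code{topology_set}: list with \code{groups}, \code{trees}
#'   (list of \code{phylo}), \code{newick}, \code{key},
#'   \code{species_index}/\code{species_key} and per-topology split sets.
#' @export
enumerate_topologies <- function(groups) {
  labels <- if (is.list(groups)) names(groups) else groups
  k <- length(labels)
  if (k < 4) stop("topology weighting needs at least 4 groups")
  # edge-list enumeration: leaves 1..k, internal nodes k+1, k+2, ...
  trees <- list(list(edges = rbind(c(k + 1L, 1L), c(k + 1L, 2L), c(k + 1L, 3L)),
                     nxt = k + 2L))
  if (k > 3) for (leaf in 4:k) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edges)), function(ei) {
        e <- tr$edges[ei, ]
        w <- tr$nxt
        list(edges = rbind(tr$edges[-ei, , drop = FALSE],
                           c(e[1], w), c(w, e[2]), c(w, leaf)),
             nxt = w + 1L)
      })
    }), recursive = FALSE)
  }
  nwk <- vapply(trees, function(tr) edges_to_newick(tr$edges, labels, k),
                character(1))
  phylos <- lapply(nwk, function(x) ape::read.tree(text = x))
  splits <- lapply(phylos, unrooted_splits)
  keys <- vapply(splits, splits_to_key, character(1), labels = labels)
  if (anyDuplicated(keys)) stop("internal error: duplicate topologies enumerated")
  o <- order(keys)
  phylos <- phylos[o]; nwk <- nwk[o]; keys <- keys[o]; splits <- splits[o]
  ladder <- paste0(paste(rep("(", k - 1), collapse = ""), labels[1], ",",
                   paste(labels[-1], collapse = "),"), ");")
  species_key <- topology_key(ape::read.tree(text = ladder), labels)
  out <- list(groups = labels, trees = phylos, newick = nwk, key = keys,
              splits = splits,
              species_key = species_key,
              species_index = match(species_key, keys))
  class(out) <- "topology_set"
  out
}

edges_to_newick <- function(edges, labels, k) {
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  rec <- function(node, parent) {
    if (node <= k) return(labels[node])
    kids <- setdiff(adj[[as.character(node)]], parent)
    paste0("(", paste(vapply(kids, rec, character(1), parent = node),
                      collapse = ","), ")")
  }
  paste0(rec(k + 1L, NA), ";")
}

#' @export
print.topology_set <- function(x, ...) {
  cat("topology_set:", length(x$key), "unrooted topologies on",
      length(x$groups), "groups (", paste(x$groups, collapse = ", "), ")\n")
  cat("species topology index:", x$species_index, "\n")
  invisible(x)
}

#' Weight a window tree over the enumerated topology set
#'
#' Iterates over all combinations of one tip per group, restricts the tree
#' to each combination, matches the induced unrooted topology against the
#' topology set, and returns match fractions.  Combinations whose induced
#' topology is unresolved (a polytomy) have their weight split equally among
#' all compatible topologies (\code{polytomy = "distribute"}, the
#' exhaustive-method convention) or are discarded.
#'
#' @param tree \code{ape::phylo} window tree (tip labels = sample names).
#' @param groups \code{\link{taxon_groups}} list.
#' @param topologies \code{\link{enumerate_topologies}} result.
#' @param polytomy Policy for unresolved induced topologies.
#' @return Numeric weight vector over the topology set (sums to 1 under
#'   \code{"distribute"}).
#' @export
weight_window <- function(tree, groups, topologies,
                          polytomy = c("distribute", "discard")) {
  polytomy <- match.arg(polytomy)
  labels <- names(groups)
  stopifnot(identical(sort(labels), sort(topologies$groups)))
  for (g in labels) {
    absent <- setdiff(groups[[g]], tree$tip.label)
    if (length(absent))
      stop("tip '", absent[1], "' of group '", g, "' absent from tree")
  }
  k <- length(labels)
  full_splits <- unrooted_splits(tree)
  topo_splitsets <- lapply(topologies$splits, function(ss)
    strsplit(splits_to_key(ss, labels), "|", fixed = TRUE)[[1]])
  combos <- expand.grid(groups, stringsAsFactors = FALSE)
  w <- numeric(length(topologies$key))
  used <- 0
  for (i in seq_len(nrow(combos))) {
    tips <- as.character(combos[i, ])
    names(tips) <- labels
    induced <- lapply(full_splits, function(s) labels[tips %in% s])
    induced <- induced[vapply(induced, function(s)
      length(s) >= 2 && length(s) <= k - 2, logical(1))]
    key <- splits_to_key(induced, labels)
    parts <- if (nzchar(key)) strsplit(key, "|", fixed = TRUE)[[1]] else character(0)
    if (length(parts) == k - 3) {          # fully resolved
      w[match(key, topologies$key)] <- w[match(key, topologies$key)] + 1
      used <- used + 1
    } else {                               # polytomy after pruning
      compat <- vapply(topo_splitsets, function(ts) all(parts %in% ts),
                       logical(1))
      if (polytomy == "distribute") {
        w[compat] <- w[compat] + 1 / sum(compat)
        used <- used + 1
      }
    }
  }
  if (used == 0) return(w)
  w / used
}

#' Weight a series of window trees
#'
#' @param wt list with \code{windows} and \code{trees}
#'   (\code{\link{read_window_trees}} / \code{\link{infer_window_trees}}).
#' @param groups \code{\link{taxon_groups}} list.
#' @param topologies \code{\link{enumerate_topologies}} result.
#' @param ... Passed to \code{\link{weight_window}}.
#' @return data.frame \code{seqid,start,end,w_1..w_T}; topology keys kept in
#'   \code{attr(,"topologies")}.
#' @export
weight_windows <- function(wt, groups, topologies, ...) {
  W <- t(vapply(wt$trees, weight_window, numeric(length(topologies$key)),
                groups = groups, topologies = topologies, ...))
  colnames(W) <- paste0("w_", seq_along(topologies$key))
  out <- cbind(wt$windows, as.data.frame(W))
  attr(out, "topologies") <- topologies
  out
}

#' Loess-smooth topology weightings along the genome
#'
#' Local linear regression (degree 1, tricube kernel) per topology per
#' seqid, evaluated at window midpoints, with the span given as the
#' fraction of windows.  Smoothing is for reporting and plots; region
#' extraction operates on the raw weights.
#'
#' @param series Weight data.frame from \code{\link{weight_windows}}.
#' @param span Loess span as a fraction of windows per seqid (default 0.05).
#' @return data.frame of the same shape with smoothed weight columns.
#' @export
smooth_weights <- function(series, span = 0.05) {
  wc <- grep("^w_", names(series), value = TRUE)
  out <- series
  for (sq in unique(series$seqid)) {
    i <- which(series$seqid == sq)
    if (length(i) < 2) {
      warning("seqid ", sq, " has a single window; returned unsmoothed")
      next
    }
    mid <- (series$start[i] + series$end[i]) / 2
    eff_span <- max(span, 3 / length(i))   # need >=2 points in every fit
    for (cc in wc) {
      sm <- tryCatch(
        stats::predict(stats::loess(series[[cc]][i] ~ mid, span = eff_span,
                                    degree = 1, surface = "direct")),
        error = function(e) series[[cc]][i])
      out[[cc]][i] <- sm
    }
  }
  attr(out, "topologies") <- attr(series, "topologies")
  out
}

#' Extract regions where a topology's weighting reaches a threshold
#'
#' Maximal runs of consecutive windows whose target weight is at or above
#' the threshold are merged into one interval spanning the first window's
#' start to the last window's end.  The default threshold 1.0 selects
#' windows where every tip combination supports the target topology, which
#' only the raw (unsmoothed) weights can reach.
#'
#' @param series Raw weight data.frame from \code{\link{weight_windows}}.
#' @param target Topology selector: a \code{w_} column name, an index into
#'   the topology set, or a canonical topology key.
#' @param threshold Weight threshold in [0, 1] (default 1.0).
#' @return data.frame of intervals \code{seqid,start,end,n_windows}.
#' @export
extract_regions <- function(series, target, threshold = 1.0) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  topo <- attr(series, "topologies")
  col <- if (is.numeric(target)) paste0("w_", target)
         else if (target %in% names(series)) target
         else if (!is.null(topo) && target %in% topo$key)
           paste0("w_", match(target, topo$key))
         else stop("target topology '", target, "' not found")
  if (!col %in% names(series)) stop("no weight column ", col)
  hits <- series[[col]] >= threshold - 1e-12
  out <- list()
  for (sq in unique(series$seqid)) {
    i <- which(series$seqid == sq)
    i <- i[order(series$start[i])]
    h <- hits[i]
    if (!any(h)) next
    # a run also breaks across genomic gaps (a window that does not touch
    # its predecessor), not only at sub-threshold windows
    gap <- c(FALSE, series$start[i][-1] > series$end[i][-length(i)])
    grp <- cumsum(gap)
    h <- ifelse(h, grp + 1, 0)   # distinct positive values per gap-group
    r <- rle(h)
    r$values <- r$values > 0
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      out[[length(out) + 1]] <- data.frame(
        seqid = sq,
        start = series$start[i[starts[j]]],
        end = series$end[i[ends[j]]],
        n_windows = r$lengths[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Infer neighbour-joining trees in sliding windows
#'
#' Windows of \code{window} bp advance by \code{window - overlap} bp along
#' each seqid.  Within a window, pairwise Hamming distances between samples
#' over genotype codes feed \code{ape::nj}.  Windows without variant sites
#' are skipped; samples with all-missing genotypes in a window are dropped
#' for that window.
#'
#' @param gm A \code{genotype_matrix}.
#' @param window Window size in bp (default 200).
#' @param overlap Overlap between consecutive windows in bp (default 40).
#' @return list with \code{windows} (data.frame) and \code{trees} (list of
#'   \code{phylo}); the number of skipped windows is in
#'   \code{attr(,"n_skipped")}.
#' @export
infer_window_trees <- function(gm, window = 200, overlap = 40) {
  stopifnot(window > overlap)
  step <- window - overlap
  wins <- list(); trees <- list(); skipped <- 0L
  for (sq in unique(gm$sites$seqid)) {
    si <- which(gm$sites$seqid == sq)
    maxp <- max(gm$sites$pos[si])
    starts <- seq(0, maxp - 1, by = step)
    for (s in starts) {
      e <- s + window
      rows <- si[gm$sites$pos[si] > s & gm$sites$pos[si] <= e]
      if (!length(rows)) { skipped <- skipped + 1L; next }
      g <- gm$geno[rows, , drop = FALSE]
      keep <- colSums(!is.na(g)) > 0
      if (sum(keep) < 4) { skipped <- skipped + 1L; next }
      g <- g[, keep, drop = FALSE]
      d <- hamming_dist(g)
      tr <- ape::nj(d)
      wins[[length(wins) + 1]] <- data.frame(seqid = sq, start = s, end = e,
                                             stringsAsFactors = FALSE)
      trees[[length(trees) + 1]] <- tr
    }
  }
  windows <- if (length(wins)) do.call(rbind, wins)
    else data.frame(seqid = character(0), start = numeric(0), end = numeric(0))
  out <- list(windows = windows, trees = trees)
  attr(out, "n_skipped") <- skipped
  out
}

# proportion of (pairwise complete) sites with differing genotype codes
hamming_dist <- function(g) {
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    d[i, j] <- d[j, i] <- if (any(ok)) mean(g[ok, i] != g[ok, j]) else 0
  }
  stats::as.dist(d)
}
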