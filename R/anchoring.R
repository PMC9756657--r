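# Linkage-group anchoring: assign scaffolds to linkage groups from probe
# hits and a genetic map, detect and break chimeric scaffolds, order and
# orient, join with 100-N gaps, and emit Marey QC tables.

#' Merge probe hits with the genetic map, keeping one best hit per probe
#'
#' Best hit = highest alignment score; probes whose best score is tied
#' across different scaffolds are dropped (count in
#' \code{attr(, "n_dropped_ties")}).
#'
#' @param hits Probe-hit data.frame (\code{\link{read_probe_hits}}).
#' @param map Genetic-map data.frame (\code{\link{read_genetic_map}}).
#' @return data.frame \code{probe_id,scaffold,bp,strand,score,lg,cm}.
#' @export
merge_probes <- function(hits, map) {
  sp <- split(seq_len(nrow(hits)), hits$probe_id)
  dropped <- 0L
  keep <- integer(0)
  for (i in sp) {
    best <- i[hits$score[i] == max(hits$score[i])]
    if (length(unique(hits$scaffold[best])) > 1) { dropped <- dropped + 1L; next }
    keep <- c(keep, best[1])
  }
  m <- hits[keep, , drop = FALSE]
  mi <- match(m$probe_id, map$probe_id)
  m$lg <- map$lg[mi]
  m$cm <- map$cm[mi]
  m <- m[!is.na(m$lg), , drop = FALSE]
  m <- m[order(m$scaffold, m$bp), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "n_dropped_ties") <- dropped
  m
}

#' Assign scaffolds to linkage groups
#'
#' Single-LG scaffolds are assigned; scaffolds with probes from two or more
#' LGs are flagged as chimera candidates; scaffolds without probes go to
#' LG0.
#'
#' @param probes Merged probe data.frame (\code{\link{merge_probes}}).
#' @param scaffold_names Optional full scaffold-name vector so probe-less
#'   scaffolds can be reported as LG0.
#' @return data.frame \code{scaffold,lg,n_probes,n_lgs,chimera}.
#' @export
assign_scaffolds <- function(probes, scaffold_names = NULL) {
  sp <- split(seq_len(nrow(probes)), probes$scaffold)
  rows <- lapply(names(sp), function(sc) {
    i <- sp[[sc]]
    lgs <- unique(probes$lg[i])
    data.frame(scaffold = sc,
               lg = if (length(lgs) == 1) lgs else NA_character_,
               n_probes = length(i), n_lgs = length(lgs),
               chimera = length(lgs) > 1, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(scaffold_names)) {
    missing <- setdiff(scaffold_names, res$scaffold)
    if (length(missing))
      res <- rbind(res, data.frame(scaffold = missing, lg = "LG0",
                                   n_probes = 0L, n_lgs = 0L, chimera = FALSE,
                                   stringsAsFactors = FALSE))
  }
  res <- res[order(res$scaffold), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Break chimeric scaffolds at the midpoint between LG probe blocks
#'
#' For each flagged scaffold the per-LG probe bp ranges must form
#' non-overlapping blocks along the scaffold; the cut falls at the midpoint
#' between the last probe of one block and the first probe of the next
#' ("most distantly mapped probes from each LG as break sites").  Pieces
#' are renamed \code{scaffold.1, scaffold.2, ...} and re-assigned to their
#' block's LG.  Scaffolds with overlapping LG blocks are left unbroken and
#' reported as unresolvable.
#'
#' @param assignments Output of \code{\link{assign_scaffolds}}.
#' @param probes Merged probe data.frame.
#' @param scaffolds Optional named sequence vector; when given, piece
#'   sequences are emitted and every input base is conserved.
#' @param scaffold_lengths Optional named lengths (required if
#'   \code{scaffolds} is absent and pieces must span to scaffold ends).
#' @return list with updated \code{assignments}, \code{probes},
#'   \code{scaffolds}, plus \code{breaks} (scaffold, cut position) and
#'   \code{unresolved} (scaffold names).
#' @export
break_chimeras <- function(assignments, probes, scaffolds = NULL,
                           scaffold_lengths = NULL) {
  if (is.null(scaffold_lengths) && !is.null(scaffolds))
    scaffold_lengths <- nchar(scaffolds)
  flagged <- assignments$scaffold[assignments$chimera]
  breaks <- list(); unresolved <- character(0)
  for (sc in flagged) {
    pi <- probes$scaffold == sc
    pr <- probes[pi, , drop = FALSE]
    rng <- do.call(rbind, lapply(split(pr$bp, pr$lg), range))
    rng <- rng[order(rng[, 1]), , drop = FALSE]
    if (any(rng[-1, 1] <= rng[-nrow(rng), 2])) {
      warning("scaffold ", sc, ": LG probe blocks overlap; left unbroken")
      unresolved <- c(unresolved, sc)
      next
    }
    cuts <- floor((rng[-nrow(rng), 2] + rng[-1, 1]) / 2)
    L <- if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths))
      scaffold_lengths[[sc]] else max(pr$bp) + 1
    edges <- c(0, cuts, L)
    for (k in seq_len(length(edges) - 1)) {
      piece <- paste0(sc, ".", k)
      a <- edges[k]; z <- edges[k + 1]
      sel <- which(pi & probes$bp >= a & probes$bp < z)
      probes$scaffold[sel] <- piece
      probes$bp[sel] <- probes$bp[sel] - a
      if (!is.null(scaffolds)) {
        scaffolds[piece] <- substr(scaffolds[[sc]], a + 1, z)
      }
    }
    if (!is.null(scaffolds)) scaffolds <- scaffolds[names(scaffolds) != sc]
    breaks[[sc]] <- data.frame(scaffold = sc, cut = cuts,
                               stringsAsFactors = FALSE)
  }
  probes <- probes[order(probes$scaffold, probes$bp), , drop = FALSE]
  rownames(probes) <- NULL
  all_names <- if (!is.null(scaffolds)) names(scaffolds) else
    unique(c(assignments$scaffold[!assignments$scaffold %in% flagged |
                                    assignments$scaffold %in% unresolved],
             unique(probes$scaffold)))
  new_assign <- assign_scaffolds(probes, scaffold_names = all_names)
  list(assignments = new_assign, probes = probes, scaffolds = scaffolds,
       breaks = if (length(breaks)) do.call(rbind, breaks) else
         data.frame(scaffold = character(0), cut = numeric(0)),
       unresolved = unresolved)
}

#' Order and orient scaffolds within each linkage group
#'
#' Scaffolds are sorted by the median centimorgan position of their probes;
#' orientation is the sign of the Spearman rank correlation between bp and
#' cM ('+' when non-negative).  Scaffolds with fewer than two distinct
#' probe positions are oriented '+' and flagged orientation-unknown.
#'
#' @param assignments Output of \code{\link{assign_scaffolds}} (chimeras
#'   already broken).
#' @param probes Merged probe data.frame.
#' @return data.frame \code{lg,position,scaffold,orientation,
#'   orientation_known,median_cm,n_probes} ordered within LG.
#' @export
order_and_orient <- function(assignments, probes) {
  a <- assignments[!is.na(assignments$lg) & assignments$lg != "LG0", ,
                   drop = FALSE]
  rows <- lapply(seq_len(nrow(a)), function(i) {
    pr <- probes[probes$scaffold == a$scaffold[i], , drop = FALSE]
    known <- length(unique(pr$bp)) >= 2 && length(unique(pr$cm)) >= 2
    rho <- if (known)
      suppressWarnings(stats::cor(pr$bp, pr$cm, method = "spearman")) else NA
    ori <- if (!known || is.na(rho) || rho == 0) "+" else
      if (rho > 0) "+" else "-"
    data.frame(lg = a$lg[i], scaffold = a$scaffold[i], orientation = ori,
               orientation_known = known && !is.na(rho) && rho != 0,
               median_cm = stats::median(pr$cm), n_probes = nrow(pr),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$lg, res$median_cm, res$scaffold), , drop = FALSE]
  res$position <- stats::ave(seq_len(nrow(res)), res$lg, FUN = seq_along)
  rownames(res) <- NULL
  res[, c("lg", "position", "scaffold", "orientation", "orientation_known",
          "median_cm", "n_probes")]
}

#' Build linkage-group sequences with 100-N gaps, plus AGP rows
#'
#' '-' scaffolds are reverse-complemented; neighbours are joined by exactly
#' \code{gap} N characters.  The AGP (2.1 conventions: W rows for
#' scaffolds, U rows for gaps, 1-based coordinates) reconstructs the FASTA
#' exactly.
#'
#' @param order_df Output of \code{\link{order_and_orient}}.
#' @param scaffolds Named sequence vector holding every listed scaffold.
#' @param gap Gap length in bp (default 100).
#' @return list with \code{sequences} (named vector, one per LG) and
#'   \code{agp} (data.frame).
#' @export
build_lg_sequences <- function(order_df, scaffolds, gap = 100) {
  missing <- setdiff(order_df$scaffold, names(scaffolds))
  if (length(missing))
    stop("scaffold absent from sequence set: ", missing[1])
  seqs <- character(0); agp <- list()
  for (lg in unique(order_df$lg)) {
    o <- order_df[order_df$lg == lg, , drop = FALSE]
    o <- o[order(o$position), , drop = FALSE]
    parts <- character(0); pos <- 0; pn <- 0
    for (i in seq_len(nrow(o))) {
      if (i > 1) {
        pn <- pn + 1
        agp[[length(agp) + 1]] <- data.frame(
          object = lg, object_beg = pos + 1, object_end = pos + gap,
          part_number = pn, component_type = "U", component_id = as.character(gap),
          component_beg = NA, component_end = NA, orientation = "scaffold",
          stringsAsFactors = FALSE)
        parts <- c(parts, strrep("N", gap)); pos <- pos + gap
      }
      s <- scaffolds[[o$scaffold[i]]]
      if (o$orientation[i] == "-") s <- revcomp(s)
      L <- nchar(s); pn <- pn + 1
      agp[[length(agp) + 1]] <- data.frame(
        object = lg, object_beg = pos + 1, object_end = pos + L,
        part_number = pn, component_type = "W", component_id = o$scaffold[i],
        component_beg = 1, component_end = L, orientation = o$orientation[i],
        stringsAsFactors = FALSE)
      parts <- c(parts, s); pos <- pos + L
    }
    seqs[lg] <- paste(parts, collapse = "")
  }
  list(sequences = seqs, agp = do.call(rbind, agp))
}

#' Marey table: genetic vs physical position on the built linkage groups
#'
#' Relocates each probe onto its built LG coordinate (scaffold offset plus
#' strand-adjusted position) and reports, per LG, the fraction of adjacent
#' probe pairs whose cM order is concordant with bp order (1.0 = perfectly
#' monotone map).
#'
#' @param order_df Output of \code{\link{order_and_orient}}.
#' @param probes Merged probe data.frame.
#' @param scaffold_lengths Named vector of scaffold lengths.
#' @param gap Gap length used in the build (default 100).
#' @return list with \code{table} (\code{lg,bp_on_lg,cm,probe_id}, sorted
#'   by bp) and \code{monotonicity} (\code{lg,score}).
#' @export
marey_table <- function(order_df, probes, scaffold_lengths, gap = 100) {
  tab <- list()
  for (lg in unique(order_df$lg)) {
    o <- order_df[order_df$lg == lg, , drop = FALSE]
    o <- o[order(o$position), , drop = FALSE]
    offset <- 0
    for (i in seq_len(nrow(o))) {
      sc <- o$scaffold[i]
      L <- scaffold_lengths[[sc]]
      pr <- probes[probes$scaffold == sc, , drop = FALSE]
      if (nrow(pr)) {
        bp_lg <- if (o$orientation[i] == "+") offset + pr$bp
                 else offset + (L - 1 - pr$bp)
        tab[[length(tab) + 1]] <- data.frame(
          lg = lg, bp_on_lg = bp_lg, cm = pr$cm, probe_id = pr$probe_id,
          stringsAsFactors = FALSE)
      }
      offset <- offset + L + gap
    }
  }
  if (!length(tab))
    return(list(table = data.frame(lg = character(0), bp_on_lg = numeric(0),
                                   cm = numeric(0), probe_id = character(0)),
                monotonicity = data.frame(lg = character(0), score = numeric(0))))
  tt <- do.call(rbind, tab)
  tt <- tt[order(tt$lg, tt$bp_on_lg), , drop = FALSE]
  rownames(tt) <- NULL
  mono <- do.call(rbind, lapply(split(tt, tt$lg), function(d) {
    if (nrow(d) < 2) return(data.frame(lg = d$lg[1], score = 1))
    dc <- diff(d$cm)
    data.frame(lg = d$lg[1], score = mean(dc >= 0), stringsAsFactors = FALSE)
  }))
  rownames(mono) <- NULL
  list(table = tt, monotonicity = mono)
}
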