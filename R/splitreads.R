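# Split-read introgression detector: reads that align fully to the focal
# assembly but split, without overlap on the read, between the two donor
# references mark putative introgression-block boundaries.

#' Drop alignments near scaffold ends
#'
#' Removes records whose target interval is not entirely within
#' \code{[trim_bp, scaffold_length - trim_bp)}, suppressing false positives
#' from reads that merely span the end of one reference scaffold and the
#' start of another.  Scaffolds shorter than \code{2 * trim_bp} contribute
#' nothing.
#'
#' @param records Alignment data.frame (see \code{\link{read_paf}}).
#' @param trim_bp Trim distance in bp (default 10000).
#' @param scaffold_lengths Optional named length vector; defaults to the
#'   records' PAF \code{target_len} column.
#' @return Filtered alignment data.frame.
#' @export
trim_scaffold_ends <- function(records, trim_bp = 10000,
                               scaffold_lengths = NULL) {
  if (nrow(records) == 0) return(records)
  if (is.null(scaffold_lengths)) {
    len <- records$target_len
  } else {
    unknown <- setdiff(unique(records$target), names(scaffold_lengths))
    if (length(unknown))
      stop("record names unknown scaffold: ", unknown[1])
    len <- unname(scaffold_lengths[records$target])
  }
  keep <- records$target_start >= trim_bp & records$target_end <= len - trim_bp
  records[keep, , drop = FALSE]
}

# total read-coordinate length covered by a set of (possibly overlapping)
# [start,end) intervals
union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > ce) { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
    else ce <- max(ce, end[i])
  }
  tot + (ce - cs)
}

#' Identify reads split cleanly between the two donor references
#'
#' A read qualifies when (i) its focal alignments cover at least
#' \code{min_focal_fraction} of the read, (ii) it has at least one donorA
#' and one donorB record (of at least \code{min_donor_len} aligned bp), and
#' (iii) no base of the read aligns to both donors (the donorA and donorB
#' read-coordinate spans are pairwise disjoint).
#'
#' @param focal_recs,donorA_recs,donorB_recs Trimmed alignment data.frames.
#' @param min_focal_fraction Fraction of the read the focal alignments must
#'   cover (default 0.95).
#' @param min_donor_len Minimum aligned read-span of a donor record in bp;
#'   shorter fragments are ignored as noise (default 200).
#' @param min_mapq Optional mapping-quality floor applied to all records
#'   (default 0, i.e. none).
#' @return Sorted character vector of qualifying read ids.
#' @export
classify_split_reads <- function(focal_recs, donorA_recs, donorB_recs,
                                 min_focal_fraction = 0.95,
                                 min_donor_len = 200, min_mapq = 0) {
  flt <- function(r) r[r$mapq >= min_mapq, , drop = FALSE]
  focal_recs <- flt(focal_recs)
  dlen_ok <- function(r) r[(r$read_end - r$read_start) >= min_donor_len, ,
                           drop = FALSE]
  donorA_recs <- dlen_ok(flt(donorA_recs))
  donorB_recs <- dlen_ok(flt(donorB_recs))
  if (nrow(focal_recs) == 0 || nrow(donorA_recs) == 0 ||
      nrow(donorB_recs) == 0) return(character(0))

  cov <- vapply(split(seq_len(nrow(focal_recs)), focal_recs$read_id),
                function(i) union_length(focal_recs$read_start[i],
                                         focal_recs$read_end[i]) /
                  focal_recs$read_len[i[1]],
                numeric(1))
  full <- names(cov)[cov >= min_focal_fraction]
  cand <- intersect(full, intersect(unique(donorA_recs$read_id),
                                    unique(donorB_recs$read_id)))
  if (!length(cand)) return(character(0))
  ia <- split(seq_len(nrow(donorA_recs)), donorA_recs$read_id)
  ib <- split(seq_len(nrow(donorB_recs)), donorB_recs$read_id)
  ok <- vapply(cand, function(rd) {
    a <- donorA_recs[ia[[rd]], , drop = FALSE]
    b <- donorB_recs[ib[[rd]], , drop = FALSE]
    # any overlap between an A span and a B span disqualifies the read
    !any(outer(a$read_start, b$read_end, `<`) &
           outer(a$read_end, b$read_start, `>`))
  }, logical(1))
  sort(cand[ok])
}

#' Call putatively introgressed intervals from split reads
#'
#' Bins the focal-assembly coverage of the split reads into 1 kb intervals
#' and merges adjacent occupied bins.  Every merged interval holding at
#' least one split read is a candidate; intervals whose best bin holds at
#' least \code{min_reads_per_interval} split reads, outside the excluded
#' linkage groups, are reported (the candidate/reported funnel).  When donor
#' records are supplied, each reported interval is paired with the donor
#' interval sharing the highest read-name intersection (ties broken by
#' coordinate, first wins).
#'
#' @param split_reads Read ids from \code{\link{classify_split_reads}}.
#' @param focal_recs Trimmed focal alignments (all reads; the split subset
#'   is selected internally).
#' @param donorA_recs,donorB_recs Optional trimmed donor alignments for
#'   partner-interval pairing.
#' @param bin Bin width in bp (default 1000).
#' @param min_count Merge threshold for the all-read coverage context
#'   (default 30, roughly the mean read coverage); reported intervals are
#'   annotated with whether they fall in such a high-coverage block.
#' @param min_reads_per_interval Reporting threshold on split reads per bin
#'   (default 10).
#' @param exclude Linkage groups excluded from reporting (default
#'   \code{"LG0"}, unplaced scaffolds).
#' @param lg_map Optional named vector scaffold -> linkage group; defaults
#'   to the scaffold name itself.
#' @return list with \code{candidates} and \code{reported} interval
#'   data.frames (class \code{split_read_calls}).
#' @export
call_intervals <- function(split_reads, focal_recs,
                           donorA_recs = NULL, donorB_recs = NULL,
                           bin = 1000, min_count = 30,
                           min_reads_per_interval = 10,
                           exclude = "LG0", lg_map = NULL) {
  lg_of <- function(sq) {
    if (is.null(lg_map)) sq
    else ifelse(sq %in% names(lg_map), unname(lg_map[sq]), sq)
  }
  empty <- data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), n_reads = integer(0),
                      linkage_group = character(0))
  srec <- focal_recs[focal_recs$read_id %in% split_reads, , drop = FALSE]
  if (nrow(srec) == 0) {
    out <- list(candidates = empty, reported = empty)
    class(out) <- "split_read_calls"
    return(out)
  }
  cand <- merge_blocks(bin_coverage(srec, bin), min_count = 1)
  cand$linkage_group <- lg_of(cand$seqid)
  rep_sel <- cand$max_bin_count >= min_reads_per_interval &
    !(cand$linkage_group %in% exclude)
  reported <- cand[rep_sel, , drop = FALSE]

  # coverage context from all reads at the 30x merge threshold
  highcov <- merge_blocks(bin_coverage(focal_recs, bin), min_count = min_count)
  if (nrow(reported)) {
    reported$in_high_coverage <- vapply(seq_len(nrow(reported)), function(i) {
      any(highcov$seqid == reported$seqid[i] &
            highcov$start < reported$end[i] &
            highcov$end > reported$start[i])
    }, logical(1))
  }
  for (side in c("A", "B")) {
    drecs <- if (side == "A") donorA_recs else donorB_recs
    if (is.null(drecs) || !nrow(reported)) next
    dsplit <- drecs[drecs$read_id %in% split_reads, , drop = FALSE]
    dblocks <- merge_blocks(bin_coverage(dsplit, bin), min_count = 1)
    pcol <- paste0("partner_donor", side)
    ncol_ <- paste0("n_shared_donor", side)
    reported[[pcol]] <- NA_character_
    reported[[ncol_]] <- 0L
    if (!nrow(dblocks)) next
    dblocks <- dblocks[order(dblocks$seqid, dblocks$start), , drop = FALSE]
    for (i in seq_len(nrow(reported))) {
      shared <- vapply(dblocks$read_names, function(rn)
        length(intersect(rn, reported$read_names[[i]])), integer(1))
      j <- which.max(shared)   # ties: first by coordinate
      if (shared[j] > 0) {
        reported[[pcol]][i] <- sprintf("%s:%d-%d", dblocks$seqid[j],
                                       dblocks$start[j], dblocks$end[j])
        reported[[ncol_]][i] <- shared[j]
      }
    }
  }
  rownames(cand) <- rownames(reported) <- NULL
  out <- list(candidates = cand, reported = reported)
  class(out) <- "split_read_calls"
  out
}

#' @export
print.split_read_calls <- function(x, ...) {
  cat("split-read calls:", nrow(x$candidates), "candidate interval(s),",
      nrow(x$reported), "reported\n")
  invisible(x)
}

#' Rank linkage groups by split-read interval burden
#'
#' @param calls Reported-interval data.frame (or a \code{split_read_calls}
#'   object, whose \code{$reported} is used).
#' @return data.frame \code{(linkage_group, n_intervals, n_reads,
#'   combined_bp)} sorted by interval count, then combined length, then
#'   name.
#' @export
rank_groups <- function(calls) {
  if (inherits(calls, "split_read_calls")) calls <- calls$reported
  if (nrow(calls) == 0)
    return(data.frame(linkage_group = character(0), n_intervals = integer(0),
                      n_reads = integer(0), combined_bp = integer(0)))
  sp <- split(seq_len(nrow(calls)), calls$linkage_group)
  res <- do.call(rbind, lapply(names(sp), function(lg) {
    i <- sp[[lg]]
    rn <- if (!is.null(calls$read_names)) unique(unlist(calls$read_names[i]))
          else NULL
    data.frame(linkage_group = lg, n_intervals = length(i),
               n_reads = if (is.null(rn)) sum(calls$n_reads[i])
                         else length(rn),
               combined_bp = as.integer(sum(calls$end[i] - calls$start[i])),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$n_intervals, -res$combined_bp, res$linkage_group), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
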