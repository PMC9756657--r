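# Interval algebra shared by the detectors: 1 kb coverage binning with
# read-name sets, threshold merging, length accounting, gene intersection.

#' Bin alignment coverage into fixed-width bins with read-name sets
#'
#' Each bin records the set of distinct reads whose target interval overlaps
#' it; bins tile each scaffold from 0 and the final partial bin is kept.
#'
#' @param records Alignment records on a single reference
#'   (see \code{\link{read_paf}}).
#' @param bin_size Bin width in bp (default 1000).
#' @param scaffold_lengths Optional named vector of scaffold lengths; when
#'   given, bins tile the full scaffold even past the last alignment.
#' @return data.frame of bins: \code{seqid,start,end,count} with a
#'   \code{read_names} list-column; only bins with \code{count > 0} are
#'   returned unless \code{scaffold_lengths} is supplied.
#' @export
bin_coverage <- function(records, bin_size = 1000, scaffold_lengths = NULL) {
  stopifnot(bin_size >= 1)
  if (nrow(records) == 0)
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), count = integer(0)))
  out <- list()
  for (sq in sort(unique(records$target))) {
    r <- records[records$target == sq, , drop = FALSE]
    max_end <- if (!is.null(scaffold_lengths) && sq %in% names(scaffold_lengths))
      scaffold_lengths[[sq]] else max(r$target_end)
    n_bins <- ceiling(max_end / bin_size)
    # bin indices overlapped by each record (half-open overlap)
    first <- r$target_start %/% bin_size
    last <- (r$target_end - 1L) %/% bin_size
    idx <- rep.int(seq_len(nrow(r)), last - first + 1L)
    bins <- unlist(mapply(seq, first, last, SIMPLIFY = FALSE)) # 0-based bin no.
    sets <- split(r$read_id[idx], bins)
    sets <- lapply(sets, unique)
    bno <- as.integer(names(sets))
    df <- data.frame(seqid = sq, start = bno * bin_size,
                     end = pmin((bno + 1L) * bin_size, max_end),
                     count = lengths(sets), stringsAsFactors = FALSE)
    df$read_names <- unname(sets)
    if (!is.null(scaffold_lengths) && sq %in% names(scaffold_lengths)) {
      all_b <- 0:(n_bins - 1L)
      miss <- setdiff(all_b, bno)
      if (length(miss)) {
        mdf <- data.frame(seqid = sq, start = miss * bin_size,
                          end = pmin((miss + 1L) * bin_size, max_end),
                          count = 0L, stringsAsFactors = FALSE)
        mdf$read_names <- rep(list(character(0)), length(miss))
        df <- rbind(df, mdf)
      }
    }
    out[[sq]] <- df[order(df$start), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge runs of qualifying coverage bins into blocks
#'
#' Maximal runs of adjacent bins holding at least \code{min_count} distinct
#' reads become one block carrying the union read-name set, mirroring the
#' merge of contiguous 1 kb intervals at the mean read coverage (30x).
#'
#' @param bins Output of \code{\link{bin_coverage}} (sorted).
#' @param min_count Minimum distinct reads per bin (default 30).
#' @return data.frame of blocks: \code{seqid,start,end,n_reads,mean_coverage,
#'   max_bin_count} with a \code{read_names} list-column.
#' @export
merge_blocks <- function(bins, min_count = 30) {
  keep <- bins[bins$count >= min_count, , drop = FALSE]
  if (nrow(keep) == 0)
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), n_reads = integer(0),
                      mean_coverage = numeric(0), max_bin_count = integer(0)))
  keep <- keep[order(keep$seqid, keep$start), , drop = FALSE]
  new_run <- c(TRUE, keep$seqid[-1] != keep$seqid[-nrow(keep)] |
                 keep$start[-1] != keep$end[-nrow(keep)])
  run <- cumsum(new_run)
  blocks <- lapply(split(seq_len(nrow(keep)), run), function(i) {
    rn <- unique(unlist(keep$read_names[i]))
    data.frame(seqid = keep$seqid[i[1]], start = keep$start[i[1]],
               end = keep$end[i[length(i)]], n_reads = length(rn),
               mean_coverage = mean(keep$count[i]),
               max_bin_count = max(keep$count[i]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, blocks)
  res$read_names <- lapply(split(seq_len(nrow(keep)), run),
                           function(i) unique(unlist(keep$read_names[i])))
  rownames(res) <- NULL
  res
}

#' Combined block length per sequence
#'
#' Per-seqid sum of block lengths, sorted descending, used to rank linkage
#' groups by how much sequence shows read splitting.
#'
#' @param blocks data.frame with \code{seqid,start,end}.
#' @param group_by Column to aggregate over (default \code{"seqid"}).
#' @return data.frame \code{(seqid,total_bp)} sorted by descending total.
#' @export
combined_length <- function(blocks, group_by = "seqid") {
  if (nrow(blocks) == 0)
    return(data.frame(seqid = character(0), total_bp = integer(0)))
  tot <- tapply(blocks$end - blocks$start, blocks[[group_by]], sum)
  res <- data.frame(seqid = names(tot), total_bp = as.integer(tot),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$total_bp, res$seqid), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Intersect regions with gene features
#'
#' Reports every (region, gene) pair sharing at least 1 bp, with
#' \code{bedtools intersect -wa -wb} semantics: a gene overlapping two
#' regions appears twice.  Overlap detection uses \pkg{GenomicRanges}.
#'
#' @param regions data.frame with \code{seqid,start,end} (0-based half-open).
#' @param genes data.frame of gene features (see \code{\link{read_gff3}}).
#' @return data.frame with region coordinates, \code{gene_id} and gene
#'   coordinates, one row per overlapping pair.
#' @export
intersect_genes <- function(regions, genes) {
  empty <- data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      gene_start = integer(0), gene_end = integer(0))
  if (nrow(regions) == 0 || nrow(genes) == 0) return(empty)
  rg <- GenomicRanges::GRanges(regions$seqid,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  gg <- GenomicRanges::GRanges(genes$seqid,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(rg, gg)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  res <- data.frame(seqid = regions$seqid[qi], start = regions$start[qi],
                    end = regions$end[qi], gene_id = genes$gene_id[si],
                    gene_start = genes$start[si], gene_end = genes$end[si],
                    stringsAsFactors = FALSE)
  res[order(res$seqid, res$start, res$gene_start), , drop = FALSE]
}
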