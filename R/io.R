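# Internal coordinate convention: 0-based half-open everywhere.  GFF3 (1-based
# closed) and VCF (1-based positions) are converted/flagged at the I/O boundary
# and nowhere else.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a named sequence vector
#'
#' Sequences are uppercased and validated against the \code{A/C/G/T/N}
#' alphabet; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (a "sequence set").
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  validate_sequence_set(seqs, path)
  seqs
}

validate_sequence_set <- function(seqs, context = "sequence set") {
  if (length(seqs) == 0) stop("empty sequence set: ", context)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence name(s) in ", context, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(!nzchar(seqs))) {
    bad <- names(seqs)[!nzchar(seqs)]
    stop("empty sequence(s) in ", context, ": ", paste(bad, collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(DNA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non-ACGTN characters in ", context, " record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  invisible(seqs)
}

#' Write a named sequence vector to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  validate_sequence_set(seqs, "write_fasta input")
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Reverse-complement sequences
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

PAF_COLS <- c("read_id", "read_len", "read_start", "read_end", "strand",
              "target", "target_len", "target_start", "target_end",
              "n_match", "block_len", "mapq")

#' Read a PAF alignment file
#'
#' Consumes minimap2-dialect PAF (columns 1-12; extra tag columns ignored).
#' Coordinates are kept 0-based half-open, as in PAF itself.
#'
#' @param path Path to a PAF file.
#' @param ref_label Label for the reference the alignments target, one of
#'   \code{"focal"}, \code{"donorA"}, \code{"donorB"} (free-form allowed).
#' @return data.frame of alignment records with an added \code{ref_label}
#'   column.
#' @export
read_paf <- function(path, ref_label) {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments(ref_label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("PAF line ", which(nf < 12)[1], " has ", nf[nf < 12][1],
         " columns; at least 12 required")
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  int_cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  ints <- suppressWarnings(apply(m[, int_cols, drop = FALSE], 2, as.integer))
  if (length(lines) == 1) ints <- matrix(ints, nrow = 1)
  if (anyNA(ints)) {
    bad <- which(apply(ints, 1, anyNA))[1]
    stop("PAF line ", bad, ": non-integer coordinate field")
  }
  rec <- data.frame(
    read_id = m[, 1], read_len = ints[, 1],
    read_start = ints[, 2], read_end = ints[, 3],
    strand = m[, 5], target = m[, 6], target_len = ints[, 4],
    target_start = ints[, 5], target_end = ints[, 6],
    n_match = ints[, 7], block_len = ints[, 8], mapq = ints[, 9],
    ref_label = ref_label, stringsAsFactors = FALSE
  )
  validate_alignments(rec)
  rec
}

empty_alignments <- function(ref_label = character(0)) {
  data.frame(read_id = character(0), read_len = integer(0),
             read_start = integer(0), read_end = integer(0),
             strand = character(0), target = character(0),
             target_len = integer(0), target_start = integer(0),
             target_end = integer(0), n_match = integer(0),
             block_len = integer(0), mapq = integer(0),
             ref_label = character(0), stringsAsFactors = FALSE)
}

validate_alignments <- function(rec) {
  bad <- which(!(rec$read_start >= 0 & rec$read_start < rec$read_end &
                   rec$read_end <= rec$read_len))
  if (length(bad))
    stop("alignment record ", bad[1], " (read ", rec$read_id[bad[1]],
         "): read coordinates violate 0 <= start < end <= read_len")
  bad <- which(!(rec$target_start >= 0 & rec$target_start < rec$target_end))
  if (length(bad))
    stop("alignment record ", bad[1], " (read ", rec$read_id[bad[1]],
         "): target coordinates violate 0 <= start < end")
  if (any(!rec$strand %in% c("+", "-")))
    stop("alignment strand must be '+' or '-'")
  invisible(rec)
}

#' Write alignment records as PAF
#' @param rec data.frame of alignment records (see \code{\link{read_paf}}).
#' @param path Output path.
#' @export
write_paf <- function(rec, path) {
  m <- rec[, PAF_COLS]
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file
#'
#' BED is already 0-based half-open and is passed through unchanged.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns \code{seqid,start,end} plus any extra
#'   columns present (\code{name,score,strand}).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  if (ncol(df) < 3) stop("BED file has fewer than 3 columns: ", path)
  names(df)[1:3] <- c("seqid", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  if (any(df$start >= df$end))
    stop("BED interval with start >= end at line ",
         which(df$start >= df$end)[1])
  df
}

#' Write intervals as BED
#' @param intervals data.frame with columns \code{seqid,start,end} (+ extras).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention at parse time.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Optional character vector restricting returned rows
#'   (e.g. \code{"gene"}); \code{NULL} keeps everything.
#' @return data.frame with \code{seqid,start,end,strand,feature_type,gene_id,
#'   confidence}.
#' @export
read_gff3 <- function(path, feature_types = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  gene_id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  if ("gene_id" %in% names(md)) {
    gid2 <- as.character(md$gene_id)
    gene_id <- ifelse(is.na(gene_id) | !nzchar(gene_id), gid2, gene_id)
  }
  conf <- if ("confidence" %in% names(md)) as.character(md$confidence)
          else NA_character_
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(md$type),
    gene_id = gene_id,
    confidence = conf,
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start))
    stop("GFF3 feature with non-positive length after conversion, row ",
         which(df$end <= df$start)[1])
  if (!is.null(feature_types)) df <- df[df$feature_type %in% feature_types, ]
  g <- df$feature_type == "gene"
  if (any(g & (is.na(df$gene_id) | !nzchar(df$gene_id))))
    stop("gene feature without a gene_id/ID attribute")
  rownames(df) <- NULL
  df
}

#' Read biallelic genotypes from VCF
#'
#' Loads SNP and indel records with total depth (INFO/DP), flags indels and
#' non-biallelic sites, computes each SNP's distance to the nearest indel,
#' and attaches population labels.  Sites failing filters are flagged, not
#' dropped; filtering is a separate documented stage
#' (\code{\link{filter_sites}}).
#'
#' @param path Path to a VCF 4.x file with GT fields.
#' @param sample_populations Named character vector mapping every sample in
#'   the file to a population label.
#' @return A \code{genotype_matrix}: list with \code{sites} (data.frame),
#'   \code{geno} (sites x samples integer matrix, codes 0/1/2, NA missing)
#'   and \code{samples} (data.frame of sample_id, population).
#' @export
read_vcf <- function(path, sample_populations) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  missing_pop <- setdiff(samples, names(sample_populations))
  if (length(missing_pop))
    stop("sample(s) without a population label: ",
         paste(missing_pop, collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, samples))
  geno <- gt_to_codes(gt)
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, element = "DP")))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  biallelic <- !grepl(",", alt, fixed = TRUE) & nzchar(alt)
  alt1 <- sub(",.*$", "", alt)
  is_indel <- nchar(ref) != 1L | (nzchar(alt1) & nchar(alt1) != 1L) |
    grepl(",", alt, fixed = TRUE) &
      vapply(strsplit(alt, ",", fixed = TRUE),
             function(a) any(nchar(a) != 1L), logical(1))
  sites <- data.frame(
    seqid = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref_allele = ref, alt_allele = alt,
    total_depth = dp,
    is_indel = is_indel,
    biallelic = biallelic,
    stringsAsFactors = FALSE
  )
  o <- order(sites$seqid, sites$pos)
  sites <- sites[o, , drop = FALSE]
  geno <- geno[o, , drop = FALSE]
  sites$dist_indel <- distance_to_nearest_indel(sites)
  rownames(sites) <- NULL
  gm <- list(
    sites = sites,
    geno = geno,
    samples = data.frame(sample_id = samples,
                         population = unname(sample_populations[samples]),
                         stringsAsFactors = FALSE)
  )
  class(gm) <- "genotype_matrix"
  gm
}

gt_to_codes <- function(gt) {
  code1 <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  m <- apply(gt, 2, code1)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = dimnames(gt))
  m
}

# bp gap between each site and the nearest indel record on the same seqid;
# 0 when overlapping an indel's REF span, NA when no indel on the seqid.
distance_to_nearest_indel <- function(sites) {
  out <- rep(NA_real_, nrow(sites))
  for (sq in unique(sites$seqid)) {
    i <- which(sites$seqid == sq)
    ind <- i[sites$is_indel[i]]
    if (!length(ind)) next
    istart <- sites$pos[ind]
    iend <- sites$pos[ind] + nchar(sites$ref_allele[ind]) - 1L
    for (j in i) {
      p <- sites$pos[j]
      d <- pmax(0L, pmax(istart - p, p - iend))
      d <- d[!(sites$is_indel[j] & ind == j)]  # an indel isn't near itself
      out[j] <- if (length(d)) min(d) else NA_real_
    }
  }
  out
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits CHROM/POS/REF/ALT, INFO DP and per-sample GT; the inverse of
#' \code{\link{read_vcf}} for synthetic data.
#'
#' @param gm A \code{genotype_matrix}.
#' @param path Output path.
#' @export
write_vcf <- function(gm, path) {
  s <- gm$sites
  gt_chr <- matrix("./.", nrow(s), nrow(gm$samples))
  gt_chr[!is.na(gm$geno)] <- c("0/0", "0/1", "1/1")[gm$geno[!is.na(gm$geno)] + 1L]
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total Depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples$sample_id), collapse = "\t"))
  body <- paste(s$seqid, s$pos, ".", s$ref_allele, s$alt_allele, ".", "PASS",
                paste0("DP=", s$total_depth), "GT",
                apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read per-window trees from TSV
#'
#' @param path TSV with header columns \code{seqid,start,end,newick}.
#' @param groups Optional taxon-group list (\code{\link{taxon_groups}}); when
#'   given, every tip of every tree must belong to a group.
#' @return list with \code{windows} (data.frame, sorted) and \code{trees}
#'   (list of \code{ape::phylo}).
#' @export
read_window_trees <- function(path, groups = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("seqid", "start", "end", "newick")
  if (!all(req %in% names(df)))
    stop("window-tree TSV must have columns: ", paste(req, collapse = ", "))
  if (any(df$start >= df$end))
    stop("window with start >= end at ",
         df$seqid[df$start >= df$end][1], ":",
         df$start[df$start >= df$end][1])
  o <- order(df$seqid, df$start)
  df <- df[o, , drop = FALSE]
  trees <- lapply(seq_len(nrow(df)), function(i) {
    tr <- tryCatch(ape::read.tree(text = df$newick[i]), error = function(e) NULL)
    if (is.null(tr))
      stop("unparseable newick in window ", df$seqid[i], ":", df$start[i],
           "-", df$end[i])
    tr
  })
  if (!is.null(groups)) {
    all_tips <- unlist(groups, use.names = FALSE)
    for (i in seq_along(trees)) {
      stray <- setdiff(trees[[i]]$tip.label, all_tips)
      if (length(stray))
        stop("tip '", stray[1], "' in window ", df$seqid[i], ":", df$start[i],
             " belongs to no taxon group")
    }
  }
  list(windows = df[, c("seqid", "start", "end")], trees = trees)
}

#' Write per-window trees to TSV
#' @param wt list with \code{windows} and \code{trees} as returned by
#'   \code{\link{read_window_trees}}.
#' @param path Output path.
#' @export
write_window_trees <- function(wt, path) {
  nwk <- vapply(wt$trees, function(tr) ape::write.tree(tr), character(1))
  df <- cbind(wt$windows, newick = nwk)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP-array probe hits (TSV)
#' @param path TSV with header \code{probe_id,scaffold,bp,strand,score}.
#' @return data.frame of probe hits, one row per alignment.
#' @export
read_probe_hits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("probe_id", "scaffold", "bp", "strand", "score")
  if (!all(req %in% names(df)))
    stop("probe-hit TSV must have columns: ", paste(req, collapse = ", "))
  df
}

#' Read a genetic map (TSV)
#' @param path TSV with header \code{probe_id,lg,cm}.
#' @return data.frame mapping probes to linkage group and centimorgan position.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("probe_id", "lg", "cm")
  if (!all(req %in% names(df)))
    stop("genetic-map TSV must have columns: ", paste(req, collapse = ", "))
  if (any(df$cm < 0)) stop("negative centimorgan position in genetic map")
  df
}
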