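# Synthetic-data module: ground-truthed fixtures with the statistical
# structure the detectors assume.  All generators are deterministic given
# params$seed (each consumes its own derived seed so stages are independent).

#' Default simulation parameters
#'
#' Returns the parameter list consumed by all \code{simulate_*} generators.
#' Defaults emulate the study conditions: a 1 Mb two-scaffold focal genome,
#' donor divergence of 2\%, admixture proportion \code{f = 0.1} in
#' exponential tracts (mean 20 kb), HiFi-like error-free 15 kb reads at 30x,
#' a five-population genotype panel with incomplete lineage sorting, and a
#' 22-linkage-group genetic map.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
sim_params <- function(...) {
  p <- list(
    seed = 1L,
    # genomes
    genome_length = 1e6, n_scaffolds = 2L, divergence = 0.02,
    f = 0.1, block_mean_length = 2e4, block_min_length = 2000,
    block_margin = 2.5e4,
    # reads
    read_length = 15000, read_length_sd = 1500, read_depth = 30,
    error_rate = 0,
    # genotypes
    n_sites = 20000L, geno_length = 2e5, n_per_pop = 2L,
    ils_rate = 0.1, mean_depth = 300,
    populations = c("focal", "niloticus", "aureus", "mossambicus", "urolepis"),
    # windows
    window_size = 200L, window_overlap = 40L,
    # genetic map
    n_lgs = 22L, scaffolds_per_lg = 4L, probes_per_scaffold = 10L,
    chimera_fraction = 0, map_scaffold_length = 10000, lg_cm_length = 100
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$f >= 0, p$f <= 1, p$ils_rate >= 0, p$ils_rate <= 1,
            p$genome_length > 0, p$read_length > 0)
  p
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at the given per-bp rate (Jukes-Cantor-like: uniform
# choice among the three alternatives)
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  pos <- which(stats::runif(n) < rate)
  if (!length(pos)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  subs <- vapply(chars[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                 character(1))
  chars[pos] <- subs
  paste(chars, collapse = "")
}

# Place non-overlapping tracts totalling ~ f * sum(lengths), exponential
# tract lengths, uniform placement with an end margin.
plant_blocks <- function(scaffold_lengths, f, mean_len, min_len, margin) {
  empty <- data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), donor = character(0))
  if (f <= 0) return(empty)
  if (f >= 1) {
    return(data.frame(seqid = names(scaffold_lengths), start = 0,
                      end = unname(scaffold_lengths), donor = "donorB",
                      stringsAsFactors = FALSE))
  }
  total <- sum(scaffold_lengths)
  target <- f * total
  if (target < min_len) {
    warning("f x genome_length smaller than the minimum tract length; ",
            "emitting a single tract of ", min_len, " bp")
    lens <- min_len
  } else {
    lens <- numeric(0)
    while (sum(lens) < target) {
      l <- max(min_len, round(stats::rexp(1, rate = 1 / mean_len)))
      lens <- c(lens, l)
    }
    over <- sum(lens) - target
    lens[length(lens)] <- max(min_len, round(lens[length(lens)] - over))
  }
  placed <- list()
  occ <- lapply(scaffold_lengths, function(x) empty[0, 1:3])
  for (l in lens) {
    usable <- pmax(0, scaffold_lengths - 2 * margin - l)
    if (all(usable <= 0)) next
    done <- FALSE
    for (try in 1:200) {
      sq <- sample(names(scaffold_lengths), 1, prob = usable / sum(usable))
      s <- floor(stats::runif(1, margin, scaffold_lengths[[sq]] - margin - l))
      e <- s + l
      prev <- occ[[sq]]
      if (nrow(prev) == 0 || all(e + 2000 <= prev$start | s >= prev$end + 2000)) {
        occ[[sq]] <- rbind(prev, data.frame(seqid = sq, start = s, end = e))
        placed[[length(placed) + 1]] <-
          data.frame(seqid = sq, start = s, end = e, donor = "donorB",
                     stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
    }
  }
  if (!length(placed)) return(empty)
  blocks <- do.call(rbind, placed)
  blocks <- blocks[order(blocks$seqid, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Simulate a focal genome and two donor references with planted tracts
#'
#' Two donor genomes diverge independently from a common ancestor at half
#' the stated pairwise divergence each.  The focal genome is a copy of
#' donorA in which tracts totalling approximately \code{f * genome_length}
#' (exponential lengths, uniform non-overlapping placement) are replaced by
#' the homologous donorB sequence.  Truth records tract coordinates.
#'
#' @param params Parameter list from \code{\link{sim_params}}.
#' @return list with \code{focal}, \code{donorA}, \code{donorB} (named
#'   sequence vectors) and \code{truth} (list with \code{$blocks}).
#' @export
simulate_genomes <- function(params = sim_params()) {
  set.seed(params$seed)
  n <- params$n_scaffolds
  lens <- rep(floor(params$genome_length / n), n)
  lens[n] <- params$genome_length - sum(lens[-n])
  names(lens) <- paste0("scaffold_", seq_len(n))
  ancestor <- vapply(lens, random_dna, character(1))
  donorA <- vapply(ancestor, mutate_seq, character(1), rate = params$divergence / 2)
  donorB <- vapply(ancestor, mutate_seq, character(1), rate = params$divergence / 2)
  names(donorA) <- names(donorB) <- names(lens)
  blocks <- plant_blocks(lens, params$f, params$block_mean_length,
                         params$block_min_length, params$block_margin)
  focal <- donorA
  if (nrow(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      sq <- blocks$seqid[i]
      substr(focal[[sq]], blocks$start[i] + 1, blocks$end[i]) <-
        substr(donorB[[sq]], blocks$start[i] + 1, blocks$end[i])
    }
  }
  list(focal = focal, donorA = donorA, donorB = donorB,
       truth = list(blocks = blocks, scaffold_lengths = lens))
}

#' Simulate HiFi-like reads from the focal genome
#'
#' Reads are sampled uniformly (start positions uniform per scaffold,
#' scaffold chosen proportional to length) with Gaussian lengths around
#' \code{read_length}, to the target fold coverage.  Error-free by default
#' (\code{error_rate} adds uniform substitutions).  Read names encode the
#' true origin interval and strand
#' (\code{read_000001|scaffold|start|end|strand}) for oracle checks.
#'
#' @param focal Named sequence vector (the focal genome).
#' @param params Parameter list from \code{\link{sim_params}}.
#' @return Named character vector of read sequences.
#' @export
simulate_reads <- function(focal, params = sim_params()) {
  stopifnot(length(focal) > 0)
  set.seed(params$seed + 1000L)
  lens <- nchar(focal)
  total <- sum(lens)
  n_reads <- round(params$read_depth * total / params$read_length)
  if (n_reads == 0) return(stats::setNames(character(0), character(0)))
  if (params$read_length > min(lens))
    warning("mean read length exceeds a scaffold length; reads truncated")
  sq <- sample(names(focal), n_reads, replace = TRUE, prob = lens / total)
  rl <- pmax(500, round(stats::rnorm(n_reads, params$read_length,
                                     params$read_length_sd)))
  rl <- pmin(rl, lens[sq])
  start <- floor(stats::runif(n_reads, 0, lens[sq] - rl + 1))
  end <- start + rl
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(focal[sq], start + 1, end)
  flip <- strand == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  if (params$error_rate > 0)
    seqs <- vapply(seqs, mutate_seq, character(1), rate = params$error_rate)
  names(seqs) <- sprintf("read_%06d|%s|%d|%d|%s", seq_len(n_reads), sq,
                         start, end, strand)
  seqs
}

parse_read_origin <- function(read_names) {
  parts <- strsplit(read_names, "|", fixed = TRUE)
  bad <- lengths(parts) != 5
  if (any(bad))
    stop("read with unknown origin encoding: ", read_names[bad][1])
  data.frame(
    read_id = read_names,
    seqid = vapply(parts, `[`, character(1), 2),
    start = as.numeric(vapply(parts, `[`, character(1), 3)),
    end = as.numeric(vapply(parts, `[`, character(1), 4)),
    strand = vapply(parts, `[`, character(1), 5),
    stringsAsFactors = FALSE
  )
}

#' Emulate read-to-reference alignments for the three references
#'
#' Each read receives one full-length focal record at its true origin.
#' Donor records follow the truth tracts: portions of the read inheriting
#' donorA ancestry align to donorA and tract portions align to donorB, at
#' the homologous coordinates, so reads spanning a tract boundary are
#' emitted as split, non-overlapping donor records.
#'
#' @param reads Named read vector from \code{\link{simulate_reads}}.
#' @param genomes Output of \code{\link{simulate_genomes}}.
#' @return list of three alignment data.frames: \code{focal}, \code{donorA},
#'   \code{donorB} (PAF-convention columns; see \code{\link{read_paf}}).
#' @export
simulate_alignments <- function(reads, genomes) {
  origin <- parse_read_origin(names(reads))
  blocks <- genomes$truth$blocks
  lens <- genomes$truth$scaffold_lengths
  rl <- origin$end - origin$start
  mk <- function(read_id, read_len, rs, re, strand, target, tlen, ts, te, label) {
    data.frame(read_id = read_id, read_len = as.integer(read_len),
               read_start = as.integer(rs), read_end = as.integer(re),
               strand = strand, target = target, target_len = as.integer(tlen),
               target_start = as.integer(ts), target_end = as.integer(te),
               n_match = as.integer(re - rs), block_len = as.integer(re - rs),
               mapq = 60L, ref_label = label, stringsAsFactors = FALSE)
  }
  focal <- mk(origin$read_id, rl, 0, rl, origin$strand, origin$seqid,
              lens[origin$seqid], origin$start, origin$end, "focal")
  donorA <- list(); donorB <- list()
  for (i in seq_len(nrow(origin))) {
    s <- origin$start[i]; e <- origin$end[i]; sq <- origin$seqid[i]
    b <- blocks[blocks$seqid == sq & blocks$end > s & blocks$start < e, ,
                drop = FALSE]
    # cut [s,e) at tract boundaries; label each piece by ancestry
    cuts <- sort(unique(c(s, e, pmax(s, b$start), pmin(e, b$end))))
    for (k in seq_len(length(cuts) - 1)) {
      a <- cuts[k]; z <- cuts[k + 1]
      inside <- nrow(b) > 0 && any(b$start <= a & b$end >= z)
      rs <- if (origin$strand[i] == "+") a - s else e - z
      re <- if (origin$strand[i] == "+") z - s else e - a
      rec <- mk(origin$read_id[i], rl[i], rs, re, origin$strand[i], sq,
                lens[[sq]], a, z, if (inside) "donorB" else "donorA")
      if (inside) donorB[[length(donorB) + 1]] <- rec
      else donorA[[length(donorA) + 1]] <- rec
    }
  }
  bind <- function(lst) if (length(lst)) do.call(rbind, lst) else empty_alignments()
  list(focal = focal, donorA = bind(donorA), donorB = bind(donorB))
}

# --- genotype simulation ----------------------------------------------------

# Rooted genealogies: the species topology, the donorB->focal introgression
# topology, and the 14 discordant alternatives.  Each is represented by its
# list of rooted clades (the possible derived-allele carriers) plus one
# mutation weight per clade edge.  Weights are proportional to
# coalescent-consistent branch lengths: under the species genealogy,
# lineages coalesce at the species splits (depths 1, 2, 3; root at 4);
# under the introgression genealogy the focal lineage sits in the donorB
# population and coalesces with it recently (depth 0.5), making the
# (focal,donorB) internal branch long.  Discordant ILS genealogies get
# uniform edge weights (they are symmetric in the focal/niloticus pair, so
# their lengths only add noise, not bias).
genealogy_clades <- function(populations) {
  topo <- enumerate_topologies(populations)
  p <- populations
  ckey <- function(x) paste(sort(x), collapse = ",")
  root_depth <- 4
  depth_maps <- list()
  depth_maps[[topo$species_key]] <- stats::setNames(
    c(1, 2, 3),
    c(ckey(p[1:2]), ckey(p[1:3]), ckey(p[1:4])))
  depth_maps[[introgression_key(topo, p)]] <- stats::setNames(
    c(0.5, 2, 3),
    c(ckey(p[c(1, 4)]), ckey(p[2:3]), ckey(p[1:4])))
  out <- lapply(seq_along(topo$trees), function(ti) {
    tr <- ape::root(topo$trees[[ti]], outgroup = p[length(p)],
                    resolve.root = TRUE)
    clades <- phylo_clades(tr)
    dm <- depth_maps[[topo$key[ti]]]
    if (is.null(dm)) {
      weights <- rep(1, length(clades))
    } else {
      depth_of <- function(cl) {
        if (length(cl) == 1) return(0)
        if (length(cl) == length(p) - 0) return(root_depth)
        d <- dm[[ckey(cl)]]
        if (is.null(d)) stop("internal error: clade without depth")
        d
      }
      # edge above a clade runs from the clade's depth to its parent's;
      # the parent is the smallest strictly-containing clade (or the root)
      weights <- vapply(clades, function(cl) {
        parents <- Filter(function(x) length(x) > length(cl) && all(cl %in% x),
                          clades)
        pd <- if (length(parents))
          min(vapply(parents, depth_of, numeric(1))) else root_depth
        pd - depth_of(cl)
      }, numeric(1))
    }
    list(clades = clades, weights = weights)
  })
  names(out) <- topo$key
  list(clades = lapply(out, `[[`, "clades"),
       weights = lapply(out, `[[`, "weights"),
       species_key = topo$species_key,
       keys = topo$key, topologies = topo)
}

# tip sets below every non-root node of a rooted tree (terminal + internal
# edges; excludes the full tip set)
phylo_clades <- function(tr) {
  nt <- length(tr$tip.label)
  root <- nt + 1L
  nodes <- setdiff(unique(as.vector(tr$edge)), root)
  cl <- lapply(nodes, function(nd) {
    if (nd <= nt) tr$tip.label[nd]
    else tr$tip.label[unlist(descendant_tips(tr, nd))]
  })
  cl[lengths(cl) < nt]
}

descendant_tips <- function(tr, node) {
  nt <- length(tr$tip.label)
  if (node <= nt) return(node)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tr = tr))
}

#' Simulate biallelic genotypes for the five-population panel
#'
#' Per site a genealogy is drawn: sites inside introgressed tracts take the
#' topology where the focal lineage groups with donorB (mossambicus-like);
#' elsewhere the species topology applies with probability
#' \code{1 - ils_rate} and a uniformly random discordant topology otherwise.
#' One derived mutation is placed uniformly on one of the rooted genealogy's
#' edges, making every population in the subtended clade homozygous derived.
#' Per-site total depth is Poisson around \code{mean_depth}.
#'
#' @param params Parameter list from \code{\link{sim_params}}.
#' @param per_site Logical; if \code{TRUE}, introgression is drawn
#'   independently per site with probability \code{f} (no tracts), the mode
#'   used for genome-wide admixture-fraction calibration.
#' @return list with \code{matrix} (a \code{genotype_matrix}) and
#'   \code{truth} (tract coordinates and per-site genealogy labels).
#' @export
simulate_genotypes <- function(params = sim_params(), per_site = FALSE) {
  if (params$n_sites < 1) stop("n_sites must be >= 1")
  set.seed(params$seed + 2000L)
  pops <- params$populations
  gen <- genealogy_clades(pops)
  keys <- gen$keys
  species_key <- gen$species_key
  intro_key <- introgression_key(gen$topologies, pops)
  discordant <- setdiff(keys, species_key)

  pos <- sort(sample.int(params$geno_length, params$n_sites))
  if (per_site) {
    blocks <- plant_blocks(stats::setNames(params$geno_length, "geno_1"),
                           0, params$block_mean_length,
                           params$block_min_length, 0)
    in_block <- stats::runif(params$n_sites) < params$f
  } else {
    blocks <- plant_blocks(stats::setNames(params$geno_length, "geno_1"),
                           params$f, params$block_mean_length,
                           params$block_min_length, 0)
    in_block <- rep(FALSE, params$n_sites)
    if (nrow(blocks))
      for (i in seq_len(nrow(blocks)))
        in_block <- in_block | (pos > blocks$start[i] & pos <= blocks$end[i])
  }
  u <- stats::runif(params$n_sites)
  label <- ifelse(in_block, "intro",
                  ifelse(u < params$ils_rate, "ils", "species"))
  topo_key <- character(params$n_sites)
  topo_key[label == "intro"] <- intro_key
  topo_key[label == "species"] <- species_key
  n_ils <- sum(label == "ils")
  if (n_ils) topo_key[label == "ils"] <- sample(discordant, n_ils, replace = TRUE)

  samples <- data.frame(
    sample_id = paste0(rep(pops, each = params$n_per_pop), "_",
                       rep(seq_len(params$n_per_pop), length(pops))),
    population = rep(pops, each = params$n_per_pop),
    stringsAsFactors = FALSE
  )
  geno <- matrix(0L, params$n_sites, nrow(samples),
                 dimnames = list(NULL, samples$sample_id))
  for (key in unique(topo_key)) {
    idx <- which(topo_key == key)
    clades <- gen$clades[[key]]
    wts <- gen$weights[[key]]
    pick <- sample.int(length(clades), length(idx), replace = TRUE,
                       prob = wts)
    for (ci in unique(pick)) {
      rows <- idx[pick == ci]
      cols <- samples$population %in% clades[[ci]]
      geno[rows, cols] <- 2L
    }
  }
  sites <- data.frame(
    seqid = "geno_1", pos = pos, ref_allele = "A", alt_allele = "T",
    total_depth = stats::rpois(params$n_sites, params$mean_depth),
    is_indel = FALSE, biallelic = TRUE, dist_indel = NA_real_,
    stringsAsFactors = FALSE
  )
  gm <- list(sites = sites, geno = geno, samples = samples)
  class(gm) <- "genotype_matrix"
  list(matrix = gm,
       truth = list(blocks = blocks, genealogy = label, topology = topo_key))
}

# canonical key of the topology in which the focal lineage is sister to the
# mossambicus-like donor, holding the rest of the species tree
introgression_key <- function(topologies, populations) {
  nwk <- sprintf("(((%s,%s),(%s,%s)),%s);", populations[2], populations[3],
                 populations[1], populations[4], populations[5])
  tr <- ape::read.tree(text = nwk)
  topology_key(tr, populations)
}

# --- genetic-map fixture ----------------------------------------------------

#' Simulate SNP-array probe hits, a genetic map, and scaffolds to anchor
#'
#' Scaffolds are assigned a true linkage group, order and orientation;
#' probes are placed at centimorgan positions consistent with bp position
#' (reversed for '-' scaffolds).  A fraction of scaffolds are made chimeric
#' by concatenating pieces from two linkage groups, with the join point
#' recorded in truth.
#'
#' @param params Parameter list from \code{\link{sim_params}}.
#' @return list with \code{hits} (probe-hit data.frame), \code{map}
#'   (genetic-map data.frame), \code{scaffolds} (named sequence vector) and
#'   \code{truth} (order/orientation per LG and chimera join records).
#' @export
simulate_probe_map <- function(params = sim_params()) {
  stopifnot(params$n_lgs >= 1)
  if (params$probes_per_scaffold < 2)
    warning("fewer than 2 probes per scaffold: orientation undefined")
  set.seed(params$seed + 3000L)
  scaffolds <- character(0); truth_rows <- list(); hit_rows <- list()
  map_rows <- list()
  probe_n <- 0L
  for (lg in seq_len(params$n_lgs)) {
    lg_name <- paste0("LG", lg)
    n_sc <- params$scaffolds_per_lg
    sc_len <- round(params$map_scaffold_length * stats::runif(n_sc, 0.5, 1.5))
    sc_name <- sprintf("sc_%02d_%02d", lg, seq_len(n_sc))
    ori <- sample(c("+", "-"), n_sc, replace = TRUE)
    cm_edges <- c(0, cumsum(sc_len / sum(sc_len))) * params$lg_cm_length
    for (i in seq_len(n_sc)) {
      seq <- random_dna(sc_len[i])
      scaffolds[sc_name[i]] <- seq
      npr <- max(params$probes_per_scaffold, 1L)
      bp <- sort(sample.int(sc_len[i], min(npr, sc_len[i])))
      frac <- bp / sc_len[i]
      if (ori[i] == "-") frac <- 1 - frac
      cm <- cm_edges[i] + frac * (cm_edges[i + 1] - cm_edges[i])
      ids <- sprintf("probe_%05d", probe_n + seq_along(bp))
      probe_n <- probe_n + length(bp)
      hit_rows[[length(hit_rows) + 1]] <-
        data.frame(probe_id = ids, scaffold = sc_name[i], bp = bp - 1L,
                   strand = "+", score = 100L, stringsAsFactors = FALSE)
      map_rows[[length(map_rows) + 1]] <-
        data.frame(probe_id = ids, lg = lg_name, cm = round(cm, 4),
                   stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1]] <-
        data.frame(scaffold = sc_name[i], lg = lg_name, order = i,
                   orientation = ori[i], length = sc_len[i],
                   stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  hits <- do.call(rbind, hit_rows)
  gmap <- do.call(rbind, map_rows)

  # chimeras: fuse pairs of scaffolds drawn from different LGs
  n_chim <- round(params$chimera_fraction * nrow(truth) / 2)
  chim <- list()
  if (n_chim > 0) {
    for (ci in seq_len(n_chim)) {
      cand <- truth$scaffold[!truth$scaffold %in%
                               unlist(lapply(chim, `[[`, "components"))]
      lgs <- truth$lg[match(cand, truth$scaffold)]
      a <- sample(cand, 1)
      b_pool <- cand[lgs != truth$lg[truth$scaffold == a]]
      if (!length(b_pool)) break
      b <- sample(b_pool, 1)
      nm <- sprintf("chim_%02d", ci)
      la <- nchar(scaffolds[[a]])
      scaffolds[nm] <- paste0(scaffolds[[a]], scaffolds[[b]])
      scaffolds <- scaffolds[setdiff(names(scaffolds), c(a, b))]
      hits$bp[hits$scaffold == b] <- hits$bp[hits$scaffold == b] + la
      hits$scaffold[hits$scaffold %in% c(a, b)] <- nm
      chim[[length(chim) + 1]] <- list(name = nm, components = c(a, b),
                                       join = la)
    }
  }
  list(hits = hits, map = gmap, scaffolds = scaffolds,
       truth = list(assignments = truth, chimeras = chim))
}
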