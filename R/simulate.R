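# Simulators for every pipeline input. Each generator is a pure function of
# its arguments plus `seed`, so regenerating any single input is reproducible
# independently of the others.

#' Default simulation configuration
#'
#' Central list of generator parameters. The gene-class mixture emulates the
#' population-level chromatin geometry of MAE: in a mosaic population one
#' allele is silenced (H3K27me3) while the other is transcribed (H3K36me3),
#' so MAE genes are enriched for \emph{both} marks; expressed BAE genes are
#' K36-high/K27-low; silent genes K27-high/K36-low. Signal levels are
#' lognormal around class means, with Poisson noise per 1 kb bin on the
#' emitted tracks.
#'
#' @param ... Overrides for individual entries.
#' @return Named list of parameters.
#' @export
simConfig <- function(...) {
  cfg <- list(
    n_genes = 2000L,
    mae_fraction = 0.15,        # autosomal MAE prevalence (up to ~15%)
    silent_fraction = 0.45,     # genes not expressed in a given cell type
    short_fraction = 0.10,      # genes under the 2.5 kb length filter
    gene_length_range = c(1000L, 50000L),
    bin_bp = 1000L,             # track resolution
    # lognormal meanlog levels per class (sdlog below):
    #            k27        k36        rna
    mu = list(MAE = c(log(6), log(6), log(5)),
              BAE = c(log(1), log(10), log(10)),
              silent = c(log(10), log(1), log(0.1))),
    sdlog = 0.5,
    input_mu = log(2), input_sdlog = 0.3,
    noise_scale = 10,           # Poisson counts per bin = scale * level
    snp_range = c(1L, 20L),     # SNPs per expressed gene
    allele_depth = 20L,         # mean reads per SNP
    mono_fraction = 0.95,       # major-allele fraction of an MAE clone
    switch_prob = 0.05,         # per-branch MAE state flip probability
    x_fraction = 0.02           # extra chrX genes (excluded downstream)
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes with 1-3 transcripts each along autosomes
#' (plus a few chrX genes to exercise the autosome restriction). Roughly
#' \code{short_fraction} of genes are shorter than 2.5 kb so the length
#' filter is exercised; the rest are log-uniform up to 50 kb.
#'
#' @param config List from \code{\link{simConfig}}.
#' @param seed Integer seed.
#' @param nChrom Number of autosomes to distribute genes over.
#' @return \code{GRanges} of transcripts (\code{gene_id}, \code{tx_id});
#'   chromosome lengths in \code{seqinfo} are sized to fit.
#' @importFrom stats runif rpois rbinom rlnorm rbeta
#' @importFrom GenomicRanges GRanges seqinfo<-
#' @importFrom IRanges IRanges
#' @export
simulateAnnotation <- function(config = simConfig(), seed = 1L, nChrom = 5L) {
  set.seed(seed)
  nAuto <- config$n_genes
  nX <- ceiling(nAuto * config$x_fraction)
  n <- nAuto + nX
  lo <- config$gene_length_range[1]; hi <- config$gene_length_range[2]
  short <- stats::runif(n) < config$short_fraction
  len <- integer(n)
  len[short] <- as.integer(round(exp(stats::runif(sum(short), log(lo),
                                                  log(2500)))))
  len[!short] <- as.integer(round(exp(stats::runif(sum(!short), log(2500),
                                                   log(hi)))))
  chrom <- c(paste0("chr", 1 + (seq_len(nAuto) - 1L) %% nChrom),
             rep("chrX", nX))
  gap <- as.integer(round(stats::runif(n, 200, 2000)))

  rows <- vector("list", n)
  cursor <- integer(0)
  for (i in seq_len(n)) {
    ch <- chrom[i]
    at <- if (is.na(cursor[ch])) 1L else cursor[ch]
    start <- at + gap[i]
    end <- start + len[i] - 1L
    cursor[ch] <- end + 1L
    gid <- sprintf("g%04d", i)
    ntx <- sample.int(3L, 1L)
    txStart <- c(start, start + as.integer(round(stats::runif(ntx - 1L, 0,
                                                              len[i] * 0.4))))
    txEnd <- c(end, pmin(end, txStart[-1] +
                           as.integer(round(len[i] * stats::runif(ntx - 1L,
                                                                  0.3, 0.9)))))
    rows[[i]] <- data.frame(chrom = ch, start = txStart, end = txEnd,
                            gene_id = gid,
                            tx_id = sprintf("%s.t%d", gid, seq_len(ntx)))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               gene_id = df$gene_id, tx_id = df$tx_id)
  gr
}

#' Assign gene classes
#'
#' Draws a label per autosomal gene: \code{MAE} with \code{mae_fraction},
#' \code{silent} with \code{silent_fraction}, otherwise \code{BAE}
#' (expressed, biallelic). chrX genes are labelled like autosomal ones; they
#' are removed by the autosome restriction downstream anyway.
#'
#' @param transcripts Annotation from \code{\link{simulateAnnotation}}.
#' @param config,seed As in \code{\link{simulateAnnotation}}.
#' @return Named character vector over genes.
#' @export
simulateLabels <- function(transcripts, config = simConfig(), seed = 1L) {
  set.seed(seed)
  genes <- sort(unique(S4Vectors::mcols(transcripts)$gene_id))
  u <- stats::runif(length(genes))
  lab <- ifelse(u < config$mae_fraction, "MAE",
         ifelse(u < config$mae_fraction + config$silent_fraction,
                "silent", "BAE"))
  stats::setNames(lab, genes)
}

# per-gene class levels on the natural scale, one row per gene:
# columns k27, k36, rna, input
.simLevels <- function(labels, config) {
  n <- length(labels)
  lv <- matrix(0, n, 4, dimnames = list(names(labels),
                                        c("k27", "k36", "rna", "input")))
  for (cls in c("MAE", "BAE", "silent")) {
    i <- labels == cls
    if (!any(i)) next
    mu <- config$mu[[cls]]
    for (j in 1:3)
      lv[i, j] <- stats::rlnorm(sum(i), mu[j], config$sdlog)
  }
  lv[, "input"] <- stats::rlnorm(n, config$input_mu, config$input_sdlog)
  lv
}

#' Simulate coverage tracks
#'
#' Emits one coverage \code{GRanges} per assay (\code{k27}, \code{k36},
#' \code{input}, \code{rna}). Each gene body (longest transcript span) is
#' tiled in \code{bin_bp} bins; the bin value is a Poisson draw around the
#' gene's class level (lognormal across genes), rescaled back to the level
#' scale, so tracks carry realistic counting noise. Regions outside gene
#' bodies have zero coverage.
#'
#' @param transcripts Annotation (\code{\link{simulateAnnotation}}).
#' @param labels Per-gene classes (\code{\link{simulateLabels}}).
#' @param config,seed As above.
#' @return Named list of coverage \code{GRanges}: \code{k27}, \code{k36},
#'   \code{input}, \code{rna}.
#' @export
simulateTracks <- function(transcripts, labels, config = simConfig(),
                           seed = 1L) {
  set.seed(seed)
  body <- longestTranscript(transcripts)
  body <- body[names(labels)[names(labels) %in% names(body)]]
  lv <- .simLevels(labels[names(body)], config)

  binStarts <- lapply(seq_along(body), function(i) {
    seq(GenomicRanges::start(body)[i], GenomicRanges::end(body)[i],
        by = config$bin_bp)
  })
  nb <- lengths(binStarts)
  starts <- unlist(binStarts)
  ends <- pmin(starts + config$bin_bp - 1L,
               rep(GenomicRanges::end(body), nb))
  chroms <- rep(as.character(GenomicRanges::seqnames(body)), nb)
  geneIdx <- rep(seq_along(body), nb)

  mkTrack <- function(level) {
    val <- stats::rpois(length(starts),
                        config$noise_scale * level[geneIdx]) /
      config$noise_scale
    gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, ends))
    S4Vectors::mcols(gr)$score <- val
    GenomicRanges::sort(gr)
  }
  list(k27 = mkTrack(lv[, "k27"]), k36 = mkTrack(lv[, "k36"]),
       input = mkTrack(lv[, "input"]), rna = mkTrack(lv[, "rna"]))
}

#' Simulate SNP allele counts
#'
#' Expressed genes carry 1-20 transcribed SNPs. In an MAE gene the clone has
#' fixed one allele, so the maternal fraction is \code{mono_fraction} or
#' \code{1 - mono_fraction} (chosen once per gene); BAE genes sit at 0.5.
#' Per-SNP depth is Poisson around \code{allele_depth} and allele counts are
#' binomial at that depth. Silent genes yield no SNP rows.
#'
#' @param labels Per-gene classes (\code{\link{simulateLabels}}).
#' @param transcripts Annotation, for SNP coordinates.
#' @param config,seed As above.
#' @return \code{data.frame} in the \code{\link{readSnpTable}} schema.
#' @export
simulateAlleleCounts <- function(labels, transcripts, config = simConfig(),
                                 seed = 1L) {
  set.seed(seed)
  body <- longestTranscript(transcripts)
  genes <- names(labels)[labels != "silent" & names(labels) %in% names(body)]
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    nsnp <- sample(seq(config$snp_range[1], config$snp_range[2]), 1L)
    frac <- if (labels[g] == "MAE") {
      if (stats::runif(1) < 0.5) config$mono_fraction
      else 1 - config$mono_fraction
    } else 0.5
    depth <- stats::rpois(nsnp, config$allele_depth)
    mat <- stats::rbinom(nsnp, depth, frac)
    pos <- sort(sample(seq(GenomicRanges::start(body[g]),
                           GenomicRanges::end(body[g])), nsnp))
    rows[[i]] <- data.frame(
      gene_id = g, chrom = as.character(GenomicRanges::seqnames(body[g])),
      pos = pos, maternal_count = mat, paternal_count = depth - mat,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a labelled classifier training table
#'
#' Draws per-gene normalized-signal levels from the same class mixture as
#' \code{\link{simulateTracks}} and converts them to quantile ranks, yielding
#' a labelled (\code{k27_qrank}, \code{k36_qrank}) training set with the
#' MAE-in-the-high/high-corner geometry. Non-MAE classes (expressed BAE and
#' silent) are labelled BAE, as in a real allelic-expression training set.
#'
#' @param n Number of training genes.
#' @param config,seed As above.
#' @return \code{data.frame} with \code{k27_qrank}, \code{k36_qrank},
#'   \code{label}.
#' @export
simulateTrainingTable <- function(n = 2000L, config = simConfig(),
                                  seed = 1L) {
  set.seed(seed)
  u <- stats::runif(n)
  lab <- ifelse(u < config$mae_fraction, "MAE",
         ifelse(u < config$mae_fraction + config$silent_fraction,
                "silent", "BAE"))
  names(lab) <- sprintf("t%05d", seq_len(n))
  lv <- .simLevels(lab, config)
  data.frame(
    k27_qrank = quantileRank(lv[, "k27"] / lv[, "input"]),
    k36_qrank = quantileRank(lv[, "k36"] / lv[, "input"]),
    label = ifelse(lab == "MAE", "MAE", "BAE"),
    row.names = names(lab), stringsAsFactors = FALSE)
}

#' Simulate MAE profiles on a lineage tree
#'
#' Each gene's MAE state starts at the root as Bernoulli(\code{mae_fraction})
#' and flips along every branch with probability \code{switch_prob}; leaf
#' states form the genes x samples profile matrix. Low switch probabilities
#' emulate MAE that is stable through differentiation, so related samples
#' share profiles.
#'
#' @param tree An \pkg{ape} \code{phylo} object or a Newick string; >= 3
#'   leaves.
#' @param nGenes Number of genes.
#' @param config,seed As above (\code{mae_fraction}, \code{switch_prob}).
#' @return List: \code{profiles} (genes x leaves 0/1 matrix) and \code{tree}
#'   (\code{phylo}).
#' @importFrom ape read.tree Ntip
#' @export
simulateProfiles <- function(tree, nGenes = 2000L, config = simConfig(),
                             seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (ape::Ntip(tree) < 3L) .err("lineage tree needs at least 3 leaves")
  set.seed(seed)
  nTip <- ape::Ntip(tree)
  nNode <- nTip + tree$Nnode
  root <- nTip + 1L
  state <- matrix(NA_integer_, nGenes, nNode)
  state[, root] <- stats::rbinom(nGenes, 1L, config$mae_fraction)
  # edges are parent-before-child in preorder after cladewise reordering
  ord <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    flip <- stats::rbinom(nGenes, 1L, config$switch_prob)
    state[, child] <- (state[, par] + flip) %% 2L
  }
  profiles <- state[, seq_len(nTip), drop = FALSE]
  colnames(profiles) <- tree$tip.label
  rownames(profiles) <- sprintf("g%05d", seq_len(nGenes))
  list(profiles = profiles, tree = tree)
}

#' Simulate a one-to-one ortholog table with planted conservation
#'
#' Builds \code{nPairs} ortholog pairs and MAE/BAE calls in each species with
#' exactly \code{round(pA * nPairs)} MAE genes in species A,
#' \code{round(pB * nPairs)} in species B, and exactly \code{nConserved}
#' pairs MAE in both; the remaining MAE assignments are disjoint between
#' species where possible.
#'
#' @param nPairs Number of one-to-one pairs.
#' @param pA,pB MAE fraction in each species.
#' @param nConserved Number of planted shared-MAE pairs.
#' @param seed Integer seed (shuffles pair order).
#' @return List: \code{pairs} (\code{gene_a}, \code{gene_b}), \code{callsA},
#'   \code{callsB} (named \code{"MAE"}/\code{"BAE"} vectors).
#' @export
simulateOrthologs <- function(nPairs, pA, pB, nConserved, seed = 1L) {
  set.seed(seed)
  kA <- round(pA * nPairs); kB <- round(pB * nPairs)
  if (nConserved > min(kA, kB))
    .err("nConserved (%d) exceeds the smaller MAE set (%d)",
         nConserved, min(kA, kB))
  if (kA + kB - nConserved > nPairs)
    .err("MAE sets cannot be made this disjoint: kA + kB - nConserved > N")
  idx <- sample.int(nPairs)        # random placement, counts exact
  both <- idx[seq_len(nConserved)]
  onlyA <- idx[nConserved + seq_len(kA - nConserved)]
  onlyB <- idx[kA + seq_len(kB - nConserved)]
  a <- sprintf("mA%05d", seq_len(nPairs))
  b <- sprintf("hB%05d", seq_len(nPairs))
  callsA <- stats::setNames(rep("BAE", nPairs), a)
  callsB <- stats::setNames(rep("BAE", nPairs), b)
  callsA[c(both, onlyA)] <- "MAE"
  callsB[c(both, onlyB)] <- "MAE"
  list(pairs = data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE),
       callsA = callsA, callsB = callsB)
}

#' Simulate a complete MaGIC input dataset
#'
#' Fans one seed out to per-generator substreams and returns every input the
#' pipeline consumes: annotation, per-gene class labels, the four coverage
#' tracks, SNP allele counts, and a labelled training table drawn from the
#' same signal model.
#'
#' @param config From \code{\link{simConfig}}.
#' @param seed Master seed; generators use \code{seed}, \code{seed + 1}, ...
#' @return List: \code{transcripts}, \code{labels}, \code{tracks},
#'   \code{snps}, \code{training}, \code{config}.
#' @export
simulateMagicDataset <- function(config = simConfig(), seed = 1L) {
  seed <- as.integer(seed) %% 2000000000L
  transcripts <- simulateAnnotation(config, seed = seed)
  labels <- simulateLabels(transcripts, config, seed = seed + 1L)
  tracks <- simulateTracks(transcripts, labels, config, seed = seed + 2L)
  snps <- simulateAlleleCounts(labels, transcripts, config, seed = seed + 3L)
  training <- simulateTrainingTable(config$n_genes, config, seed = seed + 4L)
  list(transcripts = transcripts, labels = labels, tracks = tracks,
       snps = snps, training = training, config = config)
}

#' Write simulated inputs to standard file formats
#'
#' GTF for the annotation, bedGraph per track, TSV for SNP counts, labels and
#' training table — everything re-readable through the package's readers.
#'
#' @param dataset List from \code{\link{simulateMagicDataset}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @importFrom rtracklayer export
#' @export
writeMagicDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "annotation.gtf"),
             k27 = file.path(dir, "k27.bedgraph"),
             k36 = file.path(dir, "k36.bedgraph"),
             input = file.path(dir, "input.bedgraph"),
             rna = file.path(dir, "rna.bedgraph"),
             snps = file.path(dir, "snps.tsv"),
             labels = file.path(dir, "labels.tsv"),
             training = file.path(dir, "training.tsv"))
  tx <- dataset$transcripts
  gtf <- GenomicRanges::granges(tx)
  S4Vectors::mcols(gtf)$type <- "transcript"
  S4Vectors::mcols(gtf)$source <- "magicMAE"
  S4Vectors::mcols(gtf)$gene_id <- S4Vectors::mcols(tx)$gene_id
  S4Vectors::mcols(gtf)$transcript_id <- S4Vectors::mcols(tx)$tx_id
  rtracklayer::export(gtf, paths["annotation"], format = "gtf")
  for (tr in c("k27", "k36", "input", "rna"))
    rtracklayer::export(dataset$tracks[[tr]], paths[tr], format = "bedGraph")
  writeResultTable(dataset$snps, paths["snps"], sort = FALSE)
  writeResultTable(data.frame(gene_id = names(dataset$labels),
                              label = unname(dataset$labels)),
                   paths["labels"])
  writeResultTable(cbind(gene_id = rownames(dataset$training),
                         dataset$training), paths["training"], sort = FALSE)
  invisible(paths)
}
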