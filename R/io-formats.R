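#' Read gene models from a GTF or BED12 annotation
#'
#' Parses an annotation file into a \code{GRanges} of transcript spans with
#' metadata columns \code{gene_id} and \code{tx_id}, the representation all
#' downstream gene-body operations consume. Coordinates follow the Bioconductor
#' convention (1-based, closed); \pkg{rtracklayer} performs the conversion from
#' the file's native convention on read.
#'
#' For GTF input, transcript spans are taken from \code{type == "transcript"}
#' records when present, and otherwise reconstructed as the span of each
#' transcript's exons. For BED12 input each record is treated as a
#' single-transcript gene, with the BED \code{name} serving as both
#' \code{gene_id} and \code{tx_id}.
#'
#' @param path Path to the annotation file.
#' @param format \code{"gtf"} or \code{"bed12"}.
#' @return \code{GRanges} of transcripts with \code{gene_id} and \code{tx_id}.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "transcript", "101", "200", ".", "+", ".",
#'   'gene_id "g1"; transcript_id "g1.t1";', sep = "\t"), gtf)
#' readGeneModels(gtf)
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end width
#' @importFrom S4Vectors split
#' @export
readGeneModels <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) .err("annotation file not found: %s", path)
  emptyModels <- function() {
    tx <- GenomicRanges::GRanges()
    S4Vectors::mcols(tx)$gene_id <- character()
    S4Vectors::mcols(tx)$tx_id <- character()
    tx
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")))
    return(emptyModels())
  if (format == "gtf") {
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) .err("failed to parse GTF '%s': %s",
                                            path, conditionMessage(e)))
    if (length(gr) == 0L) return(emptyModels())
    mc <- S4Vectors::mcols(gr)
    if (!"transcript_id" %in% names(mc))
      .err("GTF '%s' has no transcript_id attributes", path)
    if ("type" %in% names(mc) && any(mc$type == "transcript")) {
      tx <- gr[mc$type == "transcript"]
    } else {
      ex <- gr[mc$type %in% c("exon", "CDS")]
      if (length(ex) == 0L) ex <- gr
      key <- S4Vectors::mcols(ex)$transcript_id
      if (anyNA(key)) .err("GTF '%s': feature without transcript_id", path)
      spans <- unlist(range(S4Vectors::split(ex, key)))
      gid <- vapply(S4Vectors::split(S4Vectors::mcols(ex)$gene_id, key),
                    function(g) as.character(g[1]), character(1))
      S4Vectors::mcols(spans)$gene_id <- gid[names(spans)]
      S4Vectors::mcols(spans)$transcript_id <- names(spans)
      tx <- unname(spans)
    }
    gid <- S4Vectors::mcols(tx)$gene_id
    if (is.null(gid) || anyNA(gid))
      .err("GTF '%s': transcript without gene_id attribute", path)
    out <- GenomicRanges::granges(tx)
    S4Vectors::mcols(out)$gene_id <- as.character(gid)
    S4Vectors::mcols(out)$tx_id <- as.character(S4Vectors::mcols(tx)$transcript_id)
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) .err("failed to parse BED12 '%s': %s",
                                            path, conditionMessage(e)))
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) .err("BED12 '%s' has no name column", path)
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$gene_id <- as.character(nm)
    S4Vectors::mcols(out)$tx_id <- as.character(nm)
  }
  # all transcripts of a gene must share a chromosome
  chrByGene <- split(as.character(GenomicRanges::seqnames(out)),
                     S4Vectors::mcols(out)$gene_id)
  bad <- names(chrByGene)[vapply(chrByGene,
                                 function(x) length(unique(x)) > 1L, logical(1))]
  if (length(bad))
    .err("gene(s) with transcripts on multiple chromosomes: %s",
         paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Read a genome-wide coverage track
#'
#' Reads a bedGraph or wiggle (fixedStep/variableStep) signal track into a
#' \code{GRanges} with a numeric \code{score} column. Gaps carry implicit
#' coverage zero. Adjacent intervals with equal value are merged; overlapping
#' input intervals are rejected, since the per-base signal would be ambiguous.
#'
#' @param path Path to the track file.
#' @param format \code{"bedGraph"} or \code{"wig"} (auto-detects fixedStep vs
#'   variableStep sections).
#' @return \code{GRanges} with metadata column \code{score} (>= 0), disjoint
#'   within each chromosome.
#' @examples
#' bg <- tempfile(fileext = ".bedgraph")
#' writeLines("chr1\t0\t10\t2.0", bg)
#' readCoverage(bg, "bedGraph")
#' @importFrom GenomicRanges isDisjoint findOverlaps
#' @export
readCoverage <- function(path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  if (!file.exists(path)) .err("track file not found: %s", path)
  fmt <- if (format == "bedGraph") "bedGraph" else "wig"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) .err("failed to parse %s '%s': %s",
                                          format, path, conditionMessage(e)))
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) .err("track '%s' has no score column", path)
  if (any(score < 0))
    .err("track '%s' contains negative coverage values (min %g)",
         path, min(score))
  if (!GenomicRanges::isDisjoint(gr)) {
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    i <- S4Vectors::queryHits(ov)[1]; j <- S4Vectors::subjectHits(ov)[1]
    .err("track '%s' has overlapping intervals, e.g. %s:%d-%d and %s:%d-%d",
         path,
         as.character(GenomicRanges::seqnames(gr))[i],
         GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
         as.character(GenomicRanges::seqnames(gr))[j],
         GenomicRanges::start(gr)[j], GenomicRanges::end(gr)[j])
  }
  mergeCoverageRuns(gr)
}

#' Merge adjacent equal-value coverage intervals
#'
#' Run-length compression of a coverage \code{GRanges}: abutting intervals on
#' the same chromosome with identical score collapse into one. Per-base wiggle
#' tracks shrink considerably; the represented signal is unchanged.
#'
#' @param track \code{GRanges} with a \code{score} column, disjoint.
#' @return Equivalent compressed \code{GRanges}, sorted.
#' @export
mergeCoverageRuns <- function(track) {
  if (length(track) == 0L) return(track)
  track <- GenomicRanges::sort(track)
  chr <- as.character(GenomicRanges::seqnames(track))
  s <- GenomicRanges::start(track); e <- GenomicRanges::end(track)
  v <- S4Vectors::mcols(track)$score
  n <- length(track)
  newRun <- c(TRUE, !(chr[-1] == chr[-n] & s[-1] == e[-n] + 1L & v[-1] == v[-n]))
  run <- cumsum(newRun)
  out <- GenomicRanges::GRanges(
    chr[newRun],
    IRanges::IRanges(start = s[newRun], end = tapply(e, run, max)[unique(run)])
  )
  S4Vectors::mcols(out)$score <- v[newRun]
  out
}

#' Read a per-SNP allele count table
#'
#' Reads a tab-separated table of maternal/paternal read counts at transcribed
#' SNPs, the input for allelic-expression calling. Required header columns:
#' \code{gene_id}, \code{chrom}, \code{pos} (1-based), \code{maternal_count},
#' \code{paternal_count}. Counts must be non-negative integers and the key
#' (\code{gene_id}, \code{chrom}, \code{pos}) unique.
#'
#' @param path Path to the TSV file.
#' @return \code{data.frame} with typed columns.
#' @importFrom utils read.delim
#' @export
readSnpTable <- function(path) {
  if (!file.exists(path)) .err("SNP table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "pos", "maternal_count", "paternal_count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .err("SNP table '%s' lacks column(s): %s", path,
         paste(missing, collapse = ", "))
  for (col in c("pos", "maternal_count", "paternal_count")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)))
      .err("SNP table '%s': column '%s' must be integer-valued", path, col)
    df[[col]] <- as.integer(v)
  }
  if (any(df$maternal_count < 0) || any(df$paternal_count < 0))
    .err("SNP table '%s': negative counts", path)
  key <- paste(df$gene_id, df$chrom, df$pos, sep = "\r")
  if (anyDuplicated(key))
    .err("SNP table '%s': duplicate (gene_id, chrom, pos) key: %s", path,
         gsub("\r", "/", key[duplicated(key)][1]))
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df[need]
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row, no quoting, deterministic row order
#' (sorted on the first column unless \code{sort = FALSE}). Floats keep full
#' double precision so that write-then-read round-trips.
#'
#' @param x \code{data.frame} or \code{DataFrame} to write.
#' @param path Output path.
#' @param sort Sort rows on the first column before writing.
#' @return \code{path}, invisibly.
#' @importFrom utils write.table
#' @export
writeResultTable <- function(x, path, sort = TRUE) {
  if (is.null(x)) .err("writeResultTable: x is NULL")
  df <- as.data.frame(x)
  if (!is.null(rownames(x)) && !identical(rownames(df), as.character(seq_len(nrow(df)))) &&
      !"gene_id" %in% names(df) && nrow(df) > 0) {
    df <- cbind(gene_id = rownames(df), df)
  }
  if (sort && nrow(df) > 1) df <- df[order(df[[1]]), , drop = FALSE]
  # full precision, never scientific-only truncation below 6 significant digits
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Preflight check of annotation/track compatibility
#'
#' Reports the chromosome-name overlap between an annotation and a coverage
#' track plus basic size statistics. Chromosome matching downstream is exact
#' string match (no "chr" aliasing), so a poor overlap here means the inputs
#' disagree on naming and gene-body sums would silently be zero.
#'
#' @param annotation \code{GRanges} of transcripts (from
#'   \code{\link{readGeneModels}}) or a path to a GTF file.
#' @param track Coverage \code{GRanges} (from \code{\link{readCoverage}}) or a
#'   path to a bedGraph file.
#' @return Invisibly, a list with \code{shared}, \code{annotation_only},
#'   \code{track_only} chromosome names and counts.
#' @export
ioCheck <- function(annotation, track) {
  if (is.character(annotation)) annotation <- readGeneModels(annotation)
  if (is.character(track)) track <- readCoverage(track)
  ca <- unique(as.character(GenomicRanges::seqnames(annotation)))
  ct <- unique(as.character(GenomicRanges::seqnames(track)))
  res <- list(shared = intersect(ca, ct),
              annotation_only = setdiff(ca, ct),
              track_only = setdiff(ct, ca),
              n_transcripts = length(annotation),
              n_genes = length(unique(S4Vectors::mcols(annotation)$gene_id)),
              n_intervals = length(track))
  message(sprintf("annotation: %d genes, %d transcripts on %d chromosome(s)",
                  res$n_genes, res$n_transcripts, length(ca)))
  message(sprintf("track: %d intervals on %d chromosome(s)",
                  res$n_intervals, length(ct)))
  message(sprintf("shared chromosomes: %d [%s]", length(res$shared),
                  paste(utils::head(res$shared, 10), collapse = ", ")))
  if (length(res$annotation_only))
    message("annotation-only: ", paste(utils::head(res$annotation_only, 10),
                                       collapse = ", "))
  if (length(res$track_only))
    message("track-only: ", paste(utils::head(res$track_only, 10),
                                  collapse = ", "))
  invisible(res)
}
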