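#' Select the longest transcript per gene
#'
#' The gene body used for all signal integration is the genomic span of each
#' gene's longest transcript (introns included). Ties on span length break
#' deterministically on the lexicographically smallest \code{tx_id}.
#'
#' @param transcripts \code{GRanges} of transcripts with \code{gene_id} and
#'   \code{tx_id} metadata columns (see \code{\link{readGeneModels}}).
#' @return \code{GRanges}, one range per gene, named by \code{gene_id},
#'   keeping the chosen \code{tx_id}.
#' @examples
#' tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1), c(100, 250)))
#' tx$gene_id <- "g1"; tx$tx_id <- c("t1", "t2")
#' longestTranscript(tx)
#' @export
longestTranscript <- function(transcripts) {
  if (length(transcripts) == 0L) .err("no transcripts supplied")
  mc <- S4Vectors::mcols(transcripts)
  if (is.null(mc$gene_id) || is.null(mc$tx_id))
    .err("transcripts need gene_id and tx_id metadata columns")
  ord <- order(mc$gene_id,
               -GenomicRanges::width(transcripts),
               mc$tx_id)
  picked <- transcripts[ord][!duplicated(mc$gene_id[ord])]
  names(picked) <- S4Vectors::mcols(picked)$gene_id
  picked
}

#' Sum coverage over gene bodies
#'
#' For each region, sums the per-base coverage of a track:
#' \eqn{\sum_{b \in body} cov(b)}, computed as value times overlap length over
#' the track intervals intersecting the region. Regions on chromosomes absent
#' from the track get 0 with a warning (a likely naming mismatch; see
#' \code{\link{ioCheck}}).
#'
#' @param track Coverage \code{GRanges} with a \code{score} column.
#' @param regions \code{GRanges} of gene bodies.
#' @return Numeric vector of sums, one per region, named like \code{regions}.
#' @importFrom GenomicRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
#' @export
geneBodySum <- function(track, regions) {
  out <- numeric(length(regions))
  names(out) <- names(regions)
  if (length(track) == 0L || length(regions) == 0L) return(out)
  absent <- setdiff(unique(as.character(GenomicRanges::seqnames(regions))),
                    unique(as.character(GenomicRanges::seqnames(track))))
  if (length(absent))
    warning(sprintf("chromosome(s) absent from track (coverage 0): %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  # absent chromosomes already reported above; silence the seqlevel notice
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE))
  if (length(ov) == 0L) return(out)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(regions)[q], GenomicRanges::granges(track)[s]))
  contrib <- w * S4Vectors::mcols(track)$score[s]
  agg <- rowsum(contrib, q)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Normalize gene-body mark signal
#'
#' Mark signal is normalized to the input (chromatin, no immunoprecipitation)
#' signal over the same gene body, or to the transcript length when no input
#' is available. Genes with an input track but zero input signal are excluded
#' upstream (\code{\link{buildFeatureTable}}) rather than normalized here.
#'
#' @param markSum Numeric vector of gene-body mark sums.
#' @param inputSum Numeric vector of gene-body input sums, or \code{NULL} when
#'   no input control exists.
#' @param lengthBp Integer vector of gene-body lengths (bp), used as the
#'   fallback denominator.
#' @return Numeric vector of normalized signal.
#' @export
normalizeSignal <- function(markSum, inputSum = NULL, lengthBp) {
  if (any(lengthBp <= 0)) .err("lengthBp must be positive")
  if (is.null(inputSum)) return(markSum / lengthBp)
  if (any(inputSum <= 0))
    .err("zero input signal: drop these genes before normalizing (%d gene(s))",
         sum(inputSum <= 0))
  markSum / inputSum
}

#' Average replicate signal
#'
#' Replicate tracks are averaged on the normalized-signal scale, before
#' ranking, so that ranks remain well-defined even when replicates disagree.
#'
#' @param ... Numeric vectors (one per replicate, same genes in the same
#'   order), or a single matrix with replicates in columns.
#' @return Numeric vector of per-gene means.
#' @export
averageReplicates <- function(...) {
  args <- list(...)
  m <- if (length(args) == 1L && is.matrix(args[[1]])) args[[1]]
       else do.call(cbind, args)
  if (ncol(m) < 1L) .err("no replicates supplied")
  rowMeans(m)
}

#' Quantile rank with average ties
#'
#' Maps values to \eqn{(0, 1]}: each value's average 1-based rank in the
#' ascending sort, divided by the number of values. Tied values share an
#' identical rank. Quantile rank is invariant under any strictly monotone
#' transform of the input, which is what makes a classifier trained on one
#' dataset's ranks portable to another dataset regardless of absolute signal
#' scale.
#'
#' @param values Numeric vector without missing values.
#' @return Numeric vector in \eqn{(0, 1]}.
#' @examples
#' quantileRank(c(0.5, 2, 2, 7))  # 0.25 0.625 0.625 1
#' @export
quantileRank <- function(values) {
  if (length(values) == 0L) .err("quantileRank: empty vector")
  if (anyNA(values)) .err("quantileRank: missing values not allowed")
  rank(values, ties.method = "average") / length(values)
}

# scale identifier stored with models and feature tables; a model trained on
# one scale refuses features computed on another
.QRANK_SCALE_TAG <- "qrank-average-rank-over-n"

#' Build the per-gene feature table
#'
#' Runs the full signal pipeline: restrict to autosomal genes, take the
#' longest transcript as gene body, sum each coverage track over it, drop
#' genes with no input signal, normalize marks to input (or to length without
#' input), average replicates on the normalized scale, and compute quantile
#' ranks per mark and for expression. Expression comes either from an RNA
#' coverage track integrated and length-normalized by the same pipeline, or
#' from an externally supplied abundance (e.g. FPKM) vector.
#'
#' Genes whose mark signal is zero are kept (they take the lowest ranks);
#' only genes with zero \emph{input} signal are removed.
#'
#' @param transcripts \code{GRanges} of transcripts
#'   (\code{\link{readGeneModels}}).
#' @param k27,k36 A coverage \code{GRanges} or list of replicate tracks for
#'   H3K27me3 / H3K36me3.
#' @param input Input-control track(s), or \code{NULL} if unavailable.
#' @param rna RNA coverage track(s), or \code{NULL} when \code{abundance} is
#'   given.
#' @param abundance Named numeric vector of per-gene transcript abundance
#'   (FPKM-like), used instead of \code{rna}; genes missing from it are
#'   dropped.
#' @param autosomeExclude Regex for non-autosomal chromosome names
#'   (\code{\link{isAutosome}}).
#' @return \code{DataFrame} keyed by gene with columns \code{chrom},
#'   \code{length_bp}, \code{k27_norm}, \code{k36_norm}, \code{expr_norm},
#'   \code{k27_qrank}, \code{k36_qrank}, \code{expr_qrank}. The quantile-rank
#'   scale tag is stored in \code{metadata()}.
#' @importFrom S4Vectors metadata<-
#' @export
buildFeatureTable <- function(transcripts, k27, k36, input = NULL, rna = NULL,
                              abundance = NULL,
                              autosomeExclude = "^(chr)?(X|Y|M|MT)$") {
  asList <- function(x) if (is(x, "GRanges")) list(x) else x
  k27 <- asList(k27); k36 <- asList(k36)
  input <- if (!is.null(input)) asList(input)
  rna <- if (!is.null(rna)) asList(rna)
  if (is.null(rna) && is.null(abundance))
    .err("supply either rna tracks or an abundance vector")

  auto <- transcripts[isAutosome(
    as.character(GenomicRanges::seqnames(transcripts)), autosomeExclude)]
  if (length(auto) == 0L) .err("no autosomal genes in annotation")
  body <- longestTranscript(auto)
  body <- body[order(names(body))]
  len <- GenomicRanges::width(body)

  sumTracks <- function(tracks)
    matrix(vapply(tracks, geneBodySum, numeric(length(body)), regions = body),
           nrow = length(body),
           dimnames = list(names(body), NULL))
  k27sum <- sumTracks(k27); k36sum <- sumTracks(k36)

  inputSum <- NULL
  if (!is.null(input)) {
    inputSum <- rowMeans(sumTracks(input))
    keep <- inputSum > 0
    if (!any(keep)) .err("all genes have zero input signal")
    if (!all(keep))
      message(sprintf("dropping %d gene(s) with no input signal", sum(!keep)))
    body <- body[keep]; len <- len[keep]
    k27sum <- k27sum[keep, , drop = FALSE]; k36sum <- k36sum[keep, , drop = FALSE]
    inputSum <- inputSum[keep]
  }

  normRep <- function(sums) {
    normed <- apply(sums, 2, normalizeSignal, inputSum = inputSum,
                    lengthBp = len)
    averageReplicates(matrix(normed, nrow = length(len)))
  }
  k27norm <- normRep(k27sum)
  k36norm <- normRep(k36sum)

  if (!is.null(abundance)) {
    hit <- names(body) %in% names(abundance)
    if (!any(hit)) .err("abundance vector shares no gene ids with annotation")
    if (!all(hit))
      message(sprintf("dropping %d gene(s) absent from abundance table",
                      sum(!hit)))
    body <- body[hit]; len <- len[hit]
    k27norm <- k27norm[hit]; k36norm <- k36norm[hit]
    exprNorm <- unname(abundance[names(body)])
  } else {
    rnaSum <- rowMeans(matrix(vapply(rna, geneBodySum,
                                     numeric(length(body)), regions = body),
                              nrow = length(body)))
    exprNorm <- rnaSum / len
  }

  df <- S4Vectors::DataFrame(
    chrom = as.character(GenomicRanges::seqnames(body)),
    length_bp = len,
    k27_norm = unname(k27norm),
    k36_norm = unname(k36norm),
    expr_norm = unname(exprNorm),
    k27_qrank = unname(quantileRank(k27norm)),
    k36_qrank = unname(quantileRank(k36norm)),
    expr_qrank = unname(quantileRank(exprNorm)),
    row.names = names(body)
  )
  S4Vectors::metadata(df)$feature_scale_tag <- .QRANK_SCALE_TAG
  df
}
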