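#' Apply the MaGIC post-classification filters
#'
#' After classification, genes whose chromatin signature is unreliable are set
#' aside: genes shorter than \code{minLength} (default 2500 bp, the span of
#' the longest transcript) and genes expressed below the dataset median
#' (expression quantile rank < 0.5; genes exactly at the median are kept).
#' Filtering happens after classification, so the raw call is preserved
#' alongside the final one.
#'
#' @param calls \code{DataFrame} from \code{\link{classifyGenes}}.
#' @param features Feature table (\code{\link{buildFeatureTable}}) keyed by
#'   the same genes, providing \code{length_bp} and \code{expr_qrank}.
#' @param minLength Minimum gene-body length in bp.
#' @return \code{DataFrame} keyed by gene with \code{score}, \code{call},
#'   \code{filtered} (\code{kept}/\code{short_gene}/\code{low_expression})
#'   and \code{final_call} (\code{MAE}/\code{BAE}/\code{not_assessed}).
#' @export
applyMagicFilters <- function(calls, features, minLength = 2500L) {
  genes <- rownames(calls)
  if (!all(genes %in% rownames(features)))
    .err("calls contain genes absent from the feature table")
  ft <- features[genes, , drop = FALSE]
  filtered <- ifelse(ft$length_bp < minLength, "short_gene",
              ifelse(ft$expr_qrank < 0.5, "low_expression", "kept"))
  S4Vectors::DataFrame(
    score = calls$score,
    call = calls$call,
    filtered = filtered,
    final_call = ifelse(filtered == "kept", calls$call, "not_assessed"),
    row.names = genes
  )
}

#' Dataset dynamic-range quality check
#'
#' A dataset is informative for the MAE chromatin signature only if the two
#' marks separate genes: using the median H3K27me3 and median H3K36me3
#' normalized enrichment as thresholds, genes fall into four quadrants, and
#' the check passes when the two anti-correlated quadrants (low-K27/high-K36,
#' i.e. actively transcribed, and high-K27/low-K36, i.e. repressed) together
#' hold at least 50\% more genes than the two remaining quadrants.
#'
#' @param features Feature table with \code{k27_norm} and \code{k36_norm}.
#' @param ratio Required excess factor (default 1.5).
#' @return Named list: \code{n_low27_high36}, \code{n_high27_low36},
#'   \code{n_low27_low36}, \code{n_high27_high36}, \code{passed}.
#' @importFrom stats median
#' @export
qcDynamicRange <- function(features, ratio = 1.5) {
  if (nrow(features) < 4L) .err("dynamic-range QC needs at least 4 genes")
  hi27 <- features$k27_norm > stats::median(features$k27_norm)
  hi36 <- features$k36_norm > stats::median(features$k36_norm)
  qc <- list(
    n_low27_high36 = sum(!hi27 & hi36),
    n_high27_low36 = sum(hi27 & !hi36),
    n_low27_low36 = sum(!hi27 & !hi36),
    n_high27_high36 = sum(hi27 & hi36)
  )
  qc$passed <- (qc$n_low27_high36 + qc$n_high27_low36) >=
    ratio * (qc$n_low27_low36 + qc$n_high27_high36)
  qc
}

#' Run the MaGIC inference pipeline
#'
#' Evaluates the dynamic-range QC first and refuses datasets that fail it
#' unless \code{force = TRUE}; then classifies every gene with the ADTree
#' model and applies the length and median-expression filters. A summary of
#' call counts is emitted as a message.
#'
#' @param features Feature table from \code{\link{buildFeatureTable}}.
#' @param model \code{\linkS4class{ADTreeModel}}.
#' @param minLength Minimum gene length (bp) for the post-filter.
#' @param qcRatio Dynamic-range QC excess factor.
#' @param force Proceed (with a warning) when the QC fails.
#' @return A \code{\linkS4class{MagicResult}}.
#' @export
runMagic <- function(features, model, minLength = 2500L, qcRatio = 1.5,
                     force = FALSE) {
  qc <- qcDynamicRange(features, ratio = qcRatio)
  if (!qc$passed) {
    counts <- sprintf(
      "low27/high36=%d, high27/low36=%d, low27/low36=%d, high27/high36=%d",
      qc$n_low27_high36, qc$n_high27_low36, qc$n_low27_low36,
      qc$n_high27_high36)
    if (!force)
      .err(paste0("dataset failed the dynamic-range QC (", counts,
                  "); rerun with force = TRUE to classify anyway"))
    warning(paste0("dataset failed the dynamic-range QC (", counts,
                   "); proceeding because force = TRUE"), call. = FALSE)
  }
  calls <- classifyGenes(model, features)
  calls <- applyMagicFilters(calls, features, minLength = minLength)
  message(sprintf(
    "MaGIC: %d MAE, %d BAE, %d filtered (%d short, %d low expression)",
    sum(calls$final_call == "MAE"), sum(calls$final_call == "BAE"),
    sum(calls$filtered != "kept"), sum(calls$filtered == "short_gene"),
    sum(calls$filtered == "low_expression")))
  new("MagicResult", calls = calls, qc = qc)
}
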