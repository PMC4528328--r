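#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Alternating decision tree model for MAE inference
#'
#' An alternating decision tree (ADTree) over the two quantile-rank features
#' \code{k27_qrank} and \code{k36_qrank}. The score of a gene is the root
#' prediction plus the prediction values of every splitter node whose
#' precondition path is satisfied; genes with a strictly positive score are
#' called MAE (mosaic monoallelic expression), all others BAE.
#'
#' @slot rootPrediction Numeric scalar, the constant prediction added to every
#'   score; equals \eqn{\frac{1}{2}\log\frac{W_+ + 1}{W_- + 1}} on the
#'   training weights.
#' @slot nodes A \code{data.frame} with one row per splitter node and columns
#'   \code{node_id}, \code{precondition} (path encoded as
#'   \code{"id:branch"} steps joined by \code{","}; \code{""} is the always-true
#'   root precondition), \code{feature}, \code{threshold} (condition is
#'   \code{feature <= threshold}), \code{pred_true}, \code{pred_false}.
#' @slot nBoost Integer, number of boosting rounds requested.
#' @slot featureScaleTag Character scalar recording the feature scale the model
#'   was trained on (e.g. \code{"qrank-average-over-n"}); \code{classifyGenes}
#'   refuses feature tables carrying a different tag.
#' @slot weightTrace Numeric vector of the total training weight after the
#'   root and after each boosting round; non-increasing by the boosting
#'   guarantee. Diagnostic only, not part of the serialized model's scoring
#'   state.
#'
#' @seealso \code{\link{trainADTree}}, \code{\link{classifyGenes}},
#'   \code{\link{writeADTreeModel}}
#' @export
setClass("ADTreeModel",
  representation(
    rootPrediction = "numeric",
    nodes = "data.frame",
    nBoost = "integer",
    featureScaleTag = "character",
    weightTrace = "numeric"
  )
)

setValidity("ADTreeModel", function(object) {
  msg <- character()
  if (length(object@rootPrediction) != 1L || !is.finite(object@rootPrediction))
    msg <- c(msg, "rootPrediction must be a finite numeric scalar")
  nd <- object@nodes
  need <- c("node_id", "precondition", "feature", "threshold",
            "pred_true", "pred_false")
  if (!all(need %in% names(nd)))
    msg <- c(msg, paste("nodes must have columns:", paste(need, collapse = ", ")))
  else if (nrow(nd) > 0) {
    if (!all(nd$feature %in% c("k27_qrank", "k36_qrank")))
      msg <- c(msg, "node features must be k27_qrank or k36_qrank")
    if (!all(is.finite(nd$threshold)) ||
        !all(is.finite(nd$pred_true)) || !all(is.finite(nd$pred_false)))
      msg <- c(msg, "node thresholds and predictions must be finite")
    # preconditions may reference only earlier nodes
    for (i in seq_len(nrow(nd))) {
      refs <- .parsePrecondition(nd$precondition[i])$node_id
      if (length(refs) && any(!refs %in% nd$node_id[seq_len(i - 1L)]))
        msg <- c(msg, sprintf("node %d precondition references a later node",
                              nd$node_id[i]))
    }
  }
  if (length(object@nBoost) != 1L || object@nBoost < 1L)
    msg <- c(msg, "nBoost must be a positive integer")
  if (length(object@featureScaleTag) != 1L)
    msg <- c(msg, "featureScaleTag must be a single string")
  if (length(msg)) msg else TRUE
})

#' @describeIn ADTreeModel-class Compact display of the boosted tree.
#' @param object An \code{ADTreeModel}.
#' @export
setMethod("show", "ADTreeModel", function(object) {
  cat("ADTreeModel (alternating decision tree MAE classifier)\n")
  cat(sprintf("  root prediction : %.4f\n", object@rootPrediction))
  cat(sprintf("  splitter nodes  : %d (of %d boosting rounds)\n",
              nrow(object@nodes), object@nBoost))
  cat(sprintf("  feature scale   : %s\n", object@featureScaleTag))
  if (nrow(object@nodes)) {
    n <- min(5L, nrow(object@nodes))
    for (i in seq_len(n)) {
      nd <- object@nodes[i, ]
      pre <- if (nzchar(nd$precondition)) nd$precondition else "(root)"
      cat(sprintf("  [%d] %s | %s <= %.4f ? %+0.3f : %+0.3f\n", nd$node_id,
                  pre, nd$feature, nd$threshold, nd$pred_true, nd$pred_false))
    }
    if (nrow(object@nodes) > n) cat(sprintf("  ... %d more\n", nrow(object@nodes) - n))
  }
  invisible(NULL)
})

#' Result of a MaGIC run
#'
#' Bundles the per-gene classifier calls after filtering with the dataset
#' dynamic-range QC result.
#'
#' @slot calls A \code{DataFrame} keyed by gene with columns \code{score},
#'   \code{call} (raw classifier call), \code{filtered}
#'   (\code{kept}/\code{short_gene}/\code{low_expression}) and
#'   \code{final_call} (\code{MAE}/\code{BAE}/\code{not_assessed}).
#' @slot qc Named list with the four quadrant counts
#'   (\code{n_low27_high36}, \code{n_high27_low36}, \code{n_low27_low36},
#'   \code{n_high27_high36}) and \code{passed}.
#'
#' @seealso \code{\link{runMagic}}
#' @export
setClass("MagicResult",
  representation(calls = "DataFrame", qc = "list")
)

setValidity("MagicResult", function(object) {
  msg <- character()
  cl <- object@calls
  need <- c("score", "call", "filtered", "final_call")
  if (!all(need %in% colnames(cl)))
    msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
  else if (nrow(cl) > 0) {
    kept <- cl$filtered == "kept"
    if (!all(cl$final_call[kept] == cl$call[kept]))
      msg <- c(msg, "final_call must equal call for kept genes")
    if (!all(cl$final_call[!kept] == "not_assessed"))
      msg <- c(msg, "filtered genes must have final_call 'not_assessed'")
  }
  qneed <- c("n_low27_high36", "n_high27_low36", "n_low27_low36",
             "n_high27_high36", "passed")
  if (!all(qneed %in% names(object@qc)))
    msg <- c(msg, paste("qc must contain:", paste(qneed, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn MagicResult-class Summary display.
#' @param object A \code{MagicResult}.
#' @export
setMethod("show", "MagicResult", function(object) {
  cl <- object@calls
  cat("MagicResult\n")
  cat(sprintf("  genes assessed : %d\n", nrow(cl)))
  cat(sprintf("  MAE / BAE      : %d / %d\n",
              sum(cl$final_call == "MAE"), sum(cl$final_call == "BAE")))
  cat(sprintf("  filtered       : %d short, %d low expression\n",
              sum(cl$filtered == "short_gene"),
              sum(cl$filtered == "low_expression")))
  q <- object@qc
  cat(sprintf("  QC quadrants   : %d / %d / %d / %d -> %s\n",
              q$n_low27_high36, q$n_high27_low36, q$n_low27_low36,
              q$n_high27_high36, if (isTRUE(q$passed)) "passed" else "FAILED"))
  invisible(NULL)
})

#' @describeIn MagicResult-class Accessor for the per-gene call table.
#' @param x A \code{MagicResult}.
#' @export
magicCalls <- function(x) {
  stopifnot(is(x, "MagicResult"))
  x@calls
}

#' @describeIn MagicResult-class Accessor for the dynamic-range QC result.
#' @export
qcResult <- function(x) {
  stopifnot(is(x, "MagicResult"))
  x@qc
}
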