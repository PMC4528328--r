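# Alternating decision tree (Freund & Mason) over the two quantile-rank
# features. The boosted model is a root prediction plus splitter nodes; each
# node lives under a precondition path (a branch of an earlier node) and
# contributes pred_true or pred_false to the score of every instance whose
# path is satisfied.

# half log-odds with +1 smoothing: bounded predictions on pure partitions
.predValue <- function(wPos, wNeg) 0.5 * log((wPos + 1) / (wNeg + 1))

#' Train the alternating decision tree MAE classifier
#'
#' Boosted training over the features \code{k27_qrank} and \code{k36_qrank}:
#' instance weights start uniform; the root prediction is
#' \eqn{\frac{1}{2}\log\frac{W_+ + 1}{W_- + 1}}; each round adds, under the
#' existing precondition (path) minimizing
#' \deqn{Z = 2\left(\sqrt{W_+(P \wedge c) W_-(P \wedge c)} +
#'   \sqrt{W_+(P \wedge \neg c) W_-(P \wedge \neg c)}\right) + W(\neg P),}
#' a condition \eqn{c : feature \le t} with \eqn{t} ranging over midpoints of
#' consecutive distinct feature values, attaching branch predictions of the
#' same smoothed half log-odds form; weights update as
#' \eqn{w \leftarrow w\,e^{-y\,r(x)}} with \eqn{y = +1} for MAE. Classes are
#' weighted equally (no misclassification-cost asymmetry).
#'
#' The total training weight is recorded after every round
#' (\code{weightTrace} slot); the boosting construction guarantees it never
#' increases. If no candidate split improves on not splitting, training stops
#' early with a message.
#'
#' @param features \code{data.frame}, \code{DataFrame} or matrix with columns
#'   \code{k27_qrank} and \code{k36_qrank} in \eqn{(0, 1]}.
#' @param labels Character/factor vector of \code{"MAE"}/\code{"BAE"}, one per
#'   row of \code{features}; both classes must be present.
#' @param nBoost Number of boosting rounds (splitter nodes), default 10.
#' @param featureScaleTag Scale identifier stored in the model; must match the
#'   feature tables the model will be applied to.
#' @return An \code{\linkS4class{ADTreeModel}}.
#' @examples
#' set.seed(1)
#' n <- 400
#' f <- data.frame(k27_qrank = runif(n), k36_qrank = runif(n))
#' lab <- ifelse(f$k27_qrank > 0.6 & f$k36_qrank > 0.6, "MAE", "BAE")
#' m <- trainADTree(f, lab, nBoost = 6)
#' m
#' @export
trainADTree <- function(features, labels, nBoost = 10L,
                        featureScaleTag = .QRANK_SCALE_TAG) {
  feats <- c("k27_qrank", "k36_qrank")
  x <- as.data.frame(features)[, feats, drop = FALSE]
  if (anyNA(x)) .err("trainADTree: missing feature values")
  labels <- as.character(labels)
  if (!all(labels %in% c("MAE", "BAE")))
    .err("labels must be 'MAE' or 'BAE'")
  if (length(unique(labels)) < 2L)
    .err("training set must contain both MAE and BAE examples")
  if (length(labels) != nrow(x))
    .err("labels and features disagree in length")
  nBoost <- as.integer(nBoost)
  if (is.na(nBoost) || nBoost < 1L) .err("nBoost must be >= 1")

  n <- nrow(x)
  y <- ifelse(labels == "MAE", 1, -1)
  w <- rep(1, n)

  root <- .predValue(sum(w[y > 0]), sum(w[y < 0]))
  w <- w * exp(-y * root)
  trace <- sum(w)

  # preconditions as instance masks, keyed by encoded path
  preMasks <- list(rep(TRUE, n))
  prePaths <- ""

  nodes <- data.frame(node_id = integer(), precondition = character(),
                      feature = character(), threshold = numeric(),
                      pred_true = numeric(), pred_false = numeric(),
                      stringsAsFactors = FALSE)

  for (round in seq_len(nBoost)) {
    total <- sum(w)
    best <- list(z = Inf)
    for (p in seq_along(preMasks)) {
      mP <- preMasks[[p]]
      wNotP <- total - sum(w[mP])
      xs <- x[mP, , drop = FALSE]; ws <- w[mP]; ys <- y[mP]
      for (f in feats) {
        v <- xs[[f]]
        ord <- order(v)
        vs <- v[ord]
        wp <- cumsum(ifelse(ys[ord] > 0, ws[ord], 0))
        wm <- cumsum(ifelse(ys[ord] > 0, 0, ws[ord]))
        distinct <- which(diff(vs) > 0)      # split after these positions
        if (!length(distinct)) next
        WP <- wp[length(wp)]; WM <- wm[length(wm)]
        z <- 2 * (sqrt(wp[distinct] * wm[distinct]) +
                  sqrt((WP - wp[distinct]) * (WM - wm[distinct]))) + wNotP
        k <- which.min(z)
        if (z[k] < best$z) {
          idx <- distinct[k]
          best <- list(z = z[k], pre = p, feature = f,
                       threshold = (vs[idx] + vs[idx + 1]) / 2,
                       wpc = wp[idx], wmc = wm[idx],
                       wpn = WP - wp[idx], wmn = WM - wm[idx])
        }
      }
    }
    # no split strictly better than leaving the round empty: 2*sqrt(ab) on an
    # un-split precondition equals the best achievable only when nothing
    # separates; stop rather than add a vacuous node
    if (!is.finite(best$z) || best$z >= total - sqrt(.Machine$double.eps)) {
      message(sprintf(
        "trainADTree: no improving split at round %d; stopping with %d node(s)",
        round, nrow(nodes)))
      break
    }

    a <- .predValue(best$wpc, best$wmc)
    b <- .predValue(best$wpn, best$wmn)
    mP <- preMasks[[best$pre]]
    cond <- x[[best$feature]] <= best$threshold
    nodes[nrow(nodes) + 1L, ] <- list(round, prePaths[best$pre],
                                      best$feature, best$threshold, a, b)

    upd <- mP
    w[upd] <- w[upd] * exp(-y[upd] * ifelse(cond[upd], a, b))
    trace <- c(trace, sum(w))

    path <- prePaths[best$pre]
    preMasks <- c(preMasks, list(mP & cond, mP & !cond))
    prePaths <- c(prePaths,
                  .encodePrecondition(c(.parsePrecondition(path)$node_id, round),
                                      c(.parsePrecondition(path)$branch, TRUE)),
                  .encodePrecondition(c(.parsePrecondition(path)$node_id, round),
                                      c(.parsePrecondition(path)$branch, FALSE)))
  }

  new("ADTreeModel", rootPrediction = root, nodes = nodes,
      nBoost = nBoost, featureScaleTag = featureScaleTag,
      weightTrace = trace)
}

#' Score instances with an ADTree model
#'
#' The score of an instance is the root prediction plus, for every splitter
#' node whose precondition path is satisfied, \code{pred_true} if the node
#' condition (\code{feature <= threshold}) holds and \code{pred_false}
#' otherwise. Deterministic and independent of instance order.
#'
#' @param model An \code{\linkS4class{ADTreeModel}}.
#' @param features Table with columns \code{k27_qrank} and \code{k36_qrank}.
#' @return Numeric vector of scores.
#' @export
adtreeScore <- function(model, features) {
  stopifnot(is(model, "ADTreeModel"))
  x <- as.data.frame(features)
  n <- nrow(x)
  score <- rep(model@rootPrediction, n)
  nd <- model@nodes
  if (nrow(nd) == 0L || n == 0L) return(score)
  cond <- matrix(FALSE, n, max(nd$node_id))
  for (i in seq_len(nrow(nd))) {
    j <- nd$node_id[i]
    cond[, j] <- x[[nd$feature[i]]] <= nd$threshold[i]
    pre <- .parsePrecondition(nd$precondition[i])
    sat <- rep(TRUE, n)
    for (s in seq_len(nrow(pre)))
      sat <- sat & (cond[, pre$node_id[s]] == pre$branch[s])
    score <- score + ifelse(sat, ifelse(cond[, j], nd$pred_true[i],
                                        nd$pred_false[i]), 0)
  }
  score
}

#' Classify genes as MAE or BAE from quantile-rank features
#'
#' Applies an ADTree model to a gene feature table
#' (\code{\link{buildFeatureTable}}). The classifier recognizes MAE on a
#' strictly positive score; a score of exactly 0 is called BAE, so MAE calls
#' rest on positive evidence only. Genes with missing features are skipped
#' with a warning. The model's feature scale tag is checked against the
#' table's to prevent applying a model across incompatible rank scales.
#'
#' @param model An \code{\linkS4class{ADTreeModel}}.
#' @param features \code{DataFrame}/\code{data.frame} keyed by gene with
#'   \code{k27_qrank} and \code{k36_qrank}.
#' @return \code{DataFrame} keyed by gene with \code{score} and \code{call}
#'   (\code{"MAE"}/\code{"BAE"}).
#' @export
classifyGenes <- function(model, features) {
  stopifnot(is(model, "ADTreeModel"))
  tag <- S4Vectors::metadata(features)$feature_scale_tag
  if (!is.null(tag) && !identical(tag, model@featureScaleTag))
    .err("feature scale '%s' does not match model scale '%s'",
         tag, model@featureScaleTag)
  x <- as.data.frame(features)
  if (!all(c("k27_qrank", "k36_qrank") %in% names(x)))
    .err("features must contain k27_qrank and k36_qrank")
  ok <- !(is.na(x$k27_qrank) | is.na(x$k36_qrank))
  if (!all(ok))
    warning(sprintf("skipping %d gene(s) with missing features", sum(!ok)),
            call. = FALSE)
  sc <- adtreeScore(model, x[ok, , drop = FALSE])
  S4Vectors::DataFrame(
    score = sc,
    call = ifelse(sc > 0, "MAE", "BAE"),
    row.names = rownames(x)[ok]
  )
}

#' Serialize / deserialize an ADTree model
#'
#' The model file is versioned JSON holding the root prediction, the node
#' table, the number of boosting rounds and the feature scale tag. Numeric
#' values are written with 17 significant digits so that scores after a
#' write/read round trip are bit-identical.
#'
#' @param model An \code{\linkS4class{ADTreeModel}}.
#' @param path File path.
#' @return \code{writeADTreeModel}: \code{path} invisibly;
#'   \code{readADTreeModel}: the restored model.
#' @importFrom jsonlite toJSON fromJSON
#' @export
writeADTreeModel <- function(model, path) {
  stopifnot(is(model, "ADTreeModel"))
  obj <- list(
    format = "magicMAE-adtree",
    version = 1L,
    root_prediction = model@rootPrediction,
    n_boost = model@nBoost,
    feature_scale_tag = model@featureScaleTag,
    nodes = model@nodes
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname writeADTreeModel
#' @export
readADTreeModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "magicMAE-adtree"))
    .err("'%s' is not a magicMAE ADTree model file", path)
  nodes <- as.data.frame(obj$nodes)
  if (nrow(nodes) == 0L)
    nodes <- data.frame(node_id = integer(), precondition = character(),
                        feature = character(), threshold = numeric(),
                        pred_true = numeric(), pred_false = numeric())
  nodes$node_id <- as.integer(nodes$node_id)
  new("ADTreeModel",
      rootPrediction = as.numeric(obj$root_prediction),
      nodes = nodes,
      nBoost = as.integer(obj$n_boost),
      featureScaleTag = as.character(obj$feature_scale_tag),
      weightTrace = numeric())
}
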