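#' Gower distance between MAE profiles
#'
#' For binary MAE/BAE profiles with missing entries, the Gower coefficient on
#' symmetric binary traits reduces to the mismatch fraction over genes
#' informative (non-missing) in both samples; that pairwise restriction is
#' applied per sample pair rather than by global complete-case reduction.
#'
#' @param profiles Numeric matrix, genes x samples, entries 1 (MAE), 0 (BAE)
#'   or \code{NA} (gene not informative in that sample).
#' @return A \code{dist} object over samples (distance = mismatch fraction;
#'   similarity is \code{1 - distance}).
#' @importFrom stats as.dist
#' @export
gowerDistance <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("S", seq_len(ncol(profiles)))
  s <- ncol(profiles)
  if (s < 2L) .err("need at least 2 samples")
  if (!all(profiles %in% c(0, 1) | is.na(profiles)))
    .err("profile entries must be 0, 1 or NA")
  d <- matrix(0, s, s, dimnames = list(colnames(profiles), colnames(profiles)))
  for (i in seq_len(s - 1L)) for (j in (i + 1L):s) {
    shared <- !is.na(profiles[, i]) & !is.na(profiles[, j])
    if (!any(shared))
      .err("samples '%s' and '%s' share no informative genes",
           colnames(profiles)[i], colnames(profiles)[j])
    d[i, j] <- d[j, i] <- mean(profiles[shared, i] != profiles[shared, j])
  }
  stats::as.dist(d)
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage (UPGMA) agglomeration: repeatedly merge the closest pair
#' of clusters, placing the merge node at height \eqn{d/2} (so leaf-to-leaf
#' cophenetic distance equals the cluster distance), and update distances as
#' the size-weighted mean of the members' distances. Ties on the minimum
#' distance break deterministically on the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest leaf).
#'
#' @param d A \code{dist} object or symmetric matrix with zero diagonal.
#' @return An ultrametric \code{phylo} tree (leaves at height 0, branch
#'   lengths from merge heights); the merge table is attached as attribute
#'   \code{"merges"} (columns \code{label_a}, \code{label_b}, \code{height}).
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgmaTree(as.dist(d))
#' @importFrom ape read.tree
#' @export
upgmaTree <- function(d) {
  m <- as.matrix(d)
  s <- nrow(m)
  if (s < 2L) .err("need at least 2 items to cluster")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("S", seq_len(s))
  if (any(diag(m) != 0) || !isTRUE(all.equal(m, t(m))))
    .err("distance matrix must be symmetric with zero diagonal")

  cl <- lapply(seq_len(s), function(i)
    list(label = labs[i], size = 1L, height = 0, newick = labs[i]))
  merges <- data.frame(label_a = character(), label_b = character(),
                       height = numeric(), stringsAsFactors = FALSE)
  dm <- m
  while (length(cl) > 1L) {
    k <- length(cl)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      li <- cl[[i]]$label; lj <- cl[[j]]$label
      pair <- sort(c(li, lj))
      cand <- list(i = i, j = j, d = dm[i, j], p1 = pair[1], p2 = pair[2])
      if (is.null(best) || cand$d < best$d ||
          (cand$d == best$d && (cand$p1 < best$p1 ||
                                (cand$p1 == best$p1 && cand$p2 < best$p2))))
        best <- cand
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    ni <- cl[[i]]$size; nj <- cl[[j]]$size
    # order children by label for a deterministic newick string
    kids <- if (cl[[i]]$label <= cl[[j]]$label) c(i, j) else c(j, i)
    nwk <- sprintf("(%s:%.17g,%s:%.17g)",
                   cl[[kids[1]]]$newick, h - cl[[kids[1]]]$height,
                   cl[[kids[2]]]$newick, h - cl[[kids[2]]]$height)
    merges[nrow(merges) + 1L, ] <- list(best$p1, best$p2, h)
    newRow <- (ni * dm[i, ] + nj * dm[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newRow[keep]),
                c(newRow[keep], 0))
    cl <- c(cl[keep], list(list(label = min(cl[[i]]$label, cl[[j]]$label),
                                size = ni + nj, height = h, newick = nwk)))
  }
  tree <- ape::read.tree(text = paste0(cl[[1]]$newick, ";"))
  attr(tree, "merges") <- merges
  tree
}

#' Cluster samples by their MAE profiles
#'
#' All-pairs Gower distance over informative genes, UPGMA dendrogram, and the
#' pairwise similarity matrix (\code{1 - distance}) for heat-map display.
#'
#' @param profiles Genes x samples matrix of 1/0/\code{NA}
#'   (see \code{\link{gowerDistance}}).
#' @return List with \code{tree} (\code{phylo}), \code{distance}
#'   (\code{dist}) and \code{similarity} (matrix).
#' @export
clusterProfiles <- function(profiles) {
  d <- gowerDistance(profiles)
  sim <- 1 - as.matrix(d)
  diag(sim) <- 1
  list(tree = upgmaTree(d), distance = d, similarity = sim)
}

#' MAE proportion by expression breadth
#'
#' Groups genes by the number of samples in which they are expressed, then
#' within each bin computes, per sample, the proportion of MAE genes among
#' the expressed, determinate genes of that sample. Cell-type-specific genes
#' (narrow bins) are expected to be MAE far more often than ubiquitously
#' expressed ones.
#'
#' @param profiles Genes x samples matrix of 1/0/\code{NA}.
#' @param expressed Logical genes x samples matrix (same dimensions), whether
#'   the gene is expressed in the sample.
#' @return List with \code{per_sample} (\code{data.frame}: \code{bin},
#'   \code{sample}, \code{n_genes}, \code{proportion}) and \code{summary}
#'   (per-bin quartiles of the per-sample proportions for box plotting);
#'   empty bins are omitted.
#' @importFrom stats quantile
#' @export
specificityBins <- function(profiles, expressed) {
  profiles <- as.matrix(profiles); expressed <- as.matrix(expressed)
  if (!identical(dim(profiles), dim(expressed)))
    .err("profiles and expressed must have identical dimensions")
  if (anyNA(expressed)) .err("expressed must be defined for every gene/sample")
  bins <- rowSums(expressed)
  samples <- colnames(profiles)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(profiles)))
  rows <- list()
  for (b in sort(unique(bins[bins > 0]))) {
    inBin <- bins == b
    for (s in seq_along(samples)) {
      use <- inBin & expressed[, s] & !is.na(profiles[, s])
      if (!any(use)) next
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, sample = samples[s], n_genes = sum(use),
        proportion = mean(profiles[use, s] == 1),
        stringsAsFactors = FALSE)
    }
  }
  perSample <- do.call(rbind, rows)
  if (is.null(perSample)) .err("no expressed, determinate genes in any bin")
  summ <- do.call(rbind, lapply(split(perSample, perSample$bin), function(g) {
    q <- stats::quantile(g$proportion, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(bin = g$bin[1], n_samples = nrow(g),
               q1 = q[1], median = q[2], q3 = q[3])
  }))
  rownames(summ) <- NULL
  list(per_sample = perSample, summary = summ)
}
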