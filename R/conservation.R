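#' Restrict an orthology table to one-to-one pairs
#'
#' Orthology databases map some genes to several genes in the other species;
#' every pair involving a gene that occurs in more than one row (on either
#' side) is dropped, keeping only unambiguous one-to-one orthologs.
#'
#' @param pairs \code{data.frame} with columns \code{gene_a}, \code{gene_b}.
#' @return The filtered \code{data.frame}.
#' @examples
#' restrictOneToOne(data.frame(gene_a = c("a1", "a2", "a2"),
#'                             gene_b = c("b1", "b2", "b3")))
#' @export
restrictOneToOne <- function(pairs) {
  if (!all(c("gene_a", "gene_b") %in% names(pairs)))
    .err("pairs must have columns gene_a and gene_b")
  dupA <- pairs$gene_a %in% pairs$gene_a[duplicated(pairs$gene_a)]
  dupB <- pairs$gene_b %in% pairs$gene_b[duplicated(pairs$gene_b)]
  out <- pairs[!dupA & !dupB, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test conservation of MAE between two species
#'
#' Over one-to-one ortholog pairs with a determinate (MAE/BAE) call in both
#' species, computes the overlap expected under independence,
#' \eqn{p_A \, p_B \, N}, and the inclusive hypergeometric upper-tail
#' probability \eqn{P(X \ge observed)} with
#' \eqn{X \sim Hypergeom(N, K = } MAE in species A, \eqn{n = } MAE in species
#' B\eqn{)}. The tail is evaluated in log space, since conserved overlaps can
#' be astronomically unlikely under independence.
#'
#' @param pairs One-to-one ortholog table (\code{\link{restrictOneToOne}}).
#' @param callsA,callsB Named character vectors of \code{"MAE"}/\code{"BAE"}
#'   calls per gene in each species; pairs with a missing or indeterminate
#'   call in either species are excluded before counting.
#' @return List: \code{n_pairs}, \code{n_mae_a}, \code{n_mae_b}, \code{p_a},
#'   \code{p_b}, \code{expected_overlap}, \code{expected_overlap_rounded},
#'   \code{observed_overlap}, \code{hyper_p}, \code{log10_hyper_p}.
#' @importFrom stats phyper
#' @export
conservationTest <- function(pairs, callsA, callsB) {
  det <- function(v) v[v %in% c("MAE", "BAE")]
  callsA <- det(callsA); callsB <- det(callsB)
  keep <- pairs$gene_a %in% names(callsA) & pairs$gene_b %in% names(callsB)
  pairs <- pairs[keep, , drop = FALSE]
  N <- nrow(pairs)
  if (N == 0L) .err("no ortholog pairs with determinate calls in both species")
  maeA <- callsA[pairs$gene_a] == "MAE"
  maeB <- callsB[pairs$gene_b] == "MAE"
  K <- sum(maeA); n <- sum(maeB)
  obs <- sum(maeA & maeB)
  pA <- K / N; pB <- n / N
  logP <- stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(
    n_pairs = N, n_mae_a = K, n_mae_b = n,
    p_a = pA, p_b = pB,
    expected_overlap = pA * pB * N,
    expected_overlap_rounded = round(pA * pB * N),
    observed_overlap = obs,
    hyper_p = exp(logP),
    log10_hyper_p = logP / log(10)
  )
}
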