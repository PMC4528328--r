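#' Distribution of the true MAE sample count for one gene
#'
#' A gene predicted MAE in \eqn{k} of \eqn{n} samples is truly MAE in
#' \eqn{m} samples with probability
#' \deqn{P(m) = \binom{k}{m} a^m (1-a)^{k-m}, \quad m \le k,}
#' treating each MAE prediction as independently correct with probability
#' \eqn{a} (the MAE prediction accuracy) and taking BAE predictions at face
#' value, so \eqn{P(m) = 0} for \eqn{m > k}.
#'
#' @param k Number of samples where the gene was predicted MAE.
#' @param n Total number of samples.
#' @param accuracy MAE prediction accuracy \eqn{a \in (0, 1]}; 0.73 by
#'   default, the accuracy estimated for the clonal lymphoblast benchmark.
#' @return Numeric vector of probabilities over \eqn{m = 0, \dots, n}
#'   (named), summing to 1.
#' @examples
#' maeStateDistribution(2, 2)  # 0.0729 0.3942 0.5329
#' @importFrom stats dbinom
#' @export
maeStateDistribution <- function(k, n, accuracy = 0.73) {
  if (accuracy <= 0 || accuracy > 1) .err("accuracy must be in (0, 1]")
  if (k < 0 || k > n) .err("k must satisfy 0 <= k <= n")
  p <- numeric(n + 1L)
  p[seq_len(k + 1L)] <- stats::dbinom(0:k, k, accuracy)
  names(p) <- 0:n
  p
}

#' Correct multi-sample MAE counts for classifier accuracy
#'
#' Sums, for each possible number of samples \eqn{m}, the per-gene
#' probabilities \code{\link{maeStateDistribution}} of being truly MAE in
#' \eqn{m} samples. Each sum estimates the number of genes MAE in exactly
#' \eqn{m} samples; an expected count below 1 is reported as 0 (no gene).
#' Total probability is conserved: the expected counts sum to the number of
#' genes for any accuracy.
#'
#' @param k Integer vector: per gene, the number of samples predicted MAE.
#' @param n Total number of samples.
#' @param accuracy MAE prediction accuracy.
#' @return \code{data.frame} with \code{m}, \code{expected_count},
#'   \code{reported_count} (floored per the rule above).
#' @examples
#' correctedMaeCounts(rep(1, 10), n = 1)  # 7.3 genes MAE in one sample
#' @export
correctedMaeCounts <- function(k, n, accuracy = 0.73) {
  if (any(k < 0 | k > n)) .err("every k must satisfy 0 <= k <= n")
  expected <- Reduce(`+`, lapply(k, maeStateDistribution, n = n,
                                 accuracy = accuracy))
  expected <- unname(expected)
  data.frame(
    m = 0:n,
    expected_count = expected,
    reported_count = ifelse(expected >= 1, expected, 0)
  )
}
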