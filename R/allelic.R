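#' Mask SNP positions in reference sequences
#'
#' Replaces the base at each listed position with \code{N}. Aligning reads to
#' a SNP-masked reference removes the systematic mapping advantage of the
#' reference allele, a prerequisite for unbiased allele-specific counting.
#'
#' @param sequences A \code{DNAStringSet} (named records).
#' @param positions Named list (by record) of 1-based positions to mask;
#'   records absent from the list pass through unchanged.
#' @return A \code{DNAStringSet} with the same names.
#' @importFrom Biostrings DNAStringSet replaceLetterAt
#' @export
maskReference <- function(sequences, positions) {
  stopifnot(is(sequences, "DNAStringSet"))
  if (is.null(names(sequences))) .err("sequences must be named")
  bad <- setdiff(names(positions), names(sequences))
  if (length(bad))
    .err("positions refer to unknown record(s): %s",
         paste(utils::head(bad, 5), collapse = ", "))
  out <- sequences
  for (rec in names(positions)) {
    at <- as.integer(positions[[rec]])
    if (!length(at)) next
    len <- Biostrings::width(sequences[rec])
    if (any(at < 1L | at > len))
      .err("position %d out of range for record '%s' (length %d)",
           at[which(at < 1L | at > len)[1]], rec, len)
    out[[rec]] <- Biostrings::replaceLetterAt(sequences[[rec]], at,
                                              strrep("N", length(at)))
  }
  out
}

#' Aggregate SNP allele counts to genes
#'
#' Sums maternal and paternal read counts over all SNPs of each gene. Genes
#' without SNPs are absent from the result.
#'
#' @param snps SNP table (\code{\link{readSnpTable}}) with \code{gene_id},
#'   \code{maternal_count}, \code{paternal_count}.
#' @return \code{data.frame} with \code{gene_id}, \code{mat}, \code{pat},
#'   sorted by gene.
#' @export
aggregateSnpCounts <- function(snps) {
  mat <- rowsum(snps$maternal_count, snps$gene_id)
  pat <- rowsum(snps$paternal_count, snps$gene_id)
  data.frame(gene_id = rownames(mat), mat = mat[, 1], pat = pat[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call per-gene allelic expression state
#'
#' A gene is called \emph{monoallelic} when its maternal/paternal counts
#' deviate from 0.5 with Benjamini-Hochberg-corrected exact binomial
#' \eqn{q < \alpha} \emph{and} the major allele carries at least
#' \eqn{bias/(bias+1)} of the reads (2:1 bias by default). It is called
#' \emph{biallelic} on a positive equivalence test: two one-sided exact
#' binomial tests (TOST) showing the maternal fraction lies strictly inside
#' \code{eqBounds} (default 1/3..2/3, mirroring the 2:1 monoallelic bias),
#' both at level \eqn{\alpha}. Everything else, including genes below
#' \code{minTotal} total reads, is \emph{indeterminate}.
#'
#' The two-sided binomial p-value doubles the smaller exact tail, capped at 1.
#' BH correction runs once across all genes passing \code{minTotal}. The
#' procedure is symmetric in the maternal/paternal labels.
#'
#' @param counts \code{data.frame} from \code{\link{aggregateSnpCounts}}
#'   (\code{gene_id}, \code{mat}, \code{pat}).
#' @param alpha Significance level for both the binomial and equivalence
#'   tests.
#' @param bias Required major:minor ratio for a monoallelic call.
#' @param minTotal Minimum total reads per gene; below it the call is
#'   indeterminate.
#' @param eqBounds Lower/upper equivalence bounds on the maternal fraction.
#' @return \code{DataFrame} keyed by gene with \code{mat}, \code{pat},
#'   \code{n}, \code{major_fraction}, \code{p_binom}, \code{q_value},
#'   \code{p_eq_low}, \code{p_eq_high}, \code{call}
#'   (\code{monoallelic}/\code{biallelic}/\code{indeterminate}).
#' @examples
#' callAllelic(data.frame(gene_id = c("a", "b", "c"),
#'                        mat = c(30, 50, 6), pat = c(2, 50, 4)),
#'             minTotal = 10)
#' @importFrom stats pbinom p.adjust
#' @export
callAllelic <- function(counts, alpha = 0.05, bias = 2, minTotal = 20L,
                        eqBounds = c(1 / 3, 2 / 3)) {
  if (alpha <= 0 || alpha >= 1) .err("alpha must be in (0, 1)")
  if (length(eqBounds) != 2L || eqBounds[1] >= eqBounds[2])
    .err("eqBounds must be (low, high) with low < high")
  mat <- counts$mat; pat <- counts$pat
  if (any(mat < 0 | pat < 0) || any(mat != floor(mat) | pat != floor(pat)))
    .err("counts must be non-negative integers")
  n <- mat + pat
  majorFraction <- ifelse(n > 0, pmax(mat, pat) / n, NA_real_)

  # two-sided exact binomial vs 0.5: double the smaller tail, cap at 1
  pLow <- stats::pbinom(mat, n, 0.5)
  pHigh <- stats::pbinom(mat - 1, n, 0.5, lower.tail = FALSE)
  pBinom <- pmin(1, 2 * pmin(pLow, pHigh))

  # TOST: reject "fraction <= low" and "fraction >= high"
  pEqHigh <- stats::pbinom(mat - 1, n, eqBounds[1], lower.tail = FALSE)
  pEqLow <- stats::pbinom(mat, n, eqBounds[2])

  tested <- n >= minTotal
  q <- rep(NA_real_, length(n))
  q[tested] <- stats::p.adjust(pBinom[tested], method = "BH")

  biasFrac <- bias / (bias + 1)
  call <- rep("indeterminate", length(n))
  mono <- tested & !is.na(q) & q < alpha & majorFraction >= biasFrac
  bi <- tested & !mono & pEqLow < alpha & pEqHigh < alpha
  call[mono] <- "monoallelic"
  call[bi] <- "biallelic"

  S4Vectors::DataFrame(
    mat = as.integer(mat), pat = as.integer(pat), n = as.integer(n),
    major_fraction = majorFraction,
    p_binom = pBinom, q_value = q,
    p_eq_low = pEqLow, p_eq_high = pEqHigh,
    call = call,
    row.names = counts$gene_id
  )
}

#' Aggregate allelic calls across clonal lines
#'
#' RNA-Seq cannot measure mosaic monoallelic expression in a non-clonal
#' population directly, so calls from several clonal lines are combined into
#' a benchmark: a gene is MAE if it was called monoallelic in at least one
#' clone, BAE if it was called biallelic in at least one clone and
#' monoallelic in none, and indeterminate otherwise.
#'
#' @param cloneCalls List of per-clone call tables
#'   (\code{\link{callAllelic}}) or of named vectors of calls.
#' @return Named character vector over the union of genes, values
#'   \code{"MAE"}, \code{"BAE"}, \code{"indeterminate"}.
#' @export
aggregateClones <- function(cloneCalls) {
  if (!length(cloneCalls)) .err("need at least one clone")
  asVec <- function(x) {
    if (is.character(x)) return(x)
    stats::setNames(as.character(x$call), rownames(x))
  }
  vecs <- lapply(cloneCalls, asVec)
  genes <- sort(unique(unlist(lapply(vecs, names))))
  anyState <- function(state) Reduce(`|`, lapply(vecs, function(v) {
    out <- stats::setNames(rep(FALSE, length(genes)), genes)
    out[names(v)[v == state]] <- TRUE
    out
  }))
  mono <- anyState("monoallelic")
  bi <- anyState("biallelic")
  out <- rep("indeterminate", length(genes))
  out[bi] <- "BAE"
  out[mono] <- "MAE"
  stats::setNames(out, genes)
}

#' Concordance of chromatin-signature and allelic-expression calls
#'
#' Crosses MaGIC final calls with the allelic benchmark over genes that are
#' determinate (MAE or BAE) in both, producing the 2x2 contingency table,
#' Fisher's exact two-sided p-value, the sample odds ratio
#' \eqn{(tp \cdot tn)/(fp \cdot fn)}, and per-class confirmation rates
#' \eqn{tp/(tp+fp)} (MAE precision) and \eqn{tn/(tn+fn)}.
#'
#' @param magic Named vector of \code{"MAE"}/\code{"BAE"} calls, or a
#'   \code{\linkS4class{MagicResult}} / call table with \code{final_call}.
#' @param benchmark Named vector from \code{\link{aggregateClones}}.
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{tn},
#'   \code{fisher_p}, \code{odds_ratio}, \code{mae_confirmation},
#'   \code{bae_confirmation}, \code{n}.
#' @importFrom stats fisher.test setNames
#' @export
concordanceTable <- function(magic, benchmark) {
  if (is(magic, "MagicResult")) magic <- magicCalls(magic)
  if (!is.character(magic))
    magic <- stats::setNames(as.character(magic$final_call), rownames(magic))
  genes <- intersect(names(magic)[magic %in% c("MAE", "BAE")],
                     names(benchmark)[benchmark %in% c("MAE", "BAE")])
  if (!length(genes)) .err("no genes determinate in both call sets")
  m <- magic[genes]; b <- benchmark[genes]
  tp <- sum(m == "MAE" & b == "MAE")
  fp <- sum(m == "MAE" & b == "BAE")
  fn <- sum(m == "BAE" & b == "MAE")
  tn <- sum(m == "BAE" & b == "BAE")
  tab <- matrix(c(tp, fn, fp, tn), 2)
  orDefined <- all(c(tp + fp, fn + tn, tp + fn, fp + tn) > 0) && fp > 0 && fn > 0
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    fisher_p = stats::fisher.test(tab)$p.value,
    odds_ratio = if (orDefined) (tp * tn) / (fp * fn) else NA_real_,
    mae_confirmation = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    bae_confirmation = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    n = length(genes)
  )
}
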