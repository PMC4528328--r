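# encode/decode ADTree precondition paths: "3:TRUE,5:FALSE" etc.; "" = root
.parsePrecondition <- function(s) {
  if (!nzchar(s)) return(data.frame(node_id = integer(), branch = logical()))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  bits <- strsplit(parts, ":", fixed = TRUE)
  data.frame(
    node_id = vapply(bits, function(b) as.integer(b[1]), integer(1)),
    branch = vapply(bits, function(b) as.logical(b[2]), logical(1))
  )
}

.encodePrecondition <- function(node_id, branch) {
  if (!length(node_id)) return("")
  paste(sprintf("%d:%s", node_id, branch), collapse = ",")
}

#' Test chromosome names against an autosome pattern
#'
#' The MaGIC pipeline is restricted to autosomal genes; sex chromosomes and the
#' mitochondrial genome are excluded by name. Matching is a configurable
#' regular expression so that both UCSC-style (\code{chrX}) and Ensembl-style
#' (\code{X}) names are handled.
#'
#' @param chrom Character vector of chromosome names.
#' @param exclude Regular expression matching non-autosomal chromosome names.
#' @return Logical vector, \code{TRUE} for autosomes.
#' @examples
#' isAutosome(c("chr1", "chrX", "chrM", "2", "MT"))
#' @export
isAutosome <- function(chrom, exclude = "^(chr)?(X|Y|M|MT)$") {
  !grepl(exclude, as.character(chrom))
}

# stop() with call. = FALSE everywhere, consistent error surface
.err <- function(...) stop(sprintf(...), call. = FALSE)
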