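#' Transcripts-per-million normalisation
#'
#' The TPM of gene i with estimated count c_i and effective length l_i is
#' \eqn{10^6 (c_i/l_i) / \sum_j (c_j/l_j)}; TPM sums to one million per
#' sample whenever any count is positive. With all counts zero, all TPM are
#' zero (documented; no division error). Raw CDS length is an acceptable
#' effective length for this module's contract.
#'
#' @param counts named nonnegative numeric vector of estimated counts.
#' @param lengths named strictly positive numeric vector over the same gene
#'   ids.
#' @return data.frame of class \code{expression_table} with columns
#'   \code{gene}, \code{est_count}, \code{effective_length}, \code{tpm}.
#' @export
tpm <- function(counts, lengths) {
  if (!setequal(names(counts), names(lengths)))
    stop("counts and lengths must cover the same gene ids")
  lengths <- lengths[names(counts)]
  if (any(lengths <= 0)) stop("lengths must be strictly positive")
  if (any(counts < 0)) stop("counts must be nonnegative")
  rate <- counts / lengths
  tot <- sum(rate)
  val <- if (tot > 0) 1e6 * rate / tot else rate * 0
  out <- data.frame(gene = names(counts), est_count = as.numeric(counts),
                    effective_length = as.numeric(lengths),
                    tpm = as.numeric(val), stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Between-sample expression ratios
#'
#' Per-gene TPM ratio (a + pseudocount) / (b + pseudocount) over the shared
#' gene ids; genes absent from either table are omitted with a warning. The
#' default pseudocount of 0.5 stabilises ratios on sparse silk-gene tables.
#'
#' @param a,b \code{expression_table}s (see \code{\link{tpm}}).
#' @param pseudocount nonnegative stabiliser added to both TPM values.
#' @return named numeric vector of ratios.
#' @export
expression_ratio <- function(a, b, pseudocount = 0.5) {
  stopifnot(inherits(a, "expression_table"), inherits(b, "expression_table"))
  shared <- intersect(a$gene, b$gene)
  missing <- union(setdiff(a$gene, b$gene), setdiff(b$gene, a$gene))
  if (length(missing))
    warning("gene(s) absent from one table, omitted: ",
            paste(missing, collapse = ", "))
  ta <- setNames(a$tpm, a$gene)[shared]
  tb <- setNames(b$tpm, b$gene)[shared]
  (ta + pseudocount) / (tb + pseudocount)
}

#' Proteome composition shares
#'
#' Fraction of total intensity attributed to each protein group (e.g.
#' spidroin family): share_g = sum of intensities in g / total intensity.
#'
#' @param intensities named nonnegative numeric vector (per protein).
#' @param groups named character vector mapping the same protein ids to
#'   group labels; when missing, each protein is its own group.
#' @return named numeric vector of shares summing to 1.
#' @export
proteome_shares <- function(intensities, groups = NULL) {
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  tot <- sum(intensities)
  if (tot == 0) stop("all intensities are zero")
  if (is.null(groups)) groups <- setNames(names(intensities),
                                          names(intensities))
  g <- groups[names(intensities)]
  s <- tapply(intensities, g, sum) / tot
  setNames(as.numeric(s), names(s))
}
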