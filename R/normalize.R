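## Normalization: RPMPCG for RNA-seq counts, 75th-percentile scaling for
## miRNA signal.

#' RPMPCG normalization
#'
#' Reads per million protein-coding genes: each gene's count in a sample is
#' divided by that sample's total protein-coding count and multiplied by
#' 10^6. Linear in the counts for fixed totals and invariant to a common
#' rescaling of counts and totals.
#'
#' @param expr a [paired_expression_set()].
#' @return list with `values` (gene x sample matrix in RPMPCG units),
#'   `method = "rpmpcg"`, and the sample metadata carried through.
#' @export
rpmpcg <- function(expr) {
  stopifnot(inherits(expr, "paired_expression_set"))
  tot <- expr$pc_totals
  if (any(tot <= 0)) {
    stop("non-positive protein-coding total for sample(s): ",
         paste(names(tot)[tot <= 0], collapse = ", "))
  }
  values <- sweep(expr$counts, 2, tot, "/") * 1e6
  list(values = values, method = "rpmpcg", sample_meta = expr$sample_meta)
}

#' 75th-percentile scaling of miRNA signal
#'
#' Each sample is multiplied by a scaling factor equal to the median of the
#' 75th percentiles of all samples divided by that sample's own 75th
#' percentile. After scaling, every sample's 75th percentile equals the
#' pre-scaling median of 75th percentiles, which makes the operation
#' idempotent (up to floating point). Percentiles use the package-wide
#' type-7 convention; the median over an even number of samples is the mean
#' of the two central values.
#'
#' @param m a [mirna_matrix()].
#' @return a scaled [mirna_matrix()] (`scaled = TRUE`).
#' @export
scale_mirna <- function(m) {
  stopifnot(inherits(m, "mirna_matrix"))
  q75 <- apply(m$signal, 2, pctl, p = 0.75)
  if (any(q75 <= 0)) {
    stop("non-positive 75th percentile in sample(s): ",
         paste(colnames(m$signal)[q75 <= 0], collapse = ", "))
  }
  factors <- stats::median(q75) / q75
  out <- sweep(m$signal, 2, factors, "*")
  mirna_matrix(out, m$sample_meta, scaled = TRUE)
}
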