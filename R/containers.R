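## Core data containers. Deliberately light-weight: classed lists over base
## matrices and data frames, validated at construction.

#' Paired expression set
#'
#' Holds a gene-by-sample count matrix together with per-sample total
#' protein-coding counts (the exposure used by RPMPCG normalization and by
#' the paired negative-binomial model) and the sample-to-subject pairing.
#'
#' @param counts gene x sample matrix of nonnegative integers, with gene
#'   rownames and sample colnames.
#' @param pc_totals named vector of positive per-sample protein-coding
#'   totals; names must match `colnames(counts)`.
#' @param sample_meta data frame with columns `sample_id`, `subject_id`,
#'   `tissue` (`"carcinoma"` or `"normal"`); every subject must contribute
#'   exactly one sample of each tissue.
#' @return an object of class `paired_expression_set`.
#' @export
paired_expression_set <- function(counts, pc_totals, sample_meta) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop_invalid("counts must be nonnegative")
  req <- c("sample_id", "subject_id", "tissue")
  if (!all(req %in% names(sample_meta))) {
    stop_invalid("sample_meta needs columns ",
                 paste(req, collapse = ", "))
  }
  if (!all(sample_meta$tissue %in% c("carcinoma", "normal"))) {
    stop_invalid("tissue must be 'carcinoma' or 'normal'")
  }
  if (!setequal(colnames(counts), sample_meta$sample_id) ||
      anyDuplicated(sample_meta$sample_id)) {
    stop_invalid("sample ids in counts and sample_meta must match 1:1")
  }
  if (is.null(names(pc_totals))) names(pc_totals) <- colnames(counts)
  pc_totals <- pc_totals[colnames(counts)]
  if (anyNA(pc_totals) || any(pc_totals <= 0)) {
    bad <- colnames(counts)[is.na(pc_totals) | pc_totals <= 0]
    stop_invalid("non-positive protein-coding total for sample(s): ",
                 paste(bad, collapse = ", "))
  }
  tab <- table(sample_meta$subject_id, sample_meta$tissue)
  if (!all(tab == 1L)) {
    stop_invalid("every subject must have exactly one carcinoma and one ",
                 "normal sample")
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, pc_totals = pc_totals,
                 sample_meta = sample_meta),
            class = "paired_expression_set")
}

#' @export
print.paired_expression_set <- function(x, ...) {
  cat("paired_expression_set:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples (",
      length(unique(x$sample_meta$subject_id)), "subjects )\n")
  invisible(x)
}

#' Subset a paired expression set by subject
#'
#' Keeps both samples of each retained subject; used for MSI/MSS-restricted
#' reanalyses.
#'
#' @param expr a [paired_expression_set()].
#' @param subjects character vector of subject ids to keep.
#' @return a smaller `paired_expression_set`.
#' @export
subset_subjects <- function(expr, subjects) {
  keep <- expr$sample_meta$subject_id %in% subjects
  if (!any(keep)) stop_invalid("no samples left after subject subset")
  paired_expression_set(expr$counts[, expr$sample_meta$sample_id[keep],
                                    drop = FALSE],
                        expr$pc_totals[expr$sample_meta$sample_id[keep]],
                        expr$sample_meta[keep, ])
}

#' miRNA signal matrix
#'
#' @param signal miRNA x sample matrix of nonnegative signal values.
#' @param sample_meta as in [paired_expression_set()].
#' @param scaled logical; `TRUE` once 75th-percentile scaling has been
#'   applied.
#' @return an object of class `mirna_matrix`.
#' @export
mirna_matrix <- function(signal, sample_meta, scaled = FALSE) {
  stopifnot(is.matrix(signal), !is.null(rownames(signal)),
            !is.null(colnames(signal)))
  if (any(signal < 0) || any(!is.finite(signal))) {
    stop_invalid("signal must be finite and nonnegative")
  }
  if (!setequal(colnames(signal), sample_meta$sample_id)) {
    stop_invalid("sample ids in signal and sample_meta must match")
  }
  sample_meta <- sample_meta[match(colnames(signal), sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL
  structure(list(signal = signal, sample_meta = sample_meta,
                 scaled = isTRUE(scaled)),
            class = "mirna_matrix")
}

#' @export
print.mirna_matrix <- function(x, ...) {
  cat("mirna_matrix:", nrow(x$signal), "miRNAs x", ncol(x$signal),
      "samples;", if (x$scaled) "75th-percentile scaled" else "raw", "\n")
  invisible(x)
}
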