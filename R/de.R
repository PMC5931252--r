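## Paired carcinoma-vs-normal differential expression: negative-binomial
## regression with a log protein-coding-total offset, a tissue fixed
## effect, and per-subject intercepts absorbing the pairing.

#' Paired negative-binomial fit for one gene
#'
#' Fits counts ~ tissue + subject + offset(log(pc_total)) with a negative-
#' binomial log-link model; the per-subject intercepts absorb the pairing
#' (with two observations per subject this approximates the paired
#' contrast of a random-intercept model). The dispersion is initialised by
#' maximum likelihood ([MASS::glm.nb()]) and then re-estimated with a
#' residual-degrees-of-freedom-corrected moment estimator
#' ([MASS::theta.mm()] with df = n - p): with one nuisance intercept per
#' subject the ML dispersion is inconsistent (a Neyman-Scott effect) and
#' produces anticonservative Wald tests, while the df-corrected estimator
#' restores calibration. The Wald statistic for the tissue effect is
#' referred to a t distribution on the residual df; the dispersion is
#' floored at 1e-8. `mode = "glmm"` fits the random-intercept NB-GLMM
#' instead (Laplace approximation via \pkg{lme4}, if installed).
#'
#' @param expr a [paired_expression_set()].
#' @param gene gene id (rowname of `expr$counts`).
#' @param mode `"fixed"` (default, deterministic) or `"glmm"`.
#' @return list with `gene`, `fc_model` (exp of the tissue coefficient),
#'   `p` (Wald p-value for the tissue effect), `log_fc`, `se`,
#'   `dispersion`, and `converged`.
#' @export
fit_paired_nb <- function(expr, gene, mode = c("fixed", "glmm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "paired_expression_set"))
  if (!gene %in% rownames(expr$counts)) stop("unknown gene: ", gene)
  y <- expr$counts[gene, ]
  if (all(y == 0)) {
    stop("gene ", gene, " has all-zero counts; cannot fit")
  }
  meta <- expr$sample_meta
  n_pairs <- length(unique(meta$subject_id))
  if (n_pairs < 3) stop("need at least 3 complete pairs")
  d <- data.frame(
    y = as.numeric(y),
    tissue = factor(meta$tissue, levels = c("normal", "carcinoma")),
    subject = factor(meta$subject_id),
    off = log(expr$pc_totals[meta$sample_id])
  )
  converged <- TRUE
  if (mode == "glmm") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      stop("mode = 'glmm' requires the lme4 package")
    }
    fit <- lme4::glmer.nb(y ~ tissue + (1 | subject) + offset(off),
                          data = d)
    sm <- summary(fit)$coefficients
    est <- sm["tissuecarcinoma", "Estimate"]
    se <- sm["tissuecarcinoma", "Std. Error"]
    p <- sm["tissuecarcinoma", "Pr(>|z|)"]
    theta <- lme4::getME(fit, "glmer.nb.theta")
  } else {
    fit <- withCallingHandlers(
      MASS::glm.nb(y ~ tissue + subject + offset(off), data = d),
      warning = function(w) {
        if (grepl("iteration limit|converge", conditionMessage(w))) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }
      })
    if (!fit$converged) converged <- FALSE
    n_obs <- nrow(d)
    dfr <- n_obs - (n_pairs + 1L)       # residual df of the paired design
    theta <- max(fit$theta, 1e-8)
    # df-corrected moment dispersion, iterated to a fixed point
    for (it in 1:4) {
      th_new <- suppressWarnings(
        MASS::theta.mm(d$y, stats::fitted(fit), dfr = dfr))
      if (!is.finite(th_new) || th_new <= 0) break
      fit <- suppressWarnings(
        stats::glm(y ~ tissue + subject + offset(off), data = d,
                   family = MASS::negative.binomial(th_new)))
      done <- abs(th_new - theta) < 1e-3 * theta
      theta <- max(th_new, 1e-8)
      if (done) break
    }
    sm <- summary(fit)$coefficients
    est <- sm["tissuecarcinoma", "Estimate"]
    se <- sm["tissuecarcinoma", "Std. Error"]
    p <- 2 * stats::pt(-abs(est / se), df = dfr)
  }
  list(gene = gene, fc_model = exp(est), p = unname(p), log_fc = unname(est),
       se = unname(se), dispersion = theta, converged = converged)
}

#' Fold change from group means
#'
#' The ratio of mean carcinoma expression to mean normal expression, the
#' quantity printed in report tables (rounded half-even to 2 decimals
#' there). Values above 1 indicate up-regulation in carcinoma.
#'
#' @param mean_carcinoma,mean_normal mean normalized expression per tissue.
#' @return the fold-change ratio (unrounded).
#' @export
fold_change_from_means <- function(mean_carcinoma, mean_normal) {
  if (any(mean_normal <= 0)) {
    stop("fold change undefined: mean normal expression must be > 0")
  }
  mean_carcinoma / mean_normal
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment (monotone, capped at 1), preserving input order.
#' Delegates to [stats::p.adjust()] after validating the inputs.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order and length.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify a fold change into bands
#'
#' Strong down-regulation below `low`, strong up-regulation above `high`,
#' `within` otherwise. Inequalities are strict, so boundary values (e.g. a
#' fold change of exactly 1.50) fall in `within`.
#'
#' @param fc_ratio positive fold change(s).
#' @param low,high band thresholds (defaults 0.67 and 1.50).
#' @return character vector over `{"down_strong", "within", "up_strong"}`.
#' @export
classify_fc <- function(fc_ratio, low = 0.67, high = 1.50) {
  if (any(fc_ratio <= 0)) stop("fold changes must be positive")
  ifelse(fc_ratio < low, "down_strong",
         ifelse(fc_ratio > high, "up_strong", "within"))
}

#' Differential-expression table for a gene panel
#'
#' Runs the paired NB model per gene, computes the tissue mean RPMPCG
#' values and their ratio, BH-adjusts the Wald p-values across the panel,
#' and classifies each gene's fold change. Genes whose fit fails (all-zero
#' counts, hard non-convergence) are reported with a diagnostic in the
#' `note` column rather than dropped silently.
#'
#' @param expr a [paired_expression_set()].
#' @param genes gene ids to analyse (default: all rows).
#' @param fc_low,fc_high band thresholds passed to [classify_fc()].
#' @param mode estimator mode passed to [fit_paired_nb()].
#' @return data frame with columns `gene`, `mean_carcinoma`, `mean_normal`,
#'   `fc_ratio`, `fc_model`, `p`, `p_adj`, `band`, `note`.
#' @export
de_table <- function(expr, genes = rownames(expr$counts),
                     fc_low = 0.67, fc_high = 1.50,
                     mode = c("fixed", "glmm")) {
  mode <- match.arg(mode)
  norm <- rpmpcg(expr)
  tum <- expr$sample_meta$tissue == "carcinoma"
  res <- lapply(genes, function(g) {
    mc <- mean(norm$values[g, tum])
    mn <- mean(norm$values[g, !tum])
    fit <- tryCatch(fit_paired_nb(expr, g, mode = mode),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(gene = g, mean_carcinoma = mc, mean_normal = mn,
                        fc_ratio = if (mn > 0) mc / mn else NA_real_,
                        fc_model = NA_real_, p = NA_real_,
                        note = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    }
    data.frame(gene = g, mean_carcinoma = mc, mean_normal = mn,
               fc_ratio = if (mn > 0) mc / mn else NA_real_,
               fc_model = fit$fc_model, p = fit$p,
               note = if (fit$converged) "" else "non-convergence flagged",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_fdr(out$p[ok])
  out$band <- NA_character_
  okfc <- !is.na(out$fc_ratio) & out$fc_ratio > 0
  out$band[okfc] <- classify_fc(out$fc_ratio[okfc], fc_low, fc_high)
  out[, c("gene", "mean_carcinoma", "mean_normal", "fc_ratio", "fc_model",
          "p", "p_adj", "band", "note")]
}

#' Reference differential-expression table for the cell-cycle panel
#'
#' Published per-gene mean RPMPCG expression (carcinoma and normal mucosa)
#' and 2-dp fold changes for the 71 cell-cycle genes that passed the
#' band-and-FDR filter in a paired colorectal carcinoma study of 217
#' subjects (67 in the overall analysis, plus one MSS-specific and three
#' MSI-specific genes). Used as a worked input for fold-change and banding
#' computations.
#'
#' @param subset `"overall"` (default) restricts to the 67 overall-analysis
#'   genes; `"all"` returns all 71 rows.
#' @return data frame with columns `gene`, `mean_carcinoma`, `mean_normal`,
#'   `fold_change`, `subset`.
#' @export
cellcycle_de_reference <- function(subset = c("overall", "all")) {
  subset <- match.arg(subset)
  path <- system.file("extdata", "cellcycle_de_reference.tsv",
                      package = "ccmirnet", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (subset == "overall") d <- d[d$subset == "overall", ]
  rownames(d) <- NULL
  d
}

#' Round half-even to 2 decimals (report-table convention)
#' @param x numeric.
#' @return `x` rounded to 2 decimals with banker's rounding.
#' @export
round2 <- function(x) round(x, 2)
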