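## Gene-miRNA association on subject-level differential profiles:
## least-squares regression of the mRNA differential profile on the miRNA
## differential profile, adjusted for age and sex, with bootstrap-F
## p-values obtained by resampling residuals from the null (no-association)
## model.

#' Subject-level differential profiles
#'
#' For every feature, the per-subject difference between its value in the
#' carcinoma sample and the normal sample (carcinoma minus normal).
#' Subjects lacking either tissue are dropped with a warning; a duplicated
#' tissue within a subject is an error.
#'
#' @param values feature x sample matrix (normalized expression or scaled
#'   miRNA signal).
#' @param sample_meta data frame with `sample_id`, `subject_id`, `tissue`.
#' @return feature x subject matrix of differences.
#' @export
make_differential_profiles <- function(values, sample_meta) {
  stopifnot(all(c("sample_id", "subject_id", "tissue") %in%
                  names(sample_meta)))
  sample_meta <- sample_meta[sample_meta$sample_id %in% colnames(values), ]
  tab <- table(sample_meta$subject_id, sample_meta$tissue)
  if (any(tab > 1L)) {
    stop("duplicate tissue sample for subject(s): ",
         paste(rownames(tab)[apply(tab > 1, 1, any)], collapse = ", "))
  }
  complete <- rownames(tab)[rowSums(tab == 1L) == 2L &
                              all(c("carcinoma", "normal") %in%
                                    colnames(tab))]
  dropped <- setdiff(rownames(tab), complete)
  if (length(dropped)) {
    warning(length(dropped), " subject(s) lacking a tissue dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(complete)) stop("no complete carcinoma/normal pairs")
  carc <- sample_meta$sample_id[match(paste(complete, "carcinoma"),
                                      paste(sample_meta$subject_id,
                                            sample_meta$tissue))]
  norm <- sample_meta$sample_id[match(paste(complete, "normal"),
                                      paste(sample_meta$subject_id,
                                            sample_meta$tissue))]
  out <- values[, carc, drop = FALSE] - values[, norm, drop = FALSE]
  colnames(out) <- complete
  out
}

#' Expression filter for miRNAs
#'
#' Keeps a miRNA when the fraction of normal-tissue samples with signal
#' strictly greater than zero exceeds `min_fraction` (strict inequality:
#' exactly 20% of samples does not pass the default filter).
#'
#' @param m a [mirna_matrix()].
#' @param min_fraction minimum expressed fraction (default 0.20).
#' @return character vector of retained miRNA ids.
#' @export
filter_mirnas <- function(m, min_fraction = 0.20) {
  stopifnot(inherits(m, "mirna_matrix"))
  norm_cols <- m$sample_meta$sample_id[m$sample_meta$tissue == "normal"]
  if (!length(norm_cols)) stop("no normal-tissue samples present")
  frac <- rowMeans(m$signal[, norm_cols, drop = FALSE] > 0)
  rownames(m$signal)[frac > min_fraction]
}

#' Least-squares gene-miRNA association fit
#'
#' Full model: mrna_diff ~ mirna_diff + age + sex; null model drops the
#' miRNA term. Age is centred and sex entered as a male indicator (neither
#' changes the slope of interest or the F statistic). Returns the nested-
#' model F statistic with (1, n - 4) degrees of freedom together with the
#' null-model fit needed for the residual bootstrap.
#'
#' @param y numeric vector, mRNA differential profile per subject.
#' @param x numeric vector, miRNA differential profile per subject.
#' @param age,sex covariates per subject (`sex` coded `"male"`/`"female"`
#'   or 0/1).
#' @return list with `beta`, `f_obs`, `df`, `n`, `fitted_null`,
#'   `resid_null`, and the design matrices used.
#' @export
fit_linear <- function(y, x, age, sex) {
  n <- length(y)
  stopifnot(length(x) == n, length(age) == n, length(sex) == n)
  if (n < 5) stop("need n >= 5 subjects for the 4-parameter model")
  if (sd(x) == 0) stop("degenerate predictor: miRNA profile has zero variance")
  male <- if (is.character(sex) || is.factor(sex)) {
    as.numeric(sex == "male")
  } else as.numeric(sex)
  age_c <- age - mean(age)
  X_full <- cbind(1, x, age_c, male)
  X_null <- X_full[, -2, drop = FALSE]
  qf <- qr(X_full)
  qn <- qr(X_null)
  cf <- qr.coef(qf, y)
  rss_full <- sum(qr.resid(qf, y)^2)
  rss_null <- sum(qr.resid(qn, y)^2)
  df2 <- n - qf$rank
  f_obs <- ((rss_null - rss_full) / 1) / (rss_full / df2)
  list(beta = unname(cf[2]), f_obs = f_obs, df = c(1, df2), n = n,
       fitted_null = qr.fitted(qn, y), resid_null = qr.resid(qn, y),
       qr_full = qf, qr_null = qn, y = y)
}

## F statistics for many bootstrap responses at once, via the QR
## decompositions of the two nested designs. RSS(y) = |y|^2 - |Q'y|^2.
nested_f_many <- function(qf, qn, Y) {
  qQf <- qr.qty(qf, Y)[seq_len(qf$rank), , drop = FALSE]
  qQn <- qr.qty(qn, Y)[seq_len(qn$rank), , drop = FALSE]
  tot <- colSums(Y^2)
  rss_full <- tot - colSums(qQf^2)
  rss_null <- tot - colSums(qQn^2)
  df2 <- nrow(Y) - qf$rank
  ((rss_null - rss_full) / 1) / (rss_full / df2)
}

#' Residual-bootstrap F p-value
#'
#' Resamples the null-model residuals with replacement, adds them to the
#' null fitted values, recomputes the nested F statistic for each bootstrap
#' response (covariates held fixed), and reports
#' p = (1 + #\{F* >= F_obs\}) / (n_boot + 1). The +1 correction keeps the
#' p-value off zero, so p lies in \[1/(n_boot + 1), 1\].
#'
#' @param fit output of [fit_linear()].
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param rng_seed integer seed for the resampling stream.
#' @return bootstrap p-value.
#' @export
bootstrap_f_pvalue <- function(fit, n_boot = 10000L, rng_seed = 1L) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  n <- fit$n
  f_star <- with_seed(rng_seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    Y <- matrix(fit$fitted_null + fit$resid_null[idx], nrow = n)
    nested_f_many(fit$qr_full, fit$qr_null, Y)
  })
  (1 + sum(f_star >= fit$f_obs)) / (n_boot + 1)
}

#' Gene-level FDR for association records
#'
#' BH adjustment applied within each gene, across that gene's tested
#' miRNAs, independently of other genes.
#'
#' @param records data frame with columns `gene` and `p_boot`.
#' @return `records` with an `fdr_gene` column appended.
#' @export
gene_level_fdr <- function(records) {
  stopifnot(all(c("gene", "p_boot") %in% names(records)))
  records$fdr_gene <- NA_real_
  for (g in unique(records$gene)) {
    i <- which(records$gene == g)
    if (!length(i)) {
      warning("empty gene group skipped: ", g)
      next
    }
    records$fdr_gene[i] <- bh_fdr(records$p_boot[i])
  }
  records
}

#' Run the association stage over a candidate set
#'
#' Tests every (gene, miRNA) candidate pair: OLS slope, nested F, residual-
#' bootstrap p-value (a deterministic per-pair sub-seed is derived from
#' `rng_seed`), then gene-level BH. Direction is the sign of the slope.
#'
#' @param mrna_profiles,mirna_profiles feature x subject matrices from
#'   [make_differential_profiles()] (shared subject columns).
#' @param cohort cohort table with `subject_id`, `age`, `sex`.
#' @param pairs data frame with columns `gene`, `mirna`; default is the
#'   full cross of the profile rownames.
#' @param n_boot bootstrap resamples per pair.
#' @param rng_seed base seed.
#' @return data frame of association records: `gene`, `mirna`, `beta`,
#'   `f_obs`, `p_boot`, `fdr_gene`, `n_boot`, `direction`.
#' @export
associate_all <- function(mrna_profiles, mirna_profiles, cohort,
                          pairs = NULL, n_boot = 10000L, rng_seed = 1L) {
  subj <- intersect(colnames(mrna_profiles), colnames(mirna_profiles))
  subj <- intersect(subj, cohort$subject_id)
  if (!length(subj)) stop("no shared subjects between profiles and cohort")
  cohort <- cohort[match(subj, cohort$subject_id), ]
  if (is.null(pairs)) {
    pairs <- expand.grid(gene = rownames(mrna_profiles),
                         mirna = rownames(mirna_profiles),
                         stringsAsFactors = FALSE)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene[i]; m <- pairs$mirna[i]
    fit <- fit_linear(mrna_profiles[g, subj], mirna_profiles[m, subj],
                      cohort$age, cohort$sex)
    p <- bootstrap_f_pvalue(fit, n_boot,
                            substream_seed(rng_seed, "boot", i))
    data.frame(gene = g, mirna = m, beta = fit$beta, f_obs = fit$f_obs,
               p_boot = p, n_boot = as.integer(n_boot),
               direction = if (fit$beta > 0) "positive" else
                 if (fit$beta < 0) "negative" else "none",
               stringsAsFactors = FALSE)
  })
  gene_level_fdr(do.call(rbind, res))
}
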