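# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive re-derivations (brute force, normal
# equations, sort/cummin) so they stay independent of the implementation
# paths they check.

# Benjamini-Hochberg by explicit sort / scale / cumulative-min / unsort.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Least squares by the normal equations, plus the nested F statistic.
ols_oracle <- function(y, x, age, sex) {
  male <- as.numeric(sex == "male")
  Xf <- cbind(1, x, age - mean(age), male)
  Xn <- Xf[, -2, drop = FALSE]
  bf <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  bn <- solve(t(Xn) %*% Xn, t(Xn) %*% y)
  rss_f <- sum((y - Xf %*% bf)^2)
  rss_n <- sum((y - Xn %*% bn)^2)
  df2 <- length(y) - ncol(Xf)
  list(beta = bf[2], f = ((rss_n - rss_f) / 1) / (rss_f / df2))
}

# Naive O(n*m) substring scan: character-by-character comparison, all
# overlapping occurrences, 1-based starts. N in the subject never equals
# an A/C/G/T pattern character.
naive_scan <- function(pattern, subject) {
  s <- strsplit(toupper(subject), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  n <- length(s); m <- length(p)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1)
  for (j in seq_len(m)) {
    ok <- ok & s[j:(n - m + j)] == p[j]
  }
  which(ok)
}

# Tiny paired expression fixture: counts chosen by hand, k subjects.
toy_expr_set <- function(counts, totals = NULL) {
  k <- ncol(counts) / 2
  subj <- sprintf("s%02d", seq_len(k))
  meta <- data.frame(
    sample_id = c(paste0(subj, "_C"), paste0(subj, "_N")),
    subject_id = c(subj, subj),
    tissue = rep(c("carcinoma", "normal"), each = k),
    stringsAsFactors = FALSE)
  colnames(counts) <- meta$sample_id
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  if (is.null(totals)) totals <- rep(1e6, 2 * k)
  names(totals) <- meta$sample_id
  paired_expression_set(counts, totals, meta)
}

# Cohort with survival columns for direct survival-stage tests.
toy_cohort <- function(n, seed = 1, event_rate = 0.5, horizon = 120) {
  cfg <- sim_config(n_subjects = n, rng_seed = seed,
                    baseline_hazard = event_rate / horizon * 2,
                    censoring_horizon = horizon)
  generate_survival(cfg, generate_cohort(cfg))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
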