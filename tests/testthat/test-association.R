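test_that("differential profiles are per-subject carcinoma minus normal", {
  meta <- data.frame(
    sample_id = c("p1C", "p1N", "p2C", "p2N", "p3C", "p3N"),
    subject_id = rep(c("p1", "p2", "p3"), each = 2),
    tissue = rep(c("carcinoma", "normal"), 3),
    stringsAsFactors = FALSE)
  vals <- rbind(gA = c(5, 2, 7, 7, 1, 4),
                gB = c(0, 1, 10, 2, 3, 3))
  colnames(vals) <- meta$sample_id
  prof <- make_differential_profiles(vals, meta)
  expect_equal(prof["gA", ], c(p1 = 3, p2 = 0, p3 = -3))
  expect_equal(prof["gB", ], c(p1 = -1, p2 = 8, p3 = 0))
  # carcinoma == normal -> all-zero profile
  same <- vals
  same[, c("p1C", "p2C", "p3C")] <- same[, c("p1N", "p2N", "p3N")]
  expect_true(all(make_differential_profiles(same, meta) == 0))
  # subject missing a tissue is dropped with a warning
  expect_warning(p2 <- make_differential_profiles(vals[, -2], meta),
                 "p1")
  expect_identical(colnames(p2), c("p2", "p3"))
  # duplicated tissue within a subject is ambiguous
  dup <- meta
  dup$tissue[2] <- "carcinoma"
  expect_error(make_differential_profiles(vals, dup), "duplicate")
})

test_that("miRNA expression filter uses a strict 20% threshold", {
  n <- 100
  meta <- data.frame(
    sample_id = c(sprintf("s%03d_C", 1:n), sprintf("s%03d_N", 1:n)),
    subject_id = rep(sprintf("s%03d", 1:n), 2),
    tissue = rep(c("carcinoma", "normal"), each = n),
    stringsAsFactors = FALSE)
  sig <- matrix(0, 3, 2 * n,
                dimnames = list(c("m21", "m20", "m0"), meta$sample_id))
  norm_cols <- meta$sample_id[meta$tissue == "normal"]
  sig["m21", norm_cols[1:21]] <- 5     # 21% of normals: kept
  sig["m20", norm_cols[1:20]] <- 5     # exactly 20%: dropped
  sig[, meta$sample_id[meta$tissue == "carcinoma"]] <- 1
  m <- mirna_matrix(sig, meta)
  expect_identical(filter_mirnas(m), "m21")
  # no normal samples at all is a validation error
  tum_only <- mirna_matrix(
    sig[, meta$tissue == "carcinoma"],
    meta[meta$tissue == "carcinoma", ])
  expect_error(filter_mirnas(tum_only), "no normal")
})

test_that("the nested linear fit matches the normal-equations oracle", {
  # exact fit: y = 2x, no noise
  x <- c(1, 2, 3, 4, 5, 6)
  age <- c(60, 61, 62, 64, 66, 70)
  sex <- c("male", "female", "male", "female", "male", "female")
  fit0 <- fit_linear(2 * x, x, age, sex)
  expect_equal(fit0$beta, 2, tolerance = 1e-12)
  expect_lt(sum((fit0$y - (fit0$fitted_null + fit0$resid_null))^2), 1e-20)
  # toy n = 6 dataset against the oracle, to 1e-10
  set.seed(41)
  y <- rnorm(6)
  fit <- fit_linear(y, x, age, sex)
  orc <- ols_oracle(y, x, age, sex)
  expect_equal(fit$beta, orc$beta, tolerance = 1e-10)
  expect_equal(fit$f_obs, orc$f, tolerance = 1e-10)
  expect_identical(fit$df, c(1, 2))
  expect_error(fit_linear(y, rep(1, 6), age, sex), "zero variance")
})

test_that("the F statistic has the F-distribution mean under independence", {
  set.seed(42)
  n <- 20
  df2 <- n - 4
  f <- replicate(4000, {
    fit_linear(rnorm(n), rnorm(n), rnorm(n, 65, 10),
               sample(c("male", "female"), n, TRUE))$f_obs
  })
  expect_lt(abs(mean(f) - df2 / (df2 - 2)), 0.15)
})

test_that("bootstrap p-values hit boundaries and agree with parametric F", {
  set.seed(43)
  n <- 50
  age <- rnorm(n, 65, 10)
  sex <- sample(c("male", "female"), n, TRUE)
  x <- rnorm(n)
  y <- 0.35 * x + rnorm(n)
  fit <- fit_linear(y, x, age, sex)
  # boundary: F_obs = 0 means every resampled F is at least as large
  fit0 <- fit
  fit0$f_obs <- 0
  expect_equal(bootstrap_f_pvalue(fit0, n_boot = 500, rng_seed = 7), 1)
  expect_error(bootstrap_f_pvalue(fit, n_boot = 0), "n_boot")
  # Gaussian errors: bootstrap p within 0.02 of the parametric F p
  p_param <- stats::pf(fit$f_obs, 1, n - 4, lower.tail = FALSE)
  p_boot <- bootstrap_f_pvalue(fit, n_boot = 10000, rng_seed = 8)
  expect_lt(abs(p_boot - p_param), 0.02)
  # p respects its attainable range and determinism
  expect_gte(p_boot, 1 / 10001)
  expect_identical(p_boot, bootstrap_f_pvalue(fit, n_boot = 10000,
                                              rng_seed = 8))
})

test_that("bootstrap p is invariant to affine rescaling of x and y", {
  set.seed(44)
  n <- 30
  age <- rnorm(n, 65, 10)
  sex <- sample(c("male", "female"), n, TRUE)
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  p1 <- bootstrap_f_pvalue(fit_linear(y, x, age, sex), 2000, rng_seed = 9)
  p2 <- bootstrap_f_pvalue(fit_linear(10 * y - 3, x, age, sex), 2000,
                           rng_seed = 9)
  p3 <- bootstrap_f_pvalue(fit_linear(y, -2 * x + 7, age, sex), 2000,
                           rng_seed = 9)
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("gene-level FDR adjusts within genes independently", {
  rec <- data.frame(gene = c("gA", "gB", "gB", "gC", "gC"),
                    mirna = paste0("m", 1:5),
                    p_boot = c(0.03, 0.01, 0.04, 0.01, 0.04),
                    stringsAsFactors = FALSE)
  out <- gene_level_fdr(rec)
  expect_equal(out$fdr_gene[out$gene == "gA"], 0.03)    # m = 1
  expect_equal(out$fdr_gene[out$gene == "gB"], c(0.02, 0.04))
  # identical p-vectors in different genes give identical fdr-vectors
  expect_equal(out$fdr_gene[out$gene == "gB"],
               out$fdr_gene[out$gene == "gC"])
})

test_that("planted associations are detected with high power at n = 217", {
  # moderate planted slope, gene-level FDR < 0.05, rejection rate > 0.8
  n <- 217
  hits <- 0
  for (r in 1:25) {
    seed <- 4500 + r
    dat <- local({
      set.seed(seed)
      x <- rnorm(n, 0, 10)
      list(x = x, y = 0.3 * x + rnorm(n, 0, 8),
           age = rnorm(n, 65, 10),
           sex = sample(c("male", "female"), n, TRUE))
    })
    fit <- fit_linear(dat$y, dat$x, dat$age, dat$sex)
    p <- bootstrap_f_pvalue(fit, n_boot = 500, rng_seed = seed)
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 25, 0.8)
})

test_that("associate_all is deterministic and annotates direction", {
  cfg <- sim_config(n_subjects = 40, n_genes = 3, n_mirnas = 4,
                    rng_seed = 46,
                    assoc_effects = data.frame(gene = "g0001",
                                               mirna = "mir0001",
                                               beta = -0.5, noise_sd = 2))
  cohort <- generate_cohort(cfg)
  expr <- generate_paired_counts(cfg, cohort)
  prof <- make_differential_profiles(rpmpcg(expr)$values, expr$sample_meta)
  mir <- generate_mirna_signal(cfg, prof, cohort)
  mprof <- make_differential_profiles(mir$signal, mir$sample_meta)
  a1 <- associate_all(prof, mprof, cohort, n_boot = 300, rng_seed = 5)
  a2 <- associate_all(prof, mprof, cohort, n_boot = 300, rng_seed = 5)
  expect_identical(a1, a2)
  planted <- a1[a1$gene == "g0001" & a1$mirna == "mir0001", ]
  expect_identical(planted$direction, "negative")
  expect_lt(planted$p_boot, 0.05)
  expect_identical(a1$direction, ifelse(a1$beta > 0, "positive",
                                        "negative"))
})

test_that("null association p-values keep their nominal error rate", {
  # all-null pairs: share below 0.05 stays inside a generous binomial
  # band and gene-level FDR calls essentially nothing
  cfg <- sim_config(n_subjects = 60, n_genes = 4, n_mirnas = 50,
                    rng_seed = 47)
  cohort <- generate_cohort(cfg)
  expr <- generate_paired_counts(cfg, cohort)
  prof <- make_differential_profiles(rpmpcg(expr)$values, expr$sample_meta)
  mir <- generate_mirna_signal(cfg, prof, cohort)
  mprof <- make_differential_profiles(mir$signal, mir$sample_meta)
  a <- associate_all(prof, mprof, cohort, n_boot = 400, rng_seed = 11)
  expect_equal(nrow(a), 200)
  frac <- mean(a$p_boot < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
  expect_lte(sum(a$fdr_gene < 0.05), 2)
})
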