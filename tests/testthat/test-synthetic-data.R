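test_that("cohort generator matches its target demographics", {
  cfg <- sim_config(n_subjects = 10000, rng_seed = 101)
  cohort <- generate_cohort(cfg)
  expect_equal(mean(cohort$age), 64.8, tolerance = 0.5 / 64.8)
  expect_lt(abs(mean(cohort$sex == "male") - 0.544), 0.02)
  expect_true(all(cohort$age >= 30 & cohort$age <= 79))
  expect_true(all(cohort$ajcc_stage %in% 1:4))
  # deterministic under the config seed
  expect_identical(cohort, generate_cohort(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_subjects = 0), "positive count")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(seed_sites = data.frame(gene = "g0001",
                                                  mirna = "mir0001",
                                                  seed_length = 5L)),
               "seed_length")
  expect_error(sim_config(seed_sites = data.frame(gene = "g0001",
                                                  mirna = "mir0001",
                                                  seed_length = 7L),
                          utr_length = 8), "utr_length")
})

test_that("paired counts carry the planted fold change", {
  # null genes: carcinoma/normal RPMPCG ratio near 1
  cfg0 <- sim_config(n_subjects = 300, n_genes = 4, rng_seed = 102)
  expr0 <- generate_paired_counts(cfg0)
  norm0 <- rpmpcg(expr0)
  tum <- expr0$sample_meta$tissue == "carcinoma"
  ratios <- rowMeans(norm0$values[, tum]) / rowMeans(norm0$values[, !tum])
  expect_true(all(abs(ratios - 1) < 0.1))

  # planted ln(2): empirical fold change of that gene near 2 at 500 pairs
  cfg2 <- sim_config(n_subjects = 500, n_genes = 3,
                     planted_log_fc = c(log(2), 0, 0), rng_seed = 103)
  expr2 <- generate_paired_counts(cfg2)
  norm2 <- rpmpcg(expr2)
  tum2 <- expr2$sample_meta$tissue == "carcinoma"
  fc <- mean(norm2$values["g0001", tum2]) /
    mean(norm2$values["g0001", !tum2])
  expect_gt(fc, 1.9)
  expect_lt(fc, 2.1)

  # determinism
  expect_identical(expr2$counts, generate_paired_counts(cfg2)$counts)
})

test_that("per-gene sub-streams: adding genes leaves existing genes alone", {
  cfg_a <- sim_config(n_subjects = 30, n_genes = 3, rng_seed = 104)
  cfg_b <- sim_config(n_subjects = 30, n_genes = 6, rng_seed = 104)
  a <- generate_paired_counts(cfg_a)$counts
  b <- generate_paired_counts(cfg_b)$counts
  expect_identical(a, b[rownames(a), ])
})

test_that("miRNA generator plants a recoverable regression slope", {
  cfg <- sim_config(
    n_subjects = 500, n_genes = 2, n_mirnas = 3, rng_seed = 105,
    assoc_effects = data.frame(gene = "g0001", mirna = "mir0001",
                               beta = 0.30, noise_sd = 1))
  cohort <- generate_cohort(cfg)
  expr <- generate_paired_counts(cfg, cohort)
  prof <- make_differential_profiles(rpmpcg(expr)$values,
                                     expr$sample_meta)
  mir <- generate_mirna_signal(cfg, prof, cohort)
  mprof <- make_differential_profiles(mir$signal, mir$sample_meta)
  subj <- colnames(prof)
  fit <- fit_linear(prof["g0001", subj], mprof["mir0001", subj],
                    cohort$age, cohort$sex)
  expect_lt(abs(fit$beta - 0.30), 0.03)
  # determinism
  expect_identical(mir$signal,
                   generate_mirna_signal(cfg, prof, cohort)$signal)
  # unknown ids are reference errors
  bad <- sim_config(n_subjects = 20, n_genes = 2, n_mirnas = 2,
                    rng_seed = 1,
                    assoc_effects = data.frame(gene = "nope",
                                               mirna = "mir0001",
                                               beta = 1, noise_sd = 1))
  expect_error(generate_mirna_signal(bad, prof[, 1:20], cohort[1:20, ]),
               "unknown gene")
})

test_that("low-expression miRNAs fail the 20% filter by construction", {
  cfg <- sim_config(n_subjects = 100, n_genes = 2, n_mirnas = 10,
                    low_expr_fraction = 0.3, rng_seed = 106)
  cohort <- generate_cohort(cfg)
  expr <- generate_paired_counts(cfg, cohort)
  prof <- make_differential_profiles(rpmpcg(expr)$values, expr$sample_meta)
  mir <- generate_mirna_signal(cfg, prof, cohort)
  kept <- filter_mirnas(mir)
  low <- tail(sprintf("mir%04d", 1:10), 3)
  expect_true(all(!low %in% kept))
  expect_true(all(setdiff(rownames(mir$signal), low) %in% kept))
})

test_that("survival generator: null hazard, censoring, degenerate horizon", {
  cfg <- sim_config(n_subjects = 1000, n_genes = 2, rng_seed = 107)
  cohort <- generate_cohort(cfg)
  expr <- generate_paired_counts(cfg, cohort)
  prof <- make_differential_profiles(rpmpcg(expr)$values, expr$sample_meta)
  cohort <- generate_survival(cfg, cohort, prof)
  expect_true(all(cohort$survival_months >= 0))
  expect_identical(cohort$death_cause == "none",
                   cohort$vital_status == "alive")
  # expression independent of hazard: HR per IQR near 1 at n = 1000
  fit <- cox_iqr(setNames(prof["g0001", ], colnames(prof)), cohort)
  expect_gt(fit$hr_per_iqr, 0.9)
  expect_lt(fit$hr_per_iqr, 1.1)
  # zero horizon: everyone censored, survival fit refuses
  cfg0 <- sim_config(n_subjects = 50, n_genes = 2, rng_seed = 108,
                     censoring_horizon = 0)
  c0 <- generate_survival(cfg0, generate_cohort(cfg0), NULL)
  expect_true(all(c0$vital_status == "alive"))
  p0 <- setNames(rnorm(50), c0$subject_id)
  expect_error(cox_iqr(p0, c0), "no events")
})

test_that("sequence generator plants recoverable seed sites", {
  sites <- data.frame(gene = c("g0001", "g0001", "g0002"),
                      mirna = c("mir0001", "mir0002", "mir0001"),
                      seed_length = c(7L, 6L, 8L))
  cfg <- sim_config(n_subjects = 5, n_genes = 2, n_mirnas = 2,
                    seed_sites = sites, utr_length = 300, rng_seed = 109)
  seqs <- generate_sequences(cfg)
  expect_equal(nrow(seqs$planted_sites), 3)
  for (i in seq_len(nrow(seqs$planted_sites))) {
    row <- seqs$planted_sites[i, ]
    utr <- seqs$utrs[seqs$utrs$gene == row$gene &
                       seqs$utrs$build == row$build, ]
    rep <- scan_utr(utr, extract_seeds(seqs$mirna_seqs[[row$mirna]]),
                    mirna = row$mirna)
    hit <- rep[rep$seed_length == row$seed_length, ]
    expect_true(row$position %in% hit$position)
  }
})

test_that("FASTA output is byte-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 5, n_genes = 3, n_mirnas = 3,
                    utr_length = 150, rng_seed = 110)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s <- generate_sequences(cfg)
  write_sequence_fasta(s, file.path(d1, "m.fa"), file.path(d1, "u.fa"))
  write_sequence_fasta(generate_sequences(cfg),
                       file.path(d2, "m.fa"), file.path(d2, "u.fa"))
  expect_identical(readBin(file.path(d1, "u.fa"), "raw", 1e6),
                   readBin(file.path(d2, "u.fa"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "m.fa"), "raw", 1e6),
                   readBin(file.path(d2, "m.fa"), "raw", 1e6))
})

test_that("background 6-mer match rate matches the binomial expectation", {
  # 10,000 independent random (50-nt UTR, seed) pairs with nothing
  # planted: the scanner's expected 6-mer match count per pair is
  # 45 * 4^-6; the total over all pairs must sit within 3 SE of the
  # binomial mean.
  set.seed(111)
  n_pairs <- 10000
  width <- 50
  p_hit <- 0.25^6
  n_pos <- width - 6 + 1
  total <- 0L
  for (i in seq_len(n_pairs)) {
    seeds <- extract_seeds(random_rna(22))
    rep <- scan_utr(list(gene = "g", build = "GRCh38",
                         sequence = random_dna(width)), seeds)
    total <- total + sum(rep$seed_length == 6L)
  }
  mu <- n_pairs * n_pos * p_hit
  se <- sqrt(n_pairs * n_pos * p_hit * (1 - p_hit))
  expect_lt(abs(total - mu), 3 * se)
})
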