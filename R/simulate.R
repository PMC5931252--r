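## Synthetic-data generator with planted effects. Every pipeline stage has a
## recoverable ground truth: planted log fold changes for the paired NB
## model, planted regression slopes for the bootstrap-F association stage,
## planted log hazard ratios per IQR for the Cox stage, and planted seed
## sites for the UTR scanner.
##
## RNG discipline: one base seed in the config; each generator derives
## deterministic sub-streams per stage and per feature, so enlarging the
## gene set never perturbs the draws of existing genes.

#' Simulation configuration
#'
#' Collects every planted parameter of the synthetic cohort. Defaults
#' emulate a paired colorectal carcinoma / normal-mucosa study: 217 subject
#' pairs, age ~ Normal(64.8, 10.1) truncated to 30-79 years, 54.4% male,
#' AJCC stage probabilities (0.271, 0.285, 0.336, 0.108), and negative-
#' binomial counts with Var = mu + mu^2/dispersion.
#'
#' @param n_subjects number of paired subjects.
#' @param n_genes number of mRNA features.
#' @param n_mirnas number of miRNA features.
#' @param planted_log_fc per-gene natural-log fold change (carcinoma vs
#'   normal); recycled scalar or length `n_genes`.
#' @param nb_dispersion NB size parameter; Var = mu + mu^2/nb_dispersion.
#' @param subject_sd SD of the per-subject random intercept on the log
#'   scale.
#' @param assoc_effects data frame with columns `gene`, `mirna`, `beta`,
#'   `noise_sd`: planted linear associations between mRNA and miRNA
#'   differential profiles (at most one planted edge per miRNA).
#' @param planted_log_hr_per_iqr named numeric: per-feature planted log
#'   hazard ratio per IQR of differential expression.
#' @param seed_sites data frame with columns `gene`, `mirna`,
#'   `seed_length` (6, 7 or 8): seed sites to plant in the 3' UTRs.
#' @param utr_length length of each synthetic 3' UTR (nt).
#' @param rng_seed integer base seed; identical configs are bit-reproducible.
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param p_male probability of male sex.
#' @param stage_probs AJCC stage 1-4 probabilities (sum to 1).
#' @param pc_total_meanlog,pc_total_sdlog log-normal parameters of the
#'   per-sample protein-coding totals.
#' @param base_rpm_range range (in reads per million) of the per-gene
#'   baseline abundance, drawn log-uniformly.
#' @param mirna_diff_sd SD of miRNA differential signal without a planted
#'   association.
#' @param mirna_base_range range of baseline miRNA signal in normal tissue.
#' @param low_expr_fraction fraction of miRNAs simulated as expressed in at
#'   most 20% of normal samples (to exercise the expression filter).
#' @param assoc_age_gamma,assoc_sex_gamma covariate effects of centred age
#'   and male sex in the planted association model.
#' @param baseline_hazard monthly baseline hazard of disease-specific death.
#' @param other_cause_rate monthly hazard of death from other causes
#'   (censored in the disease-specific analysis).
#' @param censoring_horizon administrative censoring time in months.
#' @param surv_age_coef,surv_sex_coef,surv_stage_lhr survival covariate
#'   effects (log-hazard scale; stage as length-4 vector, stage 1 = 0).
#' @param builds genome builds for which UTR FASTA records are generated.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 217L,
                       n_genes = 50L,
                       n_mirnas = 40L,
                       planted_log_fc = 0,
                       nb_dispersion = 10,
                       subject_sd = 0.3,
                       assoc_effects = NULL,
                       planted_log_hr_per_iqr = NULL,
                       seed_sites = NULL,
                       utr_length = 500L,
                       rng_seed = 1L,
                       age_mean = 64.8, age_sd = 10.1,
                       age_range = c(30, 79),
                       p_male = 0.544,
                       stage_probs = c(0.271, 0.285, 0.336, 0.108),
                       pc_total_meanlog = log(2e7),
                       pc_total_sdlog = 0.25,
                       base_rpm_range = c(5, 500),
                       mirna_diff_sd = 20,
                       mirna_base_range = c(100, 1000),
                       low_expr_fraction = 0,
                       assoc_age_gamma = 0, assoc_sex_gamma = 0,
                       baseline_hazard = 0.005,
                       other_cause_rate = 0.002,
                       censoring_horizon = 120,
                       surv_age_coef = 0.02, surv_sex_coef = 0.1,
                       surv_stage_lhr = c(0, 0.4, 0.9, 1.6),
                       builds = "GRCh38") {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1) {
    stop_invalid("n_subjects must be a positive count")
  }
  if (n_genes < 1 || n_mirnas < 1) {
    stop_invalid("n_genes and n_mirnas must be positive counts")
  }
  if (!is.finite(nb_dispersion) || nb_dispersion <= 0) {
    stop_invalid("nb_dispersion must be > 0")
  }
  if (subject_sd < 0) stop_invalid("subject_sd must be >= 0")
  planted_log_fc <- rep_len(planted_log_fc, n_genes)
  if (!is.null(seed_sites)) {
    if (!all(seed_sites$seed_length %in% c(6L, 7L, 8L))) {
      stop_invalid("seed_length must be 6, 7 or 8")
    }
    if (utr_length <= 8) {
      stop_invalid("utr_length must exceed 8 to host a seed site")
    }
  }
  if (!is.null(assoc_effects) && anyDuplicated(assoc_effects$mirna)) {
    stop_invalid("at most one planted association per miRNA")
  }
  if (abs(sum(stage_probs) - 1) > 1e-8) {
    stop_invalid("stage_probs must sum to 1")
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    n_mirnas = as.integer(n_mirnas), planted_log_fc = planted_log_fc,
    nb_dispersion = nb_dispersion, subject_sd = subject_sd,
    assoc_effects = assoc_effects,
    planted_log_hr_per_iqr = planted_log_hr_per_iqr,
    seed_sites = seed_sites, utr_length = as.integer(utr_length),
    rng_seed = as.integer(rng_seed),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_male = p_male, stage_probs = stage_probs,
    pc_total_meanlog = pc_total_meanlog, pc_total_sdlog = pc_total_sdlog,
    base_rpm_range = base_rpm_range, mirna_diff_sd = mirna_diff_sd,
    mirna_base_range = mirna_base_range,
    low_expr_fraction = low_expr_fraction,
    assoc_age_gamma = assoc_age_gamma, assoc_sex_gamma = assoc_sex_gamma,
    baseline_hazard = baseline_hazard, other_cause_rate = other_cause_rate,
    censoring_horizon = censoring_horizon,
    surv_age_coef = surv_age_coef, surv_sex_coef = surv_sex_coef,
    surv_stage_lhr = surv_stage_lhr, builds = builds,
    gene_ids = sprintf("g%04d", seq_len(n_genes)),
    mirna_ids = sprintf("mir%04d", seq_len(n_mirnas))
  )
  structure(cfg, class = "sim_config")
}

subject_ids <- function(config) sprintf("s%04d", seq_len(config$n_subjects))

sim_sample_meta <- function(config) {
  subj <- subject_ids(config)
  data.frame(
    sample_id = c(paste0(subj, "_C"), paste0(subj, "_N")),
    subject_id = c(subj, subj),
    tissue = rep(c("carcinoma", "normal"), each = length(subj)),
    stringsAsFactors = FALSE
  )
}

## Moments of Normal(mu, sigma) truncated to [a, b].
trunc_norm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  dphi <- stats::dnorm(al) - stats::dnorm(be)
  m <- mu + sigma * dphi / z
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z -
                    (dphi / z)^2)
  c(mean = m, sd = sqrt(v))
}

## Parent (mu, sigma) whose truncation to [a, b] has the target moments.
## Needed because truncating Normal(64.8, 10.1) to the 30-79 eligibility
## window would drag the sample mean well below the reported 64.8.
trunc_norm_parent <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    m <- trunc_norm_moments(par[1], exp(par[2]), a, b)
    (m[1] - target_mean)^2 + (m[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate a synthetic study cohort
#'
#' Ages follow a truncated normal on `age_range` (study eligibility was
#' 30-79 years) whose parent parameters are calibrated so that the
#' truncated distribution has mean `age_mean` and SD `age_sd` - i.e. the
#' generated cohort reproduces the reported summary statistics of the
#' study population. Sex is Bernoulli with `p_male` and AJCC stage is
#' multinomial with `stage_probs`.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `subject_id`, `age`, `sex`,
#'   `ajcc_stage`. Survival columns are added by [generate_survival()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  parent <- trunc_norm_parent(config$age_mean, config$age_sd,
                              config$age_range[1], config$age_range[2])
  with_seed(substream_seed(config$rng_seed, "cohort"), {
    age <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {             # rejection sampling for truncation
      draw <- rnorm(length(todo), parent[["mu"]], parent[["sigma"]])
      ok <- draw >= config$age_range[1] & draw <= config$age_range[2]
      age[todo[ok]] <- draw[ok]
      todo <- todo[!ok]
    }
    sex <- ifelse(runif(n) < config$p_male, "male", "female")
    stage <- sample.int(4L, n, replace = TRUE, prob = config$stage_probs)
    data.frame(subject_id = subject_ids(config), age = age, sex = sex,
               ajcc_stage = stage, stringsAsFactors = FALSE)
  })
}

#' Generate paired carcinoma/normal NB counts
#'
#' For subject i, gene g, tissue t, counts are drawn
#' NB(mean = total_i * rel_g * exp(a_i + log_fc_g * 1\[t = carcinoma\]),
#' size = `nb_dispersion`) with subject intercepts a_i ~ Normal(0,
#' `subject_sd`); per-sample protein-coding totals are emitted alongside as
#' the exposure.
#'
#' @param config a [sim_config()].
#' @param cohort output of [generate_cohort()] (only its size is used).
#' @return a [paired_expression_set()].
#' @export
generate_paired_counts <- function(config, cohort = generate_cohort(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) stop_invalid("nb_dispersion must be > 0")
  meta <- sim_sample_meta(config)
  n_s <- nrow(meta)
  subj_idx <- match(meta$subject_id, subject_ids(config))
  is_tum <- as.numeric(meta$tissue == "carcinoma")
  totals <- with_seed(substream_seed(config$rng_seed, "pc_totals"), {
    tot <- exp(rnorm(config$n_subjects * 2L, config$pc_total_meanlog,
                     config$pc_total_sdlog))
    round(tot)
  })
  names(totals) <- meta$sample_id
  a <- with_seed(substream_seed(config$rng_seed, "subject_effect"),
                 rnorm(config$n_subjects, 0, config$subject_sd))
  counts <- matrix(0L, config$n_genes, n_s,
                   dimnames = list(config$gene_ids, meta$sample_id))
  for (g in seq_len(config$n_genes)) {
    base_rpm <- with_seed(substream_seed(config$rng_seed, "base_abund", g),
                          exp(runif(1, log(config$base_rpm_range[1]),
                                    log(config$base_rpm_range[2]))))
    mu <- totals * (base_rpm / 1e6) *
      exp(a[subj_idx] + config$planted_log_fc[g] * is_tum)
    counts[g, ] <- with_seed(substream_seed(config$rng_seed, "counts", g),
                             rnbinom(n_s, mu = mu,
                                     size = config$nb_dispersion))
  }
  paired_expression_set(counts, totals, meta)
}

#' Generate miRNA signal with planted linear associations
#'
#' For each planted edge (gene, miRNA, beta, noise_sd) the miRNA
#' differential profile is constructed so that the mRNA differential
#' profile satisfies mrna_diff = beta * mirna_diff + gamma * covariates +
#' noise with Normal(0, `noise_sd`) noise; i.e. mirna_diff = (mrna_diff -
#' covariate terms - noise) / beta. miRNAs without a planted edge receive
#' independent Normal(0, `mirna_diff_sd`) differentials. The
#' carcinoma/normal signal pair is reconstructed to carry exactly that
#' difference with nonnegative signal; a `low_expr_fraction` share of
#' miRNAs is made detectable in at most 20% of normal samples to exercise
#' the expression filter.
#'
#' @param config a [sim_config()].
#' @param mrna_profiles feature x subject matrix of mRNA differential
#'   profiles (e.g. from [make_differential_profiles()]).
#' @param cohort cohort table supplying age/sex for the covariate terms.
#' @return a raw (unscaled) [mirna_matrix()].
#' @export
generate_mirna_signal <- function(config, mrna_profiles,
                                  cohort = generate_cohort(config)) {
  stopifnot(inherits(config, "sim_config"))
  subj <- subject_ids(config)
  n <- length(subj)
  eff <- config$assoc_effects
  if (!is.null(eff)) {
    if (!all(eff$gene %in% rownames(mrna_profiles))) {
      stop_invalid("assoc_effects references unknown gene id(s): ",
                   paste(setdiff(eff$gene, rownames(mrna_profiles)),
                         collapse = ", "))
    }
    if (!all(eff$mirna %in% config$mirna_ids)) {
      stop_invalid("assoc_effects references unknown miRNA id(s): ",
                   paste(setdiff(eff$mirna, config$mirna_ids),
                         collapse = ", "))
    }
  }
  age_c <- cohort$age - mean(cohort$age)
  male <- as.numeric(cohort$sex == "male")
  n_low <- floor(config$low_expr_fraction * config$n_mirnas)
  low_set <- if (n_low > 0) utils::tail(config$mirna_ids, n_low) else character()
  meta <- sim_sample_meta(config)
  sig <- matrix(0, config$n_mirnas, nrow(meta),
                dimnames = list(config$mirna_ids, meta$sample_id))
  carc_cols <- paste0(subj, "_C")
  norm_cols <- paste0(subj, "_N")
  for (m in seq_len(config$n_mirnas)) {
    id <- config$mirna_ids[m]
    s <- substream_seed(config$rng_seed, "mirna", m)
    if (id %in% low_set) {
      sig[m, ] <- with_seed(s, {
        p_expr <- runif(1, 0.05, 0.18)   # detectable in <= 20% of samples
        base <- runif(1, config$mirna_base_range[1],
                      config$mirna_base_range[2])
        on_n <- rbinom(n, 1, p_expr)
        on_c <- rbinom(n, 1, p_expr)
        v <- numeric(2 * n)
        v[match(norm_cols, meta$sample_id)] <- base * on_n
        v[match(carc_cols, meta$sample_id)] <- base * on_c
        v
      })
      next
    }
    row <- if (!is.null(eff)) eff[eff$mirna == id, , drop = FALSE] else NULL
    sig[m, ] <- with_seed(s, {
      if (!is.null(row) && nrow(row) == 1L) {
        y <- mrna_profiles[row$gene, subj]
        eps <- rnorm(n, 0, row$noise_sd)
        diff <- (y - config$assoc_age_gamma * age_c -
                   config$assoc_sex_gamma * male - eps) / row$beta
      } else {
        diff <- rnorm(n, 0, config$mirna_diff_sd)
      }
      base <- runif(1, config$mirna_base_range[1],
                    config$mirna_base_range[2])
      normal <- base + abs(rnorm(n, 0, base / 20))
      carcinoma <- normal + diff
      shift <- max(0, -min(carcinoma))   # keep signal nonnegative,
      normal <- normal + shift           # difference preserved exactly
      carcinoma <- carcinoma + shift
      v <- numeric(2 * n)
      v[match(norm_cols, meta$sample_id)] <- normal
      v[match(carc_cols, meta$sample_id)] <- carcinoma
      v
    })
  }
  mirna_matrix(sig, meta, scaled = FALSE)
}

#' Generate survival outcomes with planted hazards
#'
#' Disease-specific death times are exponential with log-hazard
#' log(`baseline_hazard`) + sum_f (planted_log_hr_per_iqr_f / IQR_f) x_f +
#' covariate terms; deaths from other causes arrive independently at
#' `other_cause_rate` and are recorded as `death_cause = "other"`;
#' administrative censoring occurs at `censoring_horizon` months.
#'
#' @param config a [sim_config()].
#' @param cohort output of [generate_cohort()].
#' @param profiles feature x subject matrix of differential profiles; only
#'   features named in `planted_log_hr_per_iqr` contribute to the hazard.
#' @return `cohort` with columns `survival_months`, `vital_status`,
#'   `death_cause` appended.
#' @export
generate_survival <- function(config, cohort, profiles = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(cohort)
  lp <- config$surv_age_coef * (cohort$age - 65) +
    config$surv_sex_coef * (cohort$sex == "male") +
    config$surv_stage_lhr[cohort$ajcc_stage]
  lhr <- config$planted_log_hr_per_iqr
  if (!is.null(lhr) && length(lhr)) {
    if (is.null(names(lhr)) || !all(names(lhr) %in% rownames(profiles))) {
      stop_invalid("planted_log_hr_per_iqr must be named after rows of ",
                   "`profiles`")
    }
    for (f in names(lhr)) {
      x <- profiles[f, cohort$subject_id]
      span <- iqr_type7(x)
      if (span <= 0) stop_invalid("zero IQR for planted feature ", f)
      lp <- lp + (lhr[[f]] / span) * x
    }
  }
  with_seed(substream_seed(config$rng_seed, "survival"), {
    t_crc <- rexp(n, rate = config$baseline_hazard * exp(lp))
    t_other <- rexp(n, rate = config$other_cause_rate)
    time <- pmin(t_crc, t_other, config$censoring_horizon)
    cause <- ifelse(time >= config$censoring_horizon, "none",
                    ifelse(t_crc <= t_other, "crc", "other"))
    cohort$survival_months <- time
    cohort$vital_status <- ifelse(cause == "none", "alive", "dead")
    cohort$death_cause <- cause
    cohort
  })
}

#' Generate miRNA and 3' UTR sequences with planted seed sites
#'
#' miRNA mature sequences are random RNA of length 20-24 nt; UTRs are
#' random DNA of `utr_length` nt per genome build. For every planted site
#' (gene, miRNA, seed length) the reverse complement of the miRNA's seed is
#' written into the UTR at a recorded, non-overlapping position.
#'
#' @param config a [sim_config()].
#' @return list with `mirna_seqs` (named character, RNA), `utrs` (data
#'   frame: gene, build, sequence) and `planted_sites` (data frame: gene,
#'   mirna, build, seed_length, position).
#' @export
generate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$utr_length <= 8) {
    stop_invalid("utr_length must exceed 8")
  }
  mirna_seqs <- vapply(seq_len(config$n_mirnas), function(m) {
    with_seed(substream_seed(config$rng_seed, "mirna_seq", m), {
      len <- sample(20:24, 1)
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
            collapse = "")
    })
  }, character(1))
  names(mirna_seqs) <- config$mirna_ids
  sites <- config$seed_sites
  utrs <- expand.grid(gene = config$gene_ids, build = config$builds,
                      stringsAsFactors = FALSE)
  utrs <- utrs[order(utrs$gene, utrs$build), ]
  rownames(utrs) <- NULL
  planted <- list()
  utrs$sequence <- vapply(seq_len(nrow(utrs)), function(i) {
    g <- utrs$gene[i]
    b <- utrs$build[i]
    gi <- match(g, config$gene_ids)
    bi <- match(b, config$builds)
    with_seed(substream_seed(config$rng_seed, paste0("utr", bi), gi), {
      seq <- sample(c("A", "C", "G", "T"), config$utr_length,
                    replace = TRUE)
      if (!is.null(sites)) {
        here <- sites[sites$gene == g, , drop = FALSE]
        used <- integer(0)     # occupied positions, to avoid overlaps
        for (k in seq_len(nrow(here))) {
          ms <- match_string(
            extract_seeds(mirna_seqs[[here$mirna[k]]])$
              seeds[[as.character(here$seed_length[k])]])
          w <- nchar(ms)
          if (config$utr_length < w) {
            stop_invalid("utr_length too small to host a ", w, "-nt site")
          }
          cand <- setdiff(seq_len(config$utr_length - w + 1),
                          unlist(lapply(used, function(u)
                            (u - w + 1):(u + w - 1))))
          cand <- cand[cand >= 1]
          if (!length(cand)) {
            stop_invalid("cannot place non-overlapping site in UTR of ", g)
          }
          pos <- cand[sample.int(length(cand), 1)]
          seq[pos:(pos + w - 1)] <- strsplit(ms, "")[[1]]
          used <- c(used, pos)
          planted[[length(planted) + 1]] <<- data.frame(
            gene = g, mirna = here$mirna[k], build = b,
            seed_length = here$seed_length[k], position = pos,
            stringsAsFactors = FALSE)
        }
      }
      paste(seq, collapse = "")
    })
  }, character(1))
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene = character(), mirna = character(), build = character(),
               seed_length = integer(), position = integer())
  list(mirna_seqs = mirna_seqs, utrs = utrs, planted_sites = planted)
}

#' Write sequences as 60-column FASTA
#'
#' miRNA records are named by miRNA id; UTR records use the header grammar
#' `gene|build`.
#'
#' @param seqs output of [generate_sequences()].
#' @param mirna_path,utr_path output FASTA paths.
#' @return invisibly, the two paths.
#' @export
write_sequence_fasta <- function(seqs, mirna_path, utr_path) {
  rna <- Biostrings::RNAStringSet(seqs$mirna_seqs)
  Biostrings::writeXStringSet(rna, mirna_path, width = 60L)
  utr <- Biostrings::DNAStringSet(seqs$utrs$sequence)
  names(utr) <- paste(seqs$utrs$gene, seqs$utrs$build, sep = "|")
  Biostrings::writeXStringSet(utr, utr_path, width = 60L)
  invisible(c(mirna_path, utr_path))
}

#' Simulate a complete study and write it to disk
#'
#' Runs every generator under the config's seed and writes the standard
#' file contract: `counts.tsv`, `pc_totals.tsv`, `mirna.tsv`,
#' `metadata.tsv`, `mirna.fa`, `utr.fa` and `truth.json` (the planted
#' parameters).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with all in-memory objects.
#' @export
simulate_study <- function(config, dir = NULL) {
  cohort <- generate_cohort(config)
  expr <- generate_paired_counts(config, cohort)
  norm <- rpmpcg(expr)
  prof <- make_differential_profiles(norm$values, expr$sample_meta)
  mir <- generate_mirna_signal(config, prof, cohort)
  cohort <- generate_survival(config, cohort, prof)
  seqs <- generate_sequences(config)
  out <- list(config = config, cohort = cohort, expr = expr,
              mirna = mir, sequences = seqs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(expr$counts, file.path(dir, "counts.tsv"), "gene")
    write_table_tsv(data.frame(sample_id = names(expr$pc_totals),
                               pc_total = unname(expr$pc_totals)),
                    file.path(dir, "pc_totals.tsv"))
    write_matrix_tsv(mir$signal, file.path(dir, "mirna.tsv"), "mirna")
    meta <- merge(expr$sample_meta, cohort, by = "subject_id", sort = FALSE)
    meta <- meta[match(expr$sample_meta$sample_id, meta$sample_id), ]
    write_table_tsv(meta, file.path(dir, "metadata.tsv"))
    write_sequence_fasta(seqs, file.path(dir, "mirna.fa"),
                         file.path(dir, "utr.fa"))
    truth <- list(
      rng_seed = config$rng_seed,
      planted_log_fc = setNames(config$planted_log_fc, config$gene_ids),
      nb_dispersion = config$nb_dispersion,
      assoc_effects = config$assoc_effects,
      planted_log_hr_per_iqr = config$planted_log_hr_per_iqr,
      planted_sites = seqs$planted_sites
    )
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out)
}
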