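## Orchestration: normalize -> paired DE -> band filter -> associate ->
## seed match -> classify -> survive, with file-based stage contracts so
## every stage is independently testable and the whole run is reproducible
## from a single seed.

#' Pipeline configuration
#'
#' @param counts,pc_totals,mirna,metadata,mirna_fasta,utr_fasta input file
#'   paths (the contract written by [simulate_study()]).
#' @param fc_low,fc_high fold-change band thresholds (must satisfy
#'   `0 < fc_low < 1 < fc_high`).
#' @param de_alpha adjusted-p threshold for the DE stage.
#' @param assoc_fdr gene-level FDR threshold for reporting associations.
#' @param n_boot bootstrap resamples for association p-values.
#' @param n_perm permutations for survival p-values.
#' @param mirna_min_fraction expression-filter threshold (strict).
#' @param rng_seed base seed for all resampling.
#' @param subset `"all"`, `"msi"` or `"mss"`; restricts subjects via the
#'   metadata column `msi_status` when present.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, pc_totals, mirna, metadata,
                            mirna_fasta, utr_fasta,
                            fc_low = 0.67, fc_high = 1.50,
                            de_alpha = 0.05, assoc_fdr = 0.05,
                            n_boot = 10000L, n_perm = 10000L,
                            mirna_min_fraction = 0.20,
                            rng_seed = 1L,
                            subset = c("all", "msi", "mss")) {
  subset <- match.arg(subset)
  if (!(fc_low > 0 && fc_low < 1 && fc_high > 1)) {
    stop_invalid("need 0 < fc_low < 1 < fc_high")
  }
  if (de_alpha <= 0 || de_alpha >= 1 || assoc_fdr <= 0 || assoc_fdr >= 1) {
    stop_invalid("alpha thresholds must lie in (0, 1)")
  }
  if (n_boot < 1 || n_perm < 1) stop_invalid("n_boot and n_perm must be >= 1")
  structure(list(counts = counts, pc_totals = pc_totals, mirna = mirna,
                 metadata = metadata, mirna_fasta = mirna_fasta,
                 utr_fasta = utr_fasta, fc_low = fc_low, fc_high = fc_high,
                 de_alpha = de_alpha, assoc_fdr = assoc_fdr,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 mirna_min_fraction = mirna_min_fraction,
                 rng_seed = as.integer(rng_seed), subset = subset),
            class = "pipeline_config")
}

read_pipeline_inputs <- function(config) {
  counts <- read_matrix_tsv(config$counts)
  storage.mode(counts) <- "integer"
  totals_df <- read_table_tsv(config$pc_totals)
  totals <- setNames(totals_df$pc_total, totals_df$sample_id)
  meta <- read_table_tsv(config$metadata)
  mirna <- read_matrix_tsv(config$mirna)
  # cross-file consistency before any computation
  if (!setequal(colnames(counts), meta$sample_id)) {
    stop("sample ids differ between counts and metadata")
  }
  if (!all(colnames(counts) %in% names(totals))) {
    stop("sample ids missing from pc_totals")
  }
  if (!setequal(colnames(mirna), colnames(counts))) {
    stop("sample ids differ between mirna matrix and counts")
  }
  if (config$subset != "all") {
    if (!"msi_status" %in% names(meta)) {
      stop("subset requested but metadata lacks an msi_status column")
    }
    keep <- meta$msi_status == toupper(config$subset)
    meta <- meta[keep, ]
    counts <- counts[, meta$sample_id, drop = FALSE]
    mirna <- mirna[, meta$sample_id, drop = FALSE]
    totals <- totals[meta$sample_id]
  }
  sm <- meta[, c("sample_id", "subject_id", "tissue")]
  expr <- paired_expression_set(counts, totals, sm)
  cohort <- unique(meta[, setdiff(names(meta), c("sample_id", "tissue"))])
  list(expr = expr,
       mirna = mirna_matrix(mirna[, expr$sample_meta$sample_id,
                                  drop = FALSE], sm),
       cohort = cohort,
       mirna_seqs = read_mirna_fasta(config$mirna_fasta),
       utrs = read_utr_fasta(config$utr_fasta))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order, writing each stage's table plus a JSON
#' manifest (config echo, seed, input hashes, summary counts) into
#' `out_dir`. Reruns with the same inputs, config and seed produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_pipeline_inputs(config)
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  ## 1. normalization
  norm <- rpmpcg(inp$expr)
  mir_scaled <- scale_mirna(inp$mirna)
  write_matrix_tsv(norm$values, file.path(out_dir, "rpmpcg.tsv"), "gene")
  write_matrix_tsv(mir_scaled$signal,
                   file.path(out_dir, "mirna_scaled.tsv"), "mirna")

  ## 2. paired differential expression + band filter
  de <- de_table(inp$expr, fc_low = config$fc_low, fc_high = config$fc_high)
  write_table_tsv(de, file.path(out_dir, "de.tsv"))
  banded <- de$gene[!is.na(de$p_adj) & de$p_adj < config$de_alpha &
                      de$band %in% c("up_strong", "down_strong")]
  note("genes tested: ", nrow(de), "; banded at adj p < ", config$de_alpha,
       ": ", length(banded))

  ## 3. differential profiles + miRNA filter
  prof_mrna <- make_differential_profiles(norm$values,
                                          inp$expr$sample_meta)
  kept_mirnas <- filter_mirnas(mir_scaled, config$mirna_min_fraction)
  note("miRNAs passing the >", 100 * config$mirna_min_fraction,
       "% expression filter: ", length(kept_mirnas), " of ",
       nrow(mir_scaled$signal))
  prof_mirna <- make_differential_profiles(
    mir_scaled$signal[kept_mirnas, , drop = FALSE],
    mir_scaled$sample_meta)

  ## 4. association (banded genes x filtered miRNAs)
  assoc <- if (length(banded) && length(kept_mirnas)) {
    associate_all(prof_mrna[banded, , drop = FALSE], prof_mirna,
                  inp$cohort, n_boot = config$n_boot,
                  rng_seed = config$rng_seed)
  } else {
    data.frame(gene = character(), mirna = character(), beta = numeric(),
               f_obs = numeric(), p_boot = numeric(),
               n_boot = integer(), direction = character(),
               fdr_gene = numeric(), stringsAsFactors = FALSE)
  }
  write_table_tsv(assoc, file.path(out_dir, "association.tsv"))
  sig <- assoc[!is.na(assoc$fdr_gene) & assoc$fdr_gene < config$assoc_fdr, ]
  note("pairs tested: ", nrow(assoc), "; significant at gene-level FDR < ",
       config$assoc_fdr, ": ", nrow(sig))

  ## 5. seed matching on every tested pair
  scan <- scan_pairs(assoc[, c("gene", "mirna")], inp$mirna_seqs, inp$utrs)
  write_table_tsv(scan$matches, file.path(out_dir, "seed_matches.tsv"))
  write_table_tsv(scan$summary, file.path(out_dir, "seed_summary.tsv"))

  ## 6. survival on banded genes and significant miRNAs
  sig_mirnas <- unique(sig$mirna)
  surv_feats <- rbind(
    if (length(banded))
      data.frame(feature = banded, class = "mrna",
                 stringsAsFactors = FALSE),
    if (length(sig_mirnas))
      data.frame(feature = sig_mirnas, class = "mirna",
                 stringsAsFactors = FALSE))
  surv <- if (!is.null(surv_feats) && nrow(surv_feats)) {
    profiles <- rbind(prof_mrna[surv_feats$feature[
      surv_feats$class == "mrna"], , drop = FALSE],
      prof_mirna[surv_feats$feature[surv_feats$class == "mirna"], ,
                 drop = FALSE])
    survive_all(profiles, inp$cohort,
                classes = setNames(surv_feats$class, surv_feats$feature),
                B = config$n_perm, rng_seed = config$rng_seed)
  } else {
    data.frame(feature = character(), class = character(),
               hr_per_iqr = numeric(), ci_low = numeric(),
               ci_high = numeric(), iqr = numeric(), p_perm = numeric(),
               n_events = integer(), flagged = logical(),
               fdr = numeric(), stringsAsFactors = FALSE)
  }
  write_table_tsv(surv, file.path(out_dir, "survival.tsv"))

  ## 7. edge list
  edges <- build_edge_list(sig, scan$summary, surv)
  write_table_tsv(edges, file.path(out_dir, "edges.tsv"))
  note("significant pairs with seed match: ",
       sum(edges$class != "indirect"),
       " (positive beta: ", sum(edges$class == "direct_positive"),
       ", negative beta: ", sum(edges$class == "direct_negative"), ")")

  manifest <- list(
    config = unclass(config),
    seed = config$rng_seed,
    inputs = as.list(tools::md5sum(c(config$counts, config$pc_totals,
                                     config$mirna, config$metadata,
                                     config$mirna_fasta,
                                     config$utr_fasta))),
    summary = list(genes_tested = nrow(de), genes_banded = length(banded),
                   mirnas_kept = length(kept_mirnas),
                   pairs_tested = nrow(assoc),
                   pairs_significant = nrow(sig),
                   direct_positive = sum(edges$class == "direct_positive"),
                   direct_negative = sum(edges$class == "direct_negative")),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(de = de, association = assoc, seed = scan,
                 survival = surv, edges = edges, manifest = manifest))
}

#' Build the miRNA-mRNA edge list
#'
#' Full join of significant association records with their seed-match
#' summaries; every tested pair must have been scanned (an association
#' without a scan record is a hard error). Nodes are annotated with
#' survival significance before and after FDR adjustment.
#'
#' @param assoc association records (significant subset).
#' @param seed_summary per-pair summary from [scan_pairs()].
#' @param surv survival records from [survive_all()] (may be empty).
#' @param alpha significance threshold for survival flags.
#' @return data frame: one row per (gene, miRNA) edge with `beta_sign`,
#'   `class`, and per-node survival flags.
#' @export
build_edge_list <- function(assoc, seed_summary, surv = NULL,
                            alpha = 0.05) {
  if (!nrow(assoc)) {
    return(data.frame(gene = character(), mirna = character(),
                      beta = numeric(), beta_sign = character(),
                      class = character(),
                      gene_survival = logical(), gene_survival_fdr = logical(),
                      mirna_survival = logical(),
                      mirna_survival_fdr = logical(),
                      stringsAsFactors = FALSE))
  }
  key_a <- paste(assoc$gene, assoc$mirna)
  key_s <- paste(seed_summary$gene, seed_summary$mirna)
  miss <- setdiff(key_a, key_s)
  if (length(miss)) {
    stop("association pair(s) never scanned for seed matches: ",
         paste(miss, collapse = "; "))
  }
  any_match <- seed_summary$any_match[match(key_a, key_s)]
  flag <- function(feature, adjusted) {
    if (is.null(surv) || !nrow(surv)) return(rep(FALSE, length(feature)))
    i <- match(feature, surv$feature)
    p <- if (adjusted) surv$fdr[i] else surv$p_perm[i]
    !is.na(p) & p < alpha
  }
  data.frame(
    gene = assoc$gene, mirna = assoc$mirna, beta = assoc$beta,
    beta_sign = assoc$direction,
    class = classify_interaction(assoc$beta, any_match),
    gene_survival = flag(assoc$gene, FALSE),
    gene_survival_fdr = flag(assoc$gene, TRUE),
    mirna_survival = flag(assoc$mirna, FALSE),
    mirna_survival_fdr = flag(assoc$mirna, TRUE),
    stringsAsFactors = FALSE)
}
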