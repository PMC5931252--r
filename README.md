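# ccmirnet

Paired tumor/normal miRNA–mRNA cell-cycle network analysis in R.

`ccmirnet` is for analysts integrating three layers of a paired-tissue
cancer study — RNA-seq gene counts, miRNA total gene signal, and
survival follow-up — to ask which cell-cycle genes are dysregulated in
carcinoma versus adjacent normal mucosa, which miRNAs track that
dysregulation, whether either layer predicts disease-specific survival,
and which gene–miRNA associations carry sequence evidence of direct
targeting. The package implements the full pipeline as tested functions,
plus a synthetic-data generator with planted effects so every stage can
be validated against known ground truth.

## The statistics at the core

**Normalization.** Gene expression in RPMPCG (reads per million
protein-coding genes): `x_gs = count_gs / T_s × 10⁶` with `T_s` the
sample's total protein-coding count. miRNA signal is 75th-percentile
scaled: sample `s` is multiplied by `median_s'(q75_s') / q75_s`.

**Paired differential expression.** Per gene, a negative-binomial
log-link regression

```
count ~ tissue + subject + offset(log T_s),   Var = μ + μ²/θ
```

whose tissue coefficient estimates the log fold change. θ is estimated
with a residual-df-corrected moment estimator (the per-subject
intercepts make the ML dispersion inconsistent), and the Wald statistic
uses a t reference. Report-table fold changes are the ratio of tissue
mean RPMPCG values; genes are banded at FC < 0.67 / > 1.50 (strict) with
BH-adjusted p-values.

**Association.** On per-subject differential profiles
`Δx = x_carcinoma − x_normal`, ordinary least squares

```
Δmrna ~ β·Δmirna + age + sex
```

with a residual-bootstrap F test: resample residuals of the
covariates-only null model, recompute the nested F, and report
`p = (1 + #{F* ≥ F_obs}) / (B + 1)` (B = 10,000), BH-adjusted within
each gene across its tested miRNAs.

**Survival.** Cox proportional hazards of disease-specific mortality
(other-cause deaths censored), adjusted for age, sex and AJCC stage,
with hazard ratios per interquartile range, `HR = exp(β·IQR)`, and
p-values from 10,000 permutations of the likelihood-ratio statistic in
which only the expression profile is shuffled.

**Seed matching.** 6/7/8-nt seeds anchored at mature-miRNA position 2;
the reverse complement (U→T) is searched in 3′-UTR FASTA across genome
builds. Significant associations with a match are *direct*
(β < 0: repression-consistent; β > 0: feedback/feed-forward candidate),
otherwise *indirect*.

## Worked example

The numbered drivers under `analysis/` run a complete simulated study
(217 subject pairs, 20 genes, 30 miRNAs, planted fold changes, slopes,
hazards and seed sites):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_association.R
Rscript analysis/04_seed_match.R
Rscript analysis/05_survival.R
Rscript analysis/06_network.R
```

Step 2 prints, for the simulated panel and for the published cell-cycle
reference table shipped in `inst/extdata/`:

```
Genes tested: 20
Banded (FC > 1.50 or < 0.67, adj p < 0.05): 6 -> g0001, g0002, g0003, g0004, g0005, g0006
Planted non-null genes g0001-g0006; recovered: 6 of 6
Published cell-cycle panel: 67 genes; 4 down-regulated below 0.67; 63 of 67 printed fold changes reproduced exactly at 2 dp
```

i.e. all six planted DE genes are recovered, the published panel has
exactly four down-regulated genes, and the two-decimal ratio of the
published per-gene means reproduces the published fold change for every
row that is internally consistent at the printed precision. Step 3
recovers all three planted gene–miRNA slopes at gene-level FDR < 0.05;
step 4 finds all four planted seed sites at their recorded positions;
step 5 estimates HR 0.752 (95% CI 0.587–0.965, permutation p = 0.018)
for the feature planted at HR 0.86 per IQR; step 6 assembles the edge
list with direct/indirect classes and survival flags.

Programmatic use mirrors the drivers:

```r
library(ccmirnet)
cfg <- sim_config(n_subjects = 217, n_genes = 20, n_mirnas = 30,
                  planted_log_fc = c(log(2.9), rep(0, 19)), rng_seed = 1)
sim <- simulate_study(cfg, "run/data")
de  <- de_table(sim$expr)                      # paired NB + bands + BH
```

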