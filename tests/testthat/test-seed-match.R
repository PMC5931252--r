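test_that("seed extraction follows the position-2 anchor", {
  s <- extract_seeds("UAGCUUAUCAGACUGAUGUUGA")
  expect_identical(s$seeds[["6"]], "AGCUUA")
  expect_identical(s$seeds[["7"]], "AGCUUAU")
  expect_identical(s$seeds[["8"]], "AGCUUAUC")
  a <- extract_seeds(strrep("A", 20))
  expect_identical(unname(unlist(a$seeds)),
                   c(strrep("A", 6), strrep("A", 7), strrep("A", 8)))
  expect_error(extract_seeds("UAGCUUAU"), "too short")   # 8 nt
  expect_error(extract_seeds("UAGCTXAUCAG"), "alphabet")
  # configurable anchor
  s3 <- extract_seeds("UAGCUUAUCAGACU", seed_start = 3L)
  expect_identical(s3$seeds[["6"]], "GCUUAU")
})

test_that("target-site strings are reverse complements written as DNA", {
  expect_identical(match_string("AGCUUA"), "TAAGCT")
  expect_identical(match_string("AAAAAA"), "TTTTTT")
  expect_identical(match_string("GCGCGC"), "GCGCGC")   # palindromic
})

test_that("the scanner agrees with the naive substring oracle", {
  seeds <- extract_seeds("UAGCUUAUCAGACUGAUGUUGA")
  site6 <- match_string(seeds$seeds[["6"]])
  # identity: UTR equal to the 6-mer site matches at position 1
  rep1 <- scan_utr(list(gene = "g", build = "GRCh38", sequence = site6),
                   seeds)
  expect_equal(rep1$position[rep1$seed_length == 6], 1)
  # empty UTR: empty report, not an error
  expect_equal(nrow(scan_utr(list(gene = "g", build = "GRCh38",
                                  sequence = ""), seeds)), 0)
  # random UTRs against the brute-force oracle, all three lengths
  set.seed(61)
  for (i in 1:50) {
    utr <- random_dna(sample(200:2000, 1))
    sds <- extract_seeds(random_rna(21))
    rep <- scan_utr(list(gene = "g", build = "GRCh38", sequence = utr),
                    sds)
    for (k in 6:8) {
      expect_identical(rep$position[rep$seed_length == k],
                       naive_scan(match_string(sds$seeds[[as.character(k)]]),
                                  utr))
    }
  }
})

test_that("an 8-mer match implies nested 7- and 6-mer matches", {
  set.seed(62)
  found8 <- 0
  for (i in 1:200) {
    sds <- extract_seeds(random_rna(20))
    utr <- paste0(random_dna(30), match_string(sds$seeds[["8"]]),
                  random_dna(30))
    rep <- scan_utr(list(gene = "g", build = "GRCh38", sequence = utr),
                    sds)
    p8 <- rep$position[rep$seed_length == 8]
    found8 <- found8 + length(p8)
    for (p in p8) {
      expect_true((p + 1) %in% rep$position[rep$seed_length == 7])
      expect_true((p + 2) %in% rep$position[rep$seed_length == 6])
    }
  }
  expect_gte(found8, 200)
})

test_that("matching is case-insensitive and N never matches", {
  seeds <- extract_seeds("UAGCUUAUCAGACUGAUGUUGA")
  utr <- paste0("aacc", tolower(match_string(seeds$seeds[["7"]])), "ggtt")
  rep <- scan_utr(list(gene = "g", build = "GRCh38", sequence = utr),
                  seeds)
  expect_equal(rep$position[rep$seed_length == 7], 5)
  # every position overlapping an N is excluded (N fraction kept under
  # the 10% rejection threshold; flanks cannot host any seed site)
  utr_n <- paste0(strrep("AC", 20),
                  sub("^.", "N", match_string(seeds$seeds[["6"]])),
                  strrep("GT", 20))
  rep_n <- scan_utr(list(gene = "g", build = "GRCh38", sequence = utr_n),
                    seeds)
  expect_equal(nrow(rep_n), 0)
  # > 10% N rejected with a warning
  expect_warning(
    rep_bad <- scan_utr(list(gene = "g", build = "GRCh38",
                             sequence = paste0(strrep("N", 20),
                                               random_dna(80))),
                        seeds),
    "10% N")
  expect_equal(nrow(rep_bad), 0)
})

test_that("pair scanning aggregates isoforms and builds monotonically", {
  seeds <- extract_seeds("UAGCUUAUCAGACUGAUGUUGA")
  site <- match_string(seeds$seeds[["7"]])
  mirna_seqs <- c(m1 = "UAGCUUAUCAGACUGAUGUUGA")
  pairs <- data.frame(gene = "gX", mirna = "m1",
                      stringsAsFactors = FALSE)
  utr37 <- data.frame(gene = "gX", build = "GRCh37",
                      sequence = random_dna(60), stringsAsFactors = FALSE)
  utr38 <- data.frame(gene = "gX", build = "GRCh38",
                      sequence = paste0(random_dna(20), site,
                                        random_dna(20)),
                      stringsAsFactors = FALSE)
  only37 <- scan_pairs(pairs, mirna_seqs, utr37)
  both <- scan_pairs(pairs, mirna_seqs, rbind(utr37, utr38))
  # adding a build can only add matches, never remove them
  expect_true(all(!only37$summary$any_match |
                    both$summary$any_match))
  expect_true(both$summary$any_match)
  expect_error(scan_pairs(data.frame(gene = "gX", mirna = "mZ"),
                          mirna_seqs, utr37), "no mature sequence")
})

test_that("interactions are classified by seed match and slope sign", {
  expect_identical(classify_interaction(-0.4, TRUE), "direct_negative")
  expect_identical(classify_interaction(0.31, TRUE), "direct_positive")
  expect_identical(classify_interaction(0.8, FALSE), "indirect")
  expect_identical(classify_interaction(-0.8, FALSE), "indirect")
  expect_identical(classify_interaction(0, TRUE), "direct_none")
})

test_that("FASTA round-trip preserves ids, builds and sequences", {
  cfg <- sim_config(n_subjects = 5, n_genes = 3, n_mirnas = 2,
                    utr_length = 100, rng_seed = 63,
                    builds = c("GRCh37", "GRCh38"))
  seqs <- generate_sequences(cfg)
  d <- withr::local_tempdir()
  write_sequence_fasta(seqs, file.path(d, "m.fa"), file.path(d, "u.fa"))
  m <- read_mirna_fasta(file.path(d, "m.fa"))
  expect_identical(m, seqs$mirna_seqs)
  u <- read_utr_fasta(file.path(d, "u.fa"))
  u <- u[order(u$gene, u$build), ]
  ref <- seqs$utrs[order(seqs$utrs$gene, seqs$utrs$build), ]
  expect_equal(u, ref, ignore_attr = c("row.names", "out.attrs"))
})
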