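## miRNA seed extraction and 3' UTR target-site scanning. Seeds of 6, 7
## and 8 nt are anchored at position 2 of the mature miRNA (the canonical
## 6mer / 7mer-m8 / 8mer-family anchor); the target site searched in the
## sense-strand UTR is the reverse complement with U -> T. All overlapping
## occurrences are reported.

SEED_LENGTHS <- c(6L, 7L, 8L)

#' Extract 6/7/8-nt seeds from a mature miRNA sequence
#'
#' Seeds are contiguous subsequences anchored at `seed_start` (default 2,
#' 1-based) of the 5'->3' mature sequence: positions 2-7 (6-mer), 2-8
#' (7-mer) and 2-9 (8-mer) under the default anchor.
#'
#' @param mature mature miRNA sequence, RNA alphabet (A/C/G/U, case
#'   insensitive), length >= 9.
#' @param seed_start 1-based anchor of the seed (configurable; default 2).
#' @return list with `sequence` and `seeds` (named list `"6"`, `"7"`,
#'   `"8"`).
#' @export
extract_seeds <- function(mature, seed_start = 2L) {
  s <- toupper(mature)
  if (!grepl("^[ACGU]+$", s)) {
    stop("invalid miRNA alphabet (expected RNA A/C/G/U): ", mature)
  }
  if (nchar(s) < seed_start + max(SEED_LENGTHS) - 1L) {
    stop("mature sequence too short for an 8-nt seed at position ",
         seed_start, ": ", mature)
  }
  seeds <- lapply(SEED_LENGTHS, function(k) {
    substr(s, seed_start, seed_start + k - 1L)
  })
  names(seeds) <- as.character(SEED_LENGTHS)
  list(sequence = s, seeds = seeds)
}

#' Target-site string of a seed
#'
#' The Watson-Crick target of a seed as it appears in the sense-strand 3'
#' UTR: the reverse complement, written in DNA (U -> T).
#'
#' @param seed RNA seed from [extract_seeds()].
#' @return DNA string to search for in the UTR.
#' @export
match_string <- function(seed) {
  dna <- Biostrings::DNAString(chartr("Uu", "Tt", toupper(seed)))
  as.character(Biostrings::reverseComplement(dna))
}

#' Scan a 3' UTR for seed target sites
#'
#' Reports all (possibly overlapping) occurrences of each seed's target
#' site in the UTR, as 1-based start positions. Matching is
#' case-insensitive; `N` bases never match; sequences with more than 10% N
#' are rejected with a warning (empty report).
#'
#' @param utr list or one-row data frame with `gene`, `build`, `sequence`
#'   (DNA, may contain N).
#' @param seeds output of [extract_seeds()].
#' @param mirna miRNA id to stamp into the report.
#' @return data frame with columns `gene`, `mirna`, `build`,
#'   `seed_length`, `position` (zero rows when nothing matches).
#' @export
scan_utr <- function(utr, seeds, mirna = NA_character_) {
  seq <- toupper(utr$sequence)
  empty <- data.frame(gene = character(), mirna = character(),
                      build = character(), seed_length = integer(),
                      position = integer(), stringsAsFactors = FALSE)
  if (!nchar(seq)) return(empty)
  if (!grepl("^[ACGTN]+$", seq)) {
    stop("invalid UTR alphabet for gene ", utr$gene)
  }
  n_frac <- lengths(regmatches(seq, gregexpr("N", seq))) / nchar(seq)
  if (n_frac > 0.10) {
    warning("UTR for gene ", utr$gene, " has >10% N; skipped")
    return(empty)
  }
  subject <- Biostrings::DNAString(seq)
  out <- lapply(SEED_LENGTHS, function(k) {
    pat <- match_string(seeds$seeds[[as.character(k)]])
    hits <- Biostrings::matchPattern(pat, subject, fixed = TRUE)
    pos <- Biostrings::start(hits)
    if (!length(pos)) return(NULL)
    data.frame(gene = utr$gene, mirna = mirna, build = utr$build,
               seed_length = k, position = sort(pos),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Scan all (gene, miRNA) pairs across builds
#'
#' Multi-isoform/multi-build UTR sets are supported: a pair "has a match"
#' if any of its UTR records in any build matches (per-record detail is
#' retained in `matches`).
#'
#' @param pairs data frame with columns `gene`, `mirna`.
#' @param mirna_seqs named character vector of mature sequences.
#' @param utrs data frame with `gene`, `build`, `sequence` (one row per
#'   UTR record).
#' @return list with `matches` (all positions) and `summary` (per pair:
#'   `any_match`, per-length booleans).
#' @export
scan_pairs <- function(pairs, mirna_seqs, utrs) {
  missing_m <- setdiff(unique(pairs$mirna), names(mirna_seqs))
  if (length(missing_m)) {
    stop("no mature sequence for miRNA(s): ",
         paste(missing_m, collapse = ", "))
  }
  seed_cache <- lapply(mirna_seqs, extract_seeds)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene[i]; m <- pairs$mirna[i]
    recs <- utrs[utrs$gene == g, , drop = FALSE]
    if (!nrow(recs)) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(recs)), function(r) {
      scan_utr(recs[r, ], seed_cache[[m]], mirna = m)
    }))
  })
  matches <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(matches)) {
    matches <- data.frame(gene = character(), mirna = character(),
                          build = character(), seed_length = integer(),
                          position = integer(), stringsAsFactors = FALSE)
  }
  key <- paste(pairs$gene, pairs$mirna)
  mkey <- paste(matches$gene, matches$mirna)
  summary <- data.frame(
    gene = pairs$gene, mirna = pairs$mirna,
    match6 = key %in% mkey[matches$seed_length == 6L],
    match7 = key %in% mkey[matches$seed_length == 7L],
    match8 = key %in% mkey[matches$seed_length == 8L],
    stringsAsFactors = FALSE)
  summary$any_match <- summary$match6 | summary$match7 | summary$match8
  list(matches = matches, summary = summary)
}

#' Classify a gene-miRNA association as direct or indirect
#'
#' Direct associations have an identified seed match: with a negative slope
#' they are repression-consistent (`direct_negative`); with a positive
#' slope they are feedback / feed-forward-loop candidates
#' (`direct_positive`). Pairs without a seed match are `indirect`. A zero
#' slope with a match is classified by the match alone (`direct_none`).
#'
#' @param beta association slope.
#' @param any_match logical, seed match found for the pair.
#' @return character class.
#' @export
classify_interaction <- function(beta, any_match) {
  ifelse(!any_match, "indirect",
         ifelse(beta < 0, "direct_negative",
                ifelse(beta > 0, "direct_positive", "direct_none")))
}

#' Read mature miRNA sequences from FASTA
#' @param path FASTA path (RNA or DNA alphabet; T is read as U).
#' @return named character vector of RNA sequences.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- chartr("Tt", "Uu", toupper(as.character(ss)))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Read 3' UTR records from FASTA
#'
#' Headers follow the grammar `gene|build` (build optional, defaulting to
#' `"GRCh38"`); several records per gene (isoforms, builds) are allowed.
#'
#' @param path FASTA path.
#' @return data frame with `gene`, `build`, `sequence`.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- sub("\\s.*$", "", names(ss))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  data.frame(
    gene = vapply(parts, `[`, character(1), 1),
    build = vapply(parts, function(p) if (length(p) > 1) p[2] else "GRCh38",
                   character(1)),
    sequence = toupper(as.character(ss)),
    stringsAsFactors = FALSE, row.names = NULL)
}
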