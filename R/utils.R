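## Shared internal helpers: percentile convention, RNG sub-streams, TSV IO.

#' Percentile with the package-wide convention
#'
#' All quantiles in the package (75th percentile scaling factors, the IQR
#' used to scale hazard ratios) use linear interpolation between order
#' statistics (type 7), the default of [stats::quantile()].
#'
#' @param x numeric vector.
#' @param p probability in \[0, 1\].
#' @return the type-7 sample quantile.
#' @keywords internal
pctl <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

#' Interquartile range (q75 - q25, type-7 quantiles)
#' @param x numeric vector.
#' @return scalar IQR.
#' @export
iqr_type7 <- function(x) pctl(x, 0.75) - pctl(x, 0.25)

## Deterministic sub-stream seed derived from a base seed, a stage tag and a
## feature index, so that adding features never perturbs the draws of
## existing ones. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag)) * 10007
  s <- (abs(as.double(seed)) * 48271 + h + as.double(index) * 2654435761) %%
    2147483629
  as.integer(s)
}

## Run `expr` under a local RNG state seeded with `seed`; the caller's
## global RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Read a feature-by-sample TSV matrix
#'
#' First column = feature id, remaining columns = samples; header row carries
#' sample ids. The inverse of [write_matrix_tsv()].
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m matrix with rownames (feature ids) and colnames (sample ids).
#' @param path file path.
#' @param id_col name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV ("." for missing)
#' @param d data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#' @param path file path.
#' @return data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = ".")
}

stop_invalid <- function(...) {
  stop(structure(class = c("ccmirnet_invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
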