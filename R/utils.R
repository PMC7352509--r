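# Internal helpers: deterministic substreams, TSV io, small validators.

#' Derive a reproducible substream seed from a base seed and a name
#'
#' All stochastic generators in the package draw from per-unit substreams so
#' that adding samples (or reordering calls) never perturbs the draws of
#' units generated earlier. The substream seed is a deterministic 31-bit hash
#' of the base seed and a character label, fed to R's Mersenne-Twister.
#'
#' @param seed integer base seed.
#' @param name character label of the substream (e.g. a sample id).
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(name))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(substream_seed(seed, name), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

#' Write a data frame or matrix as tab-separated text
#'
#' Matrices are written with a leading id column holding their row names.
#'
#' @param x data frame or matrix.
#' @param path output file.
#' @param id_col name for the row-name column when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, id_col = "id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- id_col
    x <- df
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path file path.
#' @param row_col optional column name to promote to row names (returning a
#'   numeric matrix).
#' @return data frame, or numeric matrix when `row_col` is given.
#' @export
read_tsv <- function(path, row_col = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(row_col)) {
    rn <- df[[row_col]]
    df[[row_col]] <- NULL
    m <- as.matrix(df)
    rownames(m) <- rn
    return(m)
  }
  df
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
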