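#' Construct a taxa-by-sample count table
#'
#' A `count_table` holds a nonnegative numeric matrix with taxa as rows and
#' samples as columns, together with the per-sample library sizes (column
#' sums, the multinomial totals). Raw input counts are integers; after zero
#' replacement or winsorization entries may be fractional. Library sizes are
#' recomputed after every mutation so they always equal the column sums.
#'
#' @param counts numeric matrix (taxa x samples), entries >= 0. Row names are
#'   taxon identifiers, column names sample identifiers; defaults are
#'   generated when absent.
#' @return an object of class `count_table` with elements `counts`,
#'   `taxon_ids`, `sample_ids`, `library_sizes`.
#' @examples
#' ct <- count_table(matrix(rpois(12, 50), nrow = 3))
#' ct$library_sizes
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("count table entries must be finite and nonnegative")
  }
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("count table needs at least 1 taxon and 1 sample")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("taxon", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  structure(
    list(
      counts = counts,
      taxon_ids = rownames(counts),
      sample_ids = colnames(counts),
      library_sizes = colSums(counts)
    ),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "count_table: %d taxa x %d samples; depth range [%s, %s]\n",
    nrow(x$counts), ncol(x$counts),
    format(min(x$library_sizes)), format(max(x$library_sizes))
  ))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

# Rebuild the object from a (possibly mutated) matrix, keeping the class
# invariant that library_sizes == colSums.
rebuild_count_table <- function(counts) count_table(counts)

#' Read a count table from TSV/CSV or BIOM
#'
#' Plain-text tables must have taxa as rows, a first column of taxon
#' identifiers, and a header row of sample identifiers. The separator is
#' inferred from the file extension (`.csv` -> comma, otherwise tab). Files
#' ending in `.biom` are read through the biomformat package when available.
#'
#' @param path file path.
#' @return a [count_table].
#' @export
read_count_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_table(m))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  count_table(m)
}

#' Read sample metadata
#'
#' @param path TSV (or CSV) file with one row per sample.
#' @param sample_col name of the column holding sample identifiers matching
#'   the count-table headers; defaults to the first column.
#' @return data.frame with row names set to sample identifiers.
#' @export
read_metadata <- function(path, sample_col = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (is.null(sample_col)) sample_col <- names(df)[1]
  rownames(df) <- as.character(df[[sample_col]])
  df
}

#' Construct a regression design for differential abundance testing
#'
#' Assembles the per-sample design used by every per-taxon regression:
#' the variable of interest `u` (binary 0/1 or continuous), an intercept and
#' an optional covariate block `C`. Coefficients are ordered with the effect
#' of interest first, then the intercept, then covariates, so the (1,1)
#' entry of the coefficient covariance is always the variance of the effect
#' of interest.
#'
#' @param u numeric vector, variable of interest (length n).
#' @param covariates optional numeric matrix or data.frame (n x d).
#' @return object of class `daa_design` with elements `u`, `C`, `Z`
#'   (the n x (d+2) regression matrix `[u, 1, C]`), `n`, `d`, `df_resid`
#'   (= n - d - 2).
#' @export
daa_design <- function(u, covariates = NULL) {
  u <- as.numeric(u)
  n <- length(u)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    if (nrow(C) != n) stop("covariates must have one row per sample")
  } else {
    C <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  d <- ncol(C)
  Z <- cbind(u = u, intercept = 1, C)
  if (qr(cbind(1, u, C))$rank < d + 2L) {
    stop("design matrix [1, u, covariates] is rank deficient ",
         "(is the variable of interest constant?)")
  }
  if (n <= d + 2L) stop("need n > d + 2 samples for positive residual df")
  structure(
    list(u = u, C = C, Z = Z, n = n, d = d, df_resid = n - d - 2L),
    class = "daa_design"
  )
}

#' @export
print.daa_design <- function(x, ...) {
  cat(sprintf("daa_design: n = %d samples, %d covariate(s), residual df = %d\n",
              x$n, x$d, x$df_resid))
  invisible(x)
}
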