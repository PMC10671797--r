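#' Filter samples by sequencing depth
#'
#' Removes samples whose library size (total read count) falls below a
#' minimum depth. Sample order is preserved. The conventional threshold for
#' 16S data is 1000 reads.
#'
#' @param table a [count_table].
#' @param min_depth positive integer; samples with fewer total reads are
#'   dropped.
#' @return filtered [count_table].
#' @export
filter_samples <- function(table, min_depth = 1000) {
  stopifnot(inherits(table, "count_table"), min_depth >= 1)
  keep <- table$library_sizes >= min_depth
  if (!any(keep)) stop("all samples removed: no sample reaches min_depth")
  rebuild_count_table(table$counts[, keep, drop = FALSE])
}

#' Filter taxa by prevalence
#'
#' Keeps taxa observed (nonzero) in at least `min_prevalence` of the
#' samples; taxa present in strictly fewer samples are removed. Taxon order
#' is preserved. A common choice is 10% prevalence.
#'
#' @param table a [count_table].
#' @param min_prevalence fraction in (0, 1].
#' @return filtered [count_table].
#' @export
filter_taxa <- function(table, min_prevalence = 0.10) {
  stopifnot(inherits(table, "count_table"),
            min_prevalence > 0, min_prevalence <= 1)
  n <- ncol(table$counts)
  prev <- rowSums(table$counts > 0) / n
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("all taxa removed by the prevalence filter")
  rebuild_count_table(table$counts[keep, , drop = FALSE])
}

#' Choose between pseudo-count and imputation zero handling
#'
#' The hybrid rule regresses log library size on the design
#' `[1, u, covariates]` by least squares and reads off the two-sided t-test
#' p-value for the variable of interest. When library size is associated
#' with the variable of interest (p < alpha), a uniform pseudo-count would
#' induce a spurious depth-driven signal, so depth-proportional imputation
#' is selected instead.
#'
#' @param table a [count_table]; library sizes are taken from this table, so
#'   pass the raw (pre-winsorization) counts.
#' @param design a [daa_design].
#' @param alpha decision level, default 0.1.
#' @return `"imputation"` if p < alpha else `"pseudo_count"`, with the
#'   p-value attached as attribute `"pvalue"`.
#' @export
select_zero_strategy <- function(table, design, alpha = 0.1) {
  stopifnot(inherits(table, "count_table"), inherits(design, "daa_design"),
            alpha > 0, alpha < 1)
  if (length(unique(design$u)) < 2L) {
    stop("variable of interest is constant; zero-strategy test is degenerate")
  }
  y <- log(table$library_sizes)
  X <- cbind(1, design$u, design$C)
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  dfr <- length(y) - fit$rank
  sigma2 <- sum(res^2) / dfr
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se_u <- sqrt(sigma2 * XtX_inv[2, 2])
  tstat <- fit$coefficients[2] / se_u
  p <- 2 * stats::pt(abs(tstat), df = dfr, lower.tail = FALSE)
  strategy <- if (is.finite(p) && p < alpha) "imputation" else "pseudo_count"
  attr(strategy, "pvalue") <- unname(p)
  strategy
}

#' Replace zero counts
#'
#' Two strategies:
#' \describe{
#'   \item{pseudo_count}{add 0.5 to every entry.}
#'   \item{imputation}{for each taxon with at least one zero, replace each
#'     zero in sample s by `0.5 * N_s / max(N_k : Y_ik = 0)` -- larger
#'     fractions for deeper samples, on the half-count scale. Nonzero
#'     entries and zero-free taxa are untouched. Set `impute_half = FALSE`
#'     to drop the 0.5 factor and use the bare depth ratio.}
#' }
#' Library sizes are recomputed; all output entries are strictly positive
#' (under imputation only taxa that had zeros are guaranteed positive where
#' they were zero -- nonzero entries were already positive).
#'
#' @param table a [count_table].
#' @param strategy `"pseudo_count"` or `"imputation"`.
#' @param impute_half logical; multiply the imputation fraction by 0.5
#'   (default TRUE).
#' @return [count_table] with zeros replaced.
#' @export
replace_zeros <- function(table, strategy = c("pseudo_count", "imputation"),
                          impute_half = TRUE) {
  strategy <- match.arg(strategy)
  Y <- table$counts
  if (strategy == "pseudo_count") {
    Y <- Y + 0.5
  } else {
    N <- table$library_sizes
    fac <- if (impute_half) 0.5 else 1
    for (i in seq_len(nrow(Y))) {
      zero <- Y[i, ] == 0
      if (any(zero)) {
        denom <- max(N[zero])
        Y[i, zero] <- fac * N[zero] / denom
      }
    }
  }
  out <- rebuild_count_table(Y)
  attr(out, "zero_strategy") <- strategy
  out
}

#' Winsorize counts per taxon
#'
#' For each taxon, values above its empirical `tau`-quantile (linear
#' interpolation, quantile type 7) are replaced by that quantile; values at
#' or below it are unchanged. Winsorized values may be fractional. Library
#' sizes are recomputed. `tau = 1` is the identity.
#'
#' @param table a [count_table].
#' @param tau quantile level in (0, 1]; 0.97 and 0.90 are the levels used
#'   for LinDA97/LinDA90-style analyses.
#' @return winsorized [count_table].
#' @export
winsorize_counts <- function(table, tau) {
  stopifnot(inherits(table, "count_table"), tau > 0, tau <= 1)
  Y <- table$counts
  q <- apply(Y, 1, stats::quantile, probs = tau, names = FALSE, type = 7)
  Y <- pmin(Y, q)   # q recycles down columns, i.e. per taxon
  out <- rebuild_count_table(Y)
  attr(out, "winsor_tau") <- tau
  out
}

#' Centred log-ratio transform
#'
#' Maps each sample's (strictly positive) counts to CLR coordinates:
#' `W_is = log Y_is - mean_j log Y_js`. Each sample's CLR values sum to
#' zero, and the transform is invariant to rescaling a sample's counts by a
#' positive constant, so only relative abundance information survives.
#'
#' @param table a [count_table] with all entries > 0 (apply zero handling
#'   first).
#' @return numeric matrix (taxa x samples) of class `clr_matrix`, with
#'   attributes recording the zero-handling strategy and winsorization
#'   level when known.
#' @export
clr_transform <- function(table) {
  stopifnot(inherits(table, "count_table"))
  Y <- table$counts
  if (any(Y <= 0)) {
    stop("count table has nonpositive entries; apply replace_zeros() first")
  }
  L <- log(Y)
  W <- sweep(L, 2, colMeans(L), "-")
  structure(W,
            class = c("clr_matrix", "matrix", "array"),
            zero_strategy = attr(table, "zero_strategy"),
            winsor_tau = attr(table, "winsor_tau"))
}

#' Full preprocessing pipeline
#'
#' Applies, in order: depth filter, prevalence filter, optional per-taxon
#' winsorization, zero handling (automatic hybrid rule, or forced), CLR.
#' The zero-strategy test uses library sizes of the filtered but
#' pre-winsorization table, since sequencing depth is a property of the raw
#' sample.
#'
#' @param table raw [count_table].
#' @param design a [daa_design] aligned with the table's samples (required
#'   for `zero_mode = "auto"`).
#' @param min_depth,min_prevalence filter thresholds.
#' @param winsor_tau optional winsorization quantile (NULL = none).
#' @param zero_mode `"auto"`, `"pseudo"` or `"impute"`.
#' @param zero_alpha decision level for the automatic rule.
#' @return list with `clr` (the [clr_transform] output), `table` (processed
#'   counts), `zero_strategy`, and the sample/taxon ids retained.
#' @export
preprocess_counts <- function(table, design = NULL,
                              min_depth = 1000, min_prevalence = 0.10,
                              winsor_tau = NULL,
                              zero_mode = c("auto", "pseudo", "impute"),
                              zero_alpha = 0.1) {
  zero_mode <- match.arg(zero_mode)
  tab <- filter_samples(table, min_depth)
  # depth is a property of the sequenced sample: the zero-strategy test
  # uses library sizes from before the taxa filter and winsorization
  strategy <- switch(zero_mode,
    pseudo = "pseudo_count",
    impute = "imputation",
    auto = {
      if (is.null(design)) stop("zero_mode='auto' needs a design")
      as.character(select_zero_strategy(tab, design, zero_alpha))
    })
  tab <- filter_taxa(tab, min_prevalence)
  empty <- tab$library_sizes == 0
  if (any(empty)) {
    message(sum(empty), " sample(s) with no reads on retained taxa dropped")
    tab <- rebuild_count_table(tab$counts[, !empty, drop = FALSE])
  }
  if (!is.null(winsor_tau)) tab <- winsorize_counts(tab, winsor_tau)
  tab2 <- replace_zeros(tab, strategy)
  if (!is.null(winsor_tau)) attr(tab2, "winsor_tau") <- winsor_tau
  list(clr = clr_transform(tab2),
       table = tab2,
       zero_strategy = strategy,
       taxon_ids = tab2$taxon_ids,
       sample_ids = tab2$sample_ids)
}
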