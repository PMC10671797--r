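#' Kernel mode estimate
#'
#' Gaussian-kernel density estimate with Silverman's rule-of-thumb
#' bandwidth `0.9 min(sd, IQR/1.34) m^(-1/5)`, evaluated on a 512-point
#' grid spanning `[min - 3h, max + 3h]`; the mode is the grid argmax, ties
#' broken toward the smallest abscissa. Used to locate the common
#' compositional shift in a vector of per-taxon effect estimates.
#'
#' @param values numeric vector, length >= 2 (a constant vector returns its
#'   value directly).
#' @return the estimated mode, with the bandwidth attached as attribute
#'   `"bandwidth"`.
#' @export
estimate_mode <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  if (diff(range(values)) == 0) {
    out <- values[1]
    attr(out, "bandwidth") <- 0
    return(out)
  }
  h <- silverman_bw(values)
  if (h <= 0) {
    out <- stats::median(values)
    attr(out, "bandwidth") <- 0
    return(out)
  }
  grid <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = 512)
  dens <- vapply(grid,
                 function(g) mean(stats::dnorm((g - values) / h)) / h,
                 numeric(1))
  out <- grid[which.max(dens)]   # which.max breaks ties at the first (smallest) abscissa
  attr(out, "bandwidth") <- h
  out
}

#' Mode-based bias correction of compositional effect estimates
#'
#' CLR regression estimates each taxon's effect only up to a shared shift
#' (the mean effect across taxa), which is unidentifiable from relative
#' abundances. Assuming most taxa are non-differential, the per-taxon
#' estimates pile up at minus that shift, so its kernel mode recovers it:
#' `alpha_hat_i = alpha_tilde_i - mode({sqrt(n) alpha_tilde_j}) / sqrt(n)`.
#' The root-n scaling sharpens the null peak before mode estimation.
#'
#' @param alpha_tilde numeric vector of raw per-taxon effect estimates.
#' @param n sample count used in the fits.
#' @return corrected vector, with the estimated shift attached as attribute
#'   `"shift"` (the value subtracted from every element).
#' @export
bias_correct <- function(alpha_tilde, n) {
  stopifnot(length(alpha_tilde) >= 2L, n >= 1)
  shift <- as.numeric(estimate_mode(sqrt(n) * alpha_tilde)) / sqrt(n)
  out <- alpha_tilde - shift
  attr(out, "shift") <- shift
  out
}

#' Two-sided t-test p-values for corrected effects
#'
#' `p_i = 2 P(T_df >= |alpha_hat_i / se_i|)`. The t reference (rather than
#' the asymptotic normal) gives better finite-sample FDR control.
#' Degenerate standard errors: `se = 0` with a nonzero effect yields p = 0
#' (with a warning); `se = 0` with a zero effect yields p = 1.
#'
#' @param alpha_hat corrected effects.
#' @param se standard errors (>= 0).
#' @param df degrees of freedom, `n - d - 2`.
#' @return vector of p-values in [0, 1].
#' @export
t_pvalues <- function(alpha_hat, se, df) {
  stopifnot(df >= 1, length(alpha_hat) == length(se), all(se >= 0))
  p <- numeric(length(alpha_hat))
  zero_se <- se == 0
  if (any(zero_se & alpha_hat != 0)) {
    warning("zero standard error with nonzero effect: p-value set to 0")
  }
  p[zero_se] <- ifelse(alpha_hat[zero_se] == 0, 1, 0)
  ok <- !zero_se
  p[ok] <- 2 * stats::pt(abs(alpha_hat[ok] / se[ok]), df = df,
                         lower.tail = FALSE)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (`stats::p.adjust`, method `"BH"`).
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Cauchy combination of p-values across a hyperparameter grid
#'
#' Per taxon (row), transforms each grid p-value by `tan((0.5 - p) pi)`,
#' averages, and maps back: `0.5 - atan(mean)/pi`. The transform is exact
#' at a common value (all-equal rows return that value) and is valid under
#' arbitrary dependence between the grid's p-values. Entries are clipped to
#' `[1e-15, 1 - 1e-15]` before transforming.
#'
#' @param pvalue_matrix numeric matrix, taxa x grid values (a vector is
#'   treated as a single-column matrix).
#' @return vector of combined p-values, one per taxon.
#' @export
cauchy_combine <- function(pvalue_matrix) {
  p <- as.matrix(pvalue_matrix)
  if (ncol(p) == 0L) stop("empty hyperparameter grid")
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  S <- rowMeans(tan((0.5 - p) * pi))
  0.5 - atan(S) / pi
}

#' Robust differential abundance analysis
#'
#' End-to-end driver: preprocess (depth/prevalence filters, optional
#' winsorization, hybrid zero handling, CLR), then for each tuning value in
#' the loss grid fit every taxon by M-estimation, mode-correct the effect
#' estimates and compute raw t p-values; combine p-values across the grid
#' by the Cauchy rule (skipped for a single tuning value); finally apply a
#' single BH pass. Reported point estimates (`alpha_tilde`, `alpha_hat`,
#' `se`, `stat`) come from the first grid value, which is the family's
#' default tuning constant.
#'
#' @param table raw [count_table].
#' @param metadata data.frame with row names (or a column named by
#'   `var`/`covariates`) matching the table's sample ids.
#' @param var name of the metadata column holding the variable of interest.
#' @param covariates character vector of metadata columns to adjust for
#'   (default none).
#' @param loss a [loss_spec], or a family name (string) from which a
#'   default spec is built.
#' @param min_depth,min_prevalence,winsor_tau,zero_mode,zero_alpha
#'   preprocessing controls, see [preprocess_counts()].
#' @param fdr_level nominal FDR for the `reject` flag (default 0.05).
#' @return object of class `daa_result`: a data.frame `table` with columns
#'   taxon, alpha_tilde, alpha_hat, se, stat, df, pvalue, padj, reject,
#'   converged; plus `meta` (run metadata: family, grid, zero strategy,
#'   winsorization level, n, df, fdr_level).
#' @export
run_robust_daa <- function(table, metadata, var, covariates = character(),
                           loss = loss_spec("huber"),
                           min_depth = 1000, min_prevalence = 0.10,
                           winsor_tau = NULL,
                           zero_mode = c("auto", "pseudo", "impute"),
                           zero_alpha = 0.1,
                           fdr_level = 0.05) {
  zero_mode <- match.arg(zero_mode)
  if (is.character(loss)) loss <- loss_spec(loss)
  stopifnot(inherits(table, "count_table"), inherits(loss, "loss_spec"))
  metadata <- as.data.frame(metadata)

  if (!all(table$sample_ids %in% rownames(metadata))) {
    stop("metadata does not cover all samples in the count table")
  }
  if (!var %in% names(metadata)) stop("metadata lacks column: ", var)
  missing_cov <- setdiff(covariates, names(metadata))
  if (length(missing_cov)) {
    stop("metadata lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  }

  # depth filter first, then align metadata to the retained samples
  tab <- filter_samples(table, min_depth)
  md <- metadata[tab$sample_ids, , drop = FALSE]
  u <- as.numeric(md[[var]])
  C <- if (length(covariates)) {
    as.matrix(data.frame(lapply(md[covariates], as.numeric)))
  } else NULL
  design <- daa_design(u, C)

  # the zero-strategy test regresses log depth on the design; depth is a
  # property of the sequenced sample, so it uses library sizes from before
  # the taxa filter (and before winsorization)
  strategy <- switch(zero_mode,
    pseudo = "pseudo_count",
    impute = "imputation",
    auto = as.character(select_zero_strategy(tab, design, zero_alpha)))
  tab <- filter_taxa(tab, min_prevalence)
  # a sample can lose all its reads to the taxa filter (e.g. one dominant
  # rare taxon removed); it carries no information on the retained
  # composition, so drop it and re-derive the design
  empty <- tab$library_sizes == 0
  if (any(empty)) {
    message(sum(empty), " sample(s) with no reads on retained taxa dropped")
    tab <- rebuild_count_table(tab$counts[, !empty, drop = FALSE])
    md <- md[tab$sample_ids, , drop = FALSE]
    u <- as.numeric(md[[var]])
    C <- if (length(covariates)) {
      as.matrix(data.frame(lapply(md[covariates], as.numeric)))
    } else NULL
    design <- daa_design(u, C)
  }
  if (!is.null(winsor_tau)) tab <- winsorize_counts(tab, winsor_tau)
  tab <- replace_zeros(tab, strategy)
  W <- clr_transform(tab)

  grid <- loss$grid
  if (is.null(grid) || all(is.na(grid))) grid <- loss$hyper
  m <- nrow(W)
  n <- design$n
  df <- design$df_resid

  pmat <- matrix(NA_real_, m, length(grid))
  first <- NULL
  for (k in seq_along(grid)) {
    spec_k <- loss_spec(loss$family, hyper = if (loss$family == "l2") NULL
                                             else grid[k])
    fits <- apply(W, 1, fit_taxon, design = design, loss = spec_k,
                  simplify = FALSE)
    alpha_tilde <- vapply(fits, function(f) f$theta_tilde[1], numeric(1))
    se <- sqrt(pmax(vapply(fits, function(f) f$sigma2_alpha, numeric(1)), 0))
    alpha_hat <- bias_correct(alpha_tilde, n)
    pmat[, k] <- suppressWarnings(t_pvalues(as.numeric(alpha_hat), se, df))
    if (k == 1L) {
      first <- list(alpha_tilde = alpha_tilde,
                    alpha_hat = as.numeric(alpha_hat),
                    shift = attr(alpha_hat, "shift"),
                    se = se,
                    converged = vapply(fits, `[[`, logical(1), "converged"))
    }
  }
  pvalue <- if (length(grid) > 1L) cauchy_combine(pmat) else pmat[, 1]
  padj <- bh_adjust(pvalue)

  n_nc <- sum(!first$converged)
  if (n_nc > 0) {
    message(n_nc, " taxon fit(s) did not converge; results flagged")
  }

  res <- data.frame(
    taxon = rownames(W),
    alpha_tilde = unname(first$alpha_tilde),
    alpha_hat = first$alpha_hat,
    se = unname(first$se),
    stat = ifelse(first$se > 0, first$alpha_hat / first$se, NA_real_),
    df = df,
    pvalue = pvalue,
    padj = padj,
    reject = padj <= fdr_level,
    converged = unname(first$converged),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = res,
         meta = list(family = loss$family, grid = grid,
                     zero_strategy = strategy,
                     winsor_tau = winsor_tau,
                     mode_shift = first$shift,
                     n = n, d = design$d, df = df,
                     fdr_level = fdr_level,
                     n_taxa = m)),
    class = "daa_result"
  )
}

#' @export
print.daa_result <- function(x, ...) {
  cat(sprintf(
    "daa_result: %d taxa, n = %d, loss = %s (grid of %d), zeros = %s\n",
    x$meta$n_taxa, x$meta$n, x$meta$family, length(x$meta$grid),
    x$meta$zero_strategy))
  cat(sprintf("%d taxa rejected at FDR %.2f\n",
              sum(x$table$reject), x$meta$fdr_level))
  invisible(x)
}

#' Write a DAA result table to TSV (with a JSON run-metadata sidecar)
#'
#' @param result a `daa_result`.
#' @param path output TSV path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_daa_result <- function(result, path) {
  stopifnot(inherits(result, "daa_result"))
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- result$meta
  meta$r_version <- as.character(getRversion())
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
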