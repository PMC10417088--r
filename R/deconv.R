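#' Configuration for the deconvolution regression
#'
#' The bulk profile `b` over the signature genes is modeled as a non-negative
#' combination of the signature columns, `b ~ A x`, `x >= 0`. Five solvers
#' are available:
#'
#' * `epsilon_svr` (default): linear epsilon-insensitive support vector
#'   regression. Residuals inside the epsilon tube carry no loss, so the fit
#'   is robust to gene-level noise; negative raw coefficients are clipped to
#'   zero afterwards.
#' * `l1`, `l2`, `elastic_net`: minimize the mean relative absolute error
#'   `100/n * sum_n |b_n - (Ax)_n| / b_n` plus the penalty
#'   `alpha * sum(x) + beta * sum(x^2)`, subject to `x >= 0`. Genes with
#'   `b_n = 0` are dropped from the relative-error sum.
#' * `lasso`: non-negative L1-penalized least squares (via glmnet) on
#'   standardized data, with penalty weight `alpha`.
#'
#' @param model One of `"epsilon_svr"`, `"l1"`, `"l2"`, `"elastic_net"`,
#'   `"lasso"`.
#' @param epsilon Width of the SVR insensitive tube, in standardized units
#'   (default 0.1).
#' @param C SVR penalty weight (default 1).
#' @param alpha L1 penalty weight (must be 0 for `l2`, > 0 for
#'   `elastic_net`).
#' @param beta L2 penalty weight (must be 0 for `l1`, > 0 for
#'   `elastic_net`).
#' @param standardize Z-score the signature and bulk jointly over the
#'   signature genes before fitting `epsilon_svr`/`lasso` (default TRUE).
#'   The relative-error models always work in raw linear space, since their
#'   objective divides by `b_n`.
#' @return An object of class `regression_config`.
#' @export
regression_config <- function(model = c("epsilon_svr", "l1", "l2",
                                        "elastic_net", "lasso"),
                              epsilon = 0.1, C = 1.0,
                              alpha = 0.1, beta = 0.1,
                              standardize = TRUE) {
  model <- match.arg(model)
  assert_scalar_number(epsilon, "epsilon", nonneg = TRUE)
  assert_scalar_number(C, "C", positive = TRUE)
  assert_scalar_number(alpha, "alpha", nonneg = TRUE)
  assert_scalar_number(beta, "beta", nonneg = TRUE)
  if (model == "l1") beta <- 0
  if (model == "l2") alpha <- 0
  if (model == "elastic_net" && (alpha <= 0 || beta <= 0))
    stop_("elastic_net requires alpha > 0 and beta > 0")
  structure(list(model = model, epsilon = epsilon, C = C,
                 alpha = alpha, beta = beta,
                 standardize = isTRUE(standardize)),
            class = "regression_config")
}

#' Align a bulk profile to the signature gene space
#'
#' Restricts signature and bulk to their common genes, in signature order.
#'
#' @param signature A `signature_matrix`.
#' @param bulk Named numeric vector (one bulk sample over its full gene
#'   universe) or a single-column matrix.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present in the bulk profile (default 0.5); below it, an error.
#' @return List with `signature` (reduced matrix), `bulk` (reduced vector),
#'   and `coverage`.
#' @export
align_genes <- function(signature, bulk, min_coverage = 0.5) {
  if (is.matrix(bulk)) {
    if (ncol(bulk) != 1L) stop_("'bulk' must be a single sample")
    bulk <- stats::setNames(bulk[, 1L], rownames(bulk))
  }
  if (is.null(names(bulk))) stop_("'bulk' must be a named vector of gene values")
  common <- intersect(rownames(signature), names(bulk))
  coverage <- length(common) / nrow(signature)
  if (coverage < min_coverage)
    stop_(sprintf(
      "bulk profile is missing %d of %d signature genes (coverage %.2f < %.2f)",
      nrow(signature) - length(common), nrow(signature), coverage, min_coverage))
  list(signature = signature[common, , drop = FALSE],
       bulk = bulk[common], coverage = coverage)
}

## joint z-scoring: one global mean/sd over signature entries, bulk scored
## against its own mean/sd (correlation-preserving; makes fractions invariant
## to the bulk profile's scale)
standardize_system <- function(A, b) {
  sA <- stats::sd(A)
  sb <- stats::sd(b)
  if (sA == 0) stop_("degenerate fit: signature has zero variance")
  if (sb == 0) stop_("degenerate fit: bulk profile is constant over signature genes")
  list(A = (A - mean(A)) / sA, b = (b - mean(b)) / sb)
}

fit_svr <- function(A, b, config) {
  if (config$standardize) {
    z <- standardize_system(A, b)
    A <- z$A; b <- z$b
  }
  fit <- e1071::svm(x = A, y = b, type = "eps-regression",
                    kernel = "linear", cost = config$C,
                    epsilon = config$epsilon, scale = FALSE)
  drop(t(fit$coefs) %*% fit$SV)
}

## mean relative absolute error + L1/L2 penalty, x >= 0, solved by
## projected quasi-Newton on a lightly smoothed |.| (delta = 1e-6)
fit_relative_error <- function(A, b, config) {
  keep <- b > 0
  if (!all(keep)) {
    message(sprintf("dropping %d gene(s) with zero bulk expression from the relative-error sum",
                    sum(!keep)))
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
  }
  n <- length(b)
  if (n < ncol(A)) warning("fewer usable genes than cell types; fit is underdetermined")
  k <- ncol(A)
  delta <- 1e-6
  Ab <- A / b  # rows scaled so residuals are relative
  obj <- function(x) {
    u <- 1 - drop(Ab %*% x)
    100 / n * sum(sqrt(u^2 + delta^2)) +
      config$alpha * sum(x) + config$beta * sum(x^2)
  }
  grad <- function(x) {
    u <- 1 - drop(Ab %*% x)
    w <- u / sqrt(u^2 + delta^2)
    -100 / n * drop(crossprod(Ab, w)) + config$alpha + 2 * config$beta * x
  }
  start <- tryCatch(pmax(pracma::lsqnonneg(A, b)$x, 0),
                    error = function(e) rep(1 / k, k))
  if (all(start == 0)) start <- rep(1 / k, k)
  fit <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                      lower = rep(0, k),
                      control = list(maxit = 1000L, factr = 1e4))
  fit$par
}

fit_lasso <- function(A, b, config) {
  if (config$standardize) {
    z <- standardize_system(A, b)
    A <- z$A; b <- z$b
  }
  fit <- glmnet::glmnet(x = A, y = b, lambda = config$alpha,
                        lower.limits = 0, intercept = FALSE,
                        standardize = FALSE)
  as.numeric(fit$beta[, 1L])
}

## raw (pre-clipping) coefficients for one aligned system
fit_raw_coefficients <- function(A, b, config) {
  sds <- apply(A, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance signature gene(s)", sum(sds == 0)))
    A <- A[sds > 0, , drop = FALSE]
    b <- b[sds > 0]
  }
  switch(config$model,
         epsilon_svr = fit_svr(A, b, config),
         lasso = fit_lasso(A, b, config),
         fit_relative_error(A, b, config))
}

#' Deconvolve one bulk profile against a signature matrix
#'
#' Solves for raw cell-type coefficients with the configured model, clips
#' negatives to zero, and renormalizes to fractions summing to one (tumor
#' included). The reconstruction `b_hat = A x` uses the raw linear-scale
#' signature applied to the final fractions, and `fit_correlation` is the
#' Pearson correlation between the observed and reconstructed bulk over the
#' signature genes.
#'
#' @param signature A `signature_matrix`.
#' @param bulk Named numeric vector for one sample (full gene universe is
#'   fine; it is aligned to the signature genes).
#' @param config A [regression_config()].
#' @param min_coverage Passed to [align_genes()].
#' @param n_perm If > 0, a Monte-Carlo permutation p-value for the fit is
#'   computed with this many permutations (see [monte_carlo_pvalue()]).
#' @param seed Seed for the permutation test.
#' @return An object of class `deconv_result`: list with `fractions` (named,
#'   sums to 1, tumor included), `reconstruction`, `fit_correlation`,
#'   `mc_pvalue` (or NA), `coverage`, `genes_used`, and `config`.
#' @export
deconvolve <- function(signature, bulk, config = regression_config(),
                       min_coverage = 0.5, n_perm = 0L, seed = NULL) {
  if (!inherits(config, "regression_config"))
    stop_("'config' must come from regression_config()")
  aligned <- align_genes(signature, bulk, min_coverage)
  A <- unclass(aligned$signature)
  x <- fit_raw_coefficients(A, aligned$bulk, config)
  if (all(x <= 0)) stop_("degenerate fit: no positive coefficients")
  x <- pmax(x, 0)
  fr <- stats::setNames(x / sum(x), colnames(signature))
  bhat <- drop(A %*% fr)
  r <- if (stats::sd(bhat) == 0 || stats::sd(aligned$bulk) == 0) NA_real_
       else stats::cor(aligned$bulk, bhat)
  res <- structure(list(fractions = fr, reconstruction = bhat,
                        fit_correlation = r, mc_pvalue = NA_real_,
                        coverage = aligned$coverage,
                        genes_used = length(aligned$bulk),
                        config = config),
                   class = "deconv_result")
  if (n_perm > 0L)
    res$mc_pvalue <- monte_carlo_pvalue(signature, bulk, res,
                                        n_perm = n_perm, seed = seed,
                                        config = config,
                                        min_coverage = min_coverage)
  res
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("deconvolution result (%s): fit r = %.4f, coverage = %.2f\n",
              x$config$model, x$fit_correlation, x$coverage))
  if (!is.na(x$mc_pvalue)) cat(sprintf("Monte-Carlo p = %.4g\n", x$mc_pvalue))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Drop the tumor fraction and renormalize the immune fractions
#'
#' Removes the predicted tumor component and rescales the remaining sixteen
#' immune fractions to sum to one, so immune composition can be compared
#' across samples with different tumor content.
#'
#' @param fractions Named fraction vector including the tumor label.
#' @param tumor_label Label of the tumor component (default `"HCC"`).
#' @return Named immune-only fraction vector summing to 1.
#' @export
remove_tumor_and_renormalize <- function(fractions, tumor_label = hcc_tumor_label()) {
  if (inherits(fractions, "deconv_result")) fractions <- fractions$fractions
  if (!tumor_label %in% names(fractions))
    stop_("tumor label '", tumor_label, "' not present")
  immune <- fractions[setdiff(names(fractions), tumor_label)]
  s <- sum(immune)
  if (s <= 0) stop_("no immune signal: immune fractions are all zero")
  immune / s
}

#' Monte-Carlo significance of a deconvolution fit
#'
#' Tests whether the fit correlation between the observed and reconstructed
#' bulk profile could arise by chance: the bulk sample's expression values
#' are permuted across its full gene universe `n_perm` times, each permuted
#' profile is re-deconvolved, and the p-value is
#' `(1 + #permutations with r >= observed r) / (n_perm + 1)`. Ties count as
#' exceedances, and permutations whose re-fit fails are treated as
#' non-exceedances.
#'
#' @inheritParams deconvolve
#' @param fitted Optional `deconv_result` for the unpermuted profile; fitted
#'   here if missing.
#' @param n_perm Number of permutations (>= 1).
#' @return p-value in (0, 1].
#' @export
monte_carlo_pvalue <- function(signature, bulk, fitted = NULL,
                               n_perm = 100L, seed = NULL,
                               config = regression_config(),
                               min_coverage = 0.5) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop_("'n_perm' must be >= 1")
  if (is.matrix(bulk)) bulk <- stats::setNames(bulk[, 1L], rownames(bulk))
  if (is.null(fitted))
    fitted <- deconvolve(signature, bulk, config, min_coverage)
  observed <- fitted$fit_correlation
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      perm <- stats::setNames(sample(unname(bulk)), names(bulk))
      tryCatch(deconvolve(signature, perm, config, min_coverage)$fit_correlation,
               error = function(e) -Inf)
    }, numeric(1L))
  }
  null_r <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  (1 + sum(null_r >= observed, na.rm = TRUE)) / (n_perm + 1)
}

#' Deconvolve every sample of a bulk expression matrix
#'
#' Applies [deconvolve()] column by column. Per-sample failures are flagged
#' in the output rather than aborting the cohort.
#'
#' @param signature A `signature_matrix`.
#' @param bulk_matrix Genes x samples matrix.
#' @param config A [regression_config()].
#' @param n_perm Permutations for the per-sample Monte-Carlo test (0 = off).
#' @param seed Base seed; each sample uses a seed derived from it.
#' @param min_coverage Passed to [align_genes()].
#' @param tumor_label Tumor component label for the immune-only columns.
#' @return data.frame with one row per sample: tumor-inclusive fractions
#'   (cell-type columns), immune-only fractions (`imm_` columns), `fit_r`,
#'   `mc_p`, `coverage`, and `error` (NA on success).
#' @export
deconvolve_cohort <- function(signature, bulk_matrix,
                              config = regression_config(),
                              n_perm = 0L, seed = NULL, min_coverage = 0.5,
                              tumor_label = hcc_tumor_label()) {
  assert_expression_matrix(bulk_matrix, "bulk_matrix")
  types <- colnames(signature)
  imm_types <- setdiff(types, tumor_label)
  rows <- lapply(seq_len(ncol(bulk_matrix)), function(j) {
    b <- bulk_matrix[, j]
    s <- if (is.null(seed)) NULL else derive_seed(seed, j)
    res <- tryCatch(
      deconvolve(signature, b, config, min_coverage, n_perm = n_perm, seed = s),
      error = function(e) e)
    if (inherits(res, "error")) {
      out <- as.list(rep(NA_real_, length(types) + length(imm_types) + 3L))
      names(out) <- c(types, paste0("imm_", imm_types), "fit_r", "mc_p", "coverage")
      out$error <- conditionMessage(res)
    } else {
      imm <- tryCatch(remove_tumor_and_renormalize(res$fractions, tumor_label),
                      error = function(e) stats::setNames(
                        rep(NA_real_, length(imm_types)), imm_types))
      out <- c(as.list(res$fractions),
               stats::setNames(as.list(imm[imm_types]), paste0("imm_", imm_types)),
               list(fit_r = res$fit_correlation, mc_p = res$mc_pvalue,
                    coverage = res$coverage, error = NA_character_))
    }
    out
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  df <- cbind(sample = colnames(bulk_matrix), df)
  rownames(df) <- NULL
  n_bad <- sum(!is.na(df$error))
  if (n_bad) message(sprintf("%d of %d samples failed deconvolution", n_bad, nrow(df)))
  df
}
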