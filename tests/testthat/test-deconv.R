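toy_signature <- function(A, types = NULL) {
  types <- types %||% c("HCC", paste0("T", seq_len(ncol(A) - 1L)))
  dimnames(A) <- list(sprintf("g%02d", seq_len(nrow(A))), types)
  structure(A, class = c("signature_matrix", "matrix"),
            condition_number = condition_number(A))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gene alignment follows signature order and enforces coverage", {
  sig <- toy_signature(diag(c(3, 2, 5)))
  bulk <- c(g03 = 1, g01 = 2, g02 = 3, extra = 9)
  al <- align_genes(sig, bulk)
  expect_equal(al$coverage, 1)
  expect_equal(names(al$bulk), c("g01", "g02", "g03"))
  expect_error(align_genes(sig, c(g01 = 1)), "coverage")
})

test_that("an exactly representable mixture is recovered by every model", {
  set.seed(4)
  A <- matrix(rlnorm(24, log(60), 1), 8, 3)
  sig <- toy_signature(A)
  xstar <- c(0.3, 0.5, 0.2)
  bulk <- stats::setNames(drop(A %*% xstar), rownames(sig))
  configs <- list(
    tight_svr(),
    regression_config("l1", alpha = 1e-3),
    regression_config("l2", beta = 1e-3),
    regression_config("elastic_net", alpha = 1e-3, beta = 1e-3),
    regression_config("lasso", alpha = 1e-4))
  for (cfg in configs) {
    res <- deconvolve(sig, bulk, cfg)
    expect_fractions_valid(res$fractions)
    expect_lt(max(abs(res$fractions - xstar)), 0.01)
    expect_gt(res$fit_correlation, 0.999)
  }
})

test_that("a pure signature column deconvolves to its own cell type", {
  ref <- tiny_reference()
  sig <- tiny_signature(ref)
  bulk <- stats::setNames(unclass(sig)[, "Treg"], rownames(sig))
  res <- deconvolve(sig, bulk, tight_svr())
  expect_gte(res$fractions[["Treg"]], 0.99)
  expect_true(all(res$fractions[names(res$fractions) != "Treg"] <= 0.01))
})

test_that("fractions are invariant to the bulk profile's scale", {
  ref <- tiny_reference()
  sig <- tiny_signature(ref)
  suite <- generate_benchmark_suite(ref$expression, ref$annotation,
                                    levels = 0.5, n_per_level = 1, seed = 2)
  b <- suite$mixtures[, 1]
  f1 <- deconvolve(sig, b)$fractions
  f2 <- deconvolve(sig, b * 37.5)$fractions
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("tumor removal renormalizes the immune fractions", {
  fr <- c(HCC = 0.4, A = 0.3, B = 0.3)
  expect_equal(remove_tumor_and_renormalize(fr), c(A = 0.5, B = 0.5))
  fr0 <- c(HCC = 0, A = 0.6, B = 0.4)
  expect_equal(remove_tumor_and_renormalize(fr0), c(A = 0.6, B = 0.4))
  expect_error(remove_tumor_and_renormalize(c(HCC = 1, A = 0, B = 0)),
               "no immune signal")
  expect_error(remove_tumor_and_renormalize(c(A = 1, B = 0)), "HCC")
})

test_that("relative-error models drop zero-expression genes, not the fit", {
  A <- matrix(c(5, 1, 2, 1, 6, 3), 3, 2)
  sig <- toy_signature(A, c("HCC", "T1"))
  bulk <- stats::setNames(drop(A %*% c(0.5, 0.5)), rownames(sig))
  bulk["g03"] <- 0  # unmeasured gene; excluded from the relative-error sum
  expect_message(res <- deconvolve(sig, bulk, regression_config("l1", alpha = 1e-3)),
                 "zero bulk expression")
  expect_equal(unname(res$fractions), c(0.5, 0.5), tolerance = 0.01)
})

test_that("Monte-Carlo p-value is reproducible and minimal for perfect fits", {
  ref <- tiny_reference()
  sig <- tiny_signature(ref)
  suite <- generate_benchmark_suite(ref$expression, ref$annotation,
                                    levels = 0.4, n_per_level = 1, seed = 8)
  b <- suite$mixtures[, 1]
  p1 <- monte_carlo_pvalue(sig, b, n_perm = 99, seed = 42)
  p2 <- monte_carlo_pvalue(sig, b, n_perm = 99, seed = 42)
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 100)  # no permutation beats a perfect fit
  expect_error(monte_carlo_pvalue(sig, b, n_perm = 0), "n_perm")
})

test_that("cohort deconvolution flags failures and keeps rows normalized", {
  ref <- tiny_reference()
  sig <- tiny_signature(ref)
  suite <- generate_benchmark_suite(ref$expression, ref$annotation,
                                    levels = c(0.3, 0.6), n_per_level = 2,
                                    seed = 3)
  bulks <- suite$mixtures
  bulks <- cbind(bulks, flat = rep(1, nrow(bulks)))  # constant -> degenerate
  bulks[, 4] <- bulks[, 3]                           # duplicate column
  res <- suppressMessages(deconvolve_cohort(sig, bulks))
  types <- colnames(sig)
  ok <- is.na(res$error)
  expect_equal(res$sample[!ok], "flat")
  expect_equal(unname(rowSums(res[ok, types])), rep(1, sum(ok)),
               tolerance = 1e-9)
  imm <- grep("^imm_", names(res), value = TRUE)
  expect_equal(unname(rowSums(res[ok, imm])), rep(1, sum(ok)),
               tolerance = 1e-9)
  # identical inputs give identical estimates
  expect_equal(res[3, types], res[4, types], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate inputs raise the documented errors", {
  sig <- toy_signature(diag(c(1, 2, 3)))
  expect_error(deconvolve(sig, c(g01 = 5, g02 = 5, g03 = 5)), "degenerate")
  expect_error(regression_config("elastic_net", alpha = 0, beta = 1),
               "elastic_net")
})
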