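#' Aggregate fine cell-type fractions onto coarse labels
#'
#' Sums predicted fractions of subtypes onto their parent populations (e.g.,
#' naive CD8 + memory CD8 -> CD8 T), the usual step before scoring against
#' datasets that only report parent-level fractions. Mass is conserved:
#' the coarse fractions plus the explicitly dropped mass equal the input sum.
#'
#' @param fractions Named fraction vector (fine labels).
#' @param mapping Named character vector, fine label -> coarse label; the
#'   coarse label `"DROP"` discards that fraction (reported via the
#'   `dropped_mass` attribute). See [hcc_default_mapping()].
#' @return Named coarse fraction vector with attribute `dropped_mass`.
#' @export
aggregate_fractions <- function(fractions, mapping = hcc_default_mapping()) {
  unmapped <- setdiff(names(fractions), names(mapping))
  if (length(unmapped))
    stop_("unmapped cell type label(s): ", paste(unmapped, collapse = ", "))
  coarse <- mapping[names(fractions)]
  dropped <- sum(fractions[coarse == "DROP"])
  keep <- coarse != "DROP"
  out <- tapply(fractions[keep], coarse[keep], sum)
  out <- stats::setNames(as.numeric(out), names(out))
  attr(out, "dropped_mass") <- dropped
  out
}

#' Pearson correlation between two fraction vectors
#'
#' @param x,y Numeric vectors of equal length >= 3; both must be
#'   non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_("'x' and 'y' must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Per-type absolute errors and MAE between predicted and true fractions
#'
#' With `scope = "immune_only"`, the tumor entry is removed from both sides
#' and each side is renormalized to sum 1 before the errors are taken.
#'
#' @param pred Named predicted fraction vector.
#' @param truth Named true fraction vector (same labels).
#' @param scope `"with_tumor"` or `"immune_only"`.
#' @param tumor_label Tumor label for the immune-only restriction.
#' @return List with `ae` (named per-type absolute errors) and `mae`.
#' @export
absolute_errors <- function(pred, truth,
                            scope = c("with_tumor", "immune_only"),
                            tumor_label = hcc_tumor_label()) {
  scope <- match.arg(scope)
  if (scope == "immune_only") {
    if (tumor_label %in% names(pred))
      pred <- remove_tumor_and_renormalize(pred, tumor_label)
    if (tumor_label %in% names(truth))
      truth <- remove_tumor_and_renormalize(truth, tumor_label)
  }
  if (!setequal(names(pred), names(truth)))
    stop_("label mismatch between prediction and truth")
  truth <- truth[names(pred)]
  ae <- abs(pred - truth)
  list(ae = ae, mae = mean(ae))
}

#' Leave-one-out benchmark on pure cell-type reference samples
#'
#' Each reference replicate is held out in turn; the signature is rebuilt
#' from the remaining samples (same ANOVA ranking and condition-number
#' procedure) and the held-out profile, a pure sample of known type, is
#' deconvolved against it. The summary reports how often the top predicted
#' type is the sample's own type and the median predicted fraction of the
#' dominant type.
#'
#' @param ref Genes x samples reference matrix.
#' @param ann Its sample annotation.
#' @param sig_config A [signature_config()]; the default uses a singleton
#'   sweep at `k = 16`, which keeps the per-holdout rebuild cheap.
#' @param reg_config A [regression_config()].
#' @param samples Samples to hold out (default all). Samples whose type
#'   would fall below 2 replicates after holdout are skipped with a warning.
#' @return List with `per_sample` (data.frame: `sample_id`, `cell_type`,
#'   `own_fraction`, `argmax_type`, `top1`), `top1_accuracy`, and
#'   `median_dominant_fraction`.
#' @export
leave_one_out_pure_cell <- function(ref, ann,
                                    sig_config = signature_config(sweep_range = 16L),
                                    reg_config = regression_config(),
                                    samples = NULL) {
  assert_expression_matrix(ref, "ref")
  assert_annotation(ann, ref)
  samples <- samples %||% ann$sample_id
  counts <- table(ann$cell_type)
  rows <- lapply(samples, function(s) {
    ct <- ann$cell_type[ann$sample_id == s]
    if (counts[[ct]] - 1L < 2L) {
      warning("skipping holdout of '", s, "': cell type '", ct,
              "' would keep < 2 replicates")
      return(NULL)
    }
    keep <- ann$sample_id != s
    sig <- optimize_signature(ref[, ann$sample_id[keep], drop = FALSE],
                              ann[keep, , drop = FALSE], sig_config)
    res <- deconvolve(sig, ref[, s], reg_config)
    data.frame(sample_id = s, cell_type = ct,
               own_fraction = unname(res$fractions[ct]),
               argmax_type = names(which.max(res$fractions)),
               dominant_fraction = max(res$fractions),
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  if (is.null(per_sample)) stop_("no sample could be held out")
  per_sample$top1 <- per_sample$argmax_type == per_sample$cell_type
  list(per_sample = per_sample,
       top1_accuracy = mean(per_sample$top1),
       median_dominant_fraction = stats::median(per_sample$own_fraction))
}

#' Score cohort predictions against a benchmark suite's ground truth
#'
#' Computes, per mixture, the Pearson correlation between the predicted and
#' true fraction vectors (across cell types) and the mean absolute error,
#' then summarizes both by tumor-fraction level. With
#' `scope = "immune_only"` both sides are restricted to the immune types and
#' renormalized before scoring. Mixtures without a usable prediction are
#' excluded and counted.
#'
#' @param suite A `benchmark_suite`.
#' @param predictions Output of [deconvolve_cohort()] on `suite$mixtures`,
#'   or a samples x cell-types fraction matrix.
#' @param scope `"immune_only"` (default) or `"with_tumor"`.
#' @return List with `per_sample` (data.frame: `sample`, `phcc_level`, `r`,
#'   `mae`), `per_level` (data.frame: `phcc_level`, `median_r`,
#'   `median_mae`, `n`), and `n_missing`.
#' @export
evaluate_suite <- function(suite, predictions,
                           scope = c("immune_only", "with_tumor")) {
  scope <- match.arg(scope)
  if (!inherits(suite, "benchmark_suite")) stop_("'suite' must be a benchmark_suite")
  types <- setdiff(colnames(suite$truths), c("sample", "phcc_level"))
  pred_mat <- as_fraction_matrix(predictions, types)
  rows <- lapply(seq_len(nrow(suite$truths)), function(i) {
    id <- suite$truths$sample[i]
    truth <- stats::setNames(as.numeric(suite$truths[i, types]), types)
    if (!id %in% rownames(pred_mat) || anyNA(pred_mat[id, ])) return(NULL)
    pred <- pred_mat[id, ]
    if (scope == "immune_only") {
      pred <- remove_tumor_and_renormalize(pred, suite$tumor_label)
      truth <- remove_tumor_and_renormalize(truth, suite$tumor_label)
    }
    data.frame(sample = id, phcc_level = suite$truths$phcc_level[i],
               r = pearson_r(pred, truth[names(pred)]),
               mae = mean(abs(pred - truth[names(pred)])),
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  if (is.null(per_sample)) stop_("no mixture had a usable prediction")
  agg <- lapply(split(per_sample, per_sample$phcc_level), function(d)
    data.frame(phcc_level = d$phcc_level[1L],
               median_r = stats::median(d$r),
               median_mae = stats::median(d$mae), n = nrow(d)))
  per_level <- do.call(rbind, agg)
  rownames(per_level) <- NULL
  list(per_sample = per_sample, per_level = per_level,
       n_missing = nrow(suite$truths) - nrow(per_sample))
}

## accept either a deconvolve_cohort() data.frame or a bare fraction matrix
as_fraction_matrix <- function(predictions, types) {
  if (is.data.frame(predictions)) {
    if (!all(types %in% colnames(predictions)))
      stop_("predictions lack cell-type columns: ",
            paste(setdiff(types, colnames(predictions)), collapse = ", "))
    m <- as.matrix(predictions[, types, drop = FALSE])
    rownames(m) <- predictions$sample %||% rownames(predictions)
    m
  } else {
    if (!all(types %in% colnames(predictions)))
      stop_("prediction matrix lacks cell-type columns")
    predictions[, types, drop = FALSE]
  }
}
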