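## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop_(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop_(sprintf("'%s' must be >= 0", name))
  invisible(x)
}

## validate a genes x samples expression matrix
assert_expression_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_(sprintf("'%s' must be a numeric matrix (genes x samples)", name))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_(sprintf("'%s' must have gene rownames and sample colnames", name))
  if (anyNA(x) || any(!is.finite(x)))
    stop_(sprintf("'%s' contains NA or non-finite values", name))
  if (any(x < 0))
    stop_(sprintf("'%s' contains negative values; expression must be on a linear non-negative scale", name))
  if (anyDuplicated(rownames(x)))
    stop_(sprintf("'%s' has duplicated gene ids", name))
  invisible(x)
}

assert_annotation <- function(ann, mat = NULL) {
  if (!is.data.frame(ann) || !all(c("sample_id", "cell_type") %in% names(ann)))
    stop_("annotation must be a data.frame with columns 'sample_id' and 'cell_type'")
  if (anyDuplicated(ann$sample_id))
    stop_("annotation has duplicated sample ids")
  if (!is.null(mat)) {
    missing <- setdiff(ann$sample_id, colnames(mat))
    if (length(missing))
      stop_("annotated samples absent from expression matrix: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  invisible(ann)
}

## deterministic per-task seed derived from a user seed, kept within 32 bits
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1009L) %% 2147483647L
}
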