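#' Configuration for signature matrix construction
#'
#' @param k Per-group number of top differentially expressed genes to carry
#'   into the signature (default 16).
#' @param sweep_range Integer vector of candidate per-group counts scanned
#'   during condition-number minimization (default `8:24`, centered on `k`).
#'   Use `sweep_range = k` to skip the sweep.
#' @param min_expression_floor Genes whose highest per-type median expression
#'   falls below this floor are excluded from the signature. Default 0 (off),
#'   i.e., ranking is purely by the ANOVA p-value.
#' @param groups Group structure for differential-expression ranking; see
#'   [hcc_cell_groups()].
#' @return An object of class `signature_config`.
#' @export
signature_config <- function(k = 16L, sweep_range = 8:24,
                             min_expression_floor = 0,
                             groups = hcc_cell_groups()) {
  k <- as.integer(k)
  sweep_range <- sort(unique(as.integer(sweep_range)))
  if (k < 1L) stop_("'k' must be >= 1")
  if (!length(sweep_range) || any(sweep_range < 1L))
    stop_("'sweep_range' must contain positive integers")
  if (!(k %in% sweep_range) && length(sweep_range) > 1L)
    stop_("'k' must lie in 'sweep_range' (or sweep_range must be a single value)")
  assert_scalar_number(min_expression_floor, "min_expression_floor", nonneg = TRUE)
  if (!is.list(groups) || is.null(names(groups)))
    stop_("'groups' must be a named list of cell-type vectors")
  if (any(vapply(groups, length, 1L) < 2L))
    stop_("each group must contain >= 2 cell types")
  structure(list(k = k, sweep_range = sweep_range,
                 min_expression_floor = min_expression_floor,
                 groups = groups),
            class = "signature_config")
}

#' Rank genes by one-way ANOVA within a cell-type group
#'
#' For each gene, a classical (equal-variance) one-way fixed-effects ANOVA
#' F-test is computed across the cell-type labels of the group's samples.
#' Genes are ranked ascending by p-value; ties are broken by descending F,
#' then lexicographically by gene id. Genes with zero within-type variance
#' but nonzero between-type variance get `F = Inf`, `p = 0`; genes constant
#' across all samples get `F = 0`, `p = 1`.
#'
#' @param ref Genes x samples reference expression matrix.
#' @param ann Sample annotation (`sample_id`, `cell_type`).
#' @param group_types Character vector of the group's member cell types
#'   (>= 2 types, each with >= 2 replicate samples).
#' @return data.frame with columns `gene_id`, `F`, `p`, sorted by rank.
#' @export
anova_rank_genes <- function(ref, ann, group_types) {
  assert_expression_matrix(ref, "ref")
  assert_annotation(ann, ref)
  group_types <- unique(as.character(group_types))
  if (length(group_types) < 2L)
    stop_("a group needs >= 2 cell types")
  keep <- ann$cell_type %in% group_types
  labels <- factor(ann$cell_type[keep], levels = group_types)
  samples <- ann$sample_id[keep]
  counts <- table(labels)
  if (any(counts < 2L))
    stop_("cell type(s) with < 2 replicates in group: ",
          paste(names(counts)[counts < 2L], collapse = ", "))
  X <- ref[, samples, drop = FALSE]
  n <- length(samples)
  g <- nlevels(labels)

  # vectorized one-way ANOVA over all genes at once
  grp <- t(rowsum(t(X), labels))              # genes x types sums
  nj <- as.vector(counts)
  means <- sweep(grp, 2L, nj, "/")
  grand <- rowSums(grp) / n
  ss_between <- rowSums(sweep(means, 1L, grand, "-")^2 %*% diag(nj, g, g))
  ss_total <- rowSums(sweep(X, 1L, grand, "-")^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- g - 1L
  df2 <- n - g
  tol <- 1e-12 * pmax(ss_total, 1e-300)
  Fstat <- ifelse(ss_within > tol,
                  (ss_between / df1) / (ss_within / df2),
                  ifelse(ss_between > tol, Inf, 0))
  p <- ifelse(is.infinite(Fstat), 0,
              stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  p[Fstat == 0] <- 1
  # zero within-type variance makes F infinite for every separating gene;
  # such ties are ordered by between-type sum of squares, the ordering F
  # converges to as the within-type variance vanishes
  ord <- order(p, -Fstat, -ss_between, rownames(X), method = "radix")
  data.frame(gene_id = rownames(X)[ord], F = Fstat[ord], p = p[ord],
             ss_between = ss_between[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genes within every group of a group structure
#'
#' @inheritParams anova_rank_genes
#' @param groups Named list of cell-type vectors; see [hcc_cell_groups()].
#' @return Named list of ranking data.frames, one per group, in group order.
#' @export
rank_signature_groups <- function(ref, ann, groups = hcc_cell_groups()) {
  lapply(groups, function(g) anova_rank_genes(ref, ann, g))
}

#' Collect the top genes of each group ranking into a signature gene set
#'
#' Takes the top `g` genes of every group ranking and returns their union.
#' A gene ranked highly in several groups appears once, so the result can
#' hold fewer than `g * length(rankings)` genes. Order is deterministic:
#' first appearance by group order, then rank within group.
#'
#' @param rankings List of ranking data.frames from [anova_rank_genes()].
#' @param g Per-group count (>= 1). If it exceeds a ranking's length, all of
#'   that ranking is taken, with a warning.
#' @return Character vector of unique signature gene ids.
#' @export
select_signature_genes <- function(rankings, g) {
  g <- as.integer(g)
  if (g < 1L) stop_("'g' must be >= 1")
  if (!length(rankings) || any(!vapply(rankings, nrow, 1L)))
    stop_("every ranking must be nonempty")
  picked <- unlist(lapply(rankings, function(r) {
    if (g > nrow(r)) {
      warning(sprintf("requested top %d genes but ranking has only %d; taking all",
                      g, nrow(r)))
      r$gene_id
    } else r$gene_id[seq_len(g)]
  }), use.names = FALSE)
  unique(picked)
}

#' Build a signature matrix from median expression per cell type
#'
#' Entry (i, j) is the median, over the replicates of cell type j, of gene
#' i's linear-scale expression. The 2-norm condition number of the matrix is
#' computed and stored as an attribute.
#'
#' @inheritParams anova_rank_genes
#' @param genes Character vector of signature gene ids; all must exist in
#'   `ref`.
#' @param cell_types Column order; defaults to the order of first appearance
#'   in `ann`.
#' @return Numeric genes x cell-types matrix of class `signature_matrix`
#'   with attribute `condition_number`.
#' @export
build_signature_matrix <- function(ref, ann, genes, cell_types = NULL) {
  assert_expression_matrix(ref, "ref")
  assert_annotation(ann, ref)
  missing <- setdiff(genes, rownames(ref))
  if (length(missing))
    stop_("signature genes absent from reference: ",
          paste(utils::head(missing, 10L), collapse = ", "))
  cell_types <- cell_types %||% unique(ann$cell_type)
  med <- median_by_type(ref[genes, , drop = FALSE], ann, cell_types)
  if (any(rowSums(med) == 0))
    stop_("signature contains all-zero row(s)")
  structure(med, class = c("signature_matrix", "matrix"),
            condition_number = condition_number(med))
}

## median expression per cell type; rows = genes of `mat`
median_by_type <- function(mat, ann, cell_types) {
  out <- vapply(cell_types, function(ct) {
    cols <- ann$sample_id[ann$cell_type == ct]
    if (!length(cols)) stop_("cell type with no samples: ", ct)
    apply(mat[, cols, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), cell_types))
  out
}

#' Exact 2-norm condition number
#'
#' Ratio of the largest to the smallest singular value. A matrix whose
#' smallest singular value is below `1e-12 * sigma_max` is treated as rank
#' deficient and gets `Inf`.
#'
#' @param m Nonempty numeric matrix.
#' @return Positive number, possibly `Inf`.
#' @export
#' @examples
#' condition_number(diag(2))      # 1
#' condition_number(diag(c(1, 2)))  # 2
condition_number <- function(m) {
  if (!is.matrix(m) || !length(m)) stop_("'m' must be a nonempty matrix")
  d <- svd(m, nu = 0L, nv = 0L)$d
  if (min(d) < 1e-12 * max(d)) Inf else max(d) / min(d)
}

#' Build the signature matrix with condition-number minimization
#'
#' Runs the full signature construction: ranks genes within each group by
#' one-way ANOVA, then for every candidate per-group count `g` in the sweep
#' range collects the deduplicated top-`g` union, assembles the median
#' signature matrix, and scores it by its 2-norm condition number. The
#' candidate with the smallest condition number wins (ties go to the smaller
#' `g`); a low condition number makes the downstream regression less
#' sensitive to noise in the bulk profile.
#'
#' @inheritParams anova_rank_genes
#' @param config A [signature_config()].
#' @return A `signature_matrix` with attributes `condition_number`,
#'   `g_selected`, and `sweep_trace` (data.frame of `g`, `kappa`, `n_genes`).
#' @export
optimize_signature <- function(ref, ann, config = signature_config()) {
  if (!inherits(config, "signature_config"))
    stop_("'config' must come from signature_config()")
  rankings <- rank_signature_groups(ref, ann, config$groups)
  cell_types <- unique(ann$cell_type)

  # medians are computed once over every gene any sweep candidate can touch
  g_max <- max(config$sweep_range)
  pool <- select_signature_genes(rankings, g_max)
  med_pool <- median_by_type(ref[pool, , drop = FALSE], ann, cell_types)
  if (config$min_expression_floor > 0) {
    keep <- apply(med_pool, 1L, max) >= config$min_expression_floor
    med_pool <- med_pool[keep, , drop = FALSE]
  }

  trace <- data.frame(g = config$sweep_range, kappa = NA_real_,
                      n_genes = NA_integer_)
  best <- NULL
  for (i in seq_along(config$sweep_range)) {
    g <- config$sweep_range[i]
    genes <- intersect(select_signature_genes(rankings, g), rownames(med_pool))
    cand <- med_pool[genes, , drop = FALSE]
    kappa <- condition_number(cand)
    trace$kappa[i] <- kappa
    trace$n_genes[i] <- length(genes)
    if (is.finite(kappa) && (is.null(best) || kappa < attr(best, "condition_number")))
      best <- structure(cand, class = c("signature_matrix", "matrix"),
                        condition_number = kappa, g_selected = g)
  }
  if (is.null(best))
    stop_("all sweep candidates are rank deficient; widen the sweep range ",
          "or provide a reference with stronger cell-type markers")
  attr(best, "sweep_trace") <- trace
  attr(best, "config") <- config
  best
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature matrix: %d genes x %d cell types, kappa = %.3f",
              nrow(x), ncol(x), attr(x, "condition_number")))
  g <- attr(x, "g_selected")
  if (!is.null(g)) cat(sprintf(" (top %d genes per group)", g))
  cat("\n")
  invisible(x)
}

#' Write / read a signature matrix (TSV + JSON sidecar)
#'
#' The matrix goes to a TSV (first column `gene_id`); the condition number,
#' selected per-group count, and sweep trace go to `<path>.json`.
#'
#' @param sig A `signature_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_signature_matrix <- function(sig, path) {
  df <- data.frame(gene_id = rownames(sig), unclass(sig), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(condition_number = attr(sig, "condition_number"),
               g_selected = attr(sig, "g_selected"),
               sweep_trace = attr(sig, "sweep_trace"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signature_matrix
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  sidecar <- paste0(path, ".json")
  kappa <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar)$condition_number else condition_number(m)
  structure(m, class = c("signature_matrix", "matrix"),
            condition_number = as.numeric(kappa))
}
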