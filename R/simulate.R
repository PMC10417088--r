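#' Configuration for the synthetic labelled reference generator
#'
#' The generator emulates the structure of a microarray reference panel for
#' liver-tumor deconvolution: 17 cell types (one HCC line plus 16 immune
#' types) with fixed replicate counts, six correlated subsets of related
#' immune types, disjoint planted marker genes with strong cell-type-specific
#' up-regulation, and multiplicative log-normal replicate noise.
#'
#' @param n_genes Total gene count (default 2000).
#' @param markers_per_type Planted markers per cell type (default 30;
#'   `17 * markers_per_type` must not exceed `n_genes`).
#' @param marker_fold_change Multiplicative up-regulation of a type's markers
#'   over background (default 8).
#' @param within_subset_correlation Weight in \[0, 1) of the latent component
#'   shared by the cell types of a correlated subset (default 0.6); larger
#'   values make related types harder to separate.
#' @param noise_sigma Standard deviation of the log-normal replicate noise on
#'   the natural-log scale (default 0.2).
#' @param replicate_counts Named integer vector, cell type -> replicate
#'   count; defaults to [hcc_replicate_counts()]. All counts must be >= 2.
#' @param groups Group structure declaring the correlated subsets; defaults
#'   to [hcc_cell_groups()].
#' @param seed Integer seed (default 1).
#' @return Object of class `synthetic_reference_config`.
#' @export
synthetic_reference_config <- function(n_genes = 2000L, markers_per_type = 30L,
                                       marker_fold_change = 8,
                                       within_subset_correlation = 0.6,
                                       noise_sigma = 0.2,
                                       replicate_counts = hcc_replicate_counts(),
                                       groups = hcc_cell_groups(),
                                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  markers_per_type <- as.integer(markers_per_type)
  if (any(replicate_counts < 2L)) stop_("every cell type needs >= 2 replicates")
  if (marker_fold_change <= 1) stop_("'marker_fold_change' must be > 1")
  if (within_subset_correlation < 0 || within_subset_correlation >= 1)
    stop_("'within_subset_correlation' must be in [0, 1)")
  assert_scalar_number(noise_sigma, "noise_sigma", nonneg = TRUE)
  if (markers_per_type * length(replicate_counts) > n_genes)
    stop_(sprintf("%d cell types x %d markers exceed %d genes",
                  length(replicate_counts), markers_per_type, n_genes))
  structure(list(n_genes = n_genes, markers_per_type = markers_per_type,
                 marker_fold_change = marker_fold_change,
                 within_subset_correlation = within_subset_correlation,
                 noise_sigma = noise_sigma,
                 replicate_counts = replicate_counts,
                 groups = groups, seed = as.integer(seed)),
            class = "synthetic_reference_config")
}

#' Generate a synthetic labelled reference dataset
#'
#' Each cell type gets a base profile built in log space from a shared
#' per-gene background, a latent component shared with the other members of
#' its correlated subset (weighted by `within_subset_correlation`), a
#' type-specific component, and its planted markers multiplied by
#' `marker_fold_change`. Replicates are the base profile times i.i.d.
#' log-normal noise. Fully reproducible under the config seed.
#'
#' @param config A [synthetic_reference_config()].
#' @return List with `expression` (genes x samples matrix), `annotation`
#'   (data.frame `sample_id`, `cell_type`), and `markers` (named list,
#'   cell type -> planted marker gene ids).
#' @export
generate_reference_dataset <- function(config = synthetic_reference_config()) {
  if (!inherits(config, "synthetic_reference_config"))
    stop_("'config' must come from synthetic_reference_config()")
  withr::with_seed(config$seed, {
    types <- names(config$replicate_counts)
    n_types <- length(types)
    genes <- sprintf("g%04d", seq_len(config$n_genes))

    # subset membership: first group is the all-types group, the rest are
    # the correlated subsets
    subset_of <- stats::setNames(rep(NA_character_, n_types), types)
    for (grp in names(config$groups)[-1L])
      subset_of[intersect(config$groups[[grp]], types)] <- grp

    latent <- lapply(unique(stats::na.omit(subset_of)), function(g)
      stats::rnorm(config$n_genes, 0, 1))
    names(latent) <- unique(stats::na.omit(subset_of))

    # each type's log profile mixes a type-specific and (within a correlated
    # subset) a shared latent component, normalized to unit log variance, so
    # the between-type log correlation is w^2 / (w^2 + (1-w)^2) within a
    # subset and zero otherwise
    w <- config$within_subset_correlation
    markers <- vector("list", n_types)
    names(markers) <- types
    marker_slices <- split(seq_len(config$markers_per_type * n_types),
                           rep(seq_len(n_types), each = config$markers_per_type))

    base <- matrix(0, config$n_genes, n_types, dimnames = list(genes, types))
    for (i in seq_len(n_types)) {
      ct <- types[i]
      own <- stats::rnorm(config$n_genes, 0, 1)
      structure_ct <- if (is.na(subset_of[ct])) own else
        ((1 - w) * own + w * latent[[subset_of[ct]]]) / sqrt((1 - w)^2 + w^2)
      logp <- log(100) + structure_ct
      idx <- marker_slices[[i]]
      logp[idx] <- logp[idx] + log(config$marker_fold_change)
      markers[[ct]] <- genes[idx]
      base[, i] <- exp(logp)
    }

    cols <- unlist(lapply(types, function(ct)
      sprintf("%s_r%02d", ct, seq_len(config$replicate_counts[[ct]]))))
    ann <- data.frame(
      sample_id = cols,
      cell_type = rep(types, times = config$replicate_counts),
      stringsAsFactors = FALSE)
    expr <- matrix(0, config$n_genes, length(cols),
                   dimnames = list(genes, cols))
    for (j in seq_along(cols)) {
      ct <- ann$cell_type[j]
      expr[, j] <- base[, ct] *
        exp(stats::rnorm(config$n_genes, 0, config$noise_sigma))
    }
    list(expression = expr, annotation = ann, markers = markers)
  })
}

#' Mix component expression profiles into one simulated bulk profile
#'
#' The simulated bulk is the exact weighted sum of the component profiles:
#' `bulk_i = sum_c weight_c * profile_{i,c}`, with the tumor weight plus the
#' immune weights summing to one.
#'
#' @param profiles Genes x components numeric matrix (one column per mixture
#'   component), or a list of equal-length named vectors.
#' @param weights Numeric vector of mixing weights, one per component,
#'   non-negative and summing to 1 (tolerance 1e-12).
#' @return Named numeric vector, the mixed profile.
#' @export
simulate_bulk_mixture <- function(profiles, weights) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    ids <- lapply(profiles, names)
    if (length(unique(vapply(ids, paste, "", collapse = "\r"))) != 1L)
      stop_("component profiles have misaligned gene sets")
    profiles <- do.call(cbind, profiles)
  }
  if (ncol(profiles) != length(weights))
    stop_("need one weight per component profile")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop_("weights must be non-negative and sum to 1")
  drop(profiles %*% weights)
}

#' Generate a spike-in benchmark suite of simulated bulk profiles
#'
#' For each tumor-fraction level `P` in `levels` and each of `n_per_level`
#' mixtures: one tumor replicate and one replicate per immune type are drawn
#' uniformly from the reference, immune weights are drawn from a flat
#' Dirichlet over the 16 immune types and scaled to `1 - P`, and the bulk
#' profile is the exact weighted sum of the drawn replicate profiles
#' (optionally perturbed by multiplicative log-normal noise). Ground-truth
#' weights and the consumed replicate ids are recorded, so an evaluation can
#' rebuild the signature without the source replicates.
#'
#' @param ref Genes x samples reference expression matrix.
#' @param ann Its sample annotation.
#' @param levels Tumor-fraction grid (default `c(.15, .30, .45, .60, .75,
#'   .90)`).
#' @param n_per_level Mixtures per level (default 100).
#' @param seed Integer seed.
#' @param noise_sigma Log-normal noise sd applied to each mixture (default 0
#'   = exact mixtures).
#' @param dirichlet_alpha Concentration of the immune-weight Dirichlet
#'   (default 1 = flat).
#' @param tumor_label Tumor cell-type label.
#' @return Object of class `benchmark_suite`: list with `mixtures` (genes x
#'   mixtures matrix), `truths` (data.frame: `sample`, `phcc_level`, one
#'   weight column per cell type), `sources` (data.frame of consumed
#'   replicate ids per mixture), `levels`, `n_per_level`, `noise_sigma`,
#'   `seed`.
#' @export
generate_benchmark_suite <- function(ref, ann,
                                     levels = c(.15, .30, .45, .60, .75, .90),
                                     n_per_level = 100L, seed = 1L,
                                     noise_sigma = 0,
                                     dirichlet_alpha = 1,
                                     tumor_label = hcc_tumor_label()) {
  assert_expression_matrix(ref, "ref")
  assert_annotation(ann, ref)
  n_per_level <- as.integer(n_per_level)
  if (n_per_level < 1L) stop_("'n_per_level' must be >= 1")
  if (any(levels < 0) || any(levels > 1)) stop_("'levels' must be in [0, 1]")
  imm_types <- setdiff(unique(ann$cell_type), tumor_label)
  reps_by_type <- split(ann$sample_id, ann$cell_type)
  if (!tumor_label %in% names(reps_by_type))
    stop_("tumor label '", tumor_label, "' absent from annotation")

  withr::with_seed(seed, {
    total <- length(levels) * n_per_level
    mix <- matrix(0, nrow(ref), total, dimnames = list(rownames(ref), NULL))
    truths <- matrix(0, total, length(imm_types) + 1L,
                     dimnames = list(NULL, c(tumor_label, imm_types)))
    lev <- numeric(total)
    src <- vector("list", total)
    idx <- 0L
    for (p in levels) {
      for (i in seq_len(n_per_level)) {
        idx <- idx + 1L
        comp_samples <- vapply(c(tumor_label, imm_types), function(ct) {
          pool <- reps_by_type[[ct]]
          pool[sample.int(length(pool), 1L)]
        }, "")
        g <- stats::rgamma(length(imm_types), shape = dirichlet_alpha)
        wts <- c(p, (1 - p) * g / sum(g))
        m <- simulate_bulk_mixture(ref[, comp_samples, drop = FALSE], wts)
        if (noise_sigma > 0)
          m <- m * exp(stats::rnorm(length(m), 0, noise_sigma))
        mix[, idx] <- m
        truths[idx, ] <- wts
        lev[idx] <- p
        src[[idx]] <- unname(comp_samples)
      }
    }
    ids <- sprintf("mix%04d", seq_len(total))
    colnames(mix) <- ids
    truths_df <- data.frame(sample = ids, phcc_level = lev,
                            truths, check.names = FALSE,
                            stringsAsFactors = FALSE)
    sources <- data.frame(sample = rep(ids, each = length(imm_types) + 1L),
                          replicate = unlist(src),
                          stringsAsFactors = FALSE)
    structure(list(mixtures = mix, truths = truths_df, sources = sources,
                   levels = levels, n_per_level = n_per_level,
                   noise_sigma = noise_sigma, seed = seed,
                   tumor_label = tumor_label),
              class = "benchmark_suite")
  })
}

#' @export
print.benchmark_suite <- function(x, ...) {
  cat(sprintf("benchmark suite: %d mixtures (%d per tumor-fraction level: %s), noise sigma %.2f\n",
              ncol(x$mixtures), x$n_per_level,
              paste(x$levels, collapse = ", "), x$noise_sigma))
  invisible(x)
}
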