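# small fixtures built in code; everything deterministic under fixed seeds

# compact 17-type reference: 3 replicates per type, 400 genes, 10 markers
tiny_reference <- function(seed = 101, noise_sigma = 0.15, ...) {
  counts <- stats::setNames(rep(3L, 17L), hcc_cell_types())
  generate_reference_dataset(synthetic_reference_config(
    n_genes = 400L, markers_per_type = 10L, replicate_counts = counts,
    noise_sigma = noise_sigma, seed = seed, ...))
}

tiny_signature <- function(ref, sweep_range = 16L) {
  optimize_signature(ref$expression, ref$annotation,
                     signature_config(sweep_range = sweep_range))
}

# two-cell-type toy reference with disjoint strong markers and an explicit
# group structure; used where the full 17-type panel is overkill
toy_two_type_reference <- function(n_reps = 3L, noise_sigma = 0.05, seed = 5) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", 1:20)
    base <- matrix(100, 20, 2, dimnames = list(genes, c("A", "B")))
    base[1:5, "A"] <- 800
    base[6:10, "B"] <- 800
    cols <- c(sprintf("A_r%d", seq_len(n_reps)), sprintf("B_r%d", seq_len(n_reps)))
    expr <- matrix(0, 20, 2 * n_reps, dimnames = list(genes, cols))
    ann <- data.frame(sample_id = cols,
                      cell_type = rep(c("A", "B"), each = n_reps),
                      stringsAsFactors = FALSE)
    for (j in seq_along(cols))
      expr[, j] <- base[, ann$cell_type[j]] * exp(stats::rnorm(20, 0, noise_sigma))
    list(expression = expr, annotation = ann)
  })
}

# near-interpolating SVR settings for exactly representable bulk profiles
tight_svr <- function() regression_config(epsilon = 0.001, C = 1)

expect_fractions_valid <- function(fr) {
  expect_true(all(fr >= 0))
  expect_equal(sum(fr), 1, tolerance = 1e-9)
}
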