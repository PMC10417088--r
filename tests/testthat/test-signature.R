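make_two_type_ref <- function(values_by_gene) {
  genes <- names(values_by_gene)
  m <- do.call(rbind, values_by_gene)
  dimnames(m) <- list(genes, c("A_r1", "A_r2", "A_r3", "B_r1", "B_r2", "B_r3"))
  ann <- data.frame(sample_id = colnames(m),
                    cell_type = rep(c("A", "B"), each = 3),
                    stringsAsFactors = FALSE)
  list(expression = m, annotation = ann)
}

test_that("ANOVA ranking matches the classical one-way F test", {
  ref <- make_two_type_ref(list(g1 = c(1, 2, 3, 4, 5, 6),
                                g2 = c(5, 5, 5, 5, 5, 5),
                                g3 = c(2, 3, 2, 2, 3, 5)))
  rk <- anova_rank_genes(ref$expression, ref$annotation, c("A", "B"))

  # hand computation: SSB = 13.5, SSW = 4, df (1, 4) -> F = 13.5
  g1 <- rk[rk$gene_id == "g1", ]
  expect_equal(g1$F, 13.5, tolerance = 1e-12)
  expect_equal(g1$p, stats::pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # independent oracle: stats::oneway.test with equal variances
  ow <- stats::oneway.test(x ~ g, data.frame(x = c(1, 2, 3, 4, 5, 6),
                                             g = rep(c("A", "B"), each = 3)),
                           var.equal = TRUE)
  expect_equal(g1$F, unname(ow$statistic), tolerance = 1e-12)
  expect_equal(g1$p, unname(ow$p.value), tolerance = 1e-12)

  # constant gene is ranked last with F = 0, p = 1
  g2 <- rk[rk$gene_id == "g2", ]
  expect_equal(g2$F, 0)
  expect_equal(g2$p, 1)
  expect_equal(rk$gene_id[nrow(rk)], "g2")
})

test_that("zero within-type variance yields p = 0 and top rank", {
  ref <- make_two_type_ref(list(sep = c(0, 0, 0, 5, 5, 5),
                                noisy = c(1, 2, 3, 7, 8, 9)))
  rk <- anova_rank_genes(ref$expression, ref$annotation, c("A", "B"))
  expect_equal(rk$gene_id[1], "sep")
  expect_equal(rk$p[1], 0)
  expect_true(is.infinite(rk$F[1]))
})

test_that("ANOVA refuses cell types with fewer than 2 replicates", {
  ref <- make_two_type_ref(list(g1 = 1:6))
  ann <- ref$annotation
  ann$cell_type[6] <- "C"
  expect_error(anova_rank_genes(ref$expression, ann, c("A", "B", "C")), "C")
})

test_that("signature gene selection deduplicates and is monotone in g", {
  rk <- function(ids) data.frame(gene_id = ids, F = seq_along(ids), p = 0.01,
                                 stringsAsFactors = FALSE)
  disjoint <- lapply(1:7, function(i) rk(sprintf("grp%d_g%02d", i, 1:20)))
  expect_length(select_signature_genes(disjoint, 16), 7 * 16)

  shared <- list(rk(c("m", "a")), rk(c("m", "b")))
  expect_equal(select_signature_genes(shared, 1), "m")
  expect_equal(select_signature_genes(shared, 2), c("m", "a", "b"))

  for (g in 1:19)
    expect_true(all(select_signature_genes(disjoint, g) %in%
                    select_signature_genes(disjoint, g + 1)))

  expect_warning(select_signature_genes(list(rk(c("x", "y"))), 5), "only 2")
})

test_that("signature entries are per-type medians with the usual conventions", {
  m <- matrix(c(1, 2, 9, 1, 3, 100), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"),
                              c("A_r1", "A_r2", "A_r3")))
  m <- cbind(m, B_r1 = c(7, 4))
  ann <- data.frame(sample_id = colnames(m),
                    cell_type = c("A", "A", "A", "B"),
                    stringsAsFactors = FALSE)
  sig <- build_signature_matrix(m, ann, c("g1", "g2"))
  expect_equal(sig["g1", "A"], 2)        # odd n: middle value
  expect_equal(sig["g2", "A"], 3)        # (1,3,100) -> 3
  expect_equal(unname(sig[, "B"]), c(7, 4))  # single replicate verbatim
  even <- build_signature_matrix(m[, 1:2], ann[1:2, ], c("g1", "g2"))
  expect_equal(even["g1", "A"], 1.5)     # even n: mean of middle two
  expect_error(build_signature_matrix(m, ann, c("g1", "nope")), "nope")
})

test_that("condition number is the singular-value ratio with known values", {
  expect_equal(condition_number(diag(4)), 1)
  expect_equal(condition_number(diag(c(1, 2))), 2)
  expect_equal(condition_number(matrix(1, 2, 2)), Inf)
  expect_error(condition_number(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("condition number is invariant to scaling and permutations", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rnorm(35), 7, 5)
    k <- condition_number(m)
    expect_equal(condition_number(m * runif(1, 0.1, 50)), k, tolerance = 1e-9)
    expect_equal(condition_number(m[sample(7), sample(5)]), k, tolerance = 1e-9)
  }
})

test_that("condition-number sweep selects the best candidate", {
  ref <- tiny_reference()
  cfg <- signature_config(sweep_range = 10:20)
  sig <- optimize_signature(ref$expression, ref$annotation, cfg)
  trace <- attr(sig, "sweep_trace")
  expect_equal(nrow(trace), 11L)
  expect_true(attr(sig, "condition_number") <= min(trace$kappa) + 1e-12)

  # independent oracle: rebuild every candidate and score it with base R's
  # exact 2-norm kappa
  rankings <- rank_signature_groups(ref$expression, ref$annotation)
  kappas <- vapply(10:20, function(g) {
    genes <- select_signature_genes(rankings, g)
    cand <- build_signature_matrix(ref$expression, ref$annotation, genes)
    base::kappa(unclass(cand), exact = TRUE)
  }, numeric(1))
  expect_equal(trace$kappa, kappas, tolerance = 1e-9)
  expect_equal(attr(sig, "g_selected"), (10:20)[which.min(kappas)])

  # singleton sweep returns that candidate regardless of kappa
  single <- optimize_signature(ref$expression, ref$annotation,
                               signature_config(sweep_range = 16L))
  expect_equal(attr(single, "g_selected"), 16L)
})

test_that("planted markers dominate the selected signature genes", {
  # flat-background toy: markers are the only differential genes, so the
  # top-10 union is exactly the planted set
  toy <- toy_two_type_reference()
  rk <- anova_rank_genes(toy$expression, toy$annotation, c("A", "B"))
  expect_setequal(select_signature_genes(list(all = rk), 10),
                  sprintf("g%02d", 1:10))

  # full generator: per-type profile structure competes with the markers,
  # but the selection stays strongly marker-enriched (6% of genes are
  # markers; the union is over half markers)
  ref <- tiny_reference(seed = 77)
  rankings <- rank_signature_groups(ref$expression, ref$annotation)
  genes <- select_signature_genes(rankings, 16)
  planted <- unlist(ref$markers)
  expect_gt(mean(genes %in% planted), 0.5)
})

test_that("signature columns decorrelate below the subset correlation", {
  # default generator conditions: strong disjoint markers
  ref <- generate_reference_dataset(synthetic_reference_config(seed = 101))
  sig <- optimize_signature(ref$expression, ref$annotation)
  cors <- cor(unclass(sig))
  off <- cors[upper.tri(cors)]
  expect_lt(max(off), 0.6 + 0.1)
})

test_that("signature matrices round-trip through TSV with sidecar", {
  ref <- tiny_reference()
  sig <- tiny_signature(ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_matrix(sig, path)
  back <- read_signature_matrix(path)
  expect_equal(unclass(back)[, ], unclass(sig)[, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back, "condition_number"), attr(sig, "condition_number"),
               tolerance = 1e-9)
})
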