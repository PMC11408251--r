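test_that("same config and seed give bitwise-identical bundles", {
  b1 <- simulate_cohort(small_config(seed = 11))
  b2 <- simulate_cohort(small_config(seed = 11))
  expect_identical(b1, b2)
  b3 <- simulate_cohort(small_config(seed = 12))
  expect_false(identical(b1$human_expr, b3$human_expr))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(simulate_cohort(small_config(seed = 1)))
  expect_identical(rnorm(3), before)
})

test_that("null configuration yields empty truth lists", {
  b <- simulate_cohort(small_config(n_shared_signal = 0, coexpr_block_size = 0))
  expect_equal(nrow(b$truth$signal), 0)
  expect_equal(nrow(b$truth$coexpr), 0)
  expect_equal(nrow(b$truth$target), 1)  # target gene always present
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_probes = 5, n_shared_signal = 10),
               class = "crossmed_config_error")
  expect_error(sim_config(noise_sd = 0), class = "crossmed_config_error")
  expect_error(sim_config(human_effect_r = 1), class = "crossmed_config_error")
  expect_error(sim_config(n_patients = 1), class = "crossmed_config_error")
})

test_that("bundle structure honours its own invariants", {
  b <- simulate_cohort(small_config(seed = 5))
  # planted symbols exist in both species under case-insensitive matching
  expect_true(all(toupper(b$truth$signal$mouse_symbol) %in%
                    toupper(b$mouse_expr$gene_symbol)))
  expect_true(all(b$truth$signal$gene_symbol %in% b$human_expr$gene_symbol))
  # beta values within [0, 1]
  mm <- as.matrix(b$methylation[, -(1:2)])
  expect_true(all(mm >= 0 & mm <= 1))
  # raw human signal non-negative
  expect_true(all(as.matrix(b$human_expr[, -(1:2)]) >= 0))
  expect_equal(ncol(b$human_expr) - 2,
               b$config$n_patients + b$config$n_controls)
})

test_that("planted human probes hit the configured correlation on average", {
  # oracle: direct correlation of generated columns, averaged over 20 seeds
  mean_r <- sapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_probes = 230, n_mouse_genes = 230,
                      n_shared_signal = 200, coexpr_block_size = 4,
                      human_effect_r = 0.5, n_cpg = 5)
    b <- simulate_cohort(cfg)
    m <- log2(as.matrix(b$human_expr[, -(1:2)]))
    y <- b$phenotypes$reexperiencing
    planted <- b$human_expr$feature_id %in% b$truth$signal$feature_id
    mean(abs(cor(t(m[planted, ]), y)))
  })
  # Monte-Carlo error at n = 48: |r|-bias is small; band of +/- 0.05
  expect_equal(mean(mean_r), 0.5, tolerance = 0.1)
  expect_lt(abs(mean(mean_r) - 0.5), 0.05)
})

test_that("planted effects converge to configured values at large n", {
  cfg <- sim_config(seed = 42, n_patients = 333, n_controls = 167,
                    n_probes = 120, n_mouse_genes = 120,
                    n_shared_signal = 60, coexpr_block_size = 10,
                    mouse_n_per_group = 250, n_cpg = 5)
  b <- simulate_cohort(cfg)
  m <- log2(as.matrix(b$human_expr[, -(1:2)]))
  y <- b$phenotypes$reexperiencing
  planted <- b$human_expr$feature_id %in% b$truth$signal$feature_id
  rr <- as.vector(cor(t(m[planted, ]), y))
  # all planted correlations negative and near -0.55 (3 SE via Fisher z)
  se_z <- 1 / sqrt(500 - 3) / sqrt(sum(planted))
  expect_true(all(rr < 0))
  expect_lt(abs(mean(atanh(abs(rr))) - atanh(0.55)), 3 * se_z)
  # mouse fold changes near -log2(1.5): SE of a mean difference
  mm <- as.matrix(b$mouse_expr[, -(1:2)])
  react <- b$mouse_groups$group == "React-30"
  plm <- b$mouse_expr$gene_symbol %in% b$truth$signal$mouse_symbol
  fc <- rowMeans(mm[plm, react]) - rowMeans(mm[plm, !react])
  se_fc <- 0.12 * sqrt(2 / 250)
  expect_true(all(fc < 0))
  expect_lt(abs(mean(fc) + log2(1.5)), 3 * se_fc / sqrt(sum(plm)))
  # co-expression block correlates with the target at the configured loading
  tgt <- m[b$human_expr$feature_id == b$truth$target$feature_id, ]
  blk <- m[b$human_expr$feature_id %in% b$truth$coexpr$feature_id, ]
  expect_equal(mean(abs(cor(t(blk), tgt))), cfg$coexpr_loading,
               tolerance = 0.05)
})

test_that("non-planted probes behave as nulls at the |r| > 0.40 tail", {
  b <- simulate_cohort(sim_config(seed = 3, n_probes = 5000,
                                  n_mouse_genes = 100, n_shared_signal = 0,
                                  coexpr_block_size = 0, n_cpg = 5))
  m <- log2(as.matrix(b$human_expr[, -(1:2)]))
  y <- b$phenotypes$reexperiencing
  null_rows <- b$human_expr$feature_id != b$truth$target$feature_id
  rr <- as.vector(cor(t(m[null_rows, ]), y))
  n <- length(y)
  t0 <- 0.40 * sqrt(n - 2) / sqrt(1 - 0.40^2)
  analytic <- 2 * pt(-t0, n - 2)
  expect_lt(abs(mean(abs(rr) > 0.40) - analytic), 0.02)
})

test_that("one patient's reexperiencing score can be set missing", {
  b <- simulate_cohort(small_config(missing_reexperiencing = 1))
  expect_equal(sum(is.na(b$phenotypes$reexperiencing)), 1)
  expect_true(is.na(b$phenotypes$reexperiencing[b$phenotypes$group == "PTSD"][1]))
})

test_that("bundles round-trip through write_bundle/read_bundle", {
  b <- simulate_cohort(small_config(seed = 21, n_probes = 60,
                                    n_mouse_genes = 60, n_shared_signal = 5,
                                    coexpr_block_size = 3, n_cpg = 8))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$human_expr, b$human_expr)
  expect_equal(b2$mouse_expr, b$mouse_expr)
  expect_equal(b2$methylation, b$methylation)
  expect_equal(b2$phenotypes, b$phenotypes)
  expect_equal(b2$truth$signal, b$truth$signal)
  expect_equal(unclass(b2$config), unclass(b$config))
})

test_that("written files have exactly the bundle's dimensions", {
  b <- simulate_cohort(sim_config(seed = 2, n_patients = 4, n_controls = 2,
                                  n_probes = 10, n_mouse_genes = 12,
                                  n_shared_signal = 2, coexpr_block_size = 1,
                                  n_cpg = 6))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  h <- readr::read_tsv(file.path(dir, "human_expression.tsv"),
                       show_col_types = FALSE)
  expect_equal(dim(h), c(10, 2 + 6))
  tr <- readr::read_tsv(file.path(dir, "truth.tsv"), comment = "#",
                        show_col_types = FALSE)
  expect_equal(nrow(tr), 2 + 1 + 1)  # signal + target + coexpr
})

test_that("empty truth writes a header-only signal section", {
  b <- simulate_cohort(small_config(n_shared_signal = 0, coexpr_block_size = 0))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  tr <- readr::read_tsv(file.path(dir, "truth.tsv"), comment = "#",
                        show_col_types = FALSE)
  expect_equal(nrow(tr), 1)  # only the target row remains
  expect_true(all(c("role", "feature_id", "gene_symbol") %in% names(tr)))
})
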