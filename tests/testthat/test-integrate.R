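make_records <- function(human_r, mouse_log2fc, human_p = NULL, mouse_q = NULL) {
  n <- length(human_r)
  rec <- tibble::tibble(
    gene_key = sprintf("G%03d", seq_len(n)),
    human_probe = sprintf("PR%03d", seq_len(n)),
    human_symbol = sprintf("G%03d", seq_len(n)),
    mouse_feature = sprintf("MG%03d", seq_len(n)),
    mouse_symbol = sprintf("G%03d", seq_len(n)),
    human_r = human_r,
    human_p = human_p %||% cor_p(human_r, 48),
    human_ok = TRUE,
    mouse_log2fc = mouse_log2fc,
    mouse_fc_linear = sign(mouse_log2fc) * 2^abs(mouse_log2fc),
    mouse_p = 0.001, mouse_q = mouse_q %||% rep(1e-5, n),
    mouse_ok = TRUE
  )
  dplyr::bind_cols(rec, classify_direction(human_r, mouse_log2fc))
}

cor_p <- function(r, n) {
  # helper axes may exceed |1| (they are synthetic effect sizes, not r's)
  2 * pt(-abs(r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))), n - 2)
}

test_that("symbols match case-insensitively across species", {
  h <- tibble::tibble(feature_id = c("p1", "p2", "p3"),
                      gene_symbol = c("PDE4B", "RAP1A", "ONLYHUM"), r = 1:3)
  m <- tibble::tibble(feature_id = c("g1", "g2", "g3"),
                      gene_symbol = c("Pde4b", "Rap1a", "Onlymouse"), fc = 4:6)
  rec <- match_symbols(h, m)
  expect_setequal(rec$gene_key, c("PDE4B", "RAP1A"))
  expect_equal(rec$mouse_symbol[rec$gene_key == "PDE4B"], "Pde4b")
  expect_error(match_symbols(h[3, ], m[3, ]), "no gene symbols shared")
})

test_that("multi-probe genes yield one record per probe", {
  h <- tibble::tibble(feature_id = c("p1", "p2", "p3"),
                      gene_symbol = c("AA", "AA", "BB"), r = c(1, 2, 3))
  m <- tibble::tibble(feature_id = c("g1", "g2"),
                      gene_symbol = c("Aa", "Bb"), fc = c(1, 2))
  rec <- match_symbols(h, m)
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$gene_key == "AA"), 2)
  expect_true(all(rec$mouse_feature[rec$gene_key == "AA"] == "g1"))
})

test_that("toy 5-symbol lists intersect to the shared 2", {
  h <- tibble::tibble(feature_id = paste0("p", 1:5),
                      gene_symbol = c("A", "B", "C", "D", "E"))
  m <- tibble::tibble(feature_id = paste0("g", 1:5),
                      gene_symbol = c("c", "e", "x", "y", "z"))
  rec <- match_symbols(h, m)
  expect_setequal(rec$gene_key, c("C", "E"))
})

test_that("direction classification handles signs, zeros and NaN", {
  cl <- classify_direction(c(-0.46, 0.5, 0.5, -0.2, NaN),
                           c(-0.485, 0.3, 0, 0.4, 1))
  expect_equal(cl$quadrant[1], "down-down")
  expect_true(cl$consistent[1])
  expect_equal(cl$quadrant[2], "up-up")
  expect_false(cl$consistent[3])   # zero on the mouse axis: degenerate
  expect_true(cl$degenerate[3])
  expect_equal(cl$quadrant[4], "down-up")
  expect_true(is.na(cl$quadrant[5]))
  expect_false(cl$consistent[5])
})

test_that("quadrant counts match an independent sign enumeration", {
  set.seed(20)
  hr <- rnorm(1000)
  fc <- rnorm(1000)
  cl <- classify_direction(hr, fc)
  expect_equal(sum(cl$quadrant == "up-up"), sum(hr > 0 & fc > 0))
  expect_equal(sum(cl$quadrant == "down-down"), sum(hr < 0 & fc < 0))
  expect_equal(sum(cl$quadrant == "up-down"), sum(hr > 0 & fc < 0))
  expect_equal(sum(cl$quadrant == "down-up"), sum(hr < 0 & fc > 0))
  expect_equal(sum(cl$consistent), sum(sign(hr) == sign(fc)))
})

test_that("overlap gates use strict thresholds and respect emptiness", {
  rec <- make_records(c(0.40, 0.41, -0.5), c(0.5, 0.6, -0.7))
  sel <- select_overlap(rec, threshold_spec(), gate = "hybrid")
  expect_setequal(sel$gene_key, c("G002", "G003"))  # |r| = 0.40 excluded
  empty <- select_overlap(rec[0, ], threshold_spec(), gate = "stringent")
  expect_equal(nrow(empty), 0)
})

test_that("stringent gate additionally requires FC magnitude and consistency", {
  rec <- make_records(human_r = c(-0.5, -0.5, -0.5, 0.5),
                      mouse_log2fc = c(-0.6, -0.2, 0.6, 0.6))
  # gene 1: consistent, |FC| = 2^0.6 = 1.52 > 1.36 -> kept
  # gene 2: consistent but |FC| = 1.15 < 1.36 -> dropped
  # gene 3: inconsistent -> dropped;  gene 4: consistent up-up -> kept
  sel <- select_overlap(rec, threshold_spec(), gate = "stringent")
  expect_setequal(sel$gene_key, c("G001", "G004"))
  hyb <- select_overlap(rec, threshold_spec(), gate = "hybrid")
  expect_equal(nrow(hyb), 4)  # consistency not required
})

test_that("gates are monotone in their thresholds", {
  set.seed(21)
  rec <- make_records(runif(200, -0.9, 0.9), runif(200, -2, 2),
                      mouse_q = runif(200, 0, 0.01))
  base <- select_overlap(rec, threshold_spec(), gate = "stringent")
  tighter <- list(
    threshold_spec(human_abs_r_min = 0.6),
    threshold_spec(mouse_q_max = 1e-4),
    threshold_spec(mouse_abs_fc_min = 2)
  )
  for (sp in tighter) {
    sel <- select_overlap(rec, sp, gate = "stringent")
    expect_true(all(sel$gene_key %in% base$gene_key))
  }
})

test_that("single-pass outlier exclusion follows the k-SD rule", {
  expect_true(all(!exclude_outliers(rep(5, 10))$excluded))  # sd = 0: keep all
  # z can only exceed 12 when n is large enough (max z ~ (n-1)/sqrt(n)):
  # one huge value among 300 tight ones sits far beyond 12 SD, with mean and
  # SD computed including the outlier itself
  set.seed(1)
  v <- c(rnorm(300, 0, 0.1), 10)
  z <- (v - mean(v)) / sd(v)
  expect_gt(z[301], 12)
  ex <- exclude_outliers(v, 10)
  expect_equal(ex$excluded, z > 10)
  expect_true(ex$excluded[301])
  expect_true(all(!exclude_outliers(v, Inf)$excluded))
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("a >10 SD fold-change outlier is excluded from the broad gate", {
  set.seed(2)
  n <- 300
  hr <- c(runif(n - 1, -0.9, 0.9), 0.5)
  fc <- c(rnorm(n - 1, 0, 0.3), 40)
  rec <- make_records(hr, fc, human_p = rep(0.001, n),
                      mouse_q = rep(0.001, n))
  sel <- select_overlap(rec, threshold_spec(), gate = "broad")
  expect_false(sprintf("G%03d", n) %in% sel$gene_key)
  expect_equal(nrow(sel), n - 1)
})

test_that("concordance statistics behave at the boundaries", {
  v <- c(-1, -0.5, 0.3, 0.8)
  rec <- make_records(v, v)
  cc <- concordance(rec)
  expect_equal(cc$r, 1)
  expect_equal(cc$consistent_fraction, 1)
  rec2 <- make_records(c(-0.2, -0.4, -0.6), c(-0.1, -0.5, -0.9))
  cc2 <- concordance(rec2)
  expect_equal(cc2$n_down_down, 3)
  expect_equal(cc2$consistent_fraction, 1)
  expect_error(concordance(rec2[1:2, ]), "at least 3")
})

test_that("consistent fraction is invariant under joint sign flip", {
  set.seed(22)
  hr <- rnorm(300); fc <- 0.3 * hr + rnorm(300)
  a <- concordance(make_records(hr, fc))
  b <- concordance(make_records(-hr, -fc))
  expect_equal(a$consistent_fraction, b$consistent_fraction)
  expect_equal(a$r, b$r)
})

test_that("independent axes give consistent_fraction near one half", {
  set.seed(23)
  fr <- replicate(20, {
    concordance(make_records(rnorm(500), rnorm(500)))$consistent_fraction
  })
  se <- sqrt(0.25 / 500) / sqrt(20)
  expect_lt(abs(mean(fr) - 0.5), 4 * se)
})

test_that("three-way curation enforces direction agreement", {
  rec <- make_records(c(-0.5, -0.5, 0.5), c(-0.6, -0.6, 0.6))
  cc <- tibble::tibble(feature_id = c("PR001", "PR002", "PR003"),
                       t = c(-2.5, 2.8, 2.2),
                       p = c(0.03, 0.01, 0.04),
                       direction = c(-1, 1, 1))
  cur <- curate_candidates(rec, cc)
  # gene 1: negative r, lower in cases, significant -> kept
  # gene 2: negative r but higher in cases -> direction clash, dropped
  # gene 3: positive r, higher in cases -> kept
  expect_setequal(cur$gene_key, c("G001", "G003"))
  # absent from case-control table -> flagged and dropped
  expect_warning(cur2 <- curate_candidates(rec, cc[1:2, ]), "absent")
  expect_equal(cur2$gene_key, "G001")
})

test_that("planted truth set is recovered exactly at near-zero noise", {
  cfg <- sim_config(seed = 24, n_probes = 150, n_mouse_genes = 150,
                    n_shared_signal = 10, coexpr_block_size = 0,
                    human_effect_r = 0.995, mouse_log2fc = 3,
                    mouse_noise_sd = 0.02, n_cpg = 5)
  b <- simulate_cohort(cfg)
  norm <- normalize_microarray(b$human_expr)
  assoc <- correlate_phenotype(norm, b$phenotypes)
  de <- differential_expression(b$mouse_expr, b$mouse_groups)
  rec <- build_integration(assoc, de)
  sel <- select_overlap(rec, threshold_spec(), gate = "stringent")
  # every near-noiseless planted signal gene is recovered, and nothing null
  # slips in; the target gene carries residual mediation noise on its human
  # axis, so it may fall on either side of the |r| gate
  expect_true(all(toupper(b$truth$signal$gene_symbol) %in% sel$gene_key))
  expect_true(all(sel$gene_key %in%
                    toupper(c(b$truth$signal$gene_symbol,
                              b$truth$target$gene_symbol))))
})
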