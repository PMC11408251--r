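#' Per-probe correlation of expression with a symptom phenotype
#'
#' Computes, for every feature, the Pearson correlation (and optionally the
#' Spearman rank correlation) between its expression values and a chosen
#' phenotype column, across subjects present in both the matrix and the
#' phenotype table. Subjects with a missing phenotype value are dropped
#' (pairwise-complete), and the number actually used is recorded per
#' feature. Two-sided p-values come from the t distribution with
#' `n_used - 2` degrees of freedom; the Spearman statistic is the Pearson
#' correlation of the rank-transformed values with the same p machinery.
#'
#' @param expr Wide expression tibble (normalized log2 scale).
#' @param pheno Phenotype tibble with `subject_id` and the phenotype column.
#' @param phenotype Name of the phenotype column (e.g. `"reexperiencing"`).
#' @param methods Character subset of `c("pearson", "spearman")`.
#' @param covariates Optional character vector of phenotype-table columns to
#'   partial out; adds `partial_r` / `partial_p` columns (least-squares
#'   residualization, p on `n - 2 - k` degrees of freedom).
#' @return Tibble with one row per feature: `feature_id`, `gene_symbol`,
#'   `n_used`, `pearson_r`, `pearson_p`, optionally `spearman_rho`,
#'   `spearman_p`, `partial_r`, `partial_p`, and `ok` (FALSE flags features
#'   whose correlation is undefined: zero variance or `n_used < 3`).
#' @export
correlate_phenotype <- function(expr, pheno,
                                phenotype = "reexperiencing",
                                methods = c("pearson", "spearman"),
                                covariates = NULL) {
  methods <- match.arg(methods, c("pearson", "spearman"), several.ok = TRUE)
  if (!phenotype %in% names(pheno)) {
    abort(paste0("phenotype '", phenotype, "' not found in phenotype table"))
  }
  m <- as_feature_matrix(expr)
  common <- intersect(colnames(m), pheno$subject_id)
  if (length(common) == 0) abort("no subjects shared between matrix and phenotype table")
  y_all <- pheno[[phenotype]][match(common, pheno$subject_id)]
  keep <- !is.na(y_all)
  y <- y_all[keep]
  n_used <- length(y)
  if (n_used < 3) abort("fewer than 3 subjects with a non-missing phenotype")
  m <- m[, common[keep], drop = FALSE]

  out <- tibble::tibble(
    feature_id = expr$feature_id,
    gene_symbol = expr$gene_symbol,
    n_used = n_used
  )
  sds <- apply(m, 1, stats::sd)
  ok <- is.finite(sds) & sds > 0 & stats::sd(y) > 0
  if ("pearson" %in% methods) {
    r <- suppressWarnings(as.vector(stats::cor(t(m), y)))
    r[!ok] <- NA_real_
    out$pearson_r <- r
    out$pearson_p <- cor_pvalue(r, rep(n_used, length(r)))
  }
  if ("spearman" %in% methods) {
    rk <- t(apply(m, 1, rank))
    rho <- suppressWarnings(as.vector(stats::cor(t(rk), rank(y))))
    rho[!ok] <- NA_real_
    out$spearman_rho <- rho
    out$spearman_p <- cor_pvalue(rho, rep(n_used, length(rho)))
  }
  if (!is.null(covariates)) {
    cov_m <- covariate_matrix(pheno, covariates, common[keep])
    pres <- purrr::map(seq_len(nrow(m)), function(i) {
      if (!ok[i]) return(c(NA_real_, NA_real_))
      unlist(partial_correlation(m[i, ], y, cov_m)[c("partial_r", "p")])
    })
    out$partial_r <- vapply(pres, `[[`, numeric(1), 1L)
    out$partial_p <- vapply(pres, `[[`, numeric(1), 2L)
  }
  out$ok <- ok
  out
}

covariate_matrix <- function(pheno, covariates, subject_ids) {
  missing_cov <- setdiff(covariates, names(pheno))
  if (length(missing_cov) > 0) {
    abort(paste0("covariate(s) not in phenotype table: ",
                 paste(missing_cov, collapse = ", ")))
  }
  cm <- as.matrix(pheno[match(subject_ids, pheno$subject_id), covariates,
                        drop = FALSE])
  storage.mode(cm) <- "double"
  cm
}

#' Partial correlation after least-squares covariate adjustment
#'
#' Residualizes `x` and `y` on the covariates by ordinary least squares
#' (with intercept) and correlates the residuals. The two-sided p-value
#' uses `n - 2 - k` degrees of freedom for `k` covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data frame of covariates
#'   (rows aligned with `x` and `y`).
#' @return One-row tibble: `partial_r`, `p`, `n`, `df`.
#' @export
#' @examples
#' set.seed(1)
#' age <- rnorm(30); x <- age + rnorm(30); y <- -age + rnorm(30)
#' partial_correlation(x, y, age)
partial_correlation <- function(x, y, covariates) {
  z <- as.matrix(as.data.frame(covariates))
  storage.mode(z) <- "double"
  cc <- stats::complete.cases(x, y, z)
  x <- x[cc]; y <- y[cc]; z <- z[cc, , drop = FALSE]
  n <- length(x)
  k <- ncol(z)
  if (n <= k + 2) abort("need n > number of covariates + 2")
  design <- cbind(1, z)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    drop_idx <- qd$pivot[seq.int(qd$rank + 1L, ncol(design))] - 1L
    nm <- colnames(z)
    if (is.null(nm)) nm <- paste0("covariate", seq_len(k))
    abort(paste0("collinear covariate(s): ",
                 paste(nm[pmax(drop_idx, 1L)], collapse = ", ")))
  }
  rx <- stats::resid(stats::lm.fit(design, x))
  ry <- stats::resid(stats::lm.fit(design, y))
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tt <- r * sqrt(df / (1 - r^2))
  tibble::tibble(partial_r = r, p = 2 * stats::pt(-abs(tt), df), n = n, df = df)
}

#' Per-feature case-control tests (Student's t, optional ANCOVA)
#'
#' Pooled-variance (Student) two-sample t-test per feature between two
#' subject groups, with the sign convention `cases - controls`. With a
#' covariate, additionally fits a one-way analysis of covariance per
#' feature (`expression ~ covariate + group`) and reports the F statistic
#' of the group term on `(1, n - 3)` degrees of freedom.
#'
#' @param expr Wide expression tibble.
#' @param pheno Phenotype tibble with `subject_id` and the group column.
#' @param group_col Name of the group column.
#' @param case,control Labels of the case and control groups.
#' @param covariate Optional single covariate column name (e.g. `"age"`).
#' @return Tibble per feature: `t`, `p`, `direction` (sign of cases mean
#'   minus controls mean), group means, optionally `ancova_F`, `ancova_p`,
#'   and `ok`.
#' @export
case_control_tests <- function(expr, pheno, group_col = "group",
                               case = "PTSD", control = "control",
                               covariate = NULL) {
  if (!group_col %in% names(pheno)) {
    abort(paste0("group column '", group_col, "' not in phenotype table"))
  }
  m <- as_feature_matrix(expr)
  common <- intersect(colnames(m), pheno$subject_id)
  grp <- pheno[[group_col]][match(common, pheno$subject_id)]
  idx_case <- which(grp == case)
  idx_ctrl <- which(grp == control)
  if (length(idx_case) < 2 || length(idx_ctrl) < 2) {
    abort("each group needs at least 2 subjects")
  }
  m <- m[, common, drop = FALSE]
  tt <- row_t_pooled(m, idx_case, idx_ctrl)
  out <- tibble::tibble(
    feature_id = expr$feature_id,
    gene_symbol = expr$gene_symbol,
    mean_case = unname(rowMeans(m[, idx_case, drop = FALSE])),
    mean_control = unname(rowMeans(m[, idx_ctrl, drop = FALSE])),
    t = tt$t,
    p = tt$p,
    direction = sign(tt$diff)
  )
  # features identical across all subjects: difference 0, evidence absent
  flat <- !tt$ok
  out$t[flat & tt$diff == 0] <- 0
  out$p[flat & tt$diff == 0] <- 1
  if (!is.null(covariate)) {
    cov_v <- covariate_matrix(pheno, covariate, common)[, 1]
    gfac <- factor(grp, levels = c(control, case))
    n <- length(common)
    anc <- purrr::map(seq_len(nrow(m)), function(i) {
      fit <- stats::lm(m[i, ] ~ cov_v + gfac)
      av <- stats::anova(fit)
      c(av["gfac", "F value"], av["gfac", "Pr(>F)"])
    })
    out$ancova_F <- vapply(anc, `[[`, numeric(1), 1L)
    out$ancova_p <- vapply(anc, `[[`, numeric(1), 2L)
    out$ancova_df <- paste0("(1, ", n - 3L, ")")
  }
  out$ok <- tt$ok | (tt$diff == 0)
  out
}
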