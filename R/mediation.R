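#' Candidate-gene CpG tripartite screen
#'
#' For each CpG site of a candidate gene, correlates its methylation beta
#' values with (i) symptom severity and (ii) the gene's mRNA expression,
#' across aligned subjects. A site is `selected` when both site-specific
#' correlations are significant at `alpha` (two-sided); it is `compatible`
#' when the three correlation signs close consistently:
#' `sign(r_meth_expr) * sign(r_expr_symptom) == sign(r_meth_symptom)`,
#' all three signs nonzero. The expression-symptom correlation is shared
#' across rows. No multiple-testing correction is applied across sites
#' (matching the screening convention); set `adjust = "BH"` to add
#' q-value-based selection.
#'
#' @param meth Wide methylation tibble (`cpg_id`, `gene_region`, one
#'   numeric beta column per subject).
#' @param expression Numeric vector of target-gene expression, named by
#'   subject id (or aligned positionally with the sample columns).
#' @param symptom Numeric vector of symptom severity, same convention.
#' @param alpha Two-sided significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"` selection uses
#'   BH q-values across the sites instead of raw p-values.
#' @return Tibble per CpG: the three correlations with p-values,
#'   `selected`, `compatible` and `ok` (constant sites flagged FALSE and
#'   never selected).
#' @export
tripartite_screen <- function(meth, expression, symptom, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  alpha <- check_number(alpha, "alpha", 0, 1, strict = TRUE)
  m <- as_feature_matrix(meth, id_col = "cpg_id")
  expression <- align_subject_vector(expression, colnames(m), "expression")
  symptom <- align_subject_vector(symptom, colnames(m), "symptom")
  cc <- stats::complete.cases(expression, symptom)
  m <- m[, cc, drop = FALSE]
  expression <- expression[cc]
  symptom <- symptom[cc]
  n <- length(expression)
  if (n < 3) abort("need at least 3 complete subjects")

  sds <- apply(m, 1, stats::sd)
  ok <- is.finite(sds) & sds > 0
  r_ms <- suppressWarnings(as.vector(stats::cor(t(m), symptom)))
  r_me <- suppressWarnings(as.vector(stats::cor(t(m), expression)))
  r_ms[!ok] <- NA_real_
  r_me[!ok] <- NA_real_
  r_es <- stats::cor(expression, symptom)
  p_ms <- cor_pvalue(r_ms, rep(n, length(r_ms)))
  p_me <- cor_pvalue(r_me, rep(n, length(r_me)))
  p_es <- cor_pvalue(r_es, n)

  sel_ms <- if (adjust == "BH") bh_fdr(p_ms) < alpha else p_ms < alpha
  sel_me <- if (adjust == "BH") bh_fdr(p_me) < alpha else p_me < alpha
  selected <- ok & sel_ms & sel_me
  selected[is.na(selected)] <- FALSE
  compatible <- ok & sign(r_me) != 0 & sign(r_es) != 0 & sign(r_ms) != 0 &
    sign(r_me) * sign(r_es) == sign(r_ms)
  compatible[is.na(compatible)] <- FALSE

  tibble::tibble(
    cpg_id = meth$cpg_id,
    r_meth_symptom = r_ms, p_meth_symptom = p_ms,
    r_meth_expr = r_me, p_meth_expr = p_me,
    r_expr_symptom = r_es, p_expr_symptom = p_es,
    n = n,
    selected = selected,
    compatible = compatible,
    ok = ok
  )
}

align_subject_vector <- function(v, subject_ids, what) {
  if (!is.null(names(v))) {
    missing_ids <- setdiff(subject_ids, names(v))
    if (length(missing_ids) > 0) {
      abort(paste0(what, " vector missing subject(s): ",
                   paste(utils::head(missing_ids, 5), collapse = ", ")))
    }
    v <- v[subject_ids]
  } else if (length(v) != length(subject_ids)) {
    abort(paste0(what, " vector length (", length(v),
                 ") does not match number of subjects (", length(subject_ids), ")"))
  }
  as.numeric(v)
}

#' Mediation analysis with bootstrap indirect effect
#'
#' Classic three-regression product-of-coefficients mediation of
#' `x -> m -> y`: ordinary least squares for `m ~ x` (path `a`),
#' `y ~ x + m` (paths `b` and direct `c'`) and `y ~ x` (total `c`), with
#' the indirect effect `a*b`, its Sobel standard error
#' `sqrt(a^2 SE_b^2 + b^2 SE_a^2)` and normal-theory p-value, and a
#' nonparametric case-resampling bootstrap confidence interval under a
#' fixed seed. The decomposition `c = c' + a*b` holds exactly for
#' least-squares fits on complete data.
#'
#' Paths are reported on both the raw scale and the fully standardized
#' scale (x, m, y z-scored); the standardized indirect effect is the
#' headline estimate because raw-scale products are unit-dependent
#' (a beta-value slope times an expression slope does not live on the
#' symptom scale).
#'
#' @param x Independent variable (e.g. CpG methylation beta values).
#' @param m Mediator (e.g. target-gene expression).
#' @param y Outcome (e.g. symptom severity).
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Integer seed for the bootstrap.
#' @param ci_type `"percentile"` (default) or `"bca"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `crossmed_mediation`; see [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' set.seed(4)
#' x <- rnorm(32); m <- 2 * x + rnorm(32); y <- -1.5 * m + rnorm(32)
#' fit <- mediation_analysis(x, m, y, n_boot = 1000, seed = 1)
#' glance(fit)
mediation_analysis <- function(x, m, y, n_boot = 5000, seed = 1,
                               ci_type = c("percentile", "bca"),
                               conf_level = 0.95) {
  ci_type <- match.arg(ci_type)
  n_boot <- check_count(n_boot, "n_boot", 1000L)
  cc <- stats::complete.cases(x, m, y)
  x <- as.numeric(x[cc]); m <- as.numeric(m[cc]); y <- as.numeric(y[cc])
  n <- length(x)
  if (n < 10) abort("need at least 10 complete cases")
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    abort("x, m and y must all vary")
  }
  if (abs(stats::cor(x, m)) >= 1 - 1e-12) {
    abort("x and m are perfectly collinear; paths b and c' are not identifiable")
  }

  paths <- dplyr::bind_rows(
    dplyr::mutate(fit_paths(x, m, y), scale = "raw"),
    dplyr::mutate(fit_paths(zscore(x, "x"), zscore(m, "m"), zscore(y, "y")),
                  scale = "standardized")
  )
  est <- function(sc, term, col = "estimate") {
    paths[[col]][paths$scale == sc & paths$term == term]
  }
  indirect <- dplyr::bind_rows(
    lapply(c("raw", "standardized"), function(sc) {
      a <- est(sc, "a"); b <- est(sc, "b")
      se_a <- est(sc, "a", "se"); se_b <- est(sc, "b", "se")
      sobel_se <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
      zst <- (a * b) / sobel_se
      tibble::tibble(scale = sc, estimate = a * b, se = sobel_se,
                     statistic = zst, p = 2 * stats::pnorm(-abs(zst)))
    })
  )

  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    t(apply(idx, 2, function(i) boot_indirect(x[i], m[i], y[i])))
  })
  colnames(boot) <- c("raw", "standardized")
  ci <- lapply(c(raw = "raw", standardized = "standardized"), function(sc) {
    boot_ci(boot[, sc], indirect$estimate[indirect$scale == sc],
            x, m, y, sc, ci_type, conf_level)
  })

  headline <- indirect[indirect$scale == "standardized", ]
  cprime_p <- est("standardized", "c_prime", "p")
  structure(
    list(paths = dplyr::relocate(paths, "scale"),
         indirect = indirect,
         ci = ci, ci_type = ci_type, conf_level = conf_level,
         complete_mediation = headline$p < 0.05 && cprime_p >= 0.05,
         n = n, n_boot = n_boot, seed = seed),
    class = "crossmed_mediation"
  )
}

# OLS path fits for one scale; returns a, b, c_prime, c_total rows.
fit_paths <- function(x, m, y) {
  sm_a <- summary(stats::lm(m ~ x))$coefficients
  sm_bc <- summary(stats::lm(y ~ x + m))$coefficients
  sm_c <- summary(stats::lm(y ~ x))$coefficients
  tibble::tibble(
    term = c("a", "b", "c_prime", "c_total"),
    estimate = c(sm_a["x", 1], sm_bc["m", 1], sm_bc["x", 1], sm_c["x", 1]),
    se = c(sm_a["x", 2], sm_bc["m", 2], sm_bc["x", 2], sm_c["x", 2]),
    statistic = c(sm_a["x", 3], sm_bc["m", 3], sm_bc["x", 3], sm_c["x", 3]),
    p = c(sm_a["x", 4], sm_bc["m", 4], sm_bc["x", 4], sm_c["x", 4])
  )
}

# Fast indirect effect (raw and standardized) for one bootstrap resample.
boot_indirect <- function(x, m, y) {
  raw <- tryCatch({
    a <- stats::cov(x, m) / stats::var(x)
    xm <- cbind(1, x, m)
    b <- stats::lm.fit(xm, y)$coefficients[["m"]]
    a * b
  }, error = function(e) NA_real_)
  std <- tryCatch({
    zx <- (x - mean(x)) / stats::sd(x)
    zm <- (m - mean(m)) / stats::sd(m)
    zy <- (y - mean(y)) / stats::sd(y)
    a <- stats::cov(zx, zm)
    b <- stats::lm.fit(cbind(1, zx, zm), zy)$coefficients[[3]]
    a * b
  }, error = function(e) NA_real_)
  c(raw, std)
}

boot_ci <- function(draws, estimate, x, m, y, sc, ci_type, conf_level) {
  draws <- draws[is.finite(draws)]
  alpha <- (1 - conf_level) / 2
  if (ci_type == "percentile") {
    q <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 7)
    return(c(lower = q[1], upper = q[2]))
  }
  # BCa: bias-correction from the bootstrap distribution, acceleration from
  # a leave-one-out jackknife of the indirect effect
  z0 <- stats::qnorm(mean(draws < estimate))
  n <- length(x)
  jack <- vapply(seq_len(n), function(i) {
    v <- boot_indirect(x[-i], m[-i], y[-i])
    if (sc == "raw") v[1] else v[2]
  }, numeric(1))
  jm <- mean(jack)
  acc <- sum((jm - jack)^3) / (6 * (sum((jm - jack)^2))^1.5)
  zl <- stats::qnorm(alpha)
  zu <- stats::qnorm(1 - alpha)
  p1 <- stats::pnorm(z0 + (z0 + zl) / (1 - acc * (z0 + zl)))
  p2 <- stats::pnorm(z0 + (z0 + zu) / (1 - acc * (z0 + zu)))
  q <- stats::quantile(draws, c(p1, p2), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the path coefficients of a mediation fit
#'
#' @param x A [mediation_analysis()] object.
#' @param scale `"standardized"` (default), `"raw"`, or `"all"`.
#' @param ... Unused.
#' @return Tibble of path rows (`a`, `b`, `c_prime`, `c_total`,
#'   `indirect`) with estimate, SE, statistic and p-value.
#' @export
tidy.crossmed_mediation <- function(x, scale = c("standardized", "raw", "all"), ...) {
  scale <- match.arg(scale)
  ind <- dplyr::mutate(x$indirect, term = "indirect")
  out <- dplyr::bind_rows(x$paths, ind)
  out <- dplyr::relocate(out, "scale", "term")
  if (scale != "all") out <- out[out$scale == scale, , drop = FALSE]
  out
}

#' One-row summary of a mediation fit
#'
#' @param x A [mediation_analysis()] object.
#' @param ... Unused.
#' @return One-row tibble: standardized indirect estimate, Sobel SE and p,
#'   bootstrap CI bounds, direct-path p, `complete_mediation`, `n`,
#'   `n_boot`.
#' @export
glance.crossmed_mediation <- function(x, ...) {
  h <- x$indirect[x$indirect$scale == "standardized", ]
  tibble::tibble(
    indirect = h$estimate,
    indirect_se = h$se,
    indirect_p = h$p,
    ci_lower = x$ci$standardized[["lower"]],
    ci_upper = x$ci$standardized[["upper"]],
    c_prime_p = x$paths$p[x$paths$scale == "standardized" & x$paths$term == "c_prime"],
    complete_mediation = x$complete_mediation,
    n = x$n,
    n_boot = x$n_boot
  )
}

#' @export
print.crossmed_mediation <- function(x, ...) {
  cat("<crossmed_mediation>  n =", x$n, " n_boot =", x$n_boot,
      " ci =", x$ci_type, "\n\n")
  print(tidy(x, scale = "all"), n = 10)
  cat("\nstandardized indirect ", format(x$conf_level * 100), "% CI: [",
      signif(x$ci$standardized[["lower"]], 4), ", ",
      signif(x$ci$standardized[["upper"]], 4), "]  complete mediation: ",
      x$complete_mediation, "\n", sep = "")
  invisible(x)
}
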