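#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Column names reserved for feature annotation in wide expression tibbles.
.expr_annot <- c("feature_id", "gene_symbol")
.meth_annot <- c("cpg_id", "gene_region")

#' Sample columns of a wide expression or methylation tibble
#'
#' @param x Wide tibble (`feature_id`/`gene_symbol` or `cpg_id`/`gene_region`
#'   annotation columns followed by one numeric column per sample).
#' @return Character vector of sample column names.
#' @keywords internal
sample_cols <- function(x) {
  setdiff(names(x), c(.expr_annot, .meth_annot))
}

# Wide tibble -> numeric matrix (features x samples), rownames = feature ids.
as_feature_matrix <- function(x, id_col = "feature_id") {
  if (!id_col %in% names(x)) {
    abort(paste0("column '", id_col, "' not found in feature table"))
  }
  sc <- sample_cols(x)
  if (length(sc) == 0L) abort("no sample columns found")
  m <- as.matrix(x[, sc])
  if (!is.numeric(m)) abort("sample columns must all be numeric")
  rownames(m) <- x[[id_col]]
  m
}

# Matrix (features x samples) -> wide tibble, carrying annotation columns over.
matrix_to_expr <- function(m, annot) {
  dplyr::bind_cols(annot, tibble::as_tibble(m))
}

# Two-sided p-value for a Pearson correlation from the t distribution.
cor_pvalue <- function(r, n) {
  df <- n - 2
  p <- rep(NA_real_, length(r))
  ok <- is.finite(r) & df > 0
  # guard |r| == 1 (t infinite -> p = 0)
  tt <- r[ok] * sqrt(df[ok] / pmax(1 - r[ok]^2, 0))
  p[ok] <- 2 * stats::pt(-abs(tt), df[ok])
  p[ok & abs(r) >= 1] <- 0
  p
}

# Vectorized pooled-variance (Student) two-sample t over rows of a matrix.
# Returns difference of means (a - b), t, two-sided p, and a validity flag
# for rows with zero pooled variance.
row_t_pooled <- function(m, idx_a, idx_b) {
  na <- length(idx_a)
  nb <- length(idx_b)
  if (na < 2L || nb < 2L) abort("each group needs at least 2 samples")
  a <- m[, idx_a, drop = FALSE]
  b <- m[, idx_b, drop = FALSE]
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp * (1 / na + 1 / nb))
  ma <- unname(ma); mb <- unname(mb); se <- unname(se)
  ok <- se > 0
  tt <- ifelse(ok, (ma - mb) / se, NA_real_)
  df <- na + nb - 2
  p <- ifelse(ok, 2 * stats::pt(-abs(tt), df), NA_real_)
  # identical groups: define t = 0, p = 1 only when a difference is estimable;
  # zero pooled variance with equal means is a flat feature -> flagged instead
  list(diff = ma - mb, t = tt, p = p, ok = ok, df = df)
}

# z-standardize a numeric vector (sd = 0 -> error with context).
zscore <- function(v, what = "vector") {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) abort(paste0("cannot standardize ", what, ": zero variance"))
  (v - mean(v)) / s
}

# Evaluate code with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Integer counts >= 0 check used by configuration validation.
check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort(paste0("'", name, "' must be a single integer >= ", min), class = "crossmed_config_error")
  }
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  bad <- length(x) != 1L || !is.numeric(x) || is.na(x) ||
    (strict && (x <= lower || x >= upper)) ||
    (!strict && (x < lower || x > upper))
  if (bad) {
    abort(paste0("'", name, "' must be a number in ",
                 if (strict) "(" else "[", lower, ", ", upper,
                 if (strict) ")" else "]"),
          class = "crossmed_config_error")
  }
  as.numeric(x)
}
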