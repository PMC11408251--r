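#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin, validated wrapper around `stats::p.adjust(method = "BH")`:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1 and mapped back to
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed; NAs are
#'   excluded from the family and returned as NA).
#' @return Vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("p-values must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression with BH FDR
#'
#' Per-gene pooled-variance Student's t-test between two animal groups on a
#' log2-scale expression matrix, with the log2 fold change as the
#' difference of group means (`group_a - group_b`) and BH q-values computed
#' across all testable genes. Genes with zero variance in both groups are
#' flagged (`ok = FALSE`) and excluded from the BH family.
#'
#' The signed linear fold change follows the convention
#' `fc_linear = sign(log2fc) * 2^|log2fc|`, so downregulation by a factor
#' 1.4 is reported as -1.4 and `|fc_linear| >= 1` always.
#'
#' @param expr Wide expression tibble (log2-like scale).
#' @param groups Tibble with `sample_id` and `group` columns, or a named
#'   character vector of group labels.
#' @param group_a,group_b Labels of the contrast (`a - b`); defaults
#'   `"React-30"` vs `"NR"`.
#' @param input_scale `"log2"` (default) or `"counts"`; counts are
#'   transformed with `log2(x + 1)` first.
#' @return Tibble per gene: `feature_id`, `gene_symbol`, `log2fc`,
#'   `fc_linear`, `t`, `p`, `q`, `ok`.
#' @export
differential_expression <- function(expr, groups,
                                    group_a = "React-30", group_b = "NR",
                                    input_scale = c("log2", "counts")) {
  input_scale <- match.arg(input_scale)
  if (is.data.frame(groups)) {
    glab <- groups$group
    names(glab) <- groups$sample_id
  } else {
    glab <- groups
  }
  m <- as_feature_matrix(expr)
  if (!all(colnames(m) %in% names(glab))) {
    abort(paste0("group label missing for sample(s): ",
                 paste(setdiff(colnames(m), names(glab)), collapse = ", ")))
  }
  glab <- glab[colnames(m)]
  if (input_scale == "counts") m <- log2(m + 1)
  idx_a <- which(glab == group_a)
  idx_b <- which(glab == group_b)
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    abort(paste0("groups '", group_a, "' and '", group_b,
                 "' need at least 2 samples each"))
  }
  tt <- row_t_pooled(m, idx_a, idx_b)
  flat_equal <- !tt$ok & tt$diff == 0
  p <- tt$p
  t_stat <- tt$t
  p[flat_equal] <- 1
  t_stat[flat_equal] <- 0
  ok <- tt$ok | flat_equal
  q <- rep(NA_real_, length(p))
  q[ok] <- bh_fdr(p[ok])
  tibble::tibble(
    feature_id = expr$feature_id,
    gene_symbol = expr$gene_symbol,
    log2fc = tt$diff,
    fc_linear = sign(tt$diff) * 2^abs(tt$diff) + ifelse(tt$diff == 0, 1, 0),
    t = t_stat,
    p = p,
    q = q,
    ok = ok
  )
}

#' Volcano-style up/down classification
#'
#' Labels each gene `"up"` if `log2fc > log2fc_cut` and `p < p_cut`,
#' `"down"` if `log2fc < -log2fc_cut` and `p < p_cut`, otherwise `"ns"`.
#' Thresholds are strict inequalities.
#'
#' @param de A [differential_expression()] table (needs `log2fc` and `p`).
#' @param log2fc_cut,p_cut Positive thresholds (defaults 0.38 and 0.05).
#' @return `de` with an added `regulation` factor; the up/down counts are
#'   attached as attribute `"counts"`.
#' @export
classify_volcano <- function(de, log2fc_cut = 0.38, p_cut = 0.05) {
  log2fc_cut <- check_number(log2fc_cut, "log2fc_cut", 0, Inf, strict = TRUE)
  p_cut <- check_number(p_cut, "p_cut", 0, 1, strict = TRUE)
  lab <- dplyr::case_when(
    de$log2fc > log2fc_cut & de$p < p_cut ~ "up",
    de$log2fc < -log2fc_cut & de$p < p_cut ~ "down",
    TRUE ~ "ns"
  )
  lab[is.na(de$log2fc) | is.na(de$p)] <- "ns"
  out <- dplyr::mutate(de, regulation = factor(lab, levels = c("up", "down", "ns")))
  attr(out, "counts") <- c(up = sum(lab == "up"), down = sum(lab == "down"))
  out
}
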