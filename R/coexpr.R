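#' Target-gene co-expression screen
#'
#' Correlates every other probe with a target probe across all subjects and
#' keeps probes exceeding an absolute-correlation threshold (strict
#' inequality). The target itself is excluded from the output.
#'
#' @param expr Wide expression tibble (normalized scale).
#' @param target_probe `feature_id` of the target probe.
#' @param abs_r_min Absolute Pearson r threshold (default 0.6).
#' @return Tibble of retained probes sorted by decreasing |r|:
#'   `feature_id`, `gene_symbol`, `r`, `p`, `n`. The unique retained gene
#'   symbols are attached as attribute `"genes"`.
#' @export
coexpression_screen <- function(expr, target_probe, abs_r_min = 0.6) {
  abs_r_min <- check_number(abs_r_min, "abs_r_min", 0, 1)
  m <- as_feature_matrix(expr)
  if (!target_probe %in% rownames(m)) {
    abort(paste0("target probe '", target_probe, "' not in matrix"))
  }
  tv <- m[target_probe, ]
  if (stats::sd(tv) == 0) abort("target probe has zero variance")
  n <- ncol(m)
  if (n < 3) abort("need at least 3 samples")
  others <- m[rownames(m) != target_probe, , drop = FALSE]
  sds <- apply(others, 1, stats::sd)
  r <- suppressWarnings(as.vector(stats::cor(t(others), tv)))
  r[sds == 0] <- NA_real_
  out <- tibble::tibble(
    feature_id = rownames(others),
    gene_symbol = expr$gene_symbol[match(rownames(others), expr$feature_id)],
    r = r,
    p = cor_pvalue(r, rep(n, length(r))),
    n = n
  )
  out <- out[!is.na(out$r) & abs(out$r) > abs_r_min, , drop = FALSE]
  out <- out[order(-abs(out$r)), , drop = FALSE]
  attr(out, "genes") <- unique(out$gene_symbol[!is.na(out$gene_symbol)])
  out
}

#' Hypergeometric gene-set overrepresentation test
#'
#' One-sided upper-tail hypergeometric test per gene set: with `N` universe
#' genes, `K` of them in the set, and `n` hit genes, the p-value is
#' `P(X >= k)` for the observed overlap `k`, `X ~ Hypergeometric(N, K, n)`.
#' BH q-values are computed across sets. Hit genes and sets are first
#' intersected with the universe (case-insensitive symbol harmonization).
#'
#' @param hit_genes Character vector of hit gene symbols.
#' @param gene_sets A [read_gmt()] collection (or tibble with `set_name`,
#'   `description`, list-column `genes`).
#' @param universe Character vector of background gene symbols.
#' @return Tibble sorted by ascending p: `set_name`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, list-column `overlap`.
#' @export
enrich_hypergeometric <- function(hit_genes, gene_sets, universe) {
  uni <- unique(toupper(universe[!is.na(universe) & universe != ""]))
  if (length(uni) == 0) abort("empty universe")
  hits <- intersect(unique(toupper(hit_genes)), uni)
  n <- length(hits)
  N <- length(uni)
  rows <- purrr::pmap(
    list(gene_sets$set_name, gene_sets$genes),
    function(nm, members) {
      set_u <- intersect(unique(toupper(members)), uni)
      K <- length(set_u)
      ov <- intersect(hits, set_u)
      k <- length(ov)
      # P(X >= k); k = 0 gives 1 by construction
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      tibble::tibble(set_name = nm, k = k, K = K, n = n, N = N, p = p,
                     overlap = list(sort(ov)))
    }
  )
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p), , drop = FALSE]
  dplyr::relocate(out, "set_name", "k", "K", "n", "N", "p", "q")
}
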