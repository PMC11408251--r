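#' Threshold specification for cross-species overlap selection
#'
#' Collects every gate threshold of the integration stage. Defaults follow
#' the hybrid-threshold design: a human effect-size cutoff |r| > 0.40 (with
#' a p < 0.05 alternative gate), a mouse FDR cutoff q < 0.001 (with a
#' q < 0.05 alternative), a mouse linear fold-change cutoff |FC| > 1.36, a
#' case-control p cutoff 0.05 and a 10-SD outlier exclusion rule. All
#' inequalities are strict.
#'
#' @param human_abs_r_min Human |Pearson r| cutoff.
#' @param human_p_max Human p cutoff (alternative, broad gate).
#' @param mouse_q_max Mouse BH q cutoff (stringent gate).
#' @param mouse_abs_fc_min Mouse |linear FC| cutoff.
#' @param mouse_q_alt Mouse BH q cutoff (broad gate).
#' @param case_control_p_max Case-control t-test p cutoff.
#' @param outlier_sd Outlier exclusion threshold in SD units.
#' @return List of class `crossmed_thresholds`.
#' @export
threshold_spec <- function(human_abs_r_min = 0.40,
                           human_p_max = 0.05,
                           mouse_q_max = 0.001,
                           mouse_abs_fc_min = 1.36,
                           mouse_q_alt = 0.05,
                           case_control_p_max = 0.05,
                           outlier_sd = 10) {
  spec <- list(
    human_abs_r_min = check_number(human_abs_r_min, "human_abs_r_min", 0, 1, strict = TRUE),
    human_p_max = check_number(human_p_max, "human_p_max", 0, 1, strict = TRUE),
    mouse_q_max = check_number(mouse_q_max, "mouse_q_max", 0, 1, strict = TRUE),
    mouse_abs_fc_min = check_number(mouse_abs_fc_min, "mouse_abs_fc_min", 1, Inf),
    mouse_q_alt = check_number(mouse_q_alt, "mouse_q_alt", 0, 1, strict = TRUE),
    case_control_p_max = check_number(case_control_p_max, "case_control_p_max", 0, 1, strict = TRUE),
    outlier_sd = check_number(outlier_sd, "outlier_sd", 0, Inf, strict = TRUE)
  )
  structure(spec, class = "crossmed_thresholds")
}

#' Match human and mouse features by gene symbol
#'
#' Case-insensitive symbol matching (human upper-case nomenclature against
#' mouse mixed case). Features without a symbol are dropped; a human gene
#' measured by several probes contributes one record per probe, all mapped
#' to the same mouse gene.
#'
#' @param human Tibble with `feature_id` and `gene_symbol` (human side; per
#'   probe). Extra columns are carried along prefixed `human_`.
#' @param mouse Tibble with `feature_id` and `gene_symbol` (mouse side).
#'   Extra columns carried along prefixed `mouse_`.
#' @return Tibble of matched records with `gene_key` (upper-cased symbol),
#'   `human_probe`, `human_symbol`, `mouse_feature`, `mouse_symbol` and all
#'   carried statistics columns.
#' @export
match_symbols <- function(human, mouse) {
  h <- dplyr::filter(human, !is.na(.data$gene_symbol), .data$gene_symbol != "")
  m <- dplyr::filter(mouse, !is.na(.data$gene_symbol), .data$gene_symbol != "")
  h <- dplyr::mutate(h, gene_key = toupper(.data$gene_symbol))
  m <- dplyr::mutate(m, gene_key = toupper(.data$gene_symbol))
  h <- dplyr::rename(h, human_probe = "feature_id", human_symbol = "gene_symbol")
  names(h)[!names(h) %in% c("gene_key", "human_probe", "human_symbol") &
             !startsWith(names(h), "human_")] <-
    paste0("human_", names(h)[!names(h) %in% c("gene_key", "human_probe", "human_symbol") &
                                !startsWith(names(h), "human_")])
  m <- dplyr::rename(m, mouse_feature = "feature_id", mouse_symbol = "gene_symbol")
  names(m)[!names(m) %in% c("gene_key", "mouse_feature", "mouse_symbol") &
             !startsWith(names(m), "mouse_")] <-
    paste0("mouse_", names(m)[!names(m) %in% c("gene_key", "mouse_feature", "mouse_symbol") &
                                !startsWith(names(m), "mouse_")])
  out <- dplyr::inner_join(h, m, by = "gene_key", relationship = "many-to-many")
  if (nrow(out) == 0) {
    abort(paste0("no gene symbols shared between species; top unmatched human symbols: ",
                 paste(utils::head(h$human_symbol, 5), collapse = ", ")))
  }
  dplyr::relocate(out, "gene_key", "human_probe", "human_symbol",
                  "mouse_feature", "mouse_symbol")
}

#' Direction-consistency classification of a human/mouse effect pair
#'
#' A gene is consistent when its human symptom-correlation and its mouse
#' retrieval fold change share a (nonzero) sign. Zero on either axis is
#' conservatively inconsistent and flagged degenerate; NaN/NA input yields
#' an NA record to be excluded from counts.
#'
#' @param human_r Numeric vector of human Pearson correlations.
#' @param mouse_log2fc Numeric vector of mouse log2 fold changes.
#' @return Tibble with `quadrant` (`"up-up"`, `"down-down"`, `"up-down"`,
#'   `"down-up"` or NA), `consistent` and `degenerate`.
#' @export
#' @examples
#' classify_direction(c(-0.46, 0.5), c(-0.49, 0))
classify_direction <- function(human_r, mouse_log2fc) {
  sh <- sign(human_r)
  sm <- sign(mouse_log2fc)
  valid <- is.finite(human_r) & is.finite(mouse_log2fc)
  quadrant <- dplyr::case_when(
    !valid ~ NA_character_,
    sh > 0 & sm > 0 ~ "up-up",
    sh < 0 & sm < 0 ~ "down-down",
    sh > 0 & sm <= 0 ~ "up-down",
    sh < 0 & sm >= 0 ~ "down-up",
    sh == 0 & sm > 0 ~ "down-up",
    sh == 0 & sm < 0 ~ "up-down",
    TRUE ~ "down-down"  # both exactly zero: placeholder, degenerate
  )
  tibble::tibble(
    quadrant = quadrant,
    consistent = valid & sh != 0 & sm != 0 & sh == sm,
    degenerate = valid & (sh == 0 | sm == 0)
  )
}

#' Build per-probe integration records from the two species' tables
#'
#' Joins an [correlate_phenotype()] table with a
#' [differential_expression()] table on case-insensitive gene symbol and
#' attaches the direction-consistency classification.
#'
#' @param assoc Human association table (per probe).
#' @param de Mouse DE table (per gene).
#' @return Tibble of integration records.
#' @export
build_integration <- function(assoc, de) {
  h <- dplyr::select(assoc, "feature_id", "gene_symbol",
                     r = "pearson_r", p = "pearson_p", ok = "ok")
  m <- dplyr::select(de, "feature_id", "gene_symbol",
                     log2fc = "log2fc", fc_linear = "fc_linear",
                     p = "p", q = "q", ok = "ok")
  rec <- match_symbols(h, m)
  cls <- classify_direction(rec$human_r, rec$mouse_log2fc)
  dplyr::bind_cols(rec, cls)
}

#' Single-pass outlier exclusion on a numeric axis
#'
#' Flags entries more than `k_sd` standard deviations above the mean, with
#' mean and SD computed once over all values (no re-iteration). A zero SD
#' excludes nothing. With `two_sided = TRUE` the rule is applied to both
#' tails.
#'
#' @param values Numeric vector.
#' @param k_sd Threshold in SD units (default 10; `Inf` is the identity).
#' @param two_sided Flag both tails? Default `FALSE` (upper tail only).
#' @return Tibble with `value`, `excluded` and the z-score `z`.
#' @export
exclude_outliers <- function(values, k_sd = 10, two_sided = FALSE) {
  if (length(values) < 3) abort("need at least 3 values")
  mu <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  z <- if (is.finite(s) && s > 0) (values - mu) / s else rep(0, length(values))
  excl <- if (two_sided) abs(z) > k_sd else z > k_sd
  excl[is.na(excl)] <- FALSE
  tibble::tibble(value = values, z = z, excluded = excl)
}

#' Hybrid-threshold overlap selection across species
#'
#' Three gates over the integration records:
#' \describe{
#'   \item{`"hybrid"`}{|human r| > `human_abs_r_min` AND mouse
#'     q < `mouse_q_max`; direction consistency NOT required
#'     (characterization gate).}
#'   \item{`"stringent"`}{the hybrid gate plus |mouse linear FC| >
#'     `mouse_abs_fc_min` plus direction consistency (the curated overlap
#'     gate).}
#'   \item{`"broad"`}{human p < `human_p_max` AND mouse q < `mouse_q_alt`;
#'     consistency not required; single-pass outlier exclusion
#'     (> `outlier_sd` SD on the standardized mouse fold-change axis)
#'     applied.}
#' }
#' All inequalities strict. Records flagged not-ok on either axis never
#' pass.
#'
#' @param records [build_integration()] output.
#' @param spec A [threshold_spec()].
#' @param gate One of `"stringent"`, `"hybrid"`, `"broad"`.
#' @return The selected records, with logical gate provenance columns
#'   `passed_human`, `passed_mouse`, `passed_consistency` retained.
#' @export
select_overlap <- function(records, spec = threshold_spec(),
                           gate = c("stringent", "hybrid", "broad")) {
  gate <- match.arg(gate)
  if (nrow(records) == 0) return(records)
  ok <- records$human_ok & records$mouse_ok &
    is.finite(records$human_r) & is.finite(records$mouse_log2fc)
  rec <- records
  if (gate == "broad") {
    ph <- ok & rec$human_p < spec$human_p_max
    pm <- ok & rec$mouse_q < spec$mouse_q_alt
    keep <- ph & pm
    out <- rec[keep, , drop = FALSE]
    out$passed_human <- TRUE
    out$passed_mouse <- TRUE
    out$passed_consistency <- NA
    if (nrow(out) >= 3) {
      ex <- exclude_outliers(out$mouse_log2fc, spec$outlier_sd)
      out <- out[!ex$excluded, , drop = FALSE]
    }
    return(out)
  }
  ph <- ok & abs(rec$human_r) > spec$human_abs_r_min
  pm <- ok & rec$mouse_q < spec$mouse_q_max
  if (gate == "stringent") {
    pm <- pm & abs(rec$mouse_fc_linear) > spec$mouse_abs_fc_min
    keep <- ph & pm & rec$consistent
  } else {
    keep <- ph & pm
  }
  out <- rec[keep, , drop = FALSE]
  out$passed_human <- TRUE
  out$passed_mouse <- TRUE
  out$passed_consistency <- if (gate == "stringent") TRUE else NA
  out
}

#' Cross-species concordance statistics over a record set
#'
#' Standardizes the human correlation axis and the mouse fold-change axis
#' across records (z-scores), correlates them, and summarizes the
#' direction-consistency split.
#'
#' @param records Integration records (>= 3 rows with finite axes).
#' @return One-row tibble: `r`, `p`, `n`, `consistent_fraction`, and the
#'   2x2 quadrant counts `n_up_up`, `n_down_down`, `n_up_down`,
#'   `n_down_up`.
#' @export
concordance <- function(records) {
  rec <- records[is.finite(records$human_r) & is.finite(records$mouse_log2fc), ]
  n <- nrow(rec)
  if (n < 3) abort("need at least 3 records with finite axes")
  zh <- zscore(rec$human_r, "human correlation axis")
  zm <- zscore(rec$mouse_log2fc, "mouse fold-change axis")
  r <- stats::cor(zh, zm)
  cls <- classify_direction(rec$human_r, rec$mouse_log2fc)
  cnt <- function(q) sum(cls$quadrant == q, na.rm = TRUE)
  tibble::tibble(
    r = r,
    p = cor_pvalue(r, n),
    n = n,
    consistent_fraction = mean(cls$consistent),
    n_up_up = cnt("up-up"),
    n_down_down = cnt("down-down"),
    n_up_down = cnt("up-down"),
    n_down_up = cnt("down-up")
  )
}

#' Three-dataset curation of the overlap gene list
#'
#' Keeps overlap genes whose patients-vs-controls difference is significant
#' (p < `case_control_p_max`) AND whose case-control direction matches the
#' human correlation direction: a gene negatively correlated with symptom
#' severity must be lower in patients than in controls, and vice versa.
#' Genes absent from the case-control table are flagged and dropped.
#'
#' @param overlap Records selected by the stringent gate.
#' @param case_control A [case_control_tests()] table.
#' @param spec A [threshold_spec()].
#' @return Curated records with `cc_t`, `cc_p`, `cc_direction` and
#'   `passed_case_control` columns.
#' @export
curate_candidates <- function(overlap, case_control, spec = threshold_spec()) {
  cc <- dplyr::select(case_control, "feature_id",
                      cc_t = "t", cc_p = "p", cc_direction = "direction")
  out <- dplyr::left_join(overlap, cc, by = c(human_probe = "feature_id"))
  miss <- is.na(out$cc_p)
  if (any(miss)) {
    warn(paste0(sum(miss), " overlap record(s) absent from case-control table; dropped"))
  }
  out$passed_case_control <- !miss &
    out$cc_p < spec$case_control_p_max &
    out$cc_direction == sign(out$human_r) &
    out$cc_direction != 0
  out[which(out$passed_case_control), , drop = FALSE]
}
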