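#' Microarray-style normalization of a raw expression matrix
#'
#' Applies, in order: (1) thresholding of raw signal values to a floor
#' (default 1.0); (2) log2 transformation; (3) percentile-shift
#' normalization, subtracting each sample's 75th percentile so that every
#' sample's chosen percentile becomes 0; (4) baseline transformation,
#' subtracting each feature's median across all samples.
#'
#' Percentiles use the linear-interpolation convention of
#' `stats::quantile(type = 7)`; the convention is configurable because array
#' vendor software does not document its choice.
#'
#' @param raw Wide expression tibble of raw (linear-scale, non-negative)
#'   values.
#' @param floor Raw-signal floor applied before the log transform.
#' @param percentile Per-sample shift percentile, in (0, 100).
#' @param quantile_type Passed to [stats::quantile()].
#' @param keep_stages If `TRUE`, attach the intermediate post-shift matrix
#'   (before baseline transformation) as attribute `"stages"`. Each
#'   normalization invariant lives at its own stage: after the shift every
#'   sample's chosen percentile is exactly 0; after the baseline step every
#'   feature's across-sample median is exactly 0 (the baseline step then
#'   moves sample percentiles off 0 again, as any per-feature centering
#'   must).
#' @return Wide tibble of normalized log2 values, same dimensions and
#'   annotations as `raw`.
#' @export
#' @examples
#' b <- simulate_cohort(sim_config(seed = 1, n_probes = 50,
#'                                 n_mouse_genes = 50, n_shared_signal = 2,
#'                                 coexpr_block_size = 2))
#' norm <- normalize_microarray(b$human_expr)
#' # every sample's 75th percentile is 0 after the shift + baseline steps
#' max(abs(apply(as.matrix(norm[-(1:2)]), 2, stats::median)))
normalize_microarray <- function(raw, floor = 1.0, percentile = 75,
                                 quantile_type = 7, keep_stages = FALSE) {
  floor <- check_number(floor, "floor", 0, Inf, strict = TRUE)
  percentile <- check_number(percentile, "percentile", 0, 100, strict = TRUE)
  m <- as_feature_matrix(raw)
  if (ncol(m) < 2) abort("at least 2 samples required (baseline median undefined)")
  if (any(m < 0, na.rm = TRUE)) abort("raw expression values must be >= 0")
  m <- log2(pmax(m, floor))
  shift <- apply(m, 2, stats::quantile, probs = percentile / 100,
                 type = quantile_type, names = FALSE)
  m <- sweep(m, 2, shift, "-")
  annot <- raw[, intersect(names(raw), .expr_annot)]
  shifted <- if (keep_stages) matrix_to_expr(m, annot) else NULL
  baseline <- apply(m, 1, stats::median)
  m <- sweep(m, 1, baseline, "-")
  out <- matrix_to_expr(m, annot)
  if (keep_stages) attr(out, "stages") <- list(shifted = shifted)
  out
}
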