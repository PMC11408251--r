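#' Run the full cross-species integration pipeline
#'
#' Executes, in order: microarray normalization of the human matrix;
#' per-probe association with the chosen phenotype; per-gene case-control
#' tests; mouse two-group differential expression with BH FDR;
#' cross-species symbol matching and direction classification; overlap
#' selection under the broad, hybrid and stringent gates; concordance
#' statistics on the broad-gate set; three-dataset curation; target-gene
#' co-expression screen (plus gene-set overrepresentation when a
#' collection is supplied); the candidate-gene CpG tripartite screen in
#' patients; and mediation analysis of the designated mediator CpG.
#'
#' @param bundle A `crossmed_bundle` (from [simulate_cohort()] or
#'   [read_bundle()]) or a directory path understood by [read_bundle()].
#' @param thresholds A [threshold_spec()].
#' @param phenotype Phenotype column driving the human screen.
#' @param target_probe `feature_id` of the target probe; defaults to the
#'   bundle's planted target.
#' @param mediator_cpg CpG id for the mediation model; defaults to the
#'   planted mediator.
#' @param gene_sets Optional [read_gmt()] collection for enrichment.
#' @param coexpr_abs_r_min Co-expression |r| threshold (default 0.6).
#' @param screen_group Subject group for the methylation stages (default
#'   `"PTSD"`: the screen and mediation run within patients).
#' @param n_boot,seed Bootstrap settings for the mediation stage.
#' @param norm_floor,norm_percentile Normalization parameters.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV together with a JSON gate-count summary and a run log.
#' @return List of class `crossmed_run` with every stage output and a
#'   `summary` tibble of gate counts.
#' @export
run_pipeline <- function(bundle,
                         thresholds = threshold_spec(),
                         phenotype = "reexperiencing",
                         target_probe = NULL,
                         mediator_cpg = NULL,
                         gene_sets = NULL,
                         coexpr_abs_r_min = 0.6,
                         screen_group = "PTSD",
                         n_boot = 5000,
                         seed = 1,
                         norm_floor = 1.0,
                         norm_percentile = 75,
                         out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "crossmed_bundle"))
  if (is.null(target_probe)) target_probe <- bundle$truth$target$feature_id
  if (is.null(mediator_cpg)) mediator_cpg <- bundle$truth$target$cpg_id

  norm <- normalize_microarray(bundle$human_expr, floor = norm_floor,
                               percentile = norm_percentile)
  assoc <- correlate_phenotype(norm, bundle$phenotypes, phenotype = phenotype)
  cc_tests <- case_control_tests(norm, bundle$phenotypes, covariate = "age")
  de <- differential_expression(bundle$mouse_expr, bundle$mouse_groups)
  records <- build_integration(assoc, de)
  broad <- select_overlap(records, thresholds, gate = "broad")
  hybrid <- select_overlap(records, thresholds, gate = "hybrid")
  stringent <- select_overlap(records, thresholds, gate = "stringent")
  conc <- if (nrow(broad) >= 3) concordance(broad) else NULL
  curated <- curate_candidates(stringent, cc_tests, thresholds)

  coexpr <- coexpression_screen(norm, target_probe, abs_r_min = coexpr_abs_r_min)
  enrich <- if (!is.null(gene_sets)) {
    enrich_hypergeometric(attr(coexpr, "genes"), gene_sets,
                          universe = unique(norm$gene_symbol))
  } else NULL

  subj <- bundle$phenotypes$subject_id[bundle$phenotypes$group == screen_group]
  nm <- as_feature_matrix(norm)
  expr_target <- nm[target_probe, intersect(subj, colnames(nm))]
  symptom <- bundle$phenotypes[[phenotype]][match(names(expr_target),
                                                  bundle$phenotypes$subject_id)]
  names(symptom) <- names(expr_target)
  meth_sub <- bundle$methylation[, c(.meth_annot,
                                     intersect(subj, sample_cols(bundle$methylation)))]
  screen <- tripartite_screen(meth_sub, expr_target, symptom)
  med_x <- as_feature_matrix(meth_sub, id_col = "cpg_id")[mediator_cpg,
                                                          names(expr_target)]
  keep <- stats::complete.cases(med_x, expr_target, symptom)
  mediation <- mediation_analysis(med_x[keep], expr_target[keep], symptom[keep],
                                  n_boot = n_boot, seed = seed)

  summary_tbl <- tibble::tibble(
    stage = c("matched_universe_records", "matched_universe_genes",
              "human_assoc_significant_p", "human_assoc_abs_r",
              "mouse_de_q_alt", "mouse_de_q_strict_fc",
              "overlap_broad", "overlap_hybrid", "overlap_stringent",
              "curated", "coexpr_probes", "coexpr_genes",
              "tripartite_selected", "tripartite_selected_compatible"),
    count = c(nrow(records), dplyr::n_distinct(records$gene_key),
              sum(records$human_p < thresholds$human_p_max & records$human_ok,
                  na.rm = TRUE),
              sum(abs(records$human_r) > thresholds$human_abs_r_min &
                    records$human_ok, na.rm = TRUE),
              sum(records$mouse_q < thresholds$mouse_q_alt & records$mouse_ok,
                  na.rm = TRUE),
              sum(records$mouse_q < thresholds$mouse_q_max &
                    abs(records$mouse_fc_linear) > thresholds$mouse_abs_fc_min &
                    records$mouse_ok, na.rm = TRUE),
              nrow(broad), nrow(hybrid), nrow(stringent), nrow(curated),
              nrow(coexpr), length(attr(coexpr, "genes")),
              sum(screen$selected), sum(screen$selected & screen$compatible))
  )

  run <- structure(
    list(normalized = norm, assoc = assoc, case_control = cc_tests, de = de,
         records = records, broad = broad, hybrid = hybrid,
         stringent = stringent, concordance = conc, curated = curated,
         coexpr = coexpr, enrichment = enrich, tripartite = screen,
         mediation = mediation, summary = summary_tbl,
         thresholds = thresholds, phenotype = phenotype, seed = seed),
    class = "crossmed_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(run$normalized, p("normalized_expression.tsv"))
  readr::write_tsv(run$assoc, p("association.tsv"))
  readr::write_tsv(run$case_control, p("case_control.tsv"))
  readr::write_tsv(run$de, p("mouse_de.tsv"))
  readr::write_tsv(run$records, p("integration_records.tsv"))
  readr::write_tsv(run$stringent, p("overlap_stringent.tsv"))
  readr::write_tsv(run$curated, p("curated_candidates.tsv"))
  readr::write_tsv(dplyr::select(run$coexpr, -dplyr::any_of("overlap")),
                   p("coexpression.tsv"))
  if (!is.null(run$enrichment)) {
    readr::write_tsv(dplyr::mutate(run$enrichment,
                                   overlap = vapply(.data$overlap, paste,
                                                    character(1), collapse = ",")),
                     p("enrichment.tsv"))
  }
  readr::write_tsv(run$tripartite, p("tripartite_screen.tsv"))
  readr::write_tsv(tidy(run$mediation, scale = "all"), p("mediation_paths.tsv"))
  counts <- as.list(run$summary$count)
  names(counts) <- run$summary$stage
  jsonlite::write_json(counts, p("summary.json"), auto_unbox = TRUE)
  log <- c(
    paste0("crossmed ", as.character(utils::packageVersion("crossmed"))),
    paste0("R ", R.version.string),
    paste0("date ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed ", run$seed),
    paste0("phenotype ", run$phenotype),
    paste0("thresholds ", paste(names(unclass(run$thresholds)),
                                unlist(run$thresholds), sep = "=",
                                collapse = " "))
  )
  readr::write_lines(log, p("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.crossmed_run <- function(x, ...) {
  cat("<crossmed_run>  phenotype:", x$phenotype, " seed:", x$seed, "\n")
  print(x$summary, n = nrow(x$summary))
  if (!is.null(x$concordance)) {
    cat("concordance r =", signif(x$concordance$r, 3),
        " consistent fraction =", signif(x$concordance$consistent_fraction, 3), "\n")
  }
  invisible(x)
}
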