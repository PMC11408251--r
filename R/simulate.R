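#' Configuration for the synthetic two-species cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the pipeline targets: 32 patients and 16 controls with a
#' symptom-severity score on an intrusion-subscale-like 0-40 scale, a few
#' thousand expression features per species of which a planted subset shares
#' its direction of effect across species, a co-expression block around a
#' designated target gene, and one CpG site whose methylation drives target
#' expression which in turn drives symptom severity.
#'
#' Planted human probes are built as `beta * z(symptom) + noise` with `beta`
#' chosen in closed form so the population correlation magnitude equals
#' `human_effect_r`. Planted mouse genes differ between the reactivated
#' (`React-30`) and non-reactivated (`NR`) groups by `mouse_log2fc` on the
#' log2 scale. `effect_sign = -1` (the default) plants downregulation on both
#' axes, mirroring the direction of the exemplar target gene PDE4B.
#'
#' `mouse_noise_sd` (within-group SD on the log2 scale) defaults to 0.12,
#' calibrated by a power simulation so that a planted gene at the default
#' effect sizes passes the stringent mouse gate (BH q < 0.001 and
#' |FC| > 1.36 at 8 animals per group) with probability about 0.98, and the
#' joint human-mouse gate with probability about 0.9.
#'
#' @param seed Integer seed; fixes every random draw.
#' @param n_patients,n_controls Human cohort sizes.
#' @param n_probes Total human probes (planted + target + block + null).
#' @param n_mouse_genes Total mouse genes.
#' @param n_shared_signal Number of planted shared-direction signal genes
#'   (present in both species, excluding the target gene).
#' @param human_effect_r Magnitude in (0,1) of the planted human
#'   probe-symptom population correlation.
#' @param mouse_log2fc Magnitude of the planted mouse log2 fold change.
#' @param mouse_n_per_group Animals per mouse group.
#' @param noise_sd Residual SD of human probe values on the log2 scale.
#' @param mouse_noise_sd Within-group SD of mouse log2 expression.
#' @param mediation_a Slope of target expression on planted-CpG methylation
#'   (beta-value scale).
#' @param mediation_b Slope of symptom severity on target expression.
#' @param mediation_cprime Direct slope of symptom severity on methylation.
#' @param coexpr_block_size Number of probes co-expressed with the target.
#' @param coexpr_loading Loading in (0,1) of block probes on the target's
#'   latent factor (their population correlation with the target).
#' @param n_cpg Number of candidate-gene CpG sites (one of which is the
#'   planted mediator).
#' @param target_symbol Gene symbol of the designated target gene.
#' @param effect_sign -1 or +1; sign of all planted effects.
#' @param missing_reexperiencing Number of patients whose reexperiencing
#'   score is set missing (default 0).
#'
#' @return A validated list of class `crossmed_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_probes = 300, n_mouse_genes = 300,
#'                   n_shared_signal = 10, coexpr_block_size = 5)
#' cfg$n_patients
sim_config <- function(seed = 1L,
                       n_patients = 32L,
                       n_controls = 16L,
                       n_probes = 5200L,
                       n_mouse_genes = 5200L,
                       n_shared_signal = 100L,
                       human_effect_r = 0.55,
                       mouse_log2fc = log2(1.5),
                       mouse_n_per_group = 8L,
                       noise_sd = 1,
                       mouse_noise_sd = 0.12,
                       mediation_a = 3.86,
                       mediation_b = -8.54,
                       mediation_cprime = 0,
                       coexpr_block_size = 30L,
                       coexpr_loading = 0.7,
                       n_cpg = 125L,
                       target_symbol = "PDE4B",
                       effect_sign = -1,
                       missing_reexperiencing = 0L) {
  cfg <- list(
    seed = check_count(seed, "seed"),
    n_patients = check_count(n_patients, "n_patients", 2L),
    n_controls = check_count(n_controls, "n_controls", 2L),
    n_probes = check_count(n_probes, "n_probes", 1L),
    n_mouse_genes = check_count(n_mouse_genes, "n_mouse_genes", 1L),
    n_shared_signal = check_count(n_shared_signal, "n_shared_signal"),
    human_effect_r = check_number(human_effect_r, "human_effect_r", 0, 1, strict = TRUE),
    mouse_log2fc = check_number(mouse_log2fc, "mouse_log2fc", 0, Inf),
    mouse_n_per_group = check_count(mouse_n_per_group, "mouse_n_per_group", 2L),
    noise_sd = check_number(noise_sd, "noise_sd", 0, Inf, strict = TRUE),
    mouse_noise_sd = check_number(mouse_noise_sd, "mouse_noise_sd", 0, Inf, strict = TRUE),
    mediation_a = check_number(mediation_a, "mediation_a"),
    mediation_b = check_number(mediation_b, "mediation_b"),
    mediation_cprime = check_number(mediation_cprime, "mediation_cprime"),
    coexpr_block_size = check_count(coexpr_block_size, "coexpr_block_size"),
    coexpr_loading = check_number(coexpr_loading, "coexpr_loading", 0, 1, strict = TRUE),
    n_cpg = check_count(n_cpg, "n_cpg", 1L),
    target_symbol = as.character(target_symbol),
    effect_sign = if (effect_sign >= 0) 1 else -1,
    missing_reexperiencing = check_count(missing_reexperiencing, "missing_reexperiencing")
  )
  if (cfg$n_shared_signal + cfg$coexpr_block_size + 1L > cfg$n_probes) {
    abort("n_probes must cover planted signal + co-expression block + target",
          class = "crossmed_config_error")
  }
  if (cfg$n_shared_signal + 1L > cfg$n_mouse_genes) {
    abort("n_mouse_genes must cover planted signal + target",
          class = "crossmed_config_error")
  }
  if (cfg$missing_reexperiencing > cfg$n_patients) {
    abort("missing_reexperiencing cannot exceed n_patients",
          class = "crossmed_config_error")
  }
  structure(cfg, class = "crossmed_config")
}

#' Generate a coupled human/mouse synthetic cohort
#'
#' Draws one realization of the generative model described in
#' [sim_config()]: symptom severity per subject (patients shifted upward),
#' a human probe-level expression matrix on the raw (linear) scale with
#' planted symptom-correlated probes and a target-gene co-expression block,
#' a mouse gene-level log2 expression matrix with planted fold changes of
#' matching sign, a candidate-gene CpG beta-value matrix with one planted
#' mediator site, and the ground-truth lists of everything planted.
#'
#' The human matrix is emitted on the raw scale (`2^log2value`) so that the
#' microarray normalization stage ([normalize_microarray()]) can be applied
#' exactly as it would be to vendor output.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `crossmed_bundle` with elements `human_expr`,
#'   `phenotypes`, `mouse_expr`, `mouse_groups`, `methylation`, `truth`,
#'   and `config`. All tables are tibbles; `truth` is a list of tibbles
#'   (`signal`, `target`, `coexpr`).
#' @export
#' @examples
#' b <- simulate_cohort(sim_config(seed = 7, n_probes = 200,
#'                                 n_mouse_genes = 200, n_shared_signal = 5,
#'                                 coexpr_block_size = 4))
#' dim(b$human_expr)
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "crossmed_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, generate_bundle(config))
}

generate_bundle <- function(cfg) {
  n_h <- cfg$n_patients + cfg$n_controls
  subj <- c(sprintf("PT%02d", seq_len(cfg$n_patients)),
            sprintf("HC%02d", seq_len(cfg$n_controls)))
  group <- c(rep("PTSD", cfg$n_patients), rep("control", cfg$n_controls))
  sign <- cfg$effect_sign

  ## --- methylation (X) and target expression (M) carry the mediation model
  meth_latent <- stats::rnorm(n_h)
  beta_target <- stats::plogis(stats::qlogis(0.55) + 0.5 * meth_latent)
  target_dev <- cfg$mediation_a * beta_target + stats::rnorm(n_h, sd = 0.35)

  ## --- symptom severity (Y): group shift + mediation paths + residual,
  ##     on a 0-40 intrusion-subscale-like scale
  base <- ifelse(group == "PTSD", 20, 3)
  y <- base +
    cfg$mediation_b * (target_dev - mean(target_dev)) +
    cfg$mediation_cprime * (beta_target - mean(beta_target)) +
    stats::rnorm(n_h, sd = 5)
  y <- pmin(pmax(y, 0), 40)
  z_y <- zscore(y, "symptom score")

  ## --- feature bookkeeping
  n_sig <- cfg$n_shared_signal
  n_blk <- cfg$coexpr_block_size
  n_null_h <- cfg$n_probes - 1L - n_sig - n_blk
  sig_sym <- if (n_sig > 0) sprintf("SIG%04d", seq_len(n_sig)) else character()
  blk_sym <- if (n_blk > 0) sprintf("COE%04d", seq_len(n_blk)) else character()
  null_sym_h <- if (n_null_h > 0) sprintf("NUL%05d", seq_len(n_null_h)) else character()
  human_sym <- c(cfg$target_symbol, sig_sym, blk_sym, null_sym_h)
  probe_id <- sprintf("PR%05d", seq_along(human_sym))

  ## --- human expression (log2 deviations around per-probe baselines)
  dev <- matrix(stats::rnorm(cfg$n_probes * n_h, sd = cfg$noise_sd),
                nrow = cfg$n_probes)
  # planted signal probes: closed-form loading on standardized symptom
  if (n_sig > 0) {
    b_load <- cfg$noise_sd * cfg$human_effect_r / sqrt(1 - cfg$human_effect_r^2)
    dev[1L + seq_len(n_sig), ] <- sign * b_load * rep(z_y, each = n_sig) +
      matrix(stats::rnorm(n_sig * n_h, sd = cfg$noise_sd), nrow = n_sig)
  }
  # target probe: the mediation mediator, centered
  dev[1L, ] <- target_dev - mean(target_dev)
  # co-expression block: shared latent factor = standardized target expression
  if (n_blk > 0) {
    f <- zscore(target_dev, "target expression")
    lam <- cfg$coexpr_loading
    dev[1L + n_sig + seq_len(n_blk), ] <-
      cfg$noise_sd * (lam * rep(f, each = n_blk) +
                        sqrt(1 - lam^2) *
                          matrix(stats::rnorm(n_blk * n_h), nrow = n_blk))
  }
  base_probe <- stats::runif(cfg$n_probes, 4, 12)
  human_raw <- 2^(base_probe + dev)
  colnames(human_raw) <- subj
  human_expr <- dplyr::bind_cols(
    tibble::tibble(feature_id = probe_id, gene_symbol = human_sym),
    tibble::as_tibble(human_raw)
  )

  ## --- phenotypes
  reexp <- round(y, 1)
  if (cfg$missing_reexperiencing > 0) {
    reexp[seq_len(cfg$missing_reexperiencing)] <- NA_real_
  }
  phenotypes <- tibble::tibble(
    subject_id = subj,
    group = group,
    reexperiencing = reexp,
    avoidance = round(pmin(pmax(0.8 * y + stats::rnorm(n_h, sd = 4), 0), 40), 1),
    hyperarousal = round(pmin(pmax(0.7 * y + stats::rnorm(n_h, sd = 4), 0), 40), 1),
    trait_anxiety = round(pmin(pmax(38 + 0.5 * y + stats::rnorm(n_h, sd = 6), 20), 80), 1),
    state_anxiety = round(pmin(pmax(36 + 0.4 * y + stats::rnorm(n_h, sd = 8), 20), 80), 1),
    depression = round(pmin(pmax(6 + 0.4 * y + stats::rnorm(n_h, sd = 5), 0), 60), 1),
    age = round(stats::runif(n_h, 21, 59))
  )

  ## --- mouse expression (log2 scale), groups NR vs React-30
  n_m <- 2L * cfg$mouse_n_per_group
  mouse_samples <- sprintf("MS%02d", seq_len(n_m))
  mouse_group <- rep(c("NR", "React-30"), each = cfg$mouse_n_per_group)
  mouse_target <- to_mouse_symbol(cfg$target_symbol)
  n_null_m <- cfg$n_mouse_genes - 1L - n_sig
  mouse_sym <- c(mouse_target, to_mouse_symbol(sig_sym),
                 if (n_null_m > 0) to_mouse_symbol(sprintf("NUL%05d", seq_len(n_null_m))) else character())
  mouse_mat <- stats::runif(cfg$n_mouse_genes, 2, 10) +
    matrix(stats::rnorm(cfg$n_mouse_genes * n_m, sd = cfg$mouse_noise_sd),
           nrow = cfg$n_mouse_genes)
  react <- mouse_group == "React-30"
  planted_rows <- seq_len(1L + n_sig)  # target + shared-signal genes
  mouse_mat[planted_rows, react] <- mouse_mat[planted_rows, react] +
    sign * cfg$mouse_log2fc
  colnames(mouse_mat) <- mouse_samples
  mouse_expr <- dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("MG%05d", seq_len(cfg$n_mouse_genes)),
                   gene_symbol = mouse_sym),
    tibble::as_tibble(mouse_mat)
  )
  mouse_groups <- tibble::tibble(sample_id = mouse_samples, group = mouse_group)

  ## --- candidate-gene CpG methylation (planted mediator first)
  cpg_id <- c("cg14227435",
              if (cfg$n_cpg > 1) sprintf("cpg_%03d", seq_len(cfg$n_cpg - 1L)) else character())
  meth_mat <- matrix(0, nrow = cfg$n_cpg, ncol = n_h)
  meth_mat[1L, ] <- beta_target
  if (cfg$n_cpg > 1) {
    site_mu <- stats::runif(cfg$n_cpg - 1L, stats::qlogis(0.1), stats::qlogis(0.9))
    meth_mat[-1L, ] <- stats::plogis(site_mu +
      0.5 * matrix(stats::rnorm((cfg$n_cpg - 1L) * n_h), nrow = cfg$n_cpg - 1L))
  }
  colnames(meth_mat) <- subj
  methylation <- dplyr::bind_cols(
    tibble::tibble(cpg_id = cpg_id,
                   gene_region = c("Body", rep("Body", cfg$n_cpg - 1L))),
    tibble::as_tibble(meth_mat)
  )

  truth <- list(
    signal = tibble::tibble(
      feature_id = probe_id[1L + seq_len(n_sig)],
      gene_symbol = sig_sym,
      mouse_symbol = to_mouse_symbol(sig_sym),
      direction = rep(sign, n_sig)
    ),
    target = tibble::tibble(
      feature_id = probe_id[1L],
      gene_symbol = cfg$target_symbol,
      mouse_symbol = mouse_target,
      cpg_id = cpg_id[1L],
      direction = sign
    ),
    coexpr = tibble::tibble(
      feature_id = probe_id[1L + n_sig + seq_len(n_blk)],
      gene_symbol = blk_sym
    )
  )

  structure(
    list(human_expr = human_expr, phenotypes = phenotypes,
         mouse_expr = mouse_expr, mouse_groups = mouse_groups,
         methylation = methylation, truth = truth, config = cfg),
    class = "crossmed_bundle"
  )
}

# Human (upper-case) symbol -> mouse-style symbol: first letter upper, rest lower.
to_mouse_symbol <- function(sym) {
  out <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
  out[!nzchar(sym)] <- sym[!nzchar(sym)]
  out
}

#' @export
print.crossmed_bundle <- function(x, ...) {
  cat("<crossmed_bundle>\n")
  cat("  human:", nrow(x$human_expr), "probes x",
      length(sample_cols(x$human_expr)), "subjects\n")
  cat("  mouse:", nrow(x$mouse_expr), "genes x",
      length(sample_cols(x$mouse_expr)), "samples\n")
  cat("  methylation:", nrow(x$methylation), "CpG sites\n")
  cat("  planted:", nrow(x$truth$signal), "signal genes,",
      nrow(x$truth$coexpr), "co-expression probes, target",
      x$truth$target$gene_symbol, "\n")
  invisible(x)
}

#' @export
print.crossmed_config <- function(x, ...) {
  cat("<crossmed_config>\n")
  flat <- unlist(x)
  cat(paste0("  ", format(names(flat)), " = ", flat, collapse = "\n"), "\n")
  invisible(x)
}
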