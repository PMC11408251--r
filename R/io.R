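#' Read a tab-delimited expression matrix
#'
#' Expects the layout written by [write_expression()]: a header row of sample
#' ids, first column `feature_id`, second column `gene_symbol`, then one
#' numeric column per sample. Duplicate feature ids, ragged rows and
#' non-numeric cells are rejected with informative errors.
#'
#' @param path File path.
#' @return Wide tibble (features x samples).
#' @export
read_expression <- function(path) {
  x <- read_checked_tsv(path, annot = .expr_annot)
  dup <- x$feature_id[duplicated(x$feature_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated feature id(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  x
}

#' Write a tab-delimited expression matrix
#' @param expr Wide expression tibble.
#' @param path Destination path.
#' @return `expr`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(expr)
}

#' Read / write a phenotype table
#'
#' The phenotype table has one row per subject with a `subject_id` column, a
#' `group` column, symptom scores (missing values allowed) and `age`.
#'
#' @param path File path.
#' @return Tibble of subjects.
#' @export
read_phenotypes <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stop_on_problems(x, path)
  if (!"subject_id" %in% names(x)) abort(paste0("no 'subject_id' column in ", path))
  dup <- x$subject_id[duplicated(x$subject_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated subject id(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  x
}

#' @rdname read_phenotypes
#' @param pheno Phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path)
  invisible(pheno)
}

#' Read a CpG beta-value matrix
#'
#' Layout: first column `cpg_id`, second `gene_region`, then one numeric
#' column of beta values in \[0,1\] per subject.
#'
#' @param path File path.
#' @return Wide tibble (CpG sites x subjects).
#' @export
read_methylation <- function(path) {
  x <- read_checked_tsv(path, annot = .meth_annot)
  m <- as_feature_matrix(x, id_col = "cpg_id")
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    abort(paste0("beta values outside [0,1] in ", path))
  }
  x
}

#' @rdname read_methylation
#' @param meth Methylation tibble.
#' @export
write_methylation <- function(meth, path) {
  readr::write_tsv(meth, path)
  invisible(meth)
}

# Shared reader: TSV with annotation columns followed by numeric samples.
# readr's own parsing chatter is silenced; problems() is inspected instead.
read_checked_tsv <- function(path, annot) {
  x <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  stop_on_problems(x, path)
  missing_annot <- setdiff(annot, names(x))
  if (length(missing_annot) > 0) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_annot, collapse = ", ")))
  }
  sc <- setdiff(names(x), annot)
  if (length(sc) == 0) abort(paste0("no sample columns in ", path))
  bad <- sc[!vapply(x[sc], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric sample column(s) in ", path, ": ",
                 paste(bad, collapse = ", ")))
  }
  x[, c(annot, sc)]
}

stop_on_problems <- function(x, path) {
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    abort(paste0("malformed file ", path, ": ", pr$expected[1],
                 " but got ", pr$actual[1], " at line ", pr$row[1]))
  }
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: one set per line, fields `name`,
#' `description`, then one member symbol per field. Lines with fewer than
#' three fields are rejected with their line number.
#'
#' @param path File path.
#' @return Tibble with columns `set_name`, `description` and a list-column
#'   `genes`; class `crossmed_gene_sets`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0) {
    abort(paste0("GMT line ", short[1], " in ", path,
                 " has fewer than 3 tab-separated fields"))
  }
  out <- tibble::tibble(
    set_name = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  )
  dup <- out$set_name[duplicated(out$set_name)]
  if (length(dup) > 0) {
    abort(paste0("duplicated set name(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(lengths(out$genes) == 0)) abort(paste0("empty gene set in ", path))
  class(out) <- c("crossmed_gene_sets", class(out))
  out
}

#' Write a GMT gene-set collection
#' @param gene_sets Tibble as returned by [read_gmt()].
#' @param path Destination path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- mapply(function(n, d, g) paste(c(n, d, g), collapse = "\t"),
                  gene_sets$set_name, gene_sets$description, gene_sets$genes)
  readr::write_lines(lines, path)
  invisible(gene_sets)
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits `human_expression.tsv`, `phenotypes.tsv`, `mouse_expression.tsv`,
#' `mouse_groups.tsv`, `methylation.tsv`, `truth.tsv` and `sim_config.tsv`,
#' all tab-delimited and round-trippable through [read_bundle()]. The truth
#' file carries a comment line documenting the symptom-score scale.
#'
#' @param bundle A [simulate_cohort()] bundle.
#' @param dir Writable directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "crossmed_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(bundle$human_expr, p("human_expression.tsv"))
  write_phenotypes(bundle$phenotypes, p("phenotypes.tsv"))
  write_expression(bundle$mouse_expr, p("mouse_expression.tsv"))
  readr::write_tsv(bundle$mouse_groups, p("mouse_groups.tsv"))
  write_methylation(bundle$methylation, p("methylation.tsv"))

  truth_tbl <- dplyr::bind_rows(
    dplyr::mutate(bundle$truth$signal, role = "signal", cpg_id = NA_character_),
    dplyr::mutate(bundle$truth$target, role = "target"),
    dplyr::mutate(bundle$truth$coexpr, role = "coexpr",
                  mouse_symbol = NA_character_, cpg_id = NA_character_,
                  direction = NA_real_)
  )
  truth_tbl <- truth_tbl[, c("role", "feature_id", "gene_symbol",
                             "mouse_symbol", "cpg_id", "direction")]
  con <- file(p("truth.tsv"), "w")
  writeLines("# symptom scale: intrusion-subscale analog, continuous 0-40", con)
  close(con)
  readr::write_tsv(truth_tbl, p("truth.tsv"), append = TRUE, col_names = TRUE)

  cfg <- bundle$config
  readr::write_tsv(
    tibble::tibble(key = names(unclass(cfg)),
                   value = vapply(unclass(cfg), as.character, character(1))),
    p("sim_config.tsv")
  )
  invisible(dir)
}

#' Read a synthetic bundle back from [write_bundle()] output
#' @param dir Directory written by [write_bundle()].
#' @return A `crossmed_bundle`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("human_expression.tsv", "phenotypes.tsv", "mouse_expression.tsv",
              "mouse_groups.tsv", "methylation.tsv", "truth.tsv",
              "sim_config.tsv")) {
    if (!file.exists(p(f))) abort(paste0("bundle file missing: ", p(f)))
  }
  cfg_tbl <- readr::read_tsv(p("sim_config.tsv"), show_col_types = FALSE,
                             progress = FALSE)
  cfg_args <- as.list(cfg_tbl$value)
  names(cfg_args) <- cfg_tbl$key
  chr_fields <- "target_symbol"
  cfg_args[setdiff(names(cfg_args), chr_fields)] <-
    lapply(cfg_args[setdiff(names(cfg_args), chr_fields)], as.numeric)
  cfg <- do.call(sim_config, cfg_args)

  truth_tbl <- readr::read_tsv(p("truth.tsv"), comment = "#",
                               show_col_types = FALSE, progress = FALSE)
  pick <- function(role, cols) {
    out <- truth_tbl[truth_tbl$role == role, cols, drop = FALSE]
    tibble::as_tibble(out)
  }
  truth <- list(
    signal = pick("signal", c("feature_id", "gene_symbol", "mouse_symbol", "direction")),
    target = pick("target", c("feature_id", "gene_symbol", "mouse_symbol", "cpg_id", "direction")),
    coexpr = pick("coexpr", c("feature_id", "gene_symbol"))
  )
  structure(
    list(human_expr = read_expression(p("human_expression.tsv")),
         phenotypes = read_phenotypes(p("phenotypes.tsv")),
         mouse_expr = read_expression(p("mouse_expression.tsv")),
         mouse_groups = readr::read_tsv(p("mouse_groups.tsv"),
                                        show_col_types = FALSE, progress = FALSE),
         methylation = read_methylation(p("methylation.tsv")),
         truth = truth, config = cfg),
    class = "crossmed_bundle"
  )
}
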