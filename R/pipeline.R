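# End-to-end orchestration: simulate/ingest -> harmonize -> PBSI ->
# brain age -> transcription association, from a single JSON-serializable
# config, with per-stage seeds derived from one global seed and every
# intermediate persisted as CSV.

#' Read a delimited table with schema validation
#'
#' Delimiter is inferred from the extension (`.tsv` = tab, otherwise comma).
#'
#' @param path File path.
#' @param required Column names that must be present.
#' @param numeric_cols Columns that must parse as numeric.
#' @param id_col Optional column checked for duplicates.
#' @return data.frame.
#' @export
read_table <- function(path, required = character(0), numeric_cols = character(0),
                       id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) stop("missing column(s) in ", path, ": ",
                            paste(missing, collapse = ", "))
  for (cc in intersect(numeric_cols, names(x))) {
    v <- x[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) stop("non-numeric value(s) in column '", cc, "' of ",
                            path, " (e.g. row ", bad[1L], ": '", v[bad[1L]], "')")
      x[[cc]] <- vn
    }
  }
  if (!is.null(id_col) && id_col %in% names(x)) {
    dup <- x[[id_col]][duplicated(x[[id_col]])]
    if (length(dup)) stop("duplicate ", id_col, " in ", path, ": ",
                          paste(unique(utils::head(dup, 5L)), collapse = ", "))
  }
  x
}

#' Write a delimited table (delimiter from extension)
#'
#' @param x data.frame or matrix.
#' @param path Destination; `.tsv` writes tab-separated, anything else CSV.
#' @export
write_table <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

profiles_to_df <- function(profiles) {
  data.frame(subject_id = rownames(profiles), as.data.frame(profiles),
             check.names = FALSE, stringsAsFactors = FALSE)
}
df_to_profiles <- function(df) {
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(m) <- df$subject_id
  storage.mode(m) <- "double"
  m
}

#' Persist a synthetic cohort as plain-text files
#'
#' Writes `profiles.csv` (subject_id + one column per region label),
#' `phenotypes.csv`, and `truth.json` (planted effects) into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(profiles_to_df(cohort$profiles), file.path(dir, "profiles.csv"))
  write_table(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "pbsi_run",
    cohort = list(n_per_group = 60L, n_regions = 40L, n_sites = 3L),
    harmonization = list(method = "combat", covariates = c("age", "sex", "tiv"),
                         var_explained = 0.95),
    pbsi = list(group_col = "dx", case_level = "ASD"),
    brainage = list(model = "rvr", n_folds = 5L, n_shuffles = 2L, n_strata = 5L),
    expression = list(n_genes = 200L, n_planted = 10L, rho_target = 0.6),
    fdr = 0.05
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]])
    } else user[[k]]
  }
  defaults
}

load_phenotypes <- function(path) {
  read_table(path,
             required = c("subject_id", "age", "sex", "site", "tiv", "dx"),
             numeric_cols = c("age", "sex", "tiv", "fiq", "adi_rrb", "adi_soc",
                              "adi_ver"),
             id_col = "subject_id")
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages, in order, each persisted into `config$out_dir`:
#' \enumerate{
#'   \item cohort: synthetic generation from `config$cohort` (or ingestion of
#'     `config$profiles` / `config$phenotypes` file paths) ->
#'     `profiles.csv`, `phenotypes.csv`;
#'   \item harmonization (ComBat or CovBat, age/sex/TIV covariates) ->
#'     `harmonized.csv`;
#'   \item PBSI per diagnostic group, leave-one-region-out contributions,
#'     delta map and region-wise Bonferroni statistics -> `pbsi_scores.csv`,
#'     `contributions.csv`, `contribution_delta.csv`, `region_stats.csv`;
#'   \item brain age: cross-validated model on NC contributions, patient
#'     prediction, DED/PRD split and cognition comparisons -> `brainage.csv`;
#'   \item transcription association of the delta map with (synthetic or
#'     ingested) expression -> `expression.csv`, `genes.csv`;
#'   \item machine-readable summary -> `report.json`.
#' }
#' All randomness derives from `config$seed`; the same config yields
#' byte-identical outputs on rerun.
#'
#' @param config Nested list (see `default_run_config` internals for the
#'   schema) or path to a JSON file of overrides.
#' @return The run report (also written as `report.json`), invisibly the
#'   paths of all persisted files in `$files`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_run_config(), config)
  if (!is.null(cfg$profiles) && !file.exists(cfg$profiles)) {
    stop("profiles file not found: ", cfg$profiles)
  }
  if (!is.null(cfg$phenotypes) && !file.exists(cfg$phenotypes)) {
    stop("phenotypes file not found: ", cfg$phenotypes)
  }
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[pipeline] %-12s %s", stage, paste0(...)))
  }

  # -- stage 1: cohort ------------------------------------------------------
  if (!is.null(cfg$profiles)) {
    profiles <- df_to_profiles(read_table(cfg$profiles, required = "subject_id",
                                          id_col = "subject_id"))
    phenotypes <- load_phenotypes(cfg$phenotypes)
    cohort <- NULL
  } else {
    spec_args <- cfg$cohort
    spec_args$seed <- derive_seed(cfg$seed, "cohort")
    cohort <- generate_cohort(do.call(cohort_spec, spec_args))
    profiles <- cohort$profiles
    phenotypes <- cohort$phenotypes
  }
  write_table(profiles_to_df(profiles), file.path(out, "profiles.csv"))
  write_table(phenotypes, file.path(out, "phenotypes.csv"))
  log_stage("cohort", nrow(profiles), " subjects x ", ncol(profiles), " regions")

  # -- stage 2: harmonization ----------------------------------------------
  covs <- as.matrix(phenotypes[, cfg$harmonization$covariates, drop = FALSE])
  design <- batch_design(phenotypes$site, covs)
  harm <- if (identical(cfg$harmonization$method, "covbat")) {
    covbat(profiles, design, var_explained = cfg$harmonization$var_explained)
  } else {
    combat(profiles, design)
  }
  write_table(profiles_to_df(harm$adjusted), file.path(out, "harmonized.csv"))
  log_stage("harmonize", cfg$harmonization$method, ", ",
            nlevels(design$batch), " sites")

  # -- stage 3: PBSI --------------------------------------------------------
  grp <- factor(phenotypes[[cfg$pbsi$group_col]])
  scores <- numeric(nrow(harm$adjusted))
  contrib <- matrix(NA_real_, nrow(harm$adjusted), ncol(harm$adjusted),
                    dimnames = dimnames(harm$adjusted))
  for (g in levels(grp)) {
    idx <- grp == g
    sub <- harm$adjusted[idx, , drop = FALSE]
    scores[idx] <- pbsi_scores(sub)
    contrib[idx, ] <- regional_contributions(sub)
  }
  score_df <- data.frame(subject_id = rownames(harm$adjusted),
                         group = as.character(grp), pbsi = scores,
                         stringsAsFactors = FALSE)
  write_table(score_df, file.path(out, "pbsi_scores.csv"))
  write_table(profiles_to_df(contrib), file.path(out, "contributions.csv"))
  cd <- contribution_delta(contrib, grp, case_level = cfg$pbsi$case_level)
  delta_df <- data.frame(region = colnames(contrib),
                         t(cd$group_means), delta = cd$delta,
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_table(delta_df, file.path(out, "contribution_delta.csv"))
  covs_as <- cbind(age = phenotypes$age, sex = as.numeric(phenotypes$sex))
  stats_df <- regionwise_group_difference(contrib, grp, covs_as)
  write_table(stats_df, file.path(out, "region_stats.csv"))
  group_cmp <- compare_groups(scores, grp, covs_as)
  age_cor <- correlate_with_covariates(scores, phenotypes$age)
  log_stage("pbsi", "group p=", signif(group_cmp$p.value, 3),
            ", age rho=", signif(age_cor$rho, 3))

  # -- stage 4: brain age ---------------------------------------------------
  case <- cfg$pbsi$case_level
  ctrl <- setdiff(levels(grp), case)
  ba_cfg <- brainage_config(model = cfg$brainage$model,
                            n_folds = cfg$brainage$n_folds,
                            n_shuffles = cfg$brainage$n_shuffles,
                            n_strata = cfg$brainage$n_strata,
                            seed = derive_seed(cfg$seed, "brainage"))
  ba <- cross_validated_brainage(contrib[grp == ctrl, , drop = FALSE],
                                 phenotypes$age[grp == ctrl],
                                 contrib[grp == case, , drop = FALSE],
                                 phenotypes$age[grp == case], ba_cfg)
  split <- split_ded_prd(ba$asd$brain_age, ba$asd$age)
  ba_df <- rbind(
    data.frame(subject_id = rownames(profiles)[grp == ctrl], group = ctrl,
               age = ba$nc$age, brain_age = ba$nc$brain_age, gap = ba$nc$gap,
               dev_label = NA_character_, stringsAsFactors = FALSE),
    data.frame(subject_id = rownames(profiles)[grp == case], group = case,
               age = ba$asd$age, brain_age = ba$asd$brain_age, gap = ba$asd$gap,
               dev_label = as.character(split$dev_label), stringsAsFactors = FALSE))
  write_table(ba_df, file.path(out, "brainage.csv"))
  cog <- tryCatch(
    compare_ded_prd_cognition(split, phenotypes[grp == case, , drop = FALSE]),
    error = function(e) NULL)
  log_stage("brainage", cfg$brainage$model, ", rho=",
            signif(mean(ba$performance$rho), 3))

  # -- stage 5: transcription association ----------------------------------
  if (!is.null(cfg$expression$path)) {
    edf <- read_table(cfg$expression$path, required = "gene_id", id_col = "gene_id")
    expr <- as.matrix(edf[, setdiff(names(edf), "gene_id"), drop = FALSE])
    rownames(expr) <- edf$gene_id
  } else {
    espec_args <- cfg$expression[setdiff(names(cfg$expression), "path")]
    espec_args$seed <- derive_seed(cfg$seed, "expression")
    expr <- generate_expression(do.call(expression_spec, espec_args), cd$delta)$expression
  }
  edf_out <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_table(edf_out, file.path(out, "expression.csv"))
  assoc <- associate_delta_expression(cd$delta, expr, fdr_threshold = cfg$fdr)
  write_table(assoc, file.path(out, "genes.csv"))
  log_stage("associate", sum(assoc$significant), " significant genes")

  # -- stage 6: report ------------------------------------------------------
  qs <- function(x) unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  report <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("pbsitools")),
    n_subjects = nrow(profiles), n_regions = ncol(profiles),
    pbsi = list(
      group_quartiles = lapply(split(scores, grp), qs),
      group_test = list(p = group_cmp$p.value, test = group_cmp$test),
      age_correlation = list(rho = age_cor$rho, p = age_cor$p.value),
      significant_regions = sum(stats_df$significant)),
    brainage = list(
      model = cfg$brainage$model,
      rho_mean = mean(ba$performance$rho), mae_mean = mean(ba$performance$mae),
      rmse_mean = mean(ba$performance$rmse),
      n_ded = sum(split$dev_label == "DED"),
      n_prd = sum(split$dev_label == "PRD"),
      n_neither = sum(split$dev_label == "neither"),
      cognition = if (!is.null(cog)) {
        stats::setNames(as.list(cog$p), cog$score)
      } else NULL),
    association = list(n_genes = nrow(assoc),
                       n_significant = sum(assoc$significant)),
    config = cfg)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$files <- file.path(out, c(
    "profiles.csv", "phenotypes.csv", "harmonized.csv", "pbsi_scores.csv",
    "contributions.csv", "contribution_delta.csv", "region_stats.csv",
    "brainage.csv", "expression.csv", "genes.csv", "report.json"))
  invisible(report)
}
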