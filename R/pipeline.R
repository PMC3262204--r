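#' Read / write clinical tables as CSV
#'
#' Column dictionary: `sample_id`; `group` (truth or assigned label);
#' `age_lt50`, `size_gt2cm`, `node_pos` (logical bands); `grade` (1..3);
#' `er`, `pr`, `her2`, `her2tn` (logical receptor status); `et_treated`,
#' `neoadjuvant` (logical treatment flags); `time` (months), `event`
#' (logical relapse), `pcr` (logical, NA unless neoadjuvant).
#'
#' @param path file path.
#' @return `read_clinical` returns a data frame with logical flags restored.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in intersect(c("age_lt50", "size_gt2cm", "node_pos", "er", "pr",
                         "her2", "her2tn", "et_treated", "neoadjuvant",
                         "event", "pcr"), names(df)))
    df[[cc]] <- as.logical(df[[cc]])
  df
}

#' @rdname read_clinical
#' @param clinical a clinical data frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline from a single configuration
#'
#' Executes simulate -> preprocess -> derive -> classify -> evaluate in
#' dependency order from one YAML (or list) configuration, writing every
#' artifact plus a run manifest (config echo, seeds, package version, md5
#' content hash of every output file) into `out_dir`. All stages are
#' deterministic given the config, so re-running reproduces the file hashes.
#'
#' Config sections (all optional except `seed`): `cohort` (overrides for
#' [cohort_config()]), `platform` (overrides for [platform_spec()]; presence
#' enables the cross-platform validation arm), `derivation`
#' ([derivation_config()] overrides), `classifier` ([classifier_config()]
#' overrides), `preprocess` ([preprocess_config()] overrides).
#'
#' @param config path to a YAML file or a named list.
#' @param out_dir output directory, created if needed.
#' @return the run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed))
    stop("config must name a 'seed'", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ccfg <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
  pcfg <- do.call(preprocess_config, config$preprocess %||% list())
  dcfg <- do.call(derivation_config, config$derivation %||% list())
  kcfg <- do.call(classifier_config, config$classifier %||% list())

  # simulate
  cohort <- generate_cohort(ccfg)
  clinical <- simulate_outcomes(cohort$clinical, ccfg)
  write_expr_matrix(cohort$expr, file.path(out_dir, "training_matrix.tsv"))
  write_annotation(cohort$annotation, file.path(out_dir, "training_annotation.tsv"))
  write_clinical(clinical, file.path(out_dir, "training_clinical.csv"))

  # preprocess + derive
  x <- preprocess_pipeline(cohort$expr, cohort$annotation, pcfg)
  der <- derive_cmtc(x, clinical, dcfg)
  write_cmtc_model(der$model, file.path(out_dir, "model.json"))
  utils::write.csv(data.frame(sample_id = names(der$labels),
                              group = unname(der$labels)),
                   file.path(out_dir, "training_labels.csv"),
                   row.names = FALSE, quote = FALSE)

  # classify: resubstitution, plus a distorted second platform if requested
  cls <- classify_cohort(der$model, x, kcfg, clinical = clinical)
  write_classification(cls, file.path(out_dir, "classification_training.csv"))
  cls_val <- NULL
  if (!is.null(config$platform)) {
    spec <- do.call(platform_spec, config$platform)
    val <- generate_validation_platform(cohort$expr, cohort$annotation, spec,
                                        seed = config$seed + 2L)
    xv <- preprocess_pipeline(val$expr, val$annotation, pcfg)
    cls_val <- classify_cohort(der$model, xv, kcfg, clinical = clinical)
    write_classification(cls_val,
                         file.path(out_dir, "classification_validation.csv"))
  }

  # evaluate
  assigned <- der$labels[clinical$sample_id]
  km <- kaplan_meier(clinical, assigned)
  rate_tab <- group_rate_table(cbind(clinical, assigned = assigned),
                               "assigned", "event")
  utils::write.csv(rate_tab, file.path(out_dir, "recurrence_by_group.csv"),
                   row.names = FALSE, quote = FALSE)
  eval_summary <- list(logrank_chisq = km$logrank_chisq, logrank_p = km$p,
                       n_events = km$n_events)
  if (any(!is.na(clinical$pcr))) {
    neo <- which(!is.na(clinical$pcr))
    pa <- pcr_analysis(clinical$pcr[neo], assigned[neo],
                       her2 = clinical$her2[neo], tn = with(clinical[neo, ],
                         !er & !pr & !her2),
                       n_boot = 200, seed = config$seed + 3L)
    utils::write.csv(pa$rates, file.path(out_dir, "pcr_rates.csv"),
                     row.names = FALSE, quote = FALSE)
    eval_summary$pcr_auc_group3 <- pa$roc$group3$auc
  }
  jsonlite::write_json(eval_summary, file.path(out_dir, "evaluation.json"),
                       digits = NA, auto_unbox = TRUE)

  manifest <- build_manifest(config, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_manifest <- function(config, out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  paths <- file.path(out_dir, files)
  list(config = config,
       seed = config$seed,
       package_version = as.character(utils::packageVersion("cmtc")),
       timestamp = format(Sys.time(), tz = "UTC"),
       files = stats::setNames(as.list(unname(tools::md5sum(paths))), files))
}
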