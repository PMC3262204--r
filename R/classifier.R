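#' Classifier configuration
#'
#' @param correlation correlation type used against the centroids:
#'   `"pearson"` (default; the centroid framework is linear in log2 ratios) or
#'   `"spearman"`.
#' @param min_shared_frac minimum fraction of model genes that must be present
#'   in the target before classification is attempted, in (0, 1].
#' @param recenter_target gene-wise median-center the target cohort before
#'   correlating (default TRUE); the minimal harmonization for platforms with
#'   different baselines.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(correlation = c("pearson", "spearman"),
                              min_shared_frac = 0.5,
                              recenter_target = TRUE) {
  if (min_shared_frac <= 0 || min_shared_frac > 1)
    stop("min_shared_frac must be in (0,1]", call. = FALSE)
  structure(list(correlation = match.arg(correlation),
                 min_shared_frac = min_shared_frac,
                 recenter_target = isTRUE(recenter_target)),
            class = "classifier_config")
}

#' Align a target matrix with the model's feature space
#'
#' Intersects the model's features (gene symbols after collapsing) with the
#' target matrix rows and returns both restricted to the shared set in
#' identical order. Errors when the shared fraction falls below the
#' configured minimum.
#'
#' @param model a `cmtc_model`.
#' @param target an [expr_matrix()] whose rows are gene symbols (run the
#'   target through [preprocess_pipeline()] first).
#' @param config a [classifier_config()].
#' @return list with `centroids`, `target` (values matrix), `shared_genes` and
#'   `shared_frac`.
#' @export
map_features <- function(model, target, config = classifier_config()) {
  stopifnot(inherits(model, "cmtc_model"), inherits(target, "expr_matrix"))
  shared <- intersect(model$probe_set, probe_ids(target))
  frac <- length(shared) / length(model$probe_set)
  if (frac < config$min_shared_frac)
    stop(sprintf(
      "only %.1f%% of model genes found in target (minimum %.1f%%)",
      100 * frac, 100 * config$min_shared_frac), call. = FALSE)
  list(centroids = model$centroids[shared, , drop = FALSE],
       target = target$values[shared, , drop = FALSE],
       shared_genes = shared, shared_frac = frac)
}

#' Classify a single expression profile
#'
#' Correlates one sample's profile (over the shared gene space) with the three
#' group centroids and assigns the group of the uniquely highest correlation.
#' Exact ties and zero-variance profiles yield `"unclassified"` rather than an
#' arbitrary call. The correlation to the CMTC-3 centroid is reported as the
#' `r_index`, a continuous similarity score to the high-risk expression
#' pattern.
#'
#' @param model a `cmtc_model`.
#' @param profile named numeric vector over (a subset of) the model's
#'   features, or an already-aligned vector in the model's feature order.
#' @param config a [classifier_config()].
#' @param sample_id identifier used in the result row.
#' @return one-row data frame: `sample_id`, `r1`, `r2`, `r3`, `group`,
#'   `r_index`, `n_shared_genes`.
#' @export
classify_sample <- function(model, profile, config = classifier_config(),
                            sample_id = "sample") {
  stopifnot(inherits(model, "cmtc_model"))
  if (!is.null(names(profile))) {
    shared <- intersect(model$probe_set, names(profile))
    frac <- length(shared) / length(model$probe_set)
    if (frac < config$min_shared_frac)
      stop(sprintf(
        "only %.1f%% of model genes found in profile (minimum %.1f%%)",
        100 * frac, 100 * config$min_shared_frac), call. = FALSE)
    prof <- profile[shared]
    cen <- model$centroids[shared, , drop = FALSE]
  } else {
    if (length(profile) != length(model$probe_set))
      stop("unnamed profile must match the model feature length", call. = FALSE)
    prof <- profile
    cen <- model$centroids
  }
  if (stats::sd(prof) == 0) {
    warning("zero-variance profile for ", sample_id, "; unclassified",
            call. = FALSE)
    r <- c(NA_real_, NA_real_, NA_real_)
    grp <- "unclassified"
  } else {
    r <- as.vector(stats::cor(prof, cen, method = config$correlation))
    mx <- max(r)
    grp <- if (sum(r == mx) > 1) "unclassified" else
      model$group_names[which.max(r)]
  }
  data.frame(sample_id = sample_id, r1 = r[1], r2 = r[2], r3 = r[3],
             group = grp, r_index = r[3], n_shared_genes = length(prof),
             stringsAsFactors = FALSE)
}

#' Classify a cohort
#'
#' Aligns the target matrix with the model's gene space, optionally gene-wise
#' median-centers the target cohort (per-platform harmonization), classifies
#' every sample by correlation to the three centroids, and summarizes group
#' counts. Per-sample failures become `"unclassified"` rows; the cohort run
#' never aborts on one sample.
#'
#' @param model a `cmtc_model`.
#' @param target gene-level log2-ratio [expr_matrix()].
#' @param config a [classifier_config()].
#' @param clinical optional clinical table; when given, the summary includes
#'   group-by-covariate contingency tables for its categorical columns.
#' @return an object of class `cmtc_classification`: `results` (per-sample
#'   data frame), `summary` (group counts and fractions), `shared_frac`, and
#'   `crosstabs` when `clinical` is supplied.
#' @export
classify_cohort <- function(model, target, config = classifier_config(),
                            clinical = NULL) {
  mf <- map_features(model, target, config)
  v <- mf$target
  if (config$recenter_target && ncol(v) > 1)
    v <- v - apply(v, 1, stats::median)
  res <- do.call(rbind, lapply(seq_len(ncol(v)), function(j) {
    tryCatch(
      classify_sample_aligned(model, v[, j], mf$centroids, config,
                              colnames(v)[j], length(mf$shared_genes)),
      error = function(e)
        data.frame(sample_id = colnames(v)[j], r1 = NA_real_, r2 = NA_real_,
                   r3 = NA_real_, group = "unclassified", r_index = NA_real_,
                   n_shared_genes = length(mf$shared_genes),
                   stringsAsFactors = FALSE))
  }))
  counts <- table(factor(res$group,
                         levels = c(model$group_names, "unclassified")))
  summary <- data.frame(group = names(counts),
                        n = as.vector(counts),
                        frac = as.vector(counts) / nrow(res),
                        stringsAsFactors = FALSE)
  out <- list(results = res, summary = summary, shared_frac = mf$shared_frac)
  if (!is.null(clinical)) {
    idx <- match(res$sample_id, clinical$sample_id)
    cat_cols <- setdiff(names(clinical)[vapply(clinical, function(col)
      is.logical(col) || is.factor(col) || is.character(col) ||
        (is.numeric(col) && length(unique(col)) <= 4), logical(1))],
      c("sample_id"))
    out$crosstabs <- lapply(stats::setNames(cat_cols, cat_cols), function(cc)
      table(clinical[[cc]][idx], res$group))
  }
  structure(out, class = "cmtc_classification")
}

# internal: classify an already-aligned, already-recentered profile
classify_sample_aligned <- function(model, prof, centroids, config,
                                    sample_id, n_shared) {
  if (stats::sd(prof) == 0) {
    return(data.frame(sample_id = sample_id, r1 = NA_real_, r2 = NA_real_,
                      r3 = NA_real_, group = "unclassified",
                      r_index = NA_real_, n_shared_genes = n_shared,
                      stringsAsFactors = FALSE))
  }
  r <- as.vector(stats::cor(prof, centroids, method = config$correlation))
  mx <- max(r)
  grp <- if (sum(r == mx) > 1) "unclassified" else
    model$group_names[which.max(r)]
  data.frame(sample_id = sample_id, r1 = r[1], r2 = r[2], r3 = r[3],
             group = grp, r_index = r[3], n_shared_genes = n_shared,
             stringsAsFactors = FALSE)
}

#' @export
print.cmtc_classification <- function(x, ...) {
  cat(sprintf("cmtc_classification: %d samples (%.0f%% of model genes shared)\n",
              nrow(x$results), 100 * x$shared_frac))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write per-sample classification results as CSV
#'
#' Columns: sample_id, r1, r2, r3, group, r_index, n_shared_genes.
#'
#' @param x a `cmtc_classification`.
#' @param path file path.
#' @export
write_classification <- function(x, path) {
  stopifnot(inherits(x, "cmtc_classification"))
  utils::write.csv(x$results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
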