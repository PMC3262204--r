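#' Association test for an r x c contingency table
#'
#' Pearson chi-square test of independence without continuity correction (so
#' the statistic equals the textbook sum of (O-E)^2/E); for 2x2 tables with
#' any expected cell below 5 the Fisher exact test is used instead.
#'
#' @param tab matrix of non-negative integer counts, at least 2x2.
#' @return list with `statistic`, `dof`, `p` and `method`.
#' @export
contingency_association <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has an all-zero margin", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == 2) && any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, dof = NA_integer_, p = ft$p.value,
                method = "fisher"))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), dof = unname(ct$parameter),
       p = ct$p.value, method = "chisq")
}

#' Per-group counts and percentages for a categorical variable
#'
#' Cross-tabulates a categorical variable against the group labels and renders
#' percentages within group to one decimal with half-up rounding (the usual
#' clinical-table convention).
#'
#' @param clinical clinical table.
#' @param groups vector of group labels aligned with `clinical` rows (or the
#'   name of a column of `clinical`).
#' @param variable name of a categorical column of `clinical`.
#' @return data frame in long form: group, level, n, pct (numeric, 1 decimal),
#'   rendering (e.g. `"5 (12.8)"`).
#' @export
group_rate_table <- function(clinical, groups, variable) {
  if (is.character(groups) && length(groups) == 1)
    groups <- clinical[[groups]]
  v <- clinical[[variable]]
  if (is.null(v)) stop("no column '", variable, "'", call. = FALSE)
  tab <- table(group = groups, level = v)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  gtot <- rowSums(tab)
  out$pct <- pct_half_up(100 * out$n / gtot[out$group])
  out$rendering <- sprintf("%d (%.1f)", out$n, out$pct)
  out
}

# half-up rounding to one decimal (round() is round-half-even)
pct_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group with the log-rank test across
#' groups, via the survival package.
#'
#' @param records data frame with `time` and `event` columns.
#' @param grouping vector of group labels aligned with `records` rows (or a
#'   column name).
#' @return list with `fit` (a `survfit`), `logrank_chisq`, `df`, `p` and
#'   `n_events`.
#' @export
kaplan_meier <- function(records, grouping) {
  if (is.character(grouping) && length(grouping) == 1)
    grouping <- records[[grouping]]
  grouping <- factor(grouping)
  if (any(table(grouping) == 0))
    stop("a group has zero subjects", call. = FALSE)
  if (sum(records$event) < 1)
    stop("no events; log-rank test undefined", call. = FALSE)
  df <- data.frame(time = records$time, event = as.integer(records$event),
                   g = grouping)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  if (nlevels(grouping) > 1) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
    k <- length(sd$n) - 1
    p <- stats::pchisq(sd$chisq, k, lower.tail = FALSE)
    list(fit = fit, logrank_chisq = unname(sd$chisq), df = k, p = p,
         n_events = sum(df$event))
  } else {
    list(fit = fit, logrank_chisq = NA_real_, df = NA_integer_, p = NA_real_,
         n_events = sum(df$event))
  }
}

#' Cox proportional-hazards model
#'
#' Partial-likelihood fit with the Efron tie approximation; reports the hazard
#' ratio, Wald 95% CI and p-value per term.
#'
#' @param records data frame with `time`, `event` and the term columns.
#' @param terms character vector of covariate column names.
#' @param type `"univariate"` (each term fit alone is NOT implied -- the terms
#'   given are fit jointly; pass one term for a univariate fit) or
#'   `"multivariate"`; recorded in the result.
#' @param ties tie-handling method passed to the partial likelihood, default
#'   `"efron"`.
#' @return an object of class `cox_result`: data frame with `term`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, plus attributes `type` and `n_events`.
#' @export
cox_model <- function(records, terms, type = c("univariate", "multivariate"),
                      ties = c("efron", "breslow", "exact")) {
  type <- match.arg(type)
  ties <- match.arg(ties)
  for (tm in terms) {
    v <- records[[tm]]
    if (is.null(v)) stop("no column '", tm, "'", call. = FALSE)
    if (length(unique(v)) < 2)
      stop("term '", tm, "' is constant across samples", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w)))
        stop("Cox fit failed to converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  res <- data.frame(term = rownames(s$coefficients),
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, type = type, n_events = s$nevent, class = c("cox_result",
                                                             "data.frame"))
}

#' Endocrine-therapy benefit stratified by group
#'
#' Restricted to ER+ records: compares ET-treated vs untreated relapse-free
#' survival overall and within each group. Strata with an empty arm are
#' flagged rather than failing.
#'
#' @param records clinical table with `er`, `et_treated`, `time`, `event` and
#'   a group column.
#' @param group_col name of the group column, default `"group"`.
#' @return list with `overall` (log-rank result) and `by_group` (per-group
#'   list of log-rank results or `"empty arm"` flags), plus `n_treated` /
#'   `n_untreated` per stratum.
#' @export
et_benefit_analysis <- function(records, group_col = "group") {
  erp <- records[records$er %in% TRUE, ]
  if (nrow(erp) == 0) stop("no ER+ records", call. = FALSE)
  arm <- factor(ifelse(erp$et_treated, "ET", "none"), levels = c("none", "ET"))
  if (any(table(arm) == 0))
    stop("an ET arm is empty overall", call. = FALSE)
  overall <- kaplan_meier(erp, arm)
  groups <- sort(unique(as.character(erp[[group_col]])))
  by_group <- lapply(stats::setNames(groups, groups), function(g) {
    sub <- erp[erp[[group_col]] == g, ]
    a <- factor(ifelse(sub$et_treated, "ET", "none"),
                levels = c("none", "ET"))
    n <- table(a)
    if (any(n == 0) || sum(sub$event) == 0)
      return(list(flag = "empty arm or no events",
                  n_untreated = unname(n["none"]), n_treated = unname(n["ET"])))
    km <- kaplan_meier(sub, a)
    list(p = km$p, logrank_chisq = km$logrank_chisq,
         n_untreated = unname(n["none"]), n_treated = unname(n["ET"]),
         flag = NA_character_)
  })
  list(overall = overall, by_group = by_group,
       n_treated = sum(arm == "ET"), n_untreated = sum(arm == "none"))
}

#' ROC AUC by the Mann-Whitney rank statistic
#'
#' The area under the ROC curve computed exactly as the normalized
#' Mann-Whitney U statistic with midranks for ties: the probability that a
#' random positive scores above a random negative (ties count one half).
#'
#' @param labels binary outcome (logical or 0/1).
#' @param scores numeric predictor (binary predictors are handled as two-value
#'   scores, for which AUC = (sensitivity + specificity) / 2).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("labels are all-positive or all-negative; AUC undefined",
         call. = FALSE)
  r <- rank(scores)  # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sensitivity/specificity pairs at every distinct score threshold
#' (predicting positive when score >= threshold), plus the degenerate ends.
#'
#' @inheritParams roc_auc
#' @return data frame: `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.logical(labels)
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  th <- c(sort(unique(scores)), Inf)
  data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(scores[labels] >= t), 0),
    specificity = vapply(th, function(t) mean(scores[!labels] < t), 0))
}

#' Bootstrap confidence interval for an AUC
#'
#' Stratified bootstrap (resampling positives and negatives separately) of the
#' Mann-Whitney AUC; percentile interval.
#'
#' @inheritParams roc_auc
#' @param n_boot number of bootstrap replicates, default 2000.
#' @param seed integer seed.
#' @param level confidence level, default 0.95.
#' @return list with `auc`, `ci` (length-2), `n_boot`.
#' @export
auc_ci_boot <- function(labels, scores, n_boot = 2000, seed = 1,
                        level = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  pos <- which(labels); neg <- which(!labels)
  withr::with_seed(as.integer(seed), {
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      roc_auc(labels[idx], scores[idx])
    }, 0)
  })
  a <- (1 - level) / 2
  list(auc = roc_auc(labels, scores),
       ci = unname(stats::quantile(reps, c(a, 1 - a))),
       n_boot = n_boot)
}

#' Confusion metrics for a binary predictor
#'
#' @param predicted logical predictions.
#' @param labels logical outcomes.
#' @return list with the 2x2 `counts` (tp, fp, fn, tn) and `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
confusion_report <- function(predicted, labels) {
  predicted <- as.logical(predicted); labels <- as.logical(labels)
  keep <- !is.na(predicted) & !is.na(labels)
  predicted <- predicted[keep]; labels <- labels[keep]
  tp <- sum(predicted & labels);  fp <- sum(predicted & !labels)
  fn <- sum(!predicted & labels); tn <- sum(!predicted & !labels)
  list(counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = tp / (tp + fp),
       npv = tn / (tn + fn),
       accuracy = (tp + tn) / (tp + fp + fn + tn))
}

#' Pathological-complete-response analysis
#'
#' For neoadjuvant-treated samples with a binary pCR outcome: per-group pCR
#' rates; ROC/AUC (with stratified-bootstrap CI) for the group-3 indicator,
#' the Her2+/TN indicator, Her2+ alone, TN alone and the continuous r-index;
#' confusion metrics for each binary predictor.
#'
#' @param pcr logical pCR outcome.
#' @param groups CMTC group labels.
#' @param r_index continuous correlation index to the CMTC-3 centroid
#'   (optional, `NULL` to skip).
#' @param her2 logical Her2+ flags (optional).
#' @param tn logical triple-negative flags (optional).
#' @param n_boot bootstrap replicates for the AUC CIs.
#' @param seed seed for the bootstrap.
#' @return list with `rates` (per-group data frame), `roc` (named list of
#'   [auc_ci_boot()] results) and `confusion` (named list of
#'   [confusion_report()]s for the binary predictors).
#' @export
pcr_analysis <- function(pcr, groups, r_index = NULL, her2 = NULL, tn = NULL,
                         n_boot = 2000, seed = 1) {
  keep <- !is.na(pcr)
  pcr <- as.logical(pcr[keep])
  groups <- as.character(groups[keep])
  if (all(pcr) || !any(pcr))
    stop("pCR labels are all-positive or all-negative", call. = FALSE)
  rates <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    n <- sum(groups == g); k <- sum(pcr[groups == g])
    data.frame(group = g, n = n, n_pcr = k,
               pct = pct_half_up(100 * k / n), stringsAsFactors = FALSE)
  }))
  is_g3 <- groups == "CMTC-3"
  predictors <- list(group3 = as.numeric(is_g3))
  if (!is.null(her2) && !is.null(tn)) {
    her2 <- as.logical(her2[keep]); tn <- as.logical(tn[keep])
    predictors$her2tn <- as.numeric(her2 | tn)
    predictors$her2 <- as.numeric(her2)
    predictors$tn <- as.numeric(tn)
  }
  if (!is.null(r_index)) predictors$r_index <- as.numeric(r_index[keep])
  roc <- lapply(seq_along(predictors), function(i)
    auc_ci_boot(pcr, predictors[[i]], n_boot = n_boot, seed = seed + i))
  names(roc) <- names(predictors)
  binary <- names(predictors)[vapply(predictors, function(s)
    all(s %in% c(0, 1)), logical(1))]
  confusion <- lapply(stats::setNames(binary, binary), function(nm)
    confusion_report(predictors[[nm]] == 1, pcr))
  list(rates = rates, roc = roc, confusion = confusion)
}
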