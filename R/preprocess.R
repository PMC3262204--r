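#' Preprocessing configuration
#'
#' @param floor_value positive intensity floor; values below it are raised to
#'   it. Defaults to 16, the MAQC-style floor for bead-array intensities.
#' @param collapse_rule how to reduce multiple probes per gene: `"max_mean"`
#'   keeps the probe with the highest mean intensity, `"median"` takes the
#'   per-sample median across the gene's probes.
#' @param quantile_reference reference distribution for quantile
#'   normalization: mean or median of the column-sorted values.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(floor_value = 16,
                              collapse_rule = c("max_mean", "median"),
                              quantile_reference = c("mean_of_sorted",
                                                     "median_of_sorted")) {
  if (!is.numeric(floor_value) || length(floor_value) != 1 || floor_value <= 0)
    stop("floor_value must be a single positive number", call. = FALSE)
  structure(list(floor_value = floor_value,
                 collapse_rule = match.arg(collapse_rule),
                 quantile_reference = match.arg(quantile_reference)),
            class = "preprocess_config")
}

#' Quantile-normalize sample columns
#'
#' Forces every sample column onto a common reference distribution: each
#' column is replaced, rank for rank, by the reference values (the mean -- or
#' median -- across samples of the column-sorted data). Tied values within a
#' column receive the mean of the reference values their ranks span, so the
#' transform is deterministic and order-independent.
#'
#' @param x an [expr_matrix()] in raw intensity space.
#' @param reference `"mean_of_sorted"` (default) or `"median_of_sorted"`.
#' @return an `expr_matrix` in normalized space; every column has the same
#'   sorted value multiset.
#' @export
quantile_normalize <- function(x, reference = c("mean_of_sorted",
                                                "median_of_sorted")) {
  stopifnot(inherits(x, "expr_matrix"))
  reference <- match.arg(reference)
  if (value_space(x) != "raw")
    stop("quantile_normalize expects a raw-intensity matrix, got ",
         value_space(x), call. = FALSE)
  v <- x$values
  sorted <- apply(v, 2, sort)
  ref <- if (reference == "mean_of_sorted") rowMeans(sorted)
         else apply(sorted, 1, stats::median)
  out <- apply(v, 2, function(col) {
    o <- order(col)
    # tie groups along the sorted column share the mean of the reference
    # values they span
    grp <- cumsum(!duplicated(col[o]))
    res <- numeric(length(col))
    res[o] <- stats::ave(ref, grp)
    res
  })
  dimnames(out) <- dimnames(v)
  expr_matrix(out, "normalized")
}

#' Floor low intensities at a constant
#'
#' Replaces every intensity below `floor_value` by `floor_value` (the
#' floor-16 rule for normalized bead intensities). Idempotent.
#'
#' @param x an [expr_matrix()] in raw or normalized space.
#' @param floor_value positive floor, default 16.
#' @return an `expr_matrix` in the same value space with `values >= floor_value`.
#' @export
floor_intensities <- function(x, floor_value = 16) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!value_space(x) %in% c("raw", "normalized"))
    stop("flooring applies to intensity spaces only, got ", value_space(x),
         call. = FALSE)
  if (!is.numeric(floor_value) || floor_value <= 0)
    stop("floor_value must be positive", call. = FALSE)
  out <- pmax(x$values, floor_value)
  expr_matrix(out, value_space(x))
}

#' Log2 ratio to the per-probe mean
#'
#' Converts intensities to `log2(value / mean(values of that probe across all
#' samples))`, i.e. each probe is expressed relative to its own average signal
#' on the platform. The arithmetic mean is used, so a doubled intensity in one
#' sample raises that sample's ratio and lowers everyone else's.
#'
#' @param x an [expr_matrix()] in normalized space with strictly positive
#'   values.
#' @return an `expr_matrix` in log2-ratio space.
#' @export
log2_ratio_to_mean <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (value_space(x) != "normalized")
    stop("log2_ratio_to_mean expects a normalized matrix, got ",
         value_space(x), call. = FALSE)
  m <- rowMeans(x$values)
  if (any(m <= 0))
    stop("probe(s) with non-positive mean intensity: ",
         paste(utils::head(rownames(x$values)[m <= 0], 5), collapse = ", "),
         call. = FALSE)
  out <- log2(x$values / m)
  expr_matrix(out, "log2ratio")
}

#' Collapse probes to genes
#'
#' Reduces a probe-level matrix to one row per gene symbol. Under
#' `"max_mean"` the probe with the highest mean intensity represents the gene
#' (the usual array convention), so the rule is defined for intensity-space
#' matrices; under `"median"` each sample gets the median across the gene's
#' probes. Row names of the result are gene symbols.
#'
#' @param x an [expr_matrix()].
#' @param annotation a [probe_annotation()] covering every probe in `x`.
#' @param rule `"max_mean"` or `"median"`.
#' @return an `expr_matrix` with one row per gene, same value space.
#' @export
collapse_probes_to_genes <- function(x, annotation,
                                     rule = c("max_mean", "median")) {
  stopifnot(inherits(x, "expr_matrix"))
  rule <- match.arg(rule)
  pid <- probe_ids(x)
  miss <- setdiff(pid, annotation$probe_id)
  if (length(miss) > 0)
    stop("probes without annotation: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10),
         call. = FALSE)
  if (rule == "max_mean" && value_space(x) == "log2ratio")
    stop("max_mean collapsing needs an intensity-space matrix; ",
         "collapse before the log2-ratio step or use rule = 'median'",
         call. = FALSE)
  gene <- annotation$gene_symbol[match(pid, annotation$probe_id)]
  v <- x$values
  if (rule == "max_mean") {
    rm <- rowMeans(v)
    keep <- vapply(split(seq_along(pid), gene),
                   function(idx) idx[which.max(rm[idx])], integer(1))
    out <- v[keep, , drop = FALSE]
    rownames(out) <- names(keep)
  } else {
    parts <- split(seq_along(pid), gene)
    out <- t(vapply(parts, function(idx) {
      if (length(idx) == 1) v[idx, ] else apply(v[idx, , drop = FALSE], 2, stats::median)
    }, numeric(ncol(v))))
    colnames(out) <- colnames(v)
  }
  # deterministic gene order: keep first-appearance order of symbols
  out <- out[unique(gene)[unique(gene) %in% rownames(out)], , drop = FALSE]
  expr_matrix(out, value_space(x))
}

#' Full intensity-to-gene-level preprocessing pipeline
#'
#' Runs quantile normalization, intensity flooring, probe-to-gene collapsing
#' and the log2-ratio transform, in that order. Collapsing happens before the
#' ratio step so the `max_mean` rule sees intensities.
#'
#' @param x raw-intensity [expr_matrix()].
#' @param annotation [probe_annotation()]; if `NULL`, collapsing is skipped
#'   and probe IDs are kept.
#' @param config a [preprocess_config()].
#' @return a gene-level (or probe-level if `annotation` is `NULL`)
#'   `expr_matrix` in log2-ratio space.
#' @export
preprocess_pipeline <- function(x, annotation = NULL,
                                config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  x <- quantile_normalize(x, config$quantile_reference)
  x <- floor_intensities(x, config$floor_value)
  if (!is.null(annotation))
    x <- collapse_probes_to_genes(x, annotation, config$collapse_rule)
  log2_ratio_to_mean(x)
}
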