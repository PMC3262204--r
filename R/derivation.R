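#' Derivation configuration
#'
#' Parameters of the two-screen signature derivation: a Her2+/TN-anchored
#' differential t-test screen controlled at a Bonferroni-corrected level
#' (default 0.01), three-way hierarchical clustering of samples, and a one-way
#' ANOVA screen across the three clusters at an uncorrected level (default
#' 0.001).
#'
#' @param screen1_alpha Bonferroni-corrected level for the phenotype screen.
#' @param screen2_alpha uncorrected level for the three-group ANOVA screen.
#' @param n_clusters fixed at 3; the classification is a triad by definition.
#' @param distance sample-to-sample distance: `"one_minus_pearson"` (the
#'   standard choice for expression heat maps) or `"euclidean"`.
#' @param linkage agglomeration method: `"average"`, `"complete"` or `"ward"`.
#' @param ttest_variant `"welch"` (default) or `"pooled"` two-sample t. The
#'   phenotype contrast compares a small Her2+/TN class against a larger,
#'   heterogeneous remainder whose variance is inflated by the group-2
#'   mixture, so the unequal-variance (Welch) statistic is the calibrated
#'   choice; pooled variance is available for comparison.
#' @return a `derivation_config` list.
#' @export
derivation_config <- function(screen1_alpha = 0.01, screen2_alpha = 0.001,
                              n_clusters = 3,
                              distance = c("one_minus_pearson", "euclidean"),
                              linkage = c("average", "complete", "ward"),
                              ttest_variant = c("welch", "pooled")) {
  if (screen1_alpha <= 0 || screen1_alpha >= 1 ||
      screen2_alpha <= 0 || screen2_alpha >= 1)
    stop("screen alphas must be in (0,1)", call. = FALSE)
  if (n_clusters != 3)
    stop("the triad classification uses exactly 3 clusters", call. = FALSE)
  structure(list(screen1_alpha = screen1_alpha,
                 screen2_alpha = screen2_alpha,
                 n_clusters = 3L,
                 distance = match.arg(distance),
                 linkage = match.arg(linkage),
                 ttest_variant = match.arg(ttest_variant)),
            class = "derivation_config")
}

# Vectorized per-row two-sample t-test. Returns t, df and two-sided p for
# every row at once; pooled variance by default with a per-row Welch fallback
# when the pooled variance is zero.
row_t_test <- function(v, in_a, variant = "pooled") {
  a <- v[, in_a, drop = FALSE]
  b <- v[, !in_a, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  t <- (ma - mb) / se
  # degenerate variance: identical constant rows get t = 0 (never selected);
  # zero variance with a mean difference gets p = 0
  zero <- !is.finite(t)
  t[zero & abs(ma - mb) < .Machine$double.eps^0.5] <- 0
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[zero & abs(ma - mb) >= .Machine$double.eps^0.5] <- 0
  t[!is.finite(t)] <- Inf
  data.frame(t = t, df = df, p = p, row.names = rownames(v))
}

# Vectorized per-row one-way fixed-effects ANOVA across k groups.
row_anova <- function(v, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(v)
  grand <- rowMeans(v)
  ss_between <- 0
  ss_within <- 0
  for (lev in levels(groups)) {
    idx <- groups == lev
    ng <- sum(idx)
    mg <- rowMeans(v[, idx, drop = FALSE])
    ss_between <- ss_between + ng * (mg - grand)^2
    ss_within <- ss_within + rowSums((v[, idx, drop = FALSE] - mg)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # all-constant rows: F is 0/0; no group effect by definition
  p[!is.finite(f)] <- 1
  f[!is.finite(f)] <- 0
  data.frame(f = f, df1 = df1, df2 = df2, p = p, row.names = rownames(v))
}

#' Screen 1: phenotype-anchored differential probes
#'
#' Two-sample t-test of every probe between Her2+/TN samples and the rest;
#' probes with Bonferroni-corrected p below `screen1_alpha` are kept, ordered
#' by ascending corrected p. The Bonferroni factor is the number of probes
#' entering the screen.
#'
#' @param x log2-ratio [expr_matrix()].
#' @param phenotype logical vector (TRUE = Her2+/TN), aligned with samples.
#' @param config a [derivation_config()].
#' @return character vector of selected probe IDs.
#' @export
screen_differential_probes <- function(x, phenotype,
                                       config = derivation_config()) {
  stopifnot(inherits(x, "expr_matrix"))
  if (value_space(x) != "log2ratio")
    stop("screening expects a log2-ratio matrix", call. = FALSE)
  phenotype <- as.logical(phenotype)
  if (length(phenotype) != ncol(x$values))
    stop("phenotype length does not match sample count", call. = FALSE)
  if (sum(phenotype) < 2 || sum(!phenotype) < 2)
    stop("both phenotype classes need at least 2 samples", call. = FALSE)
  tt <- row_t_test(x$values, phenotype, config$ttest_variant)
  p_adj <- pmin(tt$p * nrow(x$values), 1)
  keep <- which(p_adj < config$screen1_alpha)
  rownames(tt)[keep][order(p_adj[keep])]
}

#' Three-way hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on the given probe set (default
#' distance 1 - Pearson correlation, average linkage), cut to the three MAIN
#' clusters: when the plain k = 3 cut isolates clusters below
#' `min_cluster_size` (lone outliers are common under average linkage), the
#' tree is cut progressively deeper until three clusters reach that size, and
#' every sample outside them is assigned to the main cluster at the smallest
#' average distance. Deterministic given input order and config.
#'
#' @param x log2-ratio [expr_matrix()].
#' @param probes probe IDs to cluster on (non-empty subset of `x`'s probes).
#' @param config a [derivation_config()].
#' @param min_cluster_size smallest acceptable main-cluster size, default 2
#'   (the downstream ANOVA screen needs two samples per group).
#' @return named integer vector of cluster labels in 1..3, numbered by first
#'   appearance in sample order.
#' @export
hierarchical_three_cluster <- function(x, probes,
                                       config = derivation_config(),
                                       min_cluster_size = 2) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(probes) == 0) stop("empty probe set", call. = FALSE)
  n <- ncol(x$values)
  if (n < 3) stop("need at least 3 samples to cut 3 clusters", call. = FALSE)
  v <- x$values[probes, , drop = FALSE]
  d <- if (config$distance == "one_minus_pearson") {
    stats::as.dist(1 - stats::cor(v))
  } else {
    stats::dist(t(v))
  }
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[config$linkage]]
  hc <- stats::hclust(d, method = method)
  cl <- stats::cutree(hc, k = 3)
  for (k in 3:n) {
    ck <- if (k == 3) cl else stats::cutree(hc, k = k)
    sizes <- sort(table(ck), decreasing = TRUE)
    if (length(sizes) >= 3 && sizes[3] >= min_cluster_size) {
      main <- as.integer(names(sizes)[1:3])
      if (k > 3 || !all(ck %in% main)) {
        dm <- as.matrix(d)
        minor <- which(!ck %in% main)
        for (i in minor) {
          avg <- vapply(main, function(m)
            mean(dm[i, ck == m & seq_len(n) != i]), 0)
          ck[i] <- main[which.min(avg)]
        }
      }
      cl <- ck
      break
    }
  }
  # renumber 1..3 by first appearance in sample order
  out <- match(cl, unique(cl))
  names(out) <- colnames(v)
  out
}

#' Screen 2: three-group ANOVA probes
#'
#' One-way fixed-effects ANOVA of every probe across the three sample groups;
#' probes with uncorrected p below `screen2_alpha` are kept, ordered by
#' ascending p.
#'
#' @param x log2-ratio [expr_matrix()] (typically restricted to screen-1
#'   probes).
#' @param groups 3-way sample labels.
#' @param config a [derivation_config()].
#' @return character vector of selected probe IDs.
#' @export
screen_anova_probes <- function(x, groups, config = derivation_config()) {
  stopifnot(inherits(x, "expr_matrix"))
  groups <- as.factor(groups)
  if (any(table(groups) < 2))
    stop("every group needs at least 2 samples", call. = FALSE)
  if (length(groups) != ncol(x$values))
    stop("group labels do not match sample count", call. = FALSE)
  an <- row_anova(x$values, groups)
  keep <- which(an$p < config$screen2_alpha)
  rownames(an)[keep][order(an$p[keep])]
}

#' Exclude genes overlapping published prognostic signatures
#'
#' A probe is excluded iff its gene symbol appears in the union of the catalog
#' signatures' gene sets; probes and genes are counted separately because
#' several probes can map to one gene.
#'
#' @param probes probe IDs under consideration.
#' @param annotation [probe_annotation()] covering all `probes`.
#' @param catalog list of [gene_signature()] objects.
#' @return list with `kept_probes`, `excluded_probes`, `kept_genes`,
#'   `excluded_genes` and a `counts` summary.
#' @export
exclude_overlapping_genes <- function(probes, annotation, catalog) {
  miss <- setdiff(probes, annotation$probe_id)
  if (length(miss) > 0)
    stop("probes without annotation: ", paste(utils::head(miss, 10),
                                              collapse = ", "), call. = FALSE)
  gene <- annotation$gene_symbol[match(probes, annotation$probe_id)]
  union_genes <- unique(toupper(unlist(lapply(catalog, `[[`, "genes"))))
  drop <- gene %in% union_genes
  list(kept_probes = probes[!drop],
       excluded_probes = probes[drop],
       kept_genes = unique(gene[!drop]),
       excluded_genes = unique(gene[drop]),
       counts = c(input_probes = length(probes),
                  input_genes = length(unique(gene)),
                  kept_probes = sum(!drop),
                  kept_genes = length(unique(gene[!drop])),
                  excluded_genes = length(unique(gene[drop]))))
}

#' Assign clinical identities to the three clusters
#'
#' CMTC-3 is the cluster with the highest Her2+/TN fraction; of the remaining
#' two, CMTC-1 is the cluster with the lower mean grade (tie-break: higher ER+
#' fraction). Returns a bijective mapping from cluster label to group name.
#'
#' @param groups named integer cluster labels (1..3) for every sample.
#' @param clinical clinical table with `sample_id`, `her2tn`, `grade`, `er`.
#' @return named character vector mapping cluster label -> CMTC name, with an
#'   `evidence` attribute (per-cluster Her2+/TN fraction, mean grade, ER+
#'   fraction).
#' @export
assign_group_identities <- function(groups, clinical) {
  idx <- match(names(groups), clinical$sample_id)
  if (anyNA(idx))
    stop("clinical table does not cover all samples", call. = FALSE)
  cl <- clinical[idx, ]
  labs <- sort(unique(groups))
  if (length(labs) != 3) stop("expected exactly 3 clusters", call. = FALSE)
  ev <- data.frame(
    cluster = labs,
    her2tn_frac = vapply(labs, function(k) mean(cl$her2tn[groups == k]), 0),
    mean_grade = vapply(labs, function(k) mean(cl$grade[groups == k]), 0),
    er_pos_frac = vapply(labs, function(k) mean(cl$er[groups == k]), 0))
  c3 <- labs[which.max(ev$her2tn_frac)]
  if (sum(ev$her2tn_frac == max(ev$her2tn_frac)) > 1)
    stop("clusters tie on Her2+/TN fraction; manual assignment required",
         call. = FALSE)
  rest <- setdiff(labs, c3)
  g <- ev$mean_grade[match(rest, ev$cluster)]
  if (g[1] == g[2]) {
    e <- ev$er_pos_frac[match(rest, ev$cluster)]
    if (e[1] == e[2])
      stop("remaining clusters tie on grade and ER fraction; ",
           "manual assignment required", call. = FALSE)
    c1 <- rest[which.max(e)]
  } else {
    c1 <- rest[which.min(g)]
  }
  c2 <- setdiff(rest, c1)
  map <- character(3)
  names(map) <- as.character(labs)
  map[as.character(c(c1, c2, c3))] <- c("CMTC-1", "CMTC-2", "CMTC-3")
  attr(map, "evidence") <- ev
  map
}

#' Verify separation of the three groups on a probe set
#'
#' Reports the per-probe ANOVA p distribution across the three groups and the
#' three pairwise Bonferroni-corrected t-test summaries, and flags pass/fail.
#' The verdict requires (a) at least `anova_frac_required` of the probes to
#' reject the three-group ANOVA at `anova_alpha`, and (b) every pair of
#' groups to be separated by at least `pairwise_frac_required` of the probes
#' at the corrected level `pairwise_alpha` -- a signature anchored on one
#' phenotype is not expected to separate every pair on every probe, only to
#' contain clear separating probes for every pair. The Bonferroni factor for
#' the pairwise tests is the probe-set size.
#'
#' @param x log2-ratio [expr_matrix()].
#' @param probe_set probe IDs to verify on.
#' @param groups 3-way sample labels.
#' @param anova_alpha ANOVA threshold, default 1e-5.
#' @param pairwise_alpha corrected pairwise t threshold, default 0.01.
#' @param anova_frac_required fraction of probes required to pass the ANOVA,
#'   default 0.9.
#' @param pairwise_frac_required fraction of probes required to separate each
#'   pair, default 0.05.
#' @return list with per-test pass fractions, overall `pass` flag, and the raw
#'   p-value vectors.
#' @export
verify_group_separation <- function(x, probe_set, groups,
                                    anova_alpha = 1e-5,
                                    pairwise_alpha = 0.01,
                                    anova_frac_required = 0.9,
                                    pairwise_frac_required = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  groups <- as.factor(groups)
  v <- x$values[probe_set, , drop = FALSE]
  m <- length(probe_set)
  an <- row_anova(v, groups)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    sel <- groups %in% pr
    tt <- row_t_test(v[, sel, drop = FALSE], (groups == pr[1])[sel])
    pmin(tt$p * m, 1)
  })
  names(pw) <- vapply(pairs, paste, "", collapse = "_vs_")
  anova_frac <- mean(an$p < anova_alpha)
  pw_frac <- vapply(pw, function(p) mean(p < pairwise_alpha), 0)
  list(anova_pass_frac = anova_frac,
       pairwise_pass_frac = pw_frac,
       pass = anova_frac >= anova_frac_required &&
         all(pw_frac >= pairwise_frac_required),
       anova_p = an$p, pairwise_p = pw)
}

#' Build the centroid classifier model
#'
#' Computes per-group mean log2-ratio centroids over the final probe set and
#' records the clinical identity evidence and a derivation log.
#'
#' @param x log2-ratio [expr_matrix()].
#' @param probe_set final probe/gene IDs.
#' @param groups named cluster labels for every sample.
#' @param identities mapping from [assign_group_identities()].
#' @param derivation_log optional list of screen sizes and parameters.
#' @return an object of class `cmtc_model`: `probe_set`, `centroids`
#'   (probe x 3 matrix with columns CMTC-1..3), `group_names`,
#'   `identity_evidence`, `derivation_log`.
#' @export
build_cmtc_model <- function(x, probe_set, groups, identities,
                             derivation_log = list()) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values[probe_set, names(groups), drop = FALSE]
  group_names <- c("CMTC-1", "CMTC-2", "CMTC-3")
  cmtc <- identities[as.character(groups)]
  if (any(table(cmtc) == 0) || length(unique(cmtc)) < 3)
    stop("empty group; cannot compute all three centroids", call. = FALSE)
  centroids <- vapply(group_names, function(g)
    rowMeans(v[, cmtc == g, drop = FALSE]), numeric(length(probe_set)))
  rownames(centroids) <- probe_set
  structure(list(probe_set = probe_set,
                 centroids = centroids,
                 group_names = group_names,
                 identity_evidence = attr(identities, "evidence"),
                 derivation_log = derivation_log),
            class = "cmtc_model")
}

#' @export
print.cmtc_model <- function(x, ...) {
  cat(sprintf("cmtc_model: %d features, groups %s\n",
              length(x$probe_set), paste(x$group_names, collapse = ", ")))
  invisible(x)
}

#' End-to-end signature derivation
#'
#' Runs the full derivation on a preprocessed (log2-ratio) matrix: screen 1
#' (Her2+/TN vs rest, Bonferroni-corrected t-test), hierarchical three-way
#' clustering on the screen-1 probes, screen 2 (three-group ANOVA restricted
#' to the screen-1 probes), optional exclusion of genes overlapping a
#' signature catalog, re-clustering on the final probe set, clinical identity
#' assignment and centroid-model construction.
#'
#' @param x log2-ratio [expr_matrix()].
#' @param clinical clinical table (`sample_id`, `her2tn`, `grade`, `er`).
#' @param config a [derivation_config()].
#' @param catalog optional list of [gene_signature()]s for overlap exclusion;
#'   requires `annotation`.
#' @param annotation [probe_annotation()] used by the exclusion step; defaults
#'   to the identity mapping (rows already in gene space).
#' @return list with `model` ([build_cmtc_model()] result), `labels` (named
#'   CMTC group per sample), `screen1`, `screen2`, `final_probes`,
#'   `exclusion`, `identities` and `separation`.
#' @export
derive_cmtc <- function(x, clinical, config = derivation_config(),
                        catalog = NULL, annotation = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  idx <- match(sample_ids(x), clinical$sample_id)
  if (anyNA(idx))
    stop("clinical table does not cover all samples", call. = FALSE)
  phenotype <- clinical$her2tn[idx]

  s1 <- screen_differential_probes(x, phenotype, config)
  if (length(s1) == 0) stop("screen 1 selected no probes", call. = FALSE)
  cl1 <- hierarchical_three_cluster(x, s1, config)

  x1 <- expr_matrix(x$values[s1, , drop = FALSE], "log2ratio")
  s2 <- screen_anova_probes(x1, cl1, config)
  if (length(s2) == 0) stop("screen 2 selected no probes", call. = FALSE)

  exclusion <- NULL
  final_probes <- s2
  if (!is.null(catalog)) {
    if (is.null(annotation))
      annotation <- probe_annotation(probe_ids(x), probe_ids(x))
    exclusion <- exclude_overlapping_genes(s2, annotation, catalog)
    final_probes <- exclusion$kept_probes
    if (length(final_probes) == 0)
      stop("overlap exclusion removed every probe", call. = FALSE)
  }

  cl_final <- hierarchical_three_cluster(x, final_probes, config)
  identities <- assign_group_identities(cl_final, clinical)
  labels <- identities[as.character(cl_final)]
  names(labels) <- names(cl_final)
  separation <- verify_group_separation(x, final_probes, labels)
  log <- list(n_probes_in = nrow(x$values),
              n_screen1 = length(s1), n_screen2 = length(s2),
              n_final = length(final_probes),
              screen1_alpha = config$screen1_alpha,
              screen2_alpha = config$screen2_alpha,
              distance = config$distance, linkage = config$linkage)
  model <- build_cmtc_model(x, final_probes, cl_final, identities, log)
  list(model = model, labels = labels, screen1 = s1, screen2 = s2,
       final_probes = final_probes, exclusion = exclusion,
       identities = identities, separation = separation)
}

#' Serialize / deserialize a centroid model as JSON
#'
#' The JSON carries the probe list, the three centroid vectors, the identity
#' evidence, the derivation log and an md5 content hash of the model payload.
#'
#' @param model a `cmtc_model`.
#' @param path file path.
#' @return `write_cmtc_model` returns `path` invisibly; `read_cmtc_model`
#'   returns the `cmtc_model`.
#' @export
write_cmtc_model <- function(model, path) {
  stopifnot(inherits(model, "cmtc_model"))
  payload <- list(probe_set = model$probe_set,
                  centroids = as.data.frame(model$centroids),
                  group_names = model$group_names,
                  identity_evidence = model$identity_evidence,
                  derivation_log = model$derivation_log)
  payload$content_hash <- md5_of_object(payload)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cmtc_model
#' @export
read_cmtc_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- as.matrix(p$centroids)
  rownames(centroids) <- p$probe_set
  stored <- p$content_hash
  p$content_hash <- NULL
  payload <- list(probe_set = p$probe_set,
                  centroids = as.data.frame(centroids),
                  group_names = p$group_names,
                  identity_evidence = p$identity_evidence,
                  derivation_log = p$derivation_log)
  if (!identical(md5_of_object(payload), stored))
    warning("model content hash mismatch in ", path, call. = FALSE)
  structure(list(probe_set = p$probe_set, centroids = centroids,
                 group_names = p$group_names,
                 identity_evidence = p$identity_evidence,
                 derivation_log = p$derivation_log),
            class = "cmtc_model")
}

# md5 of an R object via its canonical JSON rendering (tools::md5sum works on
# files, so serialize to a temp file first)
md5_of_object <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(f))
}
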