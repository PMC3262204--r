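#' Synthetic cohort configuration
#'
#' Parameterizes the synthetic breast-cancer cohort generator. The generator
#' plants three latent expression groups with opposed patterns: informative
#' probes are shifted by `-effect_size` in group 1 and `+effect_size` in group
#' 3 (times a random per-probe sign), while group 2 is intermediate but
#' distinct -- half of the informative probes follow the group-3 direction and
#' half the group-1 direction. Clinical covariates, relapse hazards,
#' endocrine-therapy effects and pathological-complete-response probabilities
#' are drawn per group. Defaults are calibrated once to the covariate margins,
#' treatment-arm imbalance and long-term recurrence proportions reported for
#' the cohorts on which the triad classification was characterized
#' (group sizes 45/65/39; Her2+/TN fractions ~7%/8%/92%; ~19%/40%/39% relapse
#' under exponential censoring; ET given to ~38% of ER+ group-1 vs ~64% of
#' group-2/3 patients; pCR probabilities 6%/8%/42%).
#'
#' @param n_samples_per_group integer vector of 3 group sizes.
#' @param n_probes total number of probes.
#' @param n_informative_probes number of probes carrying group structure.
#' @param effect_size mean log2 shift of informative probes (>= 0).
#' @param noise_sd per-sample log2 noise SD (> 0).
#' @param baseline_log2_mean,baseline_log2_sd log-normal base intensity model:
#'   per-probe baseline log2 levels are N(mean, sd); defaults 8 and 1.5 mimic
#'   bead-array intensity distributions and leave the floor-16 rule
#'   occasionally active.
#' @param frac_her2tn_by_group probability a sample is Her2+ or triple-negative,
#'   per group.
#' @param her2_pos_frac_within_her2tn among Her2+/TN samples, probability of
#'   being Her2+ (the rest are triple-negative).
#' @param er_pos_prob_by_group ER-positive probability per group (applied to
#'   non-TN samples).
#' @param grade_dist_by_group list of 3 probability vectors over grades 1..3.
#' @param age_lt50_prob_by_group,size_gt2_prob_by_group,node_pos_prob_by_group
#'   per-group probabilities for the age (<50), tumor size (>2 cm) and nodal
#'   (LN+) bands.
#' @param relapse_hazard_by_group exponential relapse hazards per group
#'   (events per month).
#' @param et_hazard_multiplier_by_group hazard multiplier applied only to
#'   ET-treated, ER+ samples, per group (0.5/1/1: benefit confined to group 1).
#' @param et_treated_prob_by_group probability an ER+ sample receives ET.
#' @param neoadjuvant_prob probability a sample is neoadjuvant-treated (pCR is
#'   observed only for those).
#' @param pcr_prob_by_group pCR probability per group among neoadjuvant-treated.
#' @param censoring_rate exponential censoring hazard (> 0).
#' @param admin_cutoff optional administrative censoring time (months);
#'   `Inf` disables it.
#' @param multi_probe_genes number of genes represented by two probes (0 keeps
#'   one probe per gene, isolating the collapsing rule's test surface).
#' @param seed integer seed; identical config + seed gives bit-identical output.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples_per_group = c(45, 65, 39),
                          n_probes = 2000,
                          n_informative_probes = 200,
                          effect_size = 1.5,
                          noise_sd = 0.5,
                          baseline_log2_mean = 8,
                          baseline_log2_sd = 1.5,
                          frac_her2tn_by_group = c(0.067, 0.077, 0.923),
                          her2_pos_frac_within_her2tn = 0.59,
                          er_pos_prob_by_group = c(1.0, 0.985, 0.103),
                          grade_dist_by_group = list(c(0.289, 0.600, 0.111),
                                                     c(0.015, 0.462, 0.523),
                                                     c(0.000, 0.154, 0.846)),
                          age_lt50_prob_by_group = c(0.391, 0.349, 0.436),
                          size_gt2_prob_by_group = c(0.453, 0.675, 0.676),
                          node_pos_prob_by_group = c(0.332, 0.408, 0.397),
                          relapse_hazard_by_group = c(0.010, 0.030, 0.028),
                          et_hazard_multiplier_by_group = c(0.5, 1, 1),
                          et_treated_prob_by_group = c(0.385, 0.635, 0.635),
                          neoadjuvant_prob = 0.10,
                          pcr_prob_by_group = c(0.06, 0.08, 0.42),
                          censoring_rate = 0.044,
                          admin_cutoff = Inf,
                          multi_probe_genes = 0,
                          seed = 1L) {
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              n_probes = as.integer(n_probes),
              n_informative_probes = as.integer(n_informative_probes),
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              frac_her2tn_by_group = frac_her2tn_by_group,
              her2_pos_frac_within_her2tn = her2_pos_frac_within_her2tn,
              er_pos_prob_by_group = er_pos_prob_by_group,
              grade_dist_by_group = grade_dist_by_group,
              age_lt50_prob_by_group = age_lt50_prob_by_group,
              size_gt2_prob_by_group = size_gt2_prob_by_group,
              node_pos_prob_by_group = node_pos_prob_by_group,
              relapse_hazard_by_group = relapse_hazard_by_group,
              et_hazard_multiplier_by_group = et_hazard_multiplier_by_group,
              et_treated_prob_by_group = et_treated_prob_by_group,
              neoadjuvant_prob = neoadjuvant_prob,
              pcr_prob_by_group = pcr_prob_by_group,
              censoring_rate = censoring_rate,
              admin_cutoff = admin_cutoff,
              multi_probe_genes = as.integer(multi_probe_genes),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk_prob3 <- function(p, nm) {
    if (length(p) != 3 || any(p < 0) || any(p > 1))
      stop("cohort_config field '", nm, "' must be 3 probabilities in [0,1]",
           call. = FALSE)
  }
  if (length(cfg$n_samples_per_group) != 3 || any(cfg$n_samples_per_group < 1))
    stop("cohort_config field 'n_samples_per_group' must be 3 positive integers",
         call. = FALSE)
  if (cfg$n_probes < 1)
    stop("cohort_config field 'n_probes' must be positive", call. = FALSE)
  if (cfg$n_informative_probes < 0 || cfg$n_informative_probes > cfg$n_probes)
    stop("cohort_config field 'n_informative_probes' must be in [0, n_probes]",
         call. = FALSE)
  if (cfg$effect_size < 0)
    stop("cohort_config field 'effect_size' must be non-negative", call. = FALSE)
  if (cfg$noise_sd <= 0)
    stop("cohort_config field 'noise_sd' must be positive", call. = FALSE)
  chk_prob3(cfg$frac_her2tn_by_group, "frac_her2tn_by_group")
  chk_prob3(cfg$er_pos_prob_by_group, "er_pos_prob_by_group")
  chk_prob3(cfg$age_lt50_prob_by_group, "age_lt50_prob_by_group")
  chk_prob3(cfg$size_gt2_prob_by_group, "size_gt2_prob_by_group")
  chk_prob3(cfg$node_pos_prob_by_group, "node_pos_prob_by_group")
  chk_prob3(cfg$et_treated_prob_by_group, "et_treated_prob_by_group")
  chk_prob3(cfg$pcr_prob_by_group, "pcr_prob_by_group")
  if (length(cfg$grade_dist_by_group) != 3 ||
      !all(vapply(cfg$grade_dist_by_group, function(d)
        length(d) == 3 && all(d >= 0) && abs(sum(d) - 1) < 1e-6, logical(1))))
    stop("cohort_config field 'grade_dist_by_group' must be 3 distributions over grades 1..3",
         call. = FALSE)
  if (any(cfg$relapse_hazard_by_group <= 0))
    stop("cohort_config field 'relapse_hazard_by_group' must be positive rates",
         call. = FALSE)
  if (any(cfg$et_hazard_multiplier_by_group <= 0))
    stop("cohort_config field 'et_hazard_multiplier_by_group' must be positive",
         call. = FALSE)
  if (cfg$neoadjuvant_prob < 0 || cfg$neoadjuvant_prob > 1)
    stop("cohort_config field 'neoadjuvant_prob' must be a probability",
         call. = FALSE)
  if (cfg$censoring_rate <= 0)
    stop("cohort_config field 'censoring_rate' must be positive", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic training cohort
#'
#' Draws a raw-intensity probe-by-sample matrix with three planted expression
#' groups, a probe-to-gene annotation, and a clinical table whose covariates
#' follow the per-group distributions in `config`. The Her2+/TN flag is
#' derived from the simulated receptor fields (Her2+ OR ER-/PR-/Her2-), so it
#' is always consistent with them. Truth group labels are recorded for every
#' sample. Deterministic given `config` (including its seed).
#'
#' @param config a [cohort_config()].
#' @return a list with elements `expr` (raw [expr_matrix()]), `annotation`
#'   ([probe_annotation()]), `clinical` (data frame, one row per sample),
#'   `truth` (named integer vector of group labels 1..3) and `informative`
#'   (data frame of planted probe effects: probe_id, direction, group2_follows).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n_g <- config$n_samples_per_group
    n <- sum(n_g)
    group <- rep(1:3, times = n_g)
    sample_id <- sprintf("S%04d", seq_len(n))
    names(group) <- sample_id

    np <- config$n_probes
    probe_id <- sprintf("P%05d", seq_len(np))
    # one probe per gene, except the first `multi_probe_genes` genes which get
    # a duplicate probe appended
    gene <- sprintf("GENE%05d", seq_len(np))
    if (config$multi_probe_genes > 0) {
      k <- min(config$multi_probe_genes, np)
      probe_id <- c(probe_id, sprintf("P%05dB", seq_len(k)))
      gene <- c(gene, gene[seq_len(k)])
    }
    annotation <- probe_annotation(probe_id, gene)
    npt <- length(probe_id)

    informative_idx <- sort(sample.int(np, config$n_informative_probes))
    direction <- sample(c(-1, 1), config$n_informative_probes, replace = TRUE)
    # group 2 is intermediate-but-distinct: the first half of informative
    # probes follow the group-3 direction, the rest the group-1 direction
    g2_follows <- rep(c(3L, 1L),
                      length.out = config$n_informative_probes)

    shift <- matrix(0, nrow = npt, ncol = 3)
    e <- config$effect_size
    shift[informative_idx, 1] <- -direction * e
    shift[informative_idx, 3] <- +direction * e
    shift[informative_idx, 2] <- ifelse(g2_follows == 3L, +direction * e,
                                        -direction * e)
    # duplicated probes inherit their gene's effect
    if (npt > np) {
      dup_src <- match(gene[(np + 1):npt], gene[seq_len(np)])
      shift[(np + 1):npt, ] <- shift[dup_src, , drop = FALSE]
    }

    baseline <- stats::rnorm(npt, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    log2x <- baseline + shift[, group] +
      matrix(stats::rnorm(npt * n, 0, config$noise_sd), nrow = npt)
    values <- 2^log2x
    dimnames(values) <- list(probe_id, sample_id)
    expr <- expr_matrix(values, "raw")

    clinical <- draw_clinical(group, config)
    informative <- data.frame(probe_id = probe_id[informative_idx],
                              direction = direction,
                              group2_follows = g2_follows,
                              stringsAsFactors = FALSE)
    list(expr = expr, annotation = annotation, clinical = clinical,
         truth = group, informative = informative)
  })
}

draw_clinical <- function(group, config) {
  n <- length(group)
  rbern <- function(p) stats::rbinom(n, 1, p[group]) == 1

  her2tn <- rbern(config$frac_her2tn_by_group)
  her2 <- logical(n); er <- logical(n); pr <- logical(n)
  is_her2pos <- her2tn &
    (stats::runif(n) < config$her2_pos_frac_within_her2tn)
  is_tn <- her2tn & !is_her2pos
  # Her2+ samples: ER drawn from the group ER rate; TN forces all negative
  her2[is_her2pos] <- TRUE
  er_draw <- rbern(config$er_pos_prob_by_group)
  er[is_her2pos] <- er_draw[is_her2pos]
  pr[is_her2pos] <- er[is_her2pos] & stats::runif(n)[is_her2pos] < 0.8
  # non-Her2+/TN samples: Her2-, and at least one hormone receptor positive
  rest <- !her2tn
  er[rest] <- er_draw[rest]
  pr_draw <- stats::runif(n) < 0.85
  pr[rest] <- ifelse(er[rest], pr_draw[rest], TRUE)

  grade <- integer(n)
  for (g in 1:3) {
    idx <- which(group == g)
    grade[idx] <- sample(1:3, length(idx), replace = TRUE,
                         prob = config$grade_dist_by_group[[g]])
  }

  data.frame(
    sample_id = names(group),
    group = unname(group),
    age_lt50 = rbern(config$age_lt50_prob_by_group),
    size_gt2cm = rbern(config$size_gt2_prob_by_group),
    node_pos = rbern(config$node_pos_prob_by_group),
    grade = grade,
    er = er, pr = pr, her2 = her2,
    her2tn = her2 | (!er & !pr & !her2),
    et_treated = er & rbern(config$et_treated_prob_by_group),
    neoadjuvant = stats::runif(n) < config$neoadjuvant_prob,
    stringsAsFactors = FALSE
  )
}

#' Simulate relapse and response outcomes
#'
#' Adds exponential relapse times with group-specific hazards (the
#' endocrine-therapy multiplier applies only to ET-treated ER+ samples),
#' independent exponential censoring (plus an optional administrative cutoff),
#' and a Bernoulli pathological-complete-response outcome for
#' neoadjuvant-treated samples.
#'
#' @param clinical clinical table from [generate_cohort()]; must carry a
#'   `group` column of truth labels.
#' @param config a [cohort_config()].
#' @param seed seed for the outcome draws; defaults to `config$seed + 1` so
#'   outcomes use a different stream position than the expression noise.
#' @return the clinical table with added columns `time` (months), `event`
#'   (logical relapse indicator) and `pcr` (logical, `NA` unless neoadjuvant).
#' @export
simulate_outcomes <- function(clinical, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(clinical$group) || anyNA(clinical$group))
    stop("clinical table lacks truth group labels", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    g <- clinical$group
    rate <- config$relapse_hazard_by_group[g]
    et_on <- clinical$et_treated & clinical$er
    rate[et_on] <- rate[et_on] * config$et_hazard_multiplier_by_group[g][et_on]
    t_event <- stats::rexp(nrow(clinical), rate)
    t_cens <- pmin(stats::rexp(nrow(clinical), config$censoring_rate),
                   config$admin_cutoff)
    clinical$time <- pmin(t_event, t_cens)
    clinical$event <- t_event <= t_cens
    pcr <- rep(NA, nrow(clinical))
    neo <- which(clinical$neoadjuvant)
    pcr[neo] <- stats::rbinom(length(neo), 1, config$pcr_prob_by_group[g[neo]]) == 1
    clinical$pcr <- pcr
    clinical
  })
}

#' Simulated second-platform specification
#'
#' Describes the distortion applied when re-measuring a cohort on a second
#' array platform: a random subset of genes is retained, probe IDs are
#' renamed, and intensities are transformed `v' = gain * v + offset + noise`,
#' clipped below at a small positive constant.
#'
#' @param probe_retention_frac fraction of genes measurable on the second
#'   platform, in (0, 1].
#' @param probe_id_prefix prefix for renamed probe IDs.
#' @param gain multiplicative intensity distortion (> 0).
#' @param offset additive intensity distortion.
#' @param extra_noise_sd SD of additive intensity noise (>= 0).
#' @return a `platform_spec` list.
#' @export
platform_spec <- function(probe_retention_frac = 0.8,
                          probe_id_prefix = "V",
                          gain = 1.3, offset = 50, extra_noise_sd = 0.2) {
  if (probe_retention_frac <= 0 || probe_retention_frac > 1)
    stop("platform_spec field 'probe_retention_frac' must be in (0,1]",
         call. = FALSE)
  if (gain <= 0)
    stop("platform_spec field 'gain' must be positive", call. = FALSE)
  if (extra_noise_sd < 0)
    stop("platform_spec field 'extra_noise_sd' must be non-negative",
         call. = FALSE)
  structure(list(probe_retention_frac = probe_retention_frac,
                 probe_id_prefix = probe_id_prefix,
                 gain = gain, offset = offset,
                 extra_noise_sd = extra_noise_sd),
            class = "platform_spec")
}

#' Re-measure a cohort on a simulated second platform
#'
#' Subsets probes by independent retention draws, renames probe IDs with the
#' platform prefix, applies the affine-plus-noise intensity distortion and
#' clips below at a small positive constant. The new annotation maps renamed
#' probes to the same gene symbols.
#'
#' @param x raw-intensity [expr_matrix()].
#' @param annotation [probe_annotation()] for `x`.
#' @param spec a [platform_spec()].
#' @param seed integer seed.
#' @param clip_floor small positive lower clip, default 0.001.
#' @return list with `expr` (raw `expr_matrix`) and `annotation`.
#' @export
generate_validation_platform <- function(x, annotation, spec, seed,
                                         clip_floor = 1e-3) {
  stopifnot(inherits(x, "expr_matrix"), inherits(spec, "platform_spec"))
  if (value_space(x) != "raw")
    stop("platform simulation expects a raw-intensity matrix", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    np <- nrow(x$values)
    keep <- stats::runif(np) < spec$probe_retention_frac
    if (!any(keep))
      stop("probe retention yielded zero probes", call. = FALSE)
    v <- x$values[keep, , drop = FALSE]
    v <- spec$gain * v + spec$offset +
      matrix(stats::rnorm(length(v), 0, spec$extra_noise_sd), nrow = nrow(v))
    v <- pmax(v, clip_floor)
    old_ids <- rownames(v)
    new_ids <- sprintf("%s%05d", spec$probe_id_prefix, seq_len(nrow(v)))
    rownames(v) <- new_ids
    genes <- annotation$gene_symbol[match(old_ids, annotation$probe_id)]
    list(expr = expr_matrix(v, "raw"),
         annotation = probe_annotation(new_ids, genes))
  })
}

#' Generate a catalog of decoy prognostic signatures
#'
#' Builds `n_signatures` gene signatures whose members are drawn partly from a
#' truth gene list and partly from a decoy pool, recording the exact union of
#' truth overlaps so the downstream overlap-exclusion step has a checkable
#' ground truth. When `n_overlap_union` is given, the union of
#' truth-overlapping genes across the catalog has exactly that size (each
#' overlap-pool gene is placed in at least one signature).
#'
#' @param truth_genes character vector of gene symbols to overlap with.
#' @param n_signatures number of signatures.
#' @param overlap_frac fraction of each signature drawn from `truth_genes`
#'   (ignored when `n_overlap_union` is given).
#' @param decoy_gene_pool character vector of decoy symbols, disjoint from
#'   `truth_genes`.
#' @param seed integer seed.
#' @param genes_per_signature signature size, default 60.
#' @param n_overlap_union optional exact size of the union of truth overlaps.
#' @return a list of [gene_signature()] objects with attribute
#'   `overlap_union` (the exact truth-overlap union).
#' @export
generate_signature_catalog <- function(truth_genes, n_signatures, overlap_frac,
                                       decoy_gene_pool, seed,
                                       genes_per_signature = 60,
                                       n_overlap_union = NULL) {
  truth_genes <- unique(toupper(truth_genes))
  decoy_gene_pool <- setdiff(unique(toupper(decoy_gene_pool)), truth_genes)
  withr::with_seed(as.integer(seed), {
    if (is.null(n_overlap_union)) {
      k <- round(overlap_frac * genes_per_signature)
      if (k > length(truth_genes))
        stop("overlap request exceeds the truth gene pool", call. = FALSE)
      sigs <- lapply(seq_len(n_signatures), function(i) {
        ov <- if (k > 0) sample(truth_genes, k) else character(0)
        dec <- sample(decoy_gene_pool, genes_per_signature - k)
        gene_signature(sprintf("SIG%02d", i), c(ov, dec))
      })
    } else {
      if (n_overlap_union > length(truth_genes))
        stop("overlap request exceeds the truth gene pool", call. = FALSE)
      pool <- sample(truth_genes, n_overlap_union)
      # spread the pool over signatures so every pool gene appears somewhere
      owner <- sample(rep_len(seq_len(n_signatures), n_overlap_union))
      sigs <- lapply(seq_len(n_signatures), function(i) {
        ov <- pool[owner == i]
        pad <- max(0, genes_per_signature - length(ov))
        dec <- sample(decoy_gene_pool, min(pad, length(decoy_gene_pool)))
        gene_signature(sprintf("SIG%02d", i), c(ov, dec))
      })
    }
    union_truth <- sort(intersect(
      unique(unlist(lapply(sigs, `[[`, "genes"))), truth_genes))
    structure(sigs, overlap_union = union_truth)
  })
}
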