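test_that("cohort generation is a pure function of config and seed", {
  cfg <- cohort_config(n_samples_per_group = c(50, 50, 50), n_probes = 500,
                       n_informative_probes = 50, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n_samples_per_group = c(50, 50, 50),
                                     n_probes = 500,
                                     n_informative_probes = 50, seed = 8))
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(n_informative_probes = 3000), "n_informative_probes")
  expect_error(cohort_config(frac_her2tn_by_group = c(0.5, 0.5, 1.2)),
               "frac_her2tn_by_group")
  expect_error(cohort_config(relapse_hazard_by_group = c(0, 0.1, 0.1)),
               "relapse_hazard_by_group")
})

test_that("Her2+/TN flags follow the group fractions and the receptor fields", {
  cfg <- cohort_config(n_samples_per_group = c(30, 30, 30), n_probes = 50,
                       n_informative_probes = 10,
                       frac_her2tn_by_group = c(0, 0, 1), seed = 3)
  co <- generate_cohort(cfg)
  cl <- co$clinical
  expect_true(all(cl$her2tn[cl$group == 3]))
  expect_false(any(cl$her2tn[cl$group != 3]))
  # the flag is always derivable from the receptor fields
  expect_identical(cl$her2tn, cl$her2 | (!cl$er & !cl$pr & !cl$her2))
})

test_that("zero effect size leaves informative probes indistinguishable", {
  cfg0 <- cohort_config(n_samples_per_group = c(40, 40, 40), n_probes = 400,
                        n_informative_probes = 200, effect_size = 0, seed = 5)
  co <- generate_cohort(cfg0)
  diff_stat <- function(co) {
    v <- log2(co$expr$values)
    rowMeans(v[, co$truth == 3]) - rowMeans(v[, co$truth == 1])
  }
  d <- diff_stat(co)
  inf <- rownames(co$expr$values) %in% co$informative$probe_id
  expect_gt(stats::ks.test(d[inf], d[!inf])$p.value, 0.01)
  # positive control: with a real effect the distributions split apart
  cfg1 <- cohort_config(n_samples_per_group = c(40, 40, 40), n_probes = 400,
                        n_informative_probes = 200, effect_size = 1.5, seed = 5)
  co1 <- generate_cohort(cfg1)
  d1 <- diff_stat(co1)
  inf1 <- rownames(co1$expr$values) %in% co1$informative$probe_id
  expect_lt(stats::ks.test(d1[inf1], d1[!inf1])$p.value, 1e-10)
})

test_that("categorical covariates calibrate to config probabilities", {
  cfg <- cohort_config(n_samples_per_group = c(5000, 5000, 5000),
                       n_probes = 10, n_informative_probes = 0, seed = 21)
  co <- generate_cohort(cfg)
  cl <- co$clinical
  for (g in 1:3) {
    sub <- cl[cl$group == g, ]
    n <- nrow(sub)
    chk <- function(obs_frac, p) {
      half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
      expect_lt(abs(obs_frac - p), max(half, 1e-12))
    }
    chk(mean(sub$her2tn), cfg$frac_her2tn_by_group[g])
    chk(mean(sub$age_lt50), cfg$age_lt50_prob_by_group[g])
    chk(mean(sub$size_gt2cm), cfg$size_gt2_prob_by_group[g])
    chk(mean(sub$node_pos), cfg$node_pos_prob_by_group[g])
    for (gr in 1:3)
      chk(mean(sub$grade == gr), cfg$grade_dist_by_group[[g]][gr])
  }
})

test_that("planted effect t statistic grows like sqrt(n)", {
  t_at_n <- function(n, seed) {
    cfg <- cohort_config(n_samples_per_group = c(n, n, n), n_probes = 60,
                         n_informative_probes = 30, effect_size = 1,
                         seed = seed)
    co <- generate_cohort(cfg)
    v <- log2(co$expr$values)[co$informative$probe_id, ]
    g1 <- co$truth == 1; g3 <- co$truth == 3
    abs(rowMeans(v[, g3]) - rowMeans(v[, g1])) /
      sqrt(apply(v[, g1], 1, var) / sum(g1) + apply(v[, g3], 1, var) / sum(g3))
  }
  ratio <- mean(t_at_n(200, 31)) / mean(t_at_n(50, 32))
  expect_gt(ratio, 1.5)   # sqrt(4) = 2 up to sampling noise
  expect_lt(ratio, 2.6)
})

test_that("identity platform transform only renames probes", {
  co <- generate_cohort(cohort_config(n_samples_per_group = c(5, 5, 5),
                                      n_probes = 100,
                                      n_informative_probes = 10, seed = 2))
  spec <- platform_spec(probe_retention_frac = 1, gain = 1, offset = 0,
                        extra_noise_sd = 0)
  val <- generate_validation_platform(co$expr, co$annotation, spec, seed = 4)
  expect_equal(unname(val$expr$values), unname(co$expr$values))
  expect_false(any(probe_ids(val$expr) %in% probe_ids(co$expr)))
  expect_setequal(val$annotation$gene_symbol, co$annotation$gene_symbol)
})

test_that("platform retention behaves binomially and never invents genes", {
  co <- generate_cohort(cohort_config(n_samples_per_group = c(4, 4, 4),
                                      n_probes = 2000,
                                      n_informative_probes = 10, seed = 2))
  spec <- platform_spec(probe_retention_frac = 0.5, gain = 1.3, offset = 50,
                        extra_noise_sd = 0.2)
  val <- generate_validation_platform(co$expr, co$annotation, spec, seed = 9)
  n_kept <- nrow(val$expr$values)
  half <- stats::qnorm(0.9995) * sqrt(2000 * 0.25)
  expect_lt(abs(n_kept - 1000), half)
  expect_true(all(val$annotation$gene_symbol %in% co$annotation$gene_symbol))
  expect_true(all(val$expr$values > 0))
})

test_that("zero-probe retention errors instead of returning an empty platform", {
  co <- generate_cohort(cohort_config(n_samples_per_group = c(2, 2, 2),
                                      n_probes = 5, n_informative_probes = 0,
                                      seed = 2))
  spec <- platform_spec(probe_retention_frac = 1e-4)
  expect_error(generate_validation_platform(co$expr, co$annotation, spec,
                                            seed = 1),
               "zero probes")
})

test_that("simulated survival honors the group hazard ordering", {
  cfg <- cohort_config(n_samples_per_group = c(1000, 1000, 1000),
                       n_probes = 10, n_informative_probes = 0,
                       relapse_hazard_by_group = c(0.01, 0.04, 0.04),
                       et_hazard_multiplier_by_group = c(1, 1, 1),
                       censoring_rate = 0.02, seed = 13)
  co <- generate_cohort(cfg)
  cl <- simulate_outcomes(co$clinical, cfg)
  km <- kaplan_meier(cl, cl$group)
  # group-1 curve sits above groups 2 and 3 at a fixed horizon
  s <- summary(km$fit, times = 24)
  surv_by_group <- stats::setNames(s$surv, s$strata)
  expect_gt(surv_by_group["g=1"], surv_by_group["g=2"])
  expect_gt(surv_by_group["g=1"], surv_by_group["g=3"])
  expect_lt(km$p, 1e-10)
  # and matches the exponential closed form S(t) = exp(-lambda t) broadly
  expect_lt(abs(surv_by_group["g=1"] - exp(-0.01 * 24)), 0.05)
})

test_that("pCR rates converge to config probabilities", {
  cfg <- cohort_config(n_samples_per_group = c(10000, 10000, 10000),
                       n_probes = 5, n_informative_probes = 0,
                       neoadjuvant_prob = 1, seed = 17)
  co <- generate_cohort(cfg)
  cl <- simulate_outcomes(co$clinical, cfg)
  rates <- tapply(cl$pcr, cl$group, mean)
  expect_true(all(abs(rates - c(0.06, 0.08, 0.42)) < 0.01))
})

test_that("a unit endocrine-therapy multiplier gives null log-rank p-values", {
  cfg <- cohort_config(n_samples_per_group = c(200, 200, 200), n_probes = 5,
                       n_informative_probes = 0,
                       er_pos_prob_by_group = c(1, 1, 1),
                       frac_her2tn_by_group = c(0, 0, 0),
                       et_hazard_multiplier_by_group = c(1, 1, 1),
                       et_treated_prob_by_group = c(0.5, 0.5, 0.5), seed = 19)
  co <- generate_cohort(cfg)
  ps <- vapply(1:100, function(i) {
    cl <- simulate_outcomes(co$clinical, cfg, seed = 1000 + i)
    arm <- factor(ifelse(cl$et_treated, "ET", "none"))
    kaplan_meier(cl, arm)$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("simulate_outcomes demands truth labels", {
  cfg <- cohort_config(seed = 1)
  co <- generate_cohort(cfg)
  cl <- co$clinical
  cl$group <- NULL
  expect_error(simulate_outcomes(cl, cfg), "group")
})

test_that("signature catalogs control their truth overlap exactly", {
  truth <- sprintf("T%04d", 1:1304)
  decoys <- sprintf("D%04d", 1:3000)
  # zero overlap
  cat0 <- generate_signature_catalog(truth, 5, 0, decoys, seed = 2)
  expect_length(intersect(unlist(lapply(cat0, `[[`, "genes")), truth), 0)
  # engineered exact union
  cat501 <- generate_signature_catalog(truth, 16, NA, decoys, seed = 2,
                                       n_overlap_union = 501)
  expect_length(attr(cat501, "overlap_union"), 501)
  expect_setequal(intersect(unlist(lapply(cat501, `[[`, "genes")), truth),
                  attr(cat501, "overlap_union"))
  # determinism
  cat501b <- generate_signature_catalog(truth, 16, NA, decoys, seed = 2,
                                        n_overlap_union = 501)
  expect_identical(lapply(cat501, `[[`, "genes"),
                   lapply(cat501b, `[[`, "genes"))
  # an impossible overlap request errors
  expect_error(generate_signature_catalog(truth[1:10], 2, NA, decoys,
                                          seed = 1, n_overlap_union = 50),
               "exceeds")
})
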