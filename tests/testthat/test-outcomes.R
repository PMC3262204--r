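test_that("contingency test matches the direct (O-E)^2/E computation", {
  tab <- matrix(c(30, 10, 25, 15, 20, 20), nrow = 2)
  res <- contingency_association(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  expect_identical(res$method, "chisq")
  # proportional rows = exact independence
  ind <- matrix(c(10, 20, 30, 60, 5, 10), nrow = 2)
  res0 <- contingency_association(ind)
  expect_lt(res0$statistic, 1e-20)
  expect_gt(res0$p, 0.999)
})

test_that("the training Her2+/TN x group table is overwhelmingly associated", {
  # printed counts: 3/42, 5/60, 36/3 (Her2+/TN yes/no by group)
  tab <- rbind(no = c(42, 60, 3), yes = c(3, 5, 36))
  res <- contingency_association(tab)
  expect_lt(res$p, 1e-15)
})

test_that("small 2x2 tables fall back to the Fisher exact test", {
  tab <- matrix(c(1, 9, 8, 2), nrow = 2)
  res <- contingency_association(tab)
  expect_identical(res$method, "fisher")
  expect_equal(res$p, stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  expect_error(contingency_association(matrix(c(0, 0, 3, 4), nrow = 2,
                                              byrow = TRUE)),
               "margin")
})

test_that("group rate tables render counts and half-up percentages", {
  clinical <- data.frame(
    group = rep(c("CMTC-1", "CMTC-2", "CMTC-3"), c(45, 65, 39)),
    event = c(rep(c(TRUE, FALSE), c(1, 44)), rep(c(TRUE, FALSE), c(4, 61)),
              rep(c(TRUE, FALSE), c(5, 34))))
  tab <- group_rate_table(clinical, "group", "event")
  yes <- tab[tab$level == "TRUE", ]
  expect_equal(yes$pct[yes$group == "CMTC-1"], 2.2)
  expect_equal(yes$pct[yes$group == "CMTC-2"], 6.2)
  expect_equal(yes$pct[yes$group == "CMTC-3"], 12.8)
  expect_identical(yes$rendering[yes$group == "CMTC-3"], "5 (12.8)")
  # 136 of 731 -> 18.6; 0 of n -> 0.0
  big <- data.frame(group = rep("V1", 731),
                    event = rep(c(TRUE, FALSE), c(136, 595)))
  tb <- group_rate_table(big, "group", "event")
  expect_equal(tb$pct[tb$level == "TRUE"], 18.6)
  zero <- data.frame(group = rep("a", 10), event = rep(FALSE, 10))
  tz <- group_rate_table(zero, "group", "event")
  expect_equal(tz$pct, 100)  # single observed level
})

test_that("Kaplan-Meier estimates equal the product-limit oracle exactly", {
  time <- c(2, 3, 3, 5, 7, 8, 10, 12, 13, 15)
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  rec <- data.frame(time = time, event = event)
  km <- kaplan_meier(rec, rep("all", 10))
  oracle <- km_oracle(time, event)
  s <- summary(km$fit, times = oracle$time)
  expect_equal(s$surv, oracle$surv, tolerance = 1e-12)
  # with no censoring the curve is the complement of the ECDF
  rec2 <- data.frame(time = 1:8, event = rep(TRUE, 8))
  km2 <- kaplan_meier(rec2, rep("all", 8))
  s2 <- summary(km2$fit, times = 1:8)
  expect_equal(s2$surv, 1 - (1:8) / 8, tolerance = 1e-12)
})

test_that("the log-rank statistic equals the brute-force O-E form", {
  time <- c(1, 4, 4, 6, 8, 9, 11, 13, 14, 16)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  group <- rep(c("a", "b"), 5)
  rec <- data.frame(time = time, event = event)
  km <- kaplan_meier(rec, group)
  expect_equal(km$logrank_chisq, logrank_oracle(time, event, group),
               tolerance = 1e-10)
})

test_that("log-rank p-values are uniform under the null and powered under HR 2.4", {
  withr::with_seed(77, {
    ps_null <- vapply(1:200, function(i) {
      n <- 60
      rec <- data.frame(time = pmin(rexp(n, 0.05), rexp(n, 0.03)),
                        event = NA)
      te <- rexp(n, 0.05); tc <- rexp(n, 0.03)
      rec <- data.frame(time = pmin(te, tc), event = te <= tc)
      kaplan_meier(rec, rep(c("a", "b"), n / 2))$p
    }, 0)
  })
  expect_gt(stats::ks.test(ps_null, "punif")$p.value, 0.01)
  withr::with_seed(78, {
    ps_alt <- vapply(1:11, function(i) {
      n <- 500
      g <- rep(c(0, 1), each = n)
      te <- rexp(2 * n, 0.02 * 2.4^g)
      tc <- rexp(2 * n, 0.02)
      rec <- data.frame(time = pmin(te, tc), event = te <= tc)
      kaplan_meier(rec, g)$p
    }, 0)
  })
  expect_lt(stats::median(ps_alt), 1e-6)
})

test_that("Cox fits report Wald HRs and respect likelihood scaling", {
  withr::with_seed(80, {
    n <- 400
    g <- rep(c(0, 1), each = n / 2)
    te <- rexp(n, 0.02 * 2.4^g)
    tc <- rexp(n, 0.02)
    rec <- data.frame(time = pmin(te, tc), event = te <= tc, high = g == 1)
  })
  cx <- cox_model(rec, "high", "univariate")
  expect_true(cx$ci_lower <= cx$hr && cx$hr <= cx$ci_upper)
  expect_gt(cx$hr, 0)
  # duplicating every record leaves the HR unchanged (Breslow ties make the
  # doubled likelihood an exact multiple) and shrinks the CI
  cxb <- cox_model(rec, "high", "univariate", ties = "breslow")
  cx2 <- cox_model(rbind(rec, rec), "high", "univariate", ties = "breslow")
  expect_equal(cx2$hr, cxb$hr, tolerance = 1e-6)
  expect_lt(cx2$ci_upper - cx2$ci_lower, cxb$ci_upper - cxb$ci_lower)
  expect_error(cox_model(rec, "time_zero", "univariate"), "time_zero")
  rec$flat <- TRUE
  expect_error(cox_model(rec, "flat", "univariate"), "constant")
})

test_that("null-covariate Cox CIs cover 1.0 at the nominal rate", {
  withr::with_seed(81, {
    cover <- vapply(1:100, function(i) {
      n <- 150
      g <- rep(c(FALSE, TRUE), each = n / 2)
      te <- rexp(n, 0.03)   # hazard independent of the covariate
      tc <- rexp(n, 0.02)
      rec <- data.frame(time = pmin(te, tc), event = te <= tc, g = g)
      cx <- cox_model(rec, "g", "univariate")
      cx$ci_lower <= 1 && 1 <= cx$ci_upper
    }, logical(1))
  })
  expect_gte(mean(cover), 0.93)
})

test_that("AUC equals the Mann-Whitney normalization and external reference", {
  withr::with_seed(83, {
    labels <- rep(c(TRUE, FALSE), c(40, 60))
    scores <- rnorm(100) + labels
  })
  a <- roc_auc(labels, scores)
  w <- stats::wilcox.test(scores[labels], scores[!labels], exact = FALSE)
  expect_equal(a, unname(w$statistic) / (40 * 60), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC closed forms hold for perfect and single-threshold predictors", {
  labels <- rep(c(TRUE, FALSE), c(30, 70))
  expect_equal(roc_auc(labels, as.numeric(labels)), 1)
  # a binary predictor with sensitivity s and specificity p has AUC (s+p)/2
  withr::with_seed(84, pred <- ifelse(labels, rbinom(100, 1, 0.8),
                                      rbinom(100, 1, 0.3)))
  s <- mean(pred[labels] == 1)
  p <- mean(pred[!labels] == 0)
  expect_equal(roc_auc(labels, pred), (s + p) / 2, tolerance = 1e-12)
  expect_error(roc_auc(rep(TRUE, 5), 1:5), "all-positive")
})

test_that("ROC curves are monotone and confusion metrics recompute from counts", {
  withr::with_seed(85, {
    labels <- rep(c(TRUE, FALSE), 50)
    scores <- rnorm(100) + labels
  })
  rc <- roc_curve(labels, scores)
  expect_true(all(diff(rc$sensitivity) <= 1e-12))
  expect_true(all(diff(rc$specificity) >= -1e-12))
  cr <- confusion_report(scores > 0.5, labels)
  k <- cr$counts
  expect_equal(cr$sensitivity, k["tp"] / (k["tp"] + k["fn"]), ignore_attr = TRUE)
  expect_equal(cr$specificity, k["tn"] / (k["tn"] + k["fp"]), ignore_attr = TRUE)
  expect_equal(cr$ppv, k["tp"] / (k["tp"] + k["fp"]), ignore_attr = TRUE)
  expect_equal(cr$npv, k["tn"] / (k["tn"] + k["fn"]), ignore_attr = TRUE)
  expect_equal(cr$accuracy, (k["tp"] + k["tn"]) / sum(k), ignore_attr = TRUE)
})

test_that("ET-benefit analysis flags empty strata instead of failing", {
  withr::with_seed(86, {
    n <- 120
    cl <- data.frame(
      sample_id = sprintf("S%03d", 1:n),
      group = rep(c("CMTC-1", "CMTC-2", "CMTC-3"), each = n / 3),
      er = TRUE,
      et_treated = c(rep(c(TRUE, FALSE), n / 6),      # both arms in group 1
                     rep(TRUE, n / 3),                # group 2: treated only
                     rep(c(TRUE, FALSE), n / 6)),
      time = rexp(n, 0.05), event = rexp(n, 0.05) < 10)
  })
  res <- et_benefit_analysis(cl)
  expect_false(is.na(res$by_group[["CMTC-1"]]$p))
  expect_identical(res$by_group[["CMTC-2"]]$flag, "empty arm or no events")
  expect_error(et_benefit_analysis(cl[!cl$er, ]), "ER\\+")
})

test_that("pCR analysis reports rates, AUCs with bootstrap CIs, and confusion", {
  withr::with_seed(87, {
    n <- c(80, 80, 88)
    groups <- rep(c("CMTC-1", "CMTC-2", "CMTC-3"), n)
    pcr <- rbinom(sum(n), 1, c(0.06, 0.08, 0.42)[match(groups,
      c("CMTC-1", "CMTC-2", "CMTC-3"))]) == 1
    her2 <- groups == "CMTC-3" & runif(sum(n)) < 0.5
    tn <- groups == "CMTC-3" & !her2 & runif(sum(n)) < 0.8
    r_index <- ifelse(groups == "CMTC-3", 0.5, -0.3) + rnorm(sum(n), 0, 0.2)
  })
  pa <- pcr_analysis(pcr, groups, r_index = r_index, her2 = her2, tn = tn,
                     n_boot = 200, seed = 5)
  expect_identical(pa$rates$group, c("CMTC-1", "CMTC-2", "CMTC-3"))
  expect_true(which.max(pa$rates$pct) == 3)
  expect_setequal(names(pa$roc), c("group3", "her2tn", "her2", "tn", "r_index"))
  for (r in pa$roc) {
    expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  }
  # binary-predictor AUC equals (sens+spec)/2 from its own confusion report
  cg3 <- pa$confusion$group3
  expect_equal(pa$roc$group3$auc, (cg3$sensitivity + cg3$specificity) / 2,
               tolerance = 1e-12)
  expect_error(pcr_analysis(rep(TRUE, 5), rep("CMTC-1", 5)), "all-positive")
})
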