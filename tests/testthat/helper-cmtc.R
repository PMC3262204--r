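# Small fixture builders shared across test files.

# expr_matrix from a bare numeric matrix, auto-labelling probes/samples
make_expr <- function(m, space = "log2ratio") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  expr_matrix(m, space)
}

# two-class matrix with a planted mean shift on the first `n_inf` probes
make_two_class <- function(n_probes, n_a, n_b, shift, sd = 1, n_inf, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_probes * (n_a + n_b), 0, sd), nrow = n_probes)
    m[seq_len(n_inf), seq_len(n_a)] <- m[seq_len(n_inf), seq_len(n_a)] + shift
    make_expr(m)
  })
}

# a toy centroid model with opposed group-1/group-3 patterns
make_toy_model <- function(n_genes = 40, seed = 5) {
  withr::with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    c3 <- rnorm(n_genes)
    c1 <- -c3
    c2 <- c(c3[seq_len(n_genes / 2)], c1[(n_genes / 2 + 1):n_genes])
    centroids <- cbind(`CMTC-1` = c1, `CMTC-2` = c2, `CMTC-3` = c3)
    rownames(centroids) <- genes
    structure(list(probe_set = genes, centroids = centroids,
                   group_names = c("CMTC-1", "CMTC-2", "CMTC-3"),
                   identity_evidence = NULL, derivation_log = list()),
              class = "cmtc_model")
  })
}

# hand-rolled product-limit estimator (independent oracle)
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# brute-force two-group log-rank statistic (observed minus expected form)
logrank_oracle <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  tt <- sort(unique(time[event]))
  o_minus_e <- 0
  var_sum <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / var_sum
}
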