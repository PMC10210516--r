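# Group-comparison layer: GLM identities on balanced designs, LRT
# behaviour, estimated marginal means, multiplicity adjustment, percent
# differences.

test_that("balanced gaussian fit reproduces the group sample means", {
  set.seed(1)
  d <- data.frame(treatment = rep(c("Ctrl", "RA"), each = 10),
                  value = c(stats::rnorm(10, 5), stats::rnorm(10, 7)))
  m <- fit_model(d, "value", family = "gaussian")
  em <- emm_at(m)
  means <- tapply(d$value, d$treatment, mean)
  expect_equal(em$emm$mean[em$emm$treatment == "Ctrl"], unname(means["Ctrl"]))
  expect_equal(em$emm$mean[em$emm$treatment == "RA"], unname(means["RA"]))
})

test_that("gamma log-link degenerate and simulated cases behave", {
  d <- data.frame(treatment = rep(c("Ctrl", "RA"), each = 6), value = 3.7)
  # constant response: zero dispersion makes the AIC term degenerate (NaN
  # warning from dgamma); the coefficients are still exact
  m <- suppressWarnings(fit_model(d, "value", family = "gamma"))
  expect_equal(unname(stats::coef(m$glm)[1L]), log(3.7), tolerance = 1e-8)
  expect_equal(unname(stats::coef(m$glm)[2L]), 0, tolerance = 1e-8)

  set.seed(2)
  n <- 200
  d2 <- data.frame(
    treatment = rep(c("Ctrl", "RA"), each = n),
    value = c(stats::rgamma(n, shape = 4, rate = 4 / 10),
              stats::rgamma(n, shape = 4, rate = 4 / (10 * exp(0.3))))
  )
  m2 <- fit_model(d2, "value", family = "gamma")
  est <- stats::coef(m2$glm)[["treatmentRA"]]
  se <- sqrt(m2$vcov["treatmentRA", "treatmentRA"])
  expect_lt(abs(est - 0.3), 3 * se)
  # gamma family refuses non-positive outcomes, naming rows
  d2$value[3] <- 0
  expect_error(fit_model(d2, "value", family = "gamma"), "offending rows")
})

test_that("likelihood ratio test: identity, nesting, and power", {
  set.seed(3)
  d <- data.frame(treatment = rep(c("Ctrl", "RA"), each = 30),
                  strain = rep(c(5, 10, 15), 20))
  d$value <- stats::rgamma(60, 5, 5 / exp(2 + 0.1 * d$strain +
                                            0.08 * d$strain * (d$treatment == "RA")))
  full <- fit_model(d, "value", covariate = "strain", family = "gamma")
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  no_int <- fit_model(d, "value", covariate = "strain", family = "gamma",
                      interaction = FALSE)
  lrt <- likelihood_ratio_test(full, no_int)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p, 1e-3) # strong simulated interaction
  expect_error(likelihood_ratio_test(no_int, full), "not nested|more parameters")
})

test_that("LRT type-I error is near nominal under the gamma null", {
  # scaled-down null calibration (300 reps here; the acceptance suite runs
  # the full 1000-rep version)
  set.seed(4)
  p <- vapply(1:300, function(i) {
    d <- data.frame(treatment = rep(c("Ctrl", "RA"), each = 20),
                    value = stats::rgamma(40, shape = 5, rate = 5 / 100))
    full <- fit_model(d, "value", family = "gamma")
    null <- fit_model(d, "value", family = "gamma", rhs = "1")
    likelihood_ratio_test(full, null)$p
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("EMMs at observed covariate values equal cell means on balanced noiseless data", {
  d <- expand.grid(treatment = c("Ctrl", "RA"), strain = c(5, 10, 15),
                   rep = 1:4, stringsAsFactors = FALSE)
  cell_mean <- c(Ctrl = 100, RA = 70)
  d$value <- cell_mean[d$treatment] + 2 * d$strain
  m <- fit_model(d, "value", covariate = "strain", family = "gaussian")
  em <- emm_at(m, at = c(0, 5, 10, 15))
  for (s in c(5, 10, 15)) {
    for (g in c("Ctrl", "RA")) {
      expect_equal(em$emm$mean[em$emm$treatment == g & em$emm$at == s],
                   mean(d$value[d$treatment == g & d$strain == s]),
                   tolerance = 1e-8)
    }
  }
  # 0% strain is outside the observed range: flagged as extrapolation
  expect_true(all(em$emm$extrapolated[em$emm$at == 0]))
  expect_false(any(em$emm$extrapolated[em$emm$at != 0]))
  # contrasts are RA - Ctrl on the response scale
  expect_equal(em$contrasts$estimate, rep(-30, 4), tolerance = 1e-8)
  expect_error(emm_at(m, at = NULL), "covariate")
})

test_that("contrast at 0% strain is null when groups share the intercept", {
  # generator: equal group means at 0% strain, diverging with strain
  set.seed(5)
  reps <- vapply(1:15, function(i) {
    d <- expand.grid(treatment = c("Ctrl", "RA"), strain = c(5, 10, 15),
                     rep = 1:6, stringsAsFactors = FALSE)
    mu <- exp(4.6 - 0.05 * d$strain * (d$treatment == "RA"))
    d$value <- stats::rgamma(nrow(d), shape = 30, rate = 30 / mu)
    m <- fit_model(d, "value", covariate = "strain", family = "gamma")
    em <- emm_at(m, at = c(0, 15))
    c(p0 = em$contrasts$p[em$contrasts$at == 0],
      p15 = em$contrasts$p[em$contrasts$at == 15])
  }, numeric(2))
  expect_gt(mean(reps["p0", ] > 0.05), 0.8)  # no effect at 0%
  expect_gt(mean(reps["p15", ] < 0.05), 0.95) # strong effect at 15%
})

test_that("multivariate-t adjustment: identity, Sidak and degenerate limits", {
  fake <- function(tvals, df = 500) {
    data.frame(contrast = "RA - Ctrl", at = seq_along(tvals), estimate = tvals,
               se = 1, t = tvals, df = df,
               p = 2 * stats::pt(abs(tvals), df, lower.tail = FALSE))
  }
  one <- adjust_multiplicity(fake(2.1), diag(1))
  expect_equal(one$p_adj, one$p)

  k <- 4
  ind <- adjust_multiplicity(fake(rep(2.1, k)), diag(k), nsim = 2e5)
  sidak <- 1 - (1 - ind$p[1L])^k
  expect_equal(ind$p_adj[1L], sidak, tolerance = 0.02)

  corr <- matrix(1 - 1e-9, k, k); diag(corr) <- 1
  dep <- adjust_multiplicity(fake(rep(2.1, k)), corr, nsim = 2e5)
  expect_equal(dep$p_adj[1L], dep$p[1L], tolerance = 0.01)

  # monotone in raw p, never smaller than raw p
  mix <- adjust_multiplicity(fake(c(0.5, 1.5, 2.5, 3.5)), diag(4))
  expect_true(all(mix$p_adj >= mix$p))
  expect_true(all(diff(mix$p_adj[order(mix$p)]) <= 0 + 1e-12) ||
                all(diff(mix$p_adj[order(mix$p)]) >= 0 - 1e-12))

  # singular covariance falls back to Bonferroni with a warning
  sing <- matrix(1, 2, 2)
  sing[1, 2] <- sing[2, 1] <- 1 + 1e-6 # not positive definite
  expect_warning(adjust_multiplicity(fake(c(2, 2)), sing), "Bonferroni")
})

test_that("multiplicity adjustment leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(adjust_multiplicity(
    data.frame(contrast = "a", at = 1:2, estimate = 1, se = 1, t = c(2, 2),
               df = 10, p = 0.07), diag(2), nsim = 1e4))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("percent differences match their definitions", {
  d <- data.frame(treatment = c(rep("Ctrl", 4), rep("RA", 4)),
                  step = rep(c(1, 2), 4),
                  value = c(100, 200, 100, 200, 70, 140, 70, 140))
  pd <- percent_difference(d, "value", stratum = "step")
  expect_equal(pd$per_sample$pct_diff[pd$per_sample$treatment == "RA"],
               rep(-30, 4))
  expect_equal(pd$per_sample$pct_diff[1L], 0) # sample equal to reference mean
  s <- pd$summary
  expect_equal(s$mean[s$treatment == "RA"], c(-30, -30))
  expect_error(percent_difference(d[d$treatment == "RA", ], "value"),
               "reference")
})

test_that("cluster-robust covariance inflates SEs under within-cluster correlation", {
  set.seed(6)
  n_cluster <- 40
  b <- stats::rnorm(n_cluster, 0, 1)
  d <- data.frame(
    cluster = rep(seq_len(n_cluster), each = 3),
    treatment = rep(c("Ctrl", "RA"), each = 3 * n_cluster / 2),
    e = stats::rnorm(3 * n_cluster, 0, 0.2)
  )
  d$value <- exp(2 + 0.2 * (d$treatment == "RA") + b[d$cluster] + d$e)
  m_rob <- fit_model(d, "value", family = "gamma", cluster = "cluster")
  m_iid <- fit_model(d, "value", family = "gamma")
  expect_gt(sqrt(m_rob$vcov[2, 2]), sqrt(m_iid$vcov[2, 2]))
})
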