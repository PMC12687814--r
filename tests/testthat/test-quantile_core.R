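test_that("intercept-only quantile fits recover order statistics and match brute force", {
  fit <- fit_quantile_null(c(1, 2, 3, 4, 5), NULL, 0.5)
  expect_equal(unname(fit$coefficients[1]), 3)

  y8 <- 1:8
  fit25 <- fit_quantile_null(y8, NULL, 0.25)
  expect_equal(unname(fit25$coefficients[1]), 2)
  ## objective no worse than any candidate tried by the brute-force oracle
  a_star <- brute_force_quantile(y8, 0.25)
  loss <- function(a) sum((y8 - a) * (0.25 - ((y8 - a) < 0)))
  expect_lte(fit25$objective, loss(a_star) + 1e-10)
})

test_that("a perfectly separating binary covariate yields group medians at tau = 0.5", {
  y <- c(1, 2, 3, 101, 102, 103)
  C <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
  fit <- fit_quantile_null(y, C, 0.5)
  fitted <- cbind(1, C) %*% fit$coefficients
  expect_equal(unname(fitted[1:3]), rep(2, 3))
  expect_equal(unname(fitted[4:6]), rep(102, 3))
})

test_that("null fit errors on rank-deficient covariates and invalid tau", {
  C <- cbind(1:10, 2 * (1:10))
  expect_error(fit_quantile_null(rnorm(10), C, 0.5), "rank deficient")
  expect_error(fit_quantile_null(rnorm(10), NULL, 0), "tau")
})

test_that("rank-score statistic matches direct formula evaluation on the 6-sample fixture", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- c(0, 0, 1, 1, 2, 2)
  nf <- fit_quantile_null(y, NULL, 0.5)
  rs <- rank_score_test(g, nf, NULL)
  oracle <- rank_score_direct(g, y, NULL[0], matrix(nf$coefficients), 0.5)
  expect_equal(rs$S, oracle$S, tolerance = 1e-12)
  expect_equal(rs$sigma, oracle$sigma, tolerance = 1e-12)
  ## sigma^2 identity is exact
  gstar <- g - mean(g)
  expect_identical(rs$sigma^2, 0.5 * 0.5 * sum(gstar^2) / 6)
})

test_that("constant dosage is flagged untestable with no p-value", {
  y <- rnorm(20)
  nf <- fit_quantile_null(y, NULL, 0.5)
  rs <- rank_score_test(rep(2, 20), nf, NULL)
  expect_true(rs$untestable)
  expect_true(is.na(rs$p))
})

test_that("rank-score test is invariant to adding covariate-span vectors to the dosage", {
  set.seed(7)
  n <- 120
  C <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  g <- rbinom(n, 2, 0.3)
  nf <- fit_quantile_null(y, C, 0.3)
  qrb <- qr(cbind(1, C))
  base <- rank_score_test(g, nf, C, qr_basis = qrb)
  for (k in 1:3) {
    shifted <- g + 5 * C[, k] + 2
    rs <- rank_score_test(shifted, nf, C, qr_basis = qrb)
    expect_equal(rs$S, base$S, tolerance = 1e-10)
    expect_equal(rs$p, base$p, tolerance = 1e-10)
  }
})

test_that("rank-score null p-values are calibrated and uniform", {
  set.seed(11)
  n <- 400
  reps <- 2000
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    C <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    g <- rbinom(n, 2, 0.25)
    nf <- fit_quantile_null(y, C, 0.5, method = "fn")
    pvals[r] <- rank_score_test(g, nf, C)$p
  }
  expect_gte(mean(pvals < 0.05), 0.035)
  expect_lte(mean(pvals < 0.05), 0.065)
  ## uniformity not rejected at 0.001
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("cauchy combination: fixed points, identity, monotonicity, derived value", {
  expect_equal(cauchy_combine(rep(0.05, 5)), 0.05, tolerance = 1e-12)
  expect_equal(cauchy_combine(0.3), 0.3, tolerance = 1e-12)
  ## derived by direct transform evaluation
  direct <- 0.5 - atan(mean(tan((0.5 - c(0.01, 0.5)) * pi))) / pi
  expect_equal(cauchy_combine(c(0.01, 0.5)), direct, tolerance = 1e-12)
  expect_equal(round(direct, 4), 0.02, tolerance = 1e-3)
  ## decreasing any input never increases the combined p
  set.seed(1)
  for (i in 1:20) {
    p <- runif(4)
    j <- sample(4, 1)
    p2 <- p
    p2[j] <- p[j] * 0.5
    expect_lte(cauchy_combine(p2), cauchy_combine(p) + 1e-12)
  }
  expect_error(cauchy_combine(numeric(0)), "no p-values")
})

test_that("chatterjee xi: monotone value, sign-blindness, null behavior, ties", {
  expect_equal(chatterjee_xi(1:9, 1:9)$xi, 0.7)
  expect_equal(chatterjee_xi(1:9, -(1:9))$xi, 0.7)
  set.seed(5)
  big <- chatterjee_xi(seq_len(10000), rnorm(10000))
  expect_lt(abs(big$xi), 0.05)
  expect_warning(ct <- chatterjee_xi(1:5, rep(1, 5)), "equal")
  expect_equal(ct$xi, 0)
  expect_error(chatterjee_xi(1:2, 1:2), "at least 3")
})

test_that("joint quantile fit recovers the closed-form scale-model slope", {
  set.seed(21)
  n <- 4000
  g <- rbinom(n, 2, 0.3)
  y <- (1 + 0.5 * g) * rnorm(n)
  taus <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  fit <- fit_quantile_joint(y, g, NULL, grid = quantile_grid(taus), method = "fn")
  expected <- 0.5 * qnorm(taus)
  expect_lt(sqrt(mean((as.numeric(fit$slopes) - expected)^2)), 0.08)
})

test_that("single-level joint fit is consistent with the null fit plus predictor", {
  set.seed(3)
  y <- rnorm(60)
  g <- rbinom(60, 2, 0.4)
  joint <- fit_quantile_joint(y, g, NULL, grid = quantile_grid(0.5))
  direct <- suppressWarnings(quantreg::rq.fit.br(cbind(1, g), y, tau = 0.5))
  expect_equal(as.numeric(joint$coefficients[, 1]),
               as.numeric(direct$coefficients), tolerance = 1e-10)
})

test_that("joint fit rejects predictors collinear with covariates", {
  C <- matrix(rnorm(50), 50, 1)
  expect_error(fit_quantile_joint(rnorm(50), C[, 1], C, quantile_grid(0.5)),
               "rank deficient")
})
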