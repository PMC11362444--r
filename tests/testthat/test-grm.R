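test_that("category probabilities match the brute-force formula and normalize", {
  set.seed(101)
  for (rep in 1:50) {
    m <- sample(3:7, 1)
    a <- runif(1, 0.5, 2.5)
    b <- sort(rnorm(m - 1, 0, 1.2))
    while (any(diff(b) < 1e-3)) b <- sort(rnorm(m - 1, 0, 1.2))
    th <- runif(1, -3, 3)
    p <- grm_prob(th, a, b)
    expect_equal(unname(drop(p)), oracle_grm_prob(th, a, b), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0 & p <= 1))
  }
  # cumulative curve passes through 0.5 at each threshold
  b <- c(-1, 0, 1)
  for (k in 1:3) {
    p <- grm_prob(b[k], 1.5, b)
    expect_equal(sum(p[1, (k + 1):4]), 0.5, tolerance = 1e-12)
  }
  expect_error(grm_prob(Inf, 1, c(-1, 1)), "finite")
  expect_error(grm_prob(0, 1, c(1, -1)), "increasing")
})

test_that("expected score is monotone in theta with the right limits", {
  a <- 1.5; b <- c(-1, 0, 1)
  grid <- seq(-6, 6, by = 0.1)
  e <- expected_score(grid, a, b)
  expect_true(all(diff(e) >= 0))
  expect_equal(expected_score(9, 2, c(-5.5, -5, -4.5)), 4, tolerance = 1e-4)
  # symmetric thresholds at theta 0 force the midpoint
  expect_equal(expected_score(0, 1.5, c(-1.5, -0.5, 0.5, 1.5)), 3,
               tolerance = 1e-12)
  # direct-summation oracle
  expect_equal(expected_score(0.5, 1.5, c(-1, 0, 1)),
               oracle_expected(0.5, 1.5, c(-1, 0, 1)), tolerance = 1e-12)
})

test_that("response-error scores hit their bounds and hand values", {
  a <- 1.5; b <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(response_error(3, 0, a, b), 0, tolerance = 1e-12)
  # expected score pinned at the top, observed at the bottom -> error 1
  expect_equal(response_error(1, 8, 2, c(-6, -5.5, -5, -4.5)), 1,
               tolerance = 1e-4)
  # |2 - 3.4| / 4 = 0.35 with a constructed expected score of 3.40
  th <- uniroot(function(t) expected_score(t, a, b) - 3.4, c(0, 3),
                tol = 1e-12)$root
  expect_equal(response_error(2, th, a, b), 0.35, tolerance = 1e-8)
  expect_error(response_error(6, 0, a, b), "1\\.\\.5")
  # 1000-case random grid against the independent oracle
  set.seed(202)
  for (i in 1:1000) {
    m <- sample(3:7, 1)
    aa <- runif(1, 0.6, 2.5)
    bb <- sort(runif(m - 1, -2.5, 2.5))
    bb <- bb + seq(0, 0.01 * (m - 2), length.out = m - 1)  # enforce gaps
    tt <- runif(1, -3, 3)
    yy <- sample(m, 1)
    expect_equal(response_error(yy, tt, aa, bb), oracle_error(yy, tt, aa, bb),
                 tolerance = 1e-10)
  }
})

test_that("EAP estimates are symmetric, monotone, and match the dense-grid oracle", {
  a <- c(2, 1.5); b <- list(c(-1, 0, 1), c(-1.5, 0, 1.5))
  fit <- list(a = a, b = b, quad = NULL)
  # symmetric 3-category items, all-middle responses -> theta 0
  a3 <- c(1.5, 1.5); b3 <- list(c(-1, 1), c(-1.5, 1.5))
  eap_mid <- eap_theta(matrix(c(2L, 2L), 1), list(a = a3, b = b3))
  expect_equal(eap_mid$theta, 0, tolerance = 1e-6)
  hi <- eap_theta(matrix(c(4L, 4L), 1), fit)
  lo <- eap_theta(matrix(c(1L, 1L), 1), fit)
  expect_gt(hi$theta, 0)
  expect_gt(hi$theta, lo$theta)
  expect_true(all(c(hi$sd, lo$sd) > 0))
  # single item, y = 4: dense-grid numerical integration oracle
  est <- eap_theta(matrix(4L, 1), list(a = 2, b = list(c(-1, 0, 1))),
                   n_quad = 2001)
  expect_equal(est$theta, oracle_eap(4L, 2, list(c(-1, 0, 1))),
               tolerance = 1e-4)
  expect_error(eap_theta(matrix(NA_integer_, 1, 2), fit), "non-missing")
})

test_that("GRM fitting recovers generating parameters and is deterministic", {
  bank <- fixed_bank(5, 5)
  dat <- clean_grm_responses(2000, bank, seed = 31)
  y <- responses_to_wide(dat$responses)
  fit <- fit_grm(y, se = "none", fit_stats = FALSE)
  expect_true(fit$converged)
  true_a <- bank$a
  true_b <- lapply(seq_len(5), function(j) as.numeric(bank[j, paste0("b", 1:4)]))
  mae_a <- mean(abs(fit$a - true_a))
  mae_b <- mean(abs(unlist(fit$b) - unlist(true_b)))
  expect_lt(mae_a, 0.15)
  expect_lt(mae_b, 0.15)
  # determinism: same data, same quadrature -> identical logLik
  fit2 <- fit_grm(y, se = "none", fit_stats = FALSE)
  expect_equal(fit$logLik, fit2$logLik, tolerance = 1e-6)
  # thresholds strictly increasing for every item
  for (b in fit$b) expect_true(all(diff(b) > 0))
})

test_that("statistically identical items get near-equal estimates", {
  bank <- fixed_bank(3, 4)
  dat <- clean_grm_responses(600, bank, seed = 77)
  y <- responses_to_wide(dat$responses)
  y <- cbind(y, twin = y[, 3])      # exact duplicate of item 3
  fit <- fit_grm(y, se = "none", fit_stats = FALSE)
  expect_lt(abs(fit$a[3] - fit$a[4]), 1e-4)
  expect_lt(max(abs(fit$b[[3]] - fit$b[[4]])), 1e-4)
})

test_that("single-category items are refused and reverse keying is audited", {
  y <- cbind(rep(2L, 50), sample(1:4, 50, TRUE))
  expect_error(fit_grm(y, se = "none", fit_stats = FALSE), "single observed")
  # reverse-keyed second item
  bank <- fixed_bank(3, 5)
  dat <- clean_grm_responses(800, bank, seed = 5)
  y <- responses_to_wide(dat$responses)
  y[, 2] <- 6L - y[, 2]
  fit <- fit_grm(y, se = "none", fit_stats = FALSE)
  expect_true(fit$reversed[2])
  expect_false(any(fit$reversed[c(1, 3)]))
  expect_true(all(fit$a > 0))
})

test_that("standard errors and the SRMR-style summary are produced", {
  bank <- fixed_bank(4, 4)
  dat <- clean_grm_responses(600, bank, seed = 9)
  y <- responses_to_wide(dat$responses)
  fit <- fit_grm(y, se = "hessian", fit_stats = TRUE)
  expect_true(all(is.finite(fit$se_a)))
  expect_true(all(fit$se_a > 0 & fit$se_a < 1))
  # data generated from the model: residual association summary is small
  expect_lt(fit$srmr, 0.08)
})
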