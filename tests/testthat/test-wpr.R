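test_that("cube-root transform fixes endpoints and preserves order", {
  expect_equal(cube_root_transform(0), 0)
  expect_equal(cube_root_transform(1), 1)
  expect_equal(cube_root_transform(0.729), 0.9)
  x <- sort(runif(50))
  expect_true(all(diff(cube_root_transform(x)) >= 0))
  expect_error(cube_root_transform(-0.1), "nonnegative")
  expect_error(cube_root_transform(1.1), "<= 1")
})

test_that("decile binning follows the stated partition rule", {
  x100 <- runif(100)
  d <- per_person_deciles(x100)
  s <- sort(x100)
  expect_equal(d, vapply(split(s, rep(1:10, each = 10)), mean, 1),
               ignore_attr = TRUE)
  # 102 scores: remainder to the lowest bins -> sizes 11,11,10,...,10
  x102 <- runif(102)
  d102 <- per_person_deciles(x102)
  s <- sort(x102)
  sizes <- c(11, 11, rep(10, 8))
  grp <- rep(1:10, sizes)
  expect_equal(d102, vapply(split(s, grp), mean, 1), ignore_attr = TRUE)
  # constant input -> constant deciles
  expect_equal(per_person_deciles(rep(0.3, 40)), rep(0.3, 10))
  expect_error(per_person_deciles(runif(9)), "at least 10")
  # nondecreasing by construction
  expect_true(all(diff(per_person_deciles(runif(57))) >= 0))
})

test_that("decile means are a partition average of the overall mean", {
  set.seed(31)
  for (n in c(100, 102, 57)) {
    x <- runif(n)
    d <- per_person_deciles(x)
    sizes <- rep(n %/% 10, 10)
    if (n %% 10) sizes[seq_len(n %% 10)] <- sizes[seq_len(n %% 10)] + 1L
    expect_equal(sum(d * sizes) / n, mean(x), tolerance = 1e-10)
  }
})

test_that("decile membership is the same on raw and transformed scores", {
  set.seed(32)
  x <- runif(73)
  raw_rank <- rank(x, ties.method = "first")
  tr_rank <- rank(cube_root_transform(x), ties.method = "first")
  expect_equal(raw_rank, tr_rank)
})

test_that("decile-ability correlations behave in trivial cases", {
  set.seed(33)
  err <- matrix(runif(100 * 30)^2, 100, 30,
                dimnames = list(sprintf("p%03d", 1:100), NULL))
  dec <- decile_summary(err)
  # ability identical to d10 -> r10 = 1 (self-correlation), and the
  # omnibus test rightly rejects equality of the ten correlations
  fit <- wpr_analysis(err, setNames(dec$d10, dec$person_id))
  expect_equal(unname(fit$r[10]), 1, tolerance = 1e-12)
  expect_lt(fit$wald$p, 0.05)
  # zero-variance column detection
  err0 <- err; err0[] <- 0.5
  expect_error(wpr_analysis(err0, rnorm(100)), "zero variance")
})

test_that("arctanh/tanh round trip and Wald contrast invariance hold", {
  r <- c(-0.9, -0.3, 0, 0.4, 0.85)
  expect_equal(tanh(atanh(r)), r, tolerance = 1e-12)
  set.seed(34)
  err <- matrix(runif(300 * 40), 300, 40)
  ab <- rnorm(300) - 0.3 * rowMeans(err)
  fit <- wpr_analysis(err, ab)
  # recompute the Wald statistic with a deviation-from-mean contrast
  z <- atanh(fit$r)
  Vz <- fit$cov_z
  C2 <- diag(10) - 1 / 10
  C2 <- C2[1:9, ]                      # full-rank deviation basis
  stat2 <- drop(crossprod(C2 %*% z, solve(C2 %*% Vz %*% t(C2), C2 %*% z)))
  expect_equal(fit$wald$statistic, stat2, tolerance = 1e-8)
})

test_that("identical decile vectors give a null omnibus and pairwise tests", {
  set.seed(35)
  base <- runif(50)
  D <- matrix(base, 50, 10)           # all deciles identical across persons
  ab <- rnorm(50)
  r <- drop(cor(D, ab))
  V <- diag(1e-4, 10)
  V[] <- 1e-4                          # perfectly dependent correlations
  diag(V) <- 1e-4
  test <- tryCatch(wald_equality_test(r, V), error = function(e) e)
  # a perfectly singular contrast covariance is refused with advice
  expect_true(inherits(test, "error"))
  expect_match(conditionMessage(test), "bootstrap")
  # identical correlations: all pairwise differences 0, p = 1
  pw <- pairwise_delta_tests(r, diag(0.01, 10) + 0.005)
  expect_true(all(pw$diff_z == 0))
  expect_true(all(pw$p == 1))
})

test_that("delta-method SEs agree with the person bootstrap", {
  set.seed(36)
  n <- 1200
  err <- matrix(runif(n * 40), n, 40)
  ab <- rnorm(n) - 0.5 * rowMeans(err) - 0.8 * apply(err, 1, max)
  fit_d <- wpr_analysis(err, ab, cov_method = "influence")
  fit_b <- wpr_analysis(err, ab, cov_method = "bootstrap", bootstrap_n = 400)
  se_d <- sqrt(diag(fit_d$cov_r))
  se_b <- sqrt(diag(fit_b$cov_r))
  expect_lt(max(abs(se_d - se_b) / se_b), 0.25)
  # and the two covariance choices agree on the omnibus conclusion
  expect_equal(fit_d$wald$p < 0.05, fit_b$wald$p < 0.05)
})

test_that("retest correlations hit the trivial endpoints", {
  set.seed(37)
  e1 <- data.frame(person_id = rep(sprintf("p%02d", 1:50), each = 20),
                   wave = 1L, error = runif(1000))
  e2 <- e1; e2$wave <- 2L               # identical wave data
  rt <- retest_correlations(rbind(e1, e2), deciles = FALSE)
  expect_equal(rt$r_mean, 1, tolerance = 1e-12)
  e3 <- e1; e3$wave <- 2L; e3$error <- runif(1000)  # independent waves
  rt3 <- retest_correlations(rbind(e1, e3), deciles = FALSE)
  expect_lt(abs(rt3$r_mean), 0.3)
  e4 <- e3; e4$person_id <- sprintf("q%02d", rep(1:50, each = 20))
  expect_error(retest_correlations(rbind(e1, e4), deciles = FALSE),
               "overlap")
  expect_error(retest_correlations(e1), "2 waves")
})

test_that("multi-wave scored data give attenuated positive retest correlations", {
  cfg <- sim_config(n_persons = 500, scale_sizes = rep(5, 5), categories = 5,
                    n_waves = 2, wave_retest_corr = 0.7, missing_rate = 0,
                    rng_seed = 71)
  sim <- simulate_study(cfg)
  sc <- score_scales(sim$responses)
  rt <- retest_correlations(sc$error_scores)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$n, 500L)
  # stability flows only through the retest-correlated person latents, so
  # the observed correlation is positive but attenuated below the latent one
  expect_gt(rt$r_mean, 0)
  expect_lt(rt$r_mean, 0.7)
  dcols <- paste0("r_d", 1:10)
  expect_true(all(dcols %in% names(rt)))
  expect_true(all(abs(unlist(rt[dcols])) <= 1))
})
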