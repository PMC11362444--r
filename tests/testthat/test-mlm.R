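# brute-force marginal Gaussian log-likelihood with dense per-person
# covariance assembly — the independent oracle for the mixed-model engine
oracle_mlm_loglik <- function(data, gamma, T2, sigma2) {
  ll <- 0
  for (d in split(data, data$person_id)) {
    X <- cbind(1, d$ability, d$complexity, d$ability * d$complexity)
    Z <- cbind(1, d$complexity)
    V <- Z %*% T2 %*% t(Z) + sigma2 * diag(nrow(d))
    r <- d$error - drop(X %*% gamma)
    ll <- ll - 0.5 * (nrow(d) * log(2 * pi) +
                        determinant(V)$modulus[1] +
                        drop(crossprod(r, solve(V, r))))
  }
  ll
}

test_that("engine log-likelihood matches a dense-covariance oracle", {
  s <- simulate_tch_data(n_persons = 20, n_items = 12, seed = 41)
  fit <- fit_moderated_mlm(s$data)
  ll_oracle <- oracle_mlm_loglik(s$data, fit$gamma, fit$T, fit$sigma2)
  expect_equal(fit$logLik, ll_oracle, tolerance = 1e-6)
})

test_that("engine agrees with an established mixed-model ML fit", {
  skip_if_not_installed("lme4")
  s <- simulate_tch_data(n_persons = 250, n_items = 30, seed = 42)
  fit <- fit_moderated_mlm(s$data)
  lf <- suppressWarnings(
    lme4::lmer(error ~ ability * complexity +
                 (1 + complexity | person_id),
               data = s$data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")))
  expect_equal(fit$logLik, as.numeric(logLik(lf)), tolerance = 1e-4)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(lf)), tolerance = 1e-4)
  vc <- lme4::VarCorr(lf)$person_id
  expect_equal(fit$T[1, 1], vc[1, 1], tolerance = 1e-3)
  expect_equal(fit$T[2, 2], vc[2, 2], tolerance = 1e-3)
})

test_that("null effects are recovered as null", {
  s <- simulate_tch_data(n_persons = 600, n_items = 40,
                         gamma = c(0.45, 0, 0.012, 0), seed = 43)
  fit <- fit_moderated_mlm(s$data)
  expect_lt(abs(fit$gamma["ability"]), 2 * fit$se["ability"] + 1e-12)
  expect_lt(abs(fit$gamma["ability:complexity"]),
            2 * fit$se["ability:complexity"] + 1e-12)
})

test_that("unbalanced designs (missing items) are handled", {
  s <- simulate_tch_data(n_persons = 200, n_items = 20, seed = 44)
  drop_idx <- sample(nrow(s$data), 600)
  d <- s$data[-drop_idx, ]
  fit <- fit_moderated_mlm(d)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, nrow(d))
  # oracle check on the reduced data too
  expect_equal(fit$logLik,
               oracle_mlm_loglik(d, fit$gamma, fit$T, fit$sigma2),
               tolerance = 1e-6)
})

test_that("sandwich SEs are positive and near bootstrap SEs", {
  set.seed(45)
  s <- simulate_tch_data(n_persons = 800, n_items = 30, seed = 45)
  fit <- fit_moderated_mlm(s$data)
  expect_true(all(fit$se > 0))
  ids <- unique(s$data$person_id)
  B <- 120
  boot <- matrix(NA_real_, B, 4)
  blocks <- split(s$data, s$data$person_id)
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    db <- do.call(rbind, Map(function(pid, k) {
      d <- blocks[[pid]]; d$person_id <- paste0(d$person_id, "_", k); d
    }, take, seq_along(take)))
    boot[b, ] <- coef(fit_moderated_mlm(db, n_restarts = 0))
  }
  se_boot <- apply(boot, 2, sd)
  expect_lt(max(abs(fit$se - se_boot) / se_boot), 0.3)
})

test_that("basis reparameterization is likelihood-equivalent and maps back", {
  s <- simulate_tch_data(n_persons = 400, n_items = 30, seed = 46)
  mod <- fit_moderated_mlm(s$data)
  bas <- fit_basis_mlm(s$data)
  expect_equal(bas$logLik_conditional, mod$logLik, tolerance = 1e-4)
  # basis weights: complexity 0 -> (1, 0); complexity 9 -> (0, 1)
  expect_equal((9 - 0) / 9, 1)
  expect_equal(0 / 9, 0)
  # mean mapping: g00_low = g00; g10_high = g00 + 9 * g10
  expect_equal(unname(bas$gamma["g00_low"]), unname(mod$gamma["(Intercept)"]),
               tolerance = 1e-3)
  expect_equal(unname(bas$gamma["g10_high"]),
               unname(mod$gamma["(Intercept)"] + 9 * mod$gamma["complexity"]),
               tolerance = 1e-2)
  # ability margin is saturated Gaussian: joint = conditional + margin
  a_i <- tapply(s$data$ability, s$data$person_id, `[`, 1)
  llm <- sum(dnorm(a_i, mean(a_i), sqrt(mean((a_i - mean(a_i))^2)), log = TRUE))
  expect_equal(bas$logLik, bas$logLik_conditional + llm, tolerance = 1e-8)
})

test_that("basis model recovers a known slope-ability correlation", {
  # truth: corr(u1, ability) at the high-complexity end
  n <- 3000; J <- 40
  set.seed(47)
  a <- rnorm(n, 0, 4)
  tau11 <- 4e-4
  target <- -0.40
  g11 <- target * sqrt(tau11 / (1 - target^2)) / 4   # slope per ability unit
  s <- simulate_tch_data(n_persons = n, n_items = J,
                         gamma = c(0.45, 0, 0.03, g11),
                         T2 = diag(c(0.01, tau11 * (1 - target^2))),
                         sigma2 = 0.03, ability_sd = 4, seed = 47)
  bas <- fit_basis_mlm(s$data)
  # implied corr(beta1, ability): g11 * sd(a) / sd(beta1)
  sd_b1 <- sqrt(g11^2 * 16 + tau11 * (1 - target^2))
  implied <- g11 * 4 / sd_b1
  # slope = (u_high - u_low)/9, so its moments derive from Psi
  slope_var <- (bas$Psi[1, 1] + bas$Psi[2, 2] - 2 * bas$Psi[1, 2]) / 81
  slope_ab_cov <- (bas$Psi[2, 3] - bas$Psi[1, 3]) / 9
  est <- slope_ab_cov / sqrt(slope_var * bas$Psi[3, 3])
  expect_equal(est, implied, tolerance = 0.05)
})

test_that("binned model tracks the linear model on linear truth", {
  s <- simulate_tch_data(n_persons = 1000, n_items = 50,
                         gamma = c(0.45, -0.005, 0.012, -0.004), seed = 48)
  lin <- fit_moderated_mlm(s$data)
  bin <- fit_binned_mlm(s$data)
  # monotone increase of |ability slope| across bins
  sl <- bin$ability_slopes
  expect_true(all(diff(abs(sl)) > 0))
  expect_true(all(bin$percent_change[-1] > 0))
  # bin-model predictions at bin midpoints vs linear-model predictions
  mids <- c(0.5, 2.5, 4.5, 6.5, 8.5)
  ab <- seq(-8, 8, by = 2)
  grid <- expand.grid(ability = ab, bin = seq_along(mids))
  grid$mid <- mids[grid$bin]
  pred_lin <- lin$gamma[1] + lin$gamma[2] * grid$ability +
    lin$gamma[3] * grid$mid + lin$gamma[4] * grid$ability * grid$mid
  pred_bin <- bin$gamma[grid$bin] +
    bin$gamma[5 + grid$bin] * grid$ability
  expect_gt(cor(pred_lin, pred_bin), 0.99)
})

test_that("degenerate binned designs collapse gracefully", {
  s <- simulate_tch_data(n_persons = 100, n_items = 15,
                         complexity = rep(1, 15), seed = 49)
  expect_error(fit_moderated_mlm(s$data), "vary")
  s$data$complexity <- rep(c(0, 1), length.out = nrow(s$data))
  # all items in bin 1: contrasts undefined, reported as such
  expect_warning(bin <- fit_binned_mlm(s$data), "one complexity bin")
  expect_true(is.na(bin$percent_change))
})

test_that("interaction coverage is near nominal", {
  # reduced-replicate coverage study for the cross-level interaction
  set.seed(50)
  B <- 60
  hit <- logical(B)
  for (b in seq_len(B)) {
    s <- simulate_tch_data(n_persons = 400, n_items = 40,
                           gamma = c(0.45, -0.01, 0.012, -0.003),
                           ability_sd = 4)
    f <- fit_moderated_mlm(s$data, n_restarts = 0)
    ci <- f$gamma[4] + c(-1.96, 1.96) * f$se[4]
    hit[b] <- ci[1] <= -0.003 && -0.003 <= ci[2]
  }
  expect_gte(mean(hit), 0.85)
})

test_that("scale-level meta-correlation matches a hand-computed value", {
  set.seed(51)
  n <- 300; n_scales <- 21
  sc_cx <- round(runif(n_scales, 0, 9))
  rows <- list()
  ability <- rnorm(n)
  for (s in seq_len(n_scales)) {
    pm <- -0.03 * sc_cx[s] * ability + rnorm(n)
    pm <- (pm - min(pm)) / (max(pm) - min(pm))   # into [0, 1]
    for (j in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = sprintf("p%03d", 1:n),
        scale_id = sprintf("s%02d", s),
        item_id = sprintf("s%02d_i%d", s, j),
        error = pm)
  }
  errors <- do.call(rbind, rows)
  cxt <- unique(errors[c("item_id", "scale_id")])
  cxt$composite <- sc_cx[as.integer(sub("s", "", cxt$scale_id))]
  sl <- scale_level_correlation(errors, cxt,
                                data.frame(person_id = sprintf("p%03d", 1:n),
                                           ability = ability),
                                transform = "none")
  # spreadsheet-style oracle on the 21-row table
  oracle <- cor(sl$table$mean_complexity, sl$table$r_ability)
  expect_equal(sl$meta_r, oracle, tolerance = 1e-12)
  expect_lt(sl$meta_r, 0)           # complexity amplifies the negative link
  # identical complexity across scales -> undefined meta-correlation
  cxt0 <- cxt; cxt0$composite <- 3
  expect_warning(sl0 <- scale_level_correlation(
    errors, cxt0, data.frame(person_id = sprintf("p%03d", 1:n),
                             ability = ability), transform = "none"),
    "undefined")
  expect_true(is.na(sl0$meta_r))
})
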