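test_that("config validation catches invalid settings", {
  expect_error(sim_config(n_persons = 1), "n_persons")
  expect_error(sim_config(ability_theta_corr = 1.2), "ability_theta_corr")
  expect_error(sim_config(categories = 8), "3\\.\\.7")
  expect_error(sim_config(categories = 2), "3\\.\\.7")
  expect_error(sim_config(n_waves = 0), "n_waves")
  expect_error(sim_config(wave_retest_corr = -0.1), "wave_retest_corr")
  expect_error(sim_config(complexity_prob = rep(0.1, 9)), "complexity_prob")
})

test_that("item banks have valid parameters and consistent complexity", {
  set.seed(1)
  cfg <- sim_config(n_persons = 10)
  bank <- generate_item_bank(cfg)
  expect_equal(nrow(bank), 102L)
  expect_true(all(bank$a > 0))
  expect_true(all(bank$n_categories %in% 3:7))
  for (i in seq_len(nrow(bank))) {
    b <- as.numeric(bank[i, paste0("b", seq_len(bank$n_categories[i] - 1L))])
    expect_false(anyNA(b))
    expect_true(all(diff(b) > 0))
  }
  ind <- c("WC", "DC", "UTT", "VRT", "VNP", "CON", "NEG", "DIS", "TEN", "EXC")
  expect_equal(unname(rowSums(bank[ind])), bank$complexity)
  expect_true(all(bank$complexity %in% 0:9))
  # fixed category count -> m - 1 thresholds everywhere
  bank5 <- generate_item_bank(sim_config(n_persons = 10, categories = 5))
  expect_true(all(!is.na(bank5$b4)) && all(is.na(bank5$b5)))
  # degenerate complexity distribution
  bank0 <- generate_item_bank(
    sim_config(n_persons = 10, complexity_prob = c(1, rep(0, 9))))
  expect_true(all(bank0$complexity == 0L))
})

test_that("person latents have the configured ability-trait correlation", {
  set.seed(2)
  cfg0 <- sim_config(n_persons = 10000, scale_sizes = rep(4, 3),
                     ability_theta_corr = 0)
  p0 <- generate_persons(cfg0)
  expect_lt(max(abs(cor(p0$persons$g, p0$thetas))), 0.05)
  cfg5 <- sim_config(n_persons = 10000, scale_sizes = rep(4, 3),
                     ability_theta_corr = 0.5)
  p5 <- generate_persons(cfg5)
  expect_true(all(abs(cor(p5$persons$g, p5$thetas) - 0.5) < 0.03))
})

test_that("cognitive subtests respect their ranges and load on ability", {
  set.seed(3)
  cfg <- sim_config(n_persons = 10000)
  p <- generate_persons(cfg)
  ct <- generate_cognitive_subtests(p, cfg)
  expect_true(all(ct$imm_recall %in% 0:10))
  expect_true(all(ct$del_recall %in% 0:10))
  expect_true(all(ct$serial7 %in% 0:5))
  expect_true(all(ct$backward %in% 0:2))
  expect_true(all(ct$composite >= 0 & ct$composite <= 27))
  expect_gt(cor(ct$composite, p$persons$g), 0.5)
  # composite bounds are attained exactly at the subtest extremes
  expect_equal(10 + 10 + 5 + 2, 27)
  # recall subtests share residual variance beyond the factor
  pr <- residuals(lm(cbind(imm_recall, del_recall) ~ p$persons$g, data = ct))
  expect_gt(cor(pr[, 1], pr[, 2]), 0.1)
})

test_that("responses are valid draws and lapses depend on ability", {
  cfg <- sim_config(n_persons = 3000, scale_sizes = rep(4, 4), categories = 5,
                    missing_rate = 0, rng_seed = 4)
  set.seed(4)
  p <- generate_persons(cfg)
  bank <- generate_item_bank(cfg)
  resp <- generate_responses(p, bank, cfg)
  expect_true(all(resp$response %in% 1:5))
  # lapse rate decreasing in g (negative ability slope)
  lr <- tapply(resp$lapse, cut(p$persons$g[match(resp$person_id,
                                                 p$persons$person_id)],
                               quantile(p$persons$g, 0:4 / 4),
                               include.lowest = TRUE), mean)
  expect_true(lr[1] > lr[4])
  expect_true(all(diff(lr) < 0.05))   # roughly monotone decreasing
  # scale-id mismatch is an error
  bank_bad <- bank
  bank_bad$scale_id <- "nope"
  expect_error(generate_responses(p, bank_bad, cfg), "scale ids")
  # lapse probability zero -> pure GRM draws
  cfg0 <- sim_config(n_persons = 500, scale_sizes = rep(4, 2),
                     lapse_intercept = -30, missing_rate = 0, rng_seed = 5)
  set.seed(5)
  p0 <- generate_persons(cfg0)
  r0 <- generate_responses(p0, generate_item_bank(cfg0), cfg0)
  expect_equal(sum(r0$lapse), 0L)
})

test_that("same seed and config give identical outputs", {
  cfg <- sim_config(n_persons = 60, scale_sizes = rep(3, 3), rng_seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$items, s2$items)
  expect_identical(s1$cognition, s2$cognition)
})

test_that("multi-wave panels attenuate across-wave error correlations", {
  mean_err_by_wave <- function(retest) {
    cfg <- sim_config(n_persons = 1500, scale_sizes = rep(5, 3),
                      categories = 5, n_waves = 2, wave_retest_corr = retest,
                      missing_rate = 0, rng_seed = 17)
    sim <- simulate_study(cfg)
    # person mean of a cheap error proxy: the lapse indicator itself
    m <- tapply(sim$responses$lapse,
                list(sim$responses$person_id, sim$responses$wave), mean)
    cor(m[, 1], m[, 2])
  }
  r1 <- mean_err_by_wave(1)
  r0 <- mean_err_by_wave(0)
  r7 <- mean_err_by_wave(0.7)
  expect_gt(r1, r7)          # perfectly stable latents correlate highest
  expect_lt(abs(r0), 0.08)   # independent waves are uncorrelated
  expect_gt(r7, 0.05)        # stable case sits between, attenuated below .7
  expect_lt(r7, 0.7)
})
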