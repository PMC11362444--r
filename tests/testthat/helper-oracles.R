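# Independent oracles and small fixture builders shared across tests.

# brute-force GRM category probabilities: direct two-logistic differences
oracle_grm_prob <- function(theta, a, b) {
  m <- length(b) + 1L
  cum <- c(1, 1 / (1 + exp(-a * (theta - b))), 0)
  cum[seq_len(m)] - cum[seq_len(m) + 1L]
}

# brute-force expected score and response-error statistic
oracle_expected <- function(theta, a, b) {
  p <- oracle_grm_prob(theta, a, b)
  sum(seq_along(p) * p)
}
oracle_error <- function(y, theta, a, b)
  abs(y - oracle_expected(theta, a, b)) / length(b)

# dense-grid numerical EAP (2001 nodes)
oracle_eap <- function(y, a_vec, b_list, n_grid = 2001L) {
  th <- seq(-6, 6, length.out = n_grid)
  w <- dnorm(th); w <- w / sum(w)
  ll <- rep(0, n_grid)
  for (j in seq_along(y)) {
    if (is.na(y[j])) next
    pj <- t(vapply(th, oracle_grm_prob, numeric(length(b_list[[j]]) + 1L),
                   a = a_vec[j], b = b_list[[j]]))
    ll <- ll + log(pj[, y[j]])
  }
  post <- w * exp(ll - max(ll))
  post <- post / sum(post)
  sum(th * post)
}

# item bank with fixed, well-spread parameters for recovery studies
fixed_bank <- function(n_items = 5L, m = 5L, scale_id = "s01") {
  a <- seq(1.1, 2.0, length.out = n_items)
  shift <- seq(-0.5, 0.5, length.out = n_items)
  rows <- lapply(seq_len(n_items), function(j) {
    b <- seq(-1.5, 1.5, length.out = m - 1L) + shift[j]
    bpad <- rep(NA_real_, 6); bpad[seq_len(m - 1L)] <- b
    data.frame(item_id = sprintf("%s_i%d", scale_id, j), scale_id = scale_id,
               n_categories = m, a = a[j], b1 = bpad[1], b2 = bpad[2],
               b3 = bpad[3], b4 = bpad[4], b5 = bpad[5], b6 = bpad[6],
               item_text = "placeholder", WC = 0L, DC = 0L, UTT = 0L,
               VRT = 0L, VNP = 0L, CON = 0L, NEG = 0L, DIS = 0L, TEN = 0L,
               EXC = 0L, complexity = 0L)
  })
  do.call(rbind, rows)
}

# clean (uncontaminated, complete) responses from a fixed bank
clean_grm_responses <- function(n_persons, bank, seed = 1L) {
  cfg <- sim_config(n_persons = n_persons,
                    scale_sizes = as.vector(table(bank$scale_id)),
                    categories = bank$n_categories[1],
                    lapse_intercept = -30, missing_rate = 0, rng_seed = seed)
  set.seed(seed)
  persons <- generate_persons(cfg)
  list(responses = generate_responses(persons, bank, cfg),
       persons = persons, config = cfg)
}
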