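#' Configuration for the synthetic questionnaire study generator
#'
#' Defines the statistical structure of a simulated multi-scale, multi-wave
#' questionnaire study with ability-dependent attentional-lapse
#' contamination. Defaults emulate the shape of a large panel study's
#' self-administered questionnaire battery: 21 scales totalling 102 items with 3-7
#' items each, 3-7 ordinal categories, four cognitive subtests (0-10, 0-10,
#' 0-5, 0-2) loading on a latent general-ability factor with a residual
#' correlation between the two recall subtests, and integer item complexity
#' 0-9 drawn from a beta-binomial chosen to give a realistic mean near 3.3
#' and SD near 2.5.
#'
#' The lapse mechanism: on each person-item encounter, with probability
#' `plogis(lapse_intercept + lapse_ability_slope * g + lapse_complexity_slope
#' * complexity + lapse_interaction * g * complexity + person_offset)` the
#' response is drawn off-model (uniformly over the categories, or from the
#' endpoints if `lapse_mode = "extreme"`); otherwise it is a graded response
#' model draw at the person's scale trait.
#'
#' @param n_persons number of persons (>= 2).
#' @param scale_sizes integer vector of items per scale (each in 3..7), or a
#'   single count. The default is a 21-scale composition totalling 102 items.
#' @param categories number of ordinal categories per scale: a single value
#'   in 3..7, a vector per scale, or the default `NULL` which samples 3-7
#'   with 5 most likely.
#' @param ability_theta_corr correlation in `[-1, 1]` between general ability
#'   `g` and each scale's latent trait.
#' @param lapse_intercept,lapse_ability_slope,lapse_complexity_slope,lapse_interaction
#'   log-odds coefficients of the lapse model (intercept; per ability SD; per
#'   complexity unit; per ability x complexity unit).
#' @param lapse_person_sd SD of the person-level lapse-propensity offset.
#' @param lapse_mode `"uniform"` (default) or `"extreme"` contamination.
#' @param complexity_prob probability weights over integer complexities 0..9;
#'   `NULL` uses the beta-binomial default.
#' @param recall_residual_corr residual correlation between the two recall
#'   subtests beyond the common factor.
#' @param missing_rate response-level missingness probability.
#' @param n_waves number of assessment waves.
#' @param wave_retest_corr across-wave correlation of person latents
#'   (compound-symmetric; requires a value in `[0, 1]`).
#' @param rng_seed integer seed; the single RNG stream drives all stages.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_persons = 2000L,
                       scale_sizes = c(5, 5, 6, 4, 3, 4, 4, 5, 5, 4, 5,
                                       3, 4, 5, 5, 5, 7, 7, 5, 4, 7),
                       categories = NULL,
                       ability_theta_corr = 0.2,
                       lapse_intercept = -2.8,
                       lapse_ability_slope = -0.5,
                       lapse_complexity_slope = 0.15,
                       lapse_interaction = -0.08,
                       lapse_person_sd = 0.7,
                       lapse_mode = c("uniform", "extreme"),
                       complexity_prob = NULL,
                       recall_residual_corr = 0.4,
                       missing_rate = 0.03,
                       n_waves = 1L,
                       wave_retest_corr = 0.7,
                       rng_seed = 1L) {
  lapse_mode <- match.arg(lapse_mode)
  if (length(scale_sizes) == 1L) scale_sizes <- rep(scale_sizes, 1L)
  if (n_persons < 2) stop("n_persons must be >= 2")
  if (any(scale_sizes < 2)) stop("scales need at least 2 items")
  if (abs(ability_theta_corr) > 1) stop("ability_theta_corr must be in [-1, 1]")
  if (wave_retest_corr < 0 || wave_retest_corr > 1)
    stop("wave_retest_corr must be in [0, 1]")
  if (n_waves < 1) stop("n_waves must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(categories)) {
    if (length(categories) == 1L) categories <- rep(categories, length(scale_sizes))
    if (length(categories) != length(scale_sizes))
      stop("categories must have length 1 or length(scale_sizes)")
    if (any(categories < 3 | categories > 7))
      stop("category counts must be in 3..7")
  }
  if (!is.null(complexity_prob)) {
    if (length(complexity_prob) != 10L || any(complexity_prob < 0))
      stop("complexity_prob must be 10 nonnegative weights over 0..9")
  }
  out <- list(n_persons = as.integer(n_persons), scale_sizes = as.integer(scale_sizes),
              categories = categories, ability_theta_corr = ability_theta_corr,
              lapse_intercept = lapse_intercept,
              lapse_ability_slope = lapse_ability_slope,
              lapse_complexity_slope = lapse_complexity_slope,
              lapse_interaction = lapse_interaction,
              lapse_person_sd = lapse_person_sd, lapse_mode = lapse_mode,
              complexity_prob = complexity_prob,
              recall_residual_corr = recall_residual_corr,
              missing_rate = missing_rate, n_waves = as.integer(n_waves),
              wave_retest_corr = wave_retest_corr, rng_seed = as.integer(rng_seed))
  class(out) <- "sim_config"
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study config: ", x$n_persons, " persons, ",
      length(x$scale_sizes), " scales / ", sum(x$scale_sizes), " items, ",
      x$n_waves, " wave(s)\n", sep = "")
  cat("Lapse model: logit^-1(", x$lapse_intercept, " + ", x$lapse_ability_slope,
      "*g + ", x$lapse_complexity_slope, "*cx + ", x$lapse_interaction,
      "*g*cx + offset), mode = ", x$lapse_mode, "\n", sep = "")
  invisible(x)
}

# draw integer complexities 0..9
draw_complexity <- function(n, config) {
  if (!is.null(config$complexity_prob)) {
    sample(0:9, n, replace = TRUE, prob = config$complexity_prob)
  } else {
    # beta-binomial(9, 1.05, 1.85): mean ~3.26, SD ~2.5
    rbinom(n, 9L, rbeta(n, 1.05, 1.85))
  }
}

#' Generate an item bank with complexity profiles
#'
#' Draws GRM item parameters (lognormal discriminations around 1.5, strictly
#' ordered thresholds) and assigns each item an integer complexity 0-9 with a
#' consistent binary indicator vector summing to that value. Item text is
#' constructed so that the text-derived indicators (WC, DC, CON, NEG, DIS,
#' TEN, EXC) recode exactly to the generating values with the shipped
#' lexicons; the three clarity flags (UTT, VRT, VNP) are emitted as
#' precomputed columns.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per item: `item_id, scale_id,
#'   n_categories, a, b1..b6, item_text, WC, DC, UTT, VRT, VNP, CON, NEG,
#'   DIS, TEN, EXC, complexity`.
#' @export
generate_item_bank <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  S <- length(config$scale_sizes)
  cats <- config$categories
  if (is.null(cats))
    cats <- sample(3:7, S, replace = TRUE, prob = c(.15, .2, .35, .2, .1))
  rows <- list()
  for (s in seq_len(S)) {
    for (j in seq_len(config$scale_sizes[s])) {
      m <- cats[s]
      a <- exp(rnorm(1, log(1.5), 0.25))
      b1 <- rnorm(1, qnorm(1 / m), 0.4)
      gaps <- 0.25 + rexp(m - 2L, 1.5)
      b <- b1 + c(0, cumsum(gaps))
      cx <- draw_complexity(1L, config)
      ind <- complexity_indicator_vector(cx)
      bpad <- rep(NA_real_, 6); bpad[seq_len(m - 1)] <- b
      rows[[length(rows) + 1L]] <- data.frame(
        item_id = sprintf("s%02d_i%d", s, j),
        scale_id = sprintf("s%02d", s), n_categories = m, a = a,
        b1 = bpad[1], b2 = bpad[2], b3 = bpad[3], b4 = bpad[4],
        b5 = bpad[5], b6 = bpad[6],
        item_text = synth_item_text(ind),
        WC = ind[1], DC = ind[2], UTT = ind[3], VRT = ind[4], VNP = ind[5],
        CON = ind[6], NEG = ind[7], DIS = ind[8], TEN = ind[9], EXC = ind[10],
        complexity = cx)
    }
  }
  do.call(rbind, rows)
}

# random indicator vector (WC, DC, UTT, VRT, VNP, CON, NEG, DIS, TEN, EXC)
# summing to the target complexity
complexity_indicator_vector <- function(cx) {
  ind <- integer(10)
  if (cx > 0) ind[sample.int(10, cx)] <- 1L
  ind
}

# words guaranteed on the shipped easy-word list and in no tagged category
.filler <- c("i", "feel", "good", "about", "my", "life", "these", "days",
             "people", "around", "here", "are", "friendly", "to", "me")
# off-list words guaranteed absent from every shipped lexicon
.offlist <- c("quixotic", "zeitgeist")
# single-category trigger words (each on the easy-word list)
.trigger <- c(CON = "because", NEG = "never", DIS = "should",
              TEN = "maybe", EXC = "else")

# build item text whose auto-coded indicators equal the generating vector:
# two easy filler words, category triggers / off-list words as required, then
# padded with filler to >= 10 words iff the word-count indicator is set
# (maximum without padding is 2 + 2 + 5 = 9 words, so WC stays 0)
synth_item_text <- function(ind) {
  words <- .filler[1:2]
  if (ind[2] == 1L) words <- c(words, .offlist)
  for (k in 6:10) if (ind[k] == 1L) words <- c(words, .trigger[[k - 5L]])
  if (ind[1] == 1L) {
    need <- max(0L, 10L - length(words))
    words <- c(words, .filler[2L + seq_len(need)])
  }
  paste(words, collapse = " ")
}

#' Generate true person records
#'
#' Draws general ability `g ~ N(0,1)`, per-scale latent traits correlated
#' with `g` at the configured level, a person-level lapse-propensity offset,
#' and the latent ingredients of the cognitive subtests (a shared recall
#' residual plus unique noise per subtest).
#'
#' @param config a [sim_config()].
#' @return list with `persons` (data.frame `person_id, g, lapse_offset`),
#'   `thetas` (matrix persons x scales), and `recall_resid` (vector).
#' @export
generate_persons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_persons; S <- length(config$scale_sizes)
  g <- rnorm(n)
  rho <- config$ability_theta_corr
  th <- rho * g + sqrt(1 - rho^2) * matrix(rnorm(n * S), n, S)
  colnames(th) <- sprintf("s%02d", seq_len(S))
  list(persons = data.frame(person_id = sprintf("p%05d", seq_len(n)),
                            g = g, lapse_offset = rnorm(n, 0, config$lapse_person_sd)),
       thetas = th)
}

#' Generate cognitive subtests and the ability composite
#'
#' Four subtests (immediate recall 0-10, delayed recall 0-10, serial-7s 0-5,
#' backward counting 0-2) are truncated-and-rounded linear transforms of
#' general ability, with a shared residual between the two recall subtests.
#' The composite is their sum, bounded 0-27.
#'
#' @param persons output of [generate_persons()] (or a data.frame with a `g`
#'   column).
#' @param config a [sim_config()].
#' @return data.frame `person_id, imm_recall, del_recall, serial7, backward,
#'   composite`.
#' @export
generate_cognitive_subtests <- function(persons, config) {
  df <- if (is.data.frame(persons)) persons else persons$persons
  g <- df$g; n <- length(g)
  rc <- config$recall_residual_corr
  shared <- rnorm(n)
  mk <- function(mu, load, sh_load, usd, lo, hi)
    pmin(pmax(round(mu + load * g + sh_load * shared + rnorm(n, 0, usd)), lo), hi)
  # shared recall residual scaled so the residual correlation between the two
  # recall subtests (given g) is approximately recall_residual_corr
  ssd <- sqrt(rc / (1 - rc)) * 1.1
  out <- data.frame(
    person_id = df$person_id,
    imm_recall = mk(5.2, 1.7, ssd, 1.1, 0, 10),
    del_recall = mk(4.6, 1.7, ssd, 1.1, 0, 10),
    serial7   = mk(3.3, 1.0, 0, 0.8, 0, 5),
    backward  = mk(1.7, 0.35, 0, 0.35, 0, 2))
  out$composite <- out$imm_recall + out$del_recall + out$serial7 + out$backward
  out
}

#' Generate contaminated GRM responses
#'
#' For each person-item pair, with the lapse probability given by the
#' configured logistic model the response is drawn off-model; otherwise it is
#' a GRM category draw at the person's latent trait for the item's scale.
#'
#' @param persons output of [generate_persons()].
#' @param item_bank output of [generate_item_bank()].
#' @param config a [sim_config()].
#' @param wave wave label stored in the output.
#' @return data.frame `person_id, wave, scale_id, item_id, response, lapse`
#'   (the true lapse indicator is kept for diagnostics; `response` is `NA`
#'   where masked missing).
#' @export
generate_responses <- function(persons, item_bank, config, wave = 1L) {
  th <- persons$thetas
  if (!all(item_bank$scale_id %in% colnames(th)))
    stop("item bank scale ids do not match person latent traits")
  df <- persons$persons
  n <- nrow(df); J <- nrow(item_bank)
  g <- df$g; off <- df$lapse_offset
  out <- vector("list", J)
  for (j in seq_len(J)) {
    it <- item_bank[j, ]
    m <- it$n_categories
    b <- as.numeric(it[paste0("b", seq_len(m - 1L))])
    theta <- th[, it$scale_id]
    eta <- config$lapse_intercept + config$lapse_ability_slope * g +
      config$lapse_complexity_slope * it$complexity +
      config$lapse_interaction * g * it$complexity + off
    lapse <- runif(n) < plogis(eta)
    # GRM draw via inverse CDF on cumulative curves
    cum <- grm_cum(theta, it$a, b)               # n x (m-1), P(Y >= k+1)
    u <- runif(n)
    yy <- 1L + rowSums(u < cum)
    nl <- sum(lapse)
    if (nl) {
      yy[lapse] <- if (config$lapse_mode == "uniform")
        sample.int(m, nl, replace = TRUE)
      else sample(c(1L, m), nl, replace = TRUE)
    }
    if (config$missing_rate > 0)
      yy[runif(n) < config$missing_rate] <- NA_integer_
    out[[j]] <- data.frame(person_id = df$person_id, wave = wave,
                           scale_id = it$scale_id, item_id = it$item_id,
                           response = yy, lapse = lapse)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$person_id, res$item_id), ]
  rownames(res) <- NULL
  res
}

#' Simulate a full study (single or multi-wave)
#'
#' Runs the whole generator under one seeded RNG stream: item bank, persons,
#' responses (per wave, with person latents compound-symmetrically correlated
#' at `wave_retest_corr` across waves), and cognitive subtests per wave.
#'
#' @param config a [sim_config()].
#' @return object of class `"resperr_sim"`: list with `items`, `persons`,
#'   `responses` (all waves stacked), `cognition` (per wave), `truth`
#'   (generating parameters), `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  items <- generate_item_bank(config)
  base <- generate_persons(config)
  rho <- config$wave_retest_corr
  n <- config$n_persons; S <- ncol(base$thetas)
  resp <- list(); cogn <- list()
  for (w in seq_len(config$n_waves)) {
    pw <- base
    if (config$n_waves > 1L) {
      # compound symmetry: latent_w = sqrt(rho)*common + sqrt(1-rho)*unique
      mix <- function(common, unique_draw) sqrt(rho) * common + sqrt(1 - rho) * unique_draw
      pw$persons$g <- mix(base$persons$g, rnorm(n))
      pw$persons$lapse_offset <- mix(base$persons$lapse_offset,
                                     rnorm(n, 0, config$lapse_person_sd))
      pw$thetas <- sqrt(rho) * base$thetas +
        sqrt(1 - rho) * (config$ability_theta_corr * pw$persons$g +
                           sqrt(1 - config$ability_theta_corr^2) *
                           matrix(rnorm(n * S), n, S))
      colnames(pw$thetas) <- colnames(base$thetas)
    }
    resp[[w]] <- generate_responses(pw, items, config, wave = w)
    cg <- generate_cognitive_subtests(pw, config)
    cg$wave <- w
    cogn[[w]] <- cg
  }
  out <- list(items = items, persons = base$persons,
              responses = do.call(rbind, resp),
              cognition = do.call(rbind, cogn),
              truth = config[setdiff(names(config), "rng_seed")],
              config = config)
  class(out) <- "resperr_sim"
  out
}

#' @export
print.resperr_sim <- function(x, ...) {
  cat("Simulated study: ", x$config$n_persons, " persons, ",
      nrow(x$items), " items in ", length(unique(x$items$scale_id)),
      " scales, ", x$config$n_waves, " wave(s)\n", sep = "")
  cat("Observed lapse rate:", round(mean(x$responses$lapse), 3),
      " missing rate:", round(mean(is.na(x$responses$response)), 3), "\n")
  invisible(x)
}

#' Write a simulated study to CSV/JSON files
#'
#' Emits `responses.csv`, `items.csv`, `cognition.csv`, `truth.json` in the
#' formats the pipeline stages read.
#'
#' @param sim a `"resperr_sim"` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(responses = file.path(dir, "responses.csv"),
             items = file.path(dir, "items.csv"),
             cognition = file.path(dir, "cognition.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(sim$responses[c("person_id", "wave", "scale_id", "item_id", "response")],
            paths["responses"], row.names = FALSE)
  write.csv(sim$items, paths["items"], row.names = FALSE)
  write.csv(sim$cognition, paths["cognition"], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
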