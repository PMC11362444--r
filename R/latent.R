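# Covariance-structure ML with structured means and missing-data pattern
# grouping. For persons sharing an observation pattern the contribution is
#   n_g [ p_g log(2pi) + log|S(th)_g| + tr(S(th)_g^-1 S_g)
#         + (xbar_g - mu_g)' S(th)_g^-1 (xbar_g - mu_g) ],
# with the mean coefficients profiled out by GLS at each evaluation.

covstruct_prepare <- function(Y, mean_design) {
  obs <- !is.na(Y)
  key <- apply(obs, 1, paste, collapse = "")
  groups <- split(seq_len(nrow(Y)), key)
  ginfo <- lapply(groups, function(idx) {
    sel <- which(obs[idx[1], ])
    Yg <- Y[idx, sel, drop = FALSE]
    n_g <- length(idx)
    xbar <- colMeans(Yg)
    S <- if (n_g > 1) crossprod(sweep(Yg, 2, xbar)) / n_g else
      matrix(0, length(sel), length(sel))
    list(sel = sel, n_g = n_g, xbar = xbar, S = S,
         D = mean_design[sel, , drop = FALSE])
  })
  list(groups = ginfo, n = nrow(Y), p = ncol(Y))
}

covstruct_neg2ll <- function(Sigma, prep, return_fit = FALSE) {
  # profile means: beta = (sum n D' Si^-1 D)^-1 sum n D' Si^-1 xbar
  qb <- ncol(prep$groups[[1]]$D)
  A <- matrix(0, qb, qb); b <- numeric(qb)
  pieces <- vector("list", length(prep$groups))
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    Sg <- Sigma[g$sel, g$sel, drop = FALSE]
    ch <- try(chol(Sg), silent = TRUE)
    if (inherits(ch, "try-error")) return(if (return_fit) NULL else 1e10)
    Si <- chol2inv(ch)
    pieces[[gi]] <- list(Si = Si, ld = 2 * sum(log(diag(ch))))
    A <- A + g$n_g * crossprod(g$D, Si %*% g$D)
    b <- b + g$n_g * drop(crossprod(g$D, Si %*% g$xbar))
  }
  beta <- try(solve(A, b), silent = TRUE)
  if (inherits(beta, "try-error")) return(if (return_fit) NULL else 1e10)
  neg2 <- 0
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    pc <- pieces[[gi]]
    mu <- drop(g$D %*% beta)
    d <- g$xbar - mu
    neg2 <- neg2 + g$n_g * (length(g$sel) * log(2 * pi) + pc$ld +
                              sum(pc$Si * g$S) + drop(crossprod(d, pc$Si %*% d)))
  }
  if (return_fit) list(neg2ll = neg2, beta = beta) else neg2
}

# constrained Cholesky for a 3x3 covariance with the last variance fixed to
# 1: rows 1-2 are a free lower-triangular block (log diagonals), row 3 is a
# unit vector parameterized by two unconstrained coordinates
psi_from_par <- function(p5) {
  L <- matrix(0, 3, 3)
  L[1, 1] <- exp(p5[1]); L[2, 1] <- p5[2]; L[2, 2] <- exp(p5[3])
  s <- sqrt(1 + p5[4]^2 + p5[5]^2)
  L[3, ] <- c(p5[4], p5[5], 1) / s
  tcrossprod(L)
}

#' One-factor model for the four cognitive subtests
#'
#' Maximum likelihood one-factor model with the factor variance fixed to 1
#' and a free residual covariance between the two recall subtests (their
#' shared memory-specific variance beyond the general factor). Residual
#' variances are bounded away from zero; a boundary solution is reported as
#' a Heywood warning. The model has 1 df against the saturated covariance
#' structure; the likelihood-ratio chi-square is reported.
#'
#' @param subtests data.frame or matrix with four numeric subtest columns
#'   (immediate recall, delayed recall, serial-7s, backward counting, in
#'   that order unless `recall_pair` says otherwise).
#' @param recall_pair indices of the two columns given a residual
#'   covariance.
#' @return object of class `"ability_cfa"`: `loadings`, `resid_var`,
#'   `recall_cov`, `means`, `chisq`, `df`, `p`, `scores` (regression factor
#'   scores), `score_se`, `logLik`, `converged`.
#' @export
fit_ability_factor <- function(subtests, recall_pair = c(1L, 2L)) {
  Y <- as.matrix(subtests[, vapply(as.data.frame(subtests), is.numeric, TRUE),
                          drop = FALSE])
  if (ncol(Y) != 4L) stop("need exactly four subtest columns")
  Y <- Y[complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  if (n < 100L) stop("need at least 100 persons")
  xbar <- colMeans(Y)
  S <- crossprod(sweep(Y, 2, xbar)) / n
  sdv <- sqrt(diag(S))
  build <- function(par) {
    lam <- par[1:4]
    th <- exp(par[5:8])
    t12 <- par[9]
    Sig <- tcrossprod(lam) + diag(th)
    Sig[recall_pair[1], recall_pair[2]] <- Sig[recall_pair[1], recall_pair[2]] + t12
    Sig[recall_pair[2], recall_pair[1]] <- Sig[recall_pair[2], recall_pair[1]] + t12
    Sig
  }
  fml <- function(par) {
    Sig <- build(par)
    ch <- try(chol(Sig), silent = TRUE)
    if (inherits(ch, "try-error")) return(1e10)
    2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S)
  }
  par0 <- c(0.7 * sdv, log(0.5 * diag(S)), 0.05 * prod(sdv[recall_pair]))
  opt <- nlminb(par0, fml, control = list(iter.max = 500))
  lam <- opt$par[1:4]
  if (sum(lam) < 0) { lam <- -lam }                    # sign convention
  th <- exp(opt$par[5:8])
  heywood <- any(th < 1e-4 * diag(S))
  if (heywood) warning("near-zero residual variance (Heywood case)")
  Sig <- build(c(lam, log(th), opt$par[9]))
  # LR chi-square vs saturated covariance (means saturated in both)
  F_ml <- fml(opt$par) - (2 * sum(log(diag(chol(S)))) + 4)
  chisq <- n * F_ml
  # regression factor scores
  Si <- solve(Sig)
  wts <- drop(Si %*% lam)                              # psi = 1
  scores <- drop(sweep(Y, 2, xbar) %*% wts)
  score_var <- 1 - drop(crossprod(lam, Si %*% lam))
  ll <- -0.5 * (n * 4 * log(2 * pi) + n * fml(opt$par))
  nm <- colnames(Y) %||% paste0("subtest", 1:4)
  out <- list(loadings = setNames(lam, nm), resid_var = setNames(th, nm),
              recall_cov = opt$par[9], means = setNames(xbar, nm),
              chisq = chisq, df = 1L,
              p = pchisq(max(chisq, 0), 1L, lower.tail = FALSE),
              scores = scores, score_se = sqrt(max(score_var, 0)),
              implied_cov = Sig, sample_cov = S, n = n, logLik = ll,
              converged = opt$convergence == 0, heywood = heywood)
  class(out) <- "ability_cfa"
  out
}

#' @export
print.ability_cfa <- function(x, ...) {
  cat("One-factor cognitive ability model (n = ", x$n, ")\n", sep = "")
  print(round(rbind(loading = x$loadings, resid_var = x$resid_var), 3))
  cat("Recall residual covariance:", round(x$recall_cov, 3), "\n")
  cat(sprintf("Goodness of fit: chi2(%d) = %.2f, p = %.3g\n",
              x$df, x$chisq, x$p))
  invisible(x)
}

#' Joint latent response-error / latent ability model
#'
#' The capstone model: person-level latent response errors at low and high
#' item complexity (the `(9 - c)/9`, `c/9` basis) are correlated with a
#' latent cognitive ability factor measured by the four subtests, all
#' estimated jointly by maximum likelihood on the stacked per-person vector
#' of item errors and subtest scores. The random vector `(u_low, u_high,
#' g)` has a free covariance with `var(g) = 1` for identification; the
#' subtests load on `g` with free loadings, residual variances, and the
#' recall-pair residual covariance.
#'
#' With `method = "two_step"`, factor scores from [fit_ability_factor()]
#' replace the latent factor in a manifest basis model; this is an
#' approximation (factor-score correlations are attenuated relative to the
#' joint estimates) and is labeled as such in the output.
#'
#' @param data long data.frame with `person_id`, `item_id`, `error`,
#'   `complexity`.
#' @param subtests data.frame with `person_id` plus four subtest columns.
#' @param c_max top of the complexity range (default 9).
#' @param recall_pair subtest columns given a residual covariance.
#' @param method `"joint"` (default) or `"two_step"`.
#' @return object of class `"tch_latent"`: `cor_ability` (correlations of
#'   latent ability with the low- and high-complexity latent errors),
#'   `Psi`, `loadings`, `resid_var`, `recall_cov`, `sigma2`, `gamma`,
#'   `logLik`, `method`, `converged`.
#' @export
fit_latent_mlm <- function(data, subtests, c_max = 9,
                           recall_pair = c(1L, 2L),
                           method = c("joint", "two_step")) {
  method <- match.arg(method)
  stopifnot(all(c("person_id", "item_id", "error", "complexity") %in% names(data)))
  sub_cols <- setdiff(names(subtests), c("person_id", "wave", "composite"))
  sub_cols <- sub_cols[vapply(subtests[sub_cols], is.numeric, TRUE)][1:4]
  if (method == "two_step") {
    cfa <- fit_ability_factor(subtests[sub_cols], recall_pair)
    fs <- data.frame(person_id = subtests$person_id, ability = cfa$scores)
    d <- merge(data[c("person_id", "item_id", "error", "complexity")], fs,
               by = "person_id")
    bf <- fit_basis_mlm(d, c_max = c_max)
    out <- list(cor_ability = bf$cor_ability, Psi = bf$Psi,
                loadings = cfa$loadings, resid_var = cfa$resid_var,
                recall_cov = cfa$recall_cov, sigma2 = bf$sigma2,
                gamma = bf$gamma, logLik = NA_real_, method = "two_step",
                converged = bf$converged && cfa$converged,
                note = "two-step approximation: factor scores substituted for the latent factor",
                n_persons = bf$n_persons)
    class(out) <- "tch_latent"
    return(out)
  }
  # assemble persons x (items, subtests) wide matrix
  iid <- factor(data$item_id, levels = unique(data$item_id))
  pidf <- factor(data$person_id)
  E <- matrix(NA_real_, nlevels(pidf), nlevels(iid),
              dimnames = list(levels(pidf), levels(iid)))
  E[cbind(as.integer(pidf), as.integer(iid))] <- data$error
  cx <- data$complexity[match(colnames(E), data$item_id)]
  Xs <- as.matrix(subtests[match(rownames(E), subtests$person_id), sub_cols])
  keep <- rowSums(!is.na(E)) >= 2 & complete.cases(Xs)
  E <- E[keep, , drop = FALSE]; Xs <- Xs[keep, , drop = FALSE]
  J <- ncol(E)
  w0 <- (c_max - cx) / c_max; w1 <- cx / c_max
  Y <- cbind(E, Xs)
  p <- ncol(Y)
  # mean design: item means = w0*g00 + w1*g10; subtest means free
  D <- rbind(cbind(w0, w1, matrix(0, J, 4)),
             cbind(0, 0, diag(4)))
  prep <- covstruct_prepare(Y, D)
  sdE <- sd(E, na.rm = TRUE); sdX <- apply(Xs, 2, sd)
  build_sigma <- function(par) {
    psi <- psi_from_par(par[1:5])
    lam <- par[6:9]
    th <- exp(par[10:13])
    t12 <- par[14]
    s2 <- exp(par[15])
    L <- rbind(cbind(w0, w1, rep(0, J)),
               cbind(0, 0, lam))
    Sig <- L %*% psi %*% t(L)
    diag(Sig)[1:J] <- diag(Sig)[1:J] + s2
    diag(Sig)[J + 1:4] <- diag(Sig)[J + 1:4] + th
    Sig[J + recall_pair[1], J + recall_pair[2]] <-
      Sig[J + recall_pair[1], J + recall_pair[2]] + t12
    Sig[J + recall_pair[2], J + recall_pair[1]] <-
      Sig[J + recall_pair[2], J + recall_pair[1]] + t12
    Sig
  }
  obj <- function(par) covstruct_neg2ll(build_sigma(par), prep)
  par0 <- c(log(0.5 * sdE), 0, log(0.5 * sdE), -0.2, -0.2,
            0.7 * sdX, log(0.5 * sdX^2), 0.05 * prod(sdX[recall_pair]),
            2 * log(0.6 * sdE))
  opt <- nlminb(par0, obj, control = list(iter.max = 1000, eval.max = 2000))
  par <- opt$par
  # sign convention: loadings positive on average
  if (sum(par[6:9]) < 0) { par[6:9] <- -par[6:9]; par[4:5] <- -par[4:5] }
  psi <- psi_from_par(par[1:5])
  dimnames(psi) <- list(c("u_low", "u_high", "g"), c("u_low", "u_high", "g"))
  fit <- covstruct_neg2ll(build_sigma(par), prep, return_fit = TRUE)
  out <- list(
    cor_ability = c(low = psi[1, 3] / sqrt(psi[1, 1]),
                    high = psi[2, 3] / sqrt(psi[2, 2])),
    Psi = psi,
    loadings = setNames(par[6:9], colnames(Xs)),
    resid_var = setNames(exp(par[10:13]), colnames(Xs)),
    recall_cov = par[14], sigma2 = exp(par[15]),
    gamma = setNames(fit$beta[1:2], c("g00_low", "g10_high")),
    subtest_means = setNames(fit$beta[3:6], colnames(Xs)),
    logLik = -fit$neg2ll / 2, method = "joint",
    converged = opt$convergence == 0, n_persons = nrow(Y), par = par)
  class(out) <- "tch_latent"
  out
}

#' @export
print.tch_latent <- function(x, ...) {
  cat("Latent response-error / latent ability model (", x$method,
      " estimation, ", x$n_persons, " persons)\n", sep = "")
  if (!is.null(x$note)) cat("NOTE: ", x$note, "\n", sep = "")
  cat(sprintf("corr(g, u_low)  = %.3f\ncorr(g, u_high) = %.3f\n",
              x$cor_ability["low"], x$cor_ability["high"]))
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  invisible(x)
}

# ---- direct model-based simulators (for recovery studies and tests) -------

#' Simulate data directly from the moderated mixed model
#'
#' Draws person random effects and item-level errors from the reduced-form
#' moderated model with known parameters; the workhorse for parameter
#' recovery and coverage studies.
#'
#' @param n_persons,n_items design size.
#' @param gamma fixed effects `(g00, g01, g10, g11)`.
#' @param T2 2x2 random-effect covariance.
#' @param sigma2 residual variance.
#' @param ability_sd SD of the (mean-zero) ability scores.
#' @param complexity item complexity values (recycled to `n_items`).
#' @param seed optional seed.
#' @return list with `data` (long data.frame) and `truth`.
#' @export
simulate_tch_data <- function(n_persons = 500, n_items = 50,
                              gamma = c(0.45, -0.01, 0.012, -0.003),
                              T2 = matrix(c(0.02, -5e-4, -5e-4, 2e-4), 2),
                              sigma2 = 0.03, ability_sd = 4,
                              complexity = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(complexity))
    complexity <- rep_len(rep(0:9, length.out = max(n_items, 10)), n_items)
  a <- rnorm(n_persons, 0, ability_sd)
  ch <- chol(T2)
  U <- matrix(rnorm(n_persons * 2), n_persons) %*% ch
  b0 <- gamma[1] + gamma[2] * a + U[, 1]
  b1 <- gamma[3] + gamma[4] * a + U[, 2]
  err <- outer(b0, rep(1, n_items)) + outer(b1, complexity) +
    matrix(rnorm(n_persons * n_items, 0, sqrt(sigma2)), n_persons)
  data <- data.frame(
    person_id = rep(sprintf("p%05d", seq_len(n_persons)), each = n_items),
    item_id = rep(sprintf("i%03d", seq_len(n_items)), n_persons),
    error = as.vector(t(err)),
    complexity = rep(complexity, n_persons),
    ability = rep(a, each = n_items))
  list(data = data,
       truth = list(gamma = gamma, T2 = T2, sigma2 = sigma2,
                    ability_sd = ability_sd))
}

#' Simulate subtest data from the one-factor model
#'
#' @param n_persons sample size.
#' @param loadings factor loadings of the four subtests.
#' @param resid_var residual variances.
#' @param recall_cov residual covariance of the first two subtests.
#' @param means subtest means.
#' @param g optional vector of factor values (drawn N(0,1) if `NULL`).
#' @param seed optional seed.
#' @return list with `subtests` (data.frame incl. `person_id`) and `g`.
#' @export
simulate_factor_data <- function(n_persons = 1000,
                                 loadings = c(0.8, 0.8, 0.6, 0.4),
                                 resid_var = c(0.36, 0.36, 0.64, 0.84),
                                 recall_cov = 0.15,
                                 means = c(5, 4.8, 3.3, 1.7),
                                 g = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(g)) g <- rnorm(n_persons)
  Th <- diag(resid_var)
  Th[1, 2] <- Th[2, 1] <- recall_cov
  Ep <- matrix(rnorm(n_persons * 4), n_persons) %*% chol(Th)
  Y <- sweep(outer(g, loadings) + Ep, 2, means, `+`)
  colnames(Y) <- c("imm_recall", "del_recall", "serial7", "backward")
  list(subtests = data.frame(person_id = sprintf("p%05d", seq_len(n_persons)), Y),
       g = g)
}
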