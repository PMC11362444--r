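# Marginal-likelihood engine for two-level Gaussian mixed models.
#
# Model: y_i = X_i gamma + Z_i u_i + e_i, u_i ~ N(0, T), e_i ~ N(0, s2 I).
# The per-person marginal is N(X_i gamma, Z_i T Z_i' + s2 I); gamma is
# profiled out by GLS at every evaluation, and the variance parameters
# (log-Cholesky factor of T, log sigma) are maximized directly (ML, not
# REML, so reparameterized fits are likelihood-comparable).
#
# All per-person cross-products are precomputed once; persons sharing the
# same Z pattern are grouped so each likelihood evaluation works on a few
# small (q x q) matrices per group via the Woodbury identity. Balanced
# designs (every person sees the same items) collapse to a single group.

mlm_prepare <- function(person, y, X, Z) {
  pid <- factor(person, levels = unique(person))
  N <- nlevels(pid)
  p <- ncol(X); q <- ncol(Z)
  n_i <- as.integer(tabulate(pid))
  # per-person cross products, vectorized via rowsum
  zx_cols <- do.call(cbind, lapply(seq_len(q), function(r) Z[, r] * X))
  S_zx <- rowsum(zx_cols, pid)                        # N x (q*p), [r,c] at (r-1)p+c
  S_zy <- rowsum(Z * y, pid)                          # N x q
  s_yy <- drop(rowsum(y^2, pid))
  # per-person Z'Z, packed lower-tri by column
  zz_idx <- which(lower.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  S_zz <- rowsum(Z[, zz_idx[, 1], drop = FALSE] * Z[, zz_idx[, 2], drop = FALSE], pid)
  key <- apply(cbind(n_i, round(S_zz, 9)), 1, paste, collapse = "|")
  groups <- split(seq_len(N), key)
  ginfo <- lapply(groups, function(idx) {
    ZtZ <- matrix(0, q, q)
    ZtZ[cbind(zz_idx[, 1], zz_idx[, 2])] <- S_zz[idx[1], ]
    ZtZ[cbind(zz_idx[, 2], zz_idx[, 1])] <- S_zz[idx[1], ]
    list(idx = idx, n_g = length(idx), ZtZ = ZtZ,
         B = crossprod(S_zx[idx, , drop = FALSE]),              # (qp) x (qp)
         Azy = crossprod(S_zx[idx, , drop = FALSE],
                         S_zy[idx, , drop = FALSE]),            # (qp) x q
         Czz = crossprod(S_zy[idx, , drop = FALSE]))            # q x q
  })
  list(pid = pid, N = N, p = p, q = q, n_i = n_i, N_obs = length(y),
       XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2),
       S_zx = S_zx, S_zy = S_zy, s_yy = s_yy, groups = ginfo,
       y = y, X = X, Z = Z)
}

theta_to_vc <- function(theta, q) {
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- theta[seq_len(q * (q + 1) / 2)]
  diag(L) <- exp(diag(L))
  s2 <- exp(2 * theta[length(theta)])
  list(T = tcrossprod(L), s2 = s2, L = L)
}

# contraction helpers over the (q*p) layout
contract_qq <- function(M, B, p, q) {
  out <- matrix(0, p, p)
  for (r in seq_len(q)) for (r2 in seq_len(q)) {
    rows <- (r - 1L) * p + seq_len(p); cols <- (r2 - 1L) * p + seq_len(p)
    out <- out + M[r, r2] * B[rows, cols, drop = FALSE]
  }
  out
}
contract_qv <- function(M, A, p, q) {
  out <- numeric(p)
  for (r in seq_len(q)) {
    rows <- (r - 1L) * p + seq_len(p)
    out <- out + drop(A[rows, , drop = FALSE] %*% M[r, ])
  }
  out
}

mlm_neg2ll <- function(theta, prep, return_fit = FALSE) {
  q <- prep$q; p <- prep$p
  vc <- theta_to_vc(theta, q)
  Tm <- vc$T; s2 <- vc$s2
  chT <- try(chol(Tm), silent = TRUE)
  if (inherits(chT, "try-error")) return(if (return_fit) NULL else 1e10)
  Tinv <- chol2inv(chT)
  A <- prep$XtX; b <- prep$Xty; qq <- prep$yty
  logdet <- prep$N_obs * log(s2)
  corrA <- matrix(0, p, p); corrb <- numeric(p); corrq <- 0
  Ms <- vector("list", length(prep$groups))
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    M <- solve(s2 * Tinv + g$ZtZ)
    Ms[[gi]] <- M
    d <- determinant(diag(q) + g$ZtZ %*% Tm / s2, logarithm = TRUE)
    logdet <- logdet + g$n_g * as.numeric(d$modulus)
    corrA <- corrA + contract_qq(M, g$B, p, q)
    corrb <- corrb + contract_qv(M, g$Azy, p, q)
    corrq <- corrq + sum(M * g$Czz)
  }
  Amat <- (A - corrA) / s2
  bvec <- (b - corrb) / s2
  qval <- (qq - corrq) / s2
  ch <- try(chol(Amat), silent = TRUE)
  if (inherits(ch, "try-error")) return(if (return_fit) NULL else 1e10)
  gamma <- backsolve(ch, forwardsolve(t(ch), bvec))
  neg2 <- prep$N_obs * log(2 * pi) + logdet + (qval - sum(bvec * gamma))
  if (!return_fit) return(neg2)
  list(neg2ll = neg2, gamma = gamma, Amat = Amat, T = Tm, s2 = s2, Ms = Ms)
}

mlm_start <- function(prep) {
  # OLS residual-based heuristics
  X <- prep$X; y <- prep$y
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  r <- y - drop(X %*% beta)
  v <- max(var(r), 1e-8)
  pm <- tapply(r, prep$pid, mean)
  t00 <- max(var(pm), v / 20)
  q <- prep$q
  zsd <- if (q > 1) pmax(apply(prep$Z[, -1, drop = FALSE], 2, sd), 0.1)
         else numeric(0)
  diag_sd <- c(sqrt(t00), sqrt(t00) / (2 * zsd))
  lt <- diag(log(diag_sd), q)
  c(lt[lower.tri(lt, diag = TRUE)], 0.5 * log(v / 2))
}

mlm_fit_engine <- function(person, y, X, Z, n_restarts = 3L) {
  prep <- mlm_prepare(person, y, X, Z)
  th0 <- mlm_start(prep)
  best <- NULL
  for (k in 0:n_restarts) {
    th <- if (k == 0) th0 else th0 + rnorm(length(th0), 0, 0.5)
    opt <- try(nlminb(th, mlm_neg2ll, prep = prep,
                      control = list(iter.max = 500, eval.max = 1000)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$objective < best$objective - 1e-8) best <- opt
    if (!is.null(best) && best$convergence == 0 && k >= 0) break
  }
  if (is.null(best)) stop("mixed-model optimization failed")
  fit <- mlm_neg2ll(best$par, prep, return_fit = TRUE)
  sw <- mlm_sandwich(best$par, prep, fit)
  list(prep = prep, theta = best$par, gamma = fit$gamma, T = fit$T,
       s2 = fit$s2, logLik = -best$objective / 2,
       vcov_naive = chol2inv(chol(fit$Amat)),
       vcov_sandwich = sw$vcov, ranef = sw$ranef,
       converged = best$convergence == 0, n_persons = prep$N,
       n_obs = prep$N_obs)
}

# person-clustered sandwich covariance of gamma and empirical-Bayes effects
mlm_sandwich <- function(theta, prep, fit) {
  q <- prep$q; p <- prep$p
  s2 <- fit$s2; Tm <- fit$T
  gamma <- fit$gamma
  # per-person Z'r and X'r from precomputed stats
  # Z'r_i = S_zy_i - ZtX_i gamma ; X'r_i needs per-person Xty and XtX slices,
  # recovered from raw data in one pass
  pid <- prep$pid
  Xr <- rowsum(prep$X * drop(prep$y - prep$X %*% gamma), pid)   # N x p
  Zr <- prep$S_zy - vapply(seq_len(q), function(r) {
    rows <- (r - 1L) * p + seq_len(p)
    drop(prep$S_zx[, rows, drop = FALSE] %*% gamma)
  }, numeric(prep$N))
  if (is.null(dim(Zr))) Zr <- matrix(Zr, ncol = q)
  G <- matrix(0, prep$N, p)
  U <- matrix(0, prep$N, q)
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    M <- fit$Ms[[gi]]
    idx <- g$idx
    Zr_g <- Zr[idx, , drop = FALSE]
    MZr <- Zr_g %*% M                                   # n_g x q
    # X' V^-1 r = (X'r - (Z'X)' M Z'r)/s2
    zxm <- matrix(0, length(idx), p)
    for (r in seq_len(q)) {
      rows <- (r - 1L) * p + seq_len(p)
      zxm <- zxm + prep$S_zx[idx, rows, drop = FALSE] * MZr[, r]
    }
    G[idx, ] <- (Xr[idx, , drop = FALSE] - zxm) / s2
    # u_i = T Z'V^-1 r = T (Z'r - Z'Z M Z'r)/s2
    U[idx, ] <- (Zr_g - MZr %*% g$ZtZ) %*% Tm / s2
  }
  bread <- chol2inv(chol(fit$Amat))
  meat <- crossprod(G)
  list(vcov = bread %*% meat %*% bread, ranef = U, scores = G)
}

#' Moderated random-slope mixed model of response errors
#'
#' Fits, by direct maximum likelihood, the two-level model in which a
#' person's item-level (transformed) response errors are regressed on item
#' complexity with random intercepts and random complexity slopes, and both
#' are moderated by the person's ability score: the reduced form
#' `error_ij = g00 + g01 ability_i + g10 complexity_ij +
#'  g11 ability_i x complexity_ij + u0i + u1i complexity_ij + r_ij`.
#' Fixed-effect standard errors are person-clustered sandwich estimates.
#' Ability and complexity enter uncentered, so `g01` is the ability effect
#' at complexity 0 and `g10` the complexity effect at ability 0.
#'
#' @param data data.frame with columns `person_id`, `error`, `complexity`,
#'   `ability` (one ability value per person, repeated on their rows).
#' @param scale100 multiply the outcome by 100 for reporting-friendly
#'   coefficient magnitudes (model math is unchanged otherwise).
#' @param n_restarts perturbed optimizer restarts on non-convergence.
#' @return object of class `"tch_mlm"` with elements `gamma`, `se`
#'   (sandwich), `se_naive`, `T` (2x2 random-effect covariance), `sigma2`,
#'   `logLik`, `ranef`, `converged`, plus bookkeeping.
#' @examples
#' sim <- simulate_tch_data(n_persons = 300, n_items = 40, seed = 2)
#' fit <- fit_moderated_mlm(sim$data)
#' coef(fit)
#' @export
fit_moderated_mlm <- function(data, scale100 = FALSE, n_restarts = 3L) {
  d <- check_long_data(data)
  y <- if (scale100) 100 * d$error else d$error
  X <- cbind("(Intercept)" = 1, ability = d$ability, complexity = d$complexity,
             "ability:complexity" = d$ability * d$complexity)
  Z <- cbind(1, d$complexity)
  eng <- mlm_fit_engine(d$person_id, y, X, Z, n_restarts)
  slope_var_rel <- eng$T[2, 2] * var(d$complexity) / eng$s2
  boundary <- slope_var_rel < 1e-6
  if (boundary) {
    warning("random-slope variance at boundary; refitting without random slope")
    eng <- mlm_fit_engine(d$person_id, y, X, matrix(1, length(y), 1), n_restarts)
  }
  out <- build_tch_fit(eng, X, d, scale100,
                       gamma_names = c("g00", "g01", "g10", "g11"),
                       class2 = "tch_mlm")
  out$boundary_refit <- boundary
  out
}

check_long_data <- function(data) {
  need <- c("person_id", "error", "complexity", "ability")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[need]), need]
  if (length(unique(d$complexity)) < 2L)
    stop("complexity must vary across items")
  d
}

build_tch_fit <- function(eng, X, d, scale100, gamma_names, class2) {
  gamma <- setNames(eng$gamma, colnames(X))
  out <- list(gamma = gamma,
              se = setNames(sqrt(diag(eng$vcov_sandwich)), colnames(X)),
              se_naive = setNames(sqrt(diag(eng$vcov_naive)), colnames(X)),
              vcov = eng$vcov_sandwich, vcov_naive = eng$vcov_naive,
              T = eng$T, sigma2 = eng$s2, logLik = eng$logLik,
              ranef = eng$ranef, theta = eng$theta,
              converged = eng$converged, n_persons = eng$n_persons,
              n_obs = eng$n_obs, scale100 = scale100,
              person_ids = levels(eng$prep$pid),
              gamma_labels = setNames(gamma_names, colnames(X)))
  class(out) <- c(class2, "tch_fit")
  out
}

#' @export
coef.tch_fit <- function(object, ...) object$gamma

#' @export
vcov.tch_fit <- function(object, robust = TRUE, ...)
  if (robust) object$vcov else object$vcov_naive

#' @export
logLik.tch_fit <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- length(object$gamma) + length(object$theta)
  class(val) <- "logLik"
  val
}

#' @export
print.tch_fit <- function(x, ...) {
  cat("Two-level mixed model (", x$n_persons, " persons, ", x$n_obs,
      " observations)\n", sep = "")
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  cat("Fixed effects (person-clustered robust SEs):\n")
  tab <- cbind(Estimate = x$gamma, `Robust SE` = x$se,
               z = x$gamma / x$se, `p` = 2 * pnorm(-abs(x$gamma / x$se)))
  printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE, digits = 4)
  cat("Random effects: tau00 =", format(x$T[1, 1], digits = 4))
  if (nrow(x$T) > 1)
    cat(", tau11 =", format(x$T[2, 2], digits = 4),
        ", tau10 =", format(x$T[2, 1], digits = 4))
  cat(", sigma2 =", format(x$sigma2, digits = 4), "\n")
  cat("logLik:", format(x$logLik), "\n")
  invisible(x)
}

#' @export
summary.tch_mlm <- function(object, ...) {
  cat("Simple slopes: ability at complexity 0 = ",
      format(object$gamma[2], digits = 4),
      "; complexity at ability 0 = ", format(object$gamma[3], digits = 4),
      "\n", sep = "")
  print(object)
  invisible(object)
}

#' Predicted error surface from a moderated fit
#'
#' Fixed-effect predictions over an ability-by-complexity grid, for
#' plotting the fan pattern of the interaction.
#'
#' @param object a `"tch_mlm"` fit.
#' @param newdata data.frame with `ability` and `complexity`; default a grid
#'   over observed-range quantiles.
#' @param ... unused.
#' @return `newdata` with a `predicted` column.
#' @export
predict.tch_mlm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- expand.grid(ability = seq(-2, 2, by = 0.5),
                           complexity = 0:9)
  X <- cbind(1, newdata$ability, newdata$complexity,
             newdata$ability * newdata$complexity)
  newdata$predicted <- drop(X %*% object$gamma)
  newdata
}

#' Binned-complexity sensitivity model
#'
#' Replaces the linear complexity term by five complexity bins (0-1, 2-3,
#' 4-5, 6-7, 8-9) interacted with ability, keeping the person-level random
#' intercept and random (linear) complexity slope. Reports the percent
#' change of the ability slope in each bin relative to the lowest observed
#' bin.
#'
#' @inheritParams fit_moderated_mlm
#' @return object of class `"tch_binned"`/`"tch_fit"`; extra elements
#'   `bins` (observed bins), `ability_slopes` (per bin) and
#'   `percent_change` (vs. the lowest bin; `NA` when only one bin).
#' @export
fit_binned_mlm <- function(data, scale100 = FALSE, n_restarts = 3L) {
  d <- check_long_data(data)
  y <- if (scale100) 100 * d$error else d$error
  bin <- pmin(pmax(d$complexity, 0) %/% 2 + 1, 5)
  obs_bins <- sort(unique(bin))
  if (length(obs_bins) > 1L && length(obs_bins) < 5L)
    warning("empty complexity bin(s) dropped: ",
            paste(setdiff(1:5, obs_bins), collapse = ", "))
  B <- outer(bin, obs_bins, `==`) * 1
  colnames(B) <- paste0("bin", obs_bins)
  if (length(obs_bins) == 1L) {
    X <- cbind("(Intercept)" = 1, ability = d$ability)
    Z <- matrix(1, length(y), 1)
    eng <- mlm_fit_engine(d$person_id, y, X, Z, n_restarts)
    out <- build_tch_fit(eng, X, d, scale100, colnames(X), "tch_binned")
    out$bins <- obs_bins
    out$ability_slopes <- setNames(out$gamma["ability"], paste0("bin", obs_bins))
    out$percent_change <- NA_real_
    warning("all items in one complexity bin; per-bin contrasts undefined")
    return(out)
  }
  X <- cbind(B, B * d$ability)
  colnames(X) <- c(paste0("bin", obs_bins), paste0("ability:bin", obs_bins))
  Z <- cbind(1, d$complexity)
  eng <- mlm_fit_engine(d$person_id, y, X, Z, n_restarts)
  out <- build_tch_fit(eng, X, d, scale100, colnames(X), "tch_binned")
  out$bins <- obs_bins
  sl <- out$gamma[paste0("ability:bin", obs_bins)]
  out$ability_slopes <- setNames(sl, paste0("bin", obs_bins))
  out$percent_change <- setNames(100 * (sl / sl[1] - 1), paste0("bin", obs_bins))
  out
}

#' Reparameterized low/high-complexity basis model
#'
#' Refits the moderated model with neither a traditional intercept nor
#' slope: the level-1 design uses the basis weights `(9 - complexity)/9`
#' and `complexity/9`, so the two person-level effects are latent
#' individual differences in response errors at low (complexity 0) and high
#' (complexity 9) item complexity. Ability enters as a third person-level
#' variable with free mean and variance, and the full 3x3 person-level
#' covariance is estimated; the model is fitted via its exact
#' factorization into (a) the conditional-on-ability mixed model and (b)
#' the Gaussian ability margin, which is a bijective reparameterization of
#' the joint maximum likelihood problem.
#'
#' @inheritParams fit_moderated_mlm
#' @param c_max complexity value defining the "high" end of the basis
#'   (default 9, the top of the observed 0-9 range).
#' @return object of class `"tch_basis"`/`"tch_fit"`. `gamma` holds the
#'   low/high-complexity means and the ability mean; `Psi` is the 3x3
#'   person-level covariance (u0 = low, u1 = high, u2 = ability);
#'   `cor_ability` gives `corr(u0, ability)` and `corr(u1, ability)`;
#'   `logLik` is the joint likelihood and `logLik_conditional` the
#'   conditional-on-ability component (directly comparable with
#'   [fit_moderated_mlm()]).
#' @export
fit_basis_mlm <- function(data, c_max = 9, scale100 = FALSE, n_restarts = 3L) {
  d <- check_long_data(data)
  if (max(d$complexity) > c_max || min(d$complexity) < 0)
    stop("complexity outside [0, c_max]")
  y <- if (scale100) 100 * d$error else d$error
  w0 <- (c_max - d$complexity) / c_max
  w1 <- d$complexity / c_max
  # person-level ability (constant within person)
  pid <- factor(d$person_id, levels = unique(d$person_id))
  a_i <- tapply(d$ability, pid, function(a) a[1])
  a_i <- a_i[levels(pid)]
  g20 <- mean(a_i)
  t22 <- mean((a_i - g20)^2)                     # ML variance
  ac <- d$ability - g20
  X <- cbind(w_low = w0, w_high = w1, "w_low:ability" = w0 * ac,
             "w_high:ability" = w1 * ac)
  Z <- cbind(w0, w1)
  eng <- mlm_fit_engine(d$person_id, y, X, Z, n_restarts)
  s0 <- eng$gamma[3]; s1 <- eng$gamma[4]
  Tc <- eng$T
  Psi <- matrix(0, 3, 3,
                dimnames = list(c("u_low", "u_high", "ability"),
                                c("u_low", "u_high", "ability")))
  Psi[1:2, 1:2] <- Tc + outer(c(s0, s1), c(s0, s1)) * t22
  Psi[1:2, 3] <- Psi[3, 1:2] <- c(s0, s1) * t22
  Psi[3, 3] <- t22
  ll_marg <- sum(dnorm(a_i, g20, sqrt(t22), log = TRUE))
  gamma <- setNames(c(eng$gamma[1], eng$gamma[2], g20),
                    c("g00_low", "g10_high", "g20_ability"))
  out <- list(gamma = gamma,
              se = setNames(c(sqrt(diag(eng$vcov_sandwich))[1:2],
                              sqrt(t22 / length(a_i))), names(gamma)),
              vcov = eng$vcov_sandwich,
              Psi = Psi, T_conditional = Tc, sigma2 = eng$s2,
              cor_ability = c(low = Psi[1, 3] / sqrt(Psi[1, 1] * Psi[3, 3]),
                              high = Psi[2, 3] / sqrt(Psi[2, 2] * Psi[3, 3])),
              logLik = eng$logLik + ll_marg,
              logLik_conditional = eng$logLik,
              ranef = eng$ranef, theta = eng$theta, c_max = c_max,
              converged = eng$converged, n_persons = eng$n_persons,
              n_obs = eng$n_obs, scale100 = scale100,
              gamma_labels = setNames(c("g00", "g10", "g20"), names(gamma)))
  class(out) <- c("tch_basis", "tch_fit")
  out
}

#' @export
print.tch_basis <- function(x, ...) {
  cat("Low/high-complexity basis mixed model (", x$n_persons, " persons)\n",
      sep = "")
  tab <- cbind(Estimate = x$gamma, SE = x$se)
  print(tab, digits = 4)
  cat("Person-level covariance (u_low, u_high, ability):\n")
  print(round(x$Psi, 4))
  cat(sprintf("corr(u_low, ability) = %.3f; corr(u_high, ability) = %.3f\n",
              x$cor_ability["low"], x$cor_ability["high"]))
  cat("logLik (joint):", format(x$logLik),
      " conditional:", format(x$logLik_conditional), "\n")
  invisible(x)
}

#' Scale-level complexity/correlation analysis
#'
#' For each scale, computes the mean item complexity and the correlation of
#' person-level mean error (on the analysis scale) with ability; then
#' correlates those two scale-level quantities across scales, with a
#' Fisher-z 95% confidence interval.
#'
#' @param errors long data.frame with `person_id`, `scale_id`, `item_id`,
#'   `error`.
#' @param complexity data.frame with `item_id`, `composite` (or
#'   `complexity`).
#' @param ability data.frame (`person_id`, `ability`) or named vector.
#' @param transform `"cube_root"` or `"none"`.
#' @return list of class `"scale_level"`: `table` (per scale: `scale_id`,
#'   `mean_complexity`, `r_ability`, `n`), `meta_r`, `ci`, `n_scales`.
#' @export
scale_level_correlation <- function(errors, complexity, ability,
                                    transform = c("cube_root", "none")) {
  transform <- match.arg(transform)
  cx_col <- if ("composite" %in% names(complexity)) "composite" else "complexity"
  scales <- unique(errors$scale_id)
  if (length(scales) < 3L) stop("need at least 3 scales")
  rows <- list()
  for (s in scales) {
    es <- errors[errors$scale_id == s, ]
    x <- if (transform == "cube_root") cube_root_transform(es$error) else es$error
    pm <- tapply(x, es$person_id, mean, na.rm = TRUE)
    ab <- align_ability(ability, names(pm))
    ok <- !is.na(ab) & !is.na(pm)
    if (sd(pm[ok]) == 0) {
      warning("scale ", s, " has zero error variance; excluded")
      next
    }
    cx <- complexity[[cx_col]][match(unique(es$item_id), complexity$item_id)]
    rows[[s]] <- data.frame(scale_id = s, mean_complexity = mean(cx, na.rm = TRUE),
                            r_ability = cor(pm[ok], ab[ok]), n = sum(ok))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (sd(tab$mean_complexity) == 0) {
    meta <- NA_real_; ci <- c(NA_real_, NA_real_)
    warning("all scales have identical mean complexity; meta-correlation undefined")
  } else {
    meta <- cor(tab$mean_complexity, tab$r_ability)
    zse <- 1 / sqrt(nrow(tab) - 3)
    ci <- tanh(atanh(meta) + c(-1.96, 1.96) * zse)
  }
  out <- list(table = tab, meta_r = meta, ci = ci, n_scales = nrow(tab))
  class(out) <- "scale_level"
  out
}

#' @export
print.scale_level <- function(x, ...) {
  cat("Scale-level analysis over", x$n_scales, "scales\n")
  print(x$table, digits = 3, row.names = FALSE)
  if (is.na(x$meta_r)) {
    cat("Meta-correlation undefined (no complexity variance across scales)\n")
  } else {
    cat(sprintf("corr(mean complexity, ability correlation) = %.3f (95%% CI %.3f to %.3f)\n",
                x$meta_r, x$ci[1], x$ci[2]))
  }
  invisible(x)
}
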