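#' Category probabilities under the graded response model
#'
#' Computes cumulative and category response probabilities for one item of a
#' logistic graded response model. The probability of responding in category
#' `k` or higher is `plogis(a * (theta - b[k-1]))` (and 1 for `k = 1`);
#' category probabilities are successive differences of the cumulative
#' curves. No scaling constant is applied (pure logistic metric).
#'
#' @param theta numeric vector of latent trait values.
#' @param a item discrimination (scalar; may be negative during unconstrained
#'   estimation, but fitted items are reported positively keyed).
#' @param b numeric vector of `m - 1` strictly increasing thresholds.
#' @return A matrix with `length(theta)` rows and `m` columns of category
#'   probabilities; rows sum to 1.
#' @examples
#' p <- grm_prob(0.5, a = 1.5, b = c(-1, 0, 1))
#' rowSums(p)  # 1
#' @export
grm_prob <- function(theta, a, b) {
  check_item(a, b)
  if (any(!is.finite(theta))) stop("'theta' must be finite")
  cum <- grm_cum(theta, a, b)                  # n x (m-1)
  m <- length(b) + 1L
  p <- cbind(1, cum) - cbind(cum, 0)           # P*_k - P*_{k+1}
  colnames(p) <- paste0("k", seq_len(m))
  p
}

# cumulative P(Y >= k+1), k = 1..m-1; rows = theta
grm_cum <- function(theta, a, b) {
  out <- plogis(a * outer(theta, b, `-`))
  dim(out) <- c(length(theta), length(b))
  out
}

check_item <- function(a, b) {
  if (length(a) != 1L || !is.finite(a)) stop("'a' must be a finite scalar")
  if (length(b) < 1L || any(!is.finite(b))) stop("'b' must be finite")
  if (is.unsorted(b, strictly = TRUE)) stop("thresholds 'b' must be strictly increasing")
  invisible(TRUE)
}

#' Model-expected item score
#'
#' The expected response \eqn{E(Y \mid \hat\theta) = \sum_k k P(Y = k \mid
#' \hat\theta)}, a value in `[1, m]` that serves as the reference point for
#' response-error scores.
#'
#' @inheritParams grm_prob
#' @return numeric vector, one expected score per `theta`.
#' @export
expected_score <- function(theta, a, b) {
  p <- grm_prob(theta, a, b)
  drop(p %*% seq_len(ncol(p)))
}

#' Item-level response-error score
#'
#' The absolute difference between the observed response and the
#' model-expected response, rescaled by the number of thresholds:
#' \eqn{|y - E(Y \mid \hat\theta)| / (m - 1)}. Ranges from 0 (response equals
#' the expected response) to 1 (maximally different).
#'
#' @param y observed response category, integer in `1..m` (vectorized;
#'   recycled against `theta`).
#' @inheritParams grm_prob
#' @return numeric vector of error scores in `[0, 1]`.
#' @export
response_error <- function(y, theta, a, b) {
  m <- length(b) + 1L
  if (any(!is.na(y) & (y < 1 | y > m | y != round(y))))
    stop("'y' must be integer in 1..", m)
  e <- expected_score(theta, a, b)
  abs(y - e) / (m - 1)
}

# ---- quadrature ------------------------------------------------------------

grm_quad <- function(n_quad = 61L, range = c(-6, 6)) {
  nodes <- seq(range[1], range[2], length.out = n_quad)
  w <- dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

# log-likelihood matrix (n x Q) of response rows under item parameter list;
# y is an integer matrix n x J (NA allowed), pars a list with a[j], b[[j]]
grm_loglik_matrix <- function(y, a, b, quad) {
  n <- nrow(y); Q <- length(quad$nodes)
  ll <- matrix(0, n, Q)
  for (j in seq_len(ncol(y))) {
    pj <- grm_prob(quad$nodes, a[j], b[[j]])     # Q x m
    lp <- log(pmax(t(pj), 1e-300))               # m x Q
    obs <- !is.na(y[, j])
    ll[obs, ] <- ll[obs, ] + lp[y[obs, j], , drop = FALSE]
  }
  ll
}

# marginal log-likelihood of the sample given parameters
grm_marg_loglik <- function(y, a, b, quad) {
  ll <- grm_loglik_matrix(y, a, b, quad)
  lw <- log(quad$weights)
  mx <- apply(ll, 1, max)
  sum(mx + log(rowSums(exp(sweep(ll, 1, mx) + rep(lw, each = nrow(ll))))))
}

# ---- EM fitting ------------------------------------------------------------

#' Fit a graded response model to one scale
#'
#' Marginal maximum likelihood estimation of a unidimensional logistic graded
#' response model via an EM algorithm with fixed-node Gaussian quadrature.
#' The latent trait is standardized N(0, 1). Unused response categories are
#' collapsed onto adjacent observed categories (the mapping is recorded and
#' the post-collapse category count is used everywhere downstream, including
#' the error-score denominator). Items estimated with negative discrimination
#' in an unconstrained pass are flagged, reverse-coded, and the model is
#' refitted; the audit record is kept in the fit object.
#'
#' @param y integer matrix (persons x items) of responses in `1..m_j`;
#'   `NA` allowed. Column names become item ids.
#' @param n_quad number of equally spaced quadrature nodes.
#' @param quad_range node range.
#' @param tol EM stops when the largest absolute parameter change falls
#'   below `tol`.
#' @param max_iter EM iteration cap; hitting it flags `converged = FALSE`.
#' @param se one of `"hessian"` (observed-information standard errors from a
#'   numerical Hessian of the marginal likelihood) or `"none"`.
#' @param fit_stats if `TRUE`, compute an SRMR-style summary of residual
#'   item-pair association: the root mean square difference between observed
#'   polychoric correlations and polychoric correlations of the model-implied
#'   joint category tables.
#' @param reverse_check if `TRUE` (default), run the negative-keying pass.
#' @return An object of class `"grm"` with elements `a`, `b` (list of
#'   threshold vectors), `se_a`, `se_b`, `logLik`, `n_iter`, `converged`,
#'   `reversed`, `collapse_map`, `srmr`, `quad`, `n_obs`.
#' @examples
#' sim <- simulate_study(sim_config(n_persons = 150, scale_sizes = 4,
#'                                  categories = 5, rng_seed = 7))
#' ywide <- responses_to_wide(sim$responses)
#' fit <- fit_grm(ywide, se = "none", fit_stats = FALSE)
#' coef(fit)
#' @export
fit_grm <- function(y, n_quad = 61L, quad_range = c(-6, 6), tol = 1e-4,
                    max_iter = 500L, se = c("hessian", "none"),
                    fit_stats = TRUE, reverse_check = TRUE) {
  se <- match.arg(se)
  y <- as.matrix(y)
  if (ncol(y) < 2L) stop("a scale needs at least 2 items")
  if (is.null(colnames(y))) colnames(y) <- paste0("item", seq_len(ncol(y)))
  storage.mode(y) <- "integer"

  cl <- collapse_categories(y)
  y <- cl$y
  m <- cl$m
  single <- which(m < 2L)
  if (length(single))
    stop("item(s) with a single observed category: ",
         paste(colnames(y)[single], collapse = ", "))

  # keying pre-pass: items whose item-rest correlation is negative are
  # reverse-coded before estimation (mixed keying directions put the EM in
  # a bad basin); the unconstrained EM below can still flag residual
  # negative discriminations, which triggers one more reversal and refit
  reversed <- rep(FALSE, ncol(y))
  if (reverse_check && ncol(y) > 2L) {
    for (j in seq_len(ncol(y))) {
      rest <- rowMeans(y[, -j, drop = FALSE], na.rm = TRUE)
      r <- suppressWarnings(cor(y[, j], rest, use = "complete.obs"))
      if (is.finite(r) && r < 0) {
        reversed[j] <- TRUE
        y[, j] <- m[j] + 1L - y[, j]
      }
    }
    if (mean(reversed) > 0.5) {  # orientation convention: majority positive
      for (j in seq_len(ncol(y))) y[, j] <- m[j] + 1L - y[, j]
      reversed <- !reversed
    }
  }
  fit <- grm_em(y, m, n_quad, quad_range, tol, max_iter)
  if (reverse_check && any(fit$a < 0)) {
    flip <- fit$a < 0
    reversed <- xor(reversed, flip)
    for (j in which(flip)) y[, j] <- m[j] + 1L - y[, j]
    fit <- grm_em(y, m, n_quad, quad_range, tol, max_iter)
  }

  out <- list(a = fit$a, b = fit$b, m = m, logLik = fit$logLik,
              n_iter = fit$n_iter, converged = fit$converged,
              reversed = setNames(reversed, colnames(y)),
              collapse_map = cl$map, item_ids = colnames(y),
              quad = fit$quad, n_obs = nrow(y), y = y)
  class(out) <- "grm"

  if (se == "hessian") out <- add_grm_se(out)
  if (fit_stats) out$srmr <- grm_srmr(out)
  out
}

collapse_categories <- function(y) {
  map <- vector("list", ncol(y))
  m <- integer(ncol(y))
  for (j in seq_len(ncol(y))) {
    obs <- sort(unique(y[!is.na(y[, j]), j]))
    m[j] <- length(obs)
    map[[j]] <- setNames(seq_along(obs), obs)
    y[, j] <- map[[j]][as.character(y[, j])]
  }
  names(map) <- colnames(y)
  list(y = y, m = m, map = map)
}

grm_em <- function(y, m, n_quad, quad_range, tol, max_iter) {
  J <- ncol(y)
  quad <- grm_quad(n_quad, quad_range)
  # starting values: a = 1, thresholds from marginal category proportions
  a <- numeric(J); b <- vector("list", J)
  for (j in seq_len(J)) {
    yj <- y[!is.na(y[, j]), j]
    a[j] <- 1
    pr <- cumsum(tabulate(yj, m[j]) / length(yj))
    q <- qnorm(pmin(pmax(pr[-m[j]], 0.02), 0.98))
    b[[j]] <- fix_order(q)
  }
  lw <- log(quad$weights)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll <- grm_loglik_matrix(y, a, b, quad)
    lp <- sweep(ll, 2, lw, `+`)
    mx <- apply(lp, 1, max)
    post <- exp(lp - mx)
    post <- post / rowSums(post)                 # n x Q posterior weights
    delta <- 0
    for (j in seq_len(J)) {
      obs <- !is.na(y[, j])
      ind <- matrix(0, sum(obs), m[j])
      ind[cbind(seq_len(sum(obs)), y[obs, j])] <- 1
      njk <- crossprod(ind, post[obs, , drop = FALSE])  # m x Q expected counts
      par0 <- c(a[j], pack_b(b[[j]]))
      opt <- nlminb(par0, grm_item_negQ, njk = njk, nodes = quad$nodes,
                    control = list(iter.max = 100))
      a_new <- opt$par[1]; b_new <- unpack_b(opt$par[-1])
      delta <- max(delta, abs(a_new - a[j]), abs(b_new - b[[j]]))
      a[j] <- a_new; b[[j]] <- b_new
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  # resolve the reflection invariance (theta -> -theta, a -> -a,
  # b -> rev(-b)): orient so that the majority of items key positively
  if (sum(a) < 0) {
    a <- -a
    b <- lapply(b, function(bj) rev(-bj))
  }
  list(a = setNames(a, colnames(y)), b = setNames(b, colnames(y)),
       logLik = grm_marg_loglik(y, a, b, quad),
       n_iter = it, converged = converged, quad = quad)
}

# ordered-threshold packing: (b1, log gaps)
pack_b <- function(b) c(b[1], if (length(b) > 1) log(diff(b)))
unpack_b <- function(p) p[1] + c(0, cumsum(exp(p[-1])))[seq_along(p)]

fix_order <- function(b) {
  for (k in seq_along(b)[-1]) if (b[k] <= b[k - 1] + 0.05) b[k] <- b[k - 1] + 0.05
  b
}

grm_item_negQ <- function(par, njk, nodes) {
  a <- par[1]; b <- unpack_b(par[-1])
  p <- t(grm_prob(nodes, a, b))                  # m x Q
  -sum(njk * log(pmax(p, 1e-300)))
}

add_grm_se <- function(fit) {
  y <- fit$y; quad <- fit$quad
  J <- length(fit$a)
  pack <- function(a, b) unlist(lapply(seq_len(J), function(j) c(a[j], pack_b(b[[j]]))))
  sizes <- vapply(fit$b, length, 1L) + 1L
  unpack <- function(p) {
    a <- numeric(J); b <- vector("list", J); pos <- 1L
    for (j in seq_len(J)) {
      pj <- p[pos:(pos + sizes[j] - 1L)]
      a[j] <- pj[1]; b[[j]] <- unpack_b(pj[-1]); pos <- pos + sizes[j]
    }
    list(a = a, b = b)
  }
  nll <- function(p) { pr <- unpack(p); -grm_marg_loglik(y, pr$a, pr$b, quad) }
  p0 <- pack(fit$a, fit$b)
  H <- try(optimHess(p0, nll), silent = TRUE)
  fit$se_a <- rep(NA_real_, J); fit$se_b <- lapply(fit$b, function(b) rep(NA_real_, length(b)))
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) {
      # delta method back to (a, b) from (a, b1, log-gaps)
      pos <- 1L
      for (j in seq_len(J)) {
        idx <- pos:(pos + sizes[j] - 1L)
        Vi <- V[idx, idx, drop = FALSE]
        fit$se_a[j] <- sqrt(Vi[1, 1])
        nb <- sizes[j] - 1L
        Jm <- matrix(0, nb, nb)  # d b_k / d (b1, g2..): lower-tri of 1 and gaps
        gaps <- exp(pack_b(fit$b[[j]])[-1])
        for (k in seq_len(nb)) {
          Jm[k, 1] <- 1
          if (k > 1) for (l in 2:k) Jm[k, l] <- gaps[l - 1]
        }
        Vb <- Jm %*% Vi[-1, -1, drop = FALSE] %*% t(Jm)
        fit$se_b[[j]] <- sqrt(pmax(diag(Vb), 0))
        pos <- pos + sizes[j]
      }
    }
  }
  names(fit$se_a) <- fit$item_ids
  fit
}

# SRMR-style residual summary: observed vs model-implied polychorics
grm_srmr <- function(fit) {
  y <- fit$y; J <- length(fit$a)
  if (J < 2L) return(NA_real_)
  quad <- fit$quad
  res <- c()
  for (j in seq_len(J - 1L)) for (l in (j + 1L):J) {
    ok <- !is.na(y[, j]) & !is.na(y[, l])
    if (sum(ok) < 10) next
    tab <- table(factor(y[ok, j], 1:fit$m[j]), factor(y[ok, l], 1:fit$m[l]))
    pj <- grm_prob(quad$nodes, fit$a[j], fit$b[[j]])
    pl <- grm_prob(quad$nodes, fit$a[l], fit$b[[l]])
    imp <- t(pj * quad$weights) %*% pl          # implied joint table (probs)
    r_obs <- polychoric(tab)
    r_imp <- polychoric(imp)
    res <- c(res, r_obs - r_imp)
  }
  if (!length(res)) return(NA_real_)
  sqrt(mean(res^2))
}

#' @export
print.grm <- function(x, ...) {
  cat("Graded response model (", length(x$a), " items, n = ", x$n_obs, ")\n",
      sep = "")
  cat("logLik:", format(x$logLik), " EM iterations:", x$n_iter,
      if (!x$converged) " [NOT converged]", "\n")
  if (!is.null(x$srmr) && is.finite(x$srmr)) cat("SRMR-style residual:", round(x$srmr, 4), "\n")
  if (any(x$reversed)) cat("Reverse-coded:", paste(names(which(x$reversed)), collapse = ", "), "\n")
  print(coef(x), digits = 3)
  invisible(x)
}

#' @export
coef.grm <- function(object, ...) {
  nb <- max(vapply(object$b, length, 1L))
  out <- matrix(NA_real_, length(object$a), 1L + nb,
                dimnames = list(object$item_ids, c("a", paste0("b", seq_len(nb)))))
  out[, 1] <- object$a
  for (j in seq_along(object$b)) out[j, 1L + seq_along(object$b[[j]])] <- object$b[[j]]
  out
}

#' @export
logLik.grm <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- length(object$a) + sum(vapply(object$b, length, 1L))
  class(val) <- "logLik"
  val
}
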