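#' Cube-root transform of response-error scores
#'
#' Response-error scores are strongly right-skewed; the elementwise cube root
#' maps `[0, 1]` onto itself, preserves order, and brings the distribution
#' close to normal, which stabilizes the decile-correlation analysis.
#'
#' @param x numeric vector/matrix of error scores in `[0, 1]`.
#' @return transformed values, same shape.
#' @export
cube_root_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("error scores must be nonnegative")
  if (any(x > 1, na.rm = TRUE)) stop("error scores must be <= 1")
  x^(1 / 3)
}

#' Per-person decile means
#'
#' Sorts one person's (transformed) error scores ascending and averages them
#' within 10 near-equal bins. When the item count is not a multiple of 10,
#' remainder items are allocated to the lowest bins, so bin sizes differ by
#' at most one with the larger bins at the low end.
#'
#' @param x numeric vector of one person's scores (`NA` dropped).
#' @param n_bins number of bins (10 for deciles).
#' @return numeric vector of `n_bins` bin means (nondecreasing).
#' @export
per_person_deciles <- function(x, n_bins = 10L) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < n_bins) stop("need at least ", n_bins, " scores")
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  grp <- rep(seq_len(n_bins), sizes)
  as.numeric(tapply(x, grp, mean))
}

#' Decile summaries for all persons
#'
#' @param errors long data.frame with columns `person_id` and `error`, or a
#'   persons x items numeric matrix.
#' @param transform `"cube_root"` (default) or `"none"`.
#' @param min_items persons with fewer scored items are excluded (a decile
#'   analysis cannot fill 10 bins below 10 items); exclusions are recorded.
#' @return data.frame `person_id, d1..d10, n_items`; attribute `"excluded"`
#'   lists dropped persons.
#' @export
decile_summary <- function(errors, transform = c("cube_root", "none"),
                           min_items = 10L) {
  transform <- match.arg(transform)
  if (is.matrix(errors)) {
    ids <- rownames(errors) %||% as.character(seq_len(nrow(errors)))
    lst <- split(errors, row(errors))
    names(lst) <- ids
  } else {
    stopifnot(all(c("person_id", "error") %in% names(errors)))
    lst <- split(errors$error, errors$person_id)
  }
  lst <- lapply(lst, function(x) x[!is.na(x)])
  if (transform == "cube_root") lst <- lapply(lst, cube_root_transform)
  n_items <- vapply(lst, length, 1L)
  keep <- n_items >= max(min_items, 10L)
  dec <- t(vapply(lst[keep], per_person_deciles, numeric(10)))
  out <- data.frame(person_id = names(lst)[keep], dec, n_items = n_items[keep])
  names(out)[2:11] <- paste0("d", 1:10)
  rownames(out) <- NULL
  attr(out, "excluded") <- names(lst)[!keep]
  out
}

# influence-function (joint-moment delta-method) covariance of the vector of
# correlations r_k = cor(X[,k], y); robust to non-normality of the variables
cor_influence_cov <- function(X, y) {
  n <- nrow(X)
  Zs <- scale(X); zy <- drop(scale(y))
  r <- drop(cor(X, y))
  psi <- Zs * zy - 0.5 * sweep(Zs^2 + zy^2, 2, r, `*`)
  ((n - 1) / n) * cov(psi) / n
}

# normal-theory covariance of dependent correlations sharing variable y
# (Pearson-Filon / Steiger form), used as an alternative
cor_normal_cov <- function(X, y) {
  n <- nrow(X)
  r <- drop(cor(X, y))
  Rx <- cor(X)
  K <- length(r)
  V <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    if (k == l) { V[k, k] <- (1 - r[k]^2)^2 / n; next }
    rkl <- Rx[k, l]
    V[k, l] <- (rkl * (1 - r[k]^2 - r[l]^2) -
                  0.5 * r[k] * r[l] * (1 - r[k]^2 - r[l]^2 - rkl^2)) / n
  }
  V
}

#' Worst-performance-rule decile correlation analysis
#'
#' Builds per-person decile means of (cube-root-transformed) response-error
#' scores, correlates each decile with ability, and tests equality of the
#' ten dependent correlations: the correlations are Fisher z-transformed and
#' an omnibus Wald test with a successive-difference contrast (df = 9) is
#' computed from the delta-method covariance of the correlation vector.
#' Post hoc pairwise delta-method tests of all decile pairs are included.
#'
#' @param errors long data.frame (`person_id`, `error`) or persons x items
#'   matrix of error scores in `[0, 1]`.
#' @param ability data.frame (`person_id`, `ability`) or named numeric
#'   vector of ability scores.
#' @param transform,min_items see [decile_summary()].
#' @param cov_method `"influence"` (empirical joint-moment delta method,
#'   robust to non-normality; default), `"normal"` (normal-theory), or
#'   `"bootstrap"` (person-level resampling).
#' @param bootstrap_n bootstrap resamples when `cov_method = "bootstrap"`.
#' @return object of class `"wpr_fit"`: decile summary, correlations `r`,
#'   covariance matrices, `wald` (statistic, df, p), `pairwise` table,
#'   settings.
#' @examples
#' set.seed(1)
#' err <- matrix(runif(200 * 30)^2, 200, 30)
#' abil <- rnorm(200) - rowMeans(err)
#' fit <- wpr_analysis(err, abil)
#' fit$r
#' @export
wpr_analysis <- function(errors, ability, transform = c("cube_root", "none"),
                         min_items = 10L,
                         cov_method = c("influence", "normal", "bootstrap"),
                         bootstrap_n = 2000L) {
  transform <- match.arg(transform)
  cov_method <- match.arg(cov_method)
  dec <- decile_summary(errors, transform = transform, min_items = min_items)
  ab <- align_ability(ability, dec$person_id)
  ok <- !is.na(ab)
  dec <- dec[ok, , drop = FALSE]; ab <- ab[ok]
  if (nrow(dec) < 3L) stop("need at least 3 persons with complete summaries")
  D <- as.matrix(dec[paste0("d", 1:10)])
  sds <- apply(D, 2, sd)
  if (any(sds == 0)) stop("zero variance in decile column(s): ",
                          paste(which(sds == 0), collapse = ", "))
  if (sd(ab) == 0) stop("zero variance in ability")
  r <- drop(cor(D, ab))
  names(r) <- paste0("d", 1:10)
  V <- switch(cov_method,
              influence = cor_influence_cov(D, ab),
              normal = cor_normal_cov(D, ab),
              bootstrap = cor_bootstrap_cov(D, ab, bootstrap_n))
  test <- tryCatch(wald_equality_test(r, V, n = nrow(dec)),
                   error = function(e) {
                     warning("omnibus test unavailable: ", conditionMessage(e))
                     list(statistic = NA_real_, df = length(r) - 1L,
                          p = NA_real_, reference = "none")
                   })
  pw <- pairwise_delta_tests(r, V)
  out <- list(deciles = dec, ability = ab, r = r, cov_r = V,
              cov_z = fisher_cov(r, V), wald = test, pairwise = pw,
              n = nrow(dec),
              settings = list(transform = transform, min_items = min_items,
                              cov_method = cov_method))
  class(out) <- "wpr_fit"
  out
}

align_ability <- function(ability, ids) {
  if (is.data.frame(ability)) {
    stopifnot(all(c("person_id", "ability") %in% names(ability)))
    ability$ability[match(ids, ability$person_id)]
  } else if (!is.null(names(ability))) {
    ability[ids]
  } else {
    if (length(ability) != length(ids))
      stop("unnamed ability vector must match the decile summary rows")
    ability
  }
}

cor_bootstrap_cov <- function(D, ab, B) {
  n <- nrow(D)
  R <- matrix(NA_real_, B, ncol(D))
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    R[b, ] <- drop(cor(D[i, , drop = FALSE], ab[i]))
  }
  cov(R)
}

fisher_cov <- function(r, V) {
  rc <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  d <- 1 / (1 - rc^2)
  diag(d) %*% V %*% diag(d)
}

#' Omnibus Wald test of equality of dependent correlations
#'
#' Fisher z-transforms the correlation vector and tests that all elements
#' are equal using a successive-difference contrast and the supplied
#' covariance of the correlations. The statistic is invariant to the choice
#' of full-rank contrast basis. Because the covariance is itself estimated
#' from `n` persons, the statistic is referred to Hotelling's T-squared
#' distribution (an F reference with `length(r) - 1` numerator df) when `n`
#' is supplied, which keeps the test close to its nominal level in moderate
#' samples; without `n` the asymptotic chi-square reference is used.
#'
#' @param r correlation vector.
#' @param V covariance matrix of `r`.
#' @param n number of persons behind `V` (enables the finite-sample F
#'   reference).
#' @return list `statistic`, `df`, `p`, `reference`.
#' @export
wald_equality_test <- function(r, V, n = NULL) {
  K <- length(r)
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  Vz <- fisher_cov(r, V)
  C <- diff(diag(K))                        # successive differences, (K-1) x K
  cz <- drop(C %*% z)
  M <- C %*% Vz %*% t(C)
  qr_M <- qr(M)
  if (qr_M$rank < K - 1L)
    stop("singular contrast covariance; consider cov_method = 'bootstrap'")
  stat <- drop(crossprod(cz, solve(M, cz)))
  p <- K - 1L
  if (!is.null(n) && n > p + 1L) {
    pval <- pf(stat * (n - p) / ((n - 1) * p), p, n - p, lower.tail = FALSE)
    ref <- "hotelling_f"
  } else {
    pval <- pchisq(stat, p, lower.tail = FALSE)
    ref <- "chisq"
  }
  list(statistic = stat, df = p, p = pval, reference = ref)
}

#' Pairwise delta-method comparisons of dependent correlations
#'
#' For each pair of deciles, the difference of Fisher z values, its
#' delta-method standard error, and a two-sided normal p value.
#'
#' @inheritParams wald_equality_test
#' @return data.frame `k, l, diff_z, se, p`.
#' @export
pairwise_delta_tests <- function(r, V) {
  K <- length(r)
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  Vz <- fisher_cov(r, V)
  out <- list()
  for (k in seq_len(K - 1L)) for (l in (k + 1L):K) {
    d <- z[k] - z[l]
    se <- sqrt(max(Vz[k, k] + Vz[l, l] - 2 * Vz[k, l], 0))
    p <- if (se == 0) as.numeric(d == 0) * 0 + 1 else
      2 * pnorm(-abs(d) / se)
    out[[length(out) + 1L]] <- data.frame(k = k, l = l, diff_z = d, se = se, p = p)
  }
  do.call(rbind, out)
}

#' @export
print.wpr_fit <- function(x, ...) {
  cat("Worst-performance-rule analysis (n = ", x$n, " persons, ",
      x$settings$transform, " transform, ", x$settings$cov_method,
      " covariance)\n", sep = "")
  cat("Decile-ability correlations:\n")
  print(round(x$r, 3))
  cat(sprintf("Omnibus Wald test: chi2(%d) = %.2f, p = %.3g\n",
              x$wald$df, x$wald$statistic, x$wald$p))
  invisible(x)
}

#' @export
summary.wpr_fit <- function(object, ...) {
  se <- sqrt(diag(object$cov_r))
  tab <- data.frame(decile = 1:10, r = object$r,
                    ci_lo = tanh(atanh(object$r) - 1.96 * sqrt(diag(object$cov_z))),
                    ci_hi = tanh(atanh(object$r) + 1.96 * sqrt(diag(object$cov_z))),
                    mean_error = colMeans(object$deciles[paste0("d", 1:10)]),
                    sd_error = apply(object$deciles[paste0("d", 1:10)], 2, sd))
  rownames(tab) <- NULL
  out <- list(table = tab, wald = object$wald, n = object$n,
              pairwise = object$pairwise)
  class(out) <- "summary.wpr_fit"
  out
}

#' @export
print.summary.wpr_fit <- function(x, ...) {
  cat("Decile correlations with ability (n =", x$n, "):\n")
  print(x$table, digits = 3, row.names = FALSE)
  cat(sprintf("Omnibus Wald test: chi2(%d) = %.2f, p = %.3g\n",
              x$wald$df, x$wald$statistic, x$wald$p))
  sig <- x$pairwise[x$pairwise$p < .05, ]
  cat(nrow(sig), "of", nrow(x$pairwise),
      "pairwise decile comparisons significant at alpha = .05\n")
  invisible(x)
}

#' Across-wave retest correlations of mean error scores
#'
#' Correlates person-level mean (transformed) error scores, and per-decile
#' means, across every pair of assessment waves.
#'
#' @param errors long data.frame with `person_id`, `wave`, `error`.
#' @param transform `"cube_root"` or `"none"`.
#' @param deciles if `TRUE`, also return per-decile retest correlations.
#' @param min_items minimum scored items per person-wave for the decile part.
#' @return data.frame with one row per wave pair: `wave1, wave2, n, r_mean`
#'   and, when `deciles = TRUE`, `r_d1..r_d10`.
#' @export
retest_correlations <- function(errors, transform = c("cube_root", "none"),
                                deciles = TRUE, min_items = 10L) {
  transform <- match.arg(transform)
  stopifnot(all(c("person_id", "wave", "error") %in% names(errors)))
  waves <- sort(unique(errors$wave))
  if (length(waves) < 2L) stop("need at least 2 waves")
  per_wave <- lapply(waves, function(w) {
    ew <- errors[errors$wave == w, ]
    x <- if (transform == "cube_root") cube_root_transform(ew$error) else ew$error
    mm <- tapply(x, ew$person_id, mean, na.rm = TRUE)
    dd <- if (deciles) decile_summary(ew, transform = transform,
                                      min_items = min_items) else NULL
    list(mean = mm, dec = dd)
  })
  names(per_wave) <- waves
  out <- list()
  for (i in seq_along(waves)[-length(waves)]) for (j in (i + 1L):length(waves)) {
    m1 <- per_wave[[i]]$mean; m2 <- per_wave[[j]]$mean
    common <- intersect(names(m1), names(m2))
    if (!length(common)) stop("no overlapping persons between waves ",
                              waves[i], " and ", waves[j])
    row <- data.frame(wave1 = waves[i], wave2 = waves[j], n = length(common),
                      r_mean = cor(m1[common], m2[common]))
    if (deciles) {
      d1 <- per_wave[[i]]$dec; d2 <- per_wave[[j]]$dec
      cd <- intersect(d1$person_id, d2$person_id)
      for (k in 1:10) {
        col <- paste0("d", k)
        row[[paste0("r_", col)]] <- cor(d1[[col]][match(cd, d1$person_id)],
                                        d2[[col]][match(cd, d2$person_id)])
      }
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
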