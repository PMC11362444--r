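#' Expected a posteriori (EAP) latent trait estimates
#'
#' Posterior mean and SD of the latent trait under a standard-normal prior,
#' evaluated over fixed quadrature nodes, given fitted item parameters.
#'
#' @param y integer matrix (persons x items) of responses aligned with the
#'   items of `fit`; `NA` allowed, but each row must contain at least one
#'   non-missing response.
#' @param fit a `"grm"` fit, or a list with elements `a`, `b` (and optionally
#'   `quad`).
#' @param n_quad,quad_range quadrature settings; defaults reuse the fit's
#'   quadrature.
#' @return data.frame with columns `theta` and `sd`, one row per person.
#' @export
eap_theta <- function(y, fit, n_quad = NULL, quad_range = c(-6, 6)) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  quad <- if (is.null(n_quad)) fit$quad %||% grm_quad() else grm_quad(n_quad, quad_range)
  if (any(rowSums(!is.na(y)) == 0L)) stop("some persons have no non-missing responses")
  ll <- grm_loglik_matrix(y, fit$a, fit$b, quad)
  lp <- sweep(ll, 2, log(quad$weights), `+`)
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  th <- drop(post %*% quad$nodes)
  v <- drop(post %*% quad$nodes^2) - th^2
  data.frame(theta = th, sd = sqrt(pmax(v, 0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert long responses to a wide person x item matrix
#'
#' @param responses data.frame with columns `person_id`, `item_id`,
#'   `response` (and optionally `wave`, filtered beforehand by the caller).
#' @return integer matrix with person ids as rownames and item ids as
#'   column names.
#' @export
responses_to_wide <- function(responses) {
  pid <- factor(responses$person_id)
  iid <- factor(responses$item_id, levels = unique(responses$item_id))
  y <- matrix(NA_integer_, nlevels(pid), nlevels(iid),
              dimnames = list(levels(pid), levels(iid)))
  y[cbind(as.integer(pid), as.integer(iid))] <- as.integer(responses$response)
  y
}

#' Fit GRMs and compute response-error scores for every scale
#'
#' Fits one unidimensional graded response model per scale (and per wave,
#' when a `wave` column is present), computes EAP trait estimates from each
#' person's available responses, and derives item-level response-error
#' scores. Following the complete-scale rule, error scores are only computed
#' for person-scale blocks with no missing responses; persons still
#' contribute all their available responses to GRM fitting.
#'
#' @param responses long data.frame with columns `person_id`, `scale_id`,
#'   `item_id`, `response`, and optionally `wave`.
#' @param se,fit_stats,n_quad,... passed to [fit_grm()]; standard errors and
#'   fit statistics default off here because a full battery fits many models.
#' @return An object of class `"scored_scales"`: a list with
#'   \item{error_scores}{long data.frame `person_id, wave, scale_id, item_id,
#'     y, expected, error`}
#'   \item{thetas}{data.frame `person_id, wave, scale_id, theta, sd`}
#'   \item{fits}{named list of `"grm"` objects per wave:scale}
#'   \item{n_scored}{data.frame `person_id, wave, n_items` of scored-item
#'     counts per person}
#' @export
score_scales <- function(responses, se = "none", fit_stats = FALSE,
                         n_quad = 61L, ...) {
  stopifnot(all(c("person_id", "scale_id", "item_id", "response") %in%
                  names(responses)))
  if (!"wave" %in% names(responses)) responses$wave <- 1L
  it2sc <- unique(responses[c("item_id", "scale_id")])
  if (anyDuplicated(it2sc$item_id))
    stop("each item must belong to exactly one scale")
  err <- list(); th <- list(); fits <- list()
  for (w in sort(unique(responses$wave))) {
    rw <- responses[responses$wave == w, ]
    for (s in unique(rw$scale_id)) {
      rs <- rw[rw$scale_id == s, ]
      y <- responses_to_wide(rs)
      if (ncol(y) < 2L) stop("scale ", s, " has fewer than 2 items")
      keep <- rowSums(!is.na(y)) > 0L
      y <- y[keep, , drop = FALSE]
      fit <- fit_grm(y, se = se, fit_stats = fit_stats, n_quad = n_quad, ...)
      key <- paste0("w", w, ":", s)
      fits[[key]] <- fit
      eap <- eap_theta(fit$y, fit)
      th[[key]] <- data.frame(person_id = rownames(y), wave = w, scale_id = s,
                              theta = eap$theta, sd = eap$sd)
      complete <- rowSums(is.na(fit$y)) == 0L
      if (any(complete)) {
        yc <- fit$y[complete, , drop = FALSE]
        thc <- eap$theta[complete]
        blocks <- lapply(seq_len(ncol(yc)), function(j) {
          e <- expected_score(thc, fit$a[j], fit$b[[j]])
          data.frame(person_id = rownames(yc), wave = w, scale_id = s,
                     item_id = colnames(yc)[j], y = yc[, j], expected = e,
                     error = abs(yc[, j] - e) / (fit$m[j] - 1L))
        })
        err[[key]] <- do.call(rbind, blocks)
      }
    }
  }
  error_scores <- do.call(rbind, err)
  rownames(error_scores) <- NULL
  cnt <- aggregate(list(n_items = error_scores$error),
                   error_scores[c("person_id", "wave")], length)
  out <- list(error_scores = error_scores,
              thetas = do.call(rbind, th),
              fits = fits, n_scored = cnt)
  rownames(out$thetas) <- NULL
  class(out) <- "scored_scales"
  out
}

#' @export
print.scored_scales <- function(x, ...) {
  cat("Scored scales: ", length(x$fits), " GRM fit(s), ",
      nrow(x$error_scores), " error scores for ",
      length(unique(x$error_scores$person_id)), " persons\n", sep = "")
  conv <- vapply(x$fits, `[[`, TRUE, "converged")
  if (!all(conv)) cat("Non-converged fits:", paste(names(conv)[!conv], collapse = ", "), "\n")
  cat("Median error score:", round(median(x$error_scores$error), 3), "\n")
  invisible(x)
}
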