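#' Maximum-likelihood Pareto fit
#'
#' Fits the Pareto density `p(tau; a, b) = ((a - 1)/b) (tau/b)^(-a)` on
#' `tau >= b` by maximum likelihood: `b_hat = min(tau)` and
#' `a_hat = 1 + 1 / (mean(log tau) - log b_hat)`.
#'
#' @param tau inter-event times ([iet] or positive numeric vector), n >= 2.
#' @return an object of class `pareto_fit`: `a_hat`, `b_hat`, `loglik`, `n`.
#' @export
pareto_mle <- function(tau) {
  v <- iet_values(tau)
  n <- length(v)
  stopifnot(n >= 2)
  b_hat <- min(v)
  denom <- mean(log(v)) - log(b_hat)
  if (denom <= 0)
    stop("degenerate data: all values equal, Pareto exponent diverges")
  a_hat <- 1 + 1 / denom
  structure(list(a_hat = a_hat, b_hat = b_hat,
                 loglik = pareto_loglik(v, a_hat, b_hat), n = n),
            class = "pareto_fit")
}

#' @export
print.pareto_fit <- function(x, ...) {
  cat(sprintf("Pareto fit: a = %.4f, b = %g, log-lik %.4f (n = %d)\n",
              x$a_hat, x$b_hat, x$loglik, x$n))
  invisible(x)
}

# Pareto log-likelihood, not renormalized to any subset
pareto_loglik <- function(v, a, b) {
  sum(log(a - 1) - log(b) - a * (log(v) - log(b)))
}

#' Pareto density and survival function
#'
#' @param tau evaluation points (>= b).
#' @param a exponent (> 1).
#' @param b lower bound (> 0).
#' @return density `((a-1)/b)(tau/b)^(-a)` or survival `(tau/b)^(-(a-1))`.
#' @export
pareto_pdf <- function(tau, a, b) {
  out <- rep(NA_real_, length(tau))
  ok <- tau >= b
  out[ok] <- (a - 1) / b * (tau[ok] / b)^(-a)
  out
}

#' @rdname pareto_pdf
#' @export
pareto_survival <- function(tau, a, b) {
  out <- rep(NA_real_, length(tau))
  ok <- tau >= b
  out[ok] <- (tau[ok] / b)^(-(a - 1))
  out
}

#' Sample from a Pareto distribution
#'
#' Inverse-CDF sampling from `p(tau; a, b)` on `tau >= b`.
#'
#' @param n number of draws.
#' @param a exponent (> 1).
#' @param b lower bound (> 0).
#' @param seed integer seed.
#' @return numeric vector of draws.
#' @export
sample_pareto <- function(n, a, b, seed) {
  stopifnot(a > 1, b > 0, n >= 1)
  set.seed(seed)
  b * runif(n)^(-1 / (a - 1))
}

#' Power-law tail fitting by KS minimization (PLFit)
#'
#' Selects the lower bound `b_hat` so that the data points with
#' `tau >= b_hat` are as close as possible to a Pareto distribution:
#' each unique data value is a candidate threshold; the tail exponent is the
#' maximum-likelihood estimate on the tail; the candidate minimizing the
#' Kolmogorov-Smirnov distance between the empirical tail CDF and the
#' fitted Pareto CDF wins (ties toward the smaller threshold).  Candidates
#' leaving fewer than two tail points are skipped.  This is the standard
#' continuous-data dialect of the algorithm.
#'
#' @param tau inter-event times ([iet] or positive numeric vector), n >= 2.
#' @return an object of class `plfit_result`: `b_hat`, `a_hat`, `n_prime`
#'   (tail size), `ks_distance`, `n`, `loglik` (tail Pareto log-likelihood).
#' @export
plfit <- function(tau) {
  v <- sort(iet_values(tau))
  n <- length(v)
  stopifnot(n >= 2)
  cands <- unique(v)
  best <- NULL
  for (b in cands) {
    tail <- v[v >= b]
    np <- length(tail)
    if (np < 2L) next
    denom <- mean(log(tail)) - log(b)
    if (denom <= 0) next                       # all tail values equal b
    a <- 1 + 1 / denom
    # KS distance between the empirical tail CDF and the Pareto CDF
    Fm <- 1 - (tail / b)^(-(a - 1))
    i <- seq_len(np)
    D <- max(pmax(abs(i / np - Fm), abs((i - 1) / np - Fm)))
    if (is.null(best) || D < best$ks_distance - 1e-15)
      best <- list(b_hat = b, a_hat = a, n_prime = np, ks_distance = D)
  }
  if (is.null(best))
    stop("degenerate data: no viable threshold candidate")
  best$n <- n
  best$loglik <- pareto_loglik(v[v >= best$b_hat], best$a_hat, best$b_hat)
  structure(best, class = "plfit_result")
}

#' @export
print.plfit_result <- function(x, ...) {
  cat(sprintf(
    "PLFit: b = %g, a = %.4f, tail n' = %d of %d, KS distance %.4g\n",
    x$b_hat, x$a_hat, x$n_prime, x$n, x$ks_distance))
  invisible(x)
}

#' Likelihood comparison of EMM, Pareto and PLFit on truncated data
#'
#' Sums each model's log-likelihood over three nested point sets: all points,
#' the points strictly larger than the sample minimum (count n''), and the
#' points at or above the PLFit threshold `b_hat` (count n').  The EMM and
#' Pareto densities are evaluated with their full-data fits and are not
#' renormalized on the subsets, so on the tail set the EMM pays for the
#' probability mass it assigns below `b_hat`; the PLFit likelihood uses its
#' fitted tail Pareto and is only defined on the tail set.
#'
#' @param tau inter-event times ([iet] or positive numeric vector).
#' @param emm_fit an `emm_fit` object fitted on the full `tau`.
#' @param pareto_fit a `pareto_fit` on the full `tau` (NULL if unavailable).
#' @param plfit_result a `plfit_result` on the full `tau`.
#' @return an object of class `truncation_report`: counts `n`, `n_double_prime`,
#'   `n_prime` and a data frame `loglik` with one row per model and one
#'   column per point set (NA where undefined).
#' @export
truncated_likelihood_comparison <- function(tau, emm_fit, pareto_fit,
                                            plfit_result) {
  v <- iet_values(tau)
  stopifnot(inherits(emm_fit, "emm_fit"),
            inherits(plfit_result, "plfit_result"))
  sets <- list(all = v,
               above_min = v[v > min(v)],
               tail = v[v >= plfit_result$b_hat])
  ll <- function(f) vapply(sets, function(s)
    if (length(s) == 0L) NA_real_ else f(s), numeric(1))
  emm_ll <- ll(function(s) sum(emm_log_pdf(s, emm_fit$params)))
  par_ll <- if (is.null(pareto_fit)) c(all = NA_real_, above_min = NA_real_,
                                       tail = NA_real_)
            else ll(function(s) pareto_loglik(s, pareto_fit$a_hat,
                                              pareto_fit$b_hat))
  pl_ll <- c(all = NA_real_, above_min = NA_real_,
             tail = if (length(sets$tail) == 0L) NA_real_ else
               pareto_loglik(sets$tail, plfit_result$a_hat,
                             plfit_result$b_hat))
  structure(list(n = length(v),
                 n_double_prime = length(sets$above_min),
                 n_prime = length(sets$tail),
                 loglik = data.frame(model = c("EMM", "Pareto", "PLFit"),
                                     all = c(emm_ll[1], par_ll[1], NA),
                                     above_min = c(emm_ll[2], par_ll[2], NA),
                                     tail = c(emm_ll[3], par_ll[3],
                                              pl_ll["tail"]))),
            class = "truncation_report")
}

#' @export
print.truncation_report <- function(x, ...) {
  cat(sprintf("n = %d, n'' (tau > min) = %d, n' (tau >= b_hat) = %d\n",
              x$n, x$n_double_prime, x$n_prime))
  print(x$loglik, row.names = FALSE)
  invisible(x)
}

#' Rescaled tail survival and odds ratio for a PLFit model
#'
#' A fitted tail power law only describes the `n'` points with
#' `tau >= b_hat`, so for comparison with whole-distribution models its
#' survival probability is rescaled by `n'/n`:
#' `S(tau) = (n'/n) (tau/b_hat)^(-(a_hat - 1))`, and the odds ratio is
#' `OR(tau) = (1 - S(tau)) / S(tau)`.  Evaluation points below `b_hat` are
#' undefined and returned as NA.
#'
#' @param plfit_result a `plfit_result`.
#' @param eval_points evaluation points (>= b_hat; below-threshold points
#'   give NA with a warning).
#' @return numeric vector of survival probabilities / odds ratios.
#' @export
rescaled_tail_survival <- function(plfit_result, eval_points) {
  stopifnot(inherits(plfit_result, "plfit_result"))
  bad <- eval_points < plfit_result$b_hat
  if (any(bad)) warning("evaluation points below b_hat are undefined (NA)")
  s <- plfit_result$n_prime / plfit_result$n *
    pareto_survival(eval_points, plfit_result$a_hat, plfit_result$b_hat)
  s[bad] <- NA_real_
  s
}

#' @rdname rescaled_tail_survival
#' @export
rescaled_tail_odds_ratio <- function(plfit_result, eval_points) {
  s <- rescaled_tail_survival(plfit_result, eval_points)
  (1 - s) / s
}
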