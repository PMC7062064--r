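#' Exponential mixture model parameters
#'
#' A k-component exponential mixture model (EMM) has density
#' `p(tau) = sum_j (pi_j / mu_j) exp(-tau / mu_j)`, where the weights `pi`
#' form a probability vector and the `mu_j` are the component means, in the
#' same unit as the inter-event times.
#'
#' @param weights probability vector of mixing weights.
#' @param means positive component means.
#' @return an object of class `emm_params`.
#' @export
emm_params <- function(weights, means) {
  weights <- as.numeric(weights)
  means <- as.numeric(means)
  if (length(weights) != length(means) || length(weights) < 1L)
    stop("weights and means must have equal positive length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1")
  if (any(means <= 0)) stop("means must be positive")
  structure(list(k = length(weights), weights = weights, means = means),
            class = "emm_params")
}

#' @export
print.emm_params <- function(x, ...) {
  cat(sprintf("EMM with %d component(s)\n", x$k))
  print(data.frame(weight = x$weights, mean = x$means), row.names = TRUE)
  invisible(x)
}

#' EMM density, survival function and odds ratio
#'
#' `emm_pdf` evaluates the mixture density, `emm_survival` the survival
#' probability `S(tau) = sum_j pi_j exp(-tau / mu_j)` (probability that an
#' inter-event time exceeds `tau`), and `emm_odds_ratio` the odds ratio
#' `OR(tau) = (1 - S(tau)) / S(tau)`, which magnifies differences between
#' distributions at small `tau`.
#'
#' @param tau non-negative evaluation points.
#' @param params an [emm_params] object.
#' @return numeric vector of the same length as `tau`.
#' @export
emm_pdf <- function(tau, params) {
  stopifnot(inherits(params, "emm_params"))
  if (any(tau < 0)) stop("tau must be non-negative")
  drop(exp(emm_log_pdf(tau, params)))
}

# log density via log-sum-exp; rows = tau, cols = components
emm_log_pdf <- function(tau, params) {
  lp <- outer(tau, params$means, function(t, m) -t / m)
  lp <- sweep(lp, 2L, log(params$weights) - log(params$means), "+")
  row_logsumexp(lp)
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  finite <- is.finite(mx)
  out <- mx
  out[finite] <- mx[finite] +
    log(rowSums(exp(m[finite, , drop = FALSE] - mx[finite])))
  out
}

#' @rdname emm_pdf
#' @export
emm_survival <- function(tau, params) {
  stopifnot(inherits(params, "emm_params"))
  if (any(tau < 0)) stop("tau must be non-negative")
  drop(exp(outer(tau, params$means, function(t, m) -t / m) %*% params$weights))
}

#' @rdname emm_pdf
#' @export
emm_odds_ratio <- function(tau, params) {
  s <- emm_survival(tau, params)
  (1 - s) / s
}

#' Sample inter-event times from an EMM
#'
#' Draws `n` i.i.d. values: component `j` with probability `pi_j`, then an
#' exponential with mean `mu_j`.
#'
#' @param params an [emm_params] object.
#' @param n number of draws (>= 1).
#' @param seed integer seed; draws are reproducible for a fixed seed.
#' @return an [iet] object; the generating component of each draw is kept in
#'   attribute `"labels"`.
#' @export
sample_emm <- function(params, n, seed) {
  stopifnot(inherits(params, "emm_params"), n >= 1)
  set.seed(seed)
  z <- sample.int(params$k, n, replace = TRUE, prob = params$weights)
  v <- rexp(n, rate = 1 / params$means[z])
  out <- iet(v, unit = "unitless")
  attr(out, "labels") <- z
  out
}

#' EM initialization for an EMM fit
#'
#' Weights start uniform at 1/k; initial means are drawn so that
#' `log10(mu_j)` is i.i.d. uniform on `[log10(min tau), log10(max tau)]`,
#' giving a broad initial spread over the orders of magnitude present in the
#' data, with most initial means relatively small.
#'
#' @param tau inter-event times ([iet] or positive numeric vector).
#' @param k number of components.
#' @param seed optional integer seed (the RNG state is used as-is when NULL).
#' @return an [emm_params] object.
#' @export
em_init <- function(tau, k, seed = NULL) {
  v <- iet_values(tau)
  stopifnot(k >= 1)
  if (min(v) <= 0) stop("tau must be strictly positive")
  if (!is.null(seed)) set.seed(seed)
  lo <- log10(min(v)); hi <- log10(max(v))
  mu <- 10^runif(k, lo, hi)
  emm_params(rep(1 / k, k), mu)
}

#' Fit an EMM by the EM algorithm (single run)
#'
#' Alternates the E step `gamma_ij \propto pi_j p(tau_i; mu_j)` (rows
#' normalized) and the M step `pi_j <- mean_i gamma_ij`,
#' `mu_j <- sum_i gamma_ij tau_i / sum_i gamma_ij`, stopping at `max_iter`
#' iterations or when the relative change of the marginal log-likelihood
#' falls below `tol`.  All densities are handled in log space so that means
#' spanning many orders of magnitude do not underflow.  Components whose
#' weight or mean collapses numerically are frozen out of the E step and end
#' up unused (n_j = 0) at latent-variable completion.
#'
#' @inheritParams em_init
#' @param max_iter maximum number of EM iterations.
#' @param tol relative log-likelihood tolerance for convergence.
#' @param init optional [emm_params] initial value (overrides `em_init`).
#' @return an object of class `emm_fit` with elements `k`, `params`
#'   (the EM estimator), `loglik` (marginal log-likelihood), `iterations`,
#'   `trace` (log-likelihood per iteration), `completed` (see
#'   [complete_latent]), `n` and `seed`.
#' @export
em_fit <- function(tau, k, seed = NULL, max_iter = 1000, tol = 1e-10,
                   init = NULL) {
  v <- iet_values(tau)
  if (is.null(init)) init <- em_init(v, k, seed)
  res <- cpp_em_fit(v, init$weights, init$means, as.integer(max_iter), tol)
  keep_w <- res$weights
  # frozen components keep weight 0; emm_params requires a probability vector
  params <- emm_params(keep_w / sum(keep_w), res$means)
  fit <- structure(list(k = k, params = params, loglik = res$loglik,
                        iterations = res$iterations, trace = res$trace,
                        n = length(v), seed = seed, n_restarts = 1L,
                        completed = NULL),
                   class = "emm_fit")
  fit$completed <- complete_latent(v, params)
  fit
}

#' @export
print.emm_fit <- function(x, ...) {
  cat(sprintf(
    "EMM fit: k = %d (k* = %d), n = %d, marginal log-lik %.4f, %d iteration(s)\n",
    x$k, x$completed$k_star, x$n, x$loglik, x$iterations))
  print(data.frame(weight_hat = x$completed$weights_hat,
                   mean_hat = x$completed$means_hat,
                   n_j = x$completed$counts))
  invisible(x)
}

#' Latent-variable completion of an EMM fit
#'
#' Hard-assigns each inter-event time to the component maximizing
#' `pi_j p(tau_i; mu_j)` under the final EM parameters (ties to the lowest
#' index), drops components that receive no point, and recomputes the
#' maximum-likelihood estimator of the joint distribution of data and
#' assignments: `pi_hat_j = n_j / n` and `mu_hat_j` the within-component
#' mean.  The joint negative log-likelihood is
#' `n H(n_1/n, ..., n_k*/n) + sum_j n_j log(mu_hat_j) + n`, equivalently
#' `-sum_j n_j log(pi_hat_j / (e mu_hat_j))`.
#'
#' @param tau inter-event times ([iet] or positive numeric vector).
#' @param params an [emm_params] object (typically the EM estimator).
#' @param assignments optional integer vector forcing the assignments.
#' @return an object of class `emm_completed`: `assignments`, `counts`
#'   (n_j for the k* used components), `k_star`, `weights_hat`, `means_hat`,
#'   `joint_neg_loglik`.
#' @export
complete_latent <- function(tau, params, assignments = NULL) {
  v <- iet_values(tau)
  stopifnot(inherits(params, "emm_params"))
  if (is.null(assignments)) {
    lp <- outer(v, params$means, function(t, m) -t / m)
    lp <- sweep(lp, 2L, log(params$weights) - log(params$means), "+")
    assignments <- max.col(lp, ties.method = "first")
  }
  stopifnot(length(assignments) == length(v))
  used <- sort(unique(assignments))
  counts <- vapply(used, function(j) sum(assignments == j), integer(1))
  means_hat <- vapply(used, function(j) mean(v[assignments == j]), numeric(1))
  # relabel assignments onto 1..k_star in increasing original index
  z <- match(assignments, used)
  n <- length(v)
  w_hat <- counts / n
  jnl <- n * entropy_nats(w_hat) + sum(counts * log(means_hat)) + n
  structure(list(assignments = z, counts = counts, k_star = length(used),
                 weights_hat = w_hat, means_hat = means_hat,
                 joint_neg_loglik = jnl, n = n),
            class = "emm_completed")
}

# Shannon entropy in nats with the 0 log 0 = 0 convention
entropy_nats <- function(q) {
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Fit an EMM with random restarts
#'
#' Runs [em_fit] `n_restarts` times from independent broad initializations
#' (restart r uses sub-seed `seed + r - 1`) and keeps the run with the
#' largest joint likelihood of data and completed latent assignments,
#' i.e. the smallest `joint_neg_loglik`.
#'
#' @inheritParams em_fit
#' @param n_restarts number of EM restarts (default 10).
#' @return an `emm_fit` object (the best restart), with `n_restarts` set.
#' @export
fit_emm <- function(tau, k, n_restarts = 10, seed = 1, max_iter = 1000,
                    tol = 1e-10) {
  stopifnot(n_restarts >= 1)
  v <- iet_values(tau)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- em_fit(v, k, seed = seed + r - 1L, max_iter = max_iter, tol = tol)
    if (is.null(best) ||
        fit$completed$joint_neg_loglik < best$completed$joint_neg_loglik)
      best <- fit
  }
  best$n_restarts <- n_restarts
  best$seed <- seed
  best
}

#' Serialize a fit result to JSON
#'
#' @param fit an `emm_fit` object.
#' @param path optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "emm_fit"))
  obj <- list(k = fit$k, k_star = fit$completed$k_star,
              weights = fit$params$weights, means = fit$params$means,
              weights_hat = fit$completed$weights_hat,
              means_hat = fit$completed$means_hat,
              marginal_loglik = fit$loglik,
              joint_neg_loglik = fit$completed$joint_neg_loglik,
              n = fit$n, seed = fit$seed, n_restarts = fit$n_restarts,
              iterations = fit$iterations)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
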