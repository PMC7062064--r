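#' Universal codelength for a signed integer
#'
#' Length, in nats, of a universal prefix code for signed integers: a sign
#' bit plus Rissanen's universal code for the positive integer `|m| + 1`,
#' `l_N(j) = log(c0) + log(2) * (log2 j + log2 log2 j + ...)` keeping only the
#' positive iterated logarithms, with `c0 = 2.865064` making the code satisfy
#' the Kraft inequality.  Used to encode the integer bounds on `log(mu)` that
#' close the NML codelengths; symmetric in `m` and non-decreasing in `|m|`.
#'
#' @param m integer (vectorized).
#' @return codelength(s) in nats.
#' @export
integer_codelength <- function(m) {
  vapply(m, function(mm) {
    j <- abs(mm) + 1
    acc <- 0
    x <- log2(j)
    while (x > 0) {
      acc <- acc + x
      x <- log2(x)
    }
    log(2) + log(2.865064) + log(2) * acc
  }, numeric(1))
}

#' Integer bounds on log(mu) for a completed fit
#'
#' The NML codelengths restrict the component means to
#' `[exp(m_min), exp(m_max)]` with integer `m_min`, `m_max`, so the bounds
#' themselves are cheap to encode.  For a completed fit the bounds are
#' `m_min = floor(log(min_j mu_hat_j))` and `m_max = ceiling(log(max_j
#' mu_hat_j))`; when floor and ceiling coincide (all means on an integer
#' power of e) the upper bound is widened by 1 so that the log-range is
#' positive.
#'
#' @param completed an `emm_completed` object (or anything with
#'   `$means_hat`).
#' @return a list with integer `m_min`, `m_max` and `m_range = m_max - m_min`.
#' @export
mu_bounds <- function(completed) {
  mu <- completed$means_hat
  stopifnot(all(mu > 0))
  m_min <- floor(log(min(mu)))
  m_max <- ceiling(log(max(mu)))
  if (m_max <= m_min) m_max <- m_min + 1
  list(m_min = m_min, m_max = m_max, m_range = m_max - m_min)
}

#' Parametric complexity of the exponential model
#'
#' `log_c_exp` returns `log C_exp(n) = n log n - n - log Gamma(n) +
#' log(m_max - m_min)`, the log parametric complexity of the single
#' exponential family with the mean restricted to
#' `[exp(m_min), exp(m_max)]`.
#'
#' @param n sample size.
#' @param m_min,m_max integer bounds on log(mu).
#' @return log complexity in nats.
#' @export
log_c_exp <- function(n, m_min, m_max) {
  stopifnot(n >= 1, m_max > m_min)
  n * log(n) - n - lgamma(n) + log(m_max - m_min)
}

#' NML codelength of a single exponential distribution
#'
#' `L_NML(tau) = n log(mu_hat) + n log n - log Gamma(n) +
#' log(m_max - m_min)` with `mu_hat = mean(tau)`; the returned score adds
#' the integer code for the two bounds,
#' `L~_NML = L_NML + l(m_min) + l(m_max)`.
#'
#' @param tau inter-event times ([iet] or positive numeric vector).
#' @param bounds list with `m_min` and `m_max` (integers); by default the
#'   tightest bounds around `mean(tau)` (floor/ceiling of its log, widened
#'   if degenerate).
#' @return a `criterion_value` (see [select_model]) for criterion "NML".
#' @export
nml_exponential <- function(tau, bounds = NULL) {
  v <- iet_values(tau)
  n <- length(v)
  mu_hat <- mean(v)
  if (is.null(bounds))
    bounds <- mu_bounds(list(means_hat = mu_hat))
  if (mu_hat < exp(bounds$m_min) || mu_hat > exp(bounds$m_max))
    stop("mean(tau) outside [exp(m_min), exp(m_max)]; widen the bounds")
  fit <- n * log(mu_hat) + n        # -log p(tau; mu_hat)
  cplx <- log_c_exp(n, bounds$m_min, bounds$m_max)
  intc <- sum(integer_codelength(c(bounds$m_min, bounds$m_max)))
  criterion_value("NML", k = 1L, k_star = 1L, fit = fit, penalty = cplx,
                  integer_code = intc)
}

criterion_value <- function(criterion, k, k_star, fit, penalty,
                            integer_code = 0) {
  structure(list(criterion = criterion, k = as.integer(k),
                 k_star = as.integer(k_star), score = fit + penalty +
                   integer_code, fit_term = fit, penalty_term = penalty,
                 integer_term = integer_code),
            class = "criterion_value")
}

#' @export
print.criterion_value <- function(x, ...) {
  cat(sprintf("%s (k = %d, k* = %d): %.4f = fit %.4f + penalty %.4f + integer %.4f\n",
              x$criterion, x$k, x$k_star, x$score, x$fit_term, x$penalty_term,
              x$integer_term))
  invisible(x)
}

#' AIC and BIC of an EMM fit (no latent completion)
#'
#' Codelength-scale information criteria of the marginal EM fit:
#' `AIC = -log p(tau; theta_EM) + (2k - 1)` and
#' `BIC = -log p(tau; theta_EM) + ((2k - 1)/2) log n`.  Because the EMM is
#' non-identifiable these two are not theoretically justified for k >= 2;
#' they are included for comparison with the latent-completed criteria.
#'
#' @param fit an `emm_fit` object.
#' @return a `criterion_value`.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "emm_fit"))
  criterion_value("AIC", fit$k, fit$completed$k_star,
                  fit = -fit$loglik, penalty = 2 * fit$k - 1)
}

#' @rdname aic
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "emm_fit"))
  criterion_value("BIC", fit$k, fit$completed$k_star,
                  fit = -fit$loglik,
                  penalty = (2 * fit$k - 1) / 2 * log(fit$n))
}

#' AIC and BIC with latent variable completion
#'
#' Applied to the joint likelihood of data and hard assignments, which is an
#' identifiable model: `AIC_LVC = -log p(tau, z; theta_hat) + (2 k* - 1)` and
#' `BIC_LVC = -log p(tau, z; theta_hat) + ((k* - 1)/2) log n +
#' (1/2) sum_j log n_j`, using the effective component count k* (components
#' with n_j >= 1).
#'
#' @param completed an `emm_completed` object.
#' @param k requested number of components (recorded in the result; defaults
#'   to k*).
#' @return a `criterion_value`.
#' @export
aic_lvc <- function(completed, k = completed$k_star) {
  stopifnot(inherits(completed, "emm_completed"))
  criterion_value("AIC_LVC", k, completed$k_star,
                  fit = completed$joint_neg_loglik,
                  penalty = 2 * completed$k_star - 1)
}

#' @rdname aic_lvc
#' @export
bic_lvc <- function(completed, k = completed$k_star) {
  stopifnot(inherits(completed, "emm_completed"))
  ks <- completed$k_star
  criterion_value("BIC_LVC", k, ks,
                  fit = completed$joint_neg_loglik,
                  penalty = (ks - 1) / 2 * log(completed$n) +
                    0.5 * sum(log(completed$counts)))
}

#' Parametric complexity of the completed exponential mixture
#'
#' `log C_EMM(n, k)` with the means restricted to an integer log-range of
#' width `m_range`, computed by the exact convolution recursion
#' `C_EMM(n, k+1) = sum_{r1 + r2 = n} choose(n, r1) (r1/n)^r1 (r2/n)^r2
#' C_EMM(r1, k) C_EMM(r2, 1)` with base case
#' `C_EMM(n, 1) = (n/e)^n m_range / Gamma(n)` and conventions `0^0 = 1`,
#' `C_EMM(0, .) = 1`.  Evaluated in log space; cost O(n^2 k).
#'
#' @param n sample size (>= 1).
#' @param k_star number of mixture components (>= 1).
#' @param m_range positive integer width `m_max - m_min` of the log-mean
#'   range.
#' @param all_k if TRUE return the whole vector for k = 1..k_star.
#' @return `log C_EMM(n, k_star)` in nats (or a vector when `all_k`).
#' @export
log_c_emm <- function(n, k_star, m_range, all_k = FALSE) {
  stopifnot(n >= 1, k_star >= 1, m_range >= 1)
  v <- cpp_log_c_emm(as.integer(n), as.integer(k_star), as.numeric(m_range))
  if (all_k) v else v[k_star]
}

#' Parametric complexity of the multinomial distribution
#'
#' `log C_mult(n, k)` for the multinomial model with k categories and n
#' observations, by the O(n + k) recursion `C_mult(n, 1) = 1`,
#' `C_mult(n, 2) = sum_t choose(n, t) (t/n)^t ((n-t)/n)^(n-t)` and
#' `C_mult(n, k) = C_mult(n, k-1) + (n/(k-2)) C_mult(n, k-2)` for k >= 3,
#' evaluated in log space so that large n and k do not overflow.
#'
#' @param n number of observations (>= 1).
#' @param k_star number of categories (>= 1).
#' @param all_k if TRUE return the whole vector for k = 1..k_star.
#' @return `log C_mult(n, k_star)` in nats (or a vector when `all_k`).
#' @export
log_c_mult <- function(n, k_star, all_k = FALSE) {
  stopifnot(n >= 1, k_star >= 1)
  lc <- numeric(k_star)
  lc[1L] <- 0
  if (k_star >= 2L) {
    t <- 0:n
    terms <- lchoose(n, t) + xlogx_frac(t, n) + xlogx_frac(n - t, n)
    lc[2L] <- logsumexp(terms)
  }
  if (k_star >= 3L) {
    for (k in 3:k_star)
      lc[k] <- logsumexp(c(lc[k - 1L], log(n) - log(k - 2) + lc[k - 2L]))
  }
  if (all_k) lc else lc[k_star]
}

# t * log(t/n) with 0 log 0 = 0, vectorized over t
xlogx_frac <- function(t, n) ifelse(t > 0, t * (log(t) - log(n)), 0)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' NML codelength with latent variable completion (NML_LVC)
#'
#' `L_LVC = n H(n_1/n, ..., n_k*/n) + sum_j n_j log(mu_hat_j) + n +
#' log C_EMM(n, k*)`; the first three terms are the joint negative
#' log-likelihood of data and assignments.  The returned score is
#' `L~_LVC = L_LVC + l(m'_min) + l(m'_max)` with the integer code for the
#' mean bounds.
#'
#' @inheritParams aic_lvc
#' @param bounds integer bounds from [mu_bounds] (computed when NULL).
#' @return a `criterion_value`.
#' @export
l_lvc <- function(completed, bounds = NULL, k = completed$k_star) {
  stopifnot(inherits(completed, "emm_completed"))
  if (is.null(bounds)) bounds <- mu_bounds(completed)
  cplx <- log_c_emm(completed$n, completed$k_star, bounds$m_range)
  intc <- sum(integer_codelength(c(bounds$m_min, bounds$m_max)))
  criterion_value("NML_LVC", k, completed$k_star,
                  fit = completed$joint_neg_loglik, penalty = cplx,
                  integer_code = intc)
}

#' Decomposed NML codelength (DNML)
#'
#' Splits the joint codelength into the NML codelength of the data given the
#' assignments and the NML codelength of the assignment sequence:
#' `L_NML(tau | z) = sum_j (n_j log(mu_hat_j) + n_j log n_j - log Gamma(n_j))
#' + k* log(m'_max - m'_min)` and
#' `L_NML(z) = n H(n_1/n, ...) + log C_mult(n, k*)`.  The recorded fit term
#' collects the likelihood parts (including the entropy), the penalty term
#' the two complexities `k* log(m'_max - m'_min) + log C_mult(n, k*)`, and
#' the integer term `l(m'_min) + l(m'_max)`; the score is their sum,
#' `L~_DNML`.
#'
#' @inheritParams l_lvc
#' @return a `criterion_value`.
#' @export
l_dnml <- function(completed, bounds = NULL, k = completed$k_star) {
  stopifnot(inherits(completed, "emm_completed"))
  if (is.null(bounds)) bounds <- mu_bounds(completed)
  nj <- completed$counts
  n <- completed$n
  fit <- sum(nj * log(completed$means_hat) + nj * log(nj) - lgamma(nj)) +
    n * entropy_nats(nj / n)
  cplx <- completed$k_star * log(bounds$m_range) +
    log_c_mult(n, completed$k_star)
  intc <- sum(integer_codelength(c(bounds$m_min, bounds$m_max)))
  criterion_value("DNML", k, completed$k_star, fit = fit, penalty = cplx,
                  integer_code = intc)
}

# dispatch table used by select_model and the cli layer
criterion_names <- c("AIC", "BIC", "AIC_LVC", "BIC_LVC", "NML_LVC", "DNML")

score_fit <- function(fit, criterion) {
  switch(criterion,
         AIC = aic(fit),
         BIC = bic(fit),
         AIC_LVC = aic_lvc(fit$completed, k = fit$k),
         BIC_LVC = bic_lvc(fit$completed, k = fit$k),
         NML_LVC = l_lvc(fit$completed, k = fit$k),
         DNML = l_dnml(fit$completed, k = fit$k),
         stop("unknown criterion: ", criterion))
}

#' Fit EMMs over a grid of component counts and select the best model
#'
#' For each k in the grid, fits an EMM with [fit_emm] (restart r of grid
#' entry i uses sub-seed `seed + (i - 1) * n_restarts + (r - 1)`), scores the
#' fit under each requested criterion, and returns the score table together
#' with the argmin per criterion.  Ties are broken toward smaller k (equal
#' scores usually mean the extra components collapsed to the same effective
#' model).  For AIC/BIC the marginal likelihood of the restart selected by
#' joint likelihood is used.
#'
#' @param tau inter-event times ([iet] or positive numeric vector).
#' @param k_grid candidate component counts (default `c(1:10, 20, 50, 100)`).
#' @param criteria criteria to compute (subset of
#'   `c("AIC","BIC","AIC_LVC","BIC_LVC","NML_LVC","DNML")`; default all).
#' @param n_restarts EM restarts per k (default 10).
#' @param seed master seed.
#' @param max_iter,tol EM controls, see [em_fit].
#' @return an object of class `selection_report`: `$table` (one row per
#'   criterion/k pair with score, k*, and the score components), `$selected`
#'   (one row per criterion), `$fits` (the fitted models, named by k),
#'   `$k_grid`, `$seed`.
#' @export
select_model <- function(tau, k_grid = c(1:10, 20, 50, 100),
                         criteria = criterion_names, n_restarts = 10,
                         seed = 1, max_iter = 1000, tol = 1e-10) {
  v <- iet_values(tau)
  stopifnot(length(v) >= 1, all(criteria %in% criterion_names))
  fits <- vector("list", length(k_grid))
  rows <- list()
  for (i in seq_along(k_grid)) {
    k <- k_grid[[i]]
    fit <- fit_emm(v, k, n_restarts = n_restarts,
                   seed = seed + (i - 1L) * n_restarts,
                   max_iter = max_iter, tol = tol)
    fits[[i]] <- fit
    for (cr in criteria) {
      cv <- score_fit(fit, cr)
      rows[[length(rows) + 1L]] <-
        data.frame(criterion = cr, k = k, k_star = cv$k_star,
                   score = cv$score, fit_term = cv$fit_term,
                   penalty_term = cv$penalty_term,
                   integer_term = cv$integer_term)
    }
  }
  tab <- do.call(rbind, rows)
  sel <- do.call(rbind, lapply(criteria, function(cr) {
    sub <- tab[tab$criterion == cr, ]
    sub <- sub[order(sub$k), ]           # ties break toward smaller k
    sub[which.min(sub$score), c("criterion", "k", "k_star", "score")]
  }))
  rownames(sel) <- NULL
  names(fits) <- as.character(k_grid)
  structure(list(table = tab, selected = sel, fits = fits, k_grid = k_grid,
                 criteria = criteria, seed = seed, n = length(v)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Model selection over k in {%s}, n = %d\n",
              paste(x$k_grid, collapse = ", "), x$n))
  cat("Selected models:\n")
  print(x$selected, row.names = FALSE)
  invisible(x)
}

#' Serialize a selection report
#'
#' `report_to_json` writes the nested criterion -> k -> score structure;
#' `report_to_tsv` writes the flat score table.
#'
#' @param report a `selection_report`.
#' @param path optional output path.
#' @return the JSON string, or (for TSV) the table, invisibly when written.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "selection_report"))
  by_cr <- lapply(setNames(report$criteria, report$criteria), function(cr) {
    sub <- report$table[report$table$criterion == cr, ]
    scores <- lapply(seq_len(nrow(sub)), function(i)
      list(score = sub$score[i], k_star = sub$k_star[i],
           components = list(fit = sub$fit_term[i],
                             penalty = sub$penalty_term[i],
                             integer = sub$integer_term[i])))
    names(scores) <- as.character(sub$k)
    seli <- report$selected[report$selected$criterion == cr, ]
    list(scores = scores,
         selected = list(k = seli$k, k_star = seli$k_star,
                         score = seli$score))
  })
  obj <- list(n = report$n, k_grid = report$k_grid, seed = report$seed,
              criteria = by_cr)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname report_to_json
#' @export
report_to_tsv <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  write.table(report$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(report$table)
}
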