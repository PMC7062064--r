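# Independent brute-force oracles used to validate the analytic recursions.
# These deliberately avoid the package's log-domain code paths.

# C_mult(n, k) by exhaustive enumeration over all k^n assignment vectors:
# sum over z of prod_j (n_j / n)^(n_j).
oracle_c_mult <- function(n, k) {
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    nj <- tabulate(as.integer(grid[r, ]), nbins = k)
    nj <- nj[nj > 0]
    total <- total + prod((nj / n)^nj)
  }
  total
}

# C_EMM(n, k) by the composition sum with multinomial coefficients:
# sum over (n1..nk), sum nj = n, of n!/(n1!...nk!) prod_j (nj/n)^nj C1(nj),
# with C1(0) = 1 and C1(m) = (m/e)^m * m_range / gamma(m).
oracle_c_emm <- function(n, k, m_range) {
  c1 <- function(m) if (m == 0) 1 else (m / exp(1))^m * m_range / gamma(m)
  total <- 0
  rec <- function(parts, left, slots) {
    if (slots == 1) {
      nj <- c(parts, left)
      coef <- factorial(n) / prod(factorial(nj))
      term <- coef * prod(ifelse(nj > 0, (nj / n)^nj, 1)) *
        prod(vapply(nj, c1, numeric(1)))
      total <<- total + term
      return(invisible())
    }
    for (v in 0:left) rec(c(parts, v), left - v, slots - 1)
  }
  rec(integer(0), n, k)
  total
}

# Joint negative log-likelihood of data and hard assignments, two ways:
# the entropy form and the direct product form -log prod_j (pi_j/(e mu_j))^nj.
oracle_joint_neg_loglik_entropy <- function(tau, z) {
  nj <- table(z)
  n <- length(tau)
  q <- as.numeric(nj) / n
  mu <- tapply(tau, z, mean)
  n * (-sum(q * log(q))) + sum(as.numeric(nj) * log(mu)) + n
}

oracle_joint_neg_loglik_product <- function(tau, z) {
  nj <- as.numeric(table(z))
  n <- length(tau)
  mu <- as.numeric(tapply(tau, z, mean))
  -sum(nj * log((nj / n) / (exp(1) * mu)))
}

# Simple seeded random positive datasets for property loops
random_tau <- function(n, seed) {
  set.seed(seed)
  exp(runif(n, -2, 4))
}
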