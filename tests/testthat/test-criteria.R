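test_that("AIC and BIC penalize the marginal fit on the codelength scale", {
  tau <- random_tau(400, 3)
  f1 <- em_fit(tau, 1, seed = 1)
  a1 <- aic(f1); b1 <- bic(f1)
  expect_equal(a1$score, -f1$loglik + 1)
  expect_equal(b1$score, -f1$loglik + 0.5 * log(400))
  # exponential MLE codelength: -log L = n log(mean) + n
  expect_equal(-f1$loglik, 400 * log(mean(tau)) + 400, tolerance = 1e-10)
  # nested penalty algebra
  f2 <- em_fit(tau, 2, seed = 1)
  expect_equal(aic(f2)$score - a1$score, (f1$loglik - f2$loglik) + 2)
})

test_that("latent-completed AIC/BIC use k* and the joint likelihood", {
  tau <- random_tau(200, 5)
  cc <- complete_latent(tau, emm_params(1, mean(tau)))
  # k* = 1 reduces to the single-exponential criteria
  expect_equal(aic_lvc(cc)$score, 200 * log(mean(tau)) + 200 + 1)
  expect_equal(bic_lvc(cc)$score, 200 * log(mean(tau)) + 200 + 0.5 * log(200))

  cc2 <- complete_latent(c(1, 3, 10, 30), emm_params(c(0.5, 0.5), c(2, 20)),
                         assignments = c(1, 1, 2, 2))
  expect_equal(aic_lvc(cc2)$score, 14.1503 + 3, tolerance = 1e-4)
  expect_equal(bic_lvc(cc2)$score,
               cc2$joint_neg_loglik + 0.5 * log(4) + 0.5 * (log(2) + log(2)))
})

test_that("the integer code is a symmetric, monotone prefix code", {
  m <- -50:50
  expect_equal(integer_codelength(m), integer_codelength(-m))
  scan <- integer_codelength(c(0:2000, round(10^seq(3.5, 6, by = 0.25))))
  expect_true(all(diff(scan) >= -1e-12))
  # Kraft partial sum stays below 1
  kraft <- sum(exp(-integer_codelength(-20000:20000)))
  expect_lte(kraft, 1)
})

test_that("exponential parametric complexity matches its closed form", {
  expect_equal(log_c_exp(1, 0, 1), -1)
  # n = 2, tau = {1,1}: L_NML = 2 log 2 (excluding the integer code)
  v <- nml_exponential(c(1, 1), bounds = list(m_min = 0, m_max = 1))
  expect_equal(v$fit_term + v$penalty_term, 2 * log(2), tolerance = 1e-12)
  expect_equal(v$score, v$fit_term + v$penalty_term + v$integer_term)
  # Stirling: log C_exp(n) - log(range) -> (1/2) log(n / 2 pi)
  n <- 1e5
  expect_equal(log_c_exp(n, 0, 1), 0.5 * log(n / (2 * pi)), tolerance = 1e-3)
  expect_error(nml_exponential(c(100, 200), bounds = list(m_min = 0, m_max = 1)),
               "widen")
})

test_that("integer bounds bracket the completed means and never degenerate", {
  expect_equal(mu_bounds(list(means_hat = c(2, 20)))[c("m_min", "m_max")],
               list(m_min = 0, m_max = 3))
  expect_equal(mu_bounds(list(means_hat = 1))[c("m_min", "m_max")],
               list(m_min = 0, m_max = 1))
  b <- mu_bounds(list(means_hat = exp(1)))
  expect_equal(c(b$m_min, b$m_max), c(1, 2))
})

test_that("the mixture complexity recursion matches exhaustive enumeration", {
  expect_equal(exp(log_c_emm(2, 1, 1)), (2 / exp(1))^2, tolerance = 1e-12)
  expect_equal(exp(log_c_emm(1, 2, 3)), 2 * 3 / exp(1), tolerance = 1e-12)
  for (m_range in c(1, 3)) {
    for (n in c(1, 2, 3, 5, 8, 12)) {
      lc <- log_c_emm(n, 4, m_range, all_k = TRUE)
      for (k in 1:4) {
        rel <- abs(lc[k] - log(oracle_c_emm(n, k, m_range))) / abs(lc[k])
        expect_lt(rel, 1e-9)
      }
    }
  }
})

test_that("the multinomial complexity recursion matches enumeration", {
  expect_equal(exp(log_c_mult(c(1, 10, 100, 1000)[1], 1)), 1)
  for (n in c(1, 10, 100, 1000)) expect_equal(exp(log_c_mult(n, 1)), 1)
  expect_equal(exp(log_c_mult(2, 2)), 2.5, tolerance = 1e-12)
  expect_equal(exp(log_c_mult(1, 3)), 3, tolerance = 1e-12)
  for (n in c(2, 4, 6, 8)) {
    for (k in 1:3) {
      lhs <- log_c_mult(n, k)
      rhs <- log(oracle_c_mult(n, k))
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("NML_LVC assembles the joint codelength plus mixture complexity", {
  cc <- complete_latent(c(1, 3, 10, 30), emm_params(c(0.5, 0.5), c(2, 20)),
                        assignments = c(1, 1, 2, 2))
  b <- mu_bounds(cc)
  expect_equal(c(b$m_min, b$m_max), c(0, 3))
  v <- l_lvc(cc, b)
  expect_equal(v$fit_term + v$penalty_term,
               cc$joint_neg_loglik + log_c_emm(4, 2, 3), tolerance = 1e-12)
  # widening the log-mean range strictly increases the codelength
  v_wide <- l_lvc(cc, list(m_min = -1, m_max = 4, m_range = 5))
  expect_gt(v_wide$fit_term + v_wide$penalty_term,
            v$fit_term + v$penalty_term)
})

test_that("DNML decomposes into data-given-assignment and assignment codes", {
  tau <- c(1, 3, 10, 30)
  cc <- complete_latent(tau, emm_params(c(0.5, 0.5), c(2, 20)),
                        assignments = c(1, 1, 2, 2))
  v <- l_dnml(cc, list(m_min = 0, m_max = 3, m_range = 3))
  l_tau_given_z <- (2 * log(2) + 2 * log(2) - lgamma(2)) +
    (2 * log(20) + 2 * log(2) - lgamma(2)) + 2 * log(3)
  l_z <- 4 * log(2) + log(oracle_c_mult(4, 2))
  expect_equal(v$fit_term + v$penalty_term, l_tau_given_z + l_z,
               tolerance = 1e-9)
  # a singleton component contributes only its log-mean to L_NML(tau | z)
  cc1 <- complete_latent(c(5, 2, 2), emm_params(c(0.5, 0.5), c(2, 5)),
                         assignments = c(2, 1, 1))
  v1 <- l_dnml(cc1)
  h <- -(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3)
  expect_equal(v1$fit_term, 4 * log(2) + log(5) + 3 * h, tolerance = 1e-12)
})

test_that("for k* = 1 both NML-based codelengths equal the exponential NML", {
  for (s in 1:100) {
    tau <- random_tau(20 + (s %% 30), 500 + s)
    cc <- complete_latent(tau, emm_params(1, mean(tau)))
    b <- mu_bounds(cc)
    ref <- nml_exponential(tau, b)$score
    lvc <- l_lvc(cc, b)$score
    dnml <- l_dnml(cc, b)$score
    expect_lt(abs(lvc - ref) / abs(ref), 1e-9)
    expect_lt(abs(dnml - ref) / abs(ref), 1e-9)
  }
})

test_that("every criterion decomposes into its recorded components", {
  tau <- random_tau(300, 9)
  fit <- fit_emm(tau, 3, n_restarts = 3, seed = 2)
  for (cr in c("AIC", "BIC", "AIC_LVC", "BIC_LVC", "NML_LVC", "DNML")) {
    v <- ietmix:::score_fit(fit, cr)
    expect_equal(v$score, v$fit_term + v$penalty_term + v$integer_term,
                 tolerance = 1e-9)
  }
})

test_that("mixture complexity grows with the number of components", {
  for (n in c(10, 100)) {
    lc <- log_c_emm(n, 10, 2, all_k = TRUE)
    expect_true(all(diff(lc) >= 0))
  }
})

test_that("model selection scans the grid and breaks ties toward smaller k", {
  x <- sample_emm(emm_params(1, 10), 500, seed = 31)
  one <- select_model(x, k_grid = 1, n_restarts = 2, seed = 1)
  expect_true(all(one$selected$k == 1))
  expect_equal(nrow(one$table), 6)

  rep2 <- select_model(x, k_grid = 1:3, criteria = c("DNML", "NML_LVC"),
                       n_restarts = 4, seed = 2)
  expect_setequal(unique(rep2$table$criterion), c("DNML", "NML_LVC"))
  for (cr in rep2$criteria) {
    sub <- rep2$table[rep2$table$criterion == cr, ]
    sel <- rep2$selected[rep2$selected$criterion == cr, ]
    expect_equal(sel$score, min(sub$score))
    expect_true(all(sel$k <= sub$k[sub$score <= sel$score + 1e-12]))
  }
  # single-exponential data: the MDL criteria pick one effective component
  expect_true(all(rep2$selected$k_star == 1))
})

test_that("selection reports serialize to JSON and TSV", {
  x <- sample_emm(emm_params(1, 5), 200, seed = 8)
  rep <- select_model(x, k_grid = 1:2, criteria = c("DNML"), n_restarts = 2,
                      seed = 3)
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(js$n, 200)
  expect_named(js$criteria, "DNML")
  expect_equal(js$criteria$DNML$selected$k, rep$selected$k)
  f <- withr::local_tempfile(fileext = ".tsv")
  report_to_tsv(rep, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$score, rep$table$score, tolerance = 1e-12)
})
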