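test_that("renewal kernels reduce to the Poisson case at nu = 1", {
  k <- renewal_kernels(1, 0)
  d <- seq(0.05, 3, by = 0.05)
  expect_equal(k$g(d), dexp(d), tolerance = 1e-10)
  expect_equal(k$G(d), pexp(d), tolerance = 1e-10)
  expect_equal(k$V(2), exp(-2), tolerance = 1e-10)
  expect_error(renewal_kernels(2, 0.6), "p must")
})

test_that("the inter-crossover density has mean 1/lambda1", {
  for (pars in list(c(4, 0), c(6, 0.1), c(2, 0.3), c(8, 0.5))) {
    k <- renewal_kernels(pars[1], pars[2])
    m <- integrate(function(d) d * k$g(d), 0, Inf, rel.tol = 1e-9)$value
    expect_equal(m, 1 / (1 - pars[2]), tolerance = 1e-6)
  }
})

test_that("void probability matches the quadrature cross-check", {
  for (pars in list(c(4, 0.1), c(8, 0.3))) {
    k <- renewal_kernels(pars[1], pars[2])
    v_quad <- 1 - (1 - pars[2]) *
      integrate(function(t) 1 - k$G(t), 0, 1.5, rel.tol = 1e-10)$value
    expect_equal(k$V(1.5), v_quad, tolerance = 1e-8)
  }
})

test_that("gamete likelihood handles the Poisson limit analytically", {
  # no crossovers: log V(L) * e^{-pL}; at nu=1, p=0, L=2 this is -2
  expect_equal(gamete_loglik(numeric(0), 2, 1, 0), -2, tolerance = 1e-10)
  # at nu = 1 the two pathways superpose to one unit-rate Poisson process:
  # the likelihood is p-invariant and every configuration has density e^{-L}
  for (p in c(0, 0.2, 0.4)) {
    expect_equal(gamete_loglik(c(0.3, 0.9, 1.4), 2, 1, p), -2,
                 tolerance = 1e-8)
    expect_equal(gamete_loglik(0.7, 1.5, 1, p), -1.5, tolerance = 1e-8)
  }
})

test_that("gamete likelihood guards its domain", {
  expect_error(gamete_loglik(seq(0.01, 0.21, by = 0.01), 4, 4, 0.1),
               "20 crossovers")
  expect_error(gamete_loglik(c(-0.1), 2, 4, 0.1), "inside")
  expect_error(gamete_loglik(c(2.5), 2, 4, 0.1), "inside")
})

test_that("likelihood integrates to one over configurations (small L)", {
  nu <- 4; p <- 0.1; L <- 0.5
  v <- exp(gamete_loglik(numeric(0), L, nu, p))
  ngrid <- 400
  xs <- (seq_len(ngrid) - 0.5) * L / ngrid
  one <- sum(exp(vapply(xs, function(x) gamete_loglik(x, L, nu, p),
                        numeric(1)))) * (L / ngrid)
  two <- 0
  h <- L / 80
  for (i in 1:80) {
    for (j in i:80) {
      if (j == i) next
      x <- c((i - 0.5) * h, (j - 0.5) * h)
      two <- two + exp(gamete_loglik(x, L, nu, p)) * h^2
    }
  }
  expect_lt(abs(v + one + two - 1), 0.01)
})

test_that("simulated configuration frequencies match the likelihood", {
  set.seed(51)
  nu <- 4; p <- 0.1; L <- 1.5
  n <- 100000
  sim <- simulate_gametes(n, L, meiosis_params(nu, p))
  k <- lengths(sim)
  v <- exp(gamete_loglik(numeric(0), L, nu, p))
  expect_lt(abs(mean(k == 0) - v), 3 * sqrt(v * (1 - v) / n))
  # binned 1-CO pattern densities within 3 Monte-Carlo sigmas
  y1 <- unlist(sim[k == 1])
  br <- seq(0, L, by = 0.25)
  counts <- hist(y1, breaks = br, plot = FALSE)$counts
  mids <- br[-1] - 0.125
  th <- vapply(mids, function(m) exp(gamete_loglik(m, L, nu, p)), numeric(1))
  expected <- th * 0.25 * n
  expect_true(all(abs(counts - expected) < 3 * sqrt(expected) + 3))
})

test_that("maximum likelihood recovers parameters and pools additively", {
  set.seed(52)
  gam <- gamete_tibble(simulate_gametes(2000, 1.5, meiosis_params(6, 0.1)), 1.5)
  fit <- fit_gamma_sprinkle(gam)
  expect_true(fit$convergence)
  expect_false(fit$boundary)
  expect_lt(abs(fit$nu - 6), 3 * sqrt(fit$var_nu))
  expect_lt(abs(fit$p - 0.1), 3 * sqrt(fit$var_p))

  # pooling two identical datasets doubles the log-likelihood surface
  both <- dplyr::bind_rows(gam, gam)
  ll1 <- dhrecomb:::sprinkle_loglik_cpp(gam$positions, gam$L, 5, 0.12)
  ll2 <- dhrecomb:::sprinkle_loglik_cpp(both$positions, both$L, 5, 0.12)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-12)
})

test_that("Poisson data drives nu to the boundary and flags the fit", {
  set.seed(53)
  gam <- gamete_tibble(simulate_gametes(800, 1.5, meiosis_params(1, 0)), 1.5)
  fit <- fit_gamma_sprinkle(gam)
  expect_lt(fit$nu, 1.3)
  expect_true(fit$boundary)
})

test_that("Fisher variances shrink like 1/n", {
  set.seed(54)
  vars <- vapply(c(500, 2000, 8000), function(n) {
    gam <- gamete_tibble(simulate_gametes(n, 1.5, meiosis_params(6, 0.1)), 1.5)
    fit_gamma_sprinkle(gam)$var_nu
  }, numeric(1))
  slope <- coef(lm(log(vars) ~ log(c(500, 2000, 8000))))[2]
  expect_lt(abs(slope + 1), 0.35)
})

test_that("fit comparisons use Welch statistics with Fisher variances", {
  fit_a <- structure(list(nu = 5, p = 0.1, var_nu = 0.25, var_p = 1e-4,
                          n_gametes = 1000, boundary = FALSE),
                     class = "gamma_sprinkle_fit")
  expect_equal(compare_fits(fit_a, fit_a, "nu")$raw_p, 1)

  set.seed(55)
  g3 <- gamete_tibble(simulate_gametes(2000, 1.5, meiosis_params(3, 0.1)), 1.5)
  g10 <- gamete_tibble(simulate_gametes(2000, 1.5, meiosis_params(10, 0.1)), 1.5)
  f3 <- fit_gamma_sprinkle(g3)
  f10 <- fit_gamma_sprinkle(g10)
  res <- compare_fits(f3, f10, "nu", n_tests = 253)
  expect_lt(res$adjusted_p, 0.01)
  expect_equal(res$direction, "B")
})

test_that("interference is detected against the Poisson null", {
  set.seed(56)
  gam <- gamete_tibble(simulate_gametes(1000, 1.5, meiosis_params(8, 0)), 1.5)
  res <- no_interference_test(gam, n_sim = 999, seed = 57)
  expect_true(all(res$p_value < 0.01))

  # Poisson data: p-values not extreme
  gam0 <- gamete_tibble(simulate_gametes(600, 1.5, meiosis_params(1, 0)), 1.5)
  res0 <- no_interference_test(gam0, n_sim = 999, seed = 58)
  expect_true(all(res0$p_value > 0.01))

  # all gametes with <= 1 crossover: distance statistic undefined
  gam1 <- gamete_tibble(list(0.2, numeric(0), 0.9), 1.5)
  gam1$line <- c("a", "b", "c")
  res1 <- no_interference_test(gam1, n_sim = 999, seed = 59)
  expect_true(is.na(res1$observed[res1$statistic == "mean_nearest_distance"]))
})

test_that("reduction factor follows the closed form and its monotonicities", {
  expect_equal(reduction_factor(1, 0.4), 1, tolerance = 1e-12)
  expect_equal(reduction_factor(1, 0.05), 1, tolerance = 1e-12)
  expect_equal(reduction_factor(8, 0.4),
               (1 - exp(-0.4)) / pgamma(0.4, 8, rate = 8), tolerance = 1e-12)
  # nonincreasing in d, nondecreasing in nu
  for (nu in c(2, 4, 8)) {
    vals <- reduction_factor(nu, seq(0.05, 1, by = 0.05))
    expect_true(all(diff(vals) <= 1e-9))
  }
  for (d in c(0.1, 0.4)) {
    vals <- vapply(c(1, 2, 4, 8), reduction_factor, numeric(1), d = d)
    expect_true(all(diff(vals) >= 0))
  }
  expect_error(reduction_factor(8, 0), "positive")
  expect_error(reduction_factor(0.5, 0.1), "nu")
})

test_that("tidy and glance summarise interference fits", {
  set.seed(60)
  gam <- gamete_tibble(simulate_gametes(400, 1.5, meiosis_params(5, 0.1)), 1.5)
  fit <- fit_gamma_sprinkle(gam)
  td <- tidy(fit)
  expect_equal(td$term, c("nu", "p"))
  expect_equal(td$estimate, c(fit$nu, fit$p))
  gl <- glance(fit)
  expect_equal(gl$n_gametes, 400)
})
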