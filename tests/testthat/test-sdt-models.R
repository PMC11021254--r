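# numerical-integration oracle for category probabilities
quad_probs <- function(mu, sigma, criteria) {
  bounds <- c(-Inf, criteria, Inf)
  p_low_high <- vapply(1:6, function(k) {
    integrate(function(x) dnorm(x, mu, sigma), bounds[k], bounds[k + 1],
              rel.tol = 1e-10)$value
  }, numeric(1))
  rev(p_low_high)  # def.old (highest strength region) first
}

test_that("category probabilities match the quadrature oracle", {
  prm <- sdt_params(1, sigma_target = 1.25, sigma_lure = 1,
                    criteria = c(-1, -0.5, 0, 0.5, 1),
                    variant = "UV_target_greater",
                    parameterization = "fix_lure_sd")
  p <- category_probs(prm)
  expect_equal(p$target, quad_probs(1, 1.25, prm$criteria), tolerance = 1e-8)
  expect_equal(p$lure, quad_probs(0, 1, prm$criteria), tolerance = 1e-8)
})

test_that("category probabilities are proper and symmetric when warranted", {
  same <- sdt_params(0, 1, 1, criteria = demo_criteria, variant = "EV")
  p <- category_probs(same)
  expect_equal(p$target, p$lure)

  set.seed(2)
  for (i in 1:20) {
    prm <- sdt_params(rnorm(1), 1, exp(rnorm(1, 0, 0.5)),
                      criteria = sort(rnorm(5, 0, 1.5) + c(0, 1e-3, 2e-3, 3e-3, 4e-3)),
                      variant = "UV_free")
    p <- category_probs(prm)
    expect_equal(sum(p$target), 1, tolerance = 1e-12)
    expect_equal(sum(p$lure), 1, tolerance = 1e-12)
    expect_true(all(p$target >= 0) && all(p$lure >= 0))
  }
})

test_that("parameter validation enforces the variant constraints", {
  expect_error(sdt_params(1, 1, 1, criteria = c(0, -1, 1, 2, 3)), "ascending")
  expect_error(sdt_params(1, 1, 0.8, criteria = demo_criteria, variant = "EV"),
               "EV")
  expect_error(sdt_params(1, 1, 1.2, criteria = demo_criteria,
                          variant = "UV_target_greater"), "UV_target_greater")
  expect_error(sdt_params(1, 1, 0.8, criteria = demo_criteria,
                          variant = "UV_lure_greater"), "UV_lure_greater")
  expect_error(sdt_params(1, sigma_target = 2, sigma_lure = 1.2,
                          criteria = demo_criteria), "fix_target_sd")
})

test_that("the multinomial log-likelihood matches explicit summation", {
  prm <- sdt_params(1, sigma_target = 1.25, sigma_lure = 1,
                    criteria = c(-1, -0.5, 0, 0.5, 1),
                    variant = "UV_target_greater",
                    parameterization = "fix_lure_sd")
  empty <- rating_counts(rep(0, 6), rep(0, 6))
  expect_equal(log_likelihood(empty, prm), 0)

  for (k in 1:6) {
    one <- rating_counts(tabulate(k, 6), rep(0, 6))
    expect_equal(log_likelihood(one, prm), log(category_probs(prm)$target[k]))
  }

  rc <- rating_counts(c(3, 5, 2, 1, 0, 4), c(0, 1, 2, 6, 3, 8))
  pt <- quad_probs(1, 1.25, prm$criteria)
  pl <- quad_probs(0, 1, prm$criteria)
  expect_equal(log_likelihood(rc, prm),
               sum(rc$n_target * log(pt)) + sum(rc$n_lure * log(pl)),
               tolerance = 1e-8)
  expect_error(log_likelihood(rating_counts(rep(0, 6), rep(0, 6)) |>
                                (\(x) { x$n_target[1] <- -1; x })(), prm),
               "non-negative")
})

test_that("serial likelihood collapses to the pooled likelihood", {
  crit <- demo_criteria
  prm <- serial_sdt_params(rep(1.3, 3), rep(1.4, 3), crit)
  nt <- list(c(4, 2, 1, 0, 0, 1), c(3, 3, 0, 1, 0, 0), c(5, 1, 1, 1, 0, 0))
  nl <- c(1, 2, 3, 4, 5, 9)
  ll_serial <- serial_log_likelihood(list(n_target_by_pos = nt, n_lure = nl), prm)
  pooled <- rating_counts(Reduce(`+`, nt), nl)
  pooled_prm <- sdt_params(1.3, sigma_target = 1.4, sigma_lure = 1,
                           criteria = crit, parameterization = "fix_lure_sd")
  expect_equal(ll_serial, log_likelihood(pooled, pooled_prm))

  zero <- serial_log_likelihood(
    list(n_target_by_pos = rep(list(rep(0, 6)), 3), n_lure = rep(0, 6)), prm)
  expect_equal(zero, 0)
})

test_that("serial likelihood matches an explicit two-position summation", {
  crit <- c(-0.8, -0.2, 0.4, 1.0, 1.8)
  prm <- serial_sdt_params(c(0.9, 2.1), c(1.2, 1.6), crit)
  nt <- list(c(2, 1, 0, 3, 0, 1), c(6, 1, 1, 0, 0, 0))
  nl <- c(0, 1, 1, 4, 3, 6)
  by_hand <- sum(nt[[1]] * log(quad_probs(0.9, 1.2, crit))) +
    sum(nt[[2]] * log(quad_probs(2.1, 1.6, crit))) +
    sum(nl * log(quad_probs(0, 1, crit)))
  expect_equal(
    serial_log_likelihood(list(n_target_by_pos = nt, n_lure = nl), prm),
    by_hand, tolerance = 1e-8)
  expect_error(serial_log_likelihood(
    list(n_target_by_pos = nt[1], n_lure = nl), prm), "positions")
})

test_that("the population zROC line is exact", {
  p1 <- sdt_params(0.7, sigma_target = 1.25, sigma_lure = 1,
                   criteria = demo_criteria, variant = "UV_target_greater",
                   parameterization = "fix_lure_sd")
  expect_equal(population_zroc(p1)$slope, 0.80)

  ev <- sdt_params(1, 1, 1, criteria = demo_criteria, variant = "EV")
  expect_equal(population_zroc(ev)$slope, 1.0)

  p3 <- sdt_params(1.5, sigma_target = 1, sigma_lure = 0.72,
                   criteria = demo_criteria, variant = "UV_free")
  pz <- population_zroc(p3)
  expect_equal(pz$slope, 0.72)
  expect_equal(pz$intercept, 1.5)
  # large-n simulated fit agrees within Monte-Carlo error
  set.seed(99)
  rc <- simulate_rating_counts(p3, 5e5, 5e5)
  fit <- zroc_fit(cumulative_rates(rc))
  expect_equal(fit$slope, 0.72, tolerance = 0.015)
  expect_equal(fit$intercept, 1.5, tolerance = 0.015)
})

test_that("likelihood peaks at the generating parameters for large counts", {
  set.seed(8)
  gen <- demo_params(mu = 1.2, sl = 0.8)
  rc <- simulate_rating_counts(gen, 5e4, 5e4)
  mus <- seq(0.8, 1.6, by = 0.05)
  lls <- vapply(mus, function(m)
    log_likelihood(rc, demo_params(mu = m, sl = 0.8)), numeric(1))
  expect_equal(mus[which.max(lls)], 1.2, tolerance = 0.051)
  sls <- seq(0.6, 1.1, by = 0.025)
  lls2 <- vapply(sls, function(s)
    log_likelihood(rc, demo_params(mu = 1.2, sl = s)), numeric(1))
  expect_equal(sls[which.max(lls2)], 0.8, tolerance = 0.026)
})
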