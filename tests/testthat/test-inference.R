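test_that("hierarchical log prior has the normal-kernel algebra", {
  spec <- hierarchical_spec("UV_free")
  loc <- c(1, -0.3, -1, rep(log(0.5), 4))
  scale <- rep(0.4, 7)

  at_loc <- hier_log_prior(spec, loc, loc, scale)
  # moving one parameter off the location by dev changes the prior by the
  # normal kernel -dev^2 / (2 scale^2)
  dev <- 0.25
  theta <- loc; theta[1] <- loc[1] + dev
  expect_equal(hier_log_prior(spec, theta, loc, scale) - at_loc,
               -dev^2 / (2 * 0.4^2))
  # doubling the deviation changes the term by -(4 - 1) dev^2 / (2 scale^2)
  theta2 <- loc; theta2[1] <- loc[1] + 2 * dev
  expect_equal(hier_log_prior(spec, theta2, loc, scale) -
                 hier_log_prior(spec, theta, loc, scale),
               -3 * dev^2 / (2 * 0.4^2))
  # the at-location participant term is -log(scale sqrt(2 pi)) per parameter
  expect_equal(hier_log_prior(spec, loc, loc, scale) -
                 sum(dnorm(loc, 0, spec$hyper_loc_sd, log = TRUE)) -
                 sum(dnorm(scale, 0, 1, log = TRUE) + log(2)),
               sum(-log(scale * sqrt(2 * pi))))
  # widening the scale beyond the deviation decreases the density slowly
  lp_scales <- vapply(c(1, 2, 4, 8), function(s)
    hier_log_prior(spec, theta, loc, rep(s, 7)), numeric(1))
  expect_true(all(diff(lp_scales) < 0))

  # non-positive scale is a rejected state, not an exception
  expect_identical(hier_log_prior(spec, loc, loc, c(-1, scale[-1])), -Inf)
})

test_that("DE proposals follow the difference-vector arithmetic", {
  expect_equal(de_propose(c(1, 2), c(5, 5), c(3, 3), gamma = 0, eps = 0),
               c(1, 2))
  expect_equal(de_propose(c(1, 2), c(4, 4), c(4, 4), gamma = 0.7, eps = 0),
               c(1, 2))
  expect_equal(de_propose(c(0, 0), c(1, 2), c(0, 1), gamma = 0.5, eps = 0),
               c(0.5, 0.5))
  set.seed(1)
  jittered <- de_propose(c(0, 0), c(0, 0), c(0, 0), gamma = 1, eps = 0.1)
  expect_true(all(abs(jittered) <= 0.1))
  expect_error(de_propose(c(1, 2), c(1, 2, 3), c(1, 2), 0.5, 0), "length")
})

test_that("split R-hat matches hand evaluation and flags divergence", {
  x <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  # halves (1,2) (3,4) (2,3) (4,5): W = 0.5, B = 2 var(1.5, 3.5, 2.5, 4.5)
  W <- 0.5; B <- 2 * var(c(1.5, 3.5, 2.5, 4.5))
  expect_equal(as.numeric(rhat(x)), sqrt((W / 2 + B / 2) / W))

  set.seed(3)
  chain <- rnorm(2000)
  expect_lt(abs(rhat(cbind(chain, chain)) - 1), 0.01)

  far <- cbind(rnorm(100, 0), rnorm(100, 100))
  expect_gt(rhat(far), 1.1)

  const <- matrix(1, 10, 2)
  expect_true(is.na(rhat(const)))
  expect_true(attr(rhat(const), "undefined"))
})

test_that("the DE-MCMC engine reproduces known posterior moments", {
  # 2-parameter Gaussian with known moments
  lp2 <- function(TH) {
    -0.5 * ((TH[, 1] - 1)^2 / 1 + (TH[, 2] + 1)^2 / 0.25)
  }
  res <- de_mcmc(lp2, init = matrix(rnorm(48), 24, 2),
                 n_burn = 500, n_keep = 1000, seed = 9)
  expect_equal(mean(res$draws[, , 1]), 1, tolerance = 0.05)
  expect_equal(mean(res$draws[, , 2]), -1, tolerance = 0.05)
  expect_equal(sd(res$draws[, , 1]), 1, tolerance = 0.1)
  expect_equal(sd(res$draws[, , 2]), 0.5, tolerance = 0.05)
})

test_that("the sampler agrees with a 1-D grid-integration oracle", {
  crit <- demo_criteria
  set.seed(3)
  gen <- demo_params(mu = 1.2, sl = 0.8)
  rc <- simulate_rating_counts(gen, 150, 150)
  ll_mu <- function(mu) vapply(mu, function(m)
    log_likelihood(rc, demo_params(mu = m, sl = 0.8)), numeric(1))
  grid <- seq(0, 3, length.out = 2001)
  lg <- ll_mu(grid); w <- exp(lg - max(lg))
  grid_mean <- sum(grid * w) / sum(w)
  grid_sd <- sqrt(sum(grid^2 * w) / sum(w) - grid_mean^2)
  res <- de_mcmc(function(TH) ll_mu(TH[, 1]),
                 init = matrix(rnorm(12, 1, 0.3), 12, 1),
                 n_burn = 300, n_keep = 500, seed = 5)
  expect_equal(mean(res$draws), grid_mean, tolerance = 3 * grid_sd / sqrt(100))
  expect_equal(sd(res$draws), grid_sd, tolerance = 0.25 * grid_sd)
})

test_that("degenerate runs and determinism contracts hold", {
  set.seed(6)
  cfg <- demo_config(n_participants = 3, n_trials = 60)
  sim <- simulate_experiment(cfg, seed = 2)
  ct <- aggregate_counts(sim$trials)
  none <- fit_sdt(ct, n_burn = 5, n_keep = 0, n_chains = 12, seed = 4,
                  store_pointwise = FALSE)
  expect_equal(dim(none$draws)[1], 0L)

  f1 <- fit_sdt(ct, n_burn = 50, n_keep = 50, n_chains = 12, seed = 4)
  f2 <- fit_sdt(ct, n_burn = 50, n_keep = 50, n_chains = 12, seed = 4)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pointwise$ll, f2$pointwise$ll)
})

test_that("sparse participants shrink toward the group", {
  set.seed(21)
  crit <- demo_criteria
  # five well-measured participants near mu = 1 and one sparse outlier
  # whose data alone say mu = 2.6
  mk <- function(id, mu, n) {
    prm <- demo_params(mu = mu, sl = 0.75)
    rc <- simulate_rating_counts(prm, n, n)
    rbind(make_trials("target", rep(1:6, rc$n_target), participant = id),
          make_trials("lure", rep(1:6, rc$n_lure), participant = id))
  }
  trials <- rbind(do.call(rbind, lapply(1:5, function(i)
    mk(sprintf("a%d", i), 1.0, 400))),
    mk("sparse", 2.6, 25))
  ct <- aggregate_counts(trials)
  fit <- fit_sdt(ct, variant = "UV_free", n_burn = 600, n_keep = 600,
                 store_pointwise = FALSE, seed = 13)
  # isolated maximum-likelihood estimate of the sparse participant's mu
  sparse_rc <- counts_cells(ct[ct$participant == "sparse", ])[[1]]
  mle <- optimize(function(m)
    log_likelihood(sparse_rc, demo_params(mu = m, sl = 0.75)),
    c(0, 5), maximum = TRUE)$maximum
  post_mu <- mean(fit_draws(fit, "p:sparse:mu"))
  group_mu <- mean(fit_draws(fit, "group:loc:mu"))
  expect_gt(mle, group_mu)
  expect_gt(post_mu, group_mu)
  expect_lt(post_mu, mle)
})

test_that("constrained variants never leave their admissible region", {
  set.seed(31)
  cfg <- demo_config(n_participants = 4, n_trials = 150)
  sim <- simulate_experiment(cfg, seed = 3)
  ct <- aggregate_counts(sim$trials)
  fit_tg <- fit_sdt(ct, variant = "UV_target_greater", n_burn = 100,
                    n_keep = 100, n_chains = 12, store_pointwise = FALSE,
                    seed = 1)
  r_tg <- sd_ratio_draws(fit_tg)
  expect_true(all(r_tg > 0 & r_tg < 1))
  for (pid in fit_tg$participants) {
    s <- fit_draws(fit_tg, paste0("p:", pid, ":s"))
    expect_true(all(plogis(s) < 1))
  }
  fit_lg <- fit_sdt(ct, variant = "UV_lure_greater", n_burn = 100,
                    n_keep = 100, n_chains = 12, store_pointwise = FALSE,
                    seed = 1)
  expect_true(all(sd_ratio_draws(fit_lg) > 1))
})

test_that("group parameters are recovered across seeded replications", {
  # 20 small replications; the generating group SD ratio and target mean
  # should fall inside their 95% HDIs in at least 90% of them
  reps <- run_recovery(list(
    replications = 20, seed = 1,
    simulation = list(n_participants = 8, n_trials = 150,
                      conditions = list(words = list(
                        loc = list(mu = 1.4, s = log(0.72), c1 = -0.8,
                                   g = log(0.55)),
                        scale = list(mu = 0.3, s = 0.1, c1 = 0.3, g = 0.2))),
                      rt = list(meanlog = log(900), sdlog = 0.35,
                                contamination = 0)),
    sampler = list(n_burn = 500, n_keep = 500)))
  expect_equal(nrow(reps), 40L)
  ratio <- reps[reps$quantity == "group_sd_ratio", ]
  mu <- reps[reps$quantity == "group_mu_target", ]
  expect_gte(mean(ratio$covered), 0.9)
  expect_gte(mean(mu$covered), 0.9)
  # posterior means cluster around the generating values
  expect_equal(mean(ratio$posterior_mean), 0.72, tolerance = 0.08)
  expect_equal(mean(mu$posterior_mean), 1.4, tolerance = 0.1)
})

test_that("the serial-position hierarchy fits Sternberg-style counts", {
  cfg <- generator_config(design = "sternberg3", n_participants = 4,
                          n_trials = 240)
  sim <- simulate_experiment(cfg, seed = 61)
  words <- sim$trials[sim$trials$condition == "words", ]
  ct <- aggregate_counts(words, by_position = TRUE)
  fit <- fit_sdt(ct, variant = "UV_free", n_burn = 150, n_keep = 150,
                 n_chains = 12, seed = 62)
  expect_true(fit$settings$serial)
  expect_equal(fit$settings$parameterization, "fix_lure_sd")
  expect_equal(fit$spec$n_positions, 3L)
  # 2 * 3 position parameters + anchor + 4 spacings per participant
  expect_equal(fit$spec$d, 11L)
  # per-position SD-ratio draws stay positive and the group mean objects
  # carry one target distribution per position
  for (pos in 1:3) expect_true(all(sd_ratio_draws(fit, position = pos) > 0))
  gp <- group_params(fit)
  expect_s3_class(gp, "serial_sdt_params")
  expect_length(gp$mu_target_by_pos, 3L)
  expect_true(all(diff(gp$criteria) > 0))
  expect_s3_class(waic_fit(fit), "waic_result")
})
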