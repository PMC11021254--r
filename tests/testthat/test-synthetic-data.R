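test_that("degenerate hierarchy and seeding behave as contracts", {
  cfg <- generator_config(
    design = "study_test", n_participants = 4, n_trials = 10,
    conditions = list(w = list(loc = list(mu = 1.2, s = -0.3, c1 = -1,
                                          g = log(0.5)),
                               scale = list(mu = 0, s = 0, c1 = 0, g = 0))))
  set.seed(1)
  ps <- draw_participants(cfg)
  mus <- vapply(ps, function(p) p$w$mu_target, numeric(1))
  expect_true(all(mus == 1.2))
  sls <- vapply(ps, function(p) p$w$sigma_lure, numeric(1))
  expect_true(all(abs(sls - exp(-0.3)) < 1e-12))

  cfg2 <- demo_config(n_participants = 3, n_trials = 40)
  s1 <- simulate_experiment(cfg2, seed = 7)
  s2 <- simulate_experiment(cfg2, seed = 7)
  expect_identical(s1$trials, s2$trials)
  expect_false(identical(s1$trials, simulate_experiment(cfg2, seed = 8)$trials))

  expect_equal(nrow(simulate_trials(draw_participants(
    generator_config(n_participants = 2, n_trials = 0)),
    generator_config(n_participants = 2, n_trials = 0))), 0L)
})

test_that("participant draws match the group moments at large n", {
  cfg <- demo_config(n_participants = 3000, n_trials = 1)
  set.seed(23)
  ps <- draw_participants(cfg)
  th <- t(vapply(ps, function(p) attr(p$words, "theta"), numeric(7)))
  loc <- c(1.4, log(0.72), -0.8, rep(log(0.55), 4))
  scale <- c(0.3, 0.1, 0.3, rep(0.2, 4))
  for (j in 1:7) {
    se_mean <- scale[j] / sqrt(3000)
    expect_lt(abs(mean(th[, j]) - loc[j]), 3 * se_mean)
    se_sd <- scale[j] / sqrt(2 * 2999)
    expect_lt(abs(sd(th[, j]) - scale[j]), 3 * se_sd)
  }
})

test_that("simulated response frequencies match the model probabilities", {
  cfg <- generator_config(
    design = "study_test", n_participants = 1, n_trials = 2e5,
    conditions = list(w = list(loc = list(mu = 1.1, s = log(0.8), c1 = -0.9,
                                          g = log(0.6)),
                               scale = list(mu = 0, s = 0, c1 = 0, g = 0))))
  sim <- simulate_experiment(cfg, seed = 33)
  prm <- sim$participants[[1]]$w
  p <- category_probs(prm)
  ct <- aggregate_counts(sim$trials)
  nt <- as.numeric(ct[1, paste0("t", 1:6)]); Nt <- sum(nt)
  nl <- as.numeric(ct[1, paste0("l", 1:6)]); Nl <- sum(nl)
  for (k in 1:6) {
    expect_lt(abs(nt[k] / Nt - p$target[k]),
              3 * sqrt(p$target[k] * (1 - p$target[k]) / Nt) + 1e-9)
    expect_lt(abs(nl[k] / Nl - p$lure[k]),
              3 * sqrt(p$lure[k] * (1 - p$lure[k]) / Nl) + 1e-9)
  }
})

test_that("RT contamination produces the configured exclusion fraction", {
  cfg <- demo_config(n_participants = 4, n_trials = 2500,
                     contamination = 0.1)
  sim <- simulate_experiment(cfg, seed = 3)
  f <- excluded_fraction(filter_by_rt(sim$trials))
  n <- nrow(sim$trials)
  expect_lt(abs(f - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # clean body lies fully inside the window
  clean <- demo_config(n_participants = 2, n_trials = 500, contamination = 0)
  expect_equal(excluded_fraction(filter_by_rt(simulate_experiment(
    clean, seed = 4)$trials)), 0)
})

test_that("Sternberg targets are balanced across serial positions", {
  cfg3 <- generator_config(design = "sternberg3", n_participants = 3,
                           n_trials = 120)
  sim <- simulate_experiment(cfg3, seed = 9)
  tgt <- sim$trials[sim$trials$item_type == "target", ]
  for (pid in unique(tgt$participant)) {
    for (cond in unique(tgt$condition)) {
      n_pos <- table(tgt$serial_position[tgt$participant == pid &
                                           tgt$condition == cond])
      expect_length(n_pos, 3L)
      expect_equal(max(n_pos), min(n_pos))  # 60 targets over 3 positions
    }
  }
  # lures never carry a position; targets and lures split evenly
  expect_true(all(is.na(sim$trials$serial_position[
    sim$trials$item_type == "lure"])))
  expect_equal(sum(sim$trials$item_type == "target"),
               sum(sim$trials$item_type == "lure"))

  cfg6 <- generator_config(design = "sternberg6", n_participants = 1,
                           n_trials = 100)
  sim6 <- simulate_experiment(cfg6, seed = 10)
  tgt6 <- sim6$trials[sim6$trials$item_type == "target" &
                        sim6$trials$condition == "words", ]
  n_pos <- table(tgt6$serial_position)
  expect_lte(max(n_pos) - min(n_pos), 1)  # 50 targets over 6 positions
})

test_that("generate -> filter -> aggregate -> zROC recovers the slope", {
  cfg <- generator_config(
    design = "study_test", n_participants = 1, n_trials = 4e5,
    conditions = list(w = list(loc = list(mu = 1.4, s = log(0.75), c1 = -0.8,
                                          g = log(0.55)),
                               scale = list(mu = 0, s = 0, c1 = 0, g = 0))),
    rt = list(meanlog = log(900), sdlog = 0.35, contamination = 0.05))
  sim <- simulate_experiment(cfg, seed = 44)
  ct <- aggregate_counts(filter_by_rt(sim$trials))
  fit <- zroc_fit(cumulative_rates(counts_cells(ct)[[1]]))
  expect_equal(fit$slope, 0.75, tolerance = 0.02)
  expect_equal(fit$intercept, 1.4, tolerance = 0.02)
})

test_that("configuration validation catches inconsistent settings", {
  expect_error(generator_config(p_target = 1.5), "p_target")
  expect_error(generator_config(
    design = "sternberg3",
    conditions = list(w = list(loc = list(mu = c(1, 2), s = 0, c1 = -1,
                                          g = log(0.5)),
                               scale = list(mu = 0, s = 0, c1 = 0, g = 0)))),
    "length 3")
  expect_error(generator_config(conditions = list(list(
    loc = list(mu = 1, s = 0, c1 = -1, g = 0),
    scale = list(mu = 0, s = 0, c1 = 0, g = 0)))), "named")
})
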