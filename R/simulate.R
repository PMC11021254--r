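DESIGNS <- c("study_test", "sternberg6", "sternberg3")

# Built-in group-level settings per design, on the sampling
# (transformed) scales of the hierarchical model. Locations echo the
# magnitude of published group estimates for word and face recognition
# (SD ratios around 0.7 for words and 0.85 for faces, larger target-mean
# separation for words, and stronger separation in the short-list
# designs); scales give moderate between-participant spread.
.default_conditions <- function(design, variant) {
  has_s <- variant != "EV"
  scl <- list(mu = 0.3, s = 0.1, c1 = 0.3, g = 0.2)
  if (design == "study_test") {
    # free SD = sigma_lure (target SD fixed at 1)
    list(
      words = list(loc = list(mu = 1.4, s = log(0.72), c1 = -0.8,
                              g = log(0.55)), scale = scl),
      faces = list(loc = list(mu = 0.9, s = log(0.87), c1 = -0.8,
                              g = log(0.55)), scale = scl))
  } else {
    P <- if (design == "sternberg6") 6L else 3L
    # free SD = sigma_target (lure fixed at N(0,1)); ratio = 1/sigma_target
    if (design == "sternberg6") {
      w <- list(mu = 2.68, ratio = 0.66); f <- list(mu = 1.05, ratio = 0.81)
    } else {
      w <- list(mu = 2.76, ratio = 0.48); f <- list(mu = 1.71, ratio = 0.83)
    }
    per_pos <- function(x) rep(x, P)
    list(
      words = list(loc = list(mu = per_pos(w$mu), s = per_pos(log(1 / w$ratio)),
                              c1 = -0.5, g = log(0.55)), scale = scl),
      faces = list(loc = list(mu = per_pos(f$mu), s = per_pos(log(1 / f$ratio)),
                              c1 = -0.5, g = log(0.55)), scale = scl))
  }
}

#' Configuration for the synthetic-experiment generator
#'
#' Describes a hierarchical confidence-rating recognition experiment: a
#' list design (long-term study-test, or a 6- or 3-item Sternberg
#' short-term design), a number of participants and of test trials per
#' condition, an equal target:lure allocation by default, and group-level
#' parameter locations and scales per condition on the transformed scales
#' used by the fitting machinery ([hierarchical_spec()]): target mean(s)
#' `mu`, free-SD term `s` (log scale for `UV_free`), criterion anchor
#' `c1`, and log-spacing `g`. For the Sternberg designs `mu` and `s` may
#' be per-position vectors (length 6 or 3); scalars are recycled.
#'
#' Trial counts default to the scale of the study designs the generator
#' emulates (67 participants x 768 trials per condition for study-test;
#' 33 x 336 and 29 x 648 for the 6- and 3-item Sternberg designs) and the
#' default group locations echo published group-level estimates so
#' simulated data resemble real recognition experiments.
#'
#' Reaction times are a stand-in that exists purely to exercise RT
#' filtering (nothing downstream models them): a log-normal body truncated
#' to the filter window plus a `contamination` fraction of out-of-window
#' RTs.
#'
#' @param design `"study_test"`, `"sternberg6"`, or `"sternberg3"`.
#' @param n_participants number of participants.
#' @param n_trials test trials per participant per condition.
#' @param p_target probability a test probe is a target (default 0.5; the
#'   allocation is exact up to rounding, and target trials are balanced
#'   across serial positions to within one trial).
#' @param variant generating model variant (see [sdt_params()]).
#' @param conditions named list of per-condition group settings, each
#'   `list(loc = list(mu, s, c1, g), scale = list(mu, s, c1, g))`;
#'   defaults supplied per design.
#' @param rt list with `meanlog`, `sdlog`, `contamination` (fraction of
#'   RTs generated outside the 300-4000 ms window).
#' @param n_sessions sessions the trials are split across.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(design = "study_test",
                             n_participants = NULL, n_trials = NULL,
                             p_target = 0.5, variant = "UV_free",
                             conditions = NULL,
                             rt = list(meanlog = log(900), sdlog = 0.35,
                                       contamination = 0.02),
                             n_sessions = NULL) {
  design <- match.arg(design, DESIGNS)
  variant <- match.arg(variant, SDT_VARIANTS)
  defaults <- switch(design,
                     study_test = list(n = 67L, t = 768L, sess = 2L),
                     sternberg6 = list(n = 33L, t = 336L, sess = 3L),
                     sternberg3 = list(n = 29L, t = 648L, sess = 3L))
  if (is.null(n_participants)) n_participants <- defaults$n
  if (is.null(n_trials)) n_trials <- defaults$t
  if (is.null(n_sessions)) n_sessions <- defaults$sess
  stopifnot(n_participants >= 1, n_trials >= 0,
            p_target >= 0, p_target <= 1,
            rt$contamination >= 0, rt$contamination <= 1)
  n_positions <- switch(design, study_test = NULL, sternberg6 = 6L,
                        sternberg3 = 3L)
  parameterization <- if (design == "study_test") "fix_target_sd" else
    "fix_lure_sd"
  if (is.null(conditions)) conditions <- .default_conditions(design, variant)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("conditions must be a named list")
  }
  spec <- hierarchical_spec(variant, parameterization,
                            n_positions = n_positions)
  conditions <- lapply(conditions, function(cond) {
    for (fld in c("loc", "scale")) {
      v <- cond[[fld]]
      stopifnot(all(c("mu", "c1", "g") %in% names(v)))
      if (variant != "EV" && is.null(v$s)) stop("condition lacks 's' ", fld)
      if (!is.null(n_positions)) {
        for (nm in c("mu", "s")) {
          if (!is.null(v[[nm]]) && length(v[[nm]]) == 1L) {
            v[[nm]] <- rep(v[[nm]], n_positions)
          }
          if (!is.null(v[[nm]]) && length(v[[nm]]) != n_positions) {
            stop("per-position '", nm, "' must have length ", n_positions)
          }
        }
      }
      cond[[fld]] <- v
    }
    cond
  })
  structure(list(design = design, n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials), p_target = p_target,
                 variant = variant, parameterization = parameterization,
                 n_positions = n_positions, conditions = conditions,
                 rt = rt, n_sessions = as.integer(n_sessions), spec = spec),
            class = "generator_config")
}

# Flatten a condition's loc or scale list to the spec's parameter order.
.group_vector <- function(config, condition, field) {
  v <- config$conditions[[condition]][[field]]
  spec <- config$spec
  out <- numeric(spec$d)
  for (j in seq_len(spec$d)) {
    kind <- spec$par_kind[j]
    val <- v[[kind]]
    if (kind %in% c("mu", "s") && !is.null(config$n_positions)) {
      pos <- as.integer(sub("^(mu|s)", "", spec$par_names[j]))
      out[j] <- val[pos]
    } else {
      out[j] <- val[1]
    }
  }
  out
}

#' Draw participant-level SDT parameters from the group distributions
#'
#' Realizes the hierarchy the fitting machinery assumes: each
#' participant's transformed parameter vector is drawn from independent
#' normals with the condition's group locations and scales, then mapped to
#' natural-scale [sdt_params()] / [serial_sdt_params()] objects (criteria
#' strictly ascending by construction). Zero group scales give every
#' participant the group values exactly.
#'
#' @param config a [generator_config()].
#' @return nested list `result[[participant]][[condition]]`, each element
#'   carrying the natural-scale parameter object plus the transformed
#'   vector as attribute `"theta"`.
#' @export
draw_participants <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  spec <- config$spec
  out <- vector("list", config$n_participants)
  names(out) <- sprintf("P%03d", seq_len(config$n_participants))
  for (i in seq_len(config$n_participants)) {
    per_cond <- list()
    for (cond in names(config$conditions)) {
      loc <- .group_vector(config, cond, "loc")
      scale <- .group_vector(config, cond, "scale")
      theta <- stats::rnorm(spec$d, loc, scale)
      B <- matrix(theta, 1, spec$d)
      q <- .block_quantities(spec, B)
      crit <- drop(q$crit)
      prm <- if (is.null(spec$n_positions)) {
        sf <- q$sigma_free[1]
        if (spec$parameterization == "fix_target_sd") {
          sdt_params(q$mu[1], sigma_target = 1, sigma_lure = sf,
                     criteria = crit, variant = spec$variant,
                     parameterization = spec$parameterization)
        } else {
          sdt_params(q$mu[1], sigma_target = sf, sigma_lure = 1,
                     criteria = crit, variant = spec$variant,
                     parameterization = spec$parameterization)
        }
      } else {
        serial_sdt_params(drop(q$mu), as.numeric(q$sigma_free), crit,
                          variant = spec$variant)
      }
      attr(prm, "theta") <- stats::setNames(theta, spec$par_names)
      per_cond[[cond]] <- prm
    }
    out[[i]] <- per_cond
  }
  out
}

# RTs: log-normal truncated to [300, 4000] for the clean fraction, and a
# contaminated fraction split between too-fast and too-slow.
.sim_rts <- function(n, rt) {
  if (n == 0L) return(numeric(0))
  contaminated <- stats::runif(n) < rt$contamination
  lo <- stats::plnorm(300, rt$meanlog, rt$sdlog)
  hi <- stats::plnorm(4000, rt$meanlog, rt$sdlog)
  out <- stats::qlnorm(stats::runif(n, lo, hi), rt$meanlog, rt$sdlog)
  n_bad <- sum(contaminated)
  if (n_bad > 0) {
    fast <- stats::runif(n_bad) < 0.5
    bad <- ifelse(fast, stats::runif(n_bad, 50, 299.9),
                  stats::runif(n_bad, 4000.1, 8000))
    out[contaminated] <- bad
  }
  out
}

# Balanced assignment of n items over k groups: each group's count within
# 1 of n/k, remainder positions chosen at random.
.balanced_positions <- function(n, k) {
  base <- rep(seq_len(k), n %/% k)
  extra <- if (n %% k > 0) sample(seq_len(k), n %% k) else integer(0)
  sample(c(base, extra))
}

#' Simulate test trials for drawn participants
#'
#' Forward model of the multinomial likelihood: for each participant and
#' condition, probes are allocated to target/lure by `p_target` (exact up
#' to rounding), target probes are balanced across serial positions (to
#' within one trial; exactly when divisible), responses are drawn from
#' [category_probs()] of the appropriate strength distribution, and RTs
#' from the configured log-normal-plus-contamination model. Trials are
#' split evenly across sessions.
#'
#' @param participants output of [draw_participants()].
#' @param config the [generator_config()] used to draw them.
#' @return trial data frame (see [read_trials()] for columns).
#' @export
simulate_trials <- function(participants, config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_trials
  rows <- list()
  for (pid in names(participants)) {
    for (cond in names(participants[[pid]])) {
      if (n == 0L) next
      prm <- participants[[pid]][[cond]]
      n_target <- round(n * config$p_target)
      n_lure <- n - n_target
      serial <- !is.null(config$n_positions)
      if (serial) {
        pos_t <- if (n_target > 0)
          .balanced_positions(n_target, config$n_positions) else integer(0)
        pt <- vapply(seq_len(config$n_positions), function(p)
          .cat_probs_gaussian(prm$mu_target_by_pos[p],
                              prm$sigma_target_by_pos[p], prm$criteria),
          numeric(6))
        resp_t <- if (n_target > 0)
          vapply(pos_t, function(p) sample.int(6L, 1L, prob = pt[, p]),
                 integer(1)) else integer(0)
        pl <- .cat_probs_gaussian(0, 1, prm$criteria)
      } else {
        pos_t <- rep(NA_integer_, n_target)
        p <- category_probs(prm)
        resp_t <- if (n_target > 0)
          sample.int(6L, n_target, replace = TRUE, prob = p$target) else
            integer(0)
        pl <- p$lure
      }
      resp_l <- if (n_lure > 0)
        sample.int(6L, n_lure, replace = TRUE, prob = pl) else integer(0)
      df <- data.frame(
        participant = pid,
        session = NA_integer_,
        condition = cond,
        item_type = c(rep("target", n_target), rep("lure", n_lure)),
        serial_position = c(pos_t, rep(NA_integer_, n_lure)),
        response = c(resp_t, resp_l),
        rt_ms = .sim_rts(n, config$rt),
        stringsAsFactors = FALSE)
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      df$session <- sort(rep_len(seq_len(config$n_sessions), nrow(df)))
      rows[[length(rows) + 1L]] <- df
    }
  }
  if (length(rows) == 0L) {
    return(validate_trials(data.frame(participant = character(),
                                      session = integer(),
                                      condition = character(),
                                      item_type = character(),
                                      serial_position = integer(),
                                      response = integer(),
                                      rt_ms = numeric(),
                                      stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_trials(out)
  out
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper: seeds the RNG, draws participant parameters from
#' the hierarchy, and simulates their trials.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list of class `sim_experiment` with `trials`, `participants`
#'   (drawn parameters), `config`, `seed`.
#' @export
simulate_experiment <- function(config, seed = 1) {
  set.seed(seed)
  participants <- draw_participants(config)
  trials <- simulate_trials(participants, config)
  structure(list(trials = trials, participants = participants,
                 config = config, seed = seed),
            class = "sim_experiment")
}
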