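#' Hierarchical model specification for SDT fitting
#'
#' Describes the participant-level parameter block and its hierarchical
#' prior for one condition. Each participant contributes, on sampling
#' (transformed) scales: the target mean(s) (identity scale), a free-SD
#' term mapped onto the variant's admissible region (absent for `EV`), the
#' first confidence criterion `c1` (identity), and four log-spacings
#' between adjacent criteria -- so criteria are strictly ascending by
#' construction and no proposal needs rejection. Participant-level
#' parameters are exchangeable draws from normal group distributions on
#' the transformed scale; group locations get zero-centered normal
#' hyperpriors (SD 3 for means and the criterion anchor, SD 1 for log-SD
#' and log-spacing terms) and group scales half-normal(0, 1) hyperpriors
#' -- minimally informative settings, all overridable via `prior`.
#'
#' The free SD parameter is mapped by variant: `exp` for `UV_free`, a
#' logistic map onto (0, 1) or a shifted exponential onto (1, Inf) for the
#' constrained variants, with the two parameterizations mirroring the
#' region so that the *SD ratio* `sigma_lure / sigma_target` is below 1
#' for `UV_target_greater` and above 1 for `UV_lure_greater` either way.
#'
#' @param variant model variant (see [sdt_params()]).
#' @param parameterization which SD is fixed at 1 (`"fix_target_sd"` for
#'   the study-test convention, `"fix_lure_sd"` for the serial-position
#'   convention).
#' @param n_positions number of study serial positions for the
#'   serial-position model (target mean and SD vary by position, criteria
#'   shared), or `NULL` for the basic model.
#' @param prior optional overrides: list with any of `loc_sd_mu`,
#'   `loc_sd_c1`, `loc_sd_s`, `loc_sd_g`, `scale_sd`.
#' @return object of class `hier_spec`.
#' @export
hierarchical_spec <- function(variant = "UV_free",
                              parameterization = "fix_target_sd",
                              n_positions = NULL, prior = NULL) {
  variant <- match.arg(variant, SDT_VARIANTS)
  parameterization <- match.arg(parameterization, SDT_PARAMETERIZATIONS)
  if (!is.null(n_positions)) {
    stopifnot(n_positions >= 1)
    if (parameterization != "fix_lure_sd") {
      stop("the serial-position model fixes the lure distribution at N(0, 1); ",
           "use parameterization = 'fix_lure_sd'")
    }
  }
  pr <- list(loc_sd_mu = 3, loc_sd_c1 = 3, loc_sd_s = 1, loc_sd_g = 1,
             scale_sd = 1)
  if (!is.null(prior)) {
    unknown <- setdiff(names(prior), names(pr))
    if (length(unknown)) stop("unknown prior field(s): ",
                              paste(unknown, collapse = ", "))
    pr[names(prior)] <- prior
  }
  has_s <- variant != "EV"
  if (is.null(n_positions)) {
    base <- c("mu", if (has_s) "s", "c1", paste0("g", 2:5))
    kind <- c("mu", if (has_s) "s", "c1", rep("g", 4))
  } else {
    pos <- seq_len(n_positions)
    base <- c(paste0("mu", pos), if (has_s) paste0("s", pos),
              "c1", paste0("g", 2:5))
    kind <- c(rep("mu", n_positions), if (has_s) rep("s", n_positions),
              "c1", rep("g", 4))
  }
  hyper_loc_sd <- unname(c(mu = pr$loc_sd_mu, s = pr$loc_sd_s,
                           c1 = pr$loc_sd_c1, g = pr$loc_sd_g)[kind])
  structure(list(variant = variant, parameterization = parameterization,
                 n_positions = n_positions, par_names = base,
                 par_kind = kind, d = length(base),
                 hyper_loc_sd = hyper_loc_sd, scale_sd = pr$scale_sd),
            class = "hier_spec")
}

# Map the sampled free-SD term onto the variant's admissible SD value.
# The free SD is sigma_lure under fix_target_sd, sigma_target under
# fix_lure_sd; the constrained region mirrors between the two so that the
# ratio sigma_lure / sigma_target lands on the intended side of 1.
sigma_free_from_s <- function(spec, s) {
  region <- switch(spec$variant,
                   EV = "one", UV_free = "pos",
                   UV_target_greater = if (spec$parameterization == "fix_target_sd")
                     "unit" else "gt1",
                   UV_lure_greater = if (spec$parameterization == "fix_target_sd")
                     "gt1" else "unit")
  switch(region,
         one = rep(1, length(s)),
         pos = exp(s),
         unit = stats::plogis(s),
         gt1 = 1 + exp(s))
}

# Inverse of sigma_free_from_s, for initializing / generating on the
# sampling scale.
s_from_sigma_free <- function(spec, sigma) {
  region <- switch(spec$variant,
                   EV = "one", UV_free = "pos",
                   UV_target_greater = if (spec$parameterization == "fix_target_sd")
                     "unit" else "gt1",
                   UV_lure_greater = if (spec$parameterization == "fix_target_sd")
                     "gt1" else "unit")
  switch(region,
         one = rep(0, length(sigma)),
         pos = log(sigma),
         unit = stats::qlogis(sigma),
         gt1 = log(sigma - 1))
}

# Criteria matrix (C x 5) from anchor vector a (C) and log-spacing matrix
# G (C x 4).
.criteria_from_block <- function(a, G) {
  E <- exp(G)
  cbind(a,
        a + E[, 1],
        a + E[, 1] + E[, 2],
        a + E[, 1] + E[, 2] + E[, 3],
        a + E[, 1] + E[, 2] + E[, 3] + E[, 4], deparse.level = 0)
}

# Category log-probabilities for C parameter rows at once.
# crit: C x 5; mu, sigma: length-C (or scalar). Returns C x 6 matrix of
# log category probabilities ordered def.old -> def.new, floored at 1e-12.
.log_cat_probs_mat <- function(crit, mu, sigma) {
  Q <- stats::pnorm((crit - mu) / sigma)
  P <- cbind(1 - Q[, 5], Q[, 5] - Q[, 4], Q[, 4] - Q[, 3],
             Q[, 3] - Q[, 2], Q[, 2] - Q[, 1], Q[, 1], deparse.level = 0)
  log(pmax(P, 1e-12))
}

# Interpret a block of participant parameters (C x d) as model quantities.
.block_quantities <- function(spec, TH) {
  d <- spec$d
  has_s <- spec$variant != "EV"
  if (is.null(spec$n_positions)) {
    mu <- TH[, 1, drop = TRUE]
    s <- if (has_s) TH[, 2, drop = TRUE] else rep(0, nrow(TH))
    i_c1 <- if (has_s) 3L else 2L
  } else {
    P <- spec$n_positions
    mu <- TH[, seq_len(P), drop = FALSE]
    s <- if (has_s) TH[, P + seq_len(P), drop = FALSE] else
      matrix(0, nrow(TH), P)
    i_c1 <- (if (has_s) 2L * P else P) + 1L
  }
  crit <- .criteria_from_block(TH[, i_c1], TH[, i_c1 + 1:4, drop = FALSE])
  sigma_free <- sigma_free_from_s(spec, s)
  if (!is.null(spec$n_positions) && is.matrix(s)) {
    sigma_free <- matrix(sigma_free, nrow(TH))
  }
  list(mu = mu, sigma_free = sigma_free, crit = crit)
}

# Log-likelihood of one participant's counts for C parameter rows at once.
# data_p: list(nt = 6-vector or P x 6 matrix, nl = 6-vector).
.ll_participant <- function(spec, TH, data_p) {
  q <- .block_quantities(spec, TH)
  if (is.null(spec$n_positions)) {
    if (spec$parameterization == "fix_target_sd") {
      st <- 1; sl <- q$sigma_free
    } else {
      st <- q$sigma_free; sl <- 1
    }
    ll <- .log_cat_probs_mat(q$crit, q$mu, st) %*% data_p$nt +
      .log_cat_probs_mat(q$crit, 0, sl) %*% data_p$nl
  } else {
    ll <- .log_cat_probs_mat(q$crit, 0, 1) %*% data_p$nl
    for (p in seq_len(spec$n_positions)) {
      ll <- ll + .log_cat_probs_mat(q$crit, q$mu[, p], q$sigma_free[, p]) %*%
        data_p$nt[p, ]
    }
  }
  drop(ll)
}

#' Hierarchical log prior density
#'
#' Sum of (a) independent normal log-densities of each participant-level
#' parameter around the group location with the group scale, on the
#' transformed sampling scale, and (b) the hyperprior log-densities of the
#' group locations (zero-centered normals) and scales (half-normals). A
#' non-positive group scale yields `-Inf` (a rejected state), not an
#' error.
#'
#' @param spec a [hierarchical_spec()].
#' @param theta participant-level parameters: matrix `participants x d`
#'   (or a length-d vector for one participant), transformed scale.
#' @param loc,scale group location and scale vectors, length d.
#' @return scalar log prior density.
#' @export
hier_log_prior <- function(spec, theta, loc, scale) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  stopifnot(ncol(theta) == spec$d, length(loc) == spec$d,
            length(scale) == spec$d)
  if (any(scale <= 0)) return(-Inf)
  part <- sum(stats::dnorm(t(theta), loc, scale, log = TRUE))
  hyper <- sum(stats::dnorm(loc, 0, spec$hyper_loc_sd, log = TRUE)) +
    sum(stats::dnorm(scale, 0, spec$scale_sd, log = TRUE) + log(2))
  part + hyper
}

# ---- data preparation -------------------------------------------------

# Build per-participant data blocks from a single-condition counts table.
.prepare_cells <- function(counts, serial) {
  stopifnot(nrow(counts) > 0)
  conds <- unique(counts$condition)
  if (length(conds) != 1L) {
    stop("counts span ", length(conds), " conditions; fit one condition at ",
         "a time (conditions share no parameters)")
  }
  pids <- sort(unique(counts$participant))
  tcols <- paste0("t", 1:6); lcols <- paste0("l", 1:6)
  if (serial) {
    positions <- sort(unique(counts$position))
    if (anyNA(positions)) stop("serial fit requires a position on every row")
    data <- lapply(pids, function(pid) {
      sub <- counts[counts$participant == pid, , drop = FALSE]
      nt <- matrix(0, length(positions), 6)
      for (i in seq_len(nrow(sub))) {
        nt[match(sub$position[i], positions), ] <-
          as.numeric(sub[i, tcols])
      }
      list(nt = nt, nl = as.numeric(sub[1, lcols]))
    })
  } else {
    positions <- NULL
    data <- lapply(pids, function(pid) {
      sub <- counts[counts$participant == pid, , drop = FALSE]
      if (nrow(sub) != 1L) {
        stop("participant ", pid, " has ", nrow(sub), " rows; aggregate ",
             "without by_position for the basic model")
      }
      list(nt = as.numeric(sub[1, tcols]), nl = as.numeric(sub[1, lcols]))
    })
  }
  list(pids = pids, condition = conds, positions = positions, data = data)
}

# ---- the blocked hierarchical DE-MCMC sampler -------------------------

#' Fit a hierarchical signal detection model by DE-MCMC
#'
#' Samples the joint posterior of all participants' SDT parameters and the
#' group-level locations/scales for one condition, using
#' differential-evolution MCMC blocked by participant and by the
#' group-level block: within each iteration every chain proposes, for each
#' block in turn, a move along a scaled difference of two other chains'
#' states for that block ([de_propose()]) and accepts by the Metropolis
#' rule on the conditional log posterior. During burn-in, occasional
#' migration steps cycle whole-chain states among a random subset of
#' chains. Runs are exactly reproducible given `seed`.
#'
#' Trial-level pointwise log-likelihood draws for WAIC are stored in
#' compressed form (per category-cell log-probabilities plus the observed
#' counts as weights) when `store_pointwise = TRUE`; see [waic_fit()].
#'
#' @param counts a `counts_table` ([aggregate_counts()]) for a single
#'   condition; rows per participant (and per position for the
#'   serial-position model).
#' @param variant model variant (see [sdt_params()]).
#' @param parameterization which SD is fixed at 1; defaults to the
#'   study-test convention, or `fix_lure_sd` automatically for serial
#'   fits.
#' @param serial fit the serial-position model? Default: `TRUE` when the
#'   counts table carries positions.
#' @param n_chains number of chains; default `max(12, 3 d)` for
#'   participant-block dimension d.
#' @param n_burn,n_keep burn-in and retained iterations per chain
#'   (`n_keep = 0` records only the initial states).
#' @param gamma difference scale; default `2.38 / sqrt(2 d_block)` per
#'   block.
#' @param eps uniform proposal jitter half-width.
#' @param migrate_prob probability of a migration step per burn-in
#'   iteration.
#' @param prior hyperprior overrides, see [hierarchical_spec()].
#' @param store_pointwise keep pointwise log-likelihood draws for WAIC.
#' @param seed integer RNG seed.
#' @return object of class `sdt_fit` with elements `draws` (array
#'   `n_keep x chains x parameters`, dimnames on the parameter axis),
#'   `spec`, `accept_rate` (per block), `pointwise` (or `NULL`),
#'   `participants`, `condition`, `settings`, `init`.
#' @export
fit_sdt <- function(counts, variant = "UV_free", parameterization = NULL,
                    serial = NULL, n_chains = NULL, n_burn = 1000,
                    n_keep = 1000, gamma = NULL, eps = 0.001,
                    migrate_prob = 0.05, prior = NULL,
                    store_pointwise = TRUE, seed = 1) {
  if (is.null(serial)) serial <- any(!is.na(counts$position))
  if (is.null(parameterization)) {
    parameterization <- if (serial) "fix_lure_sd" else "fix_target_sd"
  }
  cells <- .prepare_cells(counts, serial)
  spec <- hierarchical_spec(variant, parameterization,
                            n_positions = if (serial) length(cells$positions),
                            prior = prior)
  P <- length(cells$pids); d <- spec$d
  if (is.null(n_chains)) n_chains <- max(12L, 3L * d)
  C <- as.integer(n_chains)
  stopifnot(C >= 3L, n_burn >= 0, n_keep >= 0)
  set.seed(seed)

  gamma_part <- if (is.null(gamma)) 2.38 / sqrt(2 * d) else gamma
  gamma_grp <- if (is.null(gamma)) 2.38 / sqrt(2 * 2 * d) else gamma
  gamma_sub <- if (is.null(gamma)) 2.38 / 2 else gamma

  par_names <- c(unlist(lapply(cells$pids, function(pid)
    paste0("p:", pid, ":", spec$par_names))),
    paste0("group:loc:", spec$par_names),
    paste0("group:scale:", spec$par_names))
  idx_part <- lapply(seq_len(P), function(p) (p - 1L) * d + seq_len(d))
  i_loc <- P * d + seq_len(d)
  i_scale <- P * d + d + seq_len(d)
  npar <- P * d + 2L * d

  # initial states: mild dispersion around plausible values
  init_one <- function(kind) {
    switch(kind,
           mu = stats::rnorm(C, 1, 0.5),
           s = stats::rnorm(C, 0, 0.3),
           c1 = stats::rnorm(C, -1, 0.3),
           g = stats::rnorm(C, log(0.5), 0.3))
  }
  TH <- matrix(NA_real_, C, npar, dimnames = list(NULL, par_names))
  for (p in seq_len(P)) {
    TH[, idx_part[[p]]] <- vapply(spec$par_kind, init_one, numeric(C))
  }
  part_mat <- TH[, seq_len(P * d), drop = FALSE]
  dim(part_mat) <- c(C, d, P)
  TH[, i_loc] <- apply(part_mat, c(1, 2), mean) +
    matrix(stats::rnorm(C * d, 0, 0.1), C)
  TH[, i_scale] <- abs(matrix(stats::rnorm(C * d, 0, 0.2), C)) + 0.05

  # cached conditionals
  LL <- matrix(NA_real_, C, P)   # log-likelihood per participant
  PP <- matrix(NA_real_, C, P)   # participant-level prior term
  GL <- TH[, i_loc, drop = FALSE]; GS <- TH[, i_scale, drop = FALSE]
  for (p in seq_len(P)) {
    B <- TH[, idx_part[[p]], drop = FALSE]
    LL[, p] <- .ll_participant(spec, B, cells$data[[p]])
    PP[, p] <- rowSums(stats::dnorm(B, GL, GS, log = TRUE))
  }
  hyper_of <- function(loc, scale) {
    h <- rowSums(stats::dnorm(loc, 0,
                              matrix(spec$hyper_loc_sd, C, d, byrow = TRUE),
                              log = TRUE)) +
      rowSums(stats::dnorm(scale, 0, spec$scale_sd, log = TRUE) + log(2))
    h[apply(scale <= 0, 1, any)] <- -Inf
    h
  }
  HY <- hyper_of(GL, GS)
  if (!all(is.finite(LL))) {
    bad <- which(!apply(is.finite(LL), 2, any))[1]
    stop("initialization failed: no finite log posterior for participant ",
         cells$pids[bad])
  }

  draws <- array(NA_real_, c(n_keep, C, npar),
                 dimnames = list(NULL, NULL, par_names))
  acc_part <- 0; try_part <- 0; acc_grp <- 0; try_grp <- 0
  rep_loc <- rep(seq_len(d), P)  # group column for each participant column

  total <- n_burn + n_keep
  for (it in seq_len(total)) {
    in_burn <- it <= n_burn
    if (in_burn && migrate_prob > 0 && stats::runif(1) < migrate_prob) {
      take <- .migrate_accept(rowSums(LL) + rowSums(PP) + HY)
      TH <- TH[take, , drop = FALSE]
      LL <- LL[take, , drop = FALSE]; PP <- PP[take, , drop = FALSE]
      HY <- HY[take]
      GL <- TH[, i_loc, drop = FALSE]; GS <- TH[, i_scale, drop = FALSE]
    }
    g_p <- if (stats::runif(1) < 0.1) 1 else gamma_part
    for (p in seq_len(P)) {
      B <- TH[, idx_part[[p]], drop = FALSE]
      prop <- .de_propose_all(B, g_p, eps)
      ll_new <- .ll_participant(spec, prop, cells$data[[p]])
      pp_new <- rowSums(stats::dnorm(prop, GL, GS, log = TRUE))
      acc <- log(stats::runif(C)) < (ll_new + pp_new) - (LL[, p] + PP[, p])
      acc[!is.finite(ll_new + pp_new)] <- FALSE
      if (any(acc)) {
        TH[acc, idx_part[[p]]] <- prop[acc, , drop = FALSE]
        LL[acc, p] <- ll_new[acc]; PP[acc, p] <- pp_new[acc]
      }
      acc_part <- acc_part + sum(acc); try_part <- try_part + C
    }
    # group block: one full-dimensional DE move ...
    G <- TH[, c(i_loc, i_scale), drop = FALSE]
    g_g <- if (stats::runif(1) < 0.1) 1 else gamma_grp
    propG <- .de_propose_all(G, g_g, eps)
    pl <- propG[, seq_len(d), drop = FALSE]
    ps <- propG[, d + seq_len(d), drop = FALSE]
    ok <- !apply(ps <= 0, 1, any)
    part_all <- TH[, seq_len(P * d), drop = FALSE]
    D <- stats::dnorm(part_all, pl[, rep_loc, drop = FALSE],
                      abs(ps)[, rep_loc, drop = FALSE], log = TRUE)
    hy_new <- hyper_of(pl, ps)
    pp_tot_new <- rowSums(D)
    lp_new <- ifelse(ok, pp_tot_new + hy_new, -Inf)
    acc <- log(stats::runif(C)) < lp_new - (rowSums(PP) + HY)
    acc[!is.finite(lp_new)] <- FALSE
    if (any(acc)) {
      TH[acc, i_loc] <- pl[acc, , drop = FALSE]
      TH[acc, i_scale] <- ps[acc, , drop = FALSE]
      GL <- TH[, i_loc, drop = FALSE]; GS <- TH[, i_scale, drop = FALSE]
      for (p in seq_len(P)) {
        PP[acc, p] <- rowSums(D[acc, (p - 1L) * d + seq_len(d), drop = FALSE])
      }
      HY[acc] <- hy_new[acc]
    }
    acc_grp <- acc_grp + sum(acc); try_grp <- try_grp + C
    # ... then a sweep of 2-d (location, scale) subblock moves, which mix
    # the weakly-identified group scales far faster than the joint move
    for (j in seq_len(d)) {
      cols_j <- seq(j, by = d, length.out = P)
      theta_j <- TH[, cols_j, drop = FALSE]         # C x P
      Gj <- TH[, c(i_loc[j], i_scale[j]), drop = FALSE]
      propj <- .de_propose_all(Gj, gamma_sub, eps)
      lj <- propj[, 1]; sj <- propj[, 2]
      okj <- sj > 0
      terms_new <- stats::dnorm(theta_j, lj, abs(sj), log = TRUE)
      terms_old <- stats::dnorm(theta_j, GL[, j], GS[, j], log = TRUE)
      hyj_new <- stats::dnorm(lj, 0, spec$hyper_loc_sd[j], log = TRUE) +
        stats::dnorm(sj, 0, spec$scale_sd, log = TRUE) + log(2)
      delta <- ifelse(okj,
                      rowSums(terms_new) + hyj_new -
                        rowSums(terms_old) -
                        (stats::dnorm(GL[, j], 0, spec$hyper_loc_sd[j],
                                      log = TRUE) +
                           stats::dnorm(GS[, j], 0, spec$scale_sd,
                                        log = TRUE) + log(2)),
                      -Inf)
      acc <- log(stats::runif(C)) < delta
      acc[!is.finite(delta)] <- FALSE
      if (any(acc)) {
        TH[acc, i_loc[j]] <- lj[acc]
        TH[acc, i_scale[j]] <- sj[acc]
        PP[acc, ] <- PP[acc, , drop = FALSE] +
          terms_new[acc, , drop = FALSE] - terms_old[acc, , drop = FALSE]
        GL <- TH[, i_loc, drop = FALSE]; GS <- TH[, i_scale, drop = FALSE]
      }
      acc_grp <- acc_grp + sum(acc); try_grp <- try_grp + C
    }
    # interweaving move on one randomly chosen group parameter: propose a
    # new (location, scale) and carry the participant deviations along,
    # theta' = loc' + (theta - loc) * scale'/scale. The hierarchical-prior
    # ratio cancels the Jacobian exactly, so acceptance depends only on
    # the likelihood and the hyperprior -- this cuts through the funnel
    # between group scales and participant deviations.
    j <- sample.int(d, 1L)
    cols_j <- seq(j, by = d, length.out = P)
    Gj <- TH[, c(i_loc[j], i_scale[j]), drop = FALSE]
    propj <- .de_propose_all(Gj, gamma_sub, eps)
    lj <- propj[, 1]; sj <- propj[, 2]
    okj <- sj > 0
    ratio_s <- ifelse(okj, sj / GS[, j], 1)
    theta_j_new <- lj + (TH[, cols_j, drop = FALSE] - GL[, j]) * ratio_s
    LL_new <- matrix(NA_real_, C, P)
    for (p in seq_len(P)) {
      B <- TH[, idx_part[[p]], drop = FALSE]
      B[, j] <- theta_j_new[, p]
      LL_new[, p] <- .ll_participant(spec, B, cells$data[[p]])
    }
    hy_j_new <- stats::dnorm(lj, 0, spec$hyper_loc_sd[j], log = TRUE) +
      stats::dnorm(sj, 0, spec$scale_sd, log = TRUE) + log(2)
    hy_j_old <- stats::dnorm(GL[, j], 0, spec$hyper_loc_sd[j], log = TRUE) +
      stats::dnorm(GS[, j], 0, spec$scale_sd, log = TRUE) + log(2)
    delta <- ifelse(okj,
                    rowSums(LL_new) - rowSums(LL) + hy_j_new - hy_j_old,
                    -Inf)
    acc <- log(stats::runif(C)) < delta
    acc[!is.finite(delta)] <- FALSE
    if (any(acc)) {
      TH[acc, cols_j] <- theta_j_new[acc, , drop = FALSE]
      # prior terms rescale by scale_old/scale_new for every participant
      PP[acc, ] <- PP[acc, , drop = FALSE] + (log(GS[acc, j]) - log(sj[acc]))
      TH[acc, i_loc[j]] <- lj[acc]
      TH[acc, i_scale[j]] <- sj[acc]
      LL[acc, ] <- LL_new[acc, , drop = FALSE]
      GL <- TH[, i_loc, drop = FALSE]; GS <- TH[, i_scale, drop = FALSE]
    }
    acc_grp <- acc_grp + sum(acc); try_grp <- try_grp + C
    HY <- hyper_of(GL, GS)
    if (!in_burn) draws[it - n_burn, , ] <- TH
  }

  pointwise <- NULL
  if (store_pointwise && n_keep > 0) {
    pointwise <- .pointwise_loglik(spec, draws, cells, idx_part)
  }
  structure(list(draws = draws, spec = spec,
                 participants = cells$pids, condition = cells$condition,
                 positions = cells$positions,
                 accept_rate = c(participant = if (try_part) acc_part / try_part else NA,
                                 group = if (try_grp) acc_grp / try_grp else NA),
                 pointwise = pointwise,
                 settings = list(variant = variant,
                                 parameterization = parameterization,
                                 serial = serial, n_chains = C,
                                 n_burn = n_burn, n_keep = n_keep,
                                 gamma_participant = gamma_part,
                                 gamma_group = gamma_grp, eps = eps,
                                 migrate_prob = migrate_prob, seed = seed)),
            class = "sdt_fit")
}

# Pointwise log-likelihood draws in compressed (cell x category) form:
# one column per (participant, row, category) with the observed count as
# weight. Trials sharing a cell and category have identical pointwise
# log-likelihoods, so this is the exact trial-level pointwise matrix up to
# repetition of columns.
.pointwise_loglik <- function(spec, draws, cells, idx_part) {
  S <- dim(draws)[1] * dim(draws)[2]
  flat <- draws
  dim(flat) <- c(S, dim(draws)[3])
  ll_cols <- list(); w <- list()
  for (p in seq_along(cells$pids)) {
    B <- flat[, idx_part[[p]], drop = FALSE]
    q <- .block_quantities(spec, B)
    dat <- cells$data[[p]]
    if (is.null(spec$n_positions)) {
      if (spec$parameterization == "fix_target_sd") {
        st <- 1; sl <- q$sigma_free
      } else {
        st <- q$sigma_free; sl <- 1
      }
      ll_cols[[length(ll_cols) + 1L]] <- .log_cat_probs_mat(q$crit, q$mu, st)
      w[[length(w) + 1L]] <- dat$nt
      ll_cols[[length(ll_cols) + 1L]] <- .log_cat_probs_mat(q$crit, 0, sl)
      w[[length(w) + 1L]] <- dat$nl
    } else {
      for (pos in seq_len(spec$n_positions)) {
        ll_cols[[length(ll_cols) + 1L]] <-
          .log_cat_probs_mat(q$crit, q$mu[, pos], q$sigma_free[, pos])
        w[[length(w) + 1L]] <- dat$nt[pos, ]
      }
      ll_cols[[length(ll_cols) + 1L]] <- .log_cat_probs_mat(q$crit, 0, 1)
      w[[length(w) + 1L]] <- dat$nl
    }
  }
  ll <- do.call(cbind, ll_cols)
  w <- unlist(w)
  keep <- w > 0
  list(ll = ll[, keep, drop = FALSE], weights = w[keep])
}

#' @export
print.sdt_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf("sdt_fit: %s (%s%s), condition '%s'\n", s$variant,
              s$parameterization, if (s$serial) ", serial" else "",
              x$condition))
  cat(sprintf("  %d participants, %d chains x %d kept draws (burn %d), seed %d\n",
              length(x$participants), s$n_chains, s$n_keep, s$n_burn, s$seed))
  cat(sprintf("  acceptance: participant %.2f, group %.2f\n",
              x$accept_rate[["participant"]], x$accept_rate[["group"]]))
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param fit an [fit_sdt()] result.
#' @param parameter parameter name (see `dimnames(fit$draws)[[3]]`), e.g.
#'   `"group:loc:mu"` or `"p:<id>:s"`.
#' @return matrix `iterations x chains`.
#' @export
fit_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "sdt_fit"))
  pn <- dimnames(fit$draws)[[3]]
  if (!parameter %in% pn) stop("unknown parameter: ", parameter)
  fit$draws[, , parameter, drop = TRUE]
}

#' Posterior draws of the group-level SD ratio
#'
#' Maps draws of the group location of the free-SD term through the
#' variant's transform and converts to the SD ratio
#' `sigma_lure / sigma_target` (the population zROC slope). For serial
#' fits, pass the position.
#'
#' @param fit an [fit_sdt()] result (non-`EV` variant).
#' @param position study position for serial fits.
#' @return matrix `iterations x chains` of SD-ratio draws.
#' @export
sd_ratio_draws <- function(fit, position = NULL) {
  spec <- fit$spec
  if (spec$variant == "EV") stop("the EV variant has a fixed SD ratio of 1")
  par <- if (is.null(spec$n_positions)) "group:loc:s" else {
    stopifnot(!is.null(position))
    paste0("group:loc:s", position)
  }
  s <- fit_draws(fit, par)
  sf <- sigma_free_from_s(spec, s)
  ratio <- if (spec$parameterization == "fix_target_sd") sf else 1 / sf
  matrix(ratio, nrow(s), ncol(s))
}

#' Posterior summary table
#'
#' Posterior mean, SD, 95% highest-density interval and split R-hat for
#' each (or a subset of) parameters.
#'
#' @param fit an [fit_sdt()] result.
#' @param parameters optional character vector of parameter names;
#'   defaults to the group-level block.
#' @param mass HDI mass.
#' @return data frame with one row per parameter.
#' @export
posterior_summary <- function(fit, parameters = NULL, mass = 0.95) {
  pn <- dimnames(fit$draws)[[3]]
  if (is.null(parameters)) parameters <- grep("^group:", pn, value = TRUE)
  rows <- lapply(parameters, function(p) {
    x <- fit_draws(fit, p)
    h <- hdi(x, mass)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               hdi_lo = h[1], hdi_hi = h[2],
               rhat = as.numeric(rhat(x)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level SDT parameters at the posterior mean
#'
#' Builds an [sdt_params()] (or [serial_sdt_params()]) object from the
#' posterior means of the group location parameters -- the model's
#' description of the average participant, used e.g. for predicted
#' ROC/zROC overlays.
#'
#' @param fit an [fit_sdt()] result.
#' @return an `sdt_params` or `serial_sdt_params` object.
#' @export
group_params <- function(fit) {
  spec <- fit$spec
  loc <- vapply(paste0("group:loc:", spec$par_names),
                function(p) mean(fit_draws(fit, p)), numeric(1))
  names(loc) <- spec$par_names
  B <- matrix(loc, 1, spec$d)
  q <- .block_quantities(spec, B)
  crit <- drop(q$crit)
  if (is.null(spec$n_positions)) {
    sf <- q$sigma_free[1]
    if (spec$parameterization == "fix_target_sd") {
      sdt_params(mu_target = q$mu[1], sigma_target = 1, sigma_lure = sf,
                 criteria = crit, variant = spec$variant,
                 parameterization = spec$parameterization)
    } else {
      sdt_params(mu_target = q$mu[1], sigma_target = sf, sigma_lure = 1,
                 criteria = crit, variant = spec$variant,
                 parameterization = spec$parameterization)
    }
  } else {
    serial_sdt_params(mu_target_by_pos = drop(q$mu),
                      sigma_target_by_pos = as.numeric(q$sigma_free),
                      criteria = crit, variant = spec$variant)
  }
}
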