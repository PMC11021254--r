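#' Differential-evolution Metropolis proposal
#'
#' Proposes a new parameter vector for chain i from the scaled difference of
#' two other chains' states plus small uniform jitter:
#' `theta* = theta_i + gamma * (theta_m - theta_n) + U(-eps, eps)` per
#' coordinate. Because the proposal direction adapts to the current spread
#' of the chain population, the move is robust to correlated parameters.
#'
#' @param theta_i current state of the chain being updated.
#' @param theta_m,theta_n states of two other, distinct chains.
#' @param gamma scale applied to the difference vector (a common default is
#'   `2.38 / sqrt(2 d)` for block dimension d).
#' @param eps half-width of the uniform jitter.
#' @return proposed parameter vector.
#' @export
de_propose <- function(theta_i, theta_m, theta_n, gamma, eps) {
  d <- length(theta_i)
  if (length(theta_m) != d || length(theta_n) != d) {
    stop("chain state vectors must have equal length")
  }
  jitter <- if (eps > 0) stats::runif(d, -eps, eps) else numeric(d)
  theta_i + gamma * (theta_m - theta_n) + jitter
}

# Pick, for each of C chains, two distinct partner chains (both != self).
# Returns a C x 2 integer matrix.
.de_partners <- function(C) {
  m <- matrix(0L, C, 2)
  for (i in seq_len(C)) m[i, ] <- sample(seq_len(C)[-i], 2L)
  m
}

# Vectorized DE proposals for all chains of one block: TH is C x d.
.de_propose_all <- function(TH, gamma, eps) {
  C <- nrow(TH)
  pr <- .de_partners(C)
  prop <- TH + gamma * (TH[pr[, 1], , drop = FALSE] - TH[pr[, 2], , drop = FALSE])
  if (eps > 0) prop <- prop + matrix(stats::runif(length(prop), -eps, eps), C)
  prop
}

# Cyclic migration step: a random subset of chains passes its state around
# a ring; each receiving chain accepts by the usual Metropolis rule on the
# supplied total log posteriors. Returns the permutation actually applied
# per chain (index of the chain whose state each chain now holds).
.migrate_accept <- function(lp) {
  C <- length(lp)
  k <- sample(2:C, 1L)
  ring <- sample(seq_len(C), k)
  donor <- c(ring[-1], ring[1])          # chain ring[j] receives donor[j]'s state
  take <- seq_len(C)
  for (j in seq_along(ring)) {
    if (log(stats::runif(1)) < lp[donor[j]] - lp[ring[j]]) take[ring[j]] <- donor[j]
  }
  take
}

#' Differential-evolution MCMC on an arbitrary log posterior
#'
#' A population MCMC sampler: `nrow(init)` chains evolve in parallel, each
#' proposing moves along scaled difference vectors between two randomly
#' chosen other chains ([de_propose()]) and accepting by the Metropolis
#' rule. During burn-in, occasional migration steps swap states cyclically
#' among a random subset of chains to free stuck chains. This generic
#' engine is also the building block of the blocked hierarchical sampler in
#' [fit_sdt()].
#'
#' @param log_post function taking a `chains x d` matrix and returning a
#'   numeric vector of log posterior densities (use `-Inf` for invalid
#'   states).
#' @param init `chains x d` numeric matrix of starting states (chains >= 3).
#' @param n_burn,n_keep numbers of burn-in and retained iterations
#'   (`n_keep = 0` returns the initial states only, with zero draws).
#' @param gamma difference-vector scale; default `2.38 / sqrt(2 d)`.
#' @param eps uniform jitter half-width (default 0.001).
#' @param migrate_prob probability of a migration step per burn-in
#'   iteration.
#' @param seed optional integer seed set before sampling.
#' @return list with `draws` (array `n_keep x chains x d`), `log_post`
#'   (matrix `n_keep x chains`), `accept_rate`, `init`, and the settings.
#' @export
de_mcmc <- function(log_post, init, n_burn = 1000, n_keep = 1000,
                    gamma = NULL, eps = 0.001, migrate_prob = 0.05,
                    seed = NULL) {
  stopifnot(is.matrix(init), nrow(init) >= 3L, n_burn >= 0, n_keep >= 0)
  if (!is.null(seed)) set.seed(seed)
  C <- nrow(init); d <- ncol(init)
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * d)
  TH <- init
  lp <- log_post(TH)
  if (!any(is.finite(lp))) stop("no chain has a finite initial log posterior")
  draws <- array(NA_real_, c(n_keep, C, d),
                 dimnames = list(NULL, NULL, colnames(init)))
  lp_keep <- matrix(NA_real_, n_keep, C)
  n_acc <- 0L; n_try <- 0L
  total <- n_burn + n_keep
  for (it in seq_len(total)) {
    in_burn <- it <= n_burn
    if (in_burn && migrate_prob > 0 && stats::runif(1) < migrate_prob) {
      take <- .migrate_accept(lp)
      TH <- TH[take, , drop = FALSE]
      lp <- lp[take]
    }
    prop <- .de_propose_all(TH, gamma, eps)
    lp_prop <- log_post(prop)
    acc <- log(stats::runif(C)) < lp_prop - lp
    acc[!is.finite(lp_prop)] <- FALSE
    TH[acc, ] <- prop[acc, , drop = FALSE]
    lp[acc] <- lp_prop[acc]
    n_acc <- n_acc + sum(acc); n_try <- n_try + C
    if (!in_burn) {
      k <- it - n_burn
      draws[k, , ] <- TH
      lp_keep[k, ] <- lp
    }
  }
  list(draws = draws, log_post = lp_keep,
       accept_rate = if (n_try > 0) n_acc / n_try else NA_real_,
       init = init, final = TH,
       settings = list(n_burn = n_burn, n_keep = n_keep, gamma = gamma,
                       eps = eps, migrate_prob = migrate_prob, seed = seed))
}

#' Split-chain potential scale reduction factor
#'
#' The split form of the Gelman-Rubin convergence diagnostic: each chain is
#' halved, the between- and within-(half-)chain variances are compared, and
#' values near 1 indicate the chains are sampling the same distribution.
#' Convergence is conventionally declared below 1.1.
#'
#' @param draws matrix of draws, `iterations x chains` (at least 4
#'   iterations and 2 chains), or an [fit_sdt()] result together with
#'   `parameter`.
#' @param parameter parameter name when `draws` is an `sdt_fit`.
#' @return the split R-hat value; `NA` (with attribute
#'   `"undefined" = TRUE`) when the parameter is constant across all
#'   chains so the statistic is undefined.
#' @export
rhat <- function(draws, parameter = NULL) {
  if (inherits(draws, "sdt_fit")) {
    stopifnot(!is.null(parameter))
    draws <- fit_draws(draws, parameter)
  }
  stopifnot(is.matrix(draws), nrow(draws) >= 4L, ncol(draws) >= 2L)
  n_half <- floor(nrow(draws) / 2)
  splits <- cbind(draws[seq_len(n_half), , drop = FALSE],
                  draws[n_half + seq_len(n_half), , drop = FALSE])
  if (diff(range(splits)) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  m <- ncol(splits); n <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(structure(NA_real_, undefined = TRUE))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing a given posterior mass, computed from the
#' sorted pooled draws.
#'
#' @param x numeric sample (matrices are pooled).
#' @param mass probability mass (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  x <- sort(as.numeric(x))
  n <- length(x)
  stopifnot(n >= 2L, mass > 0, mass < 1)
  k <- max(2L, ceiling(mass * n))  # points inside the interval
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}
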