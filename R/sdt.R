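SDT_VARIANTS <- c("EV", "UV_free", "UV_target_greater", "UV_lure_greater")
SDT_PARAMETERIZATIONS <- c("fix_target_sd", "fix_lure_sd")

#' Gaussian signal detection parameters for one condition
#'
#' One condition's strength model: targets are `N(mu_target, sigma_target)`
#' and lures `N(mu_lure, sigma_lure)` on a latent memory-strength axis, with
#' five strictly ascending confidence criteria partitioning the axis into
#' six response categories. The lure mean is fixed at 0 to identify the
#' model, and exactly one standard deviation is fixed at 1 depending on the
#' `parameterization`: `fix_target_sd` (target SD 1, lure SD free, the
#' study-test convention) or `fix_lure_sd` (lure SD 1, target SD free, the
#' Sternberg/serial-position convention). Either way the ratio
#' `sigma_lure / sigma_target` -- the population zROC slope -- is
#' recoverable via [population_zroc()].
#'
#' Variants: `EV` (equal variance), `UV_free` (SD ratio free),
#' `UV_target_greater` (greater target variability, ratio in (0, 1)),
#' `UV_lure_greater` (greater lure variability, ratio > 1).
#'
#' @param mu_target target distribution mean (strength units).
#' @param sigma_target,sigma_lure positive standard deviations; the one
#'   fixed by `parameterization` must equal 1.
#' @param criteria strictly ascending numeric 5-vector of criteria.
#' @param mu_lure lure mean, fixed at 0.
#' @param variant one of `"EV"`, `"UV_free"`, `"UV_target_greater"`,
#'   `"UV_lure_greater"`.
#' @param parameterization `"fix_target_sd"` or `"fix_lure_sd"`.
#' @return object of class `sdt_params`.
#' @export
sdt_params <- function(mu_target, sigma_target = 1, sigma_lure = 1,
                       criteria, mu_lure = 0,
                       variant = "UV_free",
                       parameterization = "fix_target_sd") {
  variant <- match.arg(variant, SDT_VARIANTS)
  parameterization <- match.arg(parameterization, SDT_PARAMETERIZATIONS)
  stopifnot(length(criteria) == 5L, is.numeric(criteria),
            is.numeric(mu_target), length(mu_target) == 1L,
            sigma_target > 0, sigma_lure > 0)
  if (any(diff(criteria) <= 0)) stop("criteria must be strictly ascending")
  fixed <- switch(parameterization, fix_target_sd = sigma_target,
                  fix_lure_sd = sigma_lure)
  if (abs(fixed - 1) > 1e-9) {
    stop("the SD fixed by '", parameterization, "' must equal 1")
  }
  ratio <- sigma_lure / sigma_target
  if (variant == "EV" && abs(ratio - 1) > 1e-9) {
    stop("EV variant requires sigma_target == sigma_lure")
  }
  if (variant == "UV_target_greater" && ratio >= 1) {
    stop("UV_target_greater requires sigma_lure/sigma_target in (0, 1)")
  }
  if (variant == "UV_lure_greater" && ratio <= 1) {
    stop("UV_lure_greater requires sigma_lure/sigma_target > 1")
  }
  structure(list(mu_target = mu_target, sigma_target = sigma_target,
                 mu_lure = mu_lure, sigma_lure = sigma_lure,
                 criteria = as.numeric(criteria), variant = variant,
                 parameterization = parameterization),
            class = "sdt_params")
}

#' @export
print.sdt_params <- function(x, ...) {
  cat(sprintf("sdt_params [%s, %s]\n", x$variant, x$parameterization))
  cat(sprintf("  target N(%.3f, %.3f)  lure N(%.3f, %.3f)  ratio %.3f\n",
              x$mu_target, x$sigma_target, x$mu_lure, x$sigma_lure,
              x$sigma_lure / x$sigma_target))
  cat("  criteria:", paste(sprintf("%.3f", x$criteria), collapse = " "), "\n")
  invisible(x)
}

# Category probabilities for one Gaussian strength distribution.
# Categories are ordered def.old -> def.new; higher strength means an
# "older" response, so category 1 is the region above c5 and category 6
# the region below c1.
.cat_probs_gaussian <- function(mu, sigma, criteria) {
  q <- stats::pnorm((criteria - mu) / sigma)  # P(X <= c_j), ascending j
  rev(diff(c(0, q, 1)))
}

#' Response-category probabilities under a signal detection model
#'
#' With criteria `c1 < ... < c5` on the strength axis (and implicit
#' boundaries at minus/plus infinity), a strength falling between adjacent
#' criteria yields the corresponding confidence category; strengths
#' exceeding the highest criterion yield "definitely old". Probabilities
#' are returned ordered "definitely old" to "definitely new" for both the
#' target and the lure distribution; each 6-vector sums to 1.
#'
#' @param params an [sdt_params()] object.
#' @return list with numeric 6-vectors `target` and `lure`.
#' @export
category_probs <- function(params) {
  stopifnot(inherits(params, "sdt_params"))
  if (any(diff(params$criteria) <= 0)) stop("criteria must be strictly ascending")
  list(target = .cat_probs_gaussian(params$mu_target, params$sigma_target,
                                    params$criteria),
       lure = .cat_probs_gaussian(params$mu_lure, params$sigma_lure,
                                  params$criteria))
}

#' Multinomial log-likelihood of rating counts
#'
#' Categorical (multinomial, constant coefficient omitted) log-likelihood
#' of a 2 x 6 rating-count table under a signal detection model:
#' `sum_k n_target_k log p_target_k + sum_k n_lure_k log p_lure_k`.
#' Category probabilities are floored at 1e-12 before taking logs so that
#' numerically-zero tail masses cannot produce `-Inf` for empty categories.
#'
#' @param counts a [rating_counts()] object (or list with `n_target`,
#'   `n_lure`).
#' @param params an [sdt_params()] object.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(counts, params) {
  nt <- counts$n_target; nl <- counts$n_lure
  if (any(nt < 0) || any(nl < 0)) stop("counts must be non-negative")
  p <- category_probs(params)
  sum(nt * log(pmax(p$target, 1e-12))) + sum(nl * log(pmax(p$lure, 1e-12)))
}

#' Serial-position signal detection parameters
#'
#' Sternberg-style variant in which the target distribution's mean and SD
#' vary with the item's study serial position while a single standard
#' normal lure distribution (`mu = 0`, `sigma = 1`, i.e. the `fix_lure_sd`
#' parameterization) and a single shared set of five confidence criteria
#' apply across positions.
#'
#' @param mu_target_by_pos numeric vector of target means, one per study
#'   position (length = list length, e.g. 6 or 3).
#' @param sigma_target_by_pos positive vector of target SDs, same length.
#' @param criteria strictly ascending 5-vector shared across positions.
#' @param variant as in [sdt_params()] (constraints apply to the SD ratio
#'   `1 / sigma_target_p` at every position).
#' @return object of class `serial_sdt_params`.
#' @export
serial_sdt_params <- function(mu_target_by_pos, sigma_target_by_pos,
                              criteria, variant = "UV_free") {
  variant <- match.arg(variant, SDT_VARIANTS)
  P <- length(mu_target_by_pos)
  stopifnot(P >= 1L, length(sigma_target_by_pos) == P,
            all(sigma_target_by_pos > 0), length(criteria) == 5L)
  if (any(diff(criteria) <= 0)) stop("criteria must be strictly ascending")
  structure(list(mu_target_by_pos = as.numeric(mu_target_by_pos),
                 sigma_target_by_pos = as.numeric(sigma_target_by_pos),
                 criteria = as.numeric(criteria), variant = variant,
                 n_positions = P),
            class = "serial_sdt_params")
}

#' Serial-position log-likelihood
#'
#' Sums, over study positions, the multinomial target terms under that
#' position's `N(mu_p, sigma_p)` strength distribution, plus the lure terms
#' under the standard normal -- all with the shared criteria. The lure
#' counts enter once (a probe list has a single pooled lure vector, since
#' lures have no serial position).
#'
#' When all positions share identical parameters this collapses to
#' [log_likelihood()] with the target counts pooled.
#'
#' @param counts_by_pos list with `n_target_by_pos` (list or matrix of 6-
#'   vectors, one per position) and `n_lure` (pooled 6-vector); a list of
#'   [rating_counts()] objects sharing one lure vector also works, where
#'   the first element's `n_lure` is used.
#' @param params a [serial_sdt_params()] object.
#' @return scalar log-likelihood.
#' @export
serial_log_likelihood <- function(counts_by_pos, params) {
  stopifnot(inherits(params, "serial_sdt_params"))
  if (is.list(counts_by_pos) && !is.null(counts_by_pos$n_target_by_pos)) {
    nt_list <- counts_by_pos$n_target_by_pos
    if (is.matrix(nt_list)) nt_list <- asplit(nt_list, 1)
    nl <- counts_by_pos$n_lure
  } else if (is.list(counts_by_pos) && inherits(counts_by_pos[[1]], "rating_counts")) {
    nt_list <- lapply(counts_by_pos, `[[`, "n_target")
    nl <- counts_by_pos[[1]]$n_lure
  } else {
    stop("counts_by_pos must carry per-position target counts and a pooled lure vector")
  }
  P <- params$n_positions
  if (length(nt_list) != P) {
    stop("number of target count vectors (", length(nt_list),
         ") does not match the number of positions (", P, ")")
  }
  ll <- 0
  for (p in seq_len(P)) {
    nt <- nt_list[[p]]
    if (any(nt < 0)) stop("counts must be non-negative")
    pt <- .cat_probs_gaussian(params$mu_target_by_pos[p],
                              params$sigma_target_by_pos[p], params$criteria)
    ll <- ll + sum(nt * log(pmax(pt, 1e-12)))
  }
  if (any(nl < 0)) stop("counts must be non-negative")
  pl <- .cat_probs_gaussian(0, 1, params$criteria)
  ll + sum(nl * log(pmax(pl, 1e-12)))
}

#' Exact population zROC line implied by SDT parameters
#'
#' Under the Gaussian model the z-transformed ROC is exactly linear:
#' `z(HR) = (mu_target - mu_lure)/sigma_target +
#' (sigma_lure/sigma_target) * z(FAR)`. Returns that line's slope and
#' intercept -- the large-sample limit of [zroc_fit()] on data simulated
#' from the same parameters.
#'
#' @param params an [sdt_params()] object.
#' @return list with `slope` (`sigma_lure / sigma_target`) and `intercept`
#'   (`(mu_target - mu_lure) / sigma_target`).
#' @export
population_zroc <- function(params) {
  stopifnot(inherits(params, "sdt_params"))
  list(slope = params$sigma_lure / params$sigma_target,
       intercept = (params$mu_target - params$mu_lure) / params$sigma_target)
}

#' Simulate rating counts from a signal detection model
#'
#' Draws multinomial response counts for a given number of target and lure
#' trials directly from [category_probs()]. A fast forward model for
#' slope-recovery checks at large n; the trial-level generator in
#' [simulate_experiment()] should be used when RTs and serial positions
#' matter.
#'
#' @param params an [sdt_params()] object.
#' @param n_target,n_lure numbers of trials.
#' @return a [rating_counts()] object.
#' @export
simulate_rating_counts <- function(params, n_target, n_lure) {
  p <- category_probs(params)
  rating_counts(stats::rmultinom(1, n_target, p$target)[, 1],
                stats::rmultinom(1, n_lure, p$lure)[, 1])
}
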