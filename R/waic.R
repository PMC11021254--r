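#' Widely applicable information criterion
#'
#' WAIC from a draws-by-observations matrix of pointwise log-likelihoods:
#' `lppd = sum_i log mean_s exp(ll_si)` (log-mean-exp computed stably by
#' max subtraction), the effective-parameter penalty
#' `p_waic = sum_i var_s(ll_si)` (sample variance, divisor S - 1), and
#' `waic = -2 (lppd - p_waic)` on the deviance scale. Observations are
#' individual trials; `weights` lets identical trials (same cell and
#' response category) share one column, with the column counted `weights`
#' times -- exactly equivalent to repeating the column.
#'
#' With a single draw the variance penalty is undefined under the S - 1
#' divisor; `p_waic` is then reported as 0 and the result carries
#' `degenerate = TRUE`.
#'
#' @param pointwise_loglik numeric matrix, draws x observations.
#' @param weights optional non-negative weights per observation column
#'   (default all 1).
#' @return object of class `waic_result`: list with `lppd`, `p_waic`,
#'   `waic`, `n_points`, `degenerate`.
#' @export
waic <- function(pointwise_loglik, weights = NULL) {
  ll <- as.matrix(pointwise_loglik)
  S <- nrow(ll); K <- ncol(ll)
  stopifnot(S >= 1L, K >= 1L)
  if (is.null(weights)) weights <- rep(1, K)
  stopifnot(length(weights) == K, all(weights >= 0))
  mx <- apply(ll, 2, max)
  lme <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  degenerate <- S < 2L
  v <- if (degenerate) rep(0, K) else apply(ll, 2, stats::var)
  lppd <- sum(weights * lme)
  p_waic <- sum(weights * v)
  if (degenerate) {
    warning("single posterior draw: p_waic is undefined and reported as 0")
  }
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic),
                 n_points = sum(weights), degenerate = degenerate),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f (lppd %.2f, p_waic %.2f, %g observations)%s\n",
              x$waic, x$lppd, x$p_waic, x$n_points,
              if (x$degenerate) " [single-draw: penalty undefined]" else ""))
  invisible(x)
}

#' WAIC of a fitted hierarchical SDT model
#'
#' Computes [waic()] from the trial-level pointwise log-likelihood draws
#' stored by [fit_sdt()].
#'
#' @param fit an [fit_sdt()] result with `store_pointwise = TRUE`.
#' @return a `waic_result`.
#' @export
waic_fit <- function(fit) {
  stopifnot(inherits(fit, "sdt_fit"))
  if (is.null(fit$pointwise)) {
    stop("fit was run with store_pointwise = FALSE; refit to compute WAIC")
  }
  waic(fit$pointwise$ll, fit$pointwise$weights)
}

# simplicity order used to break WAIC ties: fewer free parameters first,
# then the constrained before the free unequal-variance variant
.VARIANT_ORDER <- c("EV", "UV_target_greater", "UV_lure_greater", "UV_free")

#' WAIC difference-score table across model variants
#'
#' Subtracts the minimum WAIC from each model's WAIC so the winning model
#' scores 0 and all others positive; differences of ten or more are
#' conventionally considered large and flagged. Exact ties are broken
#' toward the simpler variant in the order `EV`, `UV_target_greater`,
#' `UV_lure_greater`, `UV_free` (labels not in that list rank after it, in
#' input order).
#'
#' @param results named list of `waic_result` objects (or a named numeric
#'   vector of WAIC values); names are the model labels and must be
#'   unique.
#' @return data frame (class `waic_table`) with columns `model`, `waic`,
#'   `d_waic`, `winner`, `large`; the winning label is also attached as
#'   attribute `"winner"`.
#' @export
waic_table <- function(results) {
  if (is.list(results)) {
    w <- vapply(results, function(r) {
      if (inherits(r, "waic_result")) r$waic else as.numeric(r)
    }, numeric(1))
  } else {
    w <- as.numeric(results)
    names(w) <- names(results)
  }
  labels <- names(w)
  if (is.null(labels) || any(!nzchar(labels))) stop("results must be named")
  if (anyDuplicated(labels)) stop("duplicate model labels")
  rank_simple <- match(labels, .VARIANT_ORDER)
  rank_simple[is.na(rank_simple)] <-
    length(.VARIANT_ORDER) + seq_len(sum(is.na(rank_simple)))
  ord <- order(w, rank_simple)
  winner <- labels[ord[1]]
  d <- w - w[ord[1]]
  out <- data.frame(model = labels, waic = unname(w), d_waic = unname(d),
                    winner = labels == winner, large = unname(d) >= 10,
                    stringsAsFactors = FALSE)
  attr(out, "winner") <- winner
  class(out) <- c("waic_table", "data.frame")
  out
}
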