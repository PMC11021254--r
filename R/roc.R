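#' Cumulative-confidence ROC from rating counts
#'
#' Builds the empirical ROC for one participant cell by cumulating response
#' frequencies from the "definitely old" end of the scale: point k
#' (k = 1..5) pairs the false-alarm rate `sum(n_lure[1:k]) / N_lure` with
#' the hit rate `sum(n_target[1:k]) / N_target`. The trivial (1, 1)
#' endpoint is not emitted. Both coordinate vectors are non-decreasing by
#' construction.
#'
#' @param counts a [rating_counts()] object, or anything with numeric
#'   `n_target` and `n_lure` 6-vectors.
#' @return object of class `roc_curve`: list with `far`, `hr` (length 5),
#'   and totals `n_target`, `n_lure`.
#' @export
cumulative_rates <- function(counts) {
  nt <- counts$n_target; nl <- counts$n_lure
  Nt <- sum(nt); Nl <- sum(nl)
  if (Nt <= 0 || Nl <= 0) {
    stop("degenerate counts: need at least one target and one lure trial")
  }
  structure(list(far = cumsum(nl[1:5]) / Nl,
                 hr  = cumsum(nt[1:5]) / Nt,
                 n_target = Nt, n_lure = Nl),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve (", x$n_target, " targets, ", x$n_lure, " lures)\n", sep = "")
  print(data.frame(far = x$far, hr = x$hr))
  invisible(x)
}

#' Least-squares zROC slope and intercept
#'
#' Transforms each ROC point by the standard normal quantile function and
#' regresses z(HR) on z(FAR) by ordinary least squares, the "raw slope"
#' estimator. Points with a hit or false-alarm rate of exactly 0 or 1 are
#' dropped before transforming (the quantile is infinite there); no 0/1
#' correction is applied. If fewer than two points remain, or all remaining
#' false-alarm rates are identical (within an absolute tolerance of 1e-12
#' on the rate scale), the zROC is vertical and the fit is flagged invalid
#' rather than estimated -- the situation that arises when
#' high-performing participants use only the extreme confidence keys.
#'
#' Under the Gaussian model the population slope is
#' `sigma_lure / sigma_target`, so fitted slopes below 1 indicate greater
#' target than lure variability.
#'
#' @param roc a `roc_curve` from [cumulative_rates()].
#' @return object of class `zroc_fit`: list with `slope`, `intercept`,
#'   `n_points`, `valid`, `note`.
#' @export
zroc_fit <- function(roc) {
  keep <- roc$far > 0 & roc$far < 1 & roc$hr > 0 & roc$hr < 1
  far <- roc$far[keep]; hr <- roc$hr[keep]
  invalid <- function(note, n) {
    structure(list(slope = NA_real_, intercept = NA_real_,
                   n_points = n, valid = FALSE, note = note),
              class = "zroc_fit")
  }
  n <- length(far)
  if (n < 2L) return(invalid("fewer than 2 interior ROC points", n))
  if (diff(range(far)) <= 1e-12) return(invalid("vertical zROC: identical FARs", n))
  zf <- stats::qnorm(far); zh <- stats::qnorm(hr)
  slope <- sum((zf - mean(zf)) * (zh - mean(zh))) / sum((zf - mean(zf))^2)
  structure(list(slope = slope,
                 intercept = mean(zh) - slope * mean(zf),
                 n_points = n, valid = TRUE, note = ""),
            class = "zroc_fit")
}

#' @export
print.zroc_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("zROC fit: slope %.4f, intercept %.4f (%d points)\n",
                x$slope, x$intercept, x$n_points))
  } else {
    cat("zROC fit: invalid (", x$note, ")\n", sep = "")
  }
  invisible(x)
}

#' SD ratio implied by a zROC slope
#'
#' Under the Gaussian signal detection model the zROC slope estimates
#' `sigma_lure / sigma_target`, so its reciprocal is the ratio of target to
#' lure standard deviations: a slope of 0.80 implies targets are 1.25 times
#' as variable as lures.
#'
#' @param slope positive zROC slope.
#' @return `1 / slope`, the target-to-lure SD ratio.
#' @export
sd_ratio_from_slope <- function(slope) {
  if (!is.numeric(slope) || any(is.na(slope)) || any(slope <= 0)) {
    stop("slope must be positive")
  }
  1 / slope
}

#' Per-cell zROC fits for a counts table
#'
#' Applies [cumulative_rates()] and [zroc_fit()] to every row of a counts
#' table, returning one row per cell with the slope, intercept, number of
#' interior points used, and validity flag (vertical zROCs yield `NA`
#' estimates, to be treated as missing values in downstream averaging).
#'
#' @param counts a `counts_table` from [aggregate_counts()].
#' @return data frame with columns `participant`, `condition`, `position`,
#'   `slope`, `intercept`, `n_points`, `valid`, `note`.
#' @export
zroc_table <- function(counts) {
  cells <- counts_cells(counts)
  rows <- lapply(cells, function(cell) {
    fit <- if (sum(cell$n_target) > 0 && sum(cell$n_lure) > 0) {
      zroc_fit(cumulative_rates(cell))
    } else {
      list(slope = NA_real_, intercept = NA_real_, n_points = 0L,
           valid = FALSE, note = "empty cell")
    }
    data.frame(participant = cell$participant, condition = cell$condition,
               position = cell$position, slope = fit$slope,
               intercept = fit$intercept, n_points = fit$n_points,
               valid = fit$valid, note = fit$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
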