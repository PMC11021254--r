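#' @keywords internal
"_PACKAGE"

TRIAL_COLS <- c("participant", "session", "condition", "item_type",
                "serial_position", "response", "rt_ms")

#' Validate a trial-level data frame
#'
#' Checks the structural invariants of trial-level confidence-rating data:
#' required columns, responses on the ordinal 1..6 scale (1 = "definitely
#' old" ... 6 = "definitely new"), item types restricted to `target`/`lure`,
#' serial positions absent (`NA`) on lure trials, and non-negative reaction
#' times.
#'
#' @param trials data frame of trials (see [read_trials()] for the column
#'   contract).
#' @return `trials`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(TRIAL_COLS, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trials is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) == 0L) return(invisible(trials))
  if (!all(trials$item_type %in% c("target", "lure"))) {
    stop("item_type must be 'target' or 'lure'")
  }
  resp <- trials$response
  if (anyNA(resp) || !all(resp %in% 1:6)) {
    stop("response must be an integer in 1..6 (1 = 'def. old' ... 6 = 'def. new')")
  }
  sp <- trials$serial_position
  lure <- trials$item_type == "lure"
  if (any(!is.na(sp[lure]))) {
    stop("serial_position must be absent (NA) on lure trials")
  }
  sp_t <- sp[!lure]
  if (any(!is.na(sp_t) & sp_t < 1)) {
    stop("serial_position must be a positive integer when present")
  }
  if (anyNA(trials$rt_ms) || any(trials$rt_ms < 0)) {
    stop("rt_ms must be present and non-negative on every trial")
  }
  invisible(trials)
}

#' Read trial-level confidence-rating data
#'
#' Reads a UTF-8 delimited (CSV) file with one row per test response and a
#' header naming the fields: `participant`, `session`, `condition`,
#' `item_type` (`target`/`lure`), `serial_position` (empty for lures and for
#' study-test designs), `response` (1..6), `rt_ms` (milliseconds).
#'
#' Confidence keys are counterbalanced across sessions in typical
#' experiments, so the file's response codes need not already run from
#' "definitely old" to "definitely new". `response_map` remaps raw codes
#' onto the canonical direction: position `k` of the map gives the canonical
#' response for raw code `k` (e.g. `6:1` reverses the scale).
#'
#' @param path file path.
#' @param response_map optional integer vector of length 6, a permutation of
#'   `1:6`, applied as `response <- response_map[response]`.
#' @return validated data frame of trials.
#' @seealso [write_trials()], [validate_trials()]
#' @export
read_trials <- function(path, response_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant = "character",
                                       condition = "character"),
                        fileEncoding = "UTF-8")
  if ("serial_position" %in% names(df) && !is.numeric(df$serial_position)) {
    df$serial_position <- suppressWarnings(as.integer(df$serial_position))
  }
  if (!is.null(response_map)) {
    if (length(response_map) != 6L || !setequal(response_map, 1:6)) {
      stop("response_map must be a permutation of 1:6")
    }
    df$response <- as.integer(response_map)[df$response]
  }
  df$response <- as.integer(df$response)
  validate_trials(df)
  df
}

#' Write trial-level data to CSV
#'
#' Inverse of [read_trials()]: missing serial positions are written as empty
#' fields so a round trip reproduces the data frame field-for-field.
#'
#' @param trials validated trial data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, TRIAL_COLS, drop = FALSE], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclude trials with implausibly fast or slow reaction times
#'
#' Keeps trials with `lo <= rt_ms <= hi`; the bounds themselves are
#' retained (only responses strictly faster than `lo` or strictly slower
#' than `hi` are treated as likely guesses and dropped). Input order is
#' preserved. The excluded fraction is attached as attribute
#' `"excluded_fraction"` and retrievable with [excluded_fraction()].
#'
#' @param trials trial data frame with `rt_ms` on every row.
#' @param lo,hi inclusive bounds in milliseconds (defaults 300 and 4000).
#' @return the retained trials, with attribute `excluded_fraction`.
#' @export
filter_by_rt <- function(trials, lo = 300, hi = 4000) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi < 0 || lo > hi) {
    stop("invalid RT bounds: need 0 <= lo <= hi")
  }
  stopifnot(is.data.frame(trials), "rt_ms" %in% names(trials))
  n <- nrow(trials)
  if (n == 0L) {
    attr(trials, "excluded_fraction") <- 0
    return(trials)
  }
  if (anyNA(trials$rt_ms)) stop("rt_ms must be present on every record")
  keep <- trials$rt_ms >= lo & trials$rt_ms <= hi
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_fraction") <- sum(!keep) / n
  out
}

#' @rdname filter_by_rt
#' @param x an object returned by [filter_by_rt()].
#' @export
excluded_fraction <- function(x) {
  f <- attr(x, "excluded_fraction")
  if (is.null(f)) NA_real_ else f
}

#' Flag participant cells with at-chance performance
#'
#' Published analyses typically drop a small number of participants for poor
#' task performance or non-adherence; the precise judgments are study
#' specific, so this package exposes the exclusion as a configurable rule
#' rather than a hard-coded list. The default rule scores a response of 1-3
#' as an "old" choice and 4-6 as a "new" choice and excludes any
#' participant-by-condition cell whose overall accuracy is at or below
#' chance (`accuracy_min`, default 0.5).
#'
#' @param trials validated trial data frame.
#' @param accuracy_min cells with accuracy `<= accuracy_min` are excluded.
#' @return trials with failing participant-by-condition cells removed;
#'   attribute `"excluded_cells"` lists the removed cells.
#' @export
exclude_low_accuracy <- function(trials, accuracy_min = 0.5) {
  validate_trials(trials)
  if (nrow(trials) == 0L) {
    attr(trials, "excluded_cells") <- data.frame(participant = character(),
                                                 condition = character())
    return(trials)
  }
  old_choice <- trials$response <= 3L
  correct <- ifelse(trials$item_type == "target", old_choice, !old_choice)
  acc <- stats::aggregate(correct,
                          by = list(participant = trials$participant,
                                    condition = trials$condition),
                          FUN = mean)
  bad <- acc[acc$x <= accuracy_min, c("participant", "condition"), drop = FALSE]
  key <- paste(trials$participant, trials$condition, sep = "\r")
  badkey <- paste(bad$participant, bad$condition, sep = "\r")
  out <- trials[!(key %in% badkey), , drop = FALSE]
  rownames(out) <- NULL
  rownames(bad) <- NULL
  attr(out, "excluded_cells") <- bad
  out
}

#' Rating counts for one participant cell
#'
#' Container for the 2 x 6 table of response frequencies entering the
#' multinomial likelihood: counts of each confidence category (ordered
#' "definitely old" to "definitely new") for targets and for lures.
#'
#' @param n_target,n_lure non-negative integer 6-vectors.
#' @param participant,condition,position optional labels.
#' @return an object of class `rating_counts`.
#' @export
rating_counts <- function(n_target, n_lure, participant = NA, condition = NA,
                          position = NA) {
  n_target <- as.numeric(n_target); n_lure <- as.numeric(n_lure)
  if (length(n_target) != 6L || length(n_lure) != 6L) {
    stop("n_target and n_lure must each have 6 entries")
  }
  if (any(n_target < 0) || any(n_lure < 0)) stop("counts must be non-negative")
  structure(list(n_target = n_target, n_lure = n_lure,
                 participant = participant, condition = condition,
                 position = position),
            class = "rating_counts")
}

#' @export
print.rating_counts <- function(x, ...) {
  cat("rating_counts:", x$participant, "/", x$condition,
      if (!is.na(x$position)) paste0("/ pos ", x$position), "\n")
  m <- rbind(target = x$n_target, lure = x$n_lure)
  colnames(m) <- c("def.old", "prob.old", "maybe.old",
                   "maybe.new", "prob.new", "def.new")
  print(m)
  invisible(x)
}

#' Aggregate trials into confidence-rating count tables
#'
#' Tallies responses into one row per participant-by-condition cell (columns
#' `t1..t6` for targets, `l1..l6` for lures). With `by_position = TRUE` the
#' target tallies are split by study serial position (one row per position)
#' while all of the cell's lure trials form a single shared lure vector,
#' repeated on each row -- lures have no serial position, and the
#' serial-position model shares one lure distribution and one criterion set
#' across positions.
#'
#' Condition labels are opaque and pass through unchanged. The grand total
#' of target counts plus (for `by_position = FALSE`) lure counts equals the
#' number of input trials.
#'
#' @param trials validated trial data frame.
#' @param by_position split target counts by `serial_position`?
#' @return data frame of counts (class `counts_table`).
#' @seealso [counts_cells()] to convert rows to [rating_counts()] objects.
#' @export
aggregate_counts <- function(trials, by_position = FALSE) {
  validate_trials(trials)
  empty <- data.frame(participant = character(), condition = character(),
                      position = integer(),
                      matrix(integer(), 0, 12,
                             dimnames = list(NULL, c(paste0("t", 1:6),
                                                     paste0("l", 1:6)))),
                      stringsAsFactors = FALSE)
  class(empty) <- c("counts_table", "data.frame")
  if (nrow(trials) == 0L) return(empty)
  if (by_position && all(is.na(trials$serial_position[trials$item_type == "target"]))) {
    stop("by_position = TRUE but no target trial has a serial_position")
  }

  tab6 <- function(resp) tabulate(resp, nbins = 6L)
  cells <- split(seq_len(nrow(trials)),
                 list(participant = trials$participant,
                      condition = trials$condition),
                 drop = TRUE, sep = "\r")
  rows <- list()
  for (cell in cells) {
    sub <- trials[cell, , drop = FALSE]
    pid <- sub$participant[1L]; cond <- sub$condition[1L]
    lure_counts <- tab6(sub$response[sub$item_type == "lure"])
    tgt <- sub[sub$item_type == "target", , drop = FALSE]
    if (!by_position) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, condition = cond, position = NA_integer_,
        rbind(c(tab6(tgt$response), lure_counts)), stringsAsFactors = FALSE)
    } else {
      for (pos in sort(unique(tgt$serial_position))) {
        tp <- tgt$response[!is.na(tgt$serial_position) &
                             tgt$serial_position == pos]
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, condition = cond, position = as.integer(pos),
          rbind(c(tab6(tp), lure_counts)), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out) <- c("participant", "condition", "position",
                  paste0("t", 1:6), paste0("l", 1:6))
  out <- out[order(out$participant, out$condition, out$position), ]
  rownames(out) <- NULL
  class(out) <- c("counts_table", "data.frame")
  out
}

#' Convert count-table rows to rating_counts objects
#'
#' @param counts a `counts_table` from [aggregate_counts()] (or any data
#'   frame with the same columns).
#' @return list of [rating_counts()] objects, one per row.
#' @export
counts_cells <- function(counts) {
  lapply(seq_len(nrow(counts)), function(i) {
    rating_counts(as.numeric(counts[i, paste0("t", 1:6)]),
                  as.numeric(counts[i, paste0("l", 1:6)]),
                  participant = counts$participant[i],
                  condition = counts$condition[i],
                  position = counts$position[i])
  })
}
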