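#' Normalize a run configuration
#'
#' Accepts a list or a YAML file path and fills defaults. A configuration
#' names either an `input` CSV of trials or a `simulation` block (arguments
#' to [generator_config()]); RT filter bounds; an optional at-chance
#' exclusion rule; the model variants to fit; sampler settings; an output
#' directory; and the seed, which is recorded in every manifest.
#'
#' @param config list or path to a YAML file.
#' @return normalized configuration list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(input = NULL, simulation = NULL,
                   rt = list(lo = 300, hi = 4000),
                   exclusion = list(accuracy_min = 0.5),
                   by_position = FALSE,
                   variants = SDT_VARIANTS,
                   sampler = list(n_chains = NULL, n_burn = 1000,
                                  n_keep = 1000),
                   out_dir = "sdtroc_out", seed = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]) && nm != "simulation") {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  if (is.null(config$input) && is.null(config$simulation)) {
    stop("config must provide 'input' (trials CSV) or 'simulation'")
  }
  config$variants <- match.arg(config$variants, SDT_VARIANTS,
                               several.ok = TRUE)
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Observed and predicted ROC/zROC overlay
#'
#' Plots the group-average observed cumulative ROC (or zROC) for a counts
#' table together with the smooth curve implied by a set of model
#' parameters -- the standard visual check that a fitted signal detection
#' model captures the curvilinear ROC and linear zROC.
#'
#' @param counts single-condition `counts_table`.
#' @param params `sdt_params` for the predicted curve (e.g.
#'   [group_params()]); `NULL` omits the prediction.
#' @param z plot in z-transformed coordinates?
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of observed mean points.
#' @export
plot_roc_overlay <- function(counts, params = NULL, z = FALSE, ...) {
  cells <- counts_cells(counts)
  pts <- vapply(cells, function(cell) {
    r <- cumulative_rates(cell)
    c(r$far, r$hr)
  }, numeric(10))
  far <- rowMeans(pts[1:5, , drop = FALSE])
  hr <- rowMeans(pts[6:10, , drop = FALSE])
  obs <- data.frame(far = far, hr = hr)
  tr <- if (z) stats::qnorm else identity
  keep <- if (z) far > 0 & far < 1 & hr > 0 & hr < 1 else rep(TRUE, 5)
  lim <- if (z) c(-2.5, 2.5) else c(0, 1)
  graphics::plot(tr(obs$far[keep]), tr(obs$hr[keep]), xlim = lim, ylim = lim,
                 xlab = if (z) "z(FAR)" else "FAR",
                 ylab = if (z) "z(HR)" else "HR", pch = 19, ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  if (!is.null(params)) {
    cgrid <- seq(-4, 6, length.out = 200)
    pf <- 1 - stats::pnorm(cgrid, params$mu_lure, params$sigma_lure)
    ph <- 1 - stats::pnorm(cgrid, params$mu_target, params$sigma_target)
    ok <- if (z) pf > 1e-4 & pf < 1 - 1e-4 & ph > 1e-4 & ph < 1 - 1e-4 else
      rep(TRUE, length(cgrid))
    graphics::lines(tr(pf[ok]), tr(ph[ok]), col = "steelblue", lwd = 2)
  }
  invisible(obs)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis workflow on real or simulated trials:
#' read/simulate, RT-filter, (optionally) exclude at-chance cells,
#' aggregate to counts, fit per-cell zROC slopes, fit every requested
#' model variant per condition by hierarchical DE-MCMC, compare variants
#' by WAIC difference scores, draw ROC/zROC overlays, and write a
#' machine-readable manifest recording the package version, seed,
#' settings, and MD5 hashes of every output. A stage failure aborts with
#' an error naming the stage; outputs of completed stages are retained.
#'
#' @param config list or YAML path, see [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_analysis <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(cfg$out_dir, "run.log"), open = "at")
  on.exit(close(logcon), add = TRUE)
  outputs <- character(0)
  add_output <- function(path) outputs[[length(outputs) + 1L]] <<- path

  trials <- .stage("input", {
    if (!is.null(cfg$input)) {
      .log_line(logcon, "reading trials from ", cfg$input)
      read_trials(cfg$input)
    } else {
      .log_line(logcon, "simulating trials (design ",
                cfg$simulation$design %||% "study_test", ")")
      gc_args <- cfg$simulation
      sim <- simulate_experiment(do.call(generator_config, gc_args),
                                 seed = cfg$seed)
      p <- file.path(cfg$out_dir, "trials.csv")
      write_trials(sim$trials, p); add_output(p)
      sim$trials
    }
  })

  trials <- .stage("filter", {
    out <- filter_by_rt(trials, cfg$rt$lo, cfg$rt$hi)
    .log_line(logcon, sprintf("RT filter [%g, %g] ms excluded %.2f%% of trials",
                              cfg$rt$lo, cfg$rt$hi,
                              100 * excluded_fraction(out)))
    if (!is.null(cfg$exclusion)) {
      out <- exclude_low_accuracy(out, cfg$exclusion$accuracy_min)
      nbad <- nrow(attr(out, "excluded_cells"))
      if (nbad > 0) .log_line(logcon, "excluded ", nbad, " at-chance cell(s)")
    }
    out
  })

  counts <- .stage("counts", {
    ct <- aggregate_counts(trials, by_position = cfg$by_position)
    p <- file.path(cfg$out_dir, "counts.csv")
    utils::write.csv(ct, p, row.names = FALSE); add_output(p)
    ct
  })

  .stage("roc", {
    zt <- zroc_table(counts)
    p <- file.path(cfg$out_dir, "zroc.csv")
    utils::write.csv(zt, p, row.names = FALSE); add_output(p)
  })

  conditions <- unique(counts$condition)
  fits <- .stage("fit", {
    fits <- list()
    for (cond in conditions) {
      sub <- counts[counts$condition == cond, , drop = FALSE]
      for (v in cfg$variants) {
        .log_line(logcon, "fitting ", v, " to condition '", cond, "'")
        fit <- fit_sdt(sub, variant = v,
                       n_chains = cfg$sampler$n_chains,
                       n_burn = cfg$sampler$n_burn,
                       n_keep = cfg$sampler$n_keep,
                       seed = cfg$seed)
        key <- paste(cond, v, sep = ":")
        fits[[key]] <- fit
        sm <- posterior_summary(fit)
        p <- file.path(cfg$out_dir, paste0("fit_", cond, "_", v,
                                           "_summary.csv"))
        utils::write.csv(sm, p, row.names = FALSE); add_output(p)
        dr <- fit$draws
        grp <- grep("^group:", dimnames(dr)[[3]], value = TRUE)
        tall <- do.call(rbind, lapply(grp, function(pp) {
          m <- fit_draws(fit, pp)
          data.frame(parameter = pp,
                     chain = rep(seq_len(ncol(m)), each = nrow(m)),
                     iteration = rep(seq_len(nrow(m)), ncol(m)),
                     value = as.numeric(m))
        }))
        p <- file.path(cfg$out_dir, paste0("fit_", cond, "_", v,
                                           "_draws.csv"))
        utils::write.csv(tall, p, row.names = FALSE); add_output(p)
      }
    }
    fits
  })

  .stage("compare", {
    for (cond in conditions) {
      keys <- paste(cond, cfg$variants, sep = ":")
      wt <- waic_table(stats::setNames(lapply(keys, function(k)
        waic_fit(fits[[k]])), cfg$variants))
      p <- file.path(cfg$out_dir, paste0("waic_", cond, ".csv"))
      utils::write.csv(wt, p, row.names = FALSE); add_output(p)
      .log_line(logcon, "condition '", cond, "' WAIC winner: ",
                attr(wt, "winner"))
    }
  })

  .stage("figures", {
    if (!cfg$by_position) {
      p <- file.path(cfg$out_dir, "roc_overlays.pdf")
      grDevices::pdf(p, width = 8, height = 4)
      for (cond in conditions) {
        sub <- counts[counts$condition == cond, , drop = FALSE]
        best <- fits[[paste(cond, "UV_free", sep = ":")]] %||%
          fits[[paste(cond, cfg$variants[1], sep = ":")]]
        gp <- group_params(best)
        graphics::par(mfrow = c(1, 2))
        plot_roc_overlay(sub, gp, z = FALSE, main = paste0(cond, ": ROC"))
        plot_roc_overlay(sub, gp, z = TRUE, main = paste0(cond, ": zROC"))
      }
      grDevices::dev.off()
      add_output(p)
    }
  })

  manifest <- .stage("manifest", {
    m <- list(package = "sdtroc",
              version = as.character(utils::packageVersion("sdtroc")),
              r_version = R.version.string,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = cfg$seed,
              settings = cfg[setdiff(names(cfg), "out_dir")],
              outputs = lapply(stats::setNames(outputs, basename(outputs)),
                               function(p) list(md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(m, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
    m
  })
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameter-recovery study
#'
#' For each replication: simulate an experiment from known group values,
#' fit the generating variant by [fit_sdt()], and record the generating
#' group-level SD ratio and target mean against their posterior means and
#' 95% HDIs with coverage flags. The long-run coverage fraction should
#' approach the nominal 95%.
#'
#' @param config list (or YAML path) with optional fields `replications`
#'   (default 3), `simulation` (arguments to [generator_config()]),
#'   `sampler` (`n_chains`, `n_burn`, `n_keep`), `condition` (which
#'   simulated condition to fit; default the first), `out_dir` (optional;
#'   results CSV written there when given), `seed`.
#' @return data frame with one row per replication x quantity:
#'   `replication`, `quantity`, `generating`, `posterior_mean`, `hdi_lo`,
#'   `hdi_hi`, `covered`.
#' @export
run_recovery <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  reps <- config$replications %||% 3
  seed <- config$seed %||% 1
  sampler <- config$sampler %||% list()
  sim_args <- config$simulation %||% list(n_participants = 8, n_trials = 120)
  gcfg <- do.call(generator_config, sim_args)
  cond <- config$condition %||% names(gcfg$conditions)[1]
  if (reps == 0) {
    return(data.frame(replication = integer(), quantity = character(),
                      generating = numeric(), posterior_mean = numeric(),
                      hdi_lo = numeric(), hdi_hi = numeric(),
                      covered = logical()))
  }
  loc <- .group_vector(gcfg, cond, "loc")
  names(loc) <- gcfg$spec$par_names
  spec <- gcfg$spec
  serial <- !is.null(gcfg$n_positions)
  s_name <- if (serial) "s1" else "s"
  mu_name <- if (serial) "mu1" else "mu"
  true_ratio <- {
    sf <- sigma_free_from_s(spec, loc[[s_name]])
    if (spec$parameterization == "fix_target_sd") sf else 1 / sf
  }
  rows <- list()
  for (r in seq_len(reps)) {
    sim <- simulate_experiment(gcfg, seed = seed * 1000L + r)
    trials <- sim$trials[sim$trials$condition == cond, , drop = FALSE]
    counts <- aggregate_counts(trials, by_position = serial)
    fit <- fit_sdt(counts, variant = gcfg$variant,
                   parameterization = gcfg$parameterization,
                   n_chains = sampler$n_chains %||% NULL,
                   n_burn = sampler$n_burn %||% 500,
                   n_keep = sampler$n_keep %||% 500,
                   store_pointwise = FALSE, seed = seed * 1000L + r)
    ratio_draws <- sd_ratio_draws(fit,
                                  position = if (serial) 1L else NULL)
    mu_draws <- fit_draws(fit, paste0("group:loc:", mu_name))
    for (q in list(list(name = "group_sd_ratio", true = true_ratio,
                        draws = ratio_draws),
                   list(name = "group_mu_target", true = loc[[mu_name]],
                        draws = mu_draws))) {
      h <- hdi(q$draws)
      rows[[length(rows) + 1L]] <- data.frame(
        replication = r, quantity = q$name, generating = q$true,
        posterior_mean = mean(q$draws), hdi_lo = h[1], hdi_hi = h[2],
        covered = q$true >= h[1] & q$true <= h[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(config$out_dir, "recovery.csv"),
                     row.names = FALSE)
  }
  out
}
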