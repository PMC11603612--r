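#' Deterministic per-run seed
#'
#' Pure function of (base_seed, pH, replicate): every stochastic draw of a
#' scan is fully determined by the configuration.  Values stay below 2^31.
#'
#' @param base_seed integer base seed.
#' @param pH run pH.
#' @param replicate replicate index (1-based).
#' @export
derive_seed <- function(base_seed, pH, replicate) {
  b <- as.integer(base_seed) %% 65011L
  p <- as.integer(round(pH * 100)) + 5000L
  as.integer((b * 33013 + p * 101 + as.integer(replicate) * 7) %% 2147483629) + 1L
}

#' Run a titration scan over a pH grid
#'
#' One simulation per (pH, replicate) with a seed derived purely from the
#' base seed, followed by the full titration analysis
#' ([pka_from_trajectories()]) for every site.  Trajectories and CSV reports
#' are written to the configured output directory; re-running with the same
#' configuration reproduces them bitwise.  A failing run is logged, flagged
#' in the reports and the scan continues.
#'
#' @param config a [load_config()] / [as_run_config()] run configuration.
#' @param output_dir overrides \code{config$output_dir}.
#' @param write_trajectories write per-run TSV trajectory files (default
#'   TRUE).
#' @return invisibly, a list with \code{pka} (per-site fit table),
#'   \code{titration} (per-site, per-pH table), \code{results} (per-site
#'   [pka_from_trajectories()] output) and \code{trajectories}.
#' @export
titration_scan <- function(config, output_dir = NULL,
                           write_trajectories = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- output_dir %||% config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ph_grid <- seq(config$ph_min, config$ph_max, by = config$ph_step)
  trajs <- list()
  failed <- character(0)
  for (p in ph_grid) {
    sys <- config_system(config, p)
    for (r in seq_len(config$replicates)) {
      seed <- derive_seed(config$base_seed, p, r)
      tr <- tryCatch(
        run_simulation(sys, mode = config$mode, n_steps = config$n_steps,
                       dt = config$dt, seed = seed,
                       sample_stride = config$sample_stride,
                       m_lambda_standard = config$m_lambda_standard),
        error = function(e) e)
      tag <- sprintf("pH%04.1f_rep%d", p, r)
      if (inherits(tr, "error")) {
        failed <- c(failed, sprintf("%s: %s", tag, conditionMessage(tr)))
        next
      }
      if (write_trajectories)
        write_trajectory(tr, file.path(out, sprintf("traj_%s.tsv", tag)))
      trajs[[tag]] <- tr
    }
  }
  if (length(failed))
    writeLines(failed, file.path(out, "failed_runs.log"))
  if (!length(trajs)) stop("all runs failed")

  site_ids <- vapply(config$sites, function(s) s$id, character(1))
  results <- list(); pka_rows <- list(); tit_rows <- list()
  for (id in site_ids) {
    res <- tryCatch(
      pka_from_trajectories(trajs, id, T = config$T_physical),
      error = function(e) e)
    if (inherits(res, "error")) {
      pka_rows[[id]] <- data.frame(site = id, pKa = NA_real_, sd = NA_real_,
                                   hill_n = NA_real_,
                                   flags = conditionMessage(res))
      next
    }
    results[[id]] <- res
    hill <- mean(vapply(res$fits, function(f) f$hill_n, numeric(1)),
                 na.rm = TRUE)
    pka_rows[[id]] <- data.frame(
      site = id, pKa = res$pKa_mean, sd = res$pKa_sd, hill_n = hill,
      flags = paste(c(res$flags, if (length(failed)) "runs_failed"),
                    collapse = ";"))
    tt <- res$titration
    tt$site <- id
    tit_rows[[id]] <- tt[, c("site", setdiff(names(tt), "site"))]
  }
  pka <- do.call(rbind, pka_rows)
  titration <- do.call(rbind, tit_rows)
  rownames(pka) <- rownames(titration) <- NULL
  utils::write.csv(pka, file.path(out, "pka_report.csv"), row.names = FALSE)
  utils::write.csv(titration, file.path(out, "titration.csv"),
                   row.names = FALSE)
  invisible(list(pka = pka, titration = titration, results = results,
                 trajectories = trajs, output_dir = out))
}

#' Summarize completed scan outputs
#'
#' Reads the CSV reports written by [titration_scan()] and returns the pKa
#' table, per-site titration curves with fitted-curve overlays, and, when a
#' table of experimental values is supplied, the prediction metrics
#' (MUE/RMSE/Pearson r).
#'
#' @param results_dir directory written by [titration_scan()].
#' @param experimental optional data.frame with columns \code{site} and
#'   \code{pKa} (experimental values).
#' @return list with \code{pka}, \code{titration}, per-site \code{curves}
#'   (observed fractions plus fitted curve), and \code{metrics} when
#'   experimental values were given.
#' @export
report <- function(results_dir, experimental = NULL) {
  pf <- file.path(results_dir, "pka_report.csv")
  tf <- file.path(results_dir, "titration.csv")
  if (!file.exists(pf)) stop(sprintf("missing input: %s", pf))
  if (!file.exists(tf)) stop(sprintf("missing input: %s", tf))
  pka <- utils::read.csv(pf)
  titration <- utils::read.csv(tf)
  curves <- list()
  for (id in unique(titration$site)) {
    tt <- titration[titration$site == id, ]
    if (length(unique(tt$pH)) < 2L) {
      curves[[id]] <- list(points = tt, fit = NULL, flag = "fit_skipped")
      next
    }
    fit <- fit_hh(tt)
    grid <- seq(min(tt$pH), max(tt$pH), length.out = 101)
    curve <- if (is.finite(fit$pKa))
      data.frame(pH = grid,
                 fraction = 1 / (1 + 10^(fit$hill_n * (fit$pKa - grid))))
    else NULL
    curves[[id]] <- list(points = tt, fit = fit, curve = curve)
  }
  outp <- list(pka = pka, titration = titration, curves = curves)
  if (!is.null(experimental)) {
    stopifnot(all(c("site", "pKa") %in% names(experimental)))
    m <- merge(pka, experimental, by = "site", suffixes = c("_pred", "_exp"))
    outp$metrics <- prediction_metrics(m$pKa_pred, m$pKa_exp)
  }
  outp
}

#' Plot a titration curve
#'
#' Observed reweighted fractions with replicate error bars and the fitted
#' Henderson-Hasselbalch curve.
#'
#' @param curve one entry of \code{report()$curves}.
#' @param main plot title.
#' @export
plot_titration <- function(curve, main = "") {
  pts <- curve$points
  graphics::plot(pts$pH, pts$fraction, xlab = "pH",
                 ylab = "deprotonated fraction", ylim = c(0, 1), pch = 19,
                 main = main)
  if (!is.null(pts$sd) && any(is.finite(pts$sd)))
    graphics::arrows(pts$pH, pts$fraction - pts$sd, pts$pH,
                     pts$fraction + pts$sd, angle = 90, code = 3,
                     length = 0.03)
  if (!is.null(curve$curve))
    graphics::lines(curve$curve$pH, curve$curve$fraction, col = "red3")
  invisible(curve)
}

#' HEWL pKa benchmark table
#'
#' Published per-residue pKa predictions for hen egg white lysozyme from
#' 10 ns adiabatic constant-pH runs, 10 and 50 ns standard CpHMD runs, and
#' the experimental values, as distributed with the package.
#'
#' @return data.frame with one row per titratable residue.
#' @export
hewl_pka_benchmark <- function() {
  utils::read.csv(system.file("extdata", "hewl_pka_benchmark.csv",
                              package = "phafed"))
}
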