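#' Fit a generalized Henderson-Hasselbalch titration curve
#'
#' Weighted least-squares fit of
#' f(pH) = 1 / (1 + 10^(n (pKa - pH)))
#' to per-pH deprotonated fractions, over the midpoint pKa and the Hill
#' coefficient n (bounded to (0, 4]).  Weights are inverse replicate
#' variances where a positive \code{sd} column is available, else uniform;
#' fractions are clipped to [1e-6, 1 - 1e-6] before fitting.  The initial
#' guess is pKa at the pH whose fraction is nearest 0.5 and n = 1.
#'
#' @param points data.frame with columns \code{pH}, \code{fraction} and
#'   optionally \code{sd} (see [titration_point()]).
#' @return an object of class \code{pka_fit} with fields \code{pKa},
#'   \code{hill_n}, \code{residual_norm}, \code{converged} and \code{flags}
#'   (possible flags: \code{"low_confidence"} for fewer than 3 points or no
#'   bracketing of 0.5; \code{"no_fit"} for degenerate all-0/all-1 data).
#' @export
fit_hh <- function(points) {
  stopifnot(is.data.frame(points), all(c("pH", "fraction") %in% names(points)))
  points <- points[is.finite(points$fraction), , drop = FALSE]
  flags <- character(0)
  if (nrow(points) < 3L ||
      !(any(points$fraction < 0.5) && any(points$fraction > 0.5)))
    flags <- c(flags, "low_confidence")
  if (all(points$fraction < 1e-3) || all(points$fraction > 1 - 1e-3)) {
    return(structure(list(pKa = NA_real_, hill_n = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          flags = c(flags, "no_fit")),
                     class = "pka_fit"))
  }
  f <- pmin(pmax(points$fraction, 1e-6), 1 - 1e-6)
  w <- rep(1, nrow(points))
  if ("sd" %in% names(points) && any(is.finite(points$sd))) {
    # inverse replicate variance, floored at the counting-noise scale 0.02
    sd <- ifelse(is.finite(points$sd), pmax(points$sd, 0.02), 0.02)
    w <- 1 / sd^2
  }
  dat <- data.frame(pH = points$pH, f = f)
  start <- list(pKa = points$pH[which.min(abs(f - 0.5))], n = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ 1 / (1 + 10^(n * (pKa - pH))),
                      data = dat, start = start, weights = w,
                      lower = c(pKa = -20, n = 1e-3),
                      upper = c(pKa = 30, n = 4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(pKa = NA_real_, hill_n = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          flags = c(flags, "no_fit")),
                     class = "pka_fit"))
  }
  co <- stats::coef(fit)
  structure(list(pKa = unname(co["pKa"]), hill_n = unname(co["n"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv, flags = flags),
            class = "pka_fit")
}

#' Fit a coupled two-site titration model
#'
#' Fits the average number of bound protons of two coupled sites,
#' <P>(pH) = (2 x^2 + K1 x) / (x^2 + K1 x + K1 K2) with x = 10^-pH and
#' stepwise ionization constants K1 = 10^-pKa1, K2 = 10^-pKa2, to the sum of
#' the two sites' protonated fractions on a shared pH grid.
#'
#' @param points_site1,points_site2 data.frames as in [fit_hh()] (deprotonated
#'   fractions), on identical pH grids.
#' @return a \code{pka_fit} whose \code{pKa} field is the ordered pair
#'   (pKa1 <= pKa2).
#' @export
fit_coupled <- function(points_site1, points_site2) {
  stopifnot(is.data.frame(points_site1), is.data.frame(points_site2))
  if (nrow(points_site1) != nrow(points_site2) ||
      any(points_site1$pH != points_site2$pH))
    stop("the two sites must share the same pH grid")
  dat <- data.frame(pH = points_site1$pH,
                    P = (1 - points_site1$fraction) +
                        (1 - points_site2$fraction))
  coupled_P <- function(pH, pKa1, pKa2) {
    x <- 10^(-pH); K1 <- 10^(-pKa1); K2 <- 10^(-pKa2)
    (2 * x^2 + K1 * x) / (x^2 + K1 * x + K1 * K2)
  }
  g1 <- fit_hh(points_site1); g2 <- fit_hh(points_site2)
  s1 <- if (is.finite(g1$pKa)) g1$pKa else stats::median(dat$pH)
  s2 <- if (is.finite(g2$pKa)) g2$pKa else stats::median(dat$pH)
  start <- list(pKa1 = min(s1, s2), pKa2 = max(s1, s2))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      P ~ coupled_P(pH, pKa1, pKa2),
      data = dat, start = start,
      lower = c(pKa1 = -20, pKa2 = -20), upper = c(pKa1 = 30, pKa2 = 30),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(pKa = c(NA_real_, NA_real_), hill_n = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          flags = "no_fit"),
                     class = "pka_fit"))
  }
  co <- sort(unname(stats::coef(fit)))
  structure(list(pKa = co, hill_n = NA_real_,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv, flags = character(0)),
            class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  if (length(x$pKa) == 2L) {
    cat(sprintf("coupled titration fit: pKa1 = %.3f, pKa2 = %.3f\n",
                x$pKa[1], x$pKa[2]))
  } else {
    cat(sprintf("titration fit: pKa = %.3f, Hill n = %.3f\n",
                x$pKa, x$hill_n))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' pKa prediction error metrics
#'
#' Mean unsigned error, root-mean-square error and Pearson correlation of
#' predicted against experimental pKa values.
#'
#' @param predicted,experimental numeric vectors of equal length (>= 2).
#' @return list with \code{MUE}, \code{RMSE}, \code{r} and \code{flags}
#'   (\code{"r_undefined"} when either vector has zero variance).
#' @export
prediction_metrics <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop("predicted and experimental must have equal length")
  if (length(predicted) < 2L) stop("need at least 2 pairs")
  d <- predicted - experimental
  flags <- character(0)
  r <- if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0) {
    flags <- "r_undefined"
    NA_real_
  } else {
    stats::cor(predicted, experimental)
  }
  list(MUE = mean(abs(d)), RMSE = sqrt(mean(d^2)), r = r, flags = flags)
}

#' pKa from a replicate set of trajectories
#'
#' Full titration pipeline: classify frames of the site's lambda coordinate
#' in every trajectory, temper-reweight the counts to the physical
#' temperature, and fit the generalized Henderson-Hasselbalch curve.  The
#' headline pKa is the inverse-replicate-variance weighted fit of the
#' replicate-mean titration curve (the curve the replicate error bars belong
#' to); per-replicate fits supply the replicate mean and standard deviation,
#' and per-pH mixed-state fractions are reported alongside.
#'
#' Multisite His trajectories (three lambda columns per site) are classified
#' on the protonated coordinate and reweighted with the pooled neutral
#' counts.
#'
#' @param trajs list of \code{lambda_trajectory} objects covering >= 3 pH
#'   values (>= 1 replicate each); replicates of the same pH share the pH in
#'   their metadata.
#' @param site site id to analyze.
#' @param T physical temperature (K) for reweighting.
#' @param lo,hi classification thresholds.
#' @param burn_in fraction of initial frames discarded as equilibration
#'   (default 0.2; runs start from the protonated state, and the discard
#'   mirrors the conventional equilibration:production ratio).
#' @return list with the headline \code{pKa_mean} (aggregate-curve fit),
#'   \code{pKa_sd} and \code{replicate_pKa} (spread and values of the
#'   per-replicate fits), \code{aggregate_fit}, per-replicate \code{fits},
#'   a per-pH \code{titration} table and \code{flags}.
#' @export
pka_from_trajectories <- function(trajs, site, T = 300, lo = 0.2,
                                  hi = 0.8, burn_in = 0.2) {
  stopifnot(length(trajs) >= 1L)
  info <- lapply(trajs, function(tr) .site_counts(tr, site, lo, hi, burn_in))
  ph <- vapply(trajs, function(tr) tr$metadata$pH, numeric(1))
  if (length(unique(ph)) < 3L) stop("need at least 3 pH values")
  rep_id <- stats::ave(ph, ph, FUN = seq_along)

  fits <- list()
  for (r in sort(unique(rep_id))) {
    sel <- which(rep_id == r)
    pts <- do.call(rbind, lapply(sel, function(i) {
      ci <- info[[i]]
      rw <- if (ci$his) his_deprot_fraction(ci$n_prot, ci$n_c, ci$n_d,
                                            ci$T_lambda, T)
            else reweight_fraction(ci$n_prot, ci$n_deprot, ci$T_lambda, T)
      titration_point(ph[i], rw$fraction,
                      mixed_fraction = ci$n_mixed /
                        max(1L, ci$n_prot + ci$n_deprot + ci$n_mixed),
                      n_prot = ci$n_prot, n_deprot = ci$n_deprot,
                      n_mixed = ci$n_mixed)
    }))
    fits[[as.character(r)]] <- fit_hh(pts)
  }
  pkas <- vapply(fits, function(f) f$pKa[1], numeric(1))
  flags <- unique(unlist(lapply(fits, function(f) f$flags)))

  agg <- do.call(rbind, lapply(sort(unique(ph)), function(p) {
    sel <- which(ph == p)
    fr <- vapply(sel, function(i) {
      ci <- info[[i]]
      rw <- if (ci$his) his_deprot_fraction(ci$n_prot, ci$n_c, ci$n_d,
                                            ci$T_lambda, T)
            else reweight_fraction(ci$n_prot, ci$n_deprot, ci$T_lambda, T)
      rw$fraction
    }, numeric(1))
    mx <- vapply(sel, function(i) {
      ci <- info[[i]]
      ci$n_mixed / max(1L, ci$n_prot + ci$n_deprot + ci$n_mixed)
    }, numeric(1))
    np <- sum(vapply(sel, function(i) info[[i]]$n_prot, numeric(1)))
    nd <- sum(vapply(sel, function(i)
      if (info[[i]]$his) info[[i]]$n_c + info[[i]]$n_d
      else info[[i]]$n_deprot, numeric(1)))
    nm <- sum(vapply(sel, function(i) info[[i]]$n_mixed, numeric(1)))
    titration_point(p, mean(fr),
                    sd = if (length(fr) > 1L) stats::sd(fr) else NA_real_,
                    mixed_fraction = mean(mx),
                    n_prot = np, n_deprot = nd, n_mixed = nm)
  }))

  agg_fit <- fit_hh(agg)
  flags <- unique(c(flags, agg_fit$flags))
  pka_head <- if (is.finite(agg_fit$pKa)) agg_fit$pKa
              else mean(pkas, na.rm = TRUE)
  list(pKa_mean = pka_head,
       pKa_sd = if (length(pkas) > 1L) stats::sd(pkas, na.rm = TRUE) else NA_real_,
       replicate_pKa = unname(pkas),
       aggregate_fit = agg_fit,
       fits = fits, titration = agg, flags = flags)
}

# classified counts of one site in one trajectory, after discarding the
# equilibration prefix
.site_counts <- function(tr, site, lo, hi, burn_in = 0.2) {
  md <- tr$metadata
  if (!site %in% md$sites) stop(sprintf("site '%s' not in trajectory", site))
  i <- match(site, md$sites)
  cols <- which(md$lam_site == i)
  Tl <- md$lambda_T[cols[1]]
  nfr <- nrow(tr$lambda)
  keep <- seq.int(floor(burn_in * nfr) + 1L, nfr)
  tr$lambda <- tr$lambda[keep, , drop = FALSE]
  if (length(cols) == 3L) {                       # multisite His
    lp <- tr$lambda[, cols[1]]
    lt1 <- tr$lambda[, cols[2]]
    lt2 <- tr$lambda[, cols[3]]
    n_p <- sum(lp > hi)
    n_c <- sum(lt1 > hi)
    n_d <- sum(lt2 > hi)
    n_mixed <- length(lp) - n_p - n_c - n_d
    list(his = TRUE, n_prot = n_p, n_c = n_c, n_d = n_d,
         n_deprot = n_c + n_d, n_mixed = max(0L, n_mixed), T_lambda = Tl)
  } else {
    cf <- classify_frames(tr$lambda[, cols], lo, hi)
    list(his = FALSE, n_prot = unname(cf["n_prot"]),
         n_deprot = unname(cf["n_deprot"]),
         n_mixed = unname(cf["n_mixed"]), T_lambda = Tl)
  }
}
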