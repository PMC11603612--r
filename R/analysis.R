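#' Classify trajectory frames by protonation state
#'
#' A frame is protonated if lambda < \code{lo}, deprotonated if
#' lambda > \code{hi}, and mixed otherwise.  Mixed frames represent
#' unphysical intermediate charge states and are excluded from the
#' protonation statistics (their fraction is reported separately).
#'
#' @param lambda_series numeric lambda time series.
#' @param lo,hi classification thresholds (defaults 0.2 and 0.8).
#' @return named integer vector \code{c(n_prot, n_deprot, n_mixed)}.
#' @export
classify_frames <- function(lambda_series, lo = 0.2, hi = 0.8) {
  if (length(lambda_series) == 0L) stop("empty lambda series")
  if (lo >= hi) stop("lo must be < hi")
  n_prot <- sum(lambda_series < lo)
  n_deprot <- sum(lambda_series > hi)
  c(n_prot = n_prot, n_deprot = n_deprot,
    n_mixed = length(lambda_series) - n_prot - n_deprot)
}

#' Temper-reweighting of the deprotonated fraction
#'
#' The lambda coordinates sample their free-energy profile at the fictitious
#' temperature T_lambda; the count ratio r = n_deprot / n_prot observed there
#' maps to r^(T_lambda / T) at the physical temperature T.  The deprotonated
#' fraction at T is r^(T_lambda/T) / (1 + r^(T_lambda/T)).  With a zero count
#' on one side the fraction is pinned to 0 or 1 and flagged one-sided.
#'
#' @param n_prot,n_deprot protonated / deprotonated frame counts.
#' @param T_lambda fictitious lambda temperature (K).
#' @param T physical temperature (K).
#' @return list with \code{fraction} and logical \code{one_sided}.
#' @export
reweight_fraction <- function(n_prot, n_deprot, T_lambda, T) {
  if (T_lambda <= 0 || T <= 0) stop("temperatures must be positive")
  if (n_prot + n_deprot <= 0) stop("no classified frames to reweight")
  if (n_prot == 0) return(list(fraction = 1, one_sided = TRUE))
  if (n_deprot == 0) return(list(fraction = 0, one_sided = TRUE))
  lr <- (T_lambda / T) * (log(n_deprot) - log(n_prot))
  list(fraction = stats::plogis(lr), one_sided = FALSE)
}

#' Deprotonated fraction of a multisite histidine
#'
#' The two neutral tautomer counts are pooled as the deprotonated class and
#' reweighted against the protonated count exactly as for a single-site acid.
#'
#' @param N_p protonated-state frame count.
#' @param N_c,N_delta neutral tautomer frame counts.
#' @inheritParams reweight_fraction
#' @export
his_deprot_fraction <- function(N_p, N_c, N_delta, T_lambda, T) {
  if (N_p + N_c + N_delta <= 0) stop("no classified frames")
  reweight_fraction(N_p, N_c + N_delta, T_lambda, T)
}

#' Free energy profile of a lambda coordinate
#'
#' F(lambda) = -kB T_lambda ln P(lambda) from a histogram of the sampled
#' series, shifted so the minimum over populated bins is zero.  Empty bins
#' are returned as NA, never zero-filled.
#'
#' @param lambda_series sampled lambda values.
#' @param T_lambda sampling temperature of the lambda coordinate (K).
#' @param n_bins number of histogram bins (>= 2).
#' @param range histogram range, default the data range.
#' @return data.frame with bin midpoints \code{lambda}, \code{F} (kJ/mol) and
#'   \code{count}.
#' @export
free_energy_profile <- function(lambda_series, T_lambda, n_bins = 50L,
                                range = NULL) {
  if (length(lambda_series) == 0L) stop("empty lambda series")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (is.null(range)) range <- base::range(lambda_series)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  idx <- findInterval(lambda_series, breaks, rightmost.closed = TRUE)
  cnt <- tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
  p <- cnt / sum(cnt)
  f <- ifelse(cnt > 0, -k_boltzmann * T_lambda * log(p), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  data.frame(lambda = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
             F = f, count = cnt)
}

#' Cumulative ionization-energy time series
#'
#' At each checkpoint the ionization free energy is estimated from the
#' cumulative classified counts as dG = -kB T ln(cum_deprot / cum_prot)
#' (negative when deprotonation dominates).  The estimate is undefined (NA)
#' until both cumulative counts are nonzero.
#'
#' @param lambda_series sampled lambda values.
#' @param T temperature (K) of the reported free energy.
#' @param stride checkpoint spacing in frames.
#' @param lo,hi classification thresholds.
#' @return data.frame with \code{frame}, cumulative counts and \code{dG}.
#' @export
ionization_energy_series <- function(lambda_series, T, stride = 1L,
                                     lo = 0.2, hi = 0.8) {
  n <- length(lambda_series)
  if (n < stride) stop("series shorter than one stride")
  cp <- cumsum(lambda_series < lo)
  cd <- cumsum(lambda_series > hi)
  at <- seq(stride, n, by = stride)
  dg <- ifelse(cp[at] > 0 & cd[at] > 0,
               -k_boltzmann * T * (log(cd[at]) - log(cp[at])), NA_real_)
  data.frame(frame = at, cum_prot = cp[at], cum_deprot = cd[at], dG = dg)
}

#' Per-pH titration point
#'
#' @param pH solution pH.
#' @param fraction reweighted deprotonated fraction.
#' @param sd replicate standard deviation (NA with a single replicate).
#' @param mixed_fraction fraction of mixed frames.
#' @param n_prot,n_deprot,n_mixed pooled frame counts.
#' @return one-row data.frame.
#' @export
titration_point <- function(pH, fraction, sd = NA_real_, mixed_fraction = 0,
                            n_prot = 0L, n_deprot = 0L, n_mixed = 0L) {
  stopifnot(fraction >= 0, fraction <= 1, mixed_fraction >= 0,
            mixed_fraction <= 1, n_prot >= 0, n_deprot >= 0, n_mixed >= 0)
  data.frame(pH = pH, fraction = fraction, sd = sd,
             mixed_fraction = mixed_fraction,
             n_prot = n_prot, n_deprot = n_deprot, n_mixed = n_mixed)
}
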