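#' Thermostat parameters
#'
#' Nose-Hoover chain settings used for every thermostatted degree of freedom
#' in adiabatic mode (one independent chain per coordinate, "massive"
#' thermostatting), and the time constant reused by the stochastic
#' velocity-rescaling thermostat of standard mode.
#'
#' @param chain_length number of chain links (default 4).
#' @param time_constant thermostat time constant tau in ps (default 0.5);
#'   chain masses are Q_j = kB * target_T * tau^2.
#' @param suzuki_yoshida_order factorization order: 1, 4 (3 weights) or 6.
#' @param n_multiple_steps inner multiple-time-steps per half update.
#' @param target_T target temperature (K); filled per coordinate by the
#'   engine, kept here for stand-alone use of [nhc_half_step()].
#' @export
thermo_params <- function(chain_length = 4L, time_constant = 0.5,
                          suzuki_yoshida_order = 4L, n_multiple_steps = 5L,
                          target_T = 300) {
  if (chain_length < 1) stop("chain_length must be >= 1")
  if (time_constant <= 0) stop("time_constant must be positive")
  if (!suzuki_yoshida_order %in% c(1L, 4L, 6L))
    stop("suzuki_yoshida_order must be 1, 4 or 6")
  structure(list(chain_length = as.integer(chain_length),
                 time_constant = time_constant,
                 suzuki_yoshida_order = as.integer(suzuki_yoshida_order),
                 n_multiple_steps = as.integer(n_multiple_steps),
                 target_T = target_T),
            class = "thermo_params")
}

#' Nose-Hoover chain half step
#'
#' Applies the Suzuki-Yoshida-factorized chain update for time \code{dt} to a
#' set of independently thermostatted 1-dof velocities (the "side" scheme
#' applies this for dt/2 before and after the velocity-Verlet update).
#' Deterministic given the chain state.
#'
#' @param nhc list with matrices \code{xi} and \code{vxi} (one row per dof,
#'   one column per chain link).
#' @param velocities,masses per-dof velocity and mass vectors.
#' @param dt update time in ps.
#' @param params a [thermo_params()]; \code{target_T} may be a vector, one
#'   entry per dof.
#' @return list with updated \code{nhc} and \code{velocities}.
#' @export
nhc_half_step <- function(nhc, velocities, masses, dt,
                          params = thermo_params()) {
  if (dt <= 0) stop("dt must be positive")
  tT <- rep_len(params$target_T, length(velocities))
  out <- nhc_half_step_core(nhc$xi, nhc$vxi, velocities, masses, tT, dt,
                            params$time_constant,
                            params$suzuki_yoshida_order,
                            params$n_multiple_steps)
  list(nhc = list(xi = out$xi, vxi = out$vxi), velocities = out$v)
}

#' Charge-neutrality constraint projection
#'
#' SHAKE-like correction of unconstrained lambda positions,
#' lambda_i = lambda_i_u - zeta * alpha_i / m_i with the Lagrange multiplier
#' zeta = (sum(alpha * lambda_u) - target) / sum(alpha^2 / m), and the
#' analogous RATTLE-like projection removing the constraint-violating
#' velocity component.  Afterwards sum(alpha * lambda) = target exactly.
#'
#' @param lambda_u,velocity_u unconstrained positions and velocities.
#' @param spec list with \code{alpha} (constraint coefficients,
#'   alpha_i = N_p (q_A - q_B)) and \code{target} (conserved total).
#' @param masses lambda masses.
#' @return list with \code{lambda}, \code{velocity}, \code{zeta}.
#' @export
apply_charge_constraint <- function(lambda_u, velocity_u, spec, masses) {
  if (all(spec$alpha == 0))
    stop("charge constraint undefined: all alpha are zero")
  out <- charge_constraint_core(as.numeric(lambda_u), as.numeric(velocity_u),
                                as.numeric(spec$alpha),
                                rep_len(as.numeric(masses), length(lambda_u)),
                                spec$target)
  list(lambda = out$lambda, velocity = out$velocity, zeta = out$zeta)
}

#' d-AFED Langevin step for the extended variable
#'
#' BAOAB-style splitting: deterministic velocity/position half steps around
#' an exact Ornstein-Uhlenbeck velocity update with stationary variance
#' kB T_s / mass.  With \code{n_steps > 1} the update is iterated (the
#' harmonic coupling force to a fixed collective-variable value \code{cv} is
#' refreshed each step).  Uses R's RNG stream, so runs are reproducible under
#' \code{set.seed()}.
#'
#' @param s,v_s extended-variable position and velocity.
#' @param ev an [extended_variable()].
#' @param dt time step in ps.
#' @param n_steps number of steps to take.
#' @param cv fixed collective-variable value the spring is anchored to, or
#'   \code{NULL} for a free (uncoupled) extended particle.
#' @return list with trajectories \code{s} and \code{v_s} (length n_steps).
#' @export
langevin_ou_step <- function(s, v_s, ev, dt, n_steps = 1L, cv = NULL) {
  if (dt <= 0) stop("dt must be positive")
  langevin_run_core(s, v_s, ev$mass, ev$T_s, ev$friction_gamma,
                    ev$coupling_k, if (is.null(cv)) 0 else cv,
                    !is.null(cv), dt, as.integer(n_steps))
}

#' Advance the system by one (or a few) integration steps
#'
#' One step applies, in order: an NHC side half-step for every thermostat
#' chain, the velocity-Verlet position/velocity update with analytic forces,
#' the charge-constraint projection of lambda positions and velocities, and
#' the closing NHC half-step.  Deterministic when thermostats are
#' deterministic (adiabatic mode).
#'
#' @param state a [sim_state()].
#' @param system the matching [model_system()].
#' @param params a [thermo_params()].
#' @param dt time step in ps.
#' @param n_steps number of steps.
#' @param mode \code{"ph_afed"} (massive NHC) or \code{"standard"} (global
#'   stochastic velocity rescaling at T_physical).
#' @param thermostat,constraint logical switches (disable for NVE checks).
#' @return the advanced \code{sim_state}.
#' @export
integrate_step <- function(state, system, params = thermo_params(), dt = 0.002,
                           n_steps = 1L, mode = "ph_afed",
                           thermostat = TRUE, constraint = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  fl <- .flatten_system(system, mode = mode, thermostat = thermostat,
                        constraint = constraint, params = params)
  out <- run_core(fl$core, state, as.integer(n_steps), dt, as.integer(n_steps),
                  FALSE)
  new <- out$final_state
  new$time_ps <- state$time_ps + n_steps * dt
  class(new) <- "sim_state"
  new
}

#' Instantaneous kinetic temperatures by coordinate group
#'
#' T = m v^2 / kB per one-dimensional coordinate, averaged per group: one
#' entry per titratable site (its lambda coordinates), plus \code{buffers},
#' \code{env} (environment and gate coordinates) and \code{dafed_s} where
#' present.
#'
#' @inheritParams integrate_step
#' @return named vector of temperatures in K.
#' @export
instantaneous_temperatures <- function(state, system) {
  fl <- .flatten_system(system)
  tl <- fl$core$lam_mass * state$lambda_velocity^2 / k_boltzmann
  out <- c()
  for (i in seq_along(system$sites)) {
    out[system$sites[[i]]$site_id] <- mean(tl[fl$lam_site == i])
  }
  if (any(fl$lam_site == 0)) out["buffers"] <- mean(tl[fl$lam_site == 0])
  ne <- length(fl$core$env_mass)
  te <- c(if (ne) fl$core$env_mass * state$env_velocity^2 / k_boltzmann,
          if (length(fl$core$gate_mass))
            fl$core$gate_mass * state$gate_velocity^2 / k_boltzmann)
  if (length(te)) out["env"] <- mean(te)
  if (isTRUE(fl$core$dafed))
    out["dafed_s"] <- fl$core$dafed_mass * state$s_velocity^2 / k_boltzmann
  out
}

#' Run a constant-pH lambda-dynamics simulation
#'
#' Propagates a [model_system()] for \code{n_steps} steps of \code{dt} ps and
#' records a trajectory.  In \code{"ph_afed"} mode every coordinate has its
#' own Nose-Hoover chain: lambda coordinates at their site's fictitious
#' T_lambda, environment and gate coordinates at T_physical (adiabatic
#' decoupling relies on the large m_lambda).  In \code{"standard"} mode one
#' shared stochastic-rescaling thermostat at T_physical controls all
#' coordinates and every lambda mass is set to \code{m_lambda_standard}.
#' Initial velocities are Maxwell-distributed at each coordinate's target
#' temperature using the seeded RNG stream; identical seeds give bitwise
#' identical trajectories.
#'
#' @param system a [model_system()] (optionally with a d-AFED extended
#'   variable attached, see [attach_dafed()]).
#' @param mode \code{"ph_afed"} or \code{"standard"}.
#' @param n_steps number of integration steps (>= 1).
#' @param dt time step in ps (default 0.002, i.e. 2 fs).
#' @param seed integer seed; \code{NULL} leaves the RNG stream untouched.
#' @param sample_stride record every this-many steps.
#' @param params a [thermo_params()].
#' @param thermostat,constraint logical switches for property checks.
#' @param m_lambda_standard lambda mass used in standard mode (default 5).
#' @param record_conserved also record the extended-system conserved energy.
#' @return an object of class \code{lambda_trajectory}: sampled times, a
#'   lambda matrix (one column per coordinate), per-group temperatures,
#'   per-term energies and run metadata.
#' @export
run_simulation <- function(system, mode = c("ph_afed", "standard"),
                           n_steps, dt = 0.002, seed = NULL,
                           sample_stride = 10L, params = thermo_params(),
                           thermostat = TRUE, constraint = TRUE,
                           m_lambda_standard = 5,
                           record_conserved = FALSE) {
  mode <- match.arg(mode)
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (sample_stride < 1 || sample_stride > n_steps)
    stop("sample_stride must be in [1, n_steps]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fl <- .flatten_system(system, mode = mode, thermostat = thermostat,
                        constraint = constraint, params = params,
                        m_lambda_standard = m_lambda_standard)
  state <- sim_state(system)
  nl <- length(fl$core$lam_mass)
  ne <- length(fl$core$env_mass)
  ngt <- length(fl$core$gate_mass)
  lamT <- if (mode == "standard") rep(system$T_physical, nl) else fl$core$lam_T
  state$lambda_velocity <- stats::rnorm(nl) *
    sqrt(k_boltzmann * lamT / fl$core$lam_mass)
  if (ne) state$env_velocity <- stats::rnorm(ne) *
    sqrt(k_boltzmann * system$T_physical / fl$core$env_mass)
  if (ngt) state$gate_velocity <- stats::rnorm(ngt) *
    sqrt(k_boltzmann * system$T_physical / fl$core$gate_mass)
  if (isTRUE(fl$core$dafed))
    state$s_velocity <- stats::rnorm(1) *
      sqrt(k_boltzmann * fl$core$dafed_Ts / fl$core$dafed_mass)

  out <- run_core(fl$core, state, as.integer(n_steps), dt,
                  as.integer(sample_stride), record_conserved)

  lambda <- out$lambda
  colnames(lambda) <- fl$lam_names
  site_ids <- vapply(system$sites, function(s) s$site_id, character(1))
  temps <- .group_temps(out$temps, fl, system)
  energies <- out$energies
  colnames(energies) <- c("pH", "barrier", "restraint", "env", "gate",
                          "coupling")
  structure(list(
    step = out$step, time_ps = out$step * dt,
    lambda = lambda,
    env = if (ne) out$env else NULL,
    gate = if (ngt) out$gate else NULL,
    s = if (isTRUE(fl$core$dafed)) out$s else NULL,
    temps = temps, energies = energies,
    conserved = if (record_conserved) out$conserved else NULL,
    final_state = structure(c(out$final_state,
                              list(time_ps = n_steps * dt)),
                            class = "sim_state"),
    metadata = list(pH = system$pH, seed = seed, mode = mode,
                    T_physical = system$T_physical, dt = dt,
                    sample_stride = as.integer(sample_stride),
                    n_steps = as.integer(n_steps),
                    sites = site_ids,
                    lambda_T = fl$core$lam_T,
                    lam_site = fl$lam_site)),
    class = "lambda_trajectory")
}

# group the per-dof instantaneous temperature samples into per-site /
# buffers / env columns
.group_temps <- function(tmat, fl, system) {
  nl <- length(fl$core$lam_mass)
  ne <- length(fl$core$env_mass)
  ngt <- length(fl$core$gate_mass)
  cols <- list()
  for (i in seq_along(system$sites)) {
    sel <- which(fl$lam_site == i)
    cols[[system$sites[[i]]$site_id]] <-
      if (length(sel) == 1L) tmat[, sel] else rowMeans(tmat[, sel, drop = FALSE])
  }
  bsel <- which(fl$lam_site == 0)
  if (length(bsel))
    cols[["buffers"]] <- rowMeans(tmat[, bsel, drop = FALSE])
  esel <- nl + seq_len(ne + ngt)
  if (length(esel))
    cols[["env"]] <- rowMeans(tmat[, esel, drop = FALSE])
  if (isTRUE(fl$core$dafed))
    cols[["dafed_s"]] <- tmat[, nl + ne + ngt + 1L]
  do.call(cbind, cols)
}

#' @export
print.lambda_trajectory <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("lambda trajectory: %d samples, %d coordinates\n",
              length(x$step), ncol(x$lambda)))
  cat(sprintf("  mode = %s, pH = %g, dt = %g ps, stride = %d, seed = %s\n",
              md$mode, md$pH, md$dt, md$sample_stride,
              if (is.null(md$seed)) "none" else md$seed))
  invisible(x)
}

#' Count basin transitions of a lambda series
#'
#' Number of times the coordinate moves from one end-state basin
#' (lambda < lo) to the other (lambda > hi) or back, ignoring time spent in
#' the mixed region.
#'
#' @param lambda_series numeric lambda time series.
#' @param lo,hi basin thresholds.
#' @export
count_transitions <- function(lambda_series, lo = 0.2, hi = 0.8) {
  b <- ifelse(lambda_series < lo, 0L, ifelse(lambda_series > hi, 1L, NA))
  b <- b[!is.na(b)]
  if (length(b) < 2L) return(0L)
  sum(diff(b) != 0L)
}
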