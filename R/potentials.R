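#' pH-dependent lambda potential
#'
#' Step-function pH potential: V_pH(lambda) = ln(10) kB T (pKa_ref - pH)
#' S(lambda), where S is a quintic smoothstep rising from 0 to 1 between the
#' frame-classification thresholds (0.2, 0.8).  It is exactly zero over the
#' protonated basin and exactly the deprotonation free-energy difference
#' ln(10) kB T (pKa_ref - pH) over the deprotonated basin, so the basin
#' populations behave as a two-state system and the tempered count-ratio
#' reweighting is exact; the end-point barrier supplies the localization at
#' lambda = 0 and 1.
#'
#' @param lambda titration coordinate (vectorized).
#' @param pH solution pH.
#' @param pKa_ref reference pKa of the site.
#' @param T temperature in K.
#' @return energy in kJ/mol.
#' @export
v_ph <- function(lambda, pH, pKa_ref, T) {
  if (!all(is.finite(lambda)) || !is.finite(pH) || !is.finite(pKa_ref) ||
      !is.finite(T))
    stop("v_ph: non-finite input")
  if (T <= 0) stop("v_ph: T must be positive")
  t <- pmin(pmax((lambda - 0.2) / 0.6, 0), 1)
  s <- t^3 * (10 - 15 * t + 6 * t^2)
  .ln10 * k_boltzmann * T * (pKa_ref - pH) * s
}

#' Quartic end-point barrier
#'
#' V_barrier(lambda) = 16 h lambda^2 (1 - lambda)^2: zero at both end states,
#' maximum h at lambda = 0.5, and growing outside [0, 1] so it doubles as a
#' confining wall.
#'
#' @param lambda titration coordinate (vectorized).
#' @param height barrier height h in kJ/mol (>= 0).
#' @export
v_barrier <- function(lambda, height) {
  if (!all(is.finite(lambda)) || !is.finite(height))
    stop("v_barrier: non-finite input")
  if (height < 0) stop("v_barrier: height must be >= 0")
  16 * height * lambda^2 * (1 - lambda)^2
}

#' Hyperbolic-tangent multisite restraint energy
#'
#' With delta = |sum(lambda) - 1|, returns
#' amplitude/2 * (tanh((delta - flat_width)/switch_width) + 1): ~0 inside the
#' flat bottom, saturating at amplitude outside it, and even in
#' (sum(lambda) - 1).
#'
#' @param lambdas the three tautomer lambda coordinates.
#' @param params a [tanh_restraint_params()].
#' @export
v_tanh_restraint <- function(lambdas, params = tanh_restraint_params()) {
  if (length(lambdas) != 3L)
    stop("v_tanh_restraint: exactly 3 lambda components required")
  stopifnot(inherits(params, "tanh_restraint_params"))
  delta <- abs(sum(lambdas) - 1)
  0.5 * params$amplitude *
    (tanh((delta - params$flat_width) / params$switch_width) + 1)
}

# --- flattening of a model_system into the core representation ------------

# Returns the flat list consumed by the C++ core plus column bookkeeping.
# mode "standard" overrides every lambda mass with m_lambda_standard and
# selects the global CSVR thermostat.
.flatten_system <- function(system, mode = c("ph_afed", "standard"),
                            thermostat = TRUE, constraint = TRUE,
                            params = thermo_params(),
                            m_lambda_standard = 5) {
  stopifnot(inherits(system, "model_system"))
  mode <- match.arg(mode)
  kT <- k_boltzmann * system$T_physical

  lam_mass <- numeric(0); lam_T <- numeric(0); lam_bar <- numeric(0)
  lam_slope <- numeric(0); alpha <- numeric(0); lam_names <- character(0)
  lam_site <- integer(0)   # owning site index, 0 for buffers
  lam0 <- numeric(0)
  r_idx <- integer(0); r_amp <- numeric(0); r_flat <- numeric(0)
  r_sw <- numeric(0)
  env_mass <- numeric(0); env_minA <- numeric(0); env_kA <- numeric(0)
  env_minB <- numeric(0); env_kB <- numeric(0); env_off <- numeric(0)
  env_lam <- integer(0)
  gate_mass <- numeric(0); gate_h <- numeric(0); gate_off <- numeric(0)
  gate_lam <- integer(0)

  for (i in seq_along(system$sites)) {
    s <- system$sites[[i]]
    if (inherits(s, "his_site_spec")) {
      base <- length(lam_mass)
      # order: protonated reference coordinate, tautomer 1, tautomer 2
      lam_mass <- c(lam_mass, rep(s$m_lambda, 3))
      lam_T <- c(lam_T, rep(s$T_lambda, 3))
      lam_bar <- c(lam_bar, rep(s$barrier_height, 3))
      lam_slope <- c(lam_slope,
                     0,
                     .ln10 * kT * (s$pKa_micro[1] - system$pH),
                     .ln10 * kT * (s$pKa_micro[2] - system$pH))
      # protonated coordinate carries the +1 charge: alpha = q_A - q_B with
      # A the lambda = 0 (reference, neutral) end
      alpha <- c(alpha, -1, 0, 0)
      lam_names <- c(lam_names, paste0(s$site_id, c("_p", "_t1", "_t2")))
      lam_site <- c(lam_site, rep(i, 3))
      lam0 <- c(lam0, 1, 0, 0)
      r_idx <- c(r_idx, base + 0:2)
      r_amp <- c(r_amp, s$restraint$amplitude)
      r_flat <- c(r_flat, s$restraint$flat_width)
      r_sw <- c(r_sw, s$restraint$switch_width)
    } else {
      idx <- length(lam_mass)
      lam_mass <- c(lam_mass, s$m_lambda)
      lam_T <- c(lam_T, s$T_lambda)
      lam_bar <- c(lam_bar, s$barrier_height)
      lam_slope <- c(lam_slope, .ln10 * kT * (s$pKa_ref - system$pH))
      alpha <- c(alpha, s$N_p * (s$q_A - s$q_B))
      lam_names <- c(lam_names, s$site_id)
      lam_site <- c(lam_site, i)
      lam0 <- c(lam0, 0)
      env <- if (!is.null(system$envs)) system$envs[[i]] else NULL
      gated <- s$gate_height > 0
      if (!is.null(env)) {
        env_mass <- c(env_mass, env$mass)
        env_minA <- c(env_minA, env$min_A); env_kA <- c(env_kA, env$curv_A)
        env_minB <- c(env_minB, env$min_B); env_kB <- c(env_kB, env$curv_B)
        # a gated site's offset acts through the gate switch instead
        env_off <- c(env_off, if (gated) 0 else s$env_offset_dG)
        env_lam <- c(env_lam, idx)
      }
      if (gated) {
        # light gate: its intrinsic motion must be fast relative to the
        # extended variable for the driven-adiabatic separation to hold
        gate_mass <- c(gate_mass, 1)
        gate_h <- c(gate_h, s$gate_height)
        gate_off <- c(gate_off, s$env_offset_dG)
        gate_lam <- c(gate_lam, idx)
      } else if (is.null(env) && s$env_offset_dG != 0) {
        # offset without an explicit env coordinate: fold into the slope
        lam_slope[length(lam_slope)] <-
          lam_slope[length(lam_slope)] + s$env_offset_dG
      }
    }
  }

  site_T <- vapply(system$sites, function(s) s$T_lambda, numeric(1))
  for (b in seq_along(system$buffers)) {
    bs <- system$buffers[[b]]
    if (bs$count == 0) next
    lam_mass <- c(lam_mass, rep(bs$m_lambda, bs$count))
    lam_T <- c(lam_T, rep(bs$T_lambda, bs$count))
    lam_bar <- c(lam_bar, rep(0, bs$count))
    lam_slope <- c(lam_slope, rep(0, bs$count))
    alpha <- c(alpha, rep(bs$alpha_each, bs$count))
    lam_names <- c(lam_names, rep("", bs$count))
    lam_site <- c(lam_site, rep(0L, bs$count))
    lam0 <- c(lam0, rep(0.5, bs$count))
  }
  lam_names[lam_site == 0] <- sprintf("buf%02d", seq_len(sum(lam_site == 0)))

  if (mode == "standard") lam_mass[] <- m_lambda_standard
  if (constraint && all(alpha == 0)) constraint <- FALSE

  list(core = list(
         lam_mass = lam_mass, lam_T = lam_T, lam_barrier = lam_bar,
         lam_ph_slope = lam_slope, alpha = alpha,
         restraint_idx = as.integer(r_idx), restraint_amp = r_amp,
         restraint_flat = r_flat, restraint_sw = r_sw,
         env_mass = env_mass, env_minA = env_minA, env_kA = env_kA,
         env_minB = env_minB, env_kB = env_kB, env_off = env_off,
         env_lam = as.integer(env_lam),
         gate_mass = gate_mass, gate_height = gate_h, gate_off = gate_off,
         gate_lam = as.integer(gate_lam),
         T_physical = system$T_physical,
         dafed = !is.null(system$dafed),
         dafed_gate = if (!is.null(system$dafed)) system$dafed$gate_index else 0L,
         dafed_k = if (!is.null(system$dafed)) system$dafed$coupling_k else 0,
         dafed_mass = if (!is.null(system$dafed)) system$dafed$mass else 0,
         dafed_Ts = if (!is.null(system$dafed)) system$dafed$T_s else 0,
         dafed_gamma = if (!is.null(system$dafed)) system$dafed$friction_gamma else 0,
         constraint = isTRUE(constraint),
         constraint_target = sum(alpha * lam0),
         thermo_mode = if (!thermostat) 0L else if (mode == "ph_afed") 1L else 2L,
         nhc_length = params$chain_length,
         nhc_sy_order = params$suzuki_yoshida_order,
         nhc_n_mts = params$n_multiple_steps,
         nhc_tau = params$time_constant),
       lam_names = lam_names, lam_site = lam_site, lam0 = lam0,
       mode = mode)
}

#' Instantaneous simulation state
#'
#' Positions and velocities of every lambda, environment and gate coordinate
#' plus the thermostat chain variables.  Default initialization: acids start
#' protonated (lambda = 0), His starts in the protonated state
#' (lambda_p = 1), buffers at 0.5, environments at the state-A minimum, gates
#' in the closed basin (g = -1), all velocities zero (draw thermal velocities
#' with [run_simulation()]).
#'
#' @param system a [model_system()].
#' @param lambda,lambda_velocity optional overrides for the full lambda
#'   vector (sites then buffers).
#' @return an object of class \code{sim_state}.
#' @export
sim_state <- function(system, lambda = NULL, lambda_velocity = NULL) {
  fl <- .flatten_system(system)
  nl <- length(fl$core$lam_mass)
  ne <- length(fl$core$env_mass)
  ngt <- length(fl$core$gate_mass)
  if (is.null(lambda)) lambda <- fl$lam0
  if (is.null(lambda_velocity)) lambda_velocity <- numeric(nl)
  if (length(lambda) != nl || length(lambda_velocity) != nl)
    stop(sprintf("state has %d lambda coordinates, system expects %d",
                 length(lambda), nl))
  M <- 4L
  structure(list(
    lambda = as.numeric(lambda),
    lambda_velocity = as.numeric(lambda_velocity),
    env = fl$core$env_minA, env_velocity = numeric(ne),
    gate = rep(-0.5, ngt), gate_velocity = numeric(ngt),
    s = -0.5, s_velocity = 0,
    nhc_xi = matrix(0, nl + ne + ngt, M),
    nhc_vxi = matrix(0, nl + ne + ngt, M),
    step = 0L, time_ps = 0),
    class = "sim_state")
}

#' Total interpolated potential energy
#'
#' Evaluates the full potential: for every site,
#' (1 - lambda) V_A(R) + lambda V_B(R) + V_pH(lambda) + V_barrier(lambda),
#' plus multisite restraints, gate and extended-variable coupling terms.
#' Buffer coordinates contribute nothing (flat potential).
#'
#' @param state a [sim_state()].
#' @param system the matching [model_system()].
#' @return a list with \code{total} (kJ/mol) and the per-term breakdown
#'   \code{terms} (pH, barrier, restraint, env, gate, coupling).
#' @export
interpolated_potential <- function(state, system) {
  fl <- .flatten_system(system, thermostat = FALSE, constraint = FALSE)
  ef <- energy_forces_core(fl$core, state$lambda, state$env, state$gate,
                           state$s)
  list(total = ef$total, terms = ef$terms)
}

#' Analytic forces on all coordinates
#'
#' Negative gradients of [interpolated_potential()] with respect to every
#' lambda, environment and gate coordinate (and the d-AFED extended variable
#' when attached).
#'
#' @inheritParams interpolated_potential
#' @return list with components \code{lambda}, \code{env}, \code{gate},
#'   \code{s} (kJ/mol per unit).
#' @export
system_forces <- function(state, system) {
  fl <- .flatten_system(system, thermostat = FALSE, constraint = FALSE)
  ef <- energy_forces_core(fl$core, state$lambda, state$env, state$gate,
                           state$s)
  list(lambda = ef$f_lambda, env = ef$f_env, gate = ef$f_gate, s = ef$f_s)
}
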