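#' Titratable-site specification
#'
#' Describes one single-coordinate titratable site of a model compound.  The
#' site's protonation state is a continuous coordinate lambda in [0, 1]
#' (0 = protonated, 1 = deprotonated) that carries a pH-dependent linear
#' potential, a quartic end-point barrier, and adiabatic-decoupling
#' parameters: a fictitious temperature \code{T_lambda} and mass
#' \code{m_lambda} much larger than those of the physical coordinates.
#'
#' @param site_id character identifier, unique within a system.
#' @param site_class one of \code{"GLU"}, \code{"ASP"}, \code{"HIS_TAUTOMER"},
#'   \code{"GENERIC"}.  Sets the default reference pKa and end-state charges.
#' @param pKa_ref reference pKa of the model compound.  Defaults to the class
#'   reference value (\code{\link{reference_pka}}); required for
#'   \code{"GENERIC"}.
#' @param q_A,q_B total charge of the protonated (A) / deprotonated (B) state,
#'   in elementary charges.
#' @param N_p number of coupled copies of the site (>= 1); enters the charge
#'   constraint coefficient alpha = N_p * (q_A - q_B).
#' @param T_lambda fictitious lambda temperature (K).
#' @param m_lambda fictitious lambda mass (kJ mol^-1 ps^2).
#' @param barrier_height height of the quartic barrier between the end states
#'   (kJ/mol).
#' @param env_offset_dG free-energy offset (kJ/mol) contributed by the
#'   environment to the B state.  For an ungated site it is added to the
#'   deprotonated environment well; for a gated site it is the burial penalty
#'   switched on by the closed gate.
#' @param gate_height barrier (kJ/mol) of the conformational gate coordinate;
#'   0 means no gate.
#' @return an object of class \code{site_spec}.
#' @seealso [his_site_spec()], [model_system()], [analytic_pka()]
#' @export
site_spec <- function(site_id,
                      site_class = c("GLU", "ASP", "HIS_TAUTOMER", "GENERIC"),
                      pKa_ref = NULL,
                      q_A = NULL, q_B = NULL,
                      N_p = 1L,
                      T_lambda = 750, m_lambda = 750, barrier_height = 10,
                      env_offset_dG = 0, gate_height = 0) {
  site_class <- match.arg(site_class)
  if (is.null(pKa_ref)) {
    if (site_class == "GENERIC")
      stop("pKa_ref must be given for a GENERIC site")
    pKa_ref <- unname(reference_pka[site_class])
  }
  if (is.null(q_A)) q_A <- if (site_class == "HIS_TAUTOMER") 1 else 0
  if (is.null(q_B)) q_B <- if (site_class == "HIS_TAUTOMER") 0 else -1
  stopifnot(is.character(site_id), length(site_id) == 1L,
            is.finite(pKa_ref), is.finite(q_A), is.finite(q_B))
  if (N_p < 1) stop("N_p must be >= 1")
  if (m_lambda <= 0) stop("m_lambda must be positive")
  if (T_lambda <= 0) stop("T_lambda must be positive")
  if (barrier_height < 0) stop("barrier_height must be >= 0")
  if (gate_height < 0) stop("gate_height must be >= 0")
  structure(list(site_id = site_id, site_class = site_class,
                 pKa_ref = pKa_ref, q_A = q_A, q_B = q_B, N_p = as.integer(N_p),
                 T_lambda = T_lambda, m_lambda = m_lambda,
                 barrier_height = barrier_height,
                 env_offset_dG = env_offset_dG, gate_height = gate_height),
            class = "site_spec")
}

#' Parameters of the hyperbolic-tangent multisite restraint
#'
#' Flat-bottomed restraint keeping the sum of the three tautomer lambda
#' coordinates of a multisite histidine close to 1.  The restraint energy is
#' ~0 while |sum(lambda) - 1| < \code{flat_width} and saturates at
#' \code{amplitude} over a further \code{switch_width}.
#'
#' The default amplitude of 200 kJ/mol is large against the lambda thermal
#' energy even at T_lambda = 1500 K (kB * 1500 ~ 12.5 kJ/mol), so excursions
#' of the sum beyond +/- flat_width stay rare.
#'
#' @param amplitude plateau height in kJ/mol.
#' @param flat_width half-width of the flat bottom, in lambda units.
#' @param switch_width width of the tanh switching region, in lambda units.
#' @export
tanh_restraint_params <- function(amplitude = 200, flat_width = 0.2,
                                  switch_width = 0.05) {
  if (amplitude <= 0) stop("amplitude must be positive")
  if (switch_width <= 0) stop("switch_width must be positive")
  structure(list(amplitude = amplitude, flat_width = flat_width,
                 switch_width = switch_width),
            class = "tanh_restraint_params")
}

#' Multisite histidine specification
#'
#' Histidine titrates through three coupled lambda coordinates: one for the
#' (charged) protonated state and one for each neutral tautomer.  The
#' protonated coordinate is the reference state and carries no pH potential;
#' each tautomer coordinate carries the pH potential parameterized with its
#' microscopic pKa.  A hyperbolic-tangent restraint keeps the sum of the
#' three coordinates close to 1.
#'
#' @param site_id character identifier.
#' @param pKa_micro microscopic pKa pair (tautomer 1, tautomer 2).
#' @param restraint a [tanh_restraint_params()] object.
#' @inheritParams site_spec
#' @return an object of class \code{his_site_spec}.
#' @export
his_site_spec <- function(site_id,
                          pKa_micro = c(reference_pka[["HIS_TAUTOMER"]],
                                        reference_pka[["HIS_TAUTOMER2"]]),
                          restraint = tanh_restraint_params(),
                          T_lambda = 750, m_lambda = 750, barrier_height = 10) {
  stopifnot(length(pKa_micro) == 2L, all(is.finite(pKa_micro)),
            inherits(restraint, "tanh_restraint_params"))
  if (m_lambda <= 0) stop("m_lambda must be positive")
  if (T_lambda <= 0) stop("T_lambda must be positive")
  if (barrier_height < 0) stop("barrier_height must be >= 0")
  structure(list(site_id = site_id, lambda_count = 3L,
                 pKa_micro = as.numeric(pKa_micro), restraint = restraint,
                 T_lambda = T_lambda, m_lambda = m_lambda,
                 barrier_height = barrier_height),
            class = "his_site_spec")
}

#' Macroscopic pKa of a multisite histidine
#'
#' The macroscopic acid constant is the sum of the microscopic tautomer
#' constants: pKa_macro = -log10(10^-pKa1 + 10^-pKa2).
#'
#' @param spec a [his_site_spec()].
#' @export
his_macroscopic_pka <- function(spec) {
  stopifnot(inherits(spec, "his_site_spec"))
  -log10(sum(10^(-spec$pKa_micro)))
}

#' Harmonic environment coordinate
#'
#' A one-dimensional stand-in for the physical environment of a site.  Its
#' potential interpolates linearly in lambda between a protonated-state well
#' (minimum \code{min_A}, curvature \code{curv_A}) and a deprotonated-state
#' well (\code{min_B}, \code{curv_B}); the site's \code{env_offset_dG} is
#' added to the B well.
#'
#' @param mass mass in kJ mol^-1 ps^2.
#' @param min_A,min_B well minimum positions.
#' @param curv_A,curv_B well curvatures (kJ/mol per unit^2), must be positive.
#' @export
env_coordinate <- function(mass = 10, min_A = 0, curv_A = 100,
                           min_B = 0, curv_B = 100) {
  if (mass <= 0) stop("mass must be positive")
  if (curv_A <= 0 || curv_B <= 0) stop("curvatures must be positive")
  structure(list(mass = mass, min_A = min_A, curv_A = curv_A,
                 min_B = min_B, curv_B = curv_B),
            class = "env_coordinate")
}

#' Titratable buffer set
#'
#' Auxiliary lambda coordinates that absorb the charge released by titration
#' under the linear charge-neutrality constraint.  Buffers carry a flat
#' potential (no pH term, no barrier), so they comply with the constraint
#' with minimal perturbation of the titration coordinates.
#'
#' @param count number of buffer coordinates (>= 0).
#' @param alpha_each signed charge increment per lambda unit for each buffer.
#' @param m_lambda,T_lambda fictitious mass and thermostat target of each
#'   buffer coordinate.
#' @export
buffer_set <- function(count, alpha_each = -1, m_lambda = 750, T_lambda = 750) {
  if (count < 0) stop("count must be >= 0")
  structure(list(count = as.integer(count), alpha_each = alpha_each,
                 m_lambda = m_lambda, T_lambda = T_lambda),
            class = "buffer_set")
}

#' Assemble a titratable model system
#'
#' Bundles titratable sites, their environment coordinates, buffer particles
#' and the thermodynamic state (physical temperature, pH) into a simulatable
#' system.  By default 10 titratable buffers are added per titratable site,
#' each inheriting the site's T_lambda and m_lambda.
#'
#' @param sites a [site_spec()]/[his_site_spec()] or a list of them.
#' @param envs a single [env_coordinate()], a list parallel to \code{sites}
#'   (\code{NULL} entries allowed), or \code{NULL} for no environment
#'   coordinates.  Multisite His sites take no environment coordinate.
#' @param buffers a [buffer_set()] overriding the per-site default, or
#'   \code{NULL} for the default (10 per site).
#' @param T_physical physical temperature in K.
#' @param pH solution pH.
#' @return an object of class \code{model_system}.
#' @export
model_system <- function(sites, envs = NULL, buffers = NULL,
                         T_physical = 300, pH = 7) {
  if (inherits(sites, "site_spec") || inherits(sites, "his_site_spec"))
    sites <- list(sites)
  stopifnot(length(sites) >= 1L, T_physical > 0, is.finite(pH))
  ids <- vapply(sites, function(s) s$site_id, character(1))
  if (anyDuplicated(ids)) stop("site_id values must be unique")
  if (inherits(envs, "env_coordinate")) envs <- list(envs)
  if (!is.null(envs)) {
    if (length(envs) != length(sites))
      stop("envs must have one entry per site (NULL entries allowed)")
    for (i in seq_along(envs)) {
      if (is.null(envs[[i]])) next
      if (!inherits(envs[[i]], "env_coordinate"))
        stop("envs entries must be env_coordinate objects")
      if (inherits(sites[[i]], "his_site_spec"))
        stop("multisite His sites take no environment coordinate")
    }
  }
  if (!is.null(buffers) && !inherits(buffers, "buffer_set"))
    stop("buffers must be a buffer_set")
  if (is.null(buffers)) {
    buffers <- lapply(sites, function(s)
      buffer_set(10L, alpha_each = -1, m_lambda = s$m_lambda,
                 T_lambda = s$T_lambda))
  } else {
    buffers <- list(buffers)
  }
  structure(list(sites = sites, envs = envs, buffers = buffers,
                 T_physical = T_physical, pH = pH),
            class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  cat("Titratable model system\n")
  cat(sprintf("  T_physical: %g K, pH: %g\n", x$T_physical, x$pH))
  for (i in seq_along(x$sites)) {
    s <- x$sites[[i]]
    if (inherits(s, "his_site_spec")) {
      cat(sprintf("  site %s: His multisite, pKa_micro = %.2f/%.2f, T_lambda = %g K\n",
                  s$site_id, s$pKa_micro[1], s$pKa_micro[2], s$T_lambda))
    } else {
      cat(sprintf("  site %s: %s, pKa_ref = %.2f, T_lambda = %g K, barrier = %g kJ/mol%s\n",
                  s$site_id, s$site_class, s$pKa_ref, s$T_lambda,
                  s$barrier_height,
                  if (s$gate_height > 0) sprintf(", gated (%g kJ/mol)", s$gate_height) else ""))
    }
  }
  nb <- sum(vapply(x$buffers, function(b) b$count, integer(1)))
  cat(sprintf("  buffers: %d\n", nb))
  invisible(x)
}

#' Closed-form true pKa of a model site
#'
#' The true pKa of a configured site follows from the end-state free-energy
#' difference: pKa_true = pKa_ref + ddG / (ln(10) kB T), where ddG collects
#' the environment offset, the entropic correction (kB T / 2) * ln(curv_B /
#' curv_A) for unequal well curvatures, and (for a gated site) the
#' gate-average of the switched burial penalty computed by quadrature over
#' the gate coordinate.
#'
#' @param spec a [site_spec()].
#' @param env the site's [env_coordinate()] or \code{NULL}.
#' @param T temperature in K at which the pKa is evaluated.
#' @return the true pKa (dimensionless).
#' @export
analytic_pka <- function(spec, env = NULL, T = 300) {
  stopifnot(inherits(spec, "site_spec"), T > 0)
  kT <- k_boltzmann * T
  ddG <- 0
  if (!is.null(env)) {
    stopifnot(inherits(env, "env_coordinate"))
    if (env$curv_A <= 0 || env$curv_B <= 0) stop("curvatures must be positive")
    ddG <- ddG + 0.5 * kT * log(env$curv_B / env$curv_A)
  }
  if (spec$gate_height > 0) {
    # burial penalty lambda * env_offset_dG * s(g) averaged over the gate
    # (wells at +/- 0.5, switch width 0.2, matching the engine)
    sw <- function(g) 0.5 * (1 - tanh(g / 0.2))
    vg <- function(g) spec$gate_height * ((g / 0.5)^2 - 1)^2
    z0 <- stats::integrate(function(g) exp(-vg(g) / kT), -2, 2,
                           rel.tol = 1e-10)$value
    z1 <- stats::integrate(function(g) exp(-(vg(g) + spec$env_offset_dG * sw(g)) / kT),
                           -2, 2, rel.tol = 1e-10)$value
    ddG <- ddG - kT * log(z1 / z0)
  } else {
    ddG <- ddG + spec$env_offset_dG
  }
  spec$pKa_ref + ddG / (kT * .ln10)
}
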