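#' d-AFED extended variable
#'
#' Parameters of the driven adiabatic free energy dynamics extended variable
#' s: harmonically tethered to a conformational collective variable (here the
#' gate coordinate of a buried site), held at a high temperature T_s by a
#' Langevin thermostat, and adiabatically decoupled through its mass.
#'
#' @param coupling_k harmonic coupling constant (kJ/mol per unit^2).
#' @param mass extended-variable mass (kJ mol^-1 ps^2).
#' @param T_s extended-variable temperature (K).
#' @param friction_gamma Langevin friction in ps^-1.
#' @param cv identifier of the driven collective variable
#'   (\code{"gate:<site_id>"}).
#' @export
extended_variable <- function(coupling_k = 1000, mass = 20, T_s = 1000,
                              friction_gamma = 5.0, cv = NULL) {
  if (coupling_k < 0) stop("coupling_k must be >= 0")
  if (mass <= 0) stop("mass must be positive")
  if (T_s <= 0) stop("T_s must be positive")
  structure(list(coupling_k = coupling_k, mass = mass, T_s = T_s,
                 friction_gamma = friction_gamma, cv = cv),
            class = "extended_variable")
}

#' Harmonic coupling energy and forces
#'
#' E = k/2 (cv - s)^2 with equal and opposite forces on the collective
#' variable and the extended variable.
#'
#' @param cv_value collective-variable value.
#' @param s extended-variable value.
#' @param k coupling constant (kJ/mol per unit^2).
#' @return list with \code{energy}, \code{force_cv}, \code{force_s}.
#' @export
coupling_energy_force <- function(cv_value, s, k) {
  d <- cv_value - s
  list(energy = 0.5 * k * d^2, force_cv = -k * d, force_s = k * d)
}

#' Attach a d-AFED extended variable to a system
#'
#' Augments the force evaluation with the harmonic coupling between the
#' selected gate coordinate and the extended variable s, which is then
#' evolved by Langevin dynamics at T_s each step.  The base system's own
#' energy terms are unchanged; with \code{coupling_k = 0} the dynamics of the
#' base system is recovered.
#'
#' @param system a [model_system()] containing at least one gated site.
#' @param cv_selector collective-variable id, \code{"gate:<site_id>"} (or
#'   just the site id of a gated site).
#' @param ev_params an [extended_variable()].
#' @return the augmented \code{model_system}.
#' @export
attach_dafed <- function(system, cv_selector, ev_params = extended_variable()) {
  stopifnot(inherits(system, "model_system"),
            inherits(ev_params, "extended_variable"))
  id <- sub("^gate:", "", cv_selector)
  gated <- which(vapply(system$sites, function(s)
    !inherits(s, "his_site_spec") && s$gate_height > 0, logical(1)))
  ids <- vapply(system$sites, function(s) s$site_id, character(1))
  hit <- which(ids == id)
  if (length(hit) != 1L || !(hit %in% gated))
    stop(sprintf("unknown or ungated collective variable '%s'", cv_selector))
  ev_params$cv <- paste0("gate:", id)
  # gate coordinates are laid out in site order; index among gated sites
  system$dafed <- c(ev_params,
                    list(gate_index = as.integer(match(hit, gated) - 1L)))
  system
}

#' Remove an attached d-AFED extended variable
#'
#' @param system a [model_system()].
#' @export
detach_dafed <- function(system) {
  system$dafed <- NULL
  system
}
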