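# Shared fixture builders.  All systems are generated in code; nothing is
# read from disk.

kB <- phafed::k_boltzmann

# single ungated acid with a symmetric (offset-free) environment coordinate
make_acid_system <- function(pH, site_class = "GLU", pKa_ref = NULL,
                             T_lambda = 750, m_lambda = 750,
                             barrier_height = 10, env_offset_dG = 0,
                             buffers = NULL, T_physical = 300) {
  model_system(
    site_spec("site1", site_class, pKa_ref = pKa_ref,
              T_lambda = T_lambda, m_lambda = m_lambda,
              barrier_height = barrier_height,
              env_offset_dG = env_offset_dG),
    envs = env_coordinate(mass = 10, curv_A = 100, curv_B = 100),
    buffers = buffers, T_physical = T_physical, pH = pH)
}

# gated "buried" site: closed gate applies the burial penalty to deprotonation
make_gated_system <- function(pH, gate_height = 40, burial_dG = 30,
                              T_lambda = 1500, m_lambda = 1500,
                              barrier_height = 22) {
  model_system(
    site_spec("asp_b", "ASP", T_lambda = T_lambda, m_lambda = m_lambda,
              barrier_height = barrier_height,
              env_offset_dG = burial_dG, gate_height = gate_height),
    pH = pH)
}

make_his_system <- function(pH, ...) {
  model_system(his_site_spec("his1", ...), pH = pH)
}

# random valid state for gradient checks
random_state <- function(system, seed) {
  set.seed(seed)
  fl <- phafed:::.flatten_system(system)
  st <- sim_state(system,
                  lambda = runif(length(fl$core$lam_mass), -0.2, 1.2))
  if (length(st$env)) st$env <- st$env + rnorm(length(st$env), 0, 0.3)
  if (length(st$gate)) st$gate <- runif(length(st$gate), -1.5, 1.5)
  st$s <- st$s + rnorm(1, 0, 0.5)
  st
}

# central finite-difference gradient of the total potential w.r.t. every
# coordinate; independent oracle for system_forces()
fd_forces <- function(state, system, h = 1e-6) {
  en <- function(st) interpolated_potential(st, system)$total
  num <- function(field, i) {
    sp <- state; sm <- state
    sp[[field]][i] <- sp[[field]][i] + h
    sm[[field]][i] <- sm[[field]][i] - h
    -(en(sp) - en(sm)) / (2 * h)
  }
  list(lambda = vapply(seq_along(state$lambda), function(i) num("lambda", i),
                       numeric(1)),
       env = if (length(state$env))
         vapply(seq_along(state$env), function(i) num("env", i), numeric(1))
       else numeric(0),
       gate = if (length(state$gate))
         vapply(seq_along(state$gate), function(i) num("gate", i), numeric(1))
       else numeric(0),
       s = { sp <- state; sm <- state
             sp$s <- sp$s + h; sm$s <- sm$s - h
             -(en(sp) - en(sm)) / (2 * h) })
}

# quadrature oracle for the true pKa: integrates exp(-V/kBT) over the
# environment (and gate) coordinate at lambda = 0 and lambda = 1
quadrature_pka <- function(spec, env = NULL, T = 300) {
  kT <- kB * T
  dG <- log(10) * kT * spec$pKa_ref     # pH-independent end-state difference
  if (!is.null(env)) {
    zA <- stats::integrate(function(r)
      exp(-(0.5 * env$curv_A * (r - env$min_A)^2) / kT), -10, 10,
      rel.tol = 1e-11)$value
    off <- if (spec$gate_height > 0) 0 else spec$env_offset_dG
    zB <- stats::integrate(function(r)
      exp(-(0.5 * env$curv_B * (r - env$min_B)^2 + off) / kT), -10, 10,
      rel.tol = 1e-11)$value
    dG <- dG - kT * (log(zB) - log(zA))
  } else if (spec$gate_height == 0 && spec$env_offset_dG != 0) {
    dG <- dG + spec$env_offset_dG
  }
  if (spec$gate_height > 0) {
    vg <- function(g) spec$gate_height * ((g / 0.5)^2 - 1)^2
    sw <- function(g) 0.5 * (1 - tanh(g / 0.2))
    z0 <- stats::integrate(function(g) exp(-vg(g) / kT), -4, 4,
                           rel.tol = 1e-11)$value
    z1 <- stats::integrate(function(g)
      exp(-(vg(g) + spec$env_offset_dG * sw(g)) / kT), -4, 4,
      rel.tol = 1e-11)$value
    dG <- dG - kT * log(z1 / z0)
  }
  dG / (kT * log(10))
}

# noiseless Henderson-Hasselbalch curve
hh_curve <- function(pH, pKa, n = 1) 1 / (1 + 10^(n * (pKa - pH)))
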