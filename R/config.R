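.config_keys <- c("schema_version", "mode", "ph_min", "ph_max", "ph_step",
                  "n_steps", "dt", "sample_stride", "replicates", "base_seed",
                  "output_dir", "T_physical", "preset", "sites", "dafed",
                  "m_lambda_standard")
.site_keys <- c("id", "class", "pKa_ref", "pKa_micro", "q_A", "q_B", "N_p",
                "T_lambda", "m_lambda", "barrier_height", "env_offset_dG",
                "gate_height", "env", "restraint")
.env_keys <- c("mass", "min_A", "curv_A", "min_B", "curv_B")
.dafed_keys <- c("cv", "coupling_k", "mass", "T_s", "friction_gamma")

#' Adiabatic parameter presets
#'
#' Returns the (T_lambda, m_lambda, barrier_height) preset for
#' solvent-exposed sites (750 K, 750, 10 kJ/mol) or buried sites
#' (1500 K, 1500, 22 kJ/mol).
#'
#' @param name \code{"surface"} or \code{"buried"}.
#' @export
adiabatic_preset <- function(name = c("surface", "buried")) {
  name <- match.arg(name)
  if (name == "surface")
    list(T_lambda = 750, m_lambda = 750, barrier_height = 10)
  else
    list(T_lambda = 1500, m_lambda = 1500, barrier_height = 22)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills documented defaults (pH grid 0-9 in
#' steps of 1, 3 replicates, 2e5 steps of 2 fs, stride 10) and validates
#' every invariant with an error naming the offending key.  Unknown keys are
#' rejected.
#'
#' @param path path to a YAML configuration file.
#' @return a validated object of class \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param raw named list with the same schema as the YAML file.
#' @rdname load_config
#' @export
as_run_config <- function(raw) {
  if (!is.list(raw)) stop("config must be a mapping")
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- list(schema_version = raw$schema_version %||% 1L,
              mode = raw$mode %||% "ph_afed",
              ph_min = raw$ph_min %||% 0, ph_max = raw$ph_max %||% 9,
              ph_step = raw$ph_step %||% 1,
              n_steps = as.integer(raw$n_steps %||% 200000L),
              dt = raw$dt %||% 0.002,
              sample_stride = as.integer(raw$sample_stride %||% 10L),
              replicates = as.integer(raw$replicates %||% 3L),
              base_seed = as.integer(raw$base_seed %||% 1L),
              output_dir = raw$output_dir %||% "runs",
              T_physical = raw$T_physical %||% 300,
              preset = raw$preset,
              m_lambda_standard = raw$m_lambda_standard %||% 5)
  if (!cfg$mode %in% c("ph_afed", "standard"))
    stop("mode: must be 'ph_afed' or 'standard'")
  if (cfg$ph_min > cfg$ph_max) stop("ph_min: must be <= ph_max")
  if (cfg$ph_step <= 0) stop("ph_step: must be > 0")
  if (cfg$replicates < 1) stop("replicates: must be >= 1")
  if (cfg$n_steps < 1) stop("n_steps: must be >= 1")
  if (cfg$dt <= 0) stop("dt: must be > 0")
  if (cfg$sample_stride < 1 || cfg$sample_stride > cfg$n_steps)
    stop("sample_stride: must be in [1, n_steps]")
  if (!is.null(cfg$preset) && !cfg$preset %in% c("surface", "buried"))
    stop("preset: must be 'surface' or 'buried'")
  if (is.null(raw$sites) || !length(raw$sites))
    stop("sites: at least one site required")
  preset <- if (!is.null(cfg$preset)) adiabatic_preset(cfg$preset) else NULL
  cfg$sites <- lapply(raw$sites, .validate_site, preset = preset)
  if (!is.null(raw$dafed)) {
    unknown <- setdiff(names(raw$dafed), .dafed_keys)
    if (length(unknown))
      stop(sprintf("unknown dafed key(s): %s", paste(unknown, collapse = ", ")))
    if (is.null(raw$dafed$cv)) stop("dafed.cv: required")
    cfg$dafed <- raw$dafed
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_site <- function(s, preset = NULL) {
  unknown <- setdiff(names(s), .site_keys)
  if (length(unknown))
    stop(sprintf("unknown site key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(s$id)) stop("site id: required")
  cls <- s$class %||% "GLU"
  if (!cls %in% c("GLU", "ASP", "HIS_TAUTOMER", "GENERIC", "HIS"))
    stop(sprintf("site %s: unknown class '%s'", s$id, cls))
  tl <- s$T_lambda %||% preset$T_lambda %||% 750
  ml <- s$m_lambda %||% preset$m_lambda %||% 750
  bh <- s$barrier_height %||% preset$barrier_height %||% 10
  if (tl <= 0) stop(sprintf("site %s: T_lambda must be > 0", s$id))
  if (ml <= 0) stop(sprintf("site %s: m_lambda must be > 0", s$id))
  if (bh < 0) stop(sprintf("site %s: barrier_height must be >= 0", s$id))
  s$class <- cls; s$T_lambda <- tl; s$m_lambda <- ml; s$barrier_height <- bh
  if (!is.null(s$env)) {
    unknown <- setdiff(names(s$env), .env_keys)
    if (length(unknown))
      stop(sprintf("site %s: unknown env key(s): %s", s$id,
                   paste(unknown, collapse = ", ")))
  }
  s
}

#' Save a run configuration as YAML
#'
#' @param config a \code{run_config}.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Instantiate the model system of a configuration at one pH
#'
#' @param config a \code{run_config}.
#' @param pH solution pH.
#' @return a [model_system()] (with d-AFED attached if configured).
#' @export
config_system <- function(config, pH) {
  stopifnot(inherits(config, "run_config"))
  sites <- list(); envs <- list()
  for (s in config$sites) {
    if (s$class == "HIS") {
      rp <- s$restraint
      restraint <- if (is.null(rp)) tanh_restraint_params() else
        tanh_restraint_params(rp$amplitude %||% 200, rp$flat_width %||% 0.2,
                              rp$switch_width %||% 0.05)
      sites[[length(sites) + 1L]] <- his_site_spec(
        s$id,
        pKa_micro = s$pKa_micro %||% unname(reference_pka[c("HIS_TAUTOMER",
                                                            "HIS_TAUTOMER2")]),
        restraint = restraint,
        T_lambda = s$T_lambda, m_lambda = s$m_lambda,
        barrier_height = s$barrier_height)
      envs[length(sites)] <- list(NULL)
    } else {
      sites[[length(sites) + 1L]] <- site_spec(
        s$id, site_class = s$class, pKa_ref = s$pKa_ref,
        q_A = s$q_A, q_B = s$q_B, N_p = s$N_p %||% 1L,
        T_lambda = s$T_lambda, m_lambda = s$m_lambda,
        barrier_height = s$barrier_height,
        env_offset_dG = s$env_offset_dG %||% 0,
        gate_height = s$gate_height %||% 0)
      envs[length(sites)] <- if (is.null(s$env)) list(NULL) else
        list(env_coordinate(s$env$mass %||% 10, s$env$min_A %||% 0,
                            s$env$curv_A %||% 100, s$env$min_B %||% 0,
                            s$env$curv_B %||% 100))
    }
  }
  if (all(vapply(envs, is.null, logical(1)))) envs <- NULL
  sys <- model_system(sites, envs = envs, T_physical = config$T_physical,
                      pH = pH)
  if (!is.null(config$dafed)) {
    d <- config$dafed
    sys <- attach_dafed(sys, d$cv,
                        extended_variable(d$coupling_k %||% 1000,
                                          d$mass %||% 20, d$T_s %||% 1000,
                                          d$friction_gamma %||% 5))
  }
  sys
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: mode = %s, pH %g..%g step %g, %d replicate(s), %d sites\n",
              x$mode, x$ph_min, x$ph_max, x$ph_step, x$replicates,
              length(x$sites)))
  invisible(x)
}
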