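test_that("pH potential vanishes in the protonated basin and equals the
          deprotonation free energy in the deprotonated basin", {
  expect_equal(v_ph(1, pH = 4.25, pKa_ref = 4.25, T = 300), 0)
  expect_equal(v_ph(0, pH = 9, pKa_ref = 4.25, T = 300), 0)
  # ln(10) * kB * 300 = 5.74277... kJ/mol
  expect_equal(v_ph(1, pH = 5.25, pKa_ref = 4.25, T = 300), -5.743,
               tolerance = 1e-4)
  # flat over both classification basins, midpoint at half the gap
  dg <- log(10) * kB * 300
  expect_equal(v_ph(c(0, 0.1, 0.2), 3.25, 4.25, 300), c(0, 0, 0))
  expect_equal(v_ph(c(0.8, 0.9, 1), 3.25, 4.25, 300), rep(dg, 3))
  expect_equal(v_ph(0.5, 3.25, 4.25, 300), dg / 2)
  expect_error(v_ph(NaN, 7, 4, 300), "non-finite")
  expect_error(v_ph(0.5, 7, 4, -1), "positive")
})

test_that("barrier potential has endpoint zeros, the configured maximum at
          the midpoint, and confines outside [0,1]", {
  expect_equal(v_barrier(c(0, 1), 10), c(0, 0))
  expect_equal(v_barrier(0.5, 10), 10)
  expect_equal(v_barrier(0.25, 10), 5.625)
  # grows monotonically outside the interval
  out <- v_barrier(seq(-1, -0.1, by = 0.1), 5)
  expect_true(all(diff(out) < 0))
  expect_error(v_barrier(0.5, -1), ">= 0")
})

test_that("tanh restraint is flat-bottomed, even, and saturates", {
  p <- tanh_restraint_params()
  expect_lt(v_tanh_restraint(c(0.5, 0.3, 0.2), p), 1e-3 * p$amplitude)
  d <- 0.31
  expect_equal(v_tanh_restraint(c(1 + d, 0, 0), p),
               v_tanh_restraint(c(1 - d, 0, 0), p))
  far <- 1 + p$flat_width + 10 * p$switch_width
  expect_lt(abs(v_tanh_restraint(c(far, 0, 0), p) - p$amplitude),
            1e-4 * p$amplitude)
  expect_error(v_tanh_restraint(c(0.5, 0.5), p), "3 lambda")
})

test_that("interpolated potential reduces to the pure end-state environment
          energy at lambda = 0 and 1", {
  sys <- model_system(site_spec("g", "GLU", env_offset_dG = 7),
                      envs = env_coordinate(mass = 10, min_A = -0.4,
                                            curv_A = 80, min_B = 0.6,
                                            curv_B = 140),
                      buffers = buffer_set(0), pH = 4.25)
  env <- sys$envs[[1]]
  r <- 0.37
  va <- 0.5 * env$curv_A * (r - env$min_A)^2
  vb <- 0.5 * env$curv_B * (r - env$min_B)^2 + 7
  st <- sim_state(sys, lambda = 0)
  st$env <- r
  expect_equal(unname(interpolated_potential(st, sys)$terms["env"]), va)
  st$lambda <- 1
  expect_equal(unname(interpolated_potential(st, sys)$terms["env"]), vb)
})

test_that("with identical end-state wells the environment term is
          lambda-independent", {
  sys <- model_system(site_spec("g", "GLU"), envs = env_coordinate(),
                      buffers = buffer_set(0), pH = 3)
  st <- sim_state(sys, lambda = 0.5)
  st$env <- 0.3
  e1 <- interpolated_potential(st, sys)$terms["env"]
  st$lambda <- 0.12
  e2 <- interpolated_potential(st, sys)$terms["env"]
  expect_equal(e1, e2)
  # and the lambda force there is purely pH + barrier
  st$lambda <- 0.5
  f <- system_forces(st, sys)
  dg <- log(10) * kB * 300 * (4.25 - 3)
  # smoothstep derivative at the midpoint is 30/16 / 0.6
  expect_equal(f$lambda[1], -dg * (30 / 16) / 0.6, tolerance = 1e-12)
})

test_that("analytic forces match central finite differences on random
          states of acid, His and gated systems", {
  systems <- list(
    model_system(site_spec("g", "GLU", env_offset_dG = 4),
                 envs = env_coordinate(min_B = 0.5, curv_B = 150),
                 pH = 5),
    make_his_system(pH = 6.4),
    attach_dafed(make_gated_system(pH = 4), "gate:asp_b"))
  for (sys in systems) {
    for (seed in 1:15) {
      st <- random_state(sys, seed)
      # keep clear of the non-smooth points of |sum(lambda)-1| and the
      # classification thresholds
      st$lambda <- st$lambda + 0.013
      fa <- system_forces(st, sys)
      fn <- fd_forces(st, sys)
      scale <- max(1, abs(unlist(fa)))
      expect_equal(fa$lambda, fn$lambda, tolerance = 1e-6 * scale)
      expect_equal(fa$env, fn$env, tolerance = 1e-6 * scale)
      expect_equal(fa$gate, fn$gate, tolerance = 1e-6 * scale)
      expect_equal(fa$s, fn$s, tolerance = 1e-6 * scale)
    }
  }
})

test_that("true pKa matches the quadrature oracle and known closed forms", {
  # identity: no environment perturbation
  s0 <- site_spec("a", "GLU")
  expect_equal(analytic_pka(s0, env_coordinate(), T = 300), 4.25)
  # +1 pKa unit for ddG = ln(10) kB 300
  s1 <- site_spec("b", "GLU", env_offset_dG = 5.7434)
  expect_equal(analytic_pka(s1, env_coordinate(), T = 300), 4.25 + 1.000,
               tolerance = 1e-4)
  # curvature ratio 4 -> entropic shift ln(4) / (2 ln 10) ~ +0.301
  s2 <- site_spec("c", "GLU")
  e2 <- env_coordinate(curv_A = 50, curv_B = 200)
  expect_equal(analytic_pka(s2, e2, T = 300) - 4.25, log(4) / (2 * log(10)),
               tolerance = 1e-12)
  expect_error(analytic_pka(s2, env_coordinate(curv_A = -1)), "positive")
  # quadrature oracle agreement to 1e-3 pKa units, incl. offset + curvature
  cases <- list(
    list(spec = site_spec("d", "ASP", env_offset_dG = 3),
         env = env_coordinate(min_B = 0.4, curv_B = 260)),
    list(spec = site_spec("e", "GLU", env_offset_dG = -6),
         env = env_coordinate(curv_A = 120, curv_B = 40)),
    list(spec = site_spec("f", "ASP", env_offset_dG = 30, gate_height = 40),
         env = NULL))
  for (cs in cases) {
    expect_equal(analytic_pka(cs$spec, cs$env, T = 300),
                 quadrature_pka(cs$spec, cs$env, T = 300), tolerance = 1e-3)
  }
})

test_that("site and system constructors enforce their invariants", {
  expect_error(site_spec("x", "GENERIC"), "pKa_ref")
  expect_error(site_spec("x", "GLU", m_lambda = 0), "m_lambda")
  expect_error(site_spec("x", "GLU", T_lambda = -5), "T_lambda")
  expect_error(site_spec("x", "GLU", barrier_height = -1), "barrier")
  expect_error(his_site_spec("h", pKa_micro = c(1, Inf)), "finite")
  expect_error(env_coordinate(curv_A = 0), "curvatures")
  expect_error(buffer_set(-1), "count")
  expect_error(model_system(list(site_spec("a"), site_spec("a"))), "unique")
  # default buffer count: 10 per titratable site
  sys <- model_system(list(site_spec("a"), site_spec("b", "ASP")), pH = 4)
  expect_equal(sum(vapply(sys$buffers, function(b) b$count, integer(1))), 20L)
  # His macroscopic midpoint: K_macro = K1 + K2
  expect_equal(his_macroscopic_pka(his_site_spec("h")),
               -log10(10^-6.53 + 10^-6.92))
})
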