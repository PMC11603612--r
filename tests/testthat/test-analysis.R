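test_that("frame classification partitions the series at the 0.2/0.8
          thresholds", {
  expect_equal(classify_frames(c(0.1, 0.5, 0.9, 0.95, 0.05)),
               c(n_prot = 2L, n_deprot = 2L, n_mixed = 1L))
  expect_equal(classify_frames(rep(0.5, 7)),
               c(n_prot = 0L, n_deprot = 0L, n_mixed = 7L))
  # threshold insensitivity away from the boundaries
  x <- c(0.05, 0.1, 0.15, 0.5, 0.85, 0.9)
  expect_equal(classify_frames(x, 0.2, 0.8), classify_frames(x, 0.19, 0.81))
  expect_error(classify_frames(numeric(0)), "empty")
  expect_error(classify_frames(0.5, lo = 0.8, hi = 0.2), "lo")
})

test_that("tempered reweighting maps the count ratio with exponent
          T_lambda / T", {
  # identity at equal temperatures
  rw <- reweight_fraction(300, 700, 300, 300)
  expect_equal(rw$fraction, 0.7)
  expect_false(rw$one_sided)
  # r = 4, exponent 2.5 -> 4^2.5 = 32 -> 32/33
  rw2 <- reweight_fraction(200, 800, 750, 300)
  expect_equal(rw2$fraction, 32 / 33, tolerance = 1e-12)
  # equal counts stay at one half for any temperature ratio
  expect_equal(reweight_fraction(55, 55, 1500, 300)$fraction, 0.5)
  # one-sided cases pin to 0/1 with a flag
  expect_equal(reweight_fraction(100, 0, 750, 300),
               list(fraction = 0, one_sided = TRUE))
  expect_equal(reweight_fraction(0, 10, 750, 300),
               list(fraction = 1, one_sided = TRUE))
  expect_error(reweight_fraction(0, 0, 750, 300), "no classified")
  # monotone in the ratio for any temperature ratio
  f <- vapply(c(1, 2, 5, 20), function(nd)
    reweight_fraction(10, nd, 1500, 300)$fraction, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("His deprotonated fraction pools the neutral tautomers", {
  expect_equal(his_deprot_fraction(200, 150, 50, 300, 300)$fraction, 0.5)
  expect_equal(his_deprot_fraction(10, 0, 0, 750, 300)$fraction, 0)
  expect_equal(his_deprot_fraction(100, 300, 100, 300, 300)$fraction, 0.8)
  expect_error(his_deprot_fraction(0, 0, 0, 750, 300), "no classified")
})

test_that("free energy profile recovers a known quadratic and scales
          linearly in T_lambda", {
  set.seed(4)
  a <- 200; Tl <- 750
  # direct draws from exp(-a x^2 / kB Tl): Gaussian with sd
  # sqrt(kB Tl / (2 a))
  x <- rnorm(5e5, 0, sqrt(kB * Tl / (2 * a)))
  fp <- free_energy_profile(x, Tl, n_bins = 31, range = c(-0.4, 0.4))
  keep <- is.finite(fp$F) & fp$count > 2000
  ref <- a * fp$lambda[keep]^2
  ref <- ref - min(ref)
  expect_lt(max(abs(fp$F[keep] - min(fp$F[keep]) - ref)) / max(ref), 0.05)
  # doubling T_lambda doubles F pointwise on the same samples
  fp2 <- free_energy_profile(x, 2 * Tl, n_bins = 31, range = c(-0.4, 0.4))
  expect_equal(fp2$F[keep], 2 * fp$F[keep], tolerance = 1e-12)
  # flat profile for uniform samples
  u <- runif(2e5)
  fpu <- free_energy_profile(u, 300, n_bins = 10)
  expect_lt(max(fpu$F, na.rm = TRUE), 0.1)
  # empty bins are NA, not zero
  fpe <- free_energy_profile(c(rep(0.1, 100), rep(0.9, 100)), 300,
                             n_bins = 8)
  expect_true(anyNA(fpe$F))
})

test_that("free energy profile re-exponentiated at T reproduces the
          tempered basin fractions", {
  set.seed(8)
  Tl <- 750; Tp <- 300
  lam <- c(rnorm(7000, 0.02, 0.06), rnorm(3000, 0.98, 0.06))
  cf <- classify_frames(lam)
  rw <- reweight_fraction(cf[["n_prot"]], cf[["n_deprot"]], Tl, Tp)
  # bins aligned with the classification thresholds; recover the basin
  # probabilities from F at T_lambda, then temper the basin ratio to T
  fp <- free_energy_profile(lam, Tl, n_bins = 150, range = c(-0.25, 1.25))
  p <- exp(-fp$F / (kB * Tl))
  p[!is.finite(p)] <- 0
  pd <- sum(p[fp$lambda > 0.8]); pp <- sum(p[fp$lambda < 0.2])
  r <- (pd / pp)^(Tl / Tp)
  expect_equal(r / (1 + r), rw$fraction, tolerance = 1e-6)
})

test_that("cumulative ionization energy series follows
          -kB T log(deprot/prot) and flags undefined prefixes", {
  s <- c(0.1, 0.1, 0.9, 0.9)
  ie <- ionization_energy_series(s, T = 300)
  expect_true(all(is.na(ie$dG[1:2])))       # no deprotonated frames yet
  expect_equal(ie$dG[4], 0)                 # equal cumulative counts
  s2 <- c(0.1, rep(0.9, 10))
  ie2 <- ionization_energy_series(s2, T = 300)
  expect_equal(ie2$dG[11], -kB * 300 * log(10), tolerance = 1e-12)
  expect_error(ionization_energy_series(c(0.1), T = 300, stride = 5),
               "shorter")
})

test_that("Henderson-Hasselbalch fit inverts noiseless generating models
          exactly", {
  ph <- 2:7
  f1 <- fit_hh(data.frame(pH = ph, fraction = hh_curve(ph, 4.25)))
  expect_equal(f1$pKa, 4.25, tolerance = 1e-6)
  expect_equal(f1$hill_n, 1, tolerance = 1e-6)
  expect_true(f1$converged)
  expect_length(f1$flags, 0)
  f2 <- fit_hh(data.frame(pH = ph, fraction = hh_curve(ph, 4.6, 0.8)))
  expect_equal(f2$pKa, 4.6, tolerance = 1e-5)
  expect_equal(f2$hill_n, 0.8, tolerance = 1e-5)
})

test_that("Henderson-Hasselbalch fit flags degenerate and thin data", {
  ph <- 2:7
  fd <- fit_hh(data.frame(pH = ph, fraction = rep(0, 6)))
  expect_true("no_fit" %in% fd$flags)
  expect_false(fd$converged)
  fl <- fit_hh(data.frame(pH = c(4, 5), fraction = c(0.3, 0.7)))
  expect_true("low_confidence" %in% fl$flags)
})

test_that("Henderson-Hasselbalch estimator is accurate and nearly unbiased
          under fraction noise", {
  set.seed(123)
  ph <- 2:7
  err <- replicate(100, {
    f <- hh_curve(ph, 4.25) + rnorm(6, 0, 0.02)
    fit <- fit_hh(data.frame(pH = ph, fraction = pmin(pmax(f, 0), 1)))
    fit$pKa - 4.25
  })
  expect_lt(abs(stats::median(err)), 0.05)
  expect_lt(abs(mean(err)), 0.05)
})

test_that("coupled two-site model recovers independent sites and obeys its
          limits", {
  ph <- seq(1, 8, by = 0.5)
  p1 <- data.frame(pH = ph, fraction = hh_curve(ph, 3))
  p2 <- data.frame(pH = ph, fraction = hh_curve(ph, 5))
  fit <- fit_coupled(p1, p2)
  # algebra oracle: the binding polynomial of independent sites
  # (1 + k1 x)(1 + k2 x) has stepwise constants K1 = k1 + k2,
  # K2 = k1 k2 / (k1 + k2)
  k1 <- 10^-3; k2 <- 10^-5
  expect_equal(fit$pKa, c(-log10(k1 + k2), -log10(k1 * k2 / (k1 + k2))),
               tolerance = 1e-3)
  # identical sites with pKa 4: <P> = 1 at pH 4
  P <- function(pH, pK1, pK2) {
    x <- 10^(-pH); K1 <- 10^(-pK1); K2 <- 10^(-pK2)
    (2 * x^2 + K1 * x) / (x^2 + K1 * x + K1 * K2)
  }
  expect_equal(P(4, 4, 4), 1)
  expect_equal(P(-30, 3, 5), 2, tolerance = 1e-6)
  expect_equal(P(30, 3, 5), 0, tolerance = 1e-6)
  expect_error(fit_coupled(p1, p2[-1, ]), "grid")
})

test_that("prediction metrics reproduce the published benchmark table", {
  tab <- hewl_pka_benchmark()
  expect_equal(nrow(tab), 10L)
  # agreement with the published metrics at their printed precision
  m1 <- prediction_metrics(tab$ph_afed, tab$experimental)
  expect_lt(abs(m1$MUE - 0.60), 0.0051)
  expect_lt(abs(m1$RMSE - 0.68), 0.0051)
  m2 <- prediction_metrics(tab$standard_10ns, tab$experimental)
  expect_lt(abs(m2$MUE - 0.96), 0.0051)
  expect_lt(abs(m2$RMSE - 1.24), 0.0051)
  m3 <- prediction_metrics(tab$standard_50ns, tab$experimental)
  expect_lt(abs(m3$MUE - 0.74), 0.0051)
  expect_lt(abs(m3$RMSE - 1.00), 0.0051)
  mi <- prediction_metrics(tab$experimental, tab$experimental)
  expect_equal(mi$MUE, 0)
  expect_equal(mi$RMSE, 0)
  expect_equal(mi$r, 1)
  mz <- prediction_metrics(rep(1, 3), c(1, 2, 3))
  expect_true(is.na(mz$r))
  expect_true("r_undefined" %in% mz$flags)
  expect_error(prediction_metrics(1:3, 1:2), "equal length")
})

test_that("trajectory-to-pKa pipeline recovers a known pKa from synthetic
          tempered two-state trajectories", {
  # draw lambda series directly from the T_lambda-tempered two-state
  # distribution at known pKa, then push them through the full pipeline
  pka_true <- 4.25; Tl <- 750; Tp <- 300
  make_traj <- function(pH, seed) {
    set.seed(seed)
    # basin probability at T_lambda for a flat-basin (step) pH potential
    dg_T <- log(10) * kB * Tp * (pka_true - pH)
    p_dep <- stats::plogis(-dg_T / (kB * Tl))
    n <- 4000
    basin <- stats::rbinom(n, 1, p_dep)
    lam <- ifelse(basin == 1, stats::runif(n, 0.85, 1.0),
                  stats::runif(n, 0.0, 0.15))
    structure(list(step = seq_len(n), time_ps = seq_len(n) * 0.02,
                   lambda = matrix(lam, ncol = 1,
                                   dimnames = list(NULL, "s1")),
                   temps = NULL, energies = NULL,
                   metadata = list(pH = pH, seed = seed, mode = "ph_afed",
                                   T_physical = Tp, dt = 0.002,
                                   sample_stride = 10L, n_steps = n * 10L,
                                   sites = "s1", lambda_T = Tl,
                                   lam_site = 1L)),
              class = "lambda_trajectory")
  }
  trajs <- list(); k <- 0
  for (pH in 2:7) for (r in 1:3) {
    k <- k + 1
    trajs[[k]] <- make_traj(pH, seed = 100 * pH + r)
  }
  res <- pka_from_trajectories(trajs, "s1", T = Tp)
  expect_equal(res$pKa_mean, pka_true, tolerance = 0.05)
  expect_equal(nrow(res$titration), 6L)
  # identical replicates give zero spread
  trajs2 <- list(make_traj(3, 7), make_traj(3, 7),
                 make_traj(4, 8), make_traj(4, 8),
                 make_traj(5, 9), make_traj(5, 9))
  res2 <- pka_from_trajectories(trajs2, "s1", T = Tp)
  expect_equal(res2$pKa_sd, 0)
})
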