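# Induction-repair kinetics: closed forms, fitting, dose-response curves.

wi38 <- cell_line_defaults("WI38")
hbec <- cell_line_defaults("HBEC3KT")

test_that("steady state of the induction-repair balance is kappa*Ddot/lambda", {
  set.seed(11)
  for (i in 1:20) {
    p <- kinetics_params(kappa = runif(1, 1, 60), t_half = runif(1, 0.5, 8),
                         background = runif(1, 0, 2))
    dr <- runif(1, 0.001, 1)
    lambda <- log(2) / p$t_half
    nss <- foci_timecourse(p, dr, 1e5)
    expect_equal(nss, p$background + p$kappa * dr / lambda, tolerance = 1e-12)
    # zero dose rate stays at background; small-t limit is linear induction
    expect_equal(foci_timecourse(p, 0, c(0, 5, 24)), rep(p$background, 3))
    t_small <- 0.009 / lambda
    expect_equal(foci_timecourse(p, dr, t_small) - p$background,
                 p$kappa * dr * t_small, tolerance = 0.01)
  }
  expect_error(foci_timecourse(wi38$params, 0.1, -1), "non-negative")
  expect_error(foci_timecourse(wi38$params, -0.1, 1), "non-negative")
})

test_that("closed-form timecourse matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  p <- kinetics_params(kappa = 32.2, t_half = 2.11, background = 0.5)
  lambda <- log(2) / p$t_half
  dr <- 7.286 / 24
  sol <- deSolve::ode(y = c(N = p$background), times = seq(0, 24, by = 0.5),
                      func = function(t, y, parms)
                        list(p$kappa * dr - lambda * (y - p$background)),
                      parms = NULL, method = "ode45", rtol = 1e-10,
                      atol = 1e-12)
  expect_equal(unname(sol[, "N"]),
               foci_timecourse(p, dr, seq(0, 24, by = 0.5)),
               tolerance = 1e-8)
})

test_that("repair decay halves the above-background signal at t_half", {
  p <- kinetics_params(kappa = 30, t_half = 3.29, background = 0.7)
  expect_equal(repair_decay(p, 25, 0), 25)
  expect_equal(repair_decay(p, 25, 3.29), 0.7 + (25 - 0.7) / 2)
  expect_equal(repair_decay(p, 25, 1e6), 0.7)
})

test_that("half-time fitting recovers noise-free truth almost exactly and
           errors on underdetermined input", {
  times <- c(0.5, 1, 2, 4, 8, 24)
  p <- kinetics_params(kappa = 32.2, t_half = 2.11, background = 0.5)
  y <- repair_decay(p, p$background + p$kappa, times)
  fit <- fit_repair_halftime(times, y, background = p$background)
  expect_equal(fit$t_half, 2.11, tolerance = 1e-6)
  expect_error(fit_repair_halftime(c(1, 1), c(5, 5)), "3 distinct")
  expect_warning(fit_repair_halftime(c(1, 2, 4, 8), c(1, 2, 3, 4),
                                     background = 0), "increase")
})

test_that("seeded Poisson time-courses recover both half-times within the
           95% CI in most replicates", {
  for (def in list(wi38, hbec)) {
    truth <- def$params$t_half
    cover <- 0; est <- numeric(30)
    for (r in 1:30) {
      tc <- simulate_repair_timecourse(def$params, seed = 100 + r)
      f <- fit_repair_halftime(tc$time_h, tc$mean_foci,
                               weights = tc$n / pmax(tc$sd_foci^2, 0.1),
                               background = def$params$background)
      est[r] <- f$t_half
      if (truth >= f$ci95[1] && truth <= f$ci95[2]) cover <- cover + 1
    }
    expect_gte(cover / 30, 0.8)
    expect_lt(abs(median(est) - truth) / truth, 0.05)
  }
})

test_that("dose-response prediction reduces to the uniform curve when the
           heterogeneity knobs are off and covers the packaged ladder", {
  def0 <- wi38
  def0$params$protective_factor <- 1
  def0$params$bystander_plateau <- 0
  up <- predict_dose_response(def0, condition = "uniform")
  pp <- predict_dose_response(def0, condition = "particle")
  expect_equal(up$mean_foci, pp$mean_foci)
  expect_equal(up$cumulative_dose,
               c(0.001, 0.005, 0.010, 0.051, 0.096, 0.444, 1.005, 7.286))
  expect_equal(nrow(up), 8L)
  # uniform curve passes through the chronic calibration anchor
  expect_equal(up$mean_foci[up$cumulative_dose == 7.286],
               wi38$calibration$uniform_chronic$mean)
  # bystander on: particle curve strictly above uniform below the threshold
  pb <- predict_dose_response(wi38, condition = "particle")
  ub <- predict_dose_response(wi38, condition = "uniform")
  low <- pb$cumulative_dose < wi38$params$bystander_threshold_Gy
  expect_true(all(pb$mean_foci[low] > ub$mean_foci[low]))
})

test_that("crossover dose detection interpolates a single crossing and
           rejects coincident curves", {
  d <- c(0.001, 0.01, 0.1, 1)
  cu <- data.frame(cumulative_dose = d, mean_foci = c(1, 1, 2, 11),
                   condition = "uniform")
  cp <- data.frame(cumulative_dose = d, mean_foci = c(2, 1.5, 1.8, 10),
                   condition = "particle")
  x <- find_crossover_dose(cp, cu)
  expect_gt(x, 0.001); expect_lt(x, 0.1)
  expect_error(find_crossover_dose(cu, cu), "coincide")
  cpp <- cu; cpp$mean_foci <- cu$mean_foci + 1
  expect_error(find_crossover_dose(cpp, cu), "do not cross")
})
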