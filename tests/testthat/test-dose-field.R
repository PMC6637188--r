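# Dose-field engine: gamma kernel identities, beta MC invariants, landmarks.

small_geom <- source_geometry(radial_edges_um = seq(0, 3000, by = 100))

test_that("gamma kernel reduces to the inverse-square law with attenuation
           and buildup off", {
  g <- source_geometry(radial_edges_um = seq(0, 5000, by = 250))
  prof <- gamma_dose_analytic(hp_source, gamma_only_specs(), g, db = hp_db,
                              attenuation = FALSE, buildup = FALSE)
  e <- g$radial_edges_um
  rc <- (e[-1] + e[-length(e)]) / 2
  d2 <- rc^2 + (g$source_center[3] - g$scoring_top_um / 2)^2
  prod <- prof$dose_rate_gamma * d2
  expect_lt(max(abs(prod / prod[1] - 1)), 1e-10)
  expect_equal(prof$dose_rate_gamma[1] / prof$dose_rate_gamma[
    which.min(abs(d2 - 4 * d2[1]))], 4, tolerance = 0.02)
})

test_that("gamma kernel matches an independently coded evaluation", {
  g <- source_geometry()
  specs <- gamma_only_specs()
  prof <- gamma_dose_analytic(hp_source, specs, g, db = hp_db)
  # independent evaluation at bin 33 (r = 1625 um)
  rc <- 1625
  target <- c(rc, 0, g$scoring_top_um / 2)
  d_m <- sqrt(sum((target - g$source_center)^2)) * 1e-6
  rate <- sum(hp_source$activities) * 0.851
  E <- 661.66
  segs <- slant_path(g$source_center, target, g)
  tau <- 0; lw <- 0
  for (i in seq_len(nrow(segs))) {
    m <- segs$material[i]; len_cm <- segs$length_um[i] * 1e-4
    rho <- hp_db$materials[[m]]$density
    tau <- tau + hotparticle:::photon_coeff(hp_db, m, E) * rho * len_cm
    if (m == "water") lw <- lw + len_cm
  }
  muw <- hotparticle:::photon_coeff(hp_db, "water", E) *
    hp_db$materials$water$density
  B <- buildup_factor(hp_db, muw * lw)
  muen <- hotparticle:::photon_coeff(hp_db, "water", E, "mu_en_over_rho") * 0.1
  expected <- rate * E * 1.602176634e-16 * muen * B * exp(-tau) /
    (4 * pi * d_m^2) * 86400
  expect_equal(prof$dose_rate_gamma[33], expected, tolerance = 1e-10)
})

test_that("buildup factor tends to one in the thin-path limit", {
  expect_lt(abs(buildup_factor(hp_db, 0.01) - 1), 0.011)
  expect_equal(buildup_factor(hp_db, 0), 1)
})

test_that("beta dose vanishes beyond the maximum water-equivalent CSDA
           range while gamma does not", {
  g <- source_geometry(radial_edges_um = seq(0, 8000, by = 200))
  b <- beta_dose_mc(hp_source, hp_specs, g, 5e4, seed = 2, db = hp_db)
  gm <- gamma_dose_analytic(hp_source, hp_specs, g, db = hp_db)
  e <- g$radial_edges_um
  rc <- (e[-1] + e[-length(e)]) / 2
  rmax <- water_csda_range(hp_db, 1175.6)   # hardest electron, um
  far <- rc > rmax
  expect_true(any(far))
  expect_true(all(b$dose_rate_beta[far] == 0))
  expect_true(all(gm$dose_rate_gamma[far] > 0))
})

test_that("beta MC is reproducible, conserves energy, and its SE scales
           like 1/sqrt(n)", {
  b1 <- beta_dose_mc(hp_source, hp_specs, small_geom, 3e4, seed = 5,
                     db = hp_db)
  b2 <- beta_dose_mc(hp_source, hp_specs, small_geom, 3e4, seed = 5,
                     db = hp_db)
  expect_identical(b1$dose_rate_beta, b2$dose_rate_beta)
  expect_identical(b1$se_beta, b2$se_beta)
  expect_lte(b1$provenance$scored_keV, b1$provenance$emitted_keV)
  expect_error(beta_dose_mc(hp_source, hp_specs, small_geom, 100), "1e4")

  b4 <- beta_dose_mc(hp_source, hp_specs, small_geom, 1.2e5, seed = 5,
                     db = hp_db)
  busy <- b1$se_beta > 0 & b4$se_beta > 0 & b1$dose_rate_beta > 0
  ratio <- median(b4$se_beta[busy] / b1$se_beta[busy])
  expect_gt(ratio, 0.5 * 0.8)   # ~1/2 within 20%
  expect_lt(ratio, 0.5 * 1.2)
})

test_that("total profile is the elementwise sum and symmetric", {
  b <- beta_dose_mc(hp_source, hp_specs, small_geom, 2e4, seed = 1,
                    db = hp_db)
  gm <- gamma_dose_analytic(hp_source, hp_specs, small_geom, db = hp_db)
  tot <- total_profile(b, gm)
  expect_equal(tot$dose_rate_total, b$dose_rate_beta + gm$dose_rate_gamma)
  tot2 <- total_profile(gm, b)
  expect_equal(tot2$dose_rate_total, tot$dose_rate_total)
  nb <- length(b$dose_rate_beta)
  zero <- hotparticle:::new_dose_profile(small_geom, numeric(nb), numeric(nb))
  expect_equal(total_profile(b, zero)$dose_rate_total, b$dose_rate_total)
})

test_that("crossover detection interpolates, detects monotone shifts, and
           rejects degenerate inputs", {
  g <- source_geometry(radial_edges_um = seq(0, 1000, by = 100))
  mk <- function(beta, gamma) {
    p <- hotparticle:::new_dose_profile(g, beta, gamma)
    p$se_beta <- 0.01 * pmax(beta, 1e-6)
    p
  }
  rc <- seq(50, 950, by = 100) / 1000
  beta <- exp(-5 * rc); gamma <- rep(exp(-5 * 0.45), 10)
  p <- mk(beta, gamma)
  expect_equal(find_crossover(p, smooth = FALSE), 0.45, tolerance = 0.01)
  # scaling gamma up moves the crossover inward
  p10 <- mk(beta, gamma * 3)
  expect_lt(find_crossover(p10, smooth = FALSE),
            find_crossover(p, smooth = FALSE))
  # identical curves: no unique crossing
  expect_error(find_crossover(mk(beta, beta), smooth = FALSE), "crossover|crossings")
  expect_error(find_crossover(mk(gamma, gamma * 0.5), smooth = FALSE),
               "no beta/gamma crossover")
  # smoothed estimator agrees with the raw one on a clean profile
  g2 <- source_geometry(radial_edges_um = seq(0, 3000, by = 50))
  rc2 <- (g2$radial_edges_um[-1] + g2$radial_edges_um[-61]) / 2 / 1000
  p2 <- hotparticle:::new_dose_profile(g2, exp(-4 * rc2), rep(exp(-4 * 1.2), 60))
  p2$se_beta <- 0.01 * p2$dose_rate_beta
  expect_equal(find_crossover(p2), 1.2, tolerance = 0.03)
})

test_that("cumulative dose is linear in duration", {
  gm <- gamma_dose_analytic(hp_source, hp_specs, small_geom, db = hp_db)
  expect_equal(cumulative_dose(gm, 24), gm$dose_rate_total)
  expect_equal(cumulative_dose(gm, 48), 2 * cumulative_dose(gm, 24))
  expect_equal(cumulative_dose(gm, 0), rep(0, length(gm$dose_rate_total)))
  expect_error(cumulative_dose(gm, -1))
})

test_that("density sensitivity is zero at the reference and grows
           monotonically as density decreases", {
  ds <- density_sensitivity(hp_source, hp_specs, small_geom,
                            densities = c(2.2, 1.6, 1.0),
                            n_histories = 3e4, seed = 3, db = hp_db)
  expect_equal(unname(ds[["2.2"]]), 0)
  expect_lt(ds[["1.6"]], ds[["1.0"]])
  expect_error(density_sensitivity(hp_source, hp_specs, small_geom,
                                   densities = -1, n_histories = 3e4,
                                   db = hp_db), "positive")
})

test_that("dose profile round-trips through CSV with provenance sidecar", {
  gm <- gamma_dose_analytic(hp_source, hp_specs, small_geom, db = hp_db)
  f <- tempfile(fileext = ".csv")
  write_dose_profile(gm, f)
  back <- read.csv(f)
  expect_equal(back$dose_gamma_Gy_day, gm$dose_rate_gamma)
  expect_true(file.exists(paste0(f, ".json")))
})
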