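test_that("packaged inventory has the expected structure and key lines", {
  expect_named(hp_specs, c("Cs137", "Cs134"))
  cs137 <- hp_specs$Cs137
  g662 <- cs137$lines[cs137$lines$kind == "gamma" &
                      abs(cs137$lines$energy_keV - 661.66) < 1, ]
  expect_equal(nrow(g662), 1L)
  expect_equal(g662$yield, 0.851, tolerance = 0.01)
  cs134g <- hp_specs$Cs134$lines[hp_specs$Cs134$lines$kind == "gamma", ]
  expect_true(any(abs(cs134g$energy_keV - 605) < 5))
  expect_true(any(abs(cs134g$energy_keV - 796) < 5))
  # all packaged yields clear the documented 0.01 cutoff
  for (sp in hp_specs) {
    expect_true(all(sp$lines$yield >= 0.01))
    expect_true(all(sp$beta_branches$intensity >= 0.01))
  }
})

test_that("invalid nuclide configs are rejected with informative errors", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("nuclides:",
               "  X:",
               "    daughter_Z: 56",
               "    lines:",
               "      - {kind: gamma, energy_keV: 600, yield: -0.1}"), bad)
  expect_error(load_nuclide_data(bad), "non-negative")
  writeLines(c("nuclides:",
               "  X:",
               "    daughter_Z: 56",
               "    beta_branches:",
               "      - {endpoint_keV: -5, intensity: 0.5}"), bad)
  expect_error(load_nuclide_data(bad), "positive")
  expect_error(load_nuclide_data(tempfile()), "not found")
})

test_that("source activity bookkeeping matches the configured table", {
  expect_equal(sum(hp_source$activities), 507.7)
  frac <- hp_source$activities[["Cs134"]] / sum(hp_source$activities)
  expect_equal(frac * 100, 7.6, tolerance = 0.05)
  expect_error(source_activity(c(A = -1)), "non-negative")
  expect_error(source_activity(numeric(0)), "named")
})

test_that("beta spectrum density is normalized, vanishes at the endpoint,
           and has a physically sensible mean", {
  for (Q in c(511.6, 1175.6, 658.1)) {
    br <- list(endpoint_keV = Q)
    expect_equal(beta_pdf(br, Q), 0)
    expect_equal(beta_pdf(br, Q + 10), 0)
    expect_equal(beta_pdf(br, -1), 0)
    nrm <- stats::integrate(function(E) beta_pdf(br, E), 0, Q,
                            rel.tol = 1e-9, subdivisions = 400L)$value
    expect_equal(nrm, 1, tolerance = 1e-6)
  }
  # mean of the Q = 511.6 keV, Z = 56 branch between 0.30 and 0.40 Q
  br <- list(endpoint_keV = 511.6)
  mn <- stats::integrate(function(E) E * beta_pdf(br, E), 0, 511.6,
                         rel.tol = 1e-9, subdivisions = 400L)$value
  expect_gt(mn / 511.6, 0.30)
  expect_lt(mn / 511.6, 0.40)
})

test_that("emission sampling follows activities, yields and the beta shape", {
  set.seed(42)
  # single-nuclide source never yields the other nuclide's lines
  src137 <- source_activity(c(Cs137 = 469.2))
  draws <- sample_emission(src137, hp_specs, 1e4)
  expect_true(all(draws$nuclide == "Cs137"))
  expect_true(all(draws$energy_keV > 0))

  # activity split: fraction of Cs134 draws ~ 38.5 / 507.7 scaled by the
  # per-decay multiplicities used in sampling
  set.seed(43)
  n <- 2e5
  all_draws <- sample_emission(hp_source, hp_specs, n)
  tab <- hotparticle:::emission_table(hp_source, hp_specs, "all")
  p134 <- sum(tab$rate[tab$nuclide == "Cs134"]) / sum(tab$rate)
  obs <- mean(all_draws$nuclide == "Cs134")
  expect_lt(abs(obs - p134), 3 * sqrt(p134 * (1 - p134) / n))

  # beta sampler energies never reach the kinematic limits
  set.seed(44)
  b <- sample_emission(src137, hp_specs, 5e4, kind = "electron")
  bb <- b$energy_keV[!b$energy_keV %in% c(624.2, 655.7)]
  expect_true(all(bb > 0 & bb < 1175.6))

  # goodness of fit of sampled betas against the spectrum shape
  set.seed(45)
  src_one <- source_activity(c(B = 1))
  spec_one <- list(B = make_spec("B", beta = data.frame(endpoint_keV = 511.6,
                                                        intensity = 1)))
  x <- sample_emission(src_one, spec_one, 5e4)$energy_keV
  br <- list(endpoint_keV = 511.6)
  edges <- seq(0, 511.6, length.out = 51)
  p_bin <- vapply(seq_len(50), function(i)
    stats::integrate(function(E) beta_pdf(br, E), edges[i], edges[i + 1],
                     rel.tol = 1e-8)$value, numeric(1))
  obs <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), 50)
  gof <- suppressWarnings(stats::chisq.test(obs, p = p_bin / sum(p_bin)))
  expect_gt(gof$p.value, 0.01)

  expect_error(sample_emission(source_activity(c(Cs137 = 469.2)),
                               hp_specs, 10, kind = "gamma"), NA)
})

test_that("per-decay emitted energy is stable across seeds", {
  e_tot <- vapply(1:3, function(s) {
    set.seed(s)
    d <- sample_emission(hp_source, hp_specs, 5e4)
    mean(d$energy_keV)
  }, numeric(1))
  expect_lt(max(e_tot) - min(e_tot), 0.03 * mean(e_tot))
})
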