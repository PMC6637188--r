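# Shared fixtures: packaged data loaded once, tiny synthetic sources, and
# an independent quadrature oracle for the studentized-range CDF.

hp_db <- load_material_data()
hp_specs <- load_nuclide_data()
hp_source <- load_source_activity()

# single-emission synthetic nuclides for targeted transport tests
make_spec <- function(key, beta = NULL, lines = NULL, Z = 56L) {
  s <- list(name = key, key = key, daughter_Z = Z, includes_daughter = FALSE,
            beta_branches = if (is.null(beta))
              data.frame(endpoint_keV = numeric(), intensity = numeric())
            else beta,
            lines = if (is.null(lines))
              data.frame(kind = character(), energy_keV = numeric(),
                         yield = numeric())
            else lines)
  class(s) <- "NuclideSpec"
  s
}

# both source nuclides emit the same single gamma line, so the combined
# line rate is simply total activity x yield
gamma_only_specs <- function(energy_keV = 661.66, yield = 0.851) {
  ln <- data.frame(kind = "gamma", energy_keV = energy_keV, yield = yield)
  list(Cs137 = make_spec("Cs137", lines = ln),
       Cs134 = make_spec("Cs134", lines = ln))
}

# Independent studentized-range CDF: P(Q <= q) for k groups, df degrees of
# freedom, by direct double quadrature (normal-range probability integrated
# against the scaled-chi density of the pooled SD). Used only as a
# cross-check oracle for tukey_kramer()'s p-values.
ptukey_quadrature <- function(q, k, df) {
  range_cdf <- function(w) {   # P(range of k std normals <= w)
    vapply(w, function(wi) {
      if (wi <= 0) return(0)
      stats::integrate(function(z)
        k * stats::dnorm(z) * (stats::pnorm(z + wi) - stats::pnorm(z))^(k - 1),
        -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  # s = pooled SD / sigma has density of chi_df / sqrt(df)
  dens_s <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  stats::integrate(function(s) dens_s(s) * range_cdf(q * s), 0, Inf,
                   rel.tol = 1e-8)$value
}

# match segmented nuclei back to the generator's nuclei by centroid
match_nuclei <- function(seg, image) {
  vapply(seq_len(nrow(seg$table)), function(i) {
    d2 <- (image$nuclei$cx - seg$table$cx[i])^2 +
      (image$nuclei$cy - seg$table$cy[i])^2
    image$nuclei$id[which.min(d2)]
  }, integer(1))
}
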