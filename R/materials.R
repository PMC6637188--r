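#' Load material property tables
#'
#' Bundles densities, per-material stopping-power ratios, the water collision
#' stopping-power table, photon attenuation / energy-absorption coefficient
#' tables and Berger buildup coefficients into one object used by the dose
#' engine. All tables are packaged plain-text compilations of standard
#' reference values.
#'
#' @param materials_path,stopping_path,photon_path Optional overrides for the
#'   packaged config files.
#' @return A `MaterialDB` list with `materials` (per-material density and
#'   stopping ratio), `sp_water` (stopping power table), `range_water`
#'   (CSDA range table, integrated from `sp_water`), `photon` (coefficient
#'   table) and `buildup` coefficients.
#' @export
load_material_data <- function(materials_path = hp_extdata("materials.yaml"),
                               stopping_path = hp_extdata("stopping_power_water.csv"),
                               photon_path = hp_extdata("photon_coefficients.csv"),
                               kernel_path = hp_extdata("electron_point_kernel.csv")) {
  cfg <- yaml::read_yaml(materials_path)
  mats <- lapply(cfg$materials, function(m) {
    if (m$density <= 0) stop("material density must be positive")
    list(density = m$density, stopping_ratio = m$stopping_ratio)
  })
  sp <- read.csv(stopping_path, comment.char = "#")
  if (any(sp$S_MeV_cm2_g <= 0)) stop("stopping powers must be positive")
  ph <- read.csv(photon_path, comment.char = "#")
  if (any(ph$mu_over_rho <= 0) || any(ph$mu_en_over_rho <= 0))
    stop("photon coefficients must be positive")
  db <- list(materials = mats,
             sp_water = sp,
             range_water = csda_range_table(sp),
             photon = ph,
             buildup = cfg$buildup,
             kernel = load_point_kernel(kernel_path))
  class(db) <- "MaterialDB"
  db
}

# Scaled electron dose point kernel j(u; E0) (see
# scripts/derive_point_kernel.R). Stored as the cumulative fraction of E0
# deposited within scaled radius u, one row per tabulated energy.
load_point_kernel <- function(path) {
  k <- read.csv(path, comment.char = "#")
  energies <- sort(unique(k$E0_keV))
  du <- diff(sort(unique(k$u_mid)))[1]
  u_edges <- seq(0, 1, by = du)
  Jmat <- t(vapply(energies, function(E) {
    j <- k$j[k$E0_keV == E][order(k$u_mid[k$E0_keV == E])]
    cs <- cumsum(j) * du
    c(0, cs / cs[length(cs)])   # renormalize to exactly 1 at u = 1
  }, numeric(length(u_edges))))
  list(E_keV = energies, u_edges = u_edges, J = Jmat)
}

# Cumulative kernel J(u; E0): fraction of the initial energy deposited
# within scaled depth u. Bilinear interpolation (log-energy x u); energies
# outside the tabulated interval use the nearest row.
kernel_cum <- function(db, E0_keV, u) {
  kr <- db$kernel
  nE <- length(kr$E_keV)
  u <- pmin(pmax(u, 0), 1)
  iE <- pmin(pmax(findInterval(E0_keV, kr$E_keV), 1L), nE - 1L)
  le <- log(kr$E_keV)
  wE <- pmin(pmax((log(E0_keV) - le[iE]) / (le[iE + 1] - le[iE]), 0), 1)
  nu <- length(kr$u_edges)
  pos <- u / kr$u_edges[2]
  iu <- pmin(floor(pos) + 1L, nu - 1L)
  wu <- pos - (iu - 1L)
  jlo <- kr$J[cbind(iE, iu)] * (1 - wu) + kr$J[cbind(iE, iu + 1L)] * wu
  jhi <- kr$J[cbind(iE + 1L, iu)] * (1 - wu) + kr$J[cbind(iE + 1L, iu + 1L)] * wu
  (1 - wE) * jlo + wE * jhi
}

# CSDA range in water by trapezoidal integration of 1/S(E) on a fine
# log-spaced grid from the 1 keV transport cutoff. Units: E keV, range um
# (water at unit density; 1 g/cm^2 = 1 cm).
csda_range_table <- function(sp, E_cut = 1, n_grid = 2000L) {
  E <- exp(seq(log(E_cut), log(max(sp$E_keV)), length.out = n_grid))
  S <- exp(stats::approx(log(sp$E_keV), log(sp$S_MeV_cm2_g), xout = log(E),
                         rule = 2)$y)          # MeV cm^2/g
  invS_um <- 1 / (S * 1000 / 1e4)              # keV/um -> um per keV
  r <- c(0, cumsum((invS_um[-1] + invS_um[-n_grid]) / 2 * diff(E)))
  list(E_keV = E, range_um = r)
}

# Water CSDA range (um) at kinetic energy E_keV; below the cutoff the range
# is zero (local deposition).
water_csda_range <- function(db, E_keV) {
  t <- db$range_water
  r <- stats::approx(t$E_keV, t$range_um, xout = pmin(E_keV, max(t$E_keV)),
                     rule = 2)$y
  r[E_keV <= min(t$E_keV)] <- 0
  r
}

# Inverse: kinetic energy (keV) of an electron with residual water range um.
water_energy_from_range <- function(db, range_um) {
  t <- db$range_water
  E <- stats::approx(t$range_um, t$E_keV, xout = pmax(range_um, 0), rule = 2)$y
  E[range_um <= 0] <- 0
  E
}

# Log-log interpolation of photon coefficients for one material.
photon_coeff <- function(db, material, E_keV,
                         which = c("mu_over_rho", "mu_en_over_rho")) {
  which <- match.arg(which)
  t <- db$photon[db$photon$material == material, ]
  if (nrow(t) == 0) stop("no photon coefficients for material '", material, "'")
  if (any(E_keV < min(t$E_keV) | E_keV > max(t$E_keV)))
    stop("photon energy ", paste(E_keV[E_keV < min(t$E_keV) | E_keV > max(t$E_keV)],
                                 collapse = ", "),
         " keV outside tabulated interval for '", material, "'")
  exp(stats::approx(log(t$E_keV), log(t[[which]]), xout = log(E_keV))$y)
}

#' Berger buildup factor
#'
#' `B(x) = 1 + a * x * exp(b * x)` with `x = mu * r` the attenuation optical
#' depth; coefficients come from the material database (water only; other
#' path segments are short enough that buildup is neglected).
#'
#' @param db A `MaterialDB`.
#' @param mu_r Optical depth (dimensionless).
#' @export
buildup_factor <- function(db, mu_r) {
  a <- db$buildup$water$a
  b <- db$buildup$water$b
  1 + a * mu_r * exp(b * mu_r)
}
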