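#' Load nuclide emission inventories
#'
#' Reads the packaged (or a user-supplied) YAML table of decay emissions and
#' returns one `NuclideSpec` per radionuclide. The Cs-137 entry folds its
#' short-lived Ba-137m daughter (secular equilibrium): the 662 keV gamma,
#' Ba K X-rays and the K/L internal-conversion electrons appear with yields
#' per Cs-137 decay. Emissions with per-decay yield below 0.01 are not
#' carried in the packaged table.
#'
#' @param config_path Path to a nuclide YAML file; default is the packaged
#'   inventory.
#' @return A named list of `NuclideSpec` objects, each with elements
#'   `name`, `daughter_Z`, `includes_daughter`, `beta_branches` (data frame
#'   with `endpoint_keV`, `intensity`) and `lines` (data frame with `kind`,
#'   `energy_keV`, `yield`).
#' @export
load_nuclide_data <- function(config_path = hp_extdata("nuclides.yaml")) {
  if (!file.exists(config_path)) stop("nuclide config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$nuclides) || length(cfg$nuclides) == 0)
    stop("nuclide config has no 'nuclides' section")
  specs <- lapply(names(cfg$nuclides), function(nm) {
    nd <- cfg$nuclides[[nm]]
    bb <- do.call(rbind, lapply(nd$beta_branches, function(b)
      data.frame(endpoint_keV = as.numeric(b$endpoint_keV),
                 intensity = as.numeric(b$intensity))))
    if (is.null(bb)) bb <- data.frame(endpoint_keV = numeric(), intensity = numeric())
    ln <- do.call(rbind, lapply(nd$lines, function(l)
      data.frame(kind = as.character(l$kind),
                 energy_keV = as.numeric(l$energy_keV),
                 yield = as.numeric(l$yield))))
    if (is.null(ln))
      ln <- data.frame(kind = character(), energy_keV = numeric(), yield = numeric())
    spec <- list(name = if (!is.null(nd$name)) nd$name else nm,
                 key = nm,
                 daughter_Z = as.integer(nd$daughter_Z),
                 includes_daughter = isTRUE(nd$includes_daughter),
                 beta_branches = bb,
                 lines = ln)
    class(spec) <- "NuclideSpec"
    validate_nuclide_spec(spec)
    spec
  })
  names(specs) <- names(cfg$nuclides)
  specs
}

validate_nuclide_spec <- function(spec) {
  bb <- spec$beta_branches; ln <- spec$lines
  if (nrow(bb) + nrow(ln) == 0)
    stop("nuclide '", spec$key, "' has no emissions")
  if (nrow(bb)) {
    if (any(!is.finite(bb$endpoint_keV)) || any(bb$endpoint_keV <= 0))
      stop("nuclide '", spec$key, "': beta endpoint energies must be positive")
    if (any(!is.finite(bb$intensity)) || any(bb$intensity <= 0) || any(bb$intensity > 1))
      stop("nuclide '", spec$key, "': beta intensities must be in (0, 1]")
  }
  if (nrow(ln)) {
    if (!all(ln$kind %in% c("gamma", "electron")))
      stop("nuclide '", spec$key, "': line kind must be 'gamma' or 'electron'")
    if (any(!is.finite(ln$energy_keV)) || any(ln$energy_keV <= 0))
      stop("nuclide '", spec$key, "': line energies must be positive")
    if (any(!is.finite(ln$yield)) || any(ln$yield < 0))
      stop("nuclide '", spec$key, "': line yields must be non-negative")
  }
  invisible(spec)
}

#' Source activity of the particle
#'
#' @param config_path Nuclide YAML file; the `source` block carries the
#'   per-nuclide activities (Bq).
#' @return A `SourceActivity` list: `activities` (named numeric, Bq),
#'   `reference_note`, `total` (Bq; the configured override if present, else
#'   the sum of entries).
#' @export
load_source_activity <- function(config_path = hp_extdata("nuclides.yaml")) {
  cfg <- yaml::read_yaml(config_path)
  acts <- unlist(cfg$source$activities_Bq)
  if (is.null(acts) || length(acts) == 0) stop("source activities missing from config")
  if (any(acts < 0)) stop("activities must be non-negative")
  if (sum(acts) <= 0) stop("total activity must be positive")
  ov <- cfg$source$total_activity_override
  structure(list(activities = acts,
                 reference_note = cfg$source$reference_note,
                 total = if (is.null(ov)) sum(acts) else as.numeric(ov)),
            class = "SourceActivity")
}

#' Construct a source activity object directly
#'
#' @param activities Named numeric vector of activities in Bq.
#' @param reference_note Free-text provenance note.
#' @export
source_activity <- function(activities, reference_note = "") {
  if (length(activities) == 0 || is.null(names(activities)))
    stop("activities must be a named numeric vector")
  if (any(activities < 0) || sum(activities) <= 0)
    stop("activities must be non-negative with positive total")
  structure(list(activities = activities, reference_note = reference_note,
                 total = sum(activities)), class = "SourceActivity")
}

# ---- allowed beta spectrum shape ------------------------------------------

ELECTRON_MC2_KEV <- 510.99895
FINE_STRUCTURE <- 1 / 137.035999

# Non-relativistic Fermi (Coulomb) correction F(Z, E): eta = alpha*Z*W/p with
# W, p the total energy and momentum in mc^2 units.
fermi_function <- function(Z, E_keV) {
  W <- 1 + E_keV / ELECTRON_MC2_KEV
  p <- sqrt(pmax(W^2 - 1, .Machine$double.eps))
  eta <- FINE_STRUCTURE * Z * W / p
  x <- 2 * pi * eta
  x / (1 - exp(-x))
}

#' Allowed beta spectrum density
#'
#' Energy density of an allowed beta branch,
#' `N(E) = C * F(Z, E) * p * W * (Q - E)^2` for `0 < E < Q`, normalized so it
#' integrates to one over `(0, Q)`. `F` is the non-relativistic Fermi
#' Coulomb correction. Returns 0 outside the kinematic interval.
#'
#' @param branch A list/row with `endpoint_keV` (and optionally `daughter_Z`).
#' @param E_keV Kinetic energies (keV) at which to evaluate the density.
#' @param daughter_Z Atomic number of the daughter nucleus (default 56, Ba).
#' @return Probability density per keV (numeric, same length as `E_keV`).
#' @export
beta_pdf <- function(branch, E_keV, daughter_Z = 56L) {
  Q <- if (is.list(branch) || is.data.frame(branch)) branch$endpoint_keV else branch
  if (!is.null(branch$daughter_Z)) daughter_Z <- branch$daughter_Z
  stopifnot(is.finite(Q), Q > 0)
  norm <- beta_norm_constant(Q, daughter_Z)
  dens <- numeric(length(E_keV))
  inside <- E_keV > 0 & E_keV < Q
  if (any(inside)) {
    E <- E_keV[inside]
    W <- 1 + E / ELECTRON_MC2_KEV
    p <- sqrt(W^2 - 1)
    dens[inside] <- fermi_function(daughter_Z, E) * p * W * (Q - E)^2 / norm
  }
  dens
}

# Normalization integral of the unnormalized allowed shape over (0, Q),
# cached per (Q, Z).
beta_norm_cache <- new.env(parent = emptyenv())
beta_norm_constant <- function(Q, Z) {
  key <- sprintf("%.6g_%d", Q, as.integer(Z))
  if (!is.null(beta_norm_cache[[key]])) return(beta_norm_cache[[key]])
  f <- function(E) {
    W <- 1 + E / ELECTRON_MC2_KEV
    p <- sqrt(pmax(W^2 - 1, 0))
    fermi_function(Z, E) * p * W * (Q - E)^2
  }
  val <- stats::integrate(f, 0, Q, rel.tol = 1e-10, subdivisions = 500L)$value
  beta_norm_cache[[key]] <- val
  val
}

# Inverse-CDF table for one beta branch on a fine energy grid.
beta_sampler_table <- function(Q, Z, n_grid = 4096L) {
  E <- seq(0, Q, length.out = n_grid)
  d <- beta_pdf(list(endpoint_keV = Q), E, daughter_Z = Z)
  # trapezoid CDF
  dx <- diff(E)
  cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  list(E = E, cdf = cdf)
}

sample_beta_energy <- function(tab, n) {
  u <- runif(n)
  stats::approx(tab$cdf, tab$E, xout = u, ties = "ordered")$y
}

# Flat emission table across nuclides: one row per emission with absolute
# emission rate (per second) given the source activities.
emission_table <- function(source, specs, kind = c("all", "electron", "gamma")) {
  kind <- match.arg(kind)
  rows <- list()
  for (nm in names(source$activities)) {
    if (is.null(specs[[nm]]))
      stop("no NuclideSpec for source nuclide '", nm, "'")
    A <- source$activities[[nm]]
    sp <- specs[[nm]]
    if (nrow(sp$beta_branches) && kind != "gamma") {
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = nm, kind = "beta", energy_keV = NA_real_,
        endpoint_keV = sp$beta_branches$endpoint_keV,
        daughter_Z = sp$daughter_Z,
        yield = sp$beta_branches$intensity,
        rate = A * sp$beta_branches$intensity)
    }
    ln <- sp$lines
    if (kind == "electron") ln <- ln[ln$kind == "electron", , drop = FALSE]
    if (kind == "gamma") ln <- ln[ln$kind == "gamma", , drop = FALSE]
    if (nrow(ln)) {
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = nm, kind = ln$kind, energy_keV = ln$energy_keV,
        endpoint_keV = NA_real_, daughter_Z = sp$daughter_Z,
        yield = ln$yield, rate = A * ln$yield)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Sample emissions from the particle source
#'
#' Draws `n` emissions: the nuclide is chosen proportionally to activity,
#' the emission proportionally to its per-decay yield; beta energies are
#' drawn from the allowed spectrum shape by inverse-CDF lookup. The returned
#' `weight` is the total number of emissions per decay of the sampled
#' nuclide (so unweighted tallies normalized by `n` estimate per-emission
#' quantities, and `rate` totals convert them to per-second).
#'
#' @param source A `SourceActivity`.
#' @param specs Output of [load_nuclide_data()].
#' @param n Number of emissions to draw.
#' @param kind Restrict to `"electron"` (betas plus conversion electrons),
#'   `"gamma"`, or `"all"`.
#' @return A data frame with `nuclide`, `kind`, `energy_keV`, `weight`.
#' @export
sample_emission <- function(source, specs, n, kind = c("all", "electron", "gamma")) {
  kind <- match.arg(kind)
  tab <- emission_table(source, specs, kind)
  if (is.null(tab) || nrow(tab) == 0 || sum(tab$rate) <= 0)
    stop("source has no emissions to sample")
  idx <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$rate)
  E <- tab$energy_keV[idx]
  isb <- tab$kind[idx] == "beta"
  if (any(isb)) {
    branches <- unique(idx[isb])
    for (b in branches) {
      sel <- idx == b & isb
      stab <- beta_sampler_table(tab$endpoint_keV[b], tab$daughter_Z[b])
      E[sel] <- sample_beta_energy(stab, sum(sel))
    }
  }
  # per-decay emission multiplicity of each nuclide (within requested kind)
  mult <- tapply(tab$yield, tab$nuclide, sum)
  data.frame(nuclide = tab$nuclide[idx],
             kind = ifelse(isb, "electron", tab$kind[idx]),
             energy_keV = E,
             weight = as.numeric(mult[tab$nuclide[idx]]))
}
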