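# Synthetic cell populations: monolayers on glass-base dishes with
# per-nucleus gamma-H2AX focus counts drawn from a calibrated overdispersed
# (negative binomial) count model under particle, uniform, acute or
# half-field exposure.

#' Dish layout for a synthetic monolayer
#'
#' @param dish_radius_mm Dish radius (6 for the phi-12 mm dish, 13.5 for the
#'   phi-27 mm dish).
#' @param n_cells Number of cells.
#' @param placement `"uniform"` random placement or a square `"grid"`.
#' @param tip_jitter_sd_um SD of the capillary tip position on the dish
#'   surface (applies to the particle condition only).
#' @export
dish_layout <- function(dish_radius_mm = 6, n_cells = 500,
                        placement = c("uniform", "grid"),
                        tip_jitter_sd_um = 69.6) {
  placement <- match.arg(placement)
  stopifnot(dish_radius_mm > 0, n_cells >= 1, tip_jitter_sd_um >= 0)
  structure(list(dish_radius_mm = dish_radius_mm, n_cells = n_cells,
                 placement = placement, tip_jitter_sd_um = tip_jitter_sd_um),
            class = "DishLayout")
}

#' Negative-binomial parameters from a printed mean and SD
#'
#' Moment matching: `size = mean^2 / (sd^2 - mean)`, `mu = mean`. When the
#' variance does not exceed the mean the model falls back to Poisson (with a
#' warning if the sample is strictly underdispersed).
#'
#' @param mean,sd Target mean and standard deviation.
#' @return List with `distribution` (`"nb"` or `"poisson"`), `mu`, `size`.
#' @export
nb_from_mean_sd <- function(mean, sd) {
  stopifnot(mean >= 0, sd >= 0)
  v <- sd^2
  if (v > mean) {
    list(distribution = "nb", mu = mean, size = mean^2 / (v - mean))
  } else {
    if (v < mean)
      warning("sd^2 < mean: underdispersed target, falling back to Poisson")
    list(distribution = "poisson", mu = mean, size = Inf)
  }
}

draw_counts <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

place_cells <- function(layout) {
  R <- layout$dish_radius_mm * 1000
  n <- layout$n_cells
  if (layout$placement == "uniform") {
    r <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    data.frame(x_um = r * cos(th), y_um = r * sin(th))
  } else {
    k <- ceiling(sqrt(n * 4 / pi))
    g <- seq(-R, R, length.out = k)
    gr <- expand.grid(x_um = g, y_um = g)
    gr <- gr[gr$x_um^2 + gr$y_um^2 <= R^2, ]
    if (nrow(gr) < n) stop("grid too coarse for n_cells")
    gr[seq_len(n), ]
  }
}

#' Generate a synthetic exposed cell population
#'
#' Places cells on the dish, assigns each a cumulative dose according to the
#' exposure condition, predicts the expected focus count from the
#' calibrated kinetics, and draws per-nucleus counts from the
#' negative-binomial count model.
#'
#' Conditions:
#' * `"particle"` — chronic exposure to the particle dose field; requires
#'   `profile`. Cells are zoned `beta_dominant` / `gamma_dominant` by the
#'   `boundary_mm` radius (measured from the jittered tip position) and
#'   cells under the capillary footprint (`exclude_um`) are flagged
#'   excluded. The in-field yield is scaled by the protective factor and
#'   the bystander plateau applies below the dose threshold.
#' * `"uniform"` — chronic uniform field at `dose_rate_Gy_day` for
#'   `duration_h`.
#' * `"uniform_acute"` — acute uniform dose `dose_Gy` scored 30 min later
#'   (the full-field reference of the half-field experiment).
#' * `"half_field"` — acute `dose_Gy` to the in-field half of the dish.
#'   Exactly `floor(n/2)` cells are in-field: cells are ranked by x and the
#'   largest-x half is exposed (documented tie rule).
#'
#' @param layout A [dish_layout()].
#' @param condition Exposure condition (see Details).
#' @param defaults Output of [cell_line_defaults()].
#' @param profile A `DoseProfile` (particle condition).
#' @param dose_rate_Gy_day Uniform chronic dose rate.
#' @param duration_h Chronic exposure duration (h).
#' @param dose_Gy Acute dose for `uniform_acute` / `half_field`.
#' @param boundary_mm Beta-dominant zone boundary (default 1.65 mm).
#' @param exclude_um Capillary footprint radius; closer cells are flagged.
#' @param seed RNG seed.
#' @return Data frame of `CellRecord`s: `id`, `x_um`, `y_um`, `radial_mm`,
#'   `zone`, `cumulative_dose_Gy`, `true_foci`, `detected_foci` (NA until
#'   imaging), `excluded`.
#' @export
generate_population <- function(layout, condition = c("particle", "uniform",
                                                      "uniform_acute", "half_field"),
                                defaults,
                                profile = NULL,
                                dose_rate_Gy_day = NULL, duration_h = 24,
                                dose_Gy = 1,
                                boundary_mm = 1.65, exclude_um = 50,
                                seed = 1L) {
  condition <- match.arg(condition)
  set.seed(seed)
  p <- defaults$params
  pos <- place_cells(layout)
  n <- nrow(pos)
  bg <- p$background

  if (condition == "particle") {
    if (is.null(profile)) stop("particle condition requires a dose profile")
    tip <- rnorm(2, 0, layout$tip_jitter_sd_um)
    r_um <- sqrt((pos$x_um - tip[1])^2 + (pos$y_um - tip[2])^2)
    D <- dose_rate_at(profile, r_um) * (duration_h / 24)
    s <- condition_slope(defaults, "particle")
    mu <- bg + p$protective_factor * s * D +
      ifelse(D < p$bystander_threshold_Gy, p$bystander_plateau, 0)
    zone <- ifelse(r_um / 1000 < boundary_mm, "beta_dominant", "gamma_dominant")
    excluded <- r_um < exclude_um
    anchor <- defaults$calibration$uniform_chronic
  } else if (condition == "uniform") {
    if (is.null(dose_rate_Gy_day)) stop("uniform condition requires dose_rate_Gy_day")
    r_um <- sqrt(pos$x_um^2 + pos$y_um^2)
    D <- rep(dose_rate_Gy_day * (duration_h / 24), n)
    mu <- bg + condition_slope(defaults, "uniform") * D
    zone <- rep("uniform", n)
    excluded <- rep(FALSE, n)
    anchor <- defaults$calibration$uniform_chronic
  } else if (condition == "uniform_acute") {
    r_um <- sqrt(pos$x_um^2 + pos$y_um^2)
    D <- rep(dose_Gy, n)
    mu <- bg + condition_slope(defaults, "uniform_acute") * D
    zone <- rep("uniform", n)
    excluded <- rep(FALSE, n)
    anchor <- defaults$calibration$acute_full
  } else { # half_field
    r_um <- sqrt(pos$x_um^2 + pos$y_um^2)
    n_in <- floor(n / 2)
    in_field <- rank(pos$x_um, ties.method = "first") > n - n_in
    D <- ifelse(in_field, dose_Gy, 0)
    mu <- ifelse(in_field,
                 bg + condition_slope(defaults, "half_field") * D,
                 bg)
    zone <- ifelse(in_field, "in_field", "out_of_field")
    excluded <- rep(FALSE, n)
    anchor <- defaults$calibration$acute_half_in
  }

  # NB dispersion anchored to the condition calibration; background-only
  # cells use the background anchor
  nbp <- nb_from_mean_sd(anchor$mean, anchor$sd)
  nbbg <- nb_from_mean_sd(bg, defaults$background_sd)
  size <- ifelse(mu > bg + 1e-9, nbp$size, nbbg$size)
  true_foci <- integer(n)
  for (sz in unique(size)) {
    sel <- size == sz
    true_foci[sel] <- draw_counts(sum(sel), mu[sel], sz)
  }

  data.frame(id = seq_len(n), x_um = pos$x_um, y_um = pos$y_um,
             radial_mm = r_um / 1000, zone = zone,
             cumulative_dose_Gy = D, true_foci = true_foci,
             detected_foci = NA_integer_, excluded = excluded)
}

#' Zero-dose control population
#'
#' Convenience wrapper: background-only counts for a cell line.
#'
#' @inheritParams generate_population
#' @export
generate_control <- function(layout, defaults, seed = 1L) {
  set.seed(seed)
  pos <- place_cells(layout)
  n <- nrow(pos)
  nbbg <- nb_from_mean_sd(defaults$params$background, defaults$background_sd)
  data.frame(id = seq_len(n), x_um = pos$x_um, y_um = pos$y_um,
             radial_mm = sqrt(pos$x_um^2 + pos$y_um^2) / 1000,
             zone = "control", cumulative_dose_Gy = 0,
             true_foci = draw_counts(n, nbbg$mu, nbbg$size),
             detected_foci = NA_integer_, excluded = FALSE)
}
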