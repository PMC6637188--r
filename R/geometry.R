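#' Particle / capillary / dish scene
#'
#' Geometry of the exposure scene: an SiO2 microsphere (the Cs-bearing
#' particle) held at height `source_center[3]` above a glass-base dish
#' inside the closed air-filled tip of a capillary, with the cell monolayer
#' scored as a thin water slab at the dish surface. The capillary is
#' modelled as its closed tip only: a conformal SiO2 shell of thickness
#' `tip_wall_um` around the particle plus a vertical air column of radius
#' `tip_inner_radius_um` connecting the tip to the dish surface; the rest of
#' the dish volume is culture medium (water).
#'
#' @param particle_radius_um Sphere radius (default 135.5, i.e. 271.0 um
#'   diameter).
#' @param particle_density Sphere density in g/cm^3 (default 2.2, SiO2).
#' @param source_center Sphere centre (x, y, z) in um; default
#'   `c(0, 0, 635.5)`.
#' @param tip_wall_um SiO2 tip wall thickness (um).
#' @param tip_inner_radius_um Air column radius (um; 20 um inner diameter).
#' @param dish_depth_um Depth of culture medium above the dish surface (um).
#' @param scoring_top_um Top of the scoring water slab (um); the slab is
#'   `z` in `[0, scoring_top_um]`, a cell-monolayer-equivalent layer.
#' @param radial_edges_um Strictly increasing annulus bin edges on the dish
#'   plane (um).
#' @return A `SourceGeometry` list.
#' @export
source_geometry <- function(particle_radius_um = 135.5,
                            particle_density = 2.2,
                            source_center = c(0, 0, 635.5),
                            tip_wall_um = 10,
                            tip_inner_radius_um = 10,
                            dish_depth_um = 2000,
                            scoring_top_um = 10,
                            radial_edges_um = seq(0, 5000, by = 50)) {
  stopifnot(particle_radius_um > 0, particle_density > 0,
            length(source_center) == 3, tip_wall_um >= 0,
            tip_inner_radius_um > 0, dish_depth_um > 0, scoring_top_um > 0)
  if (any(diff(radial_edges_um) <= 0))
    stop("radial bin edges must be strictly increasing")
  if (source_center[3] - particle_radius_um - tip_wall_um <= scoring_top_um)
    stop("particle (plus tip wall) must sit above the scoring layer")
  if (source_center[3] > dish_depth_um)
    stop("source must lie inside the medium column")
  structure(list(particle_radius_um = particle_radius_um,
                 particle_density = particle_density,
                 source_center = source_center,
                 tip_wall_um = tip_wall_um,
                 tip_inner_radius_um = tip_inner_radius_um,
                 dish_depth_um = dish_depth_um,
                 scoring_top_um = scoring_top_um,
                 radial_edges_um = radial_edges_um),
            class = "SourceGeometry")
}

#' Trace a ray through the scene
#'
#' Splits the straight segment from `source_point` to `target_point` into
#' material segments (particle SiO2, tip-wall SiO2, capillary air, medium
#' water, dish glass). Segment lengths sum to the Euclidean distance.
#'
#' @param source_point,target_point Points (x, y, z) in um.
#' @param geom A [source_geometry()].
#' @return Data frame with columns `material` and `length_um`, ordered from
#'   source to target; zero-length segments are dropped.
#' @export
slant_path <- function(source_point, target_point, geom) {
  d3 <- target_point - source_point
  L <- sqrt(sum(d3^2))
  if (L <= 0) stop("degenerate zero-length ray")
  u <- d3 / L
  cen <- geom$source_center
  a <- geom$particle_radius_um
  aw <- a + geom$tip_wall_um

  brk <- c(0, L)
  sph_roots <- function(radius) {
    oc <- source_point - cen
    B <- sum(u * oc); C <- sum(oc^2) - radius^2
    disc <- B^2 - C
    if (disc <= 0) return(numeric())
    c(-B - sqrt(disc), -B + sqrt(disc))
  }
  brk <- c(brk, sph_roots(a), sph_roots(aw))
  # vertical air-column wall (cylinder about the z axis)
  A <- u[1]^2 + u[2]^2
  if (A > 1e-12) {
    B <- source_point[1] * u[1] + source_point[2] * u[2]
    C <- source_point[1]^2 + source_point[2]^2 - geom$tip_inner_radius_um^2
    disc <- B^2 - A * C
    if (disc > 0) brk <- c(brk, (-B - sqrt(disc)) / A, (-B + sqrt(disc)) / A)
  }
  # horizontal interfaces
  if (abs(u[3]) > 1e-12) {
    for (zp in c(0, geom$scoring_top_um, cen[3], geom$dish_depth_um))
      brk <- c(brk, (zp - source_point[3]) / u[3])
  }
  brk <- sort(unique(pmin(pmax(brk, 0), L)))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  lens <- diff(brk)
  classify <- function(t) {
    p <- source_point + t * u
    r2c <- sum((p - cen)^2)
    if (r2c <= a^2) return("SiO2")
    if (r2c <= aw^2) return("SiO2")
    if (p[3] < 0) return("glass")
    if (p[3] > geom$dish_depth_um) return("air")
    if (p[1]^2 + p[2]^2 <= geom$tip_inner_radius_um^2 &&
        p[3] >= geom$scoring_top_um && p[3] <= cen[3]) return("air")
    "water"
  }
  mat <- vapply(mids, classify, character(1))
  keep <- lens > 1e-9
  mat <- mat[keep]; lens <- lens[keep]
  # merge adjacent equal materials
  if (length(mat) > 1) {
    grp <- cumsum(c(TRUE, mat[-1] != mat[-length(mat)]))
    lens <- as.numeric(tapply(lens, grp, sum))
    mat <- mat[!duplicated(grp)]
  }
  data.frame(material = mat, length_um = lens)
}

#' Water-equivalent length of a material path
#'
#' Density-scaling conversion for electron transport:
#' `sum(length_i * (rho_i / rho_water) * stopping_ratio_i)`.
#'
#' @param segments Data frame from [slant_path()].
#' @param db A `MaterialDB` from [load_material_data()].
#' @return Water-equivalent length in um.
#' @export
water_equivalent_length <- function(segments, db) {
  m <- db$materials
  sum(vapply(seq_len(nrow(segments)), function(i) {
    mat <- m[[segments$material[i]]]
    if (is.null(mat)) stop("unknown material '", segments$material[i], "'")
    segments$length_um[i] * mat$density * mat$stopping_ratio
  }, numeric(1)))
}
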