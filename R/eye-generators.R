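# Eye-design generators. All generators are deterministic: uniform placements
# use the Fibonacci sphere lattice (golden-angle longitudes, offset latitudes).

golden_angle <- pi * (3 - sqrt(5))

# Fibonacci lattice of n points on the unit sphere, poles on +/- z.
# n = 1 is the documented convention case: the single point sits at +z.
fibonacci_sphere <- function(n) {
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden_angle * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Spherical eye with uniformly distributed ommatidia
#'
#' Places `n` ommatidia on a sphere using the Fibonacci lattice (deterministic,
#' near-uniform area coverage), with every axis pointing radially outward
#' (`axis = position / |position|`). With `n = 1` the single ommatidium sits
#' at `(0, 0, radius)` pointing along +z.
#'
#' @param n number of ommatidia (>= 1).
#' @param acceptance_angle full acceptance cone angle, radians, shared by all
#'   ommatidia.
#' @param radius eye radius, millimetres.
#' @return an [eye_description()].
#' @examples
#' eye <- make_spherical_eye(200, acceptance_angle = 5 * pi / 180, radius = 5)
#' @export
make_spherical_eye <- function(n, acceptance_angle, radius = 1) {
  if (!is_number(n) || n < 1) stopf("n must be >= 1")
  n <- as.integer(n)
  if (!is_number(radius) || radius <= 0) stopf("radius must be positive")
  axes <- fibonacci_sphere(n)
  eye_description(radius * axes, axes, acceptance_angle, 0,
                  name = sprintf("sphere_n%d", n))
}

# smoothstep ramp on [0, 1]
smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# acceptance-angle profile of the acute-zone design as a function of latitude
acute_zone_profile <- function(lat, base_angle, acute_angle, zone_halfwidth) {
  if (zone_halfwidth >= pi / 2) return(rep_len(acute_angle, length(lat)))
  t <- smoothstep((abs(lat) - zone_halfwidth) / (pi / 2 - zone_halfwidth))
  acute_angle + (base_angle - acute_angle) * t
}

#' Eye with a horizontal acute zone
#'
#' Generates an eye whose ommatidial density is increased and acceptance
#' angles reduced (towards `acute_angle`) inside the equatorial band
#' `|latitude| <= zone_halfwidth`, with acceptance angles growing smoothly
#' (smoothstep interpolation) towards `base_angle` at the dorsal and ventral
#' poles. Latitude is measured towards the dorsal (+y) axis.
#'
#' Density follows `1 / acceptance(latitude)^2`, so that the local ommatidial
#' spacing scales with the local acceptance angle: small sharp cones are
#' packed densely along the acute zone while large cones cover the poles,
#' giving full spherical coverage without oversampling. Latitudes are placed
#' by the deterministic inverse-CDF of this density; longitudes follow the
#' golden angle.
#'
#' @param n total number of ommatidia.
#' @param base_angle acceptance angle at the poles, radians.
#' @param acute_angle acceptance angle inside the acute zone, radians
#'   (`acute_angle <= base_angle`).
#' @param zone_halfwidth half-width of the acute latitude band, radians.
#' @param radius eye radius, millimetres.
#' @return an [eye_description()].
#' @export
make_acute_zone_eye <- function(n, base_angle, acute_angle,
                                zone_halfwidth = 15 * pi / 180, radius = 1) {
  if (!is_number(n) || n < 1) stopf("n must be >= 1")
  n <- as.integer(n)
  if (!is_number(base_angle) || !is_number(acute_angle) ||
      acute_angle <= 0 || base_angle > pi || acute_angle > base_angle)
    stopf("need 0 < acute_angle <= base_angle <= pi")
  if (!is_number(zone_halfwidth) || zone_halfwidth <= 0 || zone_halfwidth > pi / 2)
    stopf("zone_halfwidth must be in (0, pi/2]")
  # inverse CDF of latitude density cos(lat) / acceptance(lat)^2
  grid <- seq(-pi / 2, pi / 2, length.out = 4097)
  dens <- cos(grid) / acute_zone_profile(grid, base_angle, acute_angle,
                                         zone_halfwidth)^2
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2)
  cdf <- c(0, cdf / cdf[length(cdf)])
  u <- (seq_len(n) - 0.5) / n
  lat <- stats::approx(cdf, grid, xout = u, ties = "ordered")$y
  lon <- (golden_angle * (seq_len(n) - 1L)) %% (2 * pi)
  axes <- lonlat_dir(lon, lat)
  eye_description(radius * axes, axes,
                  acute_zone_profile(lat, base_angle, acute_angle, zone_halfwidth),
                  0, name = sprintf("acute_n%d", n))
}

#' Bilateral eye pair on two spherical caps
#'
#' A synthetic stand-in for a scanned bilateral compound eye: two mirrored
#' Fibonacci caps of `n/2` ommatidia each, laid on spheres of the given
#' radius centred at `(+/- separation/2, 0, 0)`, axes radial, covering
#' directions within `fov_halfangle` of the forward (+z) axis. Ommatidia are
#' labelled `"left"`/`"right"`, so the design can be collapsed with
#' [collapse_to_split()] and [collapse_to_single()]. Directions more than
#' `fov_halfangle` from +z are outside the eye pair's field of view.
#'
#' @param n total ommatidial count (split evenly between the eyes).
#' @param acceptance_angle full acceptance cone angle, radians.
#' @param radius per-eye sphere radius, mm.
#' @param separation distance between the two eye centres, mm.
#' @param fov_halfangle angular radius of each eye's cap about +z, radians.
#' @return a labelled [eye_description()].
#' @export
make_paired_eye <- function(n, acceptance_angle = 15 * pi / 180, radius = 1,
                            separation = 3, fov_halfangle = 100 * pi / 180) {
  if (!is_number(n) || n < 2) stopf("n must be >= 2")
  m <- as.integer(n) %/% 2L
  if (!is_number(fov_halfangle) || fov_halfangle <= 0 || fov_halfangle > pi)
    stopf("fov_halfangle must be in (0, pi]")
  # Fibonacci cap about +z: cos(theta) in [cos(fov), 1]
  i <- seq_len(m) - 1L
  ct <- 1 - (2 * i + 1) / (2 * m) * (1 - cos(fov_halfangle))
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- golden_angle * i
  cap <- cbind(st * cos(phi), st * sin(phi), ct)
  right <- cap
  left <- cap
  left[, 1] <- -left[, 1]  # mirror across the sagittal plane
  ctr_r <- c(separation / 2, 0, 0)
  ctr_l <- c(-separation / 2, 0, 0)
  axes <- rbind(left, right)
  pos <- rbind(sweep(radius * left, 2, ctr_l, "+"),
               sweep(radius * right, 2, ctr_r, "+"))
  eye_description(pos, axes, acceptance_angle, 0,
                  labels = rep(c("left", "right"), each = m),
                  name = sprintf("paired_n%d", 2L * m))
}

#' Fraction of the view sphere covered by an eye
#'
#' Measures coverage on a deterministic direction grid: a direction is covered
#' when it lies within the acceptance half-angle of at least one ommatidial
#' axis. Used to compare evenly sampled heterogeneous designs against
#' undersampled homogeneous ones.
#'
#' @param eye an [eye_description()].
#' @param n_dirs number of Fibonacci grid directions.
#' @return fraction in `[0, 1]`.
#' @export
eye_coverage <- function(eye, n_dirs = 4000) {
  dirs <- fibonacci_sphere(n_dirs)
  axes <- eye_axes(eye)
  coshalf <- cos(eye$ommatidia$acceptance / 2)
  covered <- rep(FALSE, n_dirs)
  block <- 512L
  for (s in seq(1L, n_dirs, by = block)) {
    e <- min(s + block - 1L, n_dirs)
    cp <- dirs[s:e, , drop = FALSE] %*% t(axes)
    covered[s:e] <- rowSums(sweep(cp, 2, coshalf, ">=")) > 0
  }
  mean(covered)
}
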