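#' Sampler configuration
#'
#' Controls the stochastic per-ommatidium cone sampler.
#'
#' @param samples_per_ommatidium rays per ommatidium per frame (>= 1).
#' @param rng_seed integer seed of the counter-based random streams. Every
#'   sample's randomness is keyed by (seed, frame, ommatidium identity,
#'   sample), where the identity is a hash of the ommatidium's own parameters,
#'   so renders are bit-reproducible, independent of evaluation order, and an
#'   ommatidium keeps its stream when the eye is reordered.
#' @param frames_to_average number of consecutive frames averaged into one
#'   view; averaging k frames of N samples is the estimator of one frame of
#'   k N samples.
#' @param measure `"gaussian_angle"` (default): the angular deviation from
#'   the axis is drawn as the absolute value of a Gaussian whose FWHM is the
#'   acceptance angle, samples equally weighted. `"weighted_cone"`: sample
#'   directions uniform in solid angle within the acceptance cone and weight
#'   them by the Gaussian — the alternative reading of the acceptance
#'   function, kept for sensitivity checks.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(samples_per_ommatidium = 1L, rng_seed = 1L,
                           frames_to_average = 1L,
                           measure = c("gaussian_angle", "weighted_cone")) {
  measure <- match.arg(measure)
  if (!is_number(samples_per_ommatidium) || samples_per_ommatidium < 1)
    stopf("samples_per_ommatidium must be >= 1")
  if (!is_number(frames_to_average) || frames_to_average < 1)
    stopf("frames_to_average must be >= 1")
  if (!is_number(rng_seed)) stopf("rng_seed must be a single number")
  structure(list(samples_per_ommatidium = as.integer(samples_per_ommatidium),
                 rng_seed = rng_seed,
                 frames_to_average = as.integer(frames_to_average),
                 measure = measure),
            class = "sampler_config")
}

measure_code <- function(cfg) if (cfg$measure == "weighted_cone") 1L else 0L

#' Gaussian width of the acceptance function
#'
#' The ommatidial sampling function is a Gaussian in angular deviation whose
#' full width at half maximum equals the acceptance angle, so
#' `sigma = acceptance_angle / (2 sqrt(2 ln 2))`.
#'
#' @param acceptance_angle full acceptance cone angle, radians.
#' @return Gaussian standard deviation, radians.
#' @examples
#' fwhm_sigma(1)                 # 0.4246609
#' fwhm_sigma(2 * sqrt(2 * log(2)))  # exactly 1
#' @export
fwhm_sigma <- function(acceptance_angle) {
  acceptance_angle / (2 * sqrt(2 * log(2)))
}

#' Draw stochastic sampling directions about an ommatidial axis
#'
#' Draws directions whose angular deviation theta from the axis follows
#' |N(0, sigma)| with `sigma = fwhm_sigma(acceptance_angle)`, truncated at pi
#' by resampling, and whose azimuth is uniform. This is the renderer's own
#' sampling routine (same code path and random streams), exposed for
#' inspection and testing. `acceptance_angle = 0` returns the axis exactly.
#'
#' @param axis unit 3-vector.
#' @param acceptance_angle full cone angle, radians.
#' @param n number of directions.
#' @param seed,frame,ommatidium stream key components (see [sampler_config()]).
#' @param measure see [sampler_config()].
#' @return an n x 3 matrix of unit directions; for `"weighted_cone"` the
#'   Gaussian sample weights are attached as attribute `"weights"`.
#' @export
sample_direction <- function(axis, acceptance_angle, n = 1L, seed = 1L,
                             frame = 0L, ommatidium = 0L,
                             measure = c("gaussian_angle", "weighted_cone")) {
  measure <- match.arg(measure)
  axis <- as_vec3(axis, "axis")
  nm <- sqrt(sum(axis^2))
  if (nm < 1e-12) stopf("axis must be non-zero")
  axis <- axis / nm
  if (!is_number(acceptance_angle) || acceptance_angle < 0 ||
      acceptance_angle > pi)
    stopf("acceptance_angle must lie in [0, pi]")
  out <- cpp_sample_directions(axis, acceptance_angle, as.integer(n),
                               seed, frame, ommatidium,
                               if (measure == "weighted_cone") 1L else 0L)
  dirs <- out$dirs
  if (measure == "weighted_cone") attr(dirs, "weights") <- out$weights
  dirs
}

view_structure <- function(values, eye, frame) {
  dimnames(values) <- list(NULL, c("r", "g", "b"))
  structure(values, eye_ref = eye$name, n_ommatidia = nrow(values),
            frame_index = frame, class = "ommatidial_view")
}

#' @export
print.ommatidial_view <- function(x, ...) {
  cat(sprintf("<ommatidial_view> %d ommatidia, frame %s, eye '%s'\n",
              nrow(x), format(attr(x, "frame_index")), attr(x, "eye_ref")))
  invisible(x)
}

#' Render the raw ommatidial view of an eye
#'
#' For every ommatidium, casts `samples_per_ommatidium` rays from the
#' world-transformed viewpoint (`position + focal_offset * axis`), each along
#' a direction drawn from the Gaussian acceptance cone about the
#' world-transformed axis, and averages the equally weighted sample colours.
#' With `frames_to_average > 1`, consecutive frames are rendered and
#' averaged, which is how the sampling rate is raised internally.
#'
#' @param x an [scene()] or [build_accel()] result.
#' @param eye an [eye_description()].
#' @param pose an [eye_pose()] placing the eye in the world.
#' @param cfg a [sampler_config()].
#' @param frame frame index of the stochastic sampling stream; rendering the
#'   same frame twice is bit-identical, consecutive frames are independent.
#' @return an `ommatidial_view`: an n x 3 matrix of RGB values in `[0, 1]`,
#'   rows ordered as the eye's ommatidia.
#' @examples
#' sc <- fixture_rings_plane()
#' eye <- make_spherical_eye(50, acceptance_angle = 0.2)
#' v <- render_eye(sc, eye, cfg = sampler_config(8, rng_seed = 7))
#' @export
render_eye <- function(x, eye, pose = eye_pose(), cfg = sampler_config(),
                       frame = 0L) {
  stopifnot(inherits(eye, "eye_description"), inherits(pose, "eye_pose"),
            inherits(cfg, "sampler_config"))
  a <- as_accel(x)
  arr <- cpp_render_eye(a$ptr, eye_positions(eye), eye_axes(eye),
                        eye$ommatidia$acceptance, eye$ommatidia$focal_offset,
                        quat_to_matrix(pose$quaternion), pose$position,
                        cfg$samples_per_ommatidium, cfg$frames_to_average,
                        cfg$rng_seed, frame, measure_code(cfg))
  n <- n_ommatidia(eye)
  vals <- if (cfg$frames_to_average == 1L) {
    matrix(arr, n, 3)
  } else {
    apply(array(arr, c(n, 3, cfg$frames_to_average)), c(1, 2), mean)
  }
  view_structure(vals, eye, frame)
}

#' Render a stack of consecutive frames
#'
#' Renders `frames` consecutive stochastic frames of the same static view.
#' Frame `f` of the stack uses stream index `frame0 + f - 1`, so stacking in
#' one call or frame-by-frame gives bit-identical results.
#'
#' @inheritParams render_eye
#' @param frames number of frames.
#' @param frame0 stream index of the first frame.
#' @return an `ommatidial_frames` array of dimension (n_ommatidia, 3, frames).
#' @export
render_frames <- function(x, eye, pose = eye_pose(), cfg = sampler_config(),
                          frames = 2L, frame0 = 0L) {
  stopifnot(inherits(eye, "eye_description"), inherits(pose, "eye_pose"),
            inherits(cfg, "sampler_config"))
  a <- as_accel(x)
  arr <- cpp_render_eye(a$ptr, eye_positions(eye), eye_axes(eye),
                        eye$ommatidia$acceptance, eye$ommatidia$focal_offset,
                        quat_to_matrix(pose$quaternion), pose$position,
                        cfg$samples_per_ommatidium, as.integer(frames),
                        cfg$rng_seed, frame0, measure_code(cfg))
  structure(array(arr, c(n_ommatidia(eye), 3L, frames)),
            eye_ref = eye$name, class = "ommatidial_frames")
}

#' Render a single ommatidium
#'
#' @param x an [scene()] or [build_accel()] result.
#' @param omm an [ommatidium()].
#' @inheritParams render_eye
#' @return an RGB 3-vector.
#' @export
render_ommatidium <- function(x, omm, pose = eye_pose(),
                              cfg = sampler_config(), frame = 0L) {
  stopifnot(inherits(omm, "ommatidium"))
  eye <- eye_description(matrix(omm$position, 1), matrix(omm$axis, 1),
                         omm$acceptance_angle, omm$focal_offset)
  as.numeric(render_eye(x, eye, pose, cfg, frame))
}

#' Average ommatidial views frame-wise
#'
#' Element-wise mean of views of the same eye; averaging k frames rendered at
#' N samples each estimates the same quantity as one frame at k N samples.
#'
#' @param views a non-empty list of `ommatidial_view`s of equal length, or an
#'   `ommatidial_frames` array.
#' @return an `ommatidial_view`.
#' @export
average_frames <- function(views) {
  if (inherits(views, "ommatidial_frames")) {
    vals <- apply(views, c(1, 2), mean)
    return(view_structure(vals, list(name = attr(views, "eye_ref")), NA))
  }
  if (!is.list(views) || !length(views)) stopf("views must be a non-empty list")
  n <- nrow(views[[1]])
  for (v in views)
    if (!inherits(v, "ommatidial_view") || nrow(v) != n)
      stopf("all views must be ommatidial_views over the same eye")
  vals <- Reduce(`+`, lapply(views, unclass)) / length(views)
  view_structure(vals, list(name = attr(views[[1]], "eye_ref")), NA)
}

#' Static concentric sampling pattern
#'
#' The classical fixed sampling scheme: rays on concentric circles at polar
#' angles `(k - 1/2) * (acceptance/2) / n_rings` (k = 1..n_rings) about the
#' axis, uniformly spaced azimuths, plus an optional central ray, each ray
#' weighted by the Gaussian acceptance function. Static patterns alias
#' structured scenes; the stochastic sampler exists to replace this.
#'
#' @param axis unit viewing axis.
#' @param acceptance_angle full cone angle, radians.
#' @param n_rings number of sample circles.
#' @param n_per_ring rays per circle.
#' @param include_centre add the axial ray.
#' @return a list with `dirs` (matrix of unit directions) and Gaussian
#'   `weights`.
#' @export
static_cone_directions <- function(axis, acceptance_angle, n_rings = 3L,
                                   n_per_ring = 12L, include_centre = TRUE) {
  axis <- as_vec3(axis, "axis")
  axis <- axis / sqrt(sum(axis^2))
  sigma <- fwhm_sigma(acceptance_angle)
  # orthonormal frame about the axis
  up <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  theta <- (seq_len(n_rings) - 0.5) * (acceptance_angle / 2) / n_rings
  phi <- (seq_len(n_per_ring) - 1L) * 2 * pi / n_per_ring
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- cos(grid$theta) %o% axis +
    sin(grid$theta) * (cos(grid$phi) %o% e1 + sin(grid$phi) %o% e2)
  w <- exp(-grid$theta^2 / (2 * sigma^2))
  if (include_centre) {
    dirs <- rbind(axis, dirs)
    w <- c(1, w)
  }
  list(dirs = unname(dirs), weights = unname(w))
}

#' Render one ommatidium with a static sampling pattern
#'
#' Weighted average of the scene colours along a fixed set of directions —
#' the aliasing-prone baseline the stochastic sampler is compared against.
#'
#' @param x an [scene()] or [build_accel()] result.
#' @param omm an [ommatidium()].
#' @param pose an [eye_pose()].
#' @param ... passed to [static_cone_directions()].
#' @return an RGB 3-vector.
#' @export
render_ommatidium_static <- function(x, omm, pose = eye_pose(), ...) {
  stopifnot(inherits(omm, "ommatidium"))
  R <- quat_to_matrix(pose$quaternion)
  axis_w <- as.numeric(R %*% omm$axis)
  origin <- as.numeric(R %*% (omm$position + omm$focal_offset * omm$axis)) +
    pose$position
  pat <- static_cone_directions(axis_w, omm$acceptance_angle, ...)
  cols <- render_rays(x, matrix(origin, 1), pat$dirs)
  as.numeric(crossprod(cols, pat$weights) / sum(pat$weights))
}

#' Render a traditional debug camera
#'
#' One deterministic primary ray per pixel through a pinhole (perspective),
#' equirectangular panoramic, or orthographic projection. These cameras exist
#' to inspect scenes, not to model eyes.
#'
#' @param x an [scene()] or [build_accel()] result.
#' @param camera a non-compound [camera_spec()].
#' @param width,height image size in pixels.
#' @return an H x W x 3 RGB array in `[0, 1]`.
#' @export
render_traditional <- function(x, camera, width = 256L, height = 128L) {
  stopifnot(inherits(camera, "camera_spec"))
  if (camera$kind == "compound")
    stopf("use render_eye() for compound cameras")
  W <- as.integer(width); H <- as.integer(height)
  px <- (seq_len(W) - 0.5) / W
  py <- (seq_len(H) - 0.5) / H
  grid <- expand.grid(i = px, j = py)   # column-fastest: i varies first
  R <- quat_to_matrix(camera$pose$quaternion)
  if (camera$kind == "perspective") {
    ty <- tan(camera$yfov / 2)
    d <- cbind((2 * grid$i - 1) * ty * (W / H), (1 - 2 * grid$j) * ty, 1)
    d <- d / row_norms(d)
    org <- matrix(camera$pose$position, 1)
  } else if (camera$kind == "panoramic") {
    lon <- -pi + grid$i * 2 * pi
    lat <- pi / 2 - grid$j * pi
    d <- lonlat_dir(lon, lat)
    org <- matrix(camera$pose$position, 1)
  } else {
    d <- matrix(rep(c(0, 0, 1), each = W * H), ncol = 3)
    org <- cbind((2 * grid$i - 1) * camera$xmag, (1 - 2 * grid$j) * camera$ymag, 0)
    org <- t(R %*% t(org) + camera$pose$position)
  }
  dw <- t(R %*% t(d))
  cols <- render_rays(x, org, dw)
  out <- array(0, c(H, W, 3))
  for (c in 1:3) out[, , c] <- matrix(cols[, c], H, W, byrow = TRUE)
  out
}

#' Write an RGB array as an 8-bit PNG
#'
#' Values are clipped to `[0, 1]` and quantised with round-half-to-even to
#' the 8-bit output colourspace.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param path output file.
#' @export
write_image <- function(img, path) {
  q <- round(pmin(pmax(img, 0), 1) * 255) / 255
  png::writePNG(q, path)
  invisible(path)
}
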