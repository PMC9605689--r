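# Sampling-noise calibration: per-ommatidium frame-to-frame colour spread,
# steradian normalisation, minimum sample-count search and variance maps.

#' Solid angle of an acceptance cone
#'
#' The solid angle subtended by an ommatidium's field of view (full cone
#' angle `acceptance_angle`) at the eye centre:
#' `Omega = 2 pi (1 - cos(acceptance_angle / 2))` steradians.
#'
#' @param acceptance_angle full cone angle, radians.
#' @return solid angle in steradians.
#' @examples
#' cone_solid_angle(pi)      # hemisphere, 2*pi
#' cone_solid_angle(2 * pi)  # full sphere, 4*pi
#' @export
cone_solid_angle <- function(acceptance_angle) {
  2 * pi * (1 - cos(acceptance_angle / 2))
}

#' Per-ommatidium colour spread over frames
#'
#' For each ommatidium, the standard deviation of its received colour across
#' a stack of stochastic frames, measured as the root mean squared Euclidean
#' distance in RGB space from the per-ommatidium mean colour, and expressed
#' as a percentage of the maximum colour difference (the length of the
#' all-white vector: `sqrt(3)` in unit scale, about 441.67 in 8-bit units).
#'
#' @param frames an `ommatidial_frames` array from [render_frames()], or a
#'   list of at least two `ommatidial_view`s of the same eye.
#' @return numeric vector of percentages, one per ommatidium.
#' @export
ommatidial_sd <- function(frames) {
  if (is.list(frames) && !is.array(frames)) {
    if (length(frames) < 2L) stopf("need at least 2 frames")
    n <- nrow(frames[[1]])
    for (v in frames) if (is.null(dim(v)) || nrow(v) != n || ncol(v) != 3L)
      stopf("all frames must be n x 3 views of the same eye")
    frames <- array(unlist(lapply(frames, unclass)),
                    c(n, 3L, length(frames)))
  }
  d <- dim(frames)
  if (length(d) != 3L || d[2] != 3L) stopf("frames must be an n x 3 x F array")
  if (d[3] < 2L) stopf("need at least 2 frames")
  mu <- apply(frames, c(1, 2), mean)
  sq <- (frames - as.vector(mu))^2          # recycles mu over the frame axis
  msd <- apply(sq, 1, sum) / d[3]           # mean over frames of |c - mu|^2
  100 * sqrt(msd) / sqrt(3)
}

#' Normalise colour spread to one steradian of coverage
#'
#' Ommatidia with wider acceptance cones need more rays: at a fixed ray
#' density the spread scales as the inverse square root of the sample count.
#' To compare spread across heterogeneous acceptance angles the measured SD
#' is therefore rescaled to the spread an ommatidium covering exactly one
#' steradian would show at the same ray density:
#' `sd_norm = sd * sqrt(Omega / 1 sr)` with `Omega = cone_solid_angle(angle)`
#' (method `"equivalent_steradian"`, the default). Under this normalisation a
#' fixed threshold corresponds to a fixed number of rays per steradian,
#' independent of the eye. Plain division by the solid angle
#' (`"per_steradian"`, spread per steradian of coverage) is kept as an
#' alternative reading.
#'
#' @param sd spread percentages from [ommatidial_sd()].
#' @param acceptance_angle acceptance angles, radians (recycled).
#' @param method `"equivalent_steradian"` or `"per_steradian"`.
#' @return normalised spread, percent per one steradian of coverage.
#' @export
normalise_sd <- function(sd, acceptance_angle,
                         method = c("equivalent_steradian", "per_steradian")) {
  method <- match.arg(method)
  omega <- cone_solid_angle(acceptance_angle)
  if (any(omega <= 0))
    stopf("acceptance angle gives zero solid angle; cannot normalise")
  if (method == "equivalent_steradian") sd * sqrt(omega) else sd / omega
}

measure_max_norm_sd <- function(accel, eye, pose, samples, frames, seed,
                                measure, method) {
  cfg <- sampler_config(samples, rng_seed = seed, measure = measure)
  stack <- render_frames(accel, eye, pose, cfg, frames = frames)
  sd <- ommatidial_sd(stack)
  nsd <- normalise_sd(sd, eye$ommatidia$acceptance, method = method)
  list(sd = sd, nsd = nsd, max = max(nsd))
}

#' Calibrate the per-ommatidium sample count for a scene
#'
#' Searches for the minimum `samples_per_ommatidium` such that, over a stack
#' of stochastic frames, the most deviant ommatidium's steradian-normalised
#' colour spread stays below `threshold` percent. The count is doubled until
#' the threshold is met, then bisected down to the minimal satisfying count.
#'
#' The spread measured over `F` frames is itself an estimate with relative
#' standard error of roughly `1 / sqrt(2 F)`; accepting a count whose
#' estimate sits exactly at the threshold would leave the true spread above
#' it half the time. The search therefore targets the effective level
#' `threshold * (1 - 2 / sqrt(2 F))` (two standard errors inside), so that
#' re-measuring the accepted count with fresh frames stays under the nominal
#' threshold.
#'
#' @param x an [scene()] or [build_accel()] result.
#' @param eye an [eye_description()].
#' @param pose the [eye_pose()] at which to calibrate (ideally the scene's
#'   variance hotspot, see [find_hotspot()]).
#' @param threshold maximum allowed normalised spread, percent of the maximum
#'   colour difference per steradian (default 1).
#' @param frames frames per measurement (default 1000).
#' @param seed RNG seed for the measurement frames.
#' @param max_samples search cap; exceeding it returns `converged = FALSE`.
#' @param measure see [sampler_config()].
#' @param method see [normalise_sd()].
#' @return an object of class `calibration_report`: the accepted
#'   `samples_used`, `frames_used`, per-ommatidium spreads (raw and
#'   normalised), their max and mean, the search `history` and a `converged`
#'   flag.
#' @export
calibrate_sample_count <- function(x, eye, pose = eye_pose(), threshold = 1,
                                   frames = 1000L, seed = 1L,
                                   max_samples = 4096L,
                                   measure = c("gaussian_angle", "weighted_cone"),
                                   method = c("equivalent_steradian",
                                              "per_steradian")) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  if (!is_number(threshold) || threshold <= 0) stopf("threshold must be > 0")
  a <- as_accel(x)
  # two-standard-error finite-sample margin on the spread estimate
  eff <- threshold * max(0.5, 1 - 2 / sqrt(2 * frames))
  history <- data.frame(samples = integer(), max_norm_sd = numeric())
  note <- function(n, m) history[nrow(history) + 1L, ] <<- list(n, m$max)

  n <- 1L
  m <- measure_max_norm_sd(a, eye, pose, n, frames, seed, measure, method)
  note(n, m)
  lo <- 0L  # highest failing count seen
  while (m$max > eff && n < max_samples) {
    lo <- n
    n <- min(2L * n, as.integer(max_samples))
    m <- measure_max_norm_sd(a, eye, pose, n, frames, seed, measure, method)
    note(n, m)
  }
  converged <- m$max <= eff
  if (converged && n > lo + 1L) {
    hi <- n; hi_m <- m
    while (hi > lo + 1L) {   # minimal count in (lo, hi]
      mid <- lo + (hi - lo) %/% 2L
      mm <- measure_max_norm_sd(a, eye, pose, mid, frames, seed, measure, method)
      note(mid, mm)
      if (mm$max <= eff) { hi <- mid; hi_m <- mm } else lo <- mid
    }
    n <- hi; m <- hi_m
  }
  structure(list(samples_used = n, frames_used = as.integer(frames),
                 threshold = threshold, effective_threshold = eff,
                 converged = converged,
                 per_omm_sd = m$sd, per_omm_sd_normalised = m$nsd,
                 max_sd = max(m$nsd), mean_sd = mean(m$nsd),
                 method = method, history = history),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %s at %d samples/ommatidium (%d frames)\n",
              if (x$converged) "converged" else "NOT converged",
              x$samples_used, x$frames_used))
  cat(sprintf("  normalised spread: max %.4g%%, mean %.4g%% (threshold %.4g%%, search level %.4g%%, %s)\n",
              x$max_sd, x$mean_sd, x$threshold, x$effective_threshold,
              x$method))
  invisible(x)
}

#' Regular grid of eye poses
#'
#' @param xlim,ylim,zlim coordinate ranges, mm.
#' @param n points per axis (scalar or length 3).
#' @return a list of [eye_pose()]s in x-fastest order.
#' @export
grid_poses <- function(xlim, ylim, zlim, n = 5L) {
  n <- rep_len(as.integer(n), 3L)
  axis_seq <- function(lim, k) if (k == 1L) mean(lim) else seq(lim[1], lim[2], length.out = k)
  g <- expand.grid(x = axis_seq(xlim, n[1]), y = axis_seq(ylim, n[2]),
                   z = axis_seq(zlim, n[3]))
  lapply(seq_len(nrow(g)), function(i) eye_pose(as.numeric(g[i, ])))
}

#' Map sampling variance over an environment
#'
#' Renders a frame stack at every pose of a grid and records the mean and
#' maximum per-ommatidium colour spread (raw and steradian-normalised) —
#' the scene's "visual complexity" map whose hotspots drive the minimum
#' sample count.
#'
#' @param x an [scene()] or [build_accel()] result.
#' @param eye an [eye_description()].
#' @param grid a list of [eye_pose()]s (see [grid_poses()]).
#' @param samples rays per ommatidium per frame.
#' @param frames frames per pose.
#' @param seed RNG seed (each pose uses its own frame window, so streams are
#'   independent across poses).
#' @param measure,method see [sampler_config()], [normalise_sd()].
#' @return an object of class `variance_map`: a data frame with the pose
#'   positions and the four spread statistics, plus the pose list.
#' @export
variance_map <- function(x, eye, grid, samples = 8L, frames = 100L, seed = 1L,
                         measure = c("gaussian_angle", "weighted_cone"),
                         method = c("equivalent_steradian", "per_steradian")) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  a <- as_accel(x)
  if (!length(grid)) stopf("grid must contain at least one pose")
  cfg <- sampler_config(samples, rng_seed = seed, measure = measure)
  rows <- lapply(seq_along(grid), function(i) {
    pose <- grid[[i]]
    stopifnot(inherits(pose, "eye_pose"))
    stack <- render_frames(a, eye, pose, cfg, frames = frames,
                           frame0 = (i - 1) * frames)
    sd <- ommatidial_sd(stack)
    nsd <- normalise_sd(sd, eye$ommatidia$acceptance, method = method)
    data.frame(x = pose$position[1], y = pose$position[2],
               z = pose$position[3], mean_sd = mean(sd), max_sd = max(sd),
               mean_sd_norm = mean(nsd), max_sd_norm = max(nsd))
  })
  structure(list(stats = do.call(rbind, rows), poses = grid,
                 samples = samples, frames = frames),
            class = "variance_map")
}

#' @export
print.variance_map <- function(x, ...) {
  cat(sprintf("<variance_map> %d poses, max-SD range [%.3g%%, %.3g%%]\n",
              nrow(x$stats), min(x$stats$max_sd), max(x$stats$max_sd)))
  invisible(x)
}

#' Locate the variance hotspot of an environment
#'
#' Returns the grid pose with the highest maximum per-ommatidium spread
#' (ties towards the lowest grid index). Calibrating the sample count at
#' this pose bounds the sampling noise everywhere on the grid.
#'
#' @param map a [variance_map()].
#' @return the hotspot [eye_pose()], with the winning row index as attribute
#'   `"index"`.
#' @export
find_hotspot <- function(map) {
  stopifnot(inherits(map, "variance_map"))
  i <- which.max(map$stats$max_sd)   # which.max takes the first maximum
  structure(map$poses[[i]], index = i)
}
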