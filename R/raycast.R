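#' Build the ray-acceleration structure for a scene
#'
#' Flattens the scene's triangles and builds a binned-SAH bounding-volume
#' hierarchy (maximum leaf size 4). Queries through the hierarchy return
#' results identical to brute force: equal-distance ties are broken towards
#' the lowest (mesh, triangle) index on both paths. Triangles that are
#' degenerate (relative area below 1e-14) are excluded from intersection.
#'
#' @param sc an [scene()].
#' @return an object of class `scene_accel` reusable across renders.
#' @export
build_accel <- function(sc) {
  stopifnot(inherits(sc, "eye_scene"))
  structure(list(ptr = cpp_build_accel(unclass(sc)), scene = sc),
            class = "scene_accel")
}

as_accel <- function(x) {
  if (inherits(x, "scene_accel")) return(x)
  if (inherits(x, "eye_scene")) return(build_accel(x))
  stopf("expected an eye_scene or scene_accel")
}

check_dirs <- function(dirs) {
  dirs <- matrix(as.numeric(dirs), ncol = 3L)
  n <- row_norms(dirs)
  if (any(abs(n - 1) > 1e-6))
    stopf("ray directions must be unit vectors (worst norm %.6g)",
          n[which.max(abs(n - 1))])
  dirs / n
}

#' Intersect rays with a scene
#'
#' Finds the nearest intersection of each ray with the scene's triangles
#' using a watertight ray-triangle test. Hits closer than 1e-6 mm are ignored
#' (self-intersection guard); a miss is a value, not an error.
#'
#' @param x an [scene()] or [build_accel()] result.
#' @param origins n x 3 matrix of ray origins (mm).
#' @param directions n x 3 matrix of unit ray directions (renormalised when
#'   within 1e-6 of unit).
#' @param method `"bvh"` (accelerated) or `"brute"` (test every triangle);
#'   both return identical hits.
#' @return a data frame with columns `hit`, `t` (distance, mm), `mesh`,
#'   `tri` (1-based ids), `b1`, `b2` (barycentric weights of the triangle's
#'   second and third vertex).
#' @export
intersect_rays <- function(x, origins, directions, method = c("bvh", "brute")) {
  method <- match.arg(method)
  a <- as_accel(x)
  origins <- matrix(as.numeric(origins), ncol = 3L)
  directions <- check_dirs(directions)
  if (nrow(origins) == 1L && nrow(directions) > 1L)
    origins <- origins[rep(1L, nrow(directions)), , drop = FALSE]
  if (nrow(origins) != nrow(directions))
    stopf("origins and directions must have matching rows")
  as.data.frame(cpp_intersect(a$ptr, origins, directions, method == "brute"))
}

#' Brute-force single-ray intersection
#'
#' Reference path: tests the ray against every triangle in the scene.
#'
#' @param sc an [scene()] or [build_accel()] result.
#' @param origin ray origin (3-vector, mm).
#' @param direction unit ray direction.
#' @return a one-row data frame as in [intersect_rays()].
#' @export
intersect_brute <- function(sc, origin, direction) {
  intersect_rays(sc, matrix(as_vec3(origin, "origin"), 1),
                 matrix(as_vec3(direction, "direction"), 1), method = "brute")
}

#' Colour for a set of hit records
#'
#' A miss returns the scene background; a hit on an untextured material its
#' base colour; a hit on a textured mesh a bilinear interpolation of the four
#' nearest texels at the barycentrically interpolated uv coordinate.
#'
#' @param x an [scene()] or [build_accel()] result.
#' @param hits a data frame from [intersect_rays()].
#' @return an n x 3 matrix of RGB values in `[0, 1]`.
#' @export
shade <- function(x, hits) {
  a <- as_accel(x)
  cpp_shade(a$ptr, hits$hit, hits$mesh, hits$tri, hits$b1, hits$b2)
}

#' Cast rays and return their colours
#'
#' Convenience composition of [intersect_rays()] and [shade()] on the
#' accelerated path.
#'
#' @inheritParams intersect_rays
#' @return an n x 3 matrix of RGB values.
#' @export
render_rays <- function(x, origins, directions) {
  a <- as_accel(x)
  origins <- matrix(as.numeric(origins), ncol = 3L)
  directions <- check_dirs(directions)
  if (nrow(origins) == 1L && nrow(directions) > 1L)
    origins <- origins[rep(1L, nrow(directions)), , drop = FALSE]
  cpp_render_rays(a$ptr, origins, directions)
}
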