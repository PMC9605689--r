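#' Triangle mesh
#'
#' @param vertices n x 3 matrix of vertex positions (mm, world frame).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param uv optional n x 2 matrix of texture coordinates.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, uv = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || any(!is.finite(vertices)))
    stopf("vertices must be a finite n x 3 matrix")
  if (ncol(triangles) != 3L) stopf("triangles must be an m x 3 index matrix")
  if (nrow(triangles) &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stopf("triangle indices out of range (1..%d)", nrow(vertices))
  if (!is.null(uv)) {
    uv <- as.matrix(uv)
    storage.mode(uv) <- "double"
    if (nrow(uv) != nrow(vertices) || ncol(uv) != 2L)
      stopf("uv must be an n x 2 matrix matching vertices")
  }
  structure(list(vertices = vertices, triangles = triangles, uv = uv),
            class = "triangle_mesh")
}

#' Flat or textured unlit material
#'
#' Materials are unlit: a surface returns its base colour, or a bilinear
#' texture lookup when a texture and mesh uv coordinates are present.
#'
#' @param base_colour RGB in `[0,1]^3`.
#' @param texture optional H x W x 3 array in `[0,1]`.
#' @return an object of class `material`.
#' @export
material <- function(base_colour = c(1, 1, 1), texture = NULL) {
  base_colour <- as_vec3(base_colour, "base_colour")
  if (any(base_colour < 0) || any(base_colour > 1))
    stopf("base_colour components must lie in [0, 1]")
  if (!is.null(texture)) {
    if (length(dim(texture)) != 3L || dim(texture)[3] != 3L)
      stopf("texture must be an H x W x 3 array")
    if (any(!is.finite(texture)) || min(texture) < 0 || max(texture) > 1)
      stopf("texture values must lie in [0, 1]")
    storage.mode(texture) <- "double"
  }
  structure(list(base_colour = base_colour, texture = texture),
            class = "material")
}

#' Scene: meshes, materials, background and cameras
#'
#' @param meshes list of [triangle_mesh()] objects.
#' @param materials list of [material()] objects, one per mesh.
#' @param background RGB colour returned when a ray misses all geometry.
#' @param cameras list of camera specifications (see [camera_spec()]).
#' @return an object of class `eye_scene`.
#' @export
scene <- function(meshes = list(), materials = list(),
                  background = c(1, 1, 1), cameras = list()) {
  if (length(materials) != length(meshes))
    stopf("need one material per mesh (%d meshes, %d materials)",
          length(meshes), length(materials))
  for (m in meshes) stopifnot(inherits(m, "triangle_mesh"))
  for (m in materials) stopifnot(inherits(m, "material"))
  background <- as_vec3(background, "background")
  structure(list(meshes = meshes, materials = materials,
                 background = background, cameras = cameras),
            class = "eye_scene")
}

#' @export
print.eye_scene <- function(x, ...) {
  nt <- sum(vapply(x$meshes, function(m) nrow(m$triangles), 0L))
  cat(sprintf("<eye_scene> %d mesh(es), %d triangles, %d camera(s), background (%.2f, %.2f, %.2f)\n",
              length(x$meshes), nt, length(x$cameras),
              x$background[1], x$background[2], x$background[3]))
  invisible(x)
}

#' Camera specification
#'
#' Cameras are either `compound` (a full compound-eye description linked via
#' an eye CSV file) or traditional debug cameras: `perspective` (pinhole),
#' `panoramic` (equirectangular) or `orthographic`. The pose follows the
#' package convention of +z forward, +y up.
#'
#' @param kind one of `"compound"`, `"perspective"`, `"panoramic"`,
#'   `"orthographic"`.
#' @param pose an [eye_pose()].
#' @param name camera name.
#' @param eye_csv path to the eye CSV file (compound cameras).
#' @param yfov vertical field of view, radians (perspective cameras).
#' @param xmag,ymag half-extents of the view volume, mm (orthographic).
#' @param projection_hint free-text display-projection hint.
#' @return an object of class `camera_spec`.
#' @export
camera_spec <- function(kind, pose = eye_pose(), name = kind, eye_csv = NULL,
                        yfov = pi / 3, xmag = 1, ymag = 1,
                        projection_hint = "") {
  kind <- match.arg(kind, c("compound", "perspective", "panoramic",
                            "orthographic"))
  stopifnot(inherits(pose, "eye_pose"))
  if (kind == "compound" && is.null(eye_csv))
    stopf("compound cameras need an eye_csv path")
  structure(list(kind = kind, pose = pose, name = name, eye_csv = eye_csv,
                 yfov = yfov, xmag = xmag, ymag = ymag,
                 projection_hint = projection_hint),
            class = "camera_spec")
}

#' Load the eye description linked by a compound camera
#'
#' @param camera a compound [camera_spec()].
#' @return an [eye_description()].
#' @export
camera_eye <- function(camera) {
  stopifnot(inherits(camera, "camera_spec"))
  if (camera$kind != "compound") stopf("camera '%s' is not compound", camera$name)
  load_eye_csv(camera$eye_csv)
}

scene_triangle_count <- function(sc) {
  sum(vapply(sc$meshes, function(m) nrow(m$triangles), 0L))
}

# scene axis-aligned bounds
scene_bounds <- function(sc) {
  v <- do.call(rbind, lapply(sc$meshes, `[[`, "vertices"))
  if (is.null(v)) return(NULL)
  rbind(lo = apply(v, 2, min), hi = apply(v, 2, max))
}
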