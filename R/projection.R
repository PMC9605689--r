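#' Projection specification for compound-eye displays
#'
#' @param kind `"orientation_voronoi"`, `"position_voronoi"` or `"vector"`.
#' @param width,height output image size in pixels.
#' @return an object of class `projection_spec`.
#' @export
projection_spec <- function(kind = c("orientation_voronoi", "position_voronoi",
                                     "vector"),
                            width = 256L, height = 128L) {
  kind <- match.arg(kind)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stopf("width and height must be positive")
  structure(list(kind = kind, width = width, height = height),
            class = "projection_spec")
}

# unit direction of every pixel centre of an equirectangular image,
# row-major within columns (column index varies fastest)
pixel_directions <- function(width, height) {
  lon <- -pi + (seq_len(width) - 0.5) * 2 * pi / width
  lat <- pi / 2 - (seq_len(height) - 0.5) * pi / height
  grid <- expand.grid(lon = lon, lat = lat)
  lonlat_dir(grid$lon, grid$lat)
}

voronoi_image <- function(dirs, axes, view, width, height) {
  n <- nrow(axes)
  npix <- nrow(dirs)
  assign <- integer(npix)
  block <- 1024L
  for (s in seq(1L, npix, by = block)) {
    e <- min(s + block - 1L, npix)
    cp <- dirs[s:e, , drop = FALSE] %*% t(axes)
    assign[s:e] <- max.col(cp, ties.method = "first")  # ties: lowest index
  }
  img <- array(0, c(height, width, 3))
  for (c in 1:3)
    img[, , c] <- matrix(view[assign, c], height, width, byrow = TRUE)
  img
}

#' Orientation-wise spherical Voronoi projection
#'
#' Maps the raw ommatidial view onto an equirectangular image: every pixel
#' centre corresponds to a viewing direction (longitude in `[-pi, pi)`,
#' latitude in `[-pi/2, pi/2]`, +z at the image centre), and takes the colour
#' of the ommatidium whose axis is angularly nearest (maximum dot product;
#' ties towards the lowest ommatidial index). This is the spherical Voronoi
#' partition by axis direction, evaluated per pixel. Like all equirectangular
#' maps it inflates the poles: dorsal and ventral ommatidia receive more
#' pixel area than their share of solid angle.
#'
#' @param eye an [eye_description()].
#' @param view the matching `ommatidial_view`.
#' @param spec a [projection_spec()].
#' @return an H x W x 3 RGB array.
#' @export
project_orientation_voronoi <- function(eye, view,
                                        spec = projection_spec("orientation_voronoi")) {
  stopifnot(inherits(eye, "eye_description"))
  if (nrow(view) != n_ommatidia(eye))
    stopf("view has %d rows but the eye has %d ommatidia",
          nrow(view), n_ommatidia(eye))
  dirs <- pixel_directions(spec$width, spec$height)
  voronoi_image(dirs, eye_axes(eye), unclass(view), spec$width, spec$height)
}

#' Position-wise spherical Voronoi projection
#'
#' As [project_orientation_voronoi()], but pixels are assigned by the
#' direction from the eye's position centroid to each ommatidial position
#' rather than by axis. For eyes whose ommatidia sit on a sphere with radial
#' axes the two projections coincide.
#'
#' @inheritParams project_orientation_voronoi
#' @return an H x W x 3 RGB array.
#' @export
project_position_voronoi <- function(eye, view,
                                     spec = projection_spec("position_voronoi")) {
  stopifnot(inherits(eye, "eye_description"))
  if (nrow(view) != n_ommatidia(eye))
    stopf("view has %d rows but the eye has %d ommatidia",
          nrow(view), n_ommatidia(eye))
  pos <- eye_positions(eye)
  rel <- sweep(pos, 2, colMeans(pos))
  nrm <- row_norms(rel)
  if (max(nrm) < 1e-9)
    stopf(paste("all ommatidial positions coincide; the position-wise projection",
                "is undefined - use the orientation-wise projection instead"))
  if (any(nrm < 1e-12))
    stopf("an ommatidium sits exactly at the eye centroid; position-wise projection undefined")
  dirs <- pixel_directions(spec$width, spec$height)
  voronoi_image(dirs, rel / nrm, unclass(view), spec$width, spec$height)
}

#' Export an ommatidial view as a vector CSV
#'
#' The projection-free vectorised output: one `(index, r, g, b)` row per
#' ommatidium, the standard input format for downstream computational
#' models. Values are validated to `[0, 1]` (clipped, with a warning, when
#' marginally outside) and written at full precision so the round trip is
#' lossless.
#'
#' @param view an `ommatidial_view` (any n x 3 matrix of RGB rows works).
#' @param path output CSV file.
#' @export
export_vector <- function(view, path) {
  m <- unclass(view)
  if (is.null(dim(m)) || ncol(m) != 3L) stopf("view must be an n x 3 matrix")
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9)
    warning("view values outside [0, 1] were clipped", call. = FALSE)
  m <- pmin(pmax(m, 0), 1)
  lines <- c("index,r,g,b",
             sprintf("%d,%.17g,%.17g,%.17g", seq_len(nrow(m)),
                     m[, 1], m[, 2], m[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a vector CSV written by [export_vector()]
#'
#' @param path CSV file.
#' @return an n x 3 matrix of RGB values, ordered by index.
#' @export
load_vector <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[order(df$index), c("r", "g", "b")])
  dimnames(m) <- list(NULL, c("r", "g", "b"))
  m
}
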