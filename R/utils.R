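# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

as_vec3 <- function(x, what = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) stopf("%s must be a finite 3-vector", what)
  x
}

row_norms <- function(m) sqrt(rowSums(m * m))

#' Unit direction for longitude/latitude
#'
#' Package convention: the local frame has +z forward and +y dorsal (up).
#' Longitude 0 / latitude 0 maps to +z; latitude is measured towards +y.
#'
#' @param lon,lat angles in radians (recycled to common length).
#' @return a matrix with one unit row vector per input pair.
#' @keywords internal
lonlat_dir <- function(lon, lat) {
  cbind(cos(lat) * sin(lon), sin(lat), cos(lat) * cos(lon))
}

# inverse of lonlat_dir for unit rows
dir_lonlat <- function(dirs) {
  lat <- asin(pmin(1, pmax(-1, dirs[, 2])))
  lon <- atan2(dirs[, 1], dirs[, 3])
  cbind(lon = lon, lat = lat)
}
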