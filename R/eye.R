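#' Single ommatidium
#'
#' One sampling element of a compound eye: a viewpoint, a viewing axis and a
#' Gaussian acceptance cone. The acceptance angle is the full cone angle and
#' equals the full width at half maximum (FWHM) of the Gaussian sampling
#' function (see [fwhm_sigma()]).
#'
#' @param position 3-vector, millimetres, in the eye-local frame.
#' @param axis ommatidial axis; unit 3-vector (renormalised when its norm is
#'   within `1e-3` of 1, rejected otherwise).
#' @param acceptance_angle full cone angle in radians, in `[0, pi]`.
#' @param focal_offset displacement of the ray origin along the axis in
#'   millimetres; 0 means rays originate at `position`.
#' @return an object of class `ommatidium`.
#' @examples
#' ommatidium(c(0, 0, 1), c(0, 0, 1), acceptance_angle = 5 * pi / 180)
#' @export
ommatidium <- function(position, axis, acceptance_angle, focal_offset = 0) {
  position <- as_vec3(position, "position")
  axis <- as_vec3(axis, "axis")
  n <- sqrt(sum(axis^2))
  if (abs(n - 1) > 1e-3)
    stopf("axis norm %.6g is not within 1e-3 of 1", n)
  if (!is_number(acceptance_angle) || acceptance_angle < 0 || acceptance_angle > pi)
    stopf("acceptance_angle must be a single value in [0, pi]")
  if (!is_number(focal_offset)) stopf("focal_offset must be a single finite number")
  structure(list(position = position, axis = axis / n,
                 acceptance_angle = acceptance_angle,
                 focal_offset = focal_offset),
            class = "ommatidium")
}

#' Eye description: an ordered collection of ommatidia
#'
#' The ordered set of ommatidia is the unit of eye design; the order defines
#' the index space of every ommatidial view rendered from this eye.
#'
#' @param positions n x 3 matrix of ommatidial positions (mm, eye-local frame),
#'   or a list of [ommatidium()] objects (in which case the remaining geometry
#'   arguments are ignored).
#' @param axes n x 3 matrix of ommatidial axes; each row must be unit within
#'   `1e-3` (renormalised).
#' @param acceptance_angles vector of full cone angles, radians, recycled.
#' @param focal_offsets vector of focal offsets, mm, recycled.
#' @param labels optional per-ommatidium `"left"`/`"right"` tags.
#' @param name free-text identifier.
#' @return an object of class `eye_description` with elements `ommatidia`
#'   (a data frame with columns `px, py, pz, dx, dy, dz, acceptance,
#'   focal_offset`), `labels` and `name`.
#' @seealso [make_spherical_eye()], [make_acute_zone_eye()], [load_eye_csv()]
#' @export
eye_description <- function(positions, axes = NULL, acceptance_angles = NULL,
                            focal_offsets = 0, labels = NULL, name = "") {
  if (is.list(positions) && !is.data.frame(positions) && !is.matrix(positions)) {
    oms <- positions
    if (!length(oms) || !all(vapply(oms, inherits, TRUE, "ommatidium")))
      stopf("expected a non-empty list of ommatidium objects")
    positions <- do.call(rbind, lapply(oms, `[[`, "position"))
    axes <- do.call(rbind, lapply(oms, `[[`, "axis"))
    acceptance_angles <- vapply(oms, `[[`, 0, "acceptance_angle")
    focal_offsets <- vapply(oms, `[[`, 0, "focal_offset")
  }
  positions <- as.matrix(positions)
  axes <- as.matrix(axes)
  if (!nrow(positions)) stopf("an eye must contain at least one ommatidium")
  if (ncol(positions) != 3L || ncol(axes) != 3L || nrow(axes) != nrow(positions))
    stopf("positions and axes must be n x 3 matrices of equal row count")
  if (any(!is.finite(positions)) || any(!is.finite(axes)))
    stopf("positions and axes must be finite")
  n <- nrow(positions)
  norms <- row_norms(axes)
  bad <- which(abs(norms - 1) > 1e-3 | norms < 1e-6)
  if (length(bad))
    stopf("axis norm out of tolerance at ommatidium %d (norm %.6g)",
          bad[1], norms[bad[1]])
  axes <- axes / norms
  acceptance_angles <- rep_len(as.numeric(acceptance_angles), n)
  focal_offsets <- rep_len(as.numeric(focal_offsets), n)
  if (any(!is.finite(acceptance_angles)) ||
      any(acceptance_angles < 0) || any(acceptance_angles > pi))
    stopf("acceptance angles must lie in [0, pi]")
  if (any(!is.finite(focal_offsets))) stopf("focal offsets must be finite")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n || !all(labels %in% c("left", "right")))
      stopf("labels must be one 'left'/'right' tag per ommatidium")
  }
  structure(list(
    ommatidia = data.frame(px = positions[, 1], py = positions[, 2],
                           pz = positions[, 3], dx = axes[, 1], dy = axes[, 2],
                           dz = axes[, 3], acceptance = acceptance_angles,
                           focal_offset = focal_offsets),
    labels = labels, name = as.character(name)[1]),
    class = "eye_description")
}

#' @export
print.eye_description <- function(x, ...) {
  acc <- range(x$ommatidia$acceptance) * 180 / pi
  cat(sprintf("<eye_description> '%s': %d ommatidia, acceptance %.2f-%.2f deg%s\n",
              x$name, nrow(x$ommatidia), acc[1], acc[2],
              if (is.null(x$labels)) "" else ", left/right labelled"))
  invisible(x)
}

#' Number of ommatidia in an eye
#' @param eye an `eye_description`.
#' @export
n_ommatidia <- function(eye) nrow(eye$ommatidia)

#' Ommatidial positions as a matrix
#' @param eye an `eye_description`.
#' @return n x 3 matrix, millimetres, eye-local frame.
#' @export
eye_positions <- function(eye) {
  unname(as.matrix(eye$ommatidia[, c("px", "py", "pz")]))
}

#' Ommatidial axes as a matrix
#' @param eye an `eye_description`.
#' @return n x 3 matrix of unit rows.
#' @export
eye_axes <- function(eye) {
  unname(as.matrix(eye$ommatidia[, c("dx", "dy", "dz")]))
}

eye_csv_header <- c("px", "py", "pz", "dx", "dy", "dz", "acceptance", "focal_offset")

#' Read an eye description from CSV
#'
#' The dialect is one header line
#' `px,py,pz,dx,dy,dz,acceptance,focal_offset[,label]` followed by one row per
#' ommatidium; positions in millimetres, angles in radians. Whitespace-
#' separated header-less files are also accepted (with a warning) for
#' compatibility with hand-made tables.
#'
#' @param path file to read.
#' @return an [eye_description()]; row order is preserved.
#' @export
load_eye_csv <- function(path) {
  if (!file.exists(path)) stopf("eye file '%s' does not exist", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stopf("eye file '%s' is empty", path)
  has_header <- grepl("px", first, fixed = TRUE)
  if (has_header) {
    df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  } else {
    warning(sprintf("eye file '%s' has no header; reading whitespace/comma separated columns",
                    path), call. = FALSE)
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            sep = if (grepl(",", first, fixed = TRUE)) "," else "")
  }
  if (ncol(df) < 8L)
    stopf("eye file '%s': expected >= 8 columns, found %d", path, ncol(df))
  num <- df[, 1:8]
  for (j in 1:8) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (any(is.na(v)))
      stopf("eye file '%s': non-numeric value in column %d, row %d",
            path, j, which(is.na(v))[1])
    num[[j]] <- v
  }
  axes <- as.matrix(num[, 4:6])
  norms <- row_norms(axes)
  bad <- which(abs(norms - 1) > 1e-3 | norms < 1e-6)
  if (length(bad))
    stopf("eye file '%s': axis norm %.6g out of tolerance at data row %d",
          path, norms[bad[1]], bad[1])
  if (any(num[[7]] < 0 | num[[7]] > pi))
    stopf("eye file '%s': acceptance angle outside [0, pi] at data row %d",
          path, which(num[[7]] < 0 | num[[7]] > pi)[1])
  labels <- NULL
  if (ncol(df) >= 9L) {
    lab <- as.character(df[[9]])
    if (any(nzchar(lab))) labels <- lab
  }
  eye_description(as.matrix(num[, 1:3]), axes, num[[7]], num[[8]],
                  labels = labels,
                  name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an eye description to CSV
#'
#' Writes the dialect read by [load_eye_csv()]; numeric fields use full
#' `%.17g` precision so a round trip reproduces every field.
#'
#' @param eye an [eye_description()].
#' @param path file to write.
#' @export
save_eye_csv <- function(eye, path) {
  stopifnot(inherits(eye, "eye_description"))
  om <- eye$ommatidia
  header <- paste(c(eye_csv_header, if (!is.null(eye$labels)) "label"),
                  collapse = ",")
  rows <- apply(as.matrix(om), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  if (!is.null(eye$labels)) rows <- paste(rows, eye$labels, sep = ",")
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write eye file '%s'", path)
  invisible(path)
}

#' Collapse all ommatidial viewpoints to a single point
#'
#' Replaces every ommatidial position with the centroid of all positions,
#' keeping axes, acceptance angles, order and labels unchanged. This is the
#' "single" eye design: one shared viewpoint for the whole eye pair, the
#' assumption made by single-viewpoint compound-eye models.
#'
#' @param eye an [eye_description()].
#' @return a new `eye_description`.
#' @export
collapse_to_single <- function(eye) {
  stopifnot(inherits(eye, "eye_description"))
  ctr <- colMeans(eye_positions(eye))
  out <- eye
  out$ommatidia$px <- rep(ctr[1], n_ommatidia(eye))
  out$ommatidia$py <- rep(ctr[2], n_ommatidia(eye))
  out$ommatidia$pz <- rep(ctr[3], n_ommatidia(eye))
  out$name <- paste0(eye$name, "_single")
  out
}

#' Collapse ommatidial viewpoints to their per-eye centres
#'
#' Replaces each ommatidium's position with the centroid of its labelled eye
#' (left or right), keeping per-ommatidial headings. This is the "split" eye
#' design: two viewpoints, one per eye, as in classical binocular models.
#'
#' @param eye an [eye_description()] with left/right labels.
#' @param auto_label if `TRUE` and the eye is unlabelled, derive labels from
#'   the sign of the x coordinate (negative x = left). Off by default:
#'   silent guessing of eye sides is unsafe.
#' @return a new `eye_description`.
#' @export
collapse_to_split <- function(eye, auto_label = FALSE) {
  stopifnot(inherits(eye, "eye_description"))
  labels <- eye$labels
  if (is.null(labels)) {
    if (!auto_label)
      stopf("eye has no left/right labels; pass auto_label = TRUE to derive them from the x coordinate")
    labels <- ifelse(eye$ommatidia$px < 0, "left", "right")
  }
  pos <- eye_positions(eye)
  out <- eye
  for (side in unique(labels)) {
    sel <- labels == side
    ctr <- colMeans(pos[sel, , drop = FALSE])
    out$ommatidia$px[sel] <- ctr[1]
    out$ommatidia$py[sel] <- ctr[2]
    out$ommatidia$pz[sel] <- ctr[3]
  }
  out$labels <- labels
  out$name <- paste0(eye$name, "_split")
  out
}
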