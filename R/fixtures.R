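# Programmatic fixture scenes. All fixtures are self-contained: textures and
# meshes are generated in code, no files on disk are required.

#' Geometry constants of the concentric-rings fixture
#'
#' @return a list with the plane distance (mm, along +z from the origin), the
#'   square plane extent, the ring inner radii, the ring width, the ring grey
#'   level and the texture resolution.
#' @export
rings_plane_geometry <- function() {
  list(distance = 50, extent = 200, radii = c(10, 20, 30), width = 4,
       grey = 0.3, tex_size = 512L)
}

#' Analytic colour of the concentric-rings plane
#'
#' Ground-truth colour of the rings pattern at plane coordinates `(x, y)`:
#' dark grey on a ring annulus, white elsewhere. This closed form is the
#' oracle against which the textured mesh is checked.
#'
#' @param x,y plane coordinates in millimetres (vectorised).
#' @return a matrix with one RGB row per point.
#' @export
rings_plane_colour <- function(x, y) {
  g <- rings_plane_geometry()
  r <- sqrt(x^2 + y^2)
  on_ring <- rep(FALSE, length(r))
  for (r0 in g$radii) on_ring <- on_ring | (r >= r0 & r <= r0 + g$width)
  v <- ifelse(on_ring, g$grey, 1)
  cbind(v, v, v)
}

#' White plane with three concentric dark-grey rings
#'
#' A white plane at `distance` millimetres in front of the origin (normal
#' facing the -z viewer), textured with three concentric dark-grey rings
#' centred on the z axis. Used by the aliasing demonstrations: a static
#' concentric sampling pattern can miss every ring, while stochastic cone
#' sampling recovers them. Constants come from [rings_plane_geometry()];
#' [rings_plane_colour()] is the analytic pattern oracle.
#'
#' @return an [scene()] with one textured mesh and white background.
#' @export
fixture_rings_plane <- function() {
  g <- rings_plane_geometry()
  h <- g$extent / 2
  ts <- g$tex_size
  # texel centre (row i, col j) maps to v=(i-0.5)/ts, u=(j-0.5)/ts
  cc <- ((seq_len(ts) - 0.5) / ts) * g$extent - h
  xg <- matrix(cc, ts, ts, byrow = TRUE)   # u -> x
  yg <- matrix(cc, ts, ts)                 # v -> y
  col <- rings_plane_colour(as.vector(xg), as.vector(yg))[, 1]
  tex <- array(rep(matrix(col, ts, ts), 3L), c(ts, ts, 3L))
  verts <- cbind(c(-h, h, h, -h), c(-h, -h, h, h), rep(g$distance, 4))
  uv <- cbind((verts[, 1] + h) / g$extent, (verts[, 2] + h) / g$extent)
  mesh <- triangle_mesh(verts, rbind(c(1, 2, 3), c(1, 3, 4)), uv)
  scene(list(mesh), list(material(c(1, 1, 1), tex)),
        background = c(1, 1, 1))
}

# one checkered face of the lab box; returns list(black = quads, white = quads)
lab_box_face <- function(corner, e1, e2, ndiv, parity) {
  black <- list()
  white <- list()
  for (i in seq_len(ndiv) - 1L) {
    for (j in seq_len(ndiv) - 1L) {
      p00 <- corner + (i / ndiv) * e1 + (j / ndiv) * e2
      p10 <- corner + ((i + 1) / ndiv) * e1 + (j / ndiv) * e2
      p11 <- corner + ((i + 1) / ndiv) * e1 + ((j + 1) / ndiv) * e2
      p01 <- corner + (i / ndiv) * e1 + ((j + 1) / ndiv) * e2
      quad <- rbind(p00, p10, p11, p01)
      if ((i + j + parity) %% 2L == 0L) black[[length(black) + 1L]] <- quad
      else white[[length(white) + 1L]] <- quad
    }
  }
  list(black = black, white = white)
}

quads_to_mesh <- function(quads) {
  verts <- do.call(rbind, quads)
  nq <- length(quads)
  base <- (seq_len(nq) - 1L) * 4L
  tris <- rbind(cbind(base + 1L, base + 2L, base + 3L),
                cbind(base + 1L, base + 3L, base + 4L))
  triangle_mesh(verts, tris)
}

#' Closed high-contrast black/white lab box
#'
#' A closed cube of the given side, centred on the origin, whose six walls
#' carry a 4 x 4 black/white checker pattern built from flat-material quads
#' (alternating parity per face, so the box contains both pure black and pure
#' white faces). The stark contrast makes it a worst-case scene for sampling
#' noise, in the spirit of the high-contrast arenas used in insect cognition
#' experiments.
#'
#' @param side inner side length, millimetres.
#' @return an [scene()] with two flat meshes (black quads, white quads).
#' @export
fixture_lab_box <- function(side = 200) {
  if (!is_number(side) || side <= 0) stopf("side must be positive")
  h <- side / 2
  faces <- list(
    lab_box_face(c(-h, -h, -h), c(side, 0, 0), c(0, side, 0), 4L, 0L),  # z = -h
    lab_box_face(c(-h, -h,  h), c(side, 0, 0), c(0, side, 0), 4L, 1L),  # z = +h
    lab_box_face(c(-h, -h, -h), c(side, 0, 0), c(0, 0, side), 4L, 0L),  # y = -h
    lab_box_face(c(-h,  h, -h), c(side, 0, 0), c(0, 0, side), 4L, 1L),  # y = +h
    lab_box_face(c(-h, -h, -h), c(0, side, 0), c(0, 0, side), 4L, 0L),  # x = -h
    lab_box_face(c( h, -h, -h), c(0, side, 0), c(0, 0, side), 4L, 1L))  # x = +h
  black <- do.call(c, lapply(faces, `[[`, "black"))
  white <- do.call(c, lapply(faces, `[[`, "white"))
  scene(list(quads_to_mesh(black), quads_to_mesh(white)),
        list(material(c(0, 0, 0)), material(c(1, 1, 1))),
        background = c(1, 1, 1))
}

#' Icosphere mesh
#'
#' Icosahedron subdivided until the maximum chord error (sagitta of the
#' longest edge) is below `chord_tol` times the radius, vertices projected to
#' the sphere.
#'
#' @param radius sphere radius, mm.
#' @param centre sphere centre, 3-vector.
#' @param chord_tol relative chord-error bound (default 1%).
#' @return a [triangle_mesh()].
#' @export
icosphere <- function(radius = 1, centre = c(0, 0, 0), chord_tol = 0.01) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / row_norms(V)
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  edge_angle <- function(V, F) {
    e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
    max(acos(pmin(1, rowSums(V[e[, 1], ] * V[e[, 2], ]))))
  }
  while (1 - cos(edge_angle(V, F) / 2) > chord_tol) {
    mid <- new.env()
    nv <- nrow(V)
    Vl <- lapply(seq_len(nv), function(i) V[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (is.null(id)) {
        m <- Vl[[a]] + Vl[[b]]
        Vl[[length(Vl) + 1L]] <<- m / sqrt(sum(m^2))
        id <- length(Vl)
        mid[[key]] <- id
      }
      id
    }
    Fn <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; cc <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      Fn <- rbind(Fn, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    V <- do.call(rbind, Vl)
    F <- Fn
  }
  triangle_mesh(sweep(radius * V, 2, centre, "+"), F)
}

#' Matte white world with a small black sphere
#'
#' An unbounded matte white environment (white miss colour) containing a
#' single matte black sphere, the target of the localisation experiment.
#'
#' @param sphere_diameter sphere diameter, millimetres.
#' @param sphere_centre sphere centre, world frame.
#' @return an [scene()].
#' @export
fixture_white_world_sphere <- function(sphere_diameter = 2,
                                       sphere_centre = c(0, 0, 0)) {
  if (!is_number(sphere_diameter) || sphere_diameter <= 0)
    stopf("sphere_diameter must be positive")
  mesh <- icosphere(sphere_diameter / 2, as_vec3(sphere_centre, "sphere_centre"))
  scene(list(mesh), list(material(c(0, 0, 0))), background = c(1, 1, 1))
}
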