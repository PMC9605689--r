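# Shared fixtures and independent oracles for the test suite.

deg <- function(x) x * pi / 180

# random eye with unit axes
random_eye <- function(n, seed) {
  set.seed(seed)
  axes <- matrix(rnorm(3 * n), n, 3)
  axes <- axes / sqrt(rowSums(axes^2))
  eye_description(matrix(runif(3 * n, -5, 5), n, 3), axes,
                  runif(n, 0.01, pi), runif(n, -1, 1),
                  labels = if (n %% 2 == 0) rep(c("left", "right"), n / 2),
                  name = sprintf("rand%d", seed))
}

# uniform directions on the sphere
random_dirs <- function(n, seed) {
  set.seed(seed)
  d <- matrix(rnorm(3 * n), n, 3)
  d / sqrt(rowSums(d^2))
}

# axis-aligned unit cube mesh (12 triangles) centred at `centre`
cube_mesh <- function(side = 1, centre = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, centre, "+")
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  triangle_mesh(v, f)
}

# scene of random triangle soup
random_soup_scene <- function(n_tri, seed, spread = 10) {
  set.seed(seed)
  v <- matrix(runif(9 * n_tri, -spread, spread), 3 * n_tri, 3)
  triangles <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  scene(list(triangle_mesh(v, triangles)), list(material(c(0.5, 0.5, 0.5))),
        background = c(1, 1, 1))
}

# Independent Moller-Trumbore nearest-hit oracle over all triangles of a
# scene (plain R). Ties on t broken towards the lowest (mesh, tri) index.
mt_intersect <- function(sc, origin, dir, t_min = 1e-6) {
  best <- list(hit = FALSE, t = Inf, mesh = NA_integer_, tri = NA_integer_,
               b1 = NA_real_, b2 = NA_real_)
  crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  for (mi in seq_along(sc$meshes)) {
    m <- sc$meshes[[mi]]
    for (fi in seq_len(nrow(m$triangles))) {
      idx <- m$triangles[fi, ]
      v0 <- m$vertices[idx[1], ]; v1 <- m$vertices[idx[2], ]
      v2 <- m$vertices[idx[3], ]
      e1 <- v1 - v0; e2 <- v2 - v0
      p <- crossp(dir, e2)
      det <- sum(e1 * p)
      if (abs(det) < 1e-14) next
      s <- origin - v0
      u <- sum(s * p) / det
      if (u < 0 || u > 1) next
      q <- crossp(s, e1)
      v <- sum(dir * q) / det
      if (v < 0 || u + v > 1) next
      t <- sum(e2 * q) / det
      if (t <= t_min) next
      if (t < best$t) best <- list(hit = TRUE, t = t, mesh = mi, tri = fi,
                                   b1 = u, b2 = v)
    }
  }
  best
}

# half-black / half-white wall: plane z = d, black for x < 0, white for x >= 0
half_wall_scene <- function(d = 10, extent = 4000) {
  mk <- function(x0, x1) {
    triangle_mesh(cbind(c(x0, x1, x1, x0), c(-extent, -extent, extent, extent),
                        rep(d, 4)),
                  rbind(c(1, 2, 3), c(1, 3, 4)))
  }
  scene(list(mk(-extent, 0), mk(0, extent)),
        list(material(c(0, 0, 0)), material(c(1, 1, 1))),
        background = c(0.5, 0.5, 0.5))
}

# uniform-colour closed world (lab-box geometry, single colour everywhere)
uniform_scene <- function(col = c(0.3, 0.7, 0.2)) {
  sc <- fixture_lab_box(100)
  sc$materials <- list(material(col), material(col))
  sc$background <- col
  sc
}
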