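test_that("scene constructors validate geometry and colours", {
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  expect_error(material(c(1.2, 0, 0)), "\\[0, 1\\]")
  expect_error(scene(list(cube_mesh()), list()), "one material per mesh")
  sc <- scene(list(cube_mesh()), list(material(c(1, 0, 0))))
  expect_s3_class(sc, "eye_scene")
})

test_that("a cube plus a perspective camera survives the glTF round trip", {
  dir <- withr::local_tempdir()
  sc <- scene(list(cube_mesh(side = 2, centre = c(0, 1, 5))),
              list(material(c(0.2, 0.4, 0.8))), background = c(0.1, 0.2, 0.3),
              cameras = list(camera_spec("perspective",
                                         eye_pose(c(1, 2, 3),
                                                  quat_from_axis_angle(c(0, 1, 0), 0.4)),
                                         name = "debug", yfov = 0.9)))
  path <- file.path(dir, "cube.gltf")
  save_gltf(sc, path)
  back <- load_gltf(path)
  expect_length(back$meshes, 1)
  expect_equal(nrow(back$meshes[[1]]$triangles), 12)
  expect_lt(max(abs(back$meshes[[1]]$vertices - sc$meshes[[1]]$vertices)), 1e-6)
  expect_identical(back$meshes[[1]]$triangles, sc$meshes[[1]]$triangles)
  expect_equal(back$materials[[1]]$base_colour, c(0.2, 0.4, 0.8),
               tolerance = 1e-12)
  expect_equal(back$background, c(0.1, 0.2, 0.3), tolerance = 1e-12)
  expect_length(back$cameras, 1)
  cam <- back$cameras[[1]]
  expect_identical(cam$kind, "perspective")
  expect_identical(cam$name, "debug")
  expect_equal(cam$yfov, 0.9, tolerance = 1e-12)
  expect_equal(cam$pose$position, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(quat_to_matrix(cam$pose$quaternion),
               quat_to_matrix(quat_from_axis_angle(c(0, 1, 0), 0.4)),
               tolerance = 1e-9)
})

test_that("textured fixtures and compound/panoramic cameras round trip", {
  dir <- withr::local_tempdir()
  eye <- make_spherical_eye(7, deg(5))
  save_eye_csv(eye, file.path(dir, "eye.csv"))
  sc <- fixture_rings_plane()
  sc$cameras <- list(
    camera_spec("compound", eye_pose(c(0, 0, -5)), name = "bug",
                eye_csv = "eye.csv", projection_hint = "orientation"),
    camera_spec("panoramic", name = "pano"),
    camera_spec("orthographic", name = "ortho", xmag = 3, ymag = 2))
  path <- file.path(dir, "rings.gltf")
  save_gltf(sc, path)
  back <- load_gltf(path)
  expect_lt(max(abs(back$meshes[[1]]$vertices - sc$meshes[[1]]$vertices)), 1e-6)
  expect_lt(max(abs(back$meshes[[1]]$uv - sc$meshes[[1]]$uv)), 1e-6)
  # textures pass through 8-bit PNG quantisation
  expect_lt(max(abs(back$materials[[1]]$texture - sc$materials[[1]]$texture)),
            1 / 255 + 1e-9)
  kinds <- vapply(back$cameras, `[[`, "", "kind")
  expect_identical(kinds, c("compound", "panoramic", "orthographic"))
  expect_equal(back$cameras[[3]]$xmag, 3)
  bug <- back$cameras[[1]]
  expect_identical(bug$projection_hint, "orientation")
  linked <- camera_eye(bug)
  expect_equal(as.matrix(linked$ommatidia), as.matrix(eye$ommatidia),
               tolerance = 1e-6)
})

test_that("a compound camera linking a missing eye file names camera and path", {
  dir <- withr::local_tempdir()
  eye <- make_spherical_eye(3, deg(5))
  save_eye_csv(eye, file.path(dir, "eye.csv"))
  sc <- scene(list(cube_mesh()), list(material()),
              cameras = list(camera_spec("compound", name = "broken",
                                         eye_csv = "gone.csv")))
  path <- file.path(dir, "bad.gltf")
  save_gltf(sc, path)
  expect_error(load_gltf(path), "broken")
  expect_error(load_gltf(path), "gone\\.csv")
  expect_error(load_gltf(file.path(dir, "missing.gltf")), "exist")
})

test_that("GLB containers load identically to their JSON form", {
  dir <- withr::local_tempdir()
  sc <- scene(list(cube_mesh(2)), list(material(c(0.9, 0.1, 0.1))))
  gltf <- file.path(dir, "c.gltf")
  save_gltf(sc, gltf)
  # repack as GLB: JSON chunk (buffer made external to the container) + BIN
  doc <- jsonlite::fromJSON(gltf, simplifyVector = FALSE)
  bin <- jsonlite::base64_dec(sub("^data:[^,]*,", "", doc$buffers[[1]]$uri))
  doc$buffers[[1]]$uri <- NULL
  json <- charToRaw(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  pad <- function(x, b) c(x, rep(b, (4 - length(x) %% 4) %% 4))
  json <- pad(json, charToRaw(" "))
  bin <- pad(bin, as.raw(0))
  glb <- file.path(dir, "c.glb")
  con <- file(glb, "wb")
  writeBin(c(0x46546C67L, 2L, 28L + length(json) + length(bin)), con,
           size = 4, endian = "little")
  writeBin(c(length(json), 0x4E4F534AL), con, size = 4, endian = "little")
  writeBin(json, con)
  writeBin(c(length(bin), 0x004E4942L), con, size = 4, endian = "little")
  writeBin(bin, con)
  close(con)
  a <- load_gltf(gltf)
  b <- load_gltf(glb)
  expect_equal(b$meshes[[1]]$vertices, a$meshes[[1]]$vertices)
  expect_identical(b$meshes[[1]]$triangles, a$meshes[[1]]$triangles)
})

test_that("glTF node transforms are applied to mesh vertices", {
  dir <- withr::local_tempdir()
  sc <- scene(list(cube_mesh(2)), list(material()))
  path <- file.path(dir, "t.gltf")
  save_gltf(sc, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$nodes[[1]]$translation <- list(5, 0, 0)
  doc$nodes[[1]]$rotation <- list(0, 1, 0, 0)  # 180 deg about +y (x,y,z,w)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  back <- load_gltf(path)
  v <- sc$meshes[[1]]$vertices
  expect_equal(back$meshes[[1]]$vertices,
               cbind(5 - v[, 1], v[, 2], -v[, 3]), tolerance = 1e-6)
})

test_that("non-triangle glTF primitives are rejected", {
  dir <- withr::local_tempdir()
  sc <- scene(list(cube_mesh()), list(material()))
  path <- file.path(dir, "l.gltf")
  save_gltf(sc, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$meshes[[1]]$primitives[[1]]$mode <- 1L  # LINES
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  expect_error(load_gltf(path), "non-triangulable")
})

test_that("rings fixture matches its analytic pattern away from ring edges", {
  g <- rings_plane_geometry()
  sc <- fixture_rings_plane()
  expect_true(all(sc$meshes[[1]]$vertices[, 3] == g$distance))
  a <- build_accel(sc)
  # points at least 2 texels from every ring boundary
  set.seed(42)
  texel <- g$extent / g$tex_size
  pts <- matrix(runif(4000, -g$extent / 2 + 1, g$extent / 2 - 1), ncol = 2)
  r <- sqrt(rowSums(pts^2))
  edges <- sort(c(g$radii, g$radii + g$width))
  dist_edge <- apply(abs(outer(r, edges, "-")), 1, min)
  keep <- which(dist_edge > 2 * texel)[1:1000]
  pts <- pts[keep, ]
  dirs <- cbind(pts[, 1], pts[, 2], g$distance)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  got <- render_rays(a, matrix(0, 1, 3), dirs)
  want <- rings_plane_colour(pts[, 1], pts[, 2])
  expect_lt(max(abs(got - want)), 1e-12)
  # a ray at a ring centre-line is dark grey
  ring_dir <- matrix(c(12, 0, 50) / sqrt(12^2 + 50^2), 1)
  expect_equal(render_rays(a, matrix(0, 1, 3), ring_dir)[1, ],
               rep(g$grey, 3), tolerance = 1e-12)
})

test_that("the lab box is closed and carries pure black and white faces", {
  sc <- fixture_lab_box(side = 200)
  b <- do.call(rbind, lapply(sc$meshes, function(m) m$vertices))
  expect_equal(apply(b, 2, min), rep(-100, 3), ignore_attr = TRUE)
  expect_equal(apply(b, 2, max), rep(100, 3), ignore_attr = TRUE)
  expect_equal(sc$materials[[1]]$base_colour, c(0, 0, 0))
  expect_equal(sc$materials[[2]]$base_colour, c(1, 1, 1))
  a <- build_accel(sc)
  dirs <- random_dirs(1e5, seed = 7)
  set.seed(8)
  org <- matrix(runif(3e5, -80, 80), 1e5, 3)
  h <- intersect_rays(a, org, dirs)
  expect_equal(mean(!h$hit), 0)
})

test_that("white-world sphere occludes the closed-form solid angle", {
  sc <- fixture_white_world_sphere(sphere_diameter = 2)
  a <- build_accel(sc)
  # aimed at the centre: black; aimed away: white
  expect_equal(render_rays(a, c(0, 0, -10), matrix(c(0, 0, 1), 1))[1, ],
               c(0, 0, 0))
  expect_equal(render_rays(a, c(0, 0, -10), matrix(c(0, 0, -1), 1))[1, ],
               c(1, 1, 1))
  d <- 10
  n <- 2e5
  dirs <- random_dirs(n, seed = 3)
  cols <- render_rays(a, c(0, 0, -d), dirs)
  frac <- mean(cols[, 1] == 0)
  want <- 2 * pi * (1 - cos(asin(1 / d))) / (4 * pi)
  se <- sqrt(want * (1 - want) / n)
  expect_lt(abs(frac - want), 3 * se + 1e-4)  # + icosphere chord tolerance
})

test_that("icosphere vertices sit on the sphere with bounded chord error", {
  m <- icosphere(radius = 3, centre = c(1, 2, 3), chord_tol = 0.01)
  r <- sqrt(rowSums(sweep(m$vertices, 2, c(1, 2, 3))^2))
  expect_equal(r, rep(3, nrow(m$vertices)), tolerance = 1e-9)
  e <- rbind(m$triangles[, 1:2], m$triangles[, 2:3], m$triangles[, c(3, 1)])
  mid <- (m$vertices[e[, 1], ] + m$vertices[e[, 2], ]) / 2
  sag <- 3 - sqrt(rowSums(sweep(mid, 2, c(1, 2, 3))^2))
  expect_lt(max(sag), 0.01 * 3)
})
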