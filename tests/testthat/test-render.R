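test_that("fwhm_sigma implements the FWHM-to-sigma conversion", {
  expect_identical(fwhm_sigma(0), 0)
  expect_identical(fwhm_sigma(2 * sqrt(2 * log(2))), 1)
  # 1 / (2 sqrt(2 ln 2)), evaluated independently
  expect_equal(fwhm_sigma(1), 0.42466090014400953, tolerance = 1e-14)
})

test_that("sample_direction draws a half-normal angular deviation", {
  sigma <- 0.2
  acc <- sigma * 2 * sqrt(2 * log(2))
  d <- sample_direction(c(0, 0, 1), acc, n = 1e5, seed = 5)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 1e5), tolerance = 1e-9)
  theta <- acos(pmin(1, d[, 3]))
  # half-normal mean sigma*sqrt(2/pi), within 3 standard errors
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(1e5)
  expect_lt(abs(mean(theta) - sigma * sqrt(2 / pi)), 3 * se)
  # goodness of fit against the half-normal CDF at alpha = 0.01
  ks <- stats::ks.test(theta, function(q) 2 * stats::pnorm(q / sigma) - 1)
  expect_gt(ks$p.value, 0.01)
  # azimuths uniform: mean resultant of the planar components is small
  expect_lt(sqrt(sum(colMeans(d[, 1:2] / sin(pmax(theta, 1e-12)))^2)), 0.02)
})

test_that("zero acceptance angle returns the axis exactly", {
  ax <- c(0.6, 0.8, 0)
  d <- sample_direction(ax, 0, n = 4, seed = 9)
  expect_identical(d, matrix(rep(ax, each = 4), 4))
  expect_error(sample_direction(c(0, 0, 0), 0.1), "non-zero")
})

test_that("angular deviations are truncated at pi", {
  d <- sample_direction(c(0, 0, 1), pi, n = 2e4, seed = 13)
  theta <- acos(pmin(1, pmax(-1, d[, 3])))
  expect_true(all(theta <= pi))
  expect_equal(sqrt(rowSums(d^2)), rep(1, 2e4), tolerance = 1e-9)
})

test_that("a uniform-colour world renders to exactly that colour", {
  col <- c(0.3, 0.7, 0.2)
  sc <- uniform_scene(col)
  eye <- make_spherical_eye(40, deg(20))
  for (N in c(1L, 7L)) {
    v <- render_eye(sc, eye, cfg = sampler_config(N, rng_seed = 3))
    expect_identical(unname(unclass(v)[, 1]), rep(col[1], 40))
    expect_identical(unname(unclass(v)[, 2]), rep(col[2], 40))
    expect_identical(unname(unclass(v)[, 3]), rep(col[3], 40))
  }
  # the weighted-cone measure shares the exactness
  vw <- render_eye(sc, eye, cfg = sampler_config(5, rng_seed = 3,
                                                 measure = "weighted_cone"))
  expect_identical(unname(unclass(vw)[, 1]), rep(col[1], 40))
  o <- ommatidium(c(0, 0, 0), c(0, 0, 1), deg(30))
  expect_identical(render_ommatidium(sc, o, cfg = sampler_config(9, rng_seed = 1)),
                   col)
})

test_that("an axis on a black/white dividing line averages to grey", {
  sc <- half_wall_scene(d = 10)
  o <- ommatidium(c(0, 0, 0), c(0, 0, 1), acceptance_angle = 0.5)
  N <- 400L
  v <- render_ommatidium(sc, o, cfg = sampler_config(N, rng_seed = 17))
  expect_lt(abs(mean(v) - 0.5), 3 * 0.5 / sqrt(N))
})

test_that("frame-to-frame spread scales as one over sqrt(samples)", {
  sc <- build_accel(half_wall_scene(d = 10))
  eye <- eye_description(matrix(0, 1, 3), matrix(c(0, 0, 1), 1), 0.5)
  Ns <- c(4, 16, 64)
  sds <- vapply(Ns, function(N) {
    st <- render_frames(sc, eye, cfg = sampler_config(N, rng_seed = 23),
                        frames = 400)
    mean(ommatidial_sd(st))
  }, 0)
  slope <- coef(lm(log(sds) ~ log(Ns)))[[2]]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("render_eye equals render_ommatidium and is order independent", {
  sc <- build_accel(fixture_rings_plane())
  o <- ommatidium(c(0.5, -0.2, 0), c(0.1, 0.1, 1) / sqrt(1.02), deg(40), 0.3)
  eye1 <- eye_description(matrix(o$position, 1), matrix(o$axis, 1),
                          o$acceptance_angle, o$focal_offset)
  cfg <- sampler_config(16, rng_seed = 29)
  expect_identical(as.numeric(render_eye(sc, eye1, cfg = cfg)),
                   render_ommatidium(sc, o, cfg = cfg))

  eye <- make_spherical_eye(30, deg(25), radius = 0.5)
  v <- render_eye(sc, eye, cfg = cfg)
  set.seed(1)
  perm <- sample(30)
  eye_p <- eye
  eye_p$ommatidia <- eye$ommatidia[perm, ]
  v_p <- render_eye(sc, eye_p, cfg = cfg)
  # each ommatidium keeps its own sampling stream under reordering
  bare <- function(x) matrix(as.numeric(x), nrow(x), 3)
  expect_identical(bare(v_p), bare(v)[perm, ])
})

test_that("renders are bit-identical for a fixed seed and differ across frames", {
  sc <- build_accel(fixture_rings_plane())
  eye <- make_spherical_eye(25, deg(30))
  cfg <- sampler_config(8, rng_seed = 31)
  expect_identical(render_eye(sc, eye, cfg = cfg, frame = 2),
                   render_eye(sc, eye, cfg = cfg, frame = 2))
  expect_false(identical(render_eye(sc, eye, cfg = cfg, frame = 2),
                         render_eye(sc, eye, cfg = cfg, frame = 3)))
  expect_false(identical(render_eye(sc, eye, cfg = sampler_config(8, rng_seed = 32)),
                         render_eye(sc, eye, cfg = cfg)))
})

test_that("frame averaging matches batched rendering and boosts sampling", {
  sc <- build_accel(fixture_rings_plane())
  eye <- make_spherical_eye(10, deg(30))
  cfg <- sampler_config(4, rng_seed = 37)
  singles <- lapply(0:3, function(f) render_eye(sc, eye, cfg = cfg, frame = f))
  avg <- average_frames(singles)
  batched <- render_eye(sc, eye, cfg = sampler_config(4, rng_seed = 37,
                                                      frames_to_average = 4))
  expect_equal(unclass(avg), unclass(batched), tolerance = 1e-14,
               ignore_attr = TRUE)
  bare <- function(x) matrix(as.numeric(x), nrow(x), 3)
  expect_identical(bare(average_frames(list(singles[[1]], singles[[1]]))),
                   bare(singles[[1]]))
  expect_error(average_frames(list()), "non-empty")

  # k frames at N samples estimate the same mean as one frame at k N:
  # paired differences across repeats are centred on zero
  o_eye <- eye_description(matrix(0, 1, 3), matrix(c(0, 0, 1), 1), 0.6)
  reps <- 200
  d <- vapply(seq_len(reps), function(r) {
    a <- average_frames(render_frames(sc, o_eye,
                                      cfg = sampler_config(4, rng_seed = 41),
                                      frames = 4, frame0 = 8 * r))
    b <- render_eye(sc, o_eye, cfg = sampler_config(16, rng_seed = 43),
                    frame = r)
    mean(a) - mean(b)
  }, 0)
  expect_gt(stats::t.test(d)$p.value, 0.01)
})

test_that("traditional cameras project deterministically", {
  # panoramic camera in a uniform world: constant image
  sc <- uniform_scene(c(0.6, 0.5, 0.4))
  img <- render_traditional(sc, camera_spec("panoramic"), 32, 16)
  expect_identical(range(img[, , 1]), c(0.6, 0.6))
  expect_identical(range(img[, , 3]), c(0.4, 0.4))

  # pinhole image of a centred square spans the predicted pixel rows
  a <- 1; dist <- 5; yfov <- 0.9; H <- 101
  sq <- triangle_mesh(rbind(c(-a, -a, dist), c(a, -a, dist),
                            c(a, a, dist), c(-a, a, dist)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  psc <- scene(list(sq), list(material(c(0, 0, 0))))
  pim <- render_traditional(psc, camera_spec("perspective", yfov = yfov),
                            H, H)
  dark_rows <- which(pim[, (H + 1) / 2, 1] == 0)
  # rows whose centre direction satisfies |y| * dist <= a
  yj <- (1 - 2 * (seq_len(H) - 0.5) / H) * tan(yfov / 2)
  want <- which(abs(yj) * dist <= a)
  expect_lte(abs(min(dark_rows) - min(want)), 1)
  expect_lte(abs(max(dark_rows) - max(want)), 1)
  expect_identical(pim, render_traditional(psc,
                                           camera_spec("perspective", yfov = yfov),
                                           H, H))

  # orthographic rays all travel along the camera forward axis
  oim <- render_traditional(psc, camera_spec("orthographic", xmag = 2, ymag = 2),
                            64, 64)
  xs <- (2 * ((seq_len(64) - 0.5) / 64) - 1) * 2
  dark_cols <- which(oim[32, , 1] == 0)
  expect_true(all(abs(xs[dark_cols]) <= a + 2 * (4 / 64)))
  expect_error(render_traditional(psc,
                                  camera_spec("compound", eye_csv = "x.csv")),
               "render_eye")
})

test_that("static concentric sampling misses the rings; stochastic finds them", {
  sc <- build_accel(fixture_rings_plane())
  o <- ommatidium(c(0, 0, 0), c(0, 0, 1), acceptance_angle = deg(70))
  static <- render_ommatidium_static(sc, o, n_rings = 3, n_per_ring = 12)
  expect_equal(static, c(1, 1, 1), tolerance = 1e-6)  # rings aliased away
  stoch <- render_ommatidium(sc, o, cfg = sampler_config(2000, rng_seed = 47))
  expect_lt(mean(stoch), 0.99)   # strictly darker than white
})

test_that("PNG export quantises to 8 bits and round trips", {
  img <- array(runif(32 * 16 * 3), c(16, 32, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  back <- png::readPNG(path)
  expect_lt(max(abs(back - img)), 1 / 255)
  expect_identical(back, round(img * 255) / 255)
})
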