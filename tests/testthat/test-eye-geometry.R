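test_that("ommatidium and eye constructors validate their invariants", {
  o <- ommatidium(c(0, 0, 1), c(0, 0, 1 + 5e-4), deg(5), 0.1)
  expect_equal(sqrt(sum(o$axis^2)), 1, tolerance = 1e-12)
  expect_error(ommatidium(c(0, 0, 1), c(0, 0, 2), deg(5)), "norm")
  expect_error(ommatidium(c(0, 0, 1), c(0, 0, 1), -0.1), "acceptance")
  expect_error(ommatidium(c(0, 0, 1), c(0, 0, 1), pi + 0.1), "acceptance")
  expect_error(ommatidium(c(0, 0, 1), c(0, 0, 1), deg(5), Inf), "focal")

  expect_error(eye_description(matrix(0, 0, 3), matrix(0, 0, 3), 1),
               "at least one")
  axes <- rbind(c(0, 0, 1), c(0, 1, 0), c(0, 0, 3))
  expect_error(eye_description(diag(3), axes, 0.1), "ommatidium 3")

  eye <- eye_description(list(ommatidium(c(1, 0, 0), c(1, 0, 0), 0.2),
                              ommatidium(c(0, 1, 0), c(0, 1, 0), 0.3)))
  expect_equal(n_ommatidia(eye), 2)
  expect_equal(eye$ommatidia$acceptance, c(0.2, 0.3))
})

test_that("a well-formed CSV loads one ommatidium per row, in order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("px,py,pz,dx,dy,dz,acceptance,focal_offset",
               "0,0,1,0,0,1,0.1,0",
               "0,1,0,0,1,0,0.2,0.5",
               "1,0,0,1,0,0,0.3,-0.5"), path)
  eye <- load_eye_csv(path)
  expect_equal(n_ommatidia(eye), 3)
  expect_equal(eye$ommatidia$acceptance, c(0.1, 0.2, 0.3))
  expect_equal(eye_positions(eye), rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)))
})

test_that("malformed eye CSV rows are rejected with their row number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("px,py,pz,dx,dy,dz,acceptance,focal_offset",
               "0,0,1,0,0,1,0.1,0",
               "0,1,0,0,0,2,0.2,0"), path)  # axis norm 2
  expect_error(load_eye_csv(path), "row 2")
  writeLines(c("px,py,pz,dx,dy,dz,acceptance,focal_offset",
               "0,0,1,0,0,1,9.1,0"), path)  # acceptance > pi
  expect_error(load_eye_csv(path), "acceptance")
  writeLines(c("px,py,pz,dx,dy,dz,acceptance,focal_offset",
               "0,0,1,0,0,one,0.1,0"), path)
  expect_error(load_eye_csv(path), "non-numeric")
  writeLines("px,py,pz,dx,dy", path)
  expect_error(load_eye_csv(path), "8 columns")
  expect_error(load_eye_csv(file.path(tempdir(), "no-such-eye.csv")), "exist")
})

test_that("CSV round trip is the identity on all fields (100 random eyes)", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (s in 1:100) {
    eye <- random_eye(n = 1 + s %% 7, seed = s)
    save_eye_csv(eye, path)
    back <- load_eye_csv(path)
    expect_lt(max(abs(as.matrix(back$ommatidia) - as.matrix(eye$ommatidia))),
              1e-9)
    expect_identical(back$labels, eye$labels)
  }
})

test_that("CSV writer emits a header plus one row per ommatidium, with labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  eye <- eye_description(matrix(c(0, 0, 1), 1), matrix(c(0, 0, 1), 1), 0.25,
                         name = "")
  save_eye_csv(eye, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  expect_match(lines[1], "^px,py,pz,dx,dy,dz,acceptance,focal_offset$")

  lab <- eye_description(rbind(c(-1, 0, 0), c(1, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 0, 1)), 0.2,
                         labels = c("left", "right"))
  save_eye_csv(lab, path)
  expect_match(readLines(path)[1], "label$")
  expect_identical(load_eye_csv(path)$labels, c("left", "right"))
  expect_error(save_eye_csv(lab, file.path(tempdir(), "no/such/dir/e.csv")),
               "cannot write")
})

test_that("header-less whitespace-separated eye tables load with a warning", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 1 0 0 1 0.1 0", "0 1 0 0 1 0 0.2 0"), path)
  expect_warning(eye <- load_eye_csv(path), "header")
  expect_equal(n_ommatidia(eye), 2)
})

test_that("spherical eye generator is radial, uniform and conventional", {
  e1 <- make_spherical_eye(1, deg(5), radius = 3)
  expect_equal(eye_positions(e1), matrix(c(0, 0, 3), 1))
  expect_equal(eye_axes(e1), matrix(c(0, 0, 1), 1))
  expect_error(make_spherical_eye(0, deg(5)), "n must be")

  eye <- make_spherical_eye(1000, deg(5), radius = 2)
  pos <- eye_positions(eye)
  axes <- eye_axes(eye)
  # radial construction: axis . position = |position|
  expect_equal(rowSums(axes * pos), sqrt(rowSums(pos^2)), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(axes^2)), rep(1, 1000), tolerance = 1e-9)
  # near-uniform placement: nearest-neighbour spacing CV < 0.25
  cp <- axes %*% t(axes)
  diag(cp) <- -1
  nn <- acos(pmin(1, apply(cp, 1, max)))
  expect_lt(sd(nn) / mean(nn), 0.25)
})

test_that("acute-zone eye sharpens and densifies the equatorial band", {
  eye <- make_acute_zone_eye(1500, base_angle = deg(40), acute_angle = deg(8),
                             zone_halfwidth = deg(15))
  lat <- asin(eye_axes(eye)[, 2])
  acc <- eye$ommatidia$acceptance
  in_zone <- abs(lat) <= deg(15)
  expect_gt(sum(in_zone), 0)
  expect_lt(mean(acc[in_zone]), mean(acc[!in_zone]))
  expect_true(all(acc >= deg(8) - 1e-12 & acc <= deg(40) + 1e-12))
  # denser band: per-ommatidium latitude density higher inside the zone
  expect_gt(mean(in_zone) / (sin(deg(15))),          # points per unit z-band
            mean(!in_zone) / (1 - sin(deg(15))))
  # full coverage for a well-sized design
  expect_gte(sum(cone_solid_angle(acc)), 0.9 * 4 * pi)
  expect_error(make_acute_zone_eye(100, deg(5), deg(10)), "acute_angle")
})

test_that("degenerate acute zone reduces to the uniform spherical design", {
  eye <- make_acute_zone_eye(400, base_angle = deg(10), acute_angle = deg(10),
                             zone_halfwidth = pi / 2)
  expect_equal(eye$ommatidia$acceptance, rep(deg(10), 400))
  axes <- eye_axes(eye)
  cp <- axes %*% t(axes)
  diag(cp) <- -1
  nn <- acos(pmin(1, apply(cp, 1, max)))
  ref <- make_spherical_eye(400, deg(10))
  axr <- eye_axes(ref)
  cpr <- axr %*% t(axr)
  diag(cpr) <- -1
  nnr <- acos(pmin(1, apply(cpr, 1, max)))
  expect_equal(mean(nn), mean(nnr), tolerance = 0.1)
  expect_lt(sd(nn) / mean(nn), 0.25)
})

test_that("generators emit unit axes and acceptance angles in [0, pi]", {
  eyes <- list(make_spherical_eye(37, deg(3)),
               make_acute_zone_eye(123, deg(30), deg(6)),
               make_paired_eye(48, deg(12)))
  for (eye in eyes) {
    expect_equal(sqrt(rowSums(eye_axes(eye)^2)), rep(1, n_ommatidia(eye)),
                 tolerance = 1e-9)
    expect_true(all(eye$ommatidia$acceptance >= 0 &
                      eye$ommatidia$acceptance <= pi))
  }
})

test_that("collapse_to_single moves every viewpoint to the centroid", {
  eye <- eye_description(rbind(c(-1, 0, 0), c(1, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 1, 0)), 0.2)
  s <- collapse_to_single(eye)
  expect_equal(eye_positions(s), matrix(0, 2, 3))
  expect_equal(eye_axes(s), eye_axes(eye))
  expect_equal(s$ommatidia$acceptance, eye$ommatidia$acceptance)
  # idempotence
  expect_equal(eye_positions(collapse_to_single(s)), eye_positions(s))
  # any eye: output position variance is zero, direction set identical
  r <- random_eye(30, seed = 4)
  rs <- collapse_to_single(r)
  expect_equal(max(apply(eye_positions(rs), 2, var)), 0)
  expect_equal(eye_axes(rs), eye_axes(r))
})

test_that("collapse_to_split keeps one viewpoint per labelled eye", {
  eye <- eye_description(rbind(c(-1, 0, 10), c(1, 0, 10),
                               c(-1, 0, -10), c(1, 0, -10)),
                         matrix(rep(c(0, 0, 1), 4), 4, 3, byrow = TRUE), 0.2,
                         labels = c("left", "left", "right", "right"))
  s <- collapse_to_split(eye)
  expect_equal(eye_positions(s),
               rbind(c(0, 0, 10), c(0, 0, 10), c(0, 0, -10), c(0, 0, -10)))
  expect_equal(nrow(unique(eye_positions(s))), 2)
  expect_equal(eye_axes(s), eye_axes(eye))

  # all-one-label eye degenerates to the single collapse
  one <- eye_description(rbind(c(-1, 0, 0), c(3, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 1, 0)), 0.2,
                         labels = c("left", "left"))
  expect_equal(eye_positions(collapse_to_split(one)),
               eye_positions(collapse_to_single(one)))

  unl <- eye_description(rbind(c(-1, 0, 0), c(3, 0, 0)),
                         rbind(c(0, 0, 1), c(0, 1, 0)), 0.2)
  expect_error(collapse_to_split(unl), "label")
  auto <- collapse_to_split(unl, auto_label = TRUE)
  expect_identical(auto$labels, c("left", "right"))
})

test_that("collapsing split then single equals collapsing single directly", {
  eye <- random_eye(40, seed = 11)
  expect_equal(eye_positions(collapse_to_single(collapse_to_split(eye))),
               eye_positions(collapse_to_single(eye)), tolerance = 1e-12)
})

test_that("paired eye is bilateral, labelled and FOV-limited", {
  eye <- make_paired_eye(100, deg(15), radius = 1, separation = 3,
                         fov_halfangle = deg(100))
  expect_equal(n_ommatidia(eye), 100)
  expect_identical(eye$labels, rep(c("left", "right"), each = 50))
  axes <- eye_axes(eye)
  expect_true(all(axes[, 3] >= cos(deg(100)) - 1e-12))
  pos <- eye_positions(eye)
  expect_equal(mean(pos[eye$labels == "left", 1]) +
                 mean(pos[eye$labels == "right", 1]), 0, tolerance = 1e-9)
  # ommatidia sit on their eye's sphere
  expect_equal(sqrt(rowSums(sweep(pos[1:50, ], 2, c(-1.5, 0, 0))^2)),
               rep(1, 50), tolerance = 1e-9)
})
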