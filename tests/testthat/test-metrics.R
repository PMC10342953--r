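test_that("displacement decomposition reproduces the Pythagorean examples", {
  d <- decompose_displacement(c(0, 0, 5), c(0, 0, 1))
  expect_equal(unlist(d[c("total", "axial", "inplane", "rel_axial", "rel_inplane")]),
               c(total = 5, axial = 5, inplane = 0, rel_axial = 1, rel_inplane = 0))

  d <- decompose_displacement(c(3, 4, 0), c(0, 0, 1))
  expect_equal(d$total, 5)
  expect_equal(d$axial, 0)
  expect_equal(d$inplane, 5)

  d <- decompose_displacement(c(3, 0, 4), c(0, 0, 1))
  expect_equal(unlist(d[c("total", "axial", "inplane", "rel_axial", "rel_inplane")]),
               c(total = 5, axial = 4, inplane = 3, rel_axial = 0.8, rel_inplane = 0.6))
  expect_equal(d$rel_axial^2 + d$rel_inplane^2, 1, tolerance = 1e-12)

  expect_error(decompose_displacement(c(1, 0, 0), c(0, 0, 2)), "unit")
  z <- decompose_displacement(c(0, 0, 0), c(0, 0, 1))
  expect_true(z$degenerate)
  expect_true(is.na(z$rel_axial) && is.na(z$rel_inplane))
})

test_that("mean plane displacement averages the field over the lumen contour", {
  cyl <- make_cylinder_mesh(radius = 1, length = 1, n_circ = 64)
  pl <- analysis_plane(c(0, 0, 0.5), c(0, 0, 1))

  uniform <- matrix(rep(c(0, 0, 5), each = n_vertices(cyl)), ncol = 3)
  expect_equal(mean_plane_displacement(cyl, uniform, pl), c(0, 0, 5),
               tolerance = 1e-12)

  # pure radial dilation about the plane origin cancels by symmetry
  radial <- cbind(cyl$vertices[, 1], cyl$vertices[, 2], 0) * 0.1
  expect_lt(norm(mean_plane_displacement(cyl, radial, pl), "2"), 1e-6)

  # linear field d(x) = A x: the contour mean equals A times the contour's
  # arc-length mean point (the circle center here)
  A <- matrix(c(0.1, 0.02, 0, -0.03, 0.2, 0.01, 0, 0.05, 0.15), 3, 3)
  lin <- cyl$vertices %*% t(A)
  expect_equal(mean_plane_displacement(cyl, lin, pl),
               drop(A %*% c(0, 0, 0.5)), tolerance = 1e-9)

  # the equal-arc-length resampling estimator agrees with the integral
  # mean at its default sample count
  expect_equal(mean_plane_displacement(cyl, lin, pl, samples = 256),
               drop(A %*% c(0, 0, 0.5)), tolerance = 1e-4)

  expect_error(mean_plane_displacement(cyl, uniform[-1, ], pl), "vertices")
})

test_that("axial tilt equals the constructed rotation angle", {
  n <- c(0, 0, 1)
  expect_equal(axial_tilt(n, n), 0)
  n5 <- drop(rootmotion:::rotate_about_axis(rbind(n), c(1, 0, 0), 5))
  expect_equal(axial_tilt(n, n5), 5, tolerance = 1e-9)
  # orientation-fixed: flipping the systolic normal changes nothing
  expect_equal(axial_tilt(n, -n5), 5, tolerance = 1e-9)

  set.seed(21)
  for (i in 1:50) {
    m <- rootmotion:::normalize3(rnorm(3))
    ms <- if (sum(m * n) < 0) -m else m
    oracle <- atan2(norm(rootmotion:::cross3(n, ms), "2"), sum(n * ms)) * 180 / pi
    expect_equal(axial_tilt(n, m), oracle, tolerance = 1e-12)
  }
  expect_error(axial_tilt(c(0, 0, 2), n), "unit")
})

test_that("aortic rotation matches constructed twists and ignores translation", {
  pl <- analysis_plane(c(0, 0, 0), c(0, 0, 1))
  cen <- c(0, 0, 0)
  ref <- c(17, 3, 0)
  ref_rot <- drop(rootmotion:::rotate_about_axis(rbind(ref), c(0, 0, 1), 10))
  expect_equal(aortic_rotation(cen, cen, ref, ref_rot, pl), 10, tolerance = 1e-9)

  tr <- c(2, -1, 3)
  expect_equal(aortic_rotation(cen, cen + tr, ref, ref + tr, pl), 0,
               tolerance = 1e-9)

  # arbitrary configuration against an explicit 2D atan2 oracle
  set.seed(33)
  for (i in 1:50) {
    c1 <- rnorm(3); c2 <- rnorm(3); r1 <- c1 + rnorm(3); r2 <- c2 + rnorm(3)
    v1 <- r1 - c1; v2 <- r2 - c2
    uv1 <- c(sum(v1 * pl$u), sum(v1 * pl$v))
    uv2 <- c(sum(v2 * pl$u), sum(v2 * pl$v))
    oracle <- abs(atan2(uv1[1] * uv2[2] - uv1[2] * uv2[1],
                        sum(uv1 * uv2))) * 180 / pi
    expect_equal(aortic_rotation(c1, c2, r1, r2, pl), oracle, tolerance = 1e-9)
  }

  expect_error(aortic_rotation(cen, cen, c(0, 0, 5), c(1, 1, 1), pl), "normal")
})

test_that("distensibility follows the area-ratio pressure formula", {
  d <- distensibility(100, 110, 50)
  expect_equal(d$area_ratio, 1.1)
  expect_equal(d$distensibility, 2.0)

  expect_equal(distensibility(250, 250, 60)$distensibility, 0)

  d <- distensibility(314.16, 351.86, 56)
  expect_equal(d$area_ratio, 351.86 / 314.16, tolerance = 1e-12)
  expect_equal(d$distensibility, (351.86 / 314.16 - 1) / 56 * 1e3,
               tolerance = 1e-12)

  # linear in systolic area; doubling pulse pressure halves the value
  a <- distensibility(100, 120, 50)$distensibility
  b <- distensibility(100, 140, 50)$distensibility
  m <- distensibility(100, 130, 50)$distensibility
  expect_equal(m, (a + b) / 2, tolerance = 1e-12)
  expect_equal(distensibility(100, 120, 100)$distensibility, a / 2,
               tolerance = 1e-12)

  expect_error(distensibility(0, 100, 50), "positive")
  expect_error(distensibility(100, 110, 0), "pulse pressure")
})

test_that("LV/Ao angle honours the oriented-normal convention", {
  th <- 2 * pi * (0:11) / 12
  ao <- cbind(10 * cos(th), 10 * sin(th), 50)      # aortic annulus, normal z
  mv <- cbind(12 * cos(th), 12 * sin(th), 30)      # coplanar mitral annulus
  # coaxial limit: oriented normals anti-aligned -> phi = 180
  res <- lv_ao_angle(ao, mv, lv_apex_hint = c(0, 0, 0),
                     aorta_hint = c(0, 0, 100))
  expect_equal(res$phi_deg, 180, tolerance = 1e-9)

  # prescribed 47-degree angle between the annulus axes -> phi = 133
  set.seed(14)
  axis_mv <- c(0, sin(47 * pi / 180), cos(47 * pi / 180))
  e1 <- rootmotion:::normalize3(rootmotion:::cross3(axis_mv, c(1, 0, 0)))
  e2 <- rootmotion:::cross3(axis_mv, e1)
  mv_c <- c(0, -20, 25)
  mv47 <- t(sapply(th, function(a) mv_c + 12 * (cos(a) * e1 + sin(a) * e2)))
  mv47 <- mv47 + matrix(rnorm(length(mv47), sd = 0.01), ncol = 3)
  res <- lv_ao_angle(ao, mv47, lv_apex_hint = mv_c - 30 * axis_mv,
                     aorta_hint = c(0, 0, 100))
  expect_equal(res$phi_deg, 133, tolerance = 0.1)

  expect_error(lv_ao_angle(cbind(1:5, 1:5, 0), mv, c(0, 0, 0), c(0, 0, 100)),
               "collinear")
})

test_that("null deformation yields null metrics", {
  ph <- standard_phantom(circumferential_resolution = 64L,
                         axial_resolution = 33L)
  zero <- matrix(0, n_vertices(ph$mesh), 3)
  m <- compute_root_metrics(ph$mesh, zero, ph$centerline, ph$landmarks, 56)
  expect_equal(m$total_disp, 0)
  expect_equal(m$axial_tilt_deg, 0, tolerance = 1e-9)
  expect_equal(m$rotation_deg, 0, tolerance = 1e-9)
  expect_equal(m$area_ratio, 1, tolerance = 1e-12)
  expect_equal(m$distensibility, 0, tolerance = 1e-12)
  expect_true(is.na(m$rel_axial))
})

test_that("pure axial phantom motion is recovered as purely axial", {
  ph <- standard_phantom(circumferential_resolution = 64L,
                         axial_resolution = 33L)
  def <- apply_deformation(ph, deformation_params(axial_translation = 5))
  m <- compute_root_metrics(ph$mesh, def$field, ph$centerline, ph$landmarks, 56)
  expect_equal(m$total_disp, 5, tolerance = 0.01)
  expect_equal(m$rel_axial, 1, tolerance = 1e-6)
  expect_lt(m$axial_tilt_deg, 1e-6)
})

test_that("relative displacements stay on the unit circle for random fields", {
  set.seed(99)
  for (i in 1:200) {
    d <- decompose_displacement(rnorm(3), rootmotion:::normalize3(rnorm(3)))
    expect_lt(abs(d$rel_axial^2 + d$rel_inplane^2 - 1), 1e-9)
  }
  # and through the full pipeline on random meshes/fields
  ph <- standard_phantom(circumferential_resolution = 32L,
                         axial_resolution = 17L)
  for (i in 1:5) {
    f <- matrix(rnorm(3 * n_vertices(ph$mesh), sd = 0.5), ncol = 3) +
      matrix(rep(rnorm(3, sd = 3), each = n_vertices(ph$mesh)), ncol = 3)
    m <- compute_root_metrics(ph$mesh, f, ph$centerline, ph$landmarks, 56,
                              systolic_planarity_tol = 5)
    expect_lt(abs(m$rel_axial^2 + m$rel_inplane^2 - 1), 1e-9)
  }
})
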