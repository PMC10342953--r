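test_that("plane at the ostia follows the centerline construction", {
  cl <- cbind(0, 0, seq(0, 20, by = 1))
  pl <- plane_at_ostia(cl, c(5, 0, 10), c(-5, 0, 12))
  expect_equal(pl$origin, c(0, 0, 11), tolerance = 1e-9)
  expect_equal(pl$n, c(0, 0, 1), tolerance = 1e-9)

  # reversing the sample order flips the normal, origin unchanged
  pl_rev <- plane_at_ostia(cl[nrow(cl):1, ], c(5, 0, 10), c(-5, 0, 12))
  expect_equal(pl_rev$origin, c(0, 0, 11), tolerance = 1e-9)
  expect_equal(pl_rev$n, c(0, 0, -1), tolerance = 1e-9)

  expect_error(plane_at_ostia(cl, c(5, 0, 30), c(-5, 0, 12)),
               "left coronary ostium")
  expect_error(plane_at_ostia(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 0, 0), c(0, 1, 0)),
               "coincident")
})

test_that("centerline tangent matches the closed-form circle tangent", {
  # quarter circle of radius 30 in the xz-plane
  th <- seq(0, pi / 2, length.out = 200)
  cl <- cbind(30 * cos(th), 0, 30 * sin(th))
  mid <- pi / 4
  p_mid <- c(30 * cos(mid), 0, 30 * sin(mid))
  # ostia chosen symmetric about the arc midpoint
  o1 <- c(30 * cos(mid - 0.05), 0, 30 * sin(mid - 0.05)) + c(0.5, 1, 0)
  o2 <- c(30 * cos(mid + 0.05), 0, 30 * sin(mid + 0.05)) + c(-0.5, -1, 0)
  pl <- plane_at_ostia(cl, o1, o2)
  tangent <- c(-sin(mid), 0, cos(mid))
  expect_lt(norm(pl$origin - p_mid, "2"), 0.05)
  expect_lt(acos(min(1, sum(pl$n * tangent))), 1e-3)
})

test_that("plane basis is orthonormal for random centerline configurations", {
  set.seed(42)
  for (i in 1:1000) {
    n <- rnorm(3)
    pl <- analysis_plane(rnorm(3, sd = 20), n)
    expect_lt(abs(norm(pl$u, "2") - 1), 1e-9)
    expect_lt(abs(norm(pl$v, "2") - 1), 1e-9)
    expect_lt(abs(norm(pl$n, "2") - 1), 1e-9)
    expect_lt(abs(sum(pl$u * pl$v)), 1e-9)
    expect_lt(abs(sum(pl$u * pl$n)), 1e-9)
    expect_lt(abs(sum(pl$v * pl$n)), 1e-9)
    # n = u x v by construction
    uxv <- c(pl$u[2] * pl$v[3] - pl$u[3] * pl$v[2],
             pl$u[3] * pl$v[1] - pl$u[1] * pl$v[3],
             pl$u[1] * pl$v[2] - pl$u[2] * pl$v[1])
    expect_lt(norm(uxv - pl$n, "2"), 1e-12)
  }
})

test_that("slicing selects the loop nearest the plane origin", {
  cyl_a <- make_cylinder_mesh(radius = 1, length = 2, n_circ = 32)
  cyl_b <- transform_mesh(cyl_a, diag(3), c(10, 0, 0))
  both <- tri_surface_mesh(rbind(cyl_a$vertices, cyl_b$vertices),
                           rbind(cyl_a$triangles,
                                 cyl_b$triangles + n_vertices(cyl_a)))
  pl <- analysis_plane(c(0, 0, 1), c(0, 0, 1))
  cont <- slice_mesh(both, pl)
  expect_true(all(sqrt(rowSums(cont$points[, 1:2]^2)) < 1.5))
  pl_b <- analysis_plane(c(10, 0, 1), c(0, 0, 1))
  cont_b <- slice_mesh(both, pl_b)
  expect_true(all(cont_b$points[, 1] > 8))

  # contour is counterclockwise viewed down n
  uv <- cbind(cont$points[, 1], cont$points[, 2])
  nxt <- c(2:nrow(uv), 1)
  expect_gt(sum(uv[, 1] * uv[nxt, 2] - uv[nxt, 1] * uv[, 2]), 0)

  expect_error(slice_mesh(cyl_a, analysis_plane(c(0, 0, 50), c(0, 0, 1))),
               "does not intersect")
})

test_that("open surfaces that end across the plane are reported", {
  # half tube: circumferential gap, so the slice cannot close
  th <- seq(0, pi, length.out = 17)
  z <- c(0, 1, 2)
  g <- expand.grid(j = seq_along(th), i = seq_along(z))
  verts <- cbind(cos(th[g$j]), sin(th[g$j]), z[g$i])
  idx <- function(i, j) (i - 1L) * length(th) + j
  tris <- do.call(rbind, lapply(1:2, function(i) {
    j <- 1:(length(th) - 1L)
    rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
          cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  }))
  half <- tri_surface_mesh(verts, tris)
  expect_error(slice_mesh(half, analysis_plane(c(0, 0, 1), c(0, 0, 1))),
               "open polyline")
})

test_that("contour area matches closed forms and is rigidly invariant", {
  sq <- square_contour()
  expect_equal(contour_area(sq), 1.0, tolerance = 1e-12)

  # regular 360-gon approximating circle r = 10: (1/2) n r^2 sin(2 pi / n)
  n <- 360L
  th <- 2 * pi * (seq_len(n) - 1) / n
  pl <- analysis_plane(c(0, 0, 0), c(0, 0, 1))
  poly <- planar_contour(cbind(10 * cos(th), 10 * sin(th), 0), pl)
  a <- contour_area(poly)
  expect_equal(a, 0.5 * n * 100 * sin(2 * pi / n), tolerance = 1e-12)
  expect_lt(abs(a - 100 * pi) / (100 * pi), 2e-4)

  # common rigid transform of points and plane leaves the area unchanged
  set.seed(5)
  for (k in 1:5) {
    R <- rootmotion:::random_rotation()
    tr <- rnorm(3, sd = 10)
    pts2 <- sweep(poly$points %*% t(R), 2, tr, "+")
    pl2 <- analysis_plane(drop(R %*% pl$origin) + tr, drop(R %*% pl$n))
    poly2 <- planar_contour(pts2, pl2)
    expect_equal(contour_area(poly2), a, tolerance = 1e-9)
    expect_equal(contour_centroid(poly2),
                 drop(R %*% contour_centroid(poly)) + tr, tolerance = 1e-9)
  }
})

test_that("contour centroid matches the fan-triangulation oracle", {
  sq <- square_contour(z0 = 3)
  expect_equal(contour_centroid(sq), c(0.5, 0.5, 3), tolerance = 1e-12)

  # cyclic reordering leaves the centroid unchanged
  pts <- sq$points[c(3, 4, 1, 2), ]
  sq2 <- planar_contour(pts, sq$plane)
  expect_equal(contour_centroid(sq2), contour_centroid(sq), tolerance = 1e-12)

  # L-shaped hexagon against an independent triangulation oracle
  L <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 3), c(0, 3))
  pl <- analysis_plane(c(0, 0, 0), c(0, 0, 1), u = c(1, 0, 0))
  cont <- planar_contour(cbind(L, 0), pl)
  oracle <- fan_centroid_2d(L)
  expect_equal(contour_centroid(cont), c(oracle, 0), tolerance = 1e-12)
})

test_that("contour validity rules reject bad inputs", {
  pl <- analysis_plane(c(0, 0, 0), c(0, 0, 1))
  expect_error(planar_contour(rbind(c(0, 0, 0), c(1, 0, 0)), pl), "3 points")
  expect_error(planar_contour(rbind(c(0, 0, 1), c(1, 0, 0), c(1, 1, 0)), pl),
               "planarity")
  expect_error(planar_contour(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)), pl),
               "duplicate")
  bow <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(planar_contour(bow, pl), "self-intersect")
})

test_that("fitted planes recover the slicing plane and obey orientation", {
  th <- 2 * pi * (0:35) / 36
  pts <- cbind(5 * cos(th), 5 * sin(th), 3)
  pl <- fit_plane(pts)
  expect_equal(abs(pl$n[3]), 1, tolerance = 1e-12)
  expect_equal(pl$origin[3], 3, tolerance = 1e-12)

  # orientation rule: reference normal forces positive dot product even
  # for clockwise-ordered points
  pl_cw <- fit_plane(pts[length(th):1, ], n_reference = c(0, 0, 1))
  expect_gt(pl_cw$n[3], 0)

  # jittered planar points: Newell normal within 1e-4 rad of both the
  # true normal and the SVD (smallest-singular-direction) oracle
  set.seed(8)
  true_n <- c(0, 0, 1)
  jit <- pts + matrix(rnorm(length(pts), sd = 1e-6), ncol = 3)
  pl_j <- fit_plane(jit, n_reference = true_n)
  expect_lt(acos(min(1, sum(pl_j$n * true_n))), 1e-4)
  sv <- svd(sweep(jit, 2, colMeans(jit)))$v[, 3]
  if (sum(sv * true_n) < 0) sv <- -sv
  expect_lt(acos(min(1, abs(sum(pl_j$n * sv)))), 1e-4)

  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 0)), "collinear")
})

test_that("exactly planar sliced contours reproduce the slicing normal", {
  cyl <- make_cylinder_mesh(radius = 3, length = 6, n_circ = 48)
  pl <- analysis_plane(c(0, 0, 2), c(0, 0, 1))
  cont <- slice_mesh(cyl, pl)
  fitted <- fit_plane(cont$points, n_reference = pl$n)
  expect_lt(acos(min(1, sum(fitted$n * pl$n))), 1e-9)
})

test_that("slice-derived areas converge to the closed form with refinement", {
  errs <- sapply(c(16, 32, 64, 128), function(nc) {
    cyl <- make_cylinder_mesh(radius = 1, length = 1, n_circ = nc)
    cont <- slice_mesh(cyl, analysis_plane(c(0, 0, 0.5), c(0, 0, 1)))
    abs(contour_area(cont) - pi) / pi
  })
  expect_true(all(diff(errs) < 0))
})
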