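# Shared fixtures: all built in code at test time.

# A unit-square contour in the z = z0 plane.
square_contour <- function(z0 = 0) {
  pl <- analysis_plane(c(0, 0, z0), c(0, 0, 1), u = c(1, 0, 0))
  planar_contour(rbind(c(0, 0, z0), c(1, 0, z0), c(1, 1, z0), c(0, 1, z0)), pl)
}

# Apply one rigid transform to every piece of a phantom subject.
transform_subject <- function(phantom, field, rotation, translation) {
  lm <- lapply(phantom$landmarks, function(x) {
    if (is.matrix(x)) sweep(x %*% t(rotation), 2L, translation, "+")
    else drop(rotation %*% x) + translation
  })
  list(mesh = transform_mesh(phantom$mesh, rotation, translation),
       field = field %*% t(rotation),
       centerline = sweep(phantom$centerline %*% t(rotation), 2L, translation, "+"),
       landmarks = lm)
}

# Area-weighted polygon centroid by fan triangulation (independent oracle
# for contour_centroid).
fan_centroid_2d <- function(uv) {
  n <- nrow(uv)
  acc <- c(0, 0); area <- 0
  for (k in 2:(n - 1L)) {
    a <- uv[1L, ]; b <- uv[k, ]; cc <- uv[k + 1L, ]
    tri_a <- ((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])) / 2
    acc <- acc + tri_a * (a + b + cc) / 3
    area <- area + tri_a
  }
  acc / area
}

# Standard phantom + prescribed deformation used across tests.
standard_phantom <- function(...) {
  args <- list(root_radius = 15, sinus_bulge_amplitude = 4,
               circumferential_resolution = 128L)
  dots <- list(...)
  do.call(make_root_phantom, utils::modifyList(args, dots))
}

standard_deformation <- function() {
  deformation_params(axial_translation = 5, inplane_translation = c(3, 0),
                     tilt_deg = 3, twist_deg = 2, dilation_factor = 1.06)
}

expect_metrics_match_truth <- function(m, gt, disp_rel = 0.02,
                                       angle_abs = 0.3, area_rel = 0.01) {
  scale <- max(gt$total_disp, 1e-9)
  expect_lt(abs(m$total_disp - gt$total_disp), disp_rel * scale)
  expect_lt(abs(m$axial_disp - gt$axial_disp), disp_rel * scale)
  expect_lt(abs(m$inplane_disp - gt$inplane_disp), disp_rel * scale)
  expect_lt(abs(m$axial_tilt_deg - gt$axial_tilt_deg), angle_abs)
  expect_lt(abs(m$rotation_deg - gt$rotation_deg), angle_abs)
  expect_lt(abs(m$area_ratio - gt$area_ratio), area_rel * gt$area_ratio)
  expect_lt(abs(m$distensibility - gt$distensibility),
            area_rel * max(abs(gt$distensibility), 1e-9) + 1e-12)
}
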