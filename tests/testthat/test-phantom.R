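test_that("zero bulge gives a cylinder with the closed-form section area", {
  ph <- make_root_phantom(root_radius = 12, sinus_bulge_amplitude = 0,
                          circumferential_resolution = 128L,
                          axial_resolution = 33L)
  cont <- slice_mesh(ph$mesh, phantom_plane(ph))
  expect_lt(abs(contour_area(cont) - pi * 144) / (pi * 144), 5e-4)
})

test_that("sinus contour has the prescribed lobe symmetry", {
  ph <- make_root_phantom(sinus_lobes = 3L, sinus_bulge_amplitude = 4,
                          circumferential_resolution = 129L,
                          axial_resolution = 33L)
  pl <- phantom_plane(ph)
  cont <- slice_mesh(ph$mesh, pl)
  a0 <- contour_area(cont)
  rot <- rootmotion:::rotate_about_axis(cont$points, c(0, 0, 1), 120)
  cont_rot <- planar_contour(rot, pl, check_simple = FALSE)
  expect_equal(contour_area(cont_rot), a0, tolerance = 1e-9)
})

test_that("phantom generation is deterministic for a fixed seed", {
  a <- make_root_phantom(vertex_noise_sd = 0.05, seed = 7L,
                         circumferential_resolution = 32L,
                         axial_resolution = 17L)
  b <- make_root_phantom(vertex_noise_sd = 0.05, seed = 7L,
                         circumferential_resolution = 32L,
                         axial_resolution = 17L)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  c <- make_root_phantom(vertex_noise_sd = 0.05, seed = 8L,
                         circumferential_resolution = 32L,
                         axial_resolution = 17L)
  expect_false(identical(a$mesh$vertices, c$mesh$vertices))
})

test_that("null deformation parameters give a zero field and identity truth", {
  ph <- standard_phantom(circumferential_resolution = 32L,
                         axial_resolution = 17L)
  def <- apply_deformation(ph, deformation_params())
  expect_equal(max(abs(def$field)), 0)
  gt <- def$ground_truth
  expect_equal(gt$total_disp, 0)
  expect_equal(gt$area_ratio, 1)
  expect_equal(gt$distensibility, 0)
})

test_that("ground truth is internally consistent", {
  dps <- random_deformations(20, seed = 5)
  ph <- standard_phantom(circumferential_resolution = 32L,
                         axial_resolution = 17L)
  for (dp in dps) {
    gt <- apply_deformation(ph, dp)$ground_truth
    expect_equal(gt$total_disp^2, gt$axial_disp^2 + gt$inplane_disp^2,
                 tolerance = 1e-12)
    expect_equal(gt$area_ratio, dp$dilation_factor^2, tolerance = 1e-12)
  }
})

test_that("dilation-only deformation gives the hand-computed distensibility", {
  ph <- standard_phantom(circumferential_resolution = 32L,
                         axial_resolution = 17L)
  gt <- apply_deformation(ph, deformation_params(dilation_factor = 1.06),
                          pulse_pressure = 56)$ground_truth
  expect_equal(gt$area_ratio, 1.1236, tolerance = 1e-12)
  expect_equal(gt$distensibility, 0.1236 / 56 * 1e3, tolerance = 1e-9)
})

test_that("a plane away from the sinus level is rejected", {
  ph <- standard_phantom(circumferential_resolution = 32L,
                         axial_resolution = 17L)
  off <- analysis_plane(c(0, 0, ph$sinus_z + 10), c(0, 0, 1))
  expect_error(apply_deformation(ph, deformation_params(), plane = off),
               "sinus level")
})

test_that("vertex noise degrades displacement recovery gracefully", {
  ph <- standard_phantom(vertex_noise_sd = 0.05, seed = 3L)
  def <- apply_deformation(ph, standard_deformation(), pulse_pressure = 56)
  m <- compute_root_metrics(ph$mesh, def$field, ph$centerline, ph$landmarks, 56)
  gt <- def$ground_truth
  expect_lt(abs(m$total_disp - gt$total_disp) / gt$total_disp, 0.05)
  expect_lt(abs(m$axial_disp - gt$axial_disp) / gt$total_disp, 0.05)
  expect_lt(abs(m$inplane_disp - gt$inplane_disp) / gt$total_disp, 0.05)
})

test_that("metric recovery error decreases with mesh refinement", {
  dp <- deformation_params(axial_translation = 4, inplane_translation = c(2, 1),
                           tilt_deg = 3, twist_deg = 2, dilation_factor = 1.08)
  err <- sapply(c(24L, 48L, 96L), function(nc) {
    ph <- make_root_phantom(circumferential_resolution = nc,
                            axial_resolution = 33L)
    def <- apply_deformation(ph, dp)
    m <- compute_root_metrics(ph$mesh, def$field, ph$centerline,
                              ph$landmarks, 56)
    gt <- def$ground_truth
    abs(m$rotation_deg - gt$rotation_deg) +
      abs(m$inplane_disp - gt$inplane_disp) / gt$total_disp
  })
  expect_true(all(diff(err) < 0))
})

test_that("phantom bundles round-trip through the subject file formats", {
  ph <- standard_phantom(circumferential_resolution = 32L,
                         axial_resolution = 17L)
  def <- apply_deformation(ph, standard_deformation(), pulse_pressure = 56)
  dir <- file.path(tempdir(), "bundle_rt")
  files <- write_phantom_bundle(ph, def$field, def$ground_truth, dir)
  mesh <- read_mesh(files$mesh)
  field <- read_displacement_csv(files$displacements, n_vertices(mesh))
  lm <- read_landmarks(files$landmarks)
  expect_equal(mesh$vertices, ph$mesh$vertices, tolerance = 1e-12)
  expect_equal(field, def$field, tolerance = 1e-12)
  m <- compute_root_metrics(mesh, field, lm$centerline, lm, 56)
  expect_metrics_match_truth(m, def$ground_truth)
  gt_json <- jsonlite::read_json(files$ground_truth, simplifyVector = TRUE)
  expect_equal(gt_json$total_disp, def$ground_truth$total_disp)
})
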