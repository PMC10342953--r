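#' Parametric aortic-root phantom
#'
#' Builds a synthetic aortic root standing in for a segmented dynamic-CTA
#' surface: a tube along +z whose radius profile carries a sinus-of-
#' Valsalva bulge,
#' \deqn{r(z, \theta) = R + b(z) (1 + \cos(L\theta)) / 2,}
#' with `b(z)` a Gaussian bump of amplitude `sinus_bulge_amplitude`
#' centered at the sinus level (`L` = `sinus_lobes`, 3 for the three
#' sinuses).  The axial grid is constructed so that one vertex ring lies
#' exactly at the sinus level; the coronary ostia are placed on surface
#' vertices of that ring, 120 degrees apart, and the centerline is the
#' z-axis.  Annulus landmark rings (aortic and mitral) and orientation
#' hints are included so the LV/Ao angle can be computed; the mitral
#' annulus is tilted so the phantom's LV/Ao angle equals
#' `lv_ao_angle_deg`.
#'
#' Optional vertex jitter (`vertex_noise_sd`) emulates segmentation noise;
#' all randomness is driven by the single integer `seed`.
#'
#' @param root_radius base lumen radius (mm).
#' @param sinus_bulge_amplitude peak extra radius of the sinus bulge (mm).
#' @param sinus_lobes number of sinus lobes (3 anatomically).
#' @param tube_length axial extent (mm), root at z = 0, arch direction +z.
#' @param axial_resolution number of vertex rings along z (>= 16).
#' @param circumferential_resolution vertices per ring (>= 16).
#' @param sinus_sigma axial half-width of the Gaussian sinus bulge (mm).
#' @param lv_ao_angle_deg LV/Ao angle built into the annulus landmarks.
#' @param vertex_noise_sd standard deviation of Gaussian vertex jitter (mm).
#' @param seed integer seed for the jitter.
#' @return An object of class `root_phantom`: list with `mesh`
#'   (`tri_surface_mesh`), `centerline` (matrix), `landmarks` (named
#'   list), `sinus_z`, and `params`.
#' @export
make_root_phantom <- function(root_radius = 15,
                              sinus_bulge_amplitude = 4,
                              sinus_lobes = 3L,
                              tube_length = 60,
                              axial_resolution = 65L,
                              circumferential_resolution = 128L,
                              sinus_sigma = 7.5,
                              lv_ao_angle_deg = 130,
                              vertex_noise_sd = 0,
                              seed = 1L) {
  stopifnot(root_radius > 0, sinus_bulge_amplitude >= 0, sinus_lobes >= 0,
            tube_length > 0, axial_resolution >= 16L,
            circumferential_resolution >= 16L, vertex_noise_sd >= 0,
            sinus_sigma > 0, lv_ao_angle_deg > 0, lv_ao_angle_deg < 180)
  n_ax <- as.integer(axial_resolution)
  n_circ <- as.integer(circumferential_resolution)
  z <- seq(0, tube_length, length.out = n_ax)
  sinus_z <- z[which.min(abs(z - tube_length / 2))]  # exact grid ring
  radius_fn <- function(zz, th) {
    bulge <- sinus_bulge_amplitude * exp(-(zz - sinus_z)^2 / (2 * sinus_sigma^2))
    root_radius + bulge * (1 + cos(sinus_lobes * th)) / 2
  }
  mesh <- tube_mesh(z, n_circ, radius_fn, cap_ends = FALSE)
  if (vertex_noise_sd > 0) {
    rng <- local({
      set.seed(as.integer(seed))
      matrix(stats::rnorm(3L * n_vertices(mesh), sd = vertex_noise_sd), ncol = 3L)
    })
    mesh <- tri_surface_mesh(mesh$vertices + rng, mesh$triangles)
  }

  i_sinus <- which(z == sinus_z)
  vid <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  j_left <- max(1L, round(n_circ * 0.25))
  j_right <- j_left + round(n_circ / 3)
  left_ostium <- mesh$vertices[vid(i_sinus, j_left), ]
  right_ostium <- mesh$vertices[vid(i_sinus, j_right), ]

  centerline <- cbind(0, 0, z)

  # annulus landmark rings below the sinus level
  z_ann <- max(z[1L], sinus_z - 10)
  th <- 2 * pi * (0:11) / 12
  aortic_annulus <- cbind(root_radius * cos(th), root_radius * sin(th), z_ann)
  # mitral annulus normal at (180 - lv_ao_angle) from -z when oriented
  # toward the apex, so the oriented-normal angle equals lv_ao_angle
  n_mv <- c(0, sin(lv_ao_angle_deg * pi / 180), cos(lv_ao_angle_deg * pi / 180))
  mv_center <- c(-2 * root_radius, 0, z_ann - 5)
  e1 <- normalize3(cross3(n_mv, c(1, 0, 0)))
  e2 <- cross3(n_mv, e1)
  r_mv <- 0.8 * root_radius
  mitral_annulus <- t(vapply(th, function(a)
    mv_center + r_mv * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  landmarks <- list(
    left_coronary_ostium = left_ostium,
    right_coronary_ostium = right_ostium,
    aortic_annulus = aortic_annulus,
    mitral_annulus = mitral_annulus,
    lv_apex_hint = mv_center + 30 * n_mv,
    aorta_hint = c(0, 0, tube_length),
    centerline = centerline)

  structure(list(
    mesh = mesh, centerline = centerline, landmarks = landmarks,
    sinus_z = sinus_z,
    params = list(root_radius = root_radius,
                  sinus_bulge_amplitude = sinus_bulge_amplitude,
                  sinus_lobes = sinus_lobes, tube_length = tube_length,
                  axial_resolution = n_ax,
                  circumferential_resolution = n_circ,
                  sinus_sigma = sinus_sigma,
                  lv_ao_angle_deg = lv_ao_angle_deg,
                  vertex_noise_sd = vertex_noise_sd, seed = seed)
  ), class = "root_phantom")
}

#' @export
print.root_phantom <- function(x, ...) {
  cat(sprintf("root_phantom: radius %g mm, bulge %g mm, %d x %d grid, sinus at z = %g\n",
              x$params$root_radius, x$params$sinus_bulge_amplitude,
              x$params$axial_resolution, x$params$circumferential_resolution,
              x$sinus_z))
  invisible(x)
}

#' Analysis plane of a phantom
#'
#' Convenience wrapper: the coronary-ostia plane of a phantom via
#' [plane_at_ostia()].
#'
#' @param phantom a `root_phantom`.
#' @return An `analysis_plane` at the sinus level.
#' @export
phantom_plane <- function(phantom) {
  plane_at_ostia(phantom$centerline,
                 phantom$landmarks$left_coronary_ostium,
                 phantom$landmarks$right_coronary_ostium)
}

#' Deformation parameters for the phantom
#'
#' Parameterizes the motion components of the aortic root over systole:
#' rigid translation along the plane normal (`axial_translation`) and
#' within the plane (`inplane_translation`, components along the plane's
#' `u`/`v` basis), a tilt of the root axis (`tilt_deg` about an in-plane
#' axis at `tilt_axis_angle_deg` from `u`), a twist about the normal
#' (`twist_deg`), and an in-plane dilation about the plane origin
#' (`dilation_factor`, linear scale).  Motion is constant at and below the
#' analysis plane and decays exponentially above it with length scale
#' `decay_length`, mimicking root motion transmitted from the left
#' ventricle below.
#'
#' @param axial_translation mm along the plane normal.
#' @param inplane_translation length-2 vector (mm) along the plane u/v axes.
#' @param tilt_deg,tilt_axis_angle_deg tilt magnitude and in-plane axis
#'   direction (degrees).
#' @param twist_deg rotation about the plane normal (degrees).
#' @param dilation_factor in-plane linear scale factor (> 0).
#' @param decay_length axial decay length of the motion above the plane (mm).
#' @return A `deformation_params` list.
#' @export
deformation_params <- function(axial_translation = 0,
                               inplane_translation = c(0, 0),
                               tilt_deg = 0, tilt_axis_angle_deg = 0,
                               twist_deg = 0, dilation_factor = 1,
                               decay_length = 20) {
  stopifnot(length(inplane_translation) == 2L, dilation_factor > 0,
            decay_length > 0)
  structure(list(axial_translation = axial_translation,
                 inplane_translation = as.numeric(inplane_translation),
                 tilt_deg = tilt_deg,
                 tilt_axis_angle_deg = tilt_axis_angle_deg,
                 twist_deg = twist_deg,
                 dilation_factor = dilation_factor,
                 decay_length = decay_length),
            class = "deformation_params")
}

#' Apply a prescribed deformation to a phantom
#'
#' Builds the vertex-wise diastole-to-systole displacement field for a
#' prescribed composite motion (dilation, then twist, then tilt, then
#' translation, all about/relative to the analysis-plane origin) weighted
#' by `w(h) = exp(-max(0, h) / decay_length)` where `h` is the height
#' above the plane; `w = 1` at and below the plane, so at the plane the
#' field equals the composite motion exactly and the implied metric
#' values are analytic:
#' axial displacement = `axial_translation`, in-plane displacement =
#' `|inplane_translation|` (dilation and twist average to zero over the
#' symmetric contour), tilt = `tilt_deg`, rotation = `twist_deg`, area
#' ratio = `dilation_factor^2`, and distensibility follows from the area
#' ratio and the stated pulse pressure.
#'
#' @param phantom a `root_phantom`.
#' @param dparams a `deformation_params`.
#' @param plane the phantom's sinus-level `analysis_plane` (checked: both
#'   coronary ostia must lie on it).
#' @param pulse_pressure pulse pressure (mmHg) used for the ground-truth
#'   distensibility.
#' @return List with `field` (`n x 3` displacement matrix) and
#'   `ground_truth` (class `phantom_ground_truth`).
#' @export
apply_deformation <- function(phantom, dparams, plane = phantom_plane(phantom),
                              pulse_pressure = 56) {
  stopifnot(inherits(phantom, "root_phantom"),
            inherits(dparams, "deformation_params"))
  tol <- max(0.5, 4 * phantom$params$vertex_noise_sd)
  h_ost <- abs(plane_height(plane, rbind(phantom$landmarks$left_coronary_ostium,
                                         phantom$landmarks$right_coronary_ostium)))
  if (max(h_ost) > tol) {
    stop("plane is not at the phantom sinus level (ostium ",
         format(max(h_ost), digits = 3), " mm off-plane)")
  }

  v <- phantom$mesh$vertices
  o <- plane$origin; u <- plane$u; vv <- plane$v; n <- plane$n
  q <- sweep(v, 2L, o)
  a <- drop(q %*% u); b <- drop(q %*% vv); h <- drop(q %*% n)
  s <- dparams$dilation_factor
  # dilation (in-plane, about plane origin)
  a1 <- a * s; b1 <- b * s
  # twist about n
  g <- dparams$twist_deg * pi / 180
  a2 <- a1 * cos(g) - b1 * sin(g)
  b2 <- a1 * sin(g) + b1 * cos(g)
  q2 <- outer(a2, u) + outer(b2, vv) + outer(h, n)
  # tilt about an in-plane axis through the origin
  beta <- dparams$tilt_axis_angle_deg * pi / 180
  tilt_axis <- cos(beta) * u + sin(beta) * vv
  q3 <- rotate_about_axis(q2, tilt_axis, dparams$tilt_deg)
  # translation
  trans <- dparams$axial_translation * n +
    dparams$inplane_translation[1L] * u + dparams$inplane_translation[2L] * vv
  target <- sweep(sweep(q3, 2L, trans, "+"), 2L, o, "+")
  w <- exp(-pmax(0, h) / dparams$decay_length)
  field <- (target - v) * w

  ax <- dparams$axial_translation
  ip <- sqrt(sum(dparams$inplane_translation^2))
  total <- sqrt(ax^2 + ip^2)
  gt <- structure(list(
    total_disp = total,
    axial_disp = abs(ax),
    inplane_disp = ip,
    rel_axial = if (total > 0) abs(ax) / total else NA_real_,
    rel_inplane = if (total > 0) ip / total else NA_real_,
    axial_tilt_deg = abs(dparams$tilt_deg),
    rotation_deg = abs(dparams$twist_deg),
    area_ratio = s^2,
    distensibility = (s^2 - 1) / pulse_pressure * 1e3,
    pulse_pressure = pulse_pressure,
    dparams = dparams
  ), class = "phantom_ground_truth")
  list(field = field, ground_truth = gt)
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat(sprintf(paste0("phantom_ground_truth: total %.3f mm (axial %.3f, ",
                     "in-plane %.3f), tilt %.2f deg, rotation %.2f deg, ",
                     "area ratio %.4f, distensibility %.4f e-3/mmHg\n"),
              x$total_disp, x$axial_disp, x$inplane_disp, x$axial_tilt_deg,
              x$rotation_deg, x$area_ratio, x$distensibility))
  invisible(x)
}

#' Draw random deformation parameters within physiological ranges
#'
#' Ranges reflect the magnitudes observed for aortic root motion over the
#' cardiac cycle: axial translation 0-8 mm, in-plane translation 0-6 mm
#' (uniform magnitude, uniform direction), twist 0-5 degrees, tilt 0-6
#' degrees, in-plane dilation 1.00-1.15.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @return List of `deformation_params`.
#' @export
random_deformations <- function(n, seed = 1L) {
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    ip_mag <- stats::runif(1, 0, 6)
    ip_dir <- stats::runif(1, 0, 2 * pi)
    deformation_params(
      axial_translation = stats::runif(1, 0, 8),
      inplane_translation = ip_mag * c(cos(ip_dir), sin(ip_dir)),
      tilt_deg = stats::runif(1, 0, 6),
      tilt_axis_angle_deg = stats::runif(1, 0, 360),
      twist_deg = stats::runif(1, 0, 5),
      dilation_factor = stats::runif(1, 1.0, 1.15))
  })
}

#' Write a phantom subject bundle to disk
#'
#' Writes the phantom in exactly the per-subject input formats consumed
#' by the metrics pipeline: a mesh file, a displacement CSV
#' (`vertex_index,dx,dy,dz`), a landmarks JSON, and a ground-truth JSON.
#' The write is atomic: files are staged in a temporary directory and
#' moved into place together.
#'
#' @param phantom a `root_phantom`.
#' @param field `n x 3` displacement matrix (mm).
#' @param ground_truth a `phantom_ground_truth` (or `NULL` to skip).
#' @param dir output directory (created if needed).
#' @param mesh_format one of `"ply"`, `"stl"`, `"vtp"`.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_phantom_bundle <- function(phantom, field, ground_truth, dir,
                                 mesh_format = c("ply", "stl", "vtp")) {
  mesh_format <- match.arg(mesh_format)
  stage <- tempfile("phantom_bundle_")
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE), add = TRUE)

  mesh_file <- paste0("mesh.", mesh_format)
  write_mesh(phantom$mesh, file.path(stage, mesh_file))
  write_displacement_csv(field, file.path(stage, "displacements.csv"))
  write_landmarks(phantom$landmarks, file.path(stage, "landmarks.json"))
  files <- list(mesh = mesh_file, displacements = "displacements.csv",
                landmarks = "landmarks.json")
  if (!is.null(ground_truth)) {
    gt <- ground_truth[setdiff(names(ground_truth), "dparams")]
    gt$deformation <- unclass(ground_truth$dparams)
    jsonlite::write_json(gt, file.path(stage, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files$ground_truth <- "ground_truth.json"
  }

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in unlist(files)) {
    file.copy(file.path(stage, f), file.path(dir, f), overwrite = TRUE)
  }
  unlink(stage, recursive = TRUE)
  ok <- TRUE
  invisible(lapply(files, function(f) file.path(dir, f)))
}
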