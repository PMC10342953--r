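#' Displacement field interpolated onto a sliced contour
#'
#' Every point of a contour produced by [slice_mesh()] lies on a mesh
#' edge; the per-vertex displacement is interpolated linearly along that
#' edge.
#'
#' @param contour a `planar_contour` with `edge_info` (from [slice_mesh()]).
#' @param field `n x 3` matrix of per-vertex displacement vectors (mm),
#'   one row per mesh vertex.
#' @return `k x 3` matrix of displacement vectors at the contour points.
#' @export
contour_displacements <- function(contour, field) {
  info <- contour$edge_info
  if (is.null(info)) stop("contour carries no mesh edge information; use slice_mesh()")
  field <- as_point_matrix(field, "displacement vectors")
  di <- field[info$i, , drop = FALSE]
  dj <- field[info$j, , drop = FALSE]
  di + (dj - di) * info$t
}

#' Mean displacement over the analysis plane
#'
#' Slices the mesh with the plane, interpolates the vertex-wise
#' displacement field onto the lumen contour, and averages it along the
#' contour.  The default average is the exact arc-length-weighted
#' (line-integral) mean of the piecewise-linear contour, which is
#' independent of where the loop starts and so is rigid-transform
#' invariant to floating-point precision.  Setting `samples` to a positive
#' integer instead averages that many equal-arc-length resampled points
#' (the integral mean is the limit of this estimator).
#'
#' @param mesh a `tri_surface_mesh` (diastolic configuration).
#' @param field `n x 3` per-vertex displacement matrix (mm).
#' @param plane the diastolic `analysis_plane`.
#' @param samples `NULL` for the exact integral mean (default), or a
#'   number of equal-arc-length samples (e.g. 256).
#' @return Length-3 mean displacement vector (mm).
#' @export
mean_plane_displacement <- function(mesh, field, plane, samples = NULL) {
  field <- as_point_matrix(field, "displacement vectors")
  if (nrow(field) != n_vertices(mesh)) {
    stop("displacement field has ", nrow(field), " vectors for ",
         n_vertices(mesh), " mesh vertices")
  }
  contour <- slice_mesh(mesh, plane)
  disp <- contour_displacements(contour, field)
  p <- contour$points
  k <- nrow(p)
  nxt <- c(2:k, 1L)
  seg <- sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2))
  if (is.null(samples)) {
    # trapezoid rule on the closed piecewise-linear loop: segment (i,
    # i+1) contributes its length times the average of the endpoint
    # values, exactly the line integral of the linear interpolant
    w <- (seg + seg[c(k, 1:(k - 1L))]) / (2 * sum(seg))
    colSums(disp * w)
  } else {
    samples <- as.integer(samples)
    stopifnot(samples >= 3L)
    s <- c(0, cumsum(seg))
    s_out <- s[k + 1L] * (seq_len(samples) - 1L) / samples
    idx <- findInterval(s_out, s, rightmost.closed = TRUE)
    idx <- pmin(idx, k)
    t <- (s_out - s[idx]) / seg[idx]
    d0 <- disp[idx, , drop = FALSE]
    d1 <- disp[nxt[idx], , drop = FALSE]
    colMeans(d0 + (d1 - d0) * t)
  }
}

#' Decompose a displacement vector against the diastolic plane normal
#'
#' Splits the mean root displacement into its axial component (projection
#' onto the diastolic analysis-plane normal) and in-plane component (the
#' perpendicular remainder), plus the relative (total-normalized)
#' fractions: relative axial = axial / total, relative in-plane =
#' in-plane / total, so that `rel_axial^2 + rel_inplane^2 = 1`.
#'
#' The axial component is reported as a magnitude; its sign against the
#' root-to-arch normal is returned in `axial_signed`.
#'
#' @param total_vec 3D displacement vector (mm).
#' @param n_dia diastolic plane unit normal.
#' @return List with `total`, `axial`, `axial_signed`, `inplane`,
#'   `rel_axial`, `rel_inplane` (the relatives are `NA` with
#'   `degenerate = TRUE` when the total displacement is zero).
#' @examples
#' decompose_displacement(c(3, 0, 4), c(0, 0, 1))  # total 5, axial 4, in-plane 3
#' @export
decompose_displacement <- function(total_vec, n_dia) {
  total_vec <- vec3(total_vec)
  n_dia <- vec3(n_dia)
  if (abs(norm3(n_dia) - 1) > 1e-9) stop("n_dia must be a unit vector")
  total <- norm3(total_vec)
  ax_signed <- sum(total_vec * n_dia)
  inpl_vec <- total_vec - ax_signed * n_dia
  inpl <- norm3(inpl_vec)
  if (total < 1e-15) {
    return(list(total = 0, axial = 0, axial_signed = 0, inplane = 0,
                rel_axial = NA_real_, rel_inplane = NA_real_,
                degenerate = TRUE))
  }
  list(total = total, axial = abs(ax_signed), axial_signed = ax_signed,
       inplane = inpl, rel_axial = abs(ax_signed) / total,
       rel_inplane = inpl / total, degenerate = FALSE)
}

#' Axial tilt between diastolic and systolic plane normals
#'
#' The acute angle between the diastolic and systolic analysis-plane
#' normals.  The systolic normal is first flipped, if needed, so that
#' `n_sys . n_dia >= 0`.
#'
#' @param n_dia,n_sys unit normals (checked to 1e-9).
#' @return Tilt angle in degrees, in `[0, 90]`.
#' @export
axial_tilt <- function(n_dia, n_sys) {
  n_dia <- vec3(n_dia); n_sys <- vec3(n_sys)
  if (abs(norm3(n_dia) - 1) > 1e-9 || abs(norm3(n_sys) - 1) > 1e-9) {
    stop("axial_tilt expects unit normals")
  }
  if (sum(n_dia * n_sys) < 0) n_sys <- -n_sys
  angle_between_deg(n_dia, n_sys)
}

#' Aortic rotation about the root axis
#'
#' Twist of the root between diastole and systole: the angle between the
#' centroid-to-reference vectors of the two phases after both are
#' projected into the diastolic analysis plane.  The reference point is an
#' anatomically stable landmark such as the origin of the left coronary
#' artery; each vector is anchored at its own phase's contour centroid.
#'
#' @param centroid_dia,centroid_sys contour centroids of the two phases (mm).
#' @param ref_dia,ref_sys reference landmark in the two phases (mm).
#' @param plane_dia the diastolic `analysis_plane`.
#' @param signed if `TRUE`, return the signed angle (positive
#'   counterclockwise about the diastolic normal); default is the unsigned
#'   magnitude.
#' @return Rotation angle in degrees.
#' @export
aortic_rotation <- function(centroid_dia, centroid_sys, ref_dia, ref_sys,
                            plane_dia, signed = FALSE) {
  n <- plane_dia$n
  proj <- function(w) w - sum(w * n) * n
  v1 <- proj(vec3(ref_dia) - vec3(centroid_dia))
  v2 <- proj(vec3(ref_sys) - vec3(centroid_sys))
  if (norm3(v1) < 1e-9 || norm3(v2) < 1e-9) {
    stop("reference point is (nearly) aligned with the plane normal; ",
         "in-plane rotation undefined")
  }
  cr <- cross3(v1, v2)
  ang <- atan2(norm3(cr), sum(v1 * v2)) * 180 / pi
  if (signed) ang * sign(sum(cr * n)) else ang
}

#' Area ratio and aortic distensibility
#'
#' Area ratio is the systolic over diastolic lumen area at the analysis
#' plane.  Distensibility relates the fractional area change to pulse
#' pressure:
#' \deqn{D = \frac{A_{sys} - A_{dia}}{A_{dia} \, PP}}
#' reported in the conventional units of `10^-3 mmHg^-1`.
#'
#' @param area_dia,area_sys diastolic and systolic areas (mm^2).
#' @param pulse_pressure systolic minus diastolic blood pressure (mmHg).
#' @return List with `area_ratio` (unitless) and `distensibility`
#'   (10^-3 mmHg^-1).
#' @examples
#' distensibility(100, 110, 50)  # ratio 1.1, distensibility 2.0
#' @export
distensibility <- function(area_dia, area_sys, pulse_pressure) {
  stopifnot(length(area_dia) == 1L, length(area_sys) == 1L,
            length(pulse_pressure) == 1L)
  if (!is.finite(area_dia) || area_dia <= 0) stop("diastolic area must be positive")
  if (!is.finite(area_sys) || area_sys < 0) stop("systolic area must be non-negative")
  if (!is.finite(pulse_pressure) || pulse_pressure <= 0) {
    stop("pulse pressure must be positive")
  }
  ratio <- area_sys / area_dia
  list(area_ratio = ratio,
       distensibility = (ratio - 1) / pulse_pressure * 1e3)
}

#' LV/Ao angle from annulus landmark rings
#'
#' The LV/Ao angle phi measures the alignment of the left-ventricular
#' long axis with the aortic root: planes are fitted to the aortic and
#' mitral annulus point rings, the aortic normal is oriented toward the
#' ascending aorta and the mitral normal toward the LV apex, and phi is
#' the angle between the two oriented normals.  A heart whose LV outflow
#' is coaxial with the aorta gives phi = 180 degrees (the oriented
#' normals are anti-aligned); clinically observed values lie around
#' 120-140 degrees, and smaller phi means a more perpendicular heart/aorta
#' arrangement.
#'
#' @param aortic_annulus_pts,mitral_annulus_pts `>= 3` ordered
#'   non-collinear points on each annulus (mm).
#' @param lv_apex_hint point toward the LV apex (orients the mitral normal).
#' @param aorta_hint point up the ascending aorta (orients the aortic normal).
#' @return List with `phi_deg` in (0, 180].
#' @export
lv_ao_angle <- function(aortic_annulus_pts, mitral_annulus_pts,
                        lv_apex_hint, aorta_hint) {
  ao <- fit_plane(aortic_annulus_pts)
  mv <- fit_plane(mitral_annulus_pts)
  n_ao <- ao$n
  if (sum(n_ao * (vec3(aorta_hint) - ao$origin)) < 0) n_ao <- -n_ao
  n_mv <- mv$n
  if (sum(n_mv * (vec3(lv_apex_hint) - mv$origin)) < 0) n_mv <- -n_mv
  list(phi_deg = angle_between_deg(n_ao, n_mv))
}

# Displacement at an arbitrary point: inverse-distance weighting over the
# 3 nearest mesh vertices (exact at a vertex).
interpolate_displacement_at <- function(mesh, field, point, k = 3L) {
  point <- vec3(point)
  d2 <- rowSums(sweep(mesh$vertices, 2L, point)^2)
  near <- order(d2)[seq_len(min(k, length(d2)))]
  d <- sqrt(d2[near])
  if (d[1L] < 1e-9) return(field[near[1L], ])
  w <- 1 / d
  w <- w / sum(w)
  colSums(field[near, , drop = FALSE] * w)
}

#' Compute the full per-subject aortic root motion record
#'
#' End-to-end extraction of the root-motion metrics from one subject's
#' inputs: places the diastolic analysis plane at the coronary-ostia
#' level, slices the diastolic lumen contour, warps the contour by the
#' interpolated displacement field to obtain the systolic contour, fits
#' the systolic plane (orientation anchored to the diastolic normal), and
#' derives displacements, tilt, rotation, areas and distensibility.
#'
#' @param mesh diastolic `tri_surface_mesh`.
#' @param field `n x 3` vertex-wise diastole-to-systole displacement
#'   matrix (mm).
#' @param centerline `k x 3` centerline sample matrix, ordered root to arch.
#' @param landmarks named list with at least `left_coronary_ostium` and
#'   `right_coronary_ostium` (3-vectors, mm), as read by
#'   [read_landmarks()].
#' @param pulse_pressure pulse pressure (mmHg).
#' @param systolic_planarity_tol planarity tolerance (mm) for the warped
#'   systolic contour, which is only approximately planar.
#' @param samples passed to [mean_plane_displacement()].
#' @return A `root_motion_metrics` list: `total_disp`, `axial_disp`,
#'   `axial_signed`, `inplane_disp`, `rel_axial`, `rel_inplane`,
#'   `axial_tilt_deg`, `rotation_deg`, `rotation_signed_deg`, `area_dia`,
#'   `area_sys`, `area_ratio`, `distensibility`, `pulse_pressure`
#'   (displacements mm, areas mm^2, angles degrees, distensibility
#'   10^-3 mmHg^-1).
#' @export
compute_root_metrics <- function(mesh, field, centerline, landmarks,
                                 pulse_pressure,
                                 systolic_planarity_tol = 0.5,
                                 samples = NULL) {
  field <- as_point_matrix(field, "displacement vectors")
  if (nrow(field) != n_vertices(mesh)) {
    stop("stage field: displacement count ", nrow(field),
         " does not match vertex count ", n_vertices(mesh))
  }
  lco <- vec3(landmarks$left_coronary_ostium)
  rco <- vec3(landmarks$right_coronary_ostium)

  plane_dia <- tryCatch(
    plane_at_ostia(centerline, lco, rco),
    error = function(e) stop("stage plane_at_ostia: ", conditionMessage(e)))
  contour_dia <- tryCatch(
    slice_mesh(mesh, plane_dia),
    error = function(e) stop("stage slice_mesh: ", conditionMessage(e)))

  disp_pts <- contour_displacements(contour_dia, field)
  warped <- contour_dia$points + disp_pts

  plane_sys <- tryCatch(
    fit_plane(warped, n_reference = plane_dia$n),
    error = function(e) stop("stage fit_plane: ", conditionMessage(e)))
  contour_sys <- tryCatch(
    planar_contour(warped, plane_sys,
                   planarity_tol = systolic_planarity_tol,
                   check_simple = FALSE),
    error = function(e) stop("stage systolic_contour: ", conditionMessage(e)))

  area_dia <- contour_area(contour_dia)
  area_sys <- contour_area(contour_sys)
  cent_dia <- contour_centroid(contour_dia)
  cent_sys <- contour_centroid(contour_sys)

  mean_disp <- mean_plane_displacement(mesh, field, plane_dia, samples = samples)
  dec <- decompose_displacement(mean_disp, plane_dia$n)

  tilt <- axial_tilt(plane_dia$n, plane_sys$n)

  ref_dia <- lco
  ref_sys <- ref_dia + interpolate_displacement_at(mesh, field, ref_dia)
  rot <- aortic_rotation(cent_dia, cent_sys, ref_dia, ref_sys, plane_dia)
  rot_signed <- aortic_rotation(cent_dia, cent_sys, ref_dia, ref_sys,
                                plane_dia, signed = TRUE)

  dist <- distensibility(area_dia, area_sys, pulse_pressure)

  structure(list(
    total_disp = dec$total,
    axial_disp = dec$axial,
    axial_signed = dec$axial_signed,
    inplane_disp = dec$inplane,
    rel_axial = dec$rel_axial,
    rel_inplane = dec$rel_inplane,
    axial_tilt_deg = tilt,
    rotation_deg = rot,
    rotation_signed_deg = rot_signed,
    area_dia = area_dia,
    area_sys = area_sys,
    area_ratio = dist$area_ratio,
    distensibility = dist$distensibility,
    pulse_pressure = pulse_pressure,
    mean_disp_vec = mean_disp,
    plane_dia = plane_dia,
    plane_sys = plane_sys
  ), class = "root_motion_metrics")
}

#' @export
print.root_motion_metrics <- function(x, ...) {
  cat("root_motion_metrics\n")
  cat(sprintf("  displacement (mm): total %.3f, axial %.3f, in-plane %.3f\n",
              x$total_disp, x$axial_disp, x$inplane_disp))
  cat(sprintf("  relative: axial %.3f, in-plane %.3f\n",
              x$rel_axial, x$rel_inplane))
  cat(sprintf("  axial tilt %.3f deg, rotation %.3f deg\n",
              x$axial_tilt_deg, x$rotation_deg))
  cat(sprintf("  area %.2f -> %.2f mm^2 (ratio %.4f), distensibility %.4f e-3/mmHg (PP %g)\n",
              x$area_dia, x$area_sys, x$area_ratio, x$distensibility,
              x$pulse_pressure))
  invisible(x)
}

#' Flatten a metrics record to a one-row data frame
#'
#' @param m a `root_motion_metrics` object.
#' @param id optional subject identifier column.
#' @return One-row `data.frame` with the scalar metric fields.
#' @export
metrics_as_row <- function(m, id = NULL) {
  df <- data.frame(
    total_disp = m$total_disp, axial_disp = m$axial_disp,
    inplane_disp = m$inplane_disp,
    rel_axial = m$rel_axial, rel_inplane = m$rel_inplane,
    axial_tilt_deg = m$axial_tilt_deg, rotation_deg = m$rotation_deg,
    area_dia = m$area_dia, area_sys = m$area_sys,
    area_ratio = m$area_ratio, distensibility = m$distensibility,
    pulse_pressure = m$pulse_pressure)
  if (!is.null(id)) df <- cbind(data.frame(id = id), df)
  df
}
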