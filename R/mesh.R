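#' Triangulated surface mesh
#'
#' Container for a triangulated vessel-wall surface: an `n x 3` matrix of
#' vertex coordinates in millimetres and an `m x 3` integer matrix of
#' 1-based triangle vertex indices.  This is the diastolic configuration on
#' which a vertex-wise displacement field is defined.
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates (mm).
#' @param triangles integer `m x 3` matrix of vertex indices (1-based).
#' @return An object of class `tri_surface_mesh` with elements `vertices`
#'   and `triangles`.
#' @examples
#' m <- tri_surface_mesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' n_vertices(m)
#' @export
tri_surface_mesh <- function(vertices, triangles) {
  vertices <- as_point_matrix(vertices, "vertices")
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 index matrix")
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (nrow(vertices) < 4L) stop("a surface mesh needs at least 4 vertices")
  if (anyNA(triangles) || min(triangles) < 1L || max(triangles) > nrow(vertices)) {
    stop("triangle indices out of range [1, ", nrow(vertices), "]")
  }
  a <- vertices[triangles[, 1L], , drop = FALSE]
  ab <- vertices[triangles[, 2L], , drop = FALSE] - a
  ac <- vertices[triangles[, 3L], , drop = FALSE] - a
  cr <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
              ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
              ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  area2 <- sqrt(rowSums(cr * cr))
  if (any(area2 / 2 <= 1e-12)) {
    stop("mesh contains degenerate (zero-area) triangles: e.g. triangle ",
         which(area2 / 2 <= 1e-12)[1L])
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_surface_mesh")
}

#' @rdname tri_surface_mesh
#' @param mesh a `tri_surface_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @export
print.tri_surface_mesh <- function(x, ...) {
  cat("tri_surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a `tri_surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2L, vec3(translation), "+")
  tri_surface_mesh(v, mesh$triangles)
}

# Closed grid triangulation of a tube parameterized by axial rings.
# `radius_fn(z, theta)` gives the radius at each (ring, angular) sample.
tube_mesh <- function(z_levels, n_circ, radius_fn, cap_ends = FALSE) {
  n_ax <- length(z_levels)
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  grid <- expand.grid(j = seq_len(n_circ), i = seq_len(n_ax))
  z <- z_levels[grid$i]
  th <- theta[grid$j]
  r <- radius_fn(z, th)
  verts <- cbind(r * cos(th), r * sin(th), z)
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  tris <- vector("list", n_ax - 1L)
  for (i in seq_len(n_ax - 1L)) {
    j <- seq_len(n_circ)
    a <- idx(i, j); b <- idx(i, j + 1L); c0 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    tris[[i]] <- rbind(cbind(a, b, d), cbind(a, d, c0))
  }
  tris <- do.call(rbind, tris)
  if (cap_ends) {
    c_bot <- nrow(verts) + 1L
    c_top <- nrow(verts) + 2L
    verts <- rbind(verts, c(0, 0, z_levels[1L]), c(0, 0, z_levels[n_ax]))
    j <- seq_len(n_circ)
    tris <- rbind(tris,
                  cbind(idx(1L, j + 1L), idx(1L, j), c_bot),
                  cbind(idx(n_ax, j), idx(n_ax, j + 1L), c_top))
  }
  tri_surface_mesh(verts, tris)
}

#' Analytic test solids
#'
#' Cylinder and UV-sphere meshes with known cross-sections, used to check
#' the mesh-slicing and area code against closed-form values (a plane at
#' height `d` cuts a sphere of radius `r` in a circle of radius
#' `sqrt(r^2 - d^2)`; any cross-section of the cylinder has area `pi r^2`).
#'
#' @param radius radius (mm).
#' @param length cylinder length (mm), axis along +z starting at z = 0.
#' @param n_circ circumferential resolution (number of angular samples).
#' @param n_axial number of axial rings.
#' @return A `tri_surface_mesh`.
#' @export
make_cylinder_mesh <- function(radius = 1, length = 1, n_circ = 64L, n_axial = 9L) {
  stopifnot(radius > 0, length > 0, n_circ >= 8L, n_axial >= 2L)
  z <- seq(0, length, length.out = n_axial)
  tube_mesh(z, as.integer(n_circ), function(z, th) rep(radius, length(z)),
            cap_ends = TRUE)
}

#' @rdname make_cylinder_mesh
#' @param n_lat number of latitude bands for the sphere.
#' @export
make_sphere_mesh <- function(radius = 1, n_circ = 64L, n_lat = 32L) {
  stopifnot(radius > 0, n_circ >= 8L, n_lat >= 4L)
  n_circ <- as.integer(n_circ); n_lat <- as.integer(n_lat)
  phi <- seq(0, pi, length.out = n_lat + 1L)[-c(1L, n_lat + 1L)]
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  grid <- expand.grid(j = seq_len(n_circ), i = seq_along(phi))
  ph <- phi[grid$i]; th <- theta[grid$j]
  verts <- radius * cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  nb <- length(phi)
  tris <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    j <- seq_len(n_circ)
    a <- idx(i, j); b <- idx(i, j + 1L); c0 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    tris[[i]] <- rbind(cbind(a, d, b), cbind(a, c0, d))
  }
  tris <- do.call(rbind, tris)
  north <- nb * n_circ + 1L
  south <- nb * n_circ + 2L
  verts <- rbind(verts, c(0, 0, radius), c(0, 0, -radius))
  j <- seq_len(n_circ)
  tris <- rbind(tris,
                cbind(idx(1L, j), idx(1L, j + 1L), north),
                cbind(idx(nb, j + 1L), idx(nb, j), south))
  tri_surface_mesh(verts, tris)
}
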