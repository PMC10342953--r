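#' Analysis plane
#'
#' An oriented measurement plane: origin, orthonormal in-plane basis
#' `(u, v)` and unit normal `n = u x v`.  For aortic root analysis the
#' plane sits at the coronary-ostia level of the sinuses of Valsalva,
#' perpendicular to the aortic centerline, and `n` points from the root
#' toward the arch.
#'
#' The in-plane basis is completed deterministically from `n`: `u` is the
#' normalized cross product of `n` with the global axis least parallel to
#' `n`, and `v = n x u`.  This makes downstream results reproducible
#' bit-for-bit.
#'
#' @param origin plane origin (mm).
#' @param n unit normal (normalized internally).
#' @param u optional in-plane unit vector; completed from `n` if missing.
#' @return An object of class `analysis_plane` with fields `origin`, `u`,
#'   `v`, `n`.
#' @export
analysis_plane <- function(origin, n, u = NULL) {
  origin <- vec3(origin)
  n <- normalize3(vec3(n), "plane normal")
  if (is.null(u)) {
    k_idx <- which.min(abs(n))  # global axis least parallel to n
    k <- c(0, 0, 0); k[k_idx] <- 1
    u <- normalize3(cross3(n, k), "in-plane basis")
  } else {
    u <- normalize3(vec3(u), "in-plane basis")
    u <- normalize3(u - sum(u * n) * n, "in-plane basis")
  }
  v <- cross3(n, u)
  structure(list(origin = origin, u = u, v = v, n = n),
            class = "analysis_plane")
}

#' @export
print.analysis_plane <- function(x, ...) {
  cat(sprintf("analysis_plane: origin (%.3f, %.3f, %.3f), n (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3], x$n[1], x$n[2], x$n[3]))
  invisible(x)
}

# Signed height of points above the plane and 2D in-plane coordinates.
plane_height <- function(plane, p) {
  p <- as_point_matrix(p)
  (p[, 1L] - plane$origin[1L]) * plane$n[1L] +
  (p[, 2L] - plane$origin[2L]) * plane$n[2L] +
  (p[, 3L] - plane$origin[3L]) * plane$n[3L]
}

plane_uv <- function(plane, p) {
  p <- as_point_matrix(p)
  q <- sweep(p, 2L, plane$origin)
  cbind(q %*% plane$u, q %*% plane$v)
}

plane_lift <- function(plane, uv, h = 0) {
  sweep(outer(uv[, 1L], plane$u) + outer(uv[, 2L], plane$v) +
          outer(rep_len(h, nrow(uv)), plane$n), 2L, plane$origin, "+")
}

#' Centerline utilities
#'
#' A centerline is an ordered matrix of 3D samples along the lumen axis,
#' ordered from the aortic root toward the arch.  `resample_centerline`
#' re-parameterizes it by arc length at a fixed spacing (linear
#' interpolation), which regularizes finite-difference tangents.
#'
#' @param centerline `k x 3` matrix of ordered samples (mm), `k >= 2`.
#' @param spacing target arc-length spacing in mm.
#' @return The resampled centerline matrix.
#' @export
resample_centerline <- function(centerline, spacing = 0.5) {
  cl <- as_point_matrix(centerline, "centerline samples")
  if (nrow(cl) < 2L) stop("centerline needs at least 2 samples")
  seg <- sqrt(rowSums((cl[-1L, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  if (any(seg < 1e-12)) stop("centerline has coincident consecutive samples")
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n_out <- max(2L, ceiling(total / spacing) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  out <- sapply(1:3, function(d) stats::approx(s, cl[, d], xout = s_out)$y)
  as_point_matrix(out)
}

# Arc-length parameter (normalized to [0,1]) of the closest point on the
# polyline to `p`, plus whether the projection clamps at an endpoint.
project_on_centerline <- function(centerline, p) {
  cl <- as_point_matrix(centerline)
  p <- vec3(p)
  a <- cl[-nrow(cl), , drop = FALSE]
  b <- cl[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  ap <- sweep(-a, 2L, p, "+")
  t <- rowSums(ap * ab) / len2
  tc <- pmin(1, pmax(0, t))
  foot <- a + ab * tc
  d2 <- rowSums(sweep(foot, 2L, p)^2)
  i <- which.min(d2)
  seg <- sqrt(len2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  list(param = (s[i] + tc[i] * seg[i]) / total,
       clamped = (i == 1L && t[1L] < 0) || (i == length(t) && t[length(t)] > 1))
}

centerline_point_at <- function(centerline, param) {
  cl <- as_point_matrix(centerline)
  seg <- sqrt(rowSums((cl[-1L, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  target <- param * s[length(s)]
  i <- max(1L, min(length(seg), findInterval(target, s, rightmost.closed = TRUE)))
  t <- (target - s[i]) / seg[i]
  cl[i, ] + t * (cl[i + 1L, ] - cl[i, ])
}

# Central-difference unit tangent at normalized arc-length `param`,
# oriented in the direction of increasing parameter (root toward arch).
centerline_tangent_at <- function(centerline, param, h_frac = NULL) {
  cl <- as_point_matrix(centerline)
  seg <- sqrt(rowSums((cl[-1L, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  total <- sum(seg)
  if (is.null(h_frac)) h_frac <- max(min(seg) / total, 1e-4)
  p0 <- max(0, param - h_frac)
  p1 <- min(1, param + h_frac)
  d <- centerline_point_at(cl, p1) - centerline_point_at(cl, p0)
  normalize3(d, "centerline tangent (coincident samples?)")
}

#' Analysis plane at the coronary-ostia level
#'
#' Places the sinus-of-Valsalva measurement plane: both coronary ostia are
#' projected onto the centerline, the plane origin is the centerline point
#' at the mean of the two arc-length parameters, and the normal is the
#' centerline unit tangent there (pointing from root toward arch, i.e. in
#' the direction of increasing sample order).  The in-plane basis is
#' completed deterministically as in [analysis_plane()].
#'
#' @param centerline `k x 3` matrix of ordered centerline samples (mm).
#' @param left_ostium,right_ostium 3D landmark positions of the coronary
#'   ostia (mm).
#' @param resample_spacing arc-length resampling spacing for tangent
#'   estimation in mm; `NULL` disables resampling.
#' @return An `analysis_plane`.
#' @examples
#' cl <- cbind(0, 0, seq(0, 20, by = 1))
#' pl <- plane_at_ostia(cl, c(5, 0, 10), c(-5, 0, 12))
#' pl$origin  # (0, 0, 11)
#' @export
plane_at_ostia <- function(centerline, left_ostium, right_ostium,
                           resample_spacing = 0.5) {
  cl <- as_point_matrix(centerline, "centerline samples")
  if (!is.null(resample_spacing)) cl <- resample_centerline(cl, resample_spacing)
  pr_l <- project_on_centerline(cl, left_ostium)
  pr_r <- project_on_centerline(cl, right_ostium)
  if (pr_l$clamped) stop("left coronary ostium projects outside the centerline span")
  if (pr_r$clamped) stop("right coronary ostium projects outside the centerline span")
  param <- (pr_l$param + pr_r$param) / 2
  origin <- centerline_point_at(cl, param)
  n <- centerline_tangent_at(cl, param)
  analysis_plane(origin, n)
}

#' Planar contour
#'
#' An ordered closed loop of 3D points lying (to within `planarity_tol`)
#' in an analysis plane, ordered counterclockwise when viewed down the
#' plane normal.  Contours from exact mesh slices are planar to numerical
#' precision; contours obtained by warping diastolic points into systole
#' are only approximately planar, so the tolerance is configurable.
#'
#' @param points `k x 3` matrix of ordered loop points (mm), `k >= 3`,
#'   without a repeated closing point.
#' @param plane the `analysis_plane` the contour lies in.
#' @param planarity_tol maximum allowed distance of any point from the
#'   plane (mm).
#' @param check_simple verify the projected polygon is non-self-intersecting.
#' @param edge_info optional data frame (`i`, `j`, `t`) recording, for each
#'   contour point, the mesh edge it lies on and the interpolation weight
#'   (used to interpolate vertex displacement fields onto the contour).
#' @return An object of class `planar_contour`.
#' @export
planar_contour <- function(points, plane, planarity_tol = 1e-6,
                           check_simple = TRUE, edge_info = NULL) {
  points <- as_point_matrix(points, "contour points")
  if (nrow(points) < 3L) stop("a contour needs at least 3 points")
  h <- plane_height(plane, points)
  if (max(abs(h)) > planarity_tol) {
    stop(sprintf("contour point %.2e mm from plane exceeds planarity tolerance %.2e",
                 max(abs(h)), planarity_tol))
  }
  d <- sqrt(rowSums((points - points[c(2:nrow(points), 1L), , drop = FALSE])^2))
  if (any(d < 1e-12)) stop("contour has consecutive duplicate points")
  if (check_simple && !is_simple_polygon(plane_uv(plane, points))) {
    stop("contour self-intersects when projected into the plane")
  }
  structure(list(points = points, plane = plane, edge_info = edge_info),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat("planar_contour:", nrow(x$points), "points, area",
      format(contour_area(x), digits = 6), "mm^2\n")
  invisible(x)
}

# Segment-intersection test on the closed polygon given by 2D rows of uv.
is_simple_polygon <- function(uv) {
  n <- nrow(uv)
  if (n < 4L) return(TRUE)
  nxt <- c(2:n, 1L)
  p1 <- uv; p2 <- uv[nxt, , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip segments adjacent to i
    if (!length(js)) next
    a <- p1[i, ]; b <- p2[i, ]
    cmat <- p1[js, , drop = FALSE]; dmat <- p2[js, , drop = FALSE]
    r <- b - a
    d1 <- (cmat[, 1L] - a[1L]) * r[2L] - (cmat[, 2L] - a[2L]) * r[1L]
    d2 <- (dmat[, 1L] - a[1L]) * r[2L] - (dmat[, 2L] - a[2L]) * r[1L]
    s <- dmat - cmat
    d3 <- (a[1L] - cmat[, 1L]) * s[, 2L] - (a[2L] - cmat[, 2L]) * s[, 1L]
    d4 <- (b[1L] - cmat[, 1L]) * s[, 2L] - (b[2L] - cmat[, 2L]) * s[, 1L]
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Slice a mesh with an analysis plane
#'
#' Intersects every triangle with the plane, stitches the resulting
#' segments into closed loops by shared mesh-edge identity, and returns
#' the loop whose centroid lies nearest the plane origin (the plane at the
#' coronary ostia can also cut other parts of the aorta; the origin is by
#' construction inside the root lumen).  Points are ordered
#' counterclockwise viewed down the plane normal.  Vertices lying exactly
#' in the plane are treated as displaced by +1e-12 mm along the normal so
#' every crossing is transversal.
#'
#' Each returned contour point lies on a mesh edge; `edge_info` records
#' the edge endpoints and interpolation weight so per-vertex fields can be
#' interpolated onto the contour.
#'
#' @param mesh a `tri_surface_mesh`.
#' @param plane an `analysis_plane`.
#' @param dedupe_tol consecutive contour points closer than this (mm) are
#'   merged (guards against slivers when the plane grazes vertices).
#' @return A `planar_contour` with `edge_info`.
#' @export
slice_mesh <- function(mesh, plane, dedupe_tol = 1e-7) {
  v <- mesh$vertices
  tr <- mesh$triangles
  d <- plane_height(plane, v)
  d[abs(d) < 1e-12] <- 1e-12
  pos <- d > 0
  tpos <- matrix(pos[tr], ncol = 3L)
  ncross <- abs(tpos[, 1L] - tpos[, 2L]) + abs(tpos[, 2L] - tpos[, 3L]) +
    abs(tpos[, 3L] - tpos[, 1L])
  cut <- which(ncross == 2L)
  if (!length(cut)) stop("plane does not intersect the mesh")

  # Canonical crossing point per mesh edge (i < j) so that the two
  # triangles sharing an edge produce bit-identical points.
  edge_cross_point <- function(i, j) {
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    t <- d[i] / (d[i] - d[j])
    list(i = i, j = j, t = t,
         p = v[i, , drop = FALSE] + (v[j, , drop = FALSE] - v[i, , drop = FALSE]) * t)
  }

  nv <- nrow(v)
  seg_ends <- lapply(cut, function(ti) {
    ids <- tr[ti, ]
    pr <- pos[ids]
    e <- rbind(c(ids[1L], ids[2L]), c(ids[2L], ids[3L]), c(ids[3L], ids[1L]))
    crossed <- c(pr[1L] != pr[2L], pr[2L] != pr[3L], pr[3L] != pr[1L])
    e <- e[crossed, , drop = FALSE]
    pmin(e[, 1L], e[, 2L]) + (pmax(e[, 1L], e[, 2L]) - 1) * nv
  })
  seg <- do.call(rbind, seg_ends)  # two edge keys per cut triangle

  keys <- sort(unique(as.vector(seg)))
  kidx <- match(seg, keys)
  dim(kidx) <- dim(seg)
  nk <- length(keys)
  # adjacency: each edge key borders at most two cut triangles
  nb1 <- integer(nk); nb2 <- integer(nk)
  for (r in seq_len(nrow(kidx))) {
    a <- kidx[r, 1L]; b <- kidx[r, 2L]
    if (nb1[a] == 0L) nb1[a] <- b else nb2[a] <- b
    if (nb1[b] == 0L) nb1[b] <- a else nb2[b] <- a
  }
  if (any(nb1 == 0L)) stop("unstitchable slice: isolated crossing segment")
  open_ends <- which(nb2 == 0L)
  if (length(open_ends)) {
    ki <- (keys[open_ends[1L]] - 1L) %/% nv + 1L
    kj <- keys[open_ends[1L]] - (ki - 1L) * nv
    stop(sprintf(paste0("slice produced an open polyline: mesh edge (%d, %d) ",
                        "borders only one cut triangle (surface not closed ",
                        "across the plane)"), kj, ki))
  }

  visited <- logical(nk)
  loops <- list()
  for (start in seq_len(nk)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- if (nb1[cur] != prev && !visited[nb1[cur]]) nb1[cur]
             else if (nb2[cur] != prev && !visited[nb2[cur]]) nb2[cur]
             else NA_integer_
      if (is.na(nxt)) {
        # closed if we can step back to start
        if (nb1[cur] == start || nb2[cur] == start || length(loop) == 1L) break
        break
      }
      prev <- cur; cur <- nxt
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  if (!length(loops)) stop("plane does not intersect the mesh in a closed loop")

  key_i <- (keys - 1L) %/% nv + 1L  # larger index
  key_j <- keys - (key_i - 1L) * nv # smaller index
  cp <- edge_cross_point(key_j, key_i)

  loop_pts <- lapply(loops, function(l) cp$p[l, , drop = FALSE])
  cent_d <- vapply(loop_pts, function(p)
    norm3(colMeans(p) - plane$origin), numeric(1))
  pick <- which.min(cent_d)
  l <- loops[[pick]]
  pts <- loop_pts[[pick]]
  info <- data.frame(i = cp$i[l], j = cp$j[l], t = cp$t[l])

  # merge consecutive near-duplicates (plane grazing a vertex yields
  # several crossings at essentially the same location)
  keep <- rep(TRUE, nrow(pts))
  dnext <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1L), , drop = FALSE])^2))
  keep[dnext < dedupe_tol] <- FALSE
  if (sum(keep) < 3L) stop("slice degenerated to fewer than 3 distinct points")
  pts <- pts[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]

  # counterclockwise when viewed down n
  uv <- plane_uv(plane, pts)
  a2 <- sum(uv[, 1L] * uv[c(2:nrow(uv), 1L), 2L] -
              uv[c(2:nrow(uv), 1L), 1L] * uv[, 2L])
  if (a2 < 0) {
    pts <- pts[nrow(pts):1L, , drop = FALSE]
    info <- info[nrow(info):1L, , drop = FALSE]
  }
  rownames(info) <- NULL
  planar_contour(pts, plane, planarity_tol = 1e-6, check_simple = FALSE,
                 edge_info = info)
}

#' Planar contour area and centroid
#'
#' `contour_area` projects the contour into the plane's `(u, v)` basis and
#' applies the shoelace formula (absolute value).  `contour_centroid`
#' returns the area-weighted centroid of the planar polygon, lifted back
#' to 3D (including the mean out-of-plane offset of the points, which is
#' zero for exact slices).
#'
#' @param contour a `planar_contour`.
#' @return `contour_area`: area in mm^2. `contour_centroid`: 3D point (mm).
#' @export
contour_area <- function(contour) {
  uv <- plane_uv(contour$plane, contour$points)
  if (nrow(uv) < 3L) stop("need at least 3 points for an area")
  nxt <- c(2:nrow(uv), 1L)
  abs(sum(uv[, 1L] * uv[nxt, 2L] - uv[nxt, 1L] * uv[, 2L])) / 2
}

#' @rdname contour_area
#' @export
contour_centroid <- function(contour) {
  uv <- plane_uv(contour$plane, contour$points)
  nxt <- c(2:nrow(uv), 1L)
  cr <- uv[, 1L] * uv[nxt, 2L] - uv[nxt, 1L] * uv[, 2L]
  a2 <- sum(cr)
  if (abs(a2) < 1e-12) stop("contour has zero area; centroid undefined")
  cx <- sum((uv[, 1L] + uv[nxt, 1L]) * cr) / (3 * a2)
  cy <- sum((uv[, 2L] + uv[nxt, 2L]) * cr) / (3 * a2)
  h <- mean(plane_height(contour$plane, contour$points))
  drop(plane_lift(contour$plane, cbind(cx, cy), h))
}

#' Fit a plane to 3D points
#'
#' Origin is the mean point; the normal is the Newell-method normal of the
#' ordered point loop (robust for near-planar polygons).  If a reference
#' normal is supplied the result is flipped so `n . n_reference > 0`; this
#' anchors the systolic plane orientation to the diastolic one.  The
#' in-plane basis is completed deterministically as in [analysis_plane()].
#'
#' @param points `k x 3` matrix of ordered points, `k >= 3`, non-collinear.
#' @param n_reference optional reference normal fixing the orientation.
#' @return An `analysis_plane`.
#' @export
fit_plane <- function(points, n_reference = NULL) {
  p <- as_point_matrix(points)
  if (nrow(p) < 3L) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(p)
  q <- sweep(p, 2L, ctr)
  nxt <- c(2:nrow(q), 1L)
  qn <- q[nxt, , drop = FALSE]
  n <- c(sum(q[, 2L] * qn[, 3L] - q[, 3L] * qn[, 2L]),
         sum(q[, 3L] * qn[, 1L] - q[, 1L] * qn[, 3L]),
         sum(q[, 1L] * qn[, 2L] - q[, 2L] * qn[, 1L]))
  scale2 <- sum(q * q)
  if (norm3(n) < 1e-10 * max(scale2, 1e-300)) {
    stop("points are collinear or coincident; plane undefined")
  }
  n <- normalize3(n, "fitted plane normal (collinear points?)")
  if (!is.null(n_reference) && sum(n * vec3(n_reference)) < 0) n <- -n
  analysis_plane(ctr, n)
}
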