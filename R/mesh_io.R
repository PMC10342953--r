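#' Read and write triangulated surface meshes
#'
#' Minimal readers/writers for the common surface-mesh exchange formats:
#' PLY (ASCII), STL (ASCII and binary) and VTP (VTK XML PolyData, ASCII).
#' PLY and VTP preserve the vertex list and indexing; STL is a triangle
#' soup, so on read identical vertex coordinates are merged back into a
#' shared vertex list (exact coordinate match).  The format is inferred
#' from the file extension unless `format` is given.
#'
#' @param path file path.
#' @param format `"ply"`, `"stl"` or `"vtp"`; inferred from the extension
#'   by default.
#' @return `read_mesh`: a `tri_surface_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         vtp = read_vtp(path),
         stop("unsupported mesh format: ", format))
}

#' @rdname read_mesh
#' @param mesh a `tri_surface_mesh`.
#' @return `write_mesh`: the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path),
         vtp = write_vtp(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated PLY header in ", path)
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1L] != "ply") stop(path, " is not a PLY file")
  fmt <- grep("^format ", header, value = TRUE)
  if (!grepl("ascii", fmt)) stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", header, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("PLY header missing vertex/face counts")
  body <- readLines(con)
  body <- body[nzchar(trimws(body))]
  vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- matrix(as.numeric(unlist(lapply(vl, `[`, 1:3))), ncol = 3L, byrow = TRUE)
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  counts <- vapply(fl, function(x) as.integer(x[1L]), integer(1))
  if (any(counts != 3L)) stop("PLY contains non-triangular faces")
  faces <- matrix(as.integer(unlist(lapply(fl, `[`, 2:4))), ncol = 3L,
                  byrow = TRUE) + 1L
  tri_surface_mesh(verts, faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeLines(paste(format(mesh$vertices[, 1L], digits = 17),
                   format(mesh$vertices[, 2L], digits = 17),
                   format(mesh$vertices[, 3L], digits = 17)), con)
  writeLines(paste(3L, mesh$triangles[, 1L] - 1L, mesh$triangles[, 2L] - 1L,
                   mesh$triangles[, 3L] - 1L), con)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 80L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (is_ascii) {
    close(con)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    coords <- matrix(as.numeric(unlist(
      lapply(strsplit(trimws(vl), "\\s+"), `[`, 2:4))), ncol = 3L, byrow = TRUE)
  } else {
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    rec <- readBin(con, "raw", n = ntri * 50L)
    close(con)
    m <- matrix(rec, nrow = 50L)
    # each 50-byte record: 3 float32 normal, 3 x 3 float32 vertices, 2 pad
    coords <- do.call(rbind, lapply(seq_len(ntri), function(k)
      rbind(t(readBin(m[13:24, k], "double", n = 3L, size = 4L, endian = "little")),
            t(readBin(m[25:36, k], "double", n = 3L, size = 4L, endian = "little")),
            t(readBin(m[37:48, k], "double", n = 3L, size = 4L, endian = "little")))))
  }
  if (nrow(coords) %% 3L != 0L) stop("malformed STL: vertex count not a multiple of 3")
  key <- paste(coords[, 1L], coords[, 2L], coords[, 3L])
  uid <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  tri_surface_mesh(verts, matrix(uid, ncol = 3L, byrow = TRUE))
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  ab <- v[tr[, 2L], , drop = FALSE] - a
  ac <- v[tr[, 3L], , drop = FALSE] - a
  n <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
             ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
             ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  n <- n / sqrt(rowSums(n * n))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("solid mesh", con)
  fm <- function(x) format(x, digits = 9)
  for (k in seq_len(nrow(tr))) {
    writeLines(c(paste("  facet normal", fm(n[k, 1L]), fm(n[k, 2L]), fm(n[k, 3L])),
                 "    outer loop",
                 paste("      vertex", fm(v[tr[k, 1L], 1L]), fm(v[tr[k, 1L], 2L]), fm(v[tr[k, 1L], 3L])),
                 paste("      vertex", fm(v[tr[k, 2L], 1L]), fm(v[tr[k, 2L], 2L]), fm(v[tr[k, 2L], 3L])),
                 paste("      vertex", fm(v[tr[k, 3L], 1L]), fm(v[tr[k, 3L], 2L]), fm(v[tr[k, 3L], 3L])),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

read_vtp <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("reading VTP requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  pieces <- xml2::xml_find_all(doc, ".//Piece")
  if (!length(pieces)) stop("no <Piece> in VTP file ", path)
  pts_node <- xml2::xml_find_first(pieces[[1L]], ".//Points/DataArray")
  if (!identical(xml2::xml_attr(pts_node, "format"), "ascii")) {
    stop("only ASCII VTP is supported")
  }
  coords <- as.numeric(strsplit(trimws(xml2::xml_text(pts_node)), "\\s+")[[1L]])
  verts <- matrix(coords, ncol = 3L, byrow = TRUE)
  polys <- xml2::xml_find_first(pieces[[1L]], ".//Polys")
  conn_node <- xml2::xml_find_first(polys, ".//DataArray[@Name='connectivity']")
  off_node <- xml2::xml_find_first(polys, ".//DataArray[@Name='offsets']")
  conn <- as.integer(strsplit(trimws(xml2::xml_text(conn_node)), "\\s+")[[1L]])
  offs <- as.integer(strsplit(trimws(xml2::xml_text(off_node)), "\\s+")[[1L]])
  sizes <- diff(c(0L, offs))
  if (any(sizes != 3L)) stop("VTP contains non-triangular polys")
  tri_surface_mesh(verts, matrix(conn, ncol = 3L, byrow = TRUE) + 1L)
}

write_vtp <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  pts <- paste(apply(format(mesh$vertices, digits = 17), 1L, paste, collapse = " "),
               collapse = "\n          ")
  conn <- paste(as.vector(t(mesh$triangles - 1L)), collapse = " ")
  offs <- paste(seq_len(nt) * 3L, collapse = " ")
  txt <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    "  <PolyData>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfPolys="%d">', nv, nt),
    "      <Points>",
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste0("          ", pts),
    "        </DataArray>",
    "      </Points>",
    "      <Polys>",
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste0("          ", conn),
    "        </DataArray>",
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste0("          ", offs),
    "        </DataArray>",
    "      </Polys>",
    "    </Piece>",
    "  </PolyData>",
    "</VTKFile>")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(txt, con)
}

#' Read and write vertex displacement CSVs
#'
#' The per-subject displacement file has a header row and columns
#' `vertex_index,dx,dy,dz` (0-based vertex index, displacements in mm),
#' one row per mesh vertex.
#'
#' @param path CSV path.
#' @param n_vertices expected vertex count (checked when given).
#' @return `read_displacement_csv`: an `n x 3` displacement matrix in
#'   vertex order.
#' @export
read_displacement_csv <- function(path, n_vertices = NULL) {
  df <- utils::read.csv(path)
  need <- c("vertex_index", "dx", "dy", "dz")
  if (!all(need %in% names(df))) {
    stop("displacement CSV must have header columns ",
         paste(need, collapse = ","))
  }
  ord <- order(df$vertex_index)
  df <- df[ord, ]
  if (!identical(as.integer(df$vertex_index), seq_len(nrow(df)) - 1L)) {
    stop("displacement CSV vertex_index must cover 0..n-1 exactly once")
  }
  m <- as.matrix(df[, c("dx", "dy", "dz")])
  if (!is.null(n_vertices) && nrow(m) != n_vertices) {
    stop("displacement CSV has ", nrow(m), " rows for ", n_vertices, " vertices")
  }
  as_point_matrix(m, "displacement vectors")
}

#' @rdname read_displacement_csv
#' @param field `n x 3` displacement matrix (mm).
#' @export
write_displacement_csv <- function(field, path) {
  field <- as_point_matrix(field, "displacement vectors")
  df <- data.frame(vertex_index = seq_len(nrow(field)) - 1L,
                   dx = field[, 1L], dy = field[, 2L], dz = field[, 3L])
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write landmark JSON files
#'
#' Landmarks are a JSON object with named entries: single 3D points
#' (`left_coronary_ostium`, `right_coronary_ostium`, hint points) and
#' point lists (`aortic_annulus`, `mitral_annulus`, `centerline`), all in
#' mm in the mesh coordinate frame.
#'
#' @param path JSON path.
#' @return `read_landmarks`: a named list; point lists become matrices.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lm, function(x) {
    if (is.matrix(x)) as_point_matrix(x) else as.numeric(x)
  })
}

#' @rdname read_landmarks
#' @param landmarks named list of points / point matrices.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
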