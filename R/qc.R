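#' Binary segmentation mask
#'
#' A 3D boolean voxel grid with physical geometry (voxel spacing and
#' origin in mm), as produced by thresholding a segmentation.  Used for
#' registration quality control: the fixed diastolic segmentation is
#' compared with the warped systolic one.
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param spacing length-3 positive voxel spacing (mm).
#' @param origin length-3 grid origin (mm).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  if (any(dim(data) < 1L)) stop("mask grid is empty")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be a finite 3-vector (mm)")
  }
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA voxels")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s voxels, spacing (%g, %g, %g) mm, %d foreground\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$data)))
  invisible(x)
}

check_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$data), dim(b$data)) ||
      any(abs(a$spacing - b$spacing) > tol) ||
      any(abs(a$origin - b$origin) > tol)) {
    stop(sprintf(paste0("mask grids differ: a = [%s] spacing (%s) origin (%s); ",
                        "b = [%s] spacing (%s) origin (%s)"),
                 paste(dim(a$data), collapse = "x"),
                 paste(format(a$spacing), collapse = ", "),
                 paste(format(a$origin), collapse = ", "),
                 paste(dim(b$data), collapse = "x"),
                 paste(format(b$spacing), collapse = ", "),
                 paste(format(b$origin), collapse = ", ")))
  }
}

#' Dice overlap between two masks
#'
#' The standard overlap score for registration quality control,
#' `2|A n B| / (|A| + |B|)`, on identical grids.  Two empty masks score 1
#' (vacuous agreement) with a warning so empty ROIs do not fail
#' pipelines silently.
#'
#' @param a,b `binary_mask` objects on the same grid (shape, spacing and
#'   origin equal within 1e-6).
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
#' dice_overlap(binary_mask(m), binary_mask(m))  # 1
#' @export
dice_overlap <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_grid(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) {
    warning("both masks are empty; Dice reported as 1 (vacuous agreement)")
    return(1)
  }
  2 * sum(a$data & b$data) / (na + nb)
}

#' Per-slice overlap report
#'
#' Dice coefficient per axial slice (third array index) plus the global
#' Dice and the mismatching voxel count.  Slice pairs where both masks
#' are empty are flagged (`both_empty`) and excluded from scoring rather
#' than given an arbitrary value.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return List of class `overlap_report`: `global_dice`,
#'   `mismatch_voxels`, and `per_slice` (data frame: `slice`, `dice`,
#'   `n_a`, `n_b`, `both_empty`).
#' @export
overlap_report <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_grid(a, b)
  nz <- dim(a$data)[3L]
  per <- lapply(seq_len(nz), function(k) {
    sa <- a$data[, , k]; sb <- b$data[, , k]
    na <- sum(sa); nb <- sum(sb)
    data.frame(slice = k,
               dice = if (na + nb == 0L) NA_real_ else 2 * sum(sa & sb) / (na + nb),
               n_a = na, n_b = nb, both_empty = na + nb == 0L)
  })
  per <- do.call(rbind, per)
  global <- if (sum(a$data) + sum(b$data) == 0L) {
    warning("both masks are empty; global Dice reported as 1")
    1
  } else {
    2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
  }
  structure(list(global_dice = global,
                 mismatch_voxels = sum(xor(a$data, b$data)),
                 per_slice = per),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: global Dice %.4f, %d mismatching voxels, %d slices\n",
              x$global_dice, x$mismatch_voxels, nrow(x$per_slice)))
  invisible(x)
}

#' Read and write binary masks
#'
#' NIfTI (`.nii`, `.nii.gz`) goes through the RNifti package; NRRD
#' (`.nrrd`) is read/written with a minimal header parser supporting
#' `raw` and `gzip` encodings.  Voxel spacing and origin are honored from
#' the headers; voxels are foreground when > 0.
#'
#' @param path mask file path.
#' @return `read_mask`: a `binary_mask`.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  switch(ext,
         nii = {
           img <- RNifti::readNifti(path)
           spc <- RNifti::pixdim(img)[1:3]
           hdr <- RNifti::niftiHeader(img)
           org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
           binary_mask(array(as.array(img) > 0, dim = dim(img)[1:3]),
                       spacing = spc, origin = org)
         },
         nrrd = read_nrrd_mask(path),
         stop("unsupported mask format: ", path))
}

#' @rdname read_mask
#' @param mask a `binary_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  switch(ext,
         nii = {
           img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
           RNifti::pixdim(img) <- mask$spacing
           aff <- diag(c(mask$spacing, 1))
           aff[1:3, 4L] <- mask$origin
           RNifti::sform(img) <- structure(aff, code = 2L)
           RNifti::qform(img) <- structure(aff, code = 2L)
           RNifti::writeNifti(img, path)
         },
         nrrd = write_nrrd_mask(mask, path),
         stop("unsupported mask format: ", path))
  invisible(path)
}

read_nrrd_mask <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop(path, " is not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ?", fixed = FALSE)[[1L]]
    fields[[tolower(kv[1L])]] <- paste(kv[-1L], collapse = ": ")
  }
  dims <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1L]])
  if (length(dims) != 3L) stop("only 3D NRRD masks are supported")
  type <- tolower(fields$type)
  enc <- tolower(fields$encoding)
  spacing <- if (!is.null(fields$spacings)) {
    as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1L]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- gsub("[()]", "", strsplit(trimws(fields[["space directions"]]), "\\s+")[[1L]])
    m <- matrix(as.numeric(unlist(strsplit(dirs, ","))), nrow = 3L)
    sqrt(colSums(m^2))
  } else c(1, 1, 1)
  origin <- if (!is.null(fields[["space origin"]])) {
    as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1L]])
  } else c(0, 0, 0)
  n <- prod(dims)
  size <- switch(type,
                 uchar = , uint8 = , "unsigned char" = 1L,
                 short = , int16 = 2L,
                 int = , int32 = 4L,
                 stop("unsupported NRRD type: ", type))
  raw_data <- readBin(con, "raw", n = file.size(path))
  if (enc == "gzip") raw_data <- memDecompress(raw_data, type = "gzip")
  if (enc %in% c("raw", "gzip")) {
    vals <- readBin(raw_data, "integer", n = n, size = size,
                    signed = size > 1L, endian = "little")
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- as.integer(strsplit(trimws(rawToChar(raw_data)), "\\s+")[[1L]])
  } else stop("unsupported NRRD encoding: ", enc)
  binary_mask(array(vals > 0, dims), spacing = spacing, origin = origin)
}

write_nrrd_mask <- function(mask, path) {
  dims <- dim(mask$data)
  header <- c(
    "NRRD0004",
    "# produced by rootmotion",
    "type: uchar",
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(dims, collapse = " ")),
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            mask$spacing[1L], mask$spacing[2L], mask$spacing[3L]),
    "endian: little",
    "encoding: gzip",
    sprintf("space origin: (%g,%g,%g)",
            mask$origin[1L], mask$origin[2L], mask$origin[3L]),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  payload <- memCompress(as.raw(as.integer(mask$data)), type = "gzip")
  writeBin(payload, con)
  invisible(path)
}
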