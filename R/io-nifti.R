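# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what the pipeline needs: 3D scalar images, the common datatypes, the
# sform/qform direction matrix reduced to an axis permutation + flips so every
# volume is presented in the package's canonical (LR, AP, IS) = RAS axis
# order. Slope/intercept scaling is applied on read. Extensions are ignored.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  r = "int16"),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  r = "int32"),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  r = "float32"),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  r = "float64"),
  `256` = list(what = "integer", size = 1L, signed = TRUE,  r = "int8"),
  `512` = list(what = "integer", size = 2L, signed = FALSE, r = "uint16")
)

.open_maybe_gz <- function(path, mode) {
  # level-1 deflate: the package writes sparse masks/volumes where higher
  # levels cost several times the CPU for little size gain
  if (grepl("\\.gz$", path)) {
    if (mode == "wb") gzfile(path, "wb", compression = 1L) else gzfile(path, mode)
  } else {
    file(path, mode)
  }
}

.read_exact <- function(con, what, n, size, signed = TRUE, endian = "little", path = "") {
  x <- readBin(con, what = what, n = n, size = size, signed = signed, endian = endian)
  if (length(x) < n)
    stop("truncated or unreadable file: ", path, call. = FALSE)
  x
}

# Parse the fixed 348-byte header into the fields we use.
.nifti_read_header <- function(con, path) {
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    stop("truncated or unreadable NIfTI file: ", path, call. = FALSE)
  rd <- function(off, what, n, size, signed = TRUE, endian = "little")
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian = "big") != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  dims <- rd(40L, "integer", 8L, 2L, endian = endian)
  if (dims[1] < 3L) stop("NIfTI file is not 3D: ", path, call. = FALSE)
  if (dims[1] > 3L && any(dims[5:(dims[1] + 1L)] > 1L))
    stop("NIfTI file has more than 3 non-singleton dimensions: ", path, call. = FALSE)
  list(
    endian = endian,
    dim = dims[2:4],
    datatype = rd(70L, "integer", 1L, 2L, endian = endian),
    pixdim = rd(76L, "double", 8L, 4L, endian = endian),
    vox_offset = rd(108L, "double", 1L, 4L, endian = endian),
    scl_slope = rd(112L, "double", 1L, 4L, endian = endian),
    scl_inter = rd(116L, "double", 1L, 4L, endian = endian),
    qform_code = rd(252L, "integer", 1L, 2L, endian = endian),
    sform_code = rd(254L, "integer", 1L, 2L, endian = endian),
    quatern = rd(256L, "double", 6L, 4L, endian = endian),
    srow = matrix(rd(280L, "double", 12L, 4L, endian = endian), 3L, 4L, byrow = TRUE)
  )
}

# 3x3 voxel-to-world direction matrix (columns = voxel axes), or NULL when the
# file carries no orientation.
.nifti_direction <- function(h) {
  if (h$sform_code > 0L) return(h$srow[, 1:3, drop = FALSE])
  if (h$qform_code > 0L) {
    b <- h$quatern[1]; c <- h$quatern[2]; d <- h$quatern[3]
    a2 <- 1 - b * b - c * c - d * d
    a <- if (a2 > 0) sqrt(a2) else 0
    R <- matrix(c(
      a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
      2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
      2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c
    ), 3L, 3L, byrow = TRUE)
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    sp <- abs(h$pixdim[2:4]); sp[sp == 0] <- 1
    R %*% diag(c(sp[1], sp[2], qfac * sp[3]))
  } else {
    NULL
  }
}

# Reduce a direction matrix to (permutation, signs): voxel axis j maps to the
# world axis with the dominant |entry| in its column.
.axis_mapping <- function(dirmat) {
  perm <- integer(3); sgn <- integer(3)
  cols <- abs(dirmat)
  taken <- logical(3)
  for (j in order(-apply(cols, 2, max))) {
    i <- order(-cols[, j])
    i <- i[!taken[i]][1]
    if (is.na(i)) stop("degenerate orientation matrix", call. = FALSE)
    taken[i] <- TRUE
    perm[j] <- i
    sgn[j] <- if (dirmat[i, j] < 0) -1L else 1L
  }
  list(perm = perm, sgn = sgn)
}

.flip_axis <- function(x, axis) {
  n <- dim(x)[axis]
  switch(axis,
         x[n:1, , , drop = FALSE],
         x[, n:1, , drop = FALSE],
         x[, , n:1, drop = FALSE])
}

# Reorder raw on-disk data + spacing into canonical (LR, AP, IS)/RAS order.
.canonicalize <- function(data, spacing, dirmat) {
  m <- .axis_mapping(dirmat)
  for (j in 1:3) if (m$sgn[j] < 0L) data <- .flip_axis(data, j)
  inv <- order(m$perm)        # voxel axis that lands on world axis i
  data <- aperm(data, inv)
  list(data = data, spacing = spacing[inv])
}

.nifti_read <- function(path) {
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  h <- .nifti_read_header(con, path)
  dt <- .nifti_dtypes[[as.character(h$datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype ", h$datatype, " in ", path, call. = FALSE)
  skip <- max(h$vox_offset, 352) - 348
  if (skip > 0) .read_exact(con, "raw", as.integer(skip), 1L, path = path)
  n <- prod(h$dim)
  vals <- .read_exact(con, dt$what, n, dt$size, signed = dt$signed,
                      endian = h$endian, path = path)
  if (dt$r == "uint16") vals[vals < 0] <- vals[vals < 0] + 65536
  vals <- as.double(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  data <- array(vals, h$dim)
  spacing <- abs(h$pixdim[2:4])
  spacing[spacing == 0] <- 1
  dirmat <- .nifti_direction(h)
  if (is.null(dirmat)) {
    warning("no orientation metadata in ", path, "; assuming canonical axes",
            call. = FALSE)
    dirmat <- diag(spacing)
  } else {
    nrm <- sqrt(colSums(dirmat^2))
    spacing <- ifelse(nrm > 0, nrm, spacing)
  }
  cano <- .canonicalize(data, spacing, dirmat)
  volume(cano$data, cano$spacing)
}

# affine: optional 3x4 voxel-to-world matrix written as the sform (tests use
# this to fabricate flipped/permuted on-disk orientations). Default canonical.
.nifti_write <- function(v, path, dtype = c("float32", "uint8"), affine = NULL) {
  dtype <- match.arg(dtype)
  dims <- dim(v$data)
  if (is.null(affine)) affine <- cbind(diag(v$spacing), c(0, 0, 0))
  code <- if (dtype == "float32") 16L else 2L
  bitpix <- if (dtype == "float32") 32L else 8L
  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                   # sizeof_hdr
  w(raw(36L), 1L)                               # unused
  w(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  w(raw(14L), 1L)                               # intent params/codes
  w(code, 2L); w(bitpix, 2L)                    # datatype, bitpix
  w(0L, 2L)                                     # slice_start
  w(c(1, v$spacing, rep(0, 4)), 4L)             # pixdim[8]
  w(352, 4L)                                    # vox_offset
  w(c(1, 0), 4L)                                # scl_slope, scl_inter
  w(raw(4L), 1L)                                # slice_end, slice_code, xyzt_units
  w(c(0, 0), 4L)                                # cal_max, cal_min
  w(c(0, 0), 4L)                                # slice_duration, toffset
  w(c(0L, 0L), 4L)                              # glmax, glmin
  w(raw(104L), 1L)                              # descrip + aux_file
  w(c(0L, 1L), 2L)                              # qform_code, sform_code
  w(rep(0, 6), 4L)                              # quaternion + offsets
  w(as.numeric(t(affine)), 4L)                  # srow_x/y/z
  w(raw(16L), 1L)                               # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  w(as.raw(c(0L, 0L, 0L, 0L, 0L)), 1L)          # magic pad + 4-byte extender
  vals <- as.vector(v$data)
  if (dtype == "uint8") {
    if (!is.integer(vals)) vals <- as.integer(round(vals))
    w(vals, 1L)
  } else {
    w(as.numeric(vals), 4L)
  }
  invisible(path)
}

# Header-only read: canonical dims + spacing without touching voxel data.
.nifti_read_shape <- function(path) {
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  h <- .nifti_read_header(con, path)
  spacing <- abs(h$pixdim[2:4]); spacing[spacing == 0] <- 1
  dirmat <- .nifti_direction(h)
  if (is.null(dirmat)) {
    dirmat <- diag(spacing)
  } else {
    nrm <- sqrt(colSums(dirmat^2))
    spacing <- ifelse(nrm > 0, nrm, spacing)
  }
  m <- .axis_mapping(dirmat)
  inv <- order(m$perm)
  list(dim = h$dim[inv], spacing = spacing[inv])
}
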