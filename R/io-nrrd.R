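# Minimal NRRD0004 reader and writer (detached headers not supported).
#
# Covers 3D scalar grids with raw or gzip encoding, little/big endian, and
# `space directions` reduced to a permutation + flips for canonical axis
# order, mirroring the NIfTI path.

.nrrd_types <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "double",  size = 4L, signed = TRUE),
  double = list(what = "double",  size = 8L, signed = TRUE)
)

.nrrd_type_alias <- c(
  "unsigned char" = "uint8", uchar = "uint8", uint8 = "uint8", uint8_t = "uint8",
  short = "int16", "short int" = "int16", int16 = "int16", int16_t = "int16",
  int = "int32", int32 = "int32", int32_t = "int32", "signed int" = "int32",
  float = "float", double = "double"
)

.nrrd_parse_vectors <- function(s) {
  m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
  if (m[1] == -1) return(NULL)
  vecs <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(vecs, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

.nrrd_read <- function(path) {
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) != 1L || !grepl("^NRRD000[1-5]$", magic))
    stop("not a NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("truncated NRRD header: ", path, call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:", line))
    if (length(kv) == 0L) next
    key <- tolower(trimws(sub(":$", "", kv)))
    fields[[key]] <- trimws(sub("^[^:]+:=?", "", line))
  }
  dimension <- as.integer(fields[["dimension"]])
  if (is.na(dimension) || dimension != 3L)
    stop("NRRD file is not 3D: ", path, call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  tname <- .nrrd_type_alias[[tolower(fields[["type"]])]]
  if (is.null(tname)) stop("unsupported NRRD type '", fields[["type"]], "'", call. = FALSE)
  dt <- .nrrd_types[[tname]]
  endian <- if (!is.null(fields[["endian"]]) && fields[["endian"]] == "big") "big" else "little"
  encoding <- tolower(fields[["encoding"]])
  n <- prod(sizes)
  if (encoding %in% c("raw")) {
    vals <- .read_exact(con, dt$what, n, dt$size, signed = dt$signed,
                        endian = endian, path = path)
  } else if (encoding %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = 2^31 - 2)
    raw <- memDecompress(comp, type = "gzip")
    if (length(raw) < n * dt$size)
      stop("truncated or unreadable file: ", path, call. = FALSE)
    vals <- readBin(raw, dt$what, n = n, size = dt$size, signed = dt$signed,
                    endian = endian)
  } else {
    stop("unsupported NRRD encoding '", encoding, "'", call. = FALSE)
  }
  data <- array(as.double(vals), sizes)
  dirs <- if (!is.null(fields[["space directions"]]))
    .nrrd_parse_vectors(fields[["space directions"]]) else NULL
  spacings <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]) else NULL
  if (!is.null(dirs) && length(dirs) == 3L && all(lengths(dirs) == 3L)) {
    dirmat <- do.call(cbind, dirs)
    spacing <- sqrt(colSums(dirmat^2))
    spacing[spacing == 0] <- 1
  } else if (!is.null(spacings)) {
    spacing <- abs(spacings); spacing[!is.finite(spacing) | spacing == 0] <- 1
    dirmat <- diag(spacing)
  } else {
    warning("no orientation metadata in ", path, "; assuming canonical axes",
            call. = FALSE)
    spacing <- c(1, 1, 1)
    dirmat <- diag(3)
  }
  cano <- .canonicalize(data, spacing, dirmat)
  volume(cano$data, cano$spacing)
}

.nrrd_write <- function(v, path, dtype = c("float32", "uint8"), directions = NULL) {
  dtype <- match.arg(dtype)
  dims <- dim(v$data)
  if (is.null(directions)) directions <- diag(v$spacing)
  tname <- if (dtype == "float32") "float" else "uint8"
  dirtxt <- paste(apply(directions, 2, function(col)
    sprintf("(%.10g,%.10g,%.10g)", col[1], col[2], col[3])), collapse = " ")
  hdr <- c(
    "NRRD0004",
    "# produced by triplanr",
    paste0("type: ", tname),
    "dimension: 3",
    "space dimension: 3",
    paste0("sizes: ", paste(dims, collapse = " ")),
    paste0("space directions: ", dirtxt),
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (dtype == "uint8") {
    writeBin(as.integer(round(as.vector(v$data))), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(as.vector(v$data)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

.nrrd_read_shape <- function(path) {
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) != 1L || !grepl("^NRRD000[1-5]$", magic))
    stop("not a NRRD file: ", path, call. = FALSE)
  sizes <- NULL; dirs <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L || line == "") break
    if (grepl("^sizes:", line))
      sizes <- as.integer(strsplit(trimws(sub("^sizes:", "", line)), "\\s+")[[1]])
    if (grepl("^space directions:", line))
      dirs <- .nrrd_parse_vectors(line)
  }
  if (is.null(sizes)) stop("NRRD header missing sizes: ", path, call. = FALSE)
  spacing <- c(1, 1, 1); dirmat <- diag(3)
  if (!is.null(dirs) && length(dirs) == 3L && all(lengths(dirs) == 3L)) {
    dirmat <- do.call(cbind, dirs)
    spacing <- sqrt(colSums(dirmat^2)); spacing[spacing == 0] <- 1
  }
  m <- .axis_mapping(dirmat)
  inv <- order(m$perm)
  list(dim = sizes[inv], spacing = spacing[inv])
}
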