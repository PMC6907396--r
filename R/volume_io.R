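#' Read a 3D volume from disk
#'
#' Accepts a multipage grayscale TIFF, a directory of equally shaped 2D
#' TIFF/PNG slices (stacked in natural-number order of their file names, so
#' `s2` sorts before `s10`), or an NRRD file. The result uses axis order
#' `(z, y, x)` with the slice index as `z`.
#'
#' Spacing is taken from NRRD metadata when present, from
#' `spacing_override` when given (the override wins over metadata), and
#' otherwise defaults to isotropic 1 with a warning. The random-walk
#' distance transform is graph-based and spacing-free; only the Euclidean
#' transform and physical volumes consume spacing.
#'
#' @param path file or directory path.
#' @param spacing_override optional numeric length-3 `(sz, sy, sx)`.
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  spacing <- NULL
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no TIFF/PNG slices in directory '", path, "'", call. = FALSE)
    files <- files[natural_order(basename(files))]
    slices <- lapply(files, read_slice)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("slices in '", path, "' have inconsistent shapes", call. = FALSE)
    data <- stack_slices(slices)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    nr <- read_nrrd(path)
    data <- nr$data
    spacing <- nr$spacing
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, drop_channels)
    data <- stack_slices(pages)
  }
  if (!is.null(spacing_override)) {
    spacing <- check_spacing(spacing_override)
  } else if (is.null(spacing)) {
    warning("no spacing metadata for '", path, "'; assuming isotropic 1", call. = FALSE)
    spacing <- c(1, 1, 1)
  }
  intensity_volume(data, spacing)
}

#' Read a label volume
#'
#' Like [read_volume()] but returns integer labels.
#' @inheritParams read_volume
#' @return A [label_volume()].
#' @export
read_labels <- function(path, spacing_override = NULL) {
  v <- read_volume(path, spacing_override)
  d <- round(v$data)
  storage.mode(d) <- "integer"
  label_volume(d, v$spacing)
}

#' Write a volume, mask, or label grid to disk
#'
#' The format follows the file extension: `.tif`/`.tiff` for integer-valued
#' grids (8/16/32-bit unsigned, chosen from the value range) and `.nrrd`
#' for anything, including floating-point distance maps. Round trips are
#' bit-exact.
#'
#' @param vol a `tw_volume` (or array).
#' @param path destination ending in `.tif`, `.tiff`, or `.nrrd`.
#' @param min_bits minimum integer width (8, 16 or 32) for integer grids.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, min_bits = 8) {
  if (!inherits(vol, "tw_volume")) vol <- intensity_volume(vol)
  data <- vol$data
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    type <- if (is.logical(data)) "uint8"
            else if (is.integer(data)) pick_int_type(max(data), min(data), min_bits)
            else "double"
    write_nrrd(data, path, vol$spacing, type)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.logical(data)) {
      storage.mode(data) <- "integer"
    }
    if (is.double(data) && !all(data == round(data)))
      stop("TIFF output is for integer-valued grids; use .nrrd for floating point",
           call. = FALSE)
    lo <- min(data); hi <- max(data)
    if (lo < 0) stop("TIFF output requires non-negative values", call. = FALSE)
    bits <- max(min_bits, if (hi < 256) 8L else if (hi < 65536) 16L else 32L)
    if (hi >= 2^32) stop("values exceed 32-bit unsigned range", call. = FALSE)
    scale <- 2^bits - 1
    pages <- lapply(seq_len(dim(data)[1]), function(z) data[z, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  } else stop("unsupported extension for '", path, "' (use .tif, .tiff or .nrrd)",
              call. = FALSE)
  invisible(path)
}

#' Write a label volume
#'
#' Uses 16-bit storage when the maximum label is below 65536 and 32-bit
#' otherwise, for both TIFF and NRRD targets.
#' @param labels a [label_volume()].
#' @inheritParams write_volume
#' @export
write_labels <- function(labels, path) {
  labels <- as_labels(labels)
  write_volume(labels, path, min_bits = 16)
}

pick_int_type <- function(hi, lo, min_bits = 8) {
  if (lo < 0) "int32"
  else if (hi < 256 && min_bits <= 8) "uint8"
  else if (hi < 65536 && min_bits <= 16) "uint16"
  else "uint32"
}

read_slice <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    img <- png::readPNG(f, info = TRUE)
    depth <- tryCatch(attr(img, "info")$bit.depth, error = function(e) NULL)
    if (is.null(depth)) depth <- 8
    img <- drop_channels(img)
    round(img * (2^depth - 1))
  } else {
    drop_channels(tiff::readTIFF(f, as.is = TRUE))
  }
}

drop_channels <- function(m) {
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] == 1L) m <- m[, , 1]
    else stop("multi-channel slices are not supported; grayscale expected", call. = FALSE)
  }
  m
}

stack_slices <- function(slices) {
  nz <- length(slices)
  d2 <- dim(slices[[1]])
  out <- array(0, c(nz, d2[1], d2[2]))
  for (z in seq_len(nz)) out[z, , ] <- slices[[z]]
  out
}

#' Natural-number file ordering
#'
#' Orders names so that embedded integers compare numerically
#' (`s2 < s10`), avoiding the lexicographic `s10 < s2` misordering.
#' @param x character vector of names.
#' @return An integer permutation, as [order()].
#' @export
natural_order <- function(x) {
  keys <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(d)
      formatC(sub("^0+(?=.)", "", d, perl = TRUE), width = 20, flag = "0"))
    s
  }, character(1), USE.NAMES = FALSE)
  order(keys, x)
}

# --- minimal NRRD support (raw and gzip encodings, scalar types) ---------

nrrd_types <- list(
  uint8 = list(mode = "int", size = 1, signed = FALSE),
  uchar = list(mode = "int", size = 1, signed = FALSE),
  uint16 = list(mode = "int", size = 2, signed = FALSE),
  `unsigned short` = list(mode = "int", size = 2, signed = FALSE),
  int16 = list(mode = "int", size = 2, signed = TRUE),
  short = list(mode = "int", size = 2, signed = TRUE),
  int32 = list(mode = "int", size = 4, signed = TRUE),
  int = list(mode = "int", size = 4, signed = TRUE),
  uint32 = list(mode = "int", size = 4, signed = FALSE),
  `unsigned int` = list(mode = "int", size = 4, signed = FALSE),
  float = list(mode = "float", size = 4, signed = TRUE),
  double = list(mode = "float", size = 8, signed = TRUE)
)

read_nrrd_bin <- function(src, spec, n, endian) {
  if (spec$mode == "float") {
    readBin(src, "numeric", n = n, size = spec$size, endian = endian)
  } else {
    # readBin has no unsigned 4-byte mode; reinterpret negatives
    signed <- if (spec$size < 4) spec$signed else TRUE
    v <- readBin(src, "integer", n = n, size = spec$size, signed = signed, endian = endian)
    if (!spec$signed && spec$size == 4 && any(v < 0)) v <- ifelse(v < 0, v + 2^32, v)
    v
  }
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) stop("'", path, "' is not an NRRD file", call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in '", path, "'", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  type <- fields[["type"]]
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type '", type, "'", call. = FALSE)
  ndim <- as.integer(fields[["dimension"]])
  if (!identical(ndim, 3L)) stop("only 3D NRRD volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  n <- prod(sizes)
  enc <- tolower(fields[["encoding"]] %||% "raw")
  endian <- if (grepl("big", fields[["endian"]] %||% "little")) "big" else "little"
  if (enc %in% c("raw")) {
    vals <- read_nrrd_bin(con, spec, n, endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.info(path)$size)
    buf <- memDecompress(comp, type = "gzip")
    vals <- read_nrrd_bin(buf, spec, n, endian)
  } else stop("unsupported NRRD encoding '", enc, "'", call. = FALSE)
  if (length(vals) != n) stop("NRRD data shorter than header promises", call. = FALSE)
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    # sizes/spacings are fastest-axis first = (z, y, x) in our layout
    spacing <- sp
  }
  list(data = array(vals, dim = sizes), spacing = spacing)
}

write_nrrd <- function(data, path, spacing, type = "double") {
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type '", type, "'", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(data), collapse = " ")),
           paste0("spacings: ", paste(format(spacing, digits = 17), collapse = " ")),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con)
  vals <- as.vector(data)
  if (spec$mode == "int") storage.mode(vals) <- "integer"
  writeBin(vals, con, size = spec$size, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
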