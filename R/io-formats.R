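# Readers/writers for the supported observation formats.
#
# NIfTI volumes go through RNifti. The MGH volume format and the FreeSurfer
# curvature (per-vertex scalar) format have no reader in the installed R
# stack, so both are implemented here directly against their on-disk
# layouts (big-endian binary; .mgz and .nii.gz are gzip-wrapped).

image_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nii")
  if (grepl("\\.mg[hz]$", p)) return("mgh")
  if (grepl("\\.(thickness|area|curv)$", p)) return("curv")
  abort(sprintf("unsupported image extension: %s", basename(path)))
}

#' Read a single image
#'
#' Reads one observation image: a NIfTI (`.nii`/`.nii.gz`) or MGH
#' (`.mgh`/`.mgz`) volume, or a FreeSurfer curvature-style per-vertex file
#' (`.thickness`/`.area`/`.curv`).
#'
#' @param path File path.
#' @return A list: `data` (3D array for volumes, numeric vector for
#'   surfaces), `type`, `dim`, `affine` (volumes), `format`, and
#'   format-specific metadata used to write compatible outputs.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image not found: %s", path))
  fmt <- image_format(path)
  switch(fmt,
    nii = {
      im <- RNifti::readNifti(path)
      list(data = array(as.numeric(im), dim = dim(im)), type = "volume",
           dim = dim(im), affine = unclass(RNifti::xform(im)),
           format = "nii", template = RNifti::niftiHeader(im))
    },
    mgh = read_mgh(path),
    curv = {
      v <- read_curv(path)
      list(data = v, type = "surface", dim = length(v), affine = NULL,
           format = "curv", template = NULL)
    })
}

#' Write a single image
#'
#' Writes an array (or per-vertex vector) in the format implied by the file
#' extension, carrying over the geometry of a reference image read with
#' [read_image()]. Volumes keep the reference affine exactly.
#'
#' @param data 3D/4D array (volumes) or numeric vector (surfaces).
#' @param path Output path; its extension selects the format and must match
#'   the reference's format.
#' @param reference A list from [read_image()] (or the `geometry` element
#'   of an observation stack) providing affine/header information.
#' @param datatype Storage type for NIfTI/MGH output: `"float"` or
#'   `"int32"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(data, path, reference = NULL, datatype = "float") {
  fmt <- image_format(path)
  if (!is.null(reference$format) && reference$format != fmt) {
    abort(sprintf("output extension '%s' does not match the input format '%s'",
                  fmt, reference$format))
  }
  switch(fmt,
    nii = {
      im <- if (!is.null(reference$template)) {
        RNifti::asNifti(data, reference = reference$template)
      } else RNifti::asNifti(data)
      RNifti::writeNifti(im, path, datatype = datatype)
    },
    mgh = write_mgh(data, path, reference, datatype),
    curv = write_curv(as.numeric(data), path))
  invisible(path)
}

# ---- MGH volumes --------------------------------------------------------

MGH_HEADER_BYTES <- 284L

read_mgh <- function(path) {
  con <- if (grepl("\\.mgz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  rint <- function(n) readBin(con, "integer", n, size = 4, endian = "big")
  version <- rint(1)
  if (version != 1) abort(sprintf("unsupported MGH version %d in %s", version, path))
  d <- rint(4)                       # width, height, depth, nframes
  type <- rint(1)
  rint(1)                            # dof
  goodras <- readBin(con, "integer", 1, size = 2, endian = "big")
  spacing <- c(1, 1, 1); Mdc <- diag(3); c_ras <- c(0, 0, 0)
  used <- 30L
  if (goodras == 1) {
    spacing <- readBin(con, "numeric", 3, size = 4, endian = "big")
    Mdc <- matrix(readBin(con, "numeric", 9, size = 4, endian = "big"), 3, 3)
    c_ras <- readBin(con, "numeric", 3, size = 4, endian = "big")
    used <- used + 60L
  }
  readBin(con, "raw", MGH_HEADER_BYTES - used)
  nvox <- prod(d)
  vals <- switch(as.character(type),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = FALSE, endian = "big")),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 4, endian = "big")),
    "3" = readBin(con, "numeric", nvox, size = 4, endian = "big"),
    "4" = as.numeric(readBin(con, "integer", nvox, size = 2, endian = "big")),
    abort(sprintf("unsupported MGH data type %d", type)))
  dims <- d[1:3]
  arr <- array(vals, dim = if (d[4] > 1) d else dims)
  R <- Mdc %*% diag(spacing)
  affine <- diag(4)
  affine[1:3, 1:3] <- R
  affine[1:3, 4] <- c_ras - R %*% (dims / 2)
  list(data = arr, type = "volume", dim = dims, affine = affine,
       format = "mgh",
       template = list(spacing = spacing, Mdc = Mdc, c_ras = c_ras))
}

write_mgh <- function(data, path, reference = NULL, datatype = "float") {
  dims <- dim(data) %||% length(data)
  if (length(dims) == 3) dims <- c(dims, 1L)
  tpl <- reference$template %||% list(spacing = c(1, 1, 1), Mdc = diag(3),
                                      c_ras = c(0, 0, 0))
  con <- if (grepl("\\.mgz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size = 4) writeBin(as.integer(x), con, size = size, endian = "big")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "big")
  wint(1); wint(dims)
  wint(if (datatype == "int32") 1L else 3L)
  wint(0)                                  # dof
  wint(1, size = 2)                        # goodRASflag
  wflt(tpl$spacing); wflt(as.numeric(tpl$Mdc)); wflt(tpl$c_ras)
  writeBin(raw(MGH_HEADER_BYTES - 90L), con)
  if (datatype == "int32") wint(as.vector(data)) else wflt(as.vector(data))
  invisible(path)
}

# ---- FreeSurfer curvature files -----------------------------------------

CURV_MAGIC <- 16777215L  # 0xFFFFFF, the "new format" tag

read_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  b <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  magic <- b[1] * 65536L + b[2] * 256L + b[3]
  if (magic != CURV_MAGIC) abort(sprintf("not a curvature file: %s", path))
  vnum <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 4, endian = "big")  # fnum, vals/vertex
  readBin(con, "numeric", vnum, size = 4, endian = "big")
}

write_curv <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255, 255, 255)), con)
  writeBin(c(length(values), 0L, 1L), con, size = 4, endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}
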