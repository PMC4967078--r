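#' Construct a 3D CT volume grid
#'
#' A `volume_grid` is a 3D array of scalar voxel values (Hounsfield Units for
#' CT) together with the physical voxel spacing in mm. It is the container on
#' which regions of interest are defined and features are computed.
#'
#' @param values numeric 3D array of voxel values (HU).
#' @param spacing numeric length-3 vector, mm per voxel along each axis; all
#'   components must be positive.
#' @return An object of class `volume_grid` with elements `values` (3D array),
#'   `spacing` and `shape`.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v$values)
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive lengths (mm/voxel)")
  structure(
    list(values = values, spacing = spacing, shape = dim(values)),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  v <- x$values
  cat("  value range [", format(min(v)), ", ", format(max(v)), "] HU\n", sep = "")
  invisible(x)
}

#' Construct a binary region-of-interest mask
#'
#' An `roi_mask` marks the voxel set over which features are computed. It
#' shares the voxel grid (shape) of its volume; voxel indices are 1-based in R
#' but the mask is stored as a logical array so set operations are cheap.
#'
#' @param mask logical (or 0/1 numeric) 3D array; `TRUE` marks member voxels.
#' @return An object of class `roi_mask` with elements `mask` (logical array),
#'   `shape` and `size` (number of member voxels).
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
#' roi_mask(m)$size
#' @export
roi_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("'mask' must be a logical 3D array")
  mask[is.na(mask)] <- FALSE
  structure(
    list(mask = mask, shape = dim(mask), size = sum(mask)),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(x$shape, collapse = " x "),
      " grid, |Omega| = ", x$size, " voxels\n", sep = "")
  invisible(x)
}

check_mask_on_volume <- function(volume, mask) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "roi_mask"))
  if (!all(volume$shape == mask$shape))
    stop("mask shape (", paste(mask$shape, collapse = "x"),
         ") does not match volume shape (",
         paste(volume$shape, collapse = "x"), ")")
  if (mask$size < 1L) stop("mask is empty: |Omega| >= 1 required")
  invisible(TRUE)
}

roi_values <- function(volume, mask) {
  check_mask_on_volume(volume, mask)
  volume$values[mask$mask]
}

## ---- I/O: NIfTI via RNifti, MetaImage by hand ------------------------------

#' Read and write volumes and masks
#'
#' Volumes and masks are exchanged as NIfTI (`.nii`, `.nii.gz`) through
#' \pkg{RNifti}, or as MetaImage (`.mha` single-file, `.mhd` + `.raw`)
#' written/read directly (uncompressed, MET_UCHAR / MET_SHORT / MET_FLOAT /
#' MET_DOUBLE). Masks are stored as 0/1 volumes on the same grid.
#'
#' @param x a `volume_grid` or `roi_mask`.
#' @param path file path; the extension selects the format.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a `volume_grid`; `read_mask()` returns an `roi_mask` (non-zero voxels).
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "roi_mask"))
    x <- volume_grid(array(as.numeric(x$mask), x$shape), c(1, 1, 1))
  stopifnot(inherits(x, "volume_grid"))
  ext <- tolower(file_ext2(path))
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(x$values)
    RNifti::pixdim(img) <- x$spacing
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(x, path)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  ext <- tolower(file_ext2(path))
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim(img)[1:3])
    sp <- RNifti::pixdim(img)[1:3]
    volume_grid(vals, sp)
  } else if (ext %in% c("mha", "mhd")) {
    read_metaimage(path)
  } else stop("unsupported volume format: ", path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  roi_mask(v$values != 0)
}

file_ext2 <- function(path) {
  b <- basename(path)
  if (grepl("\\.nii\\.gz$", b, ignore.case = TRUE)) return("nii.gz")
  tools::file_ext(b)
}

# MetaImage: plain-text header, raw little-endian data block.
write_metaimage <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(x$shape, collapse = " ")),
    paste("ElementSpacing =", paste(format(x$spacing, trim = TRUE), collapse = " ")),
    "ElementType = MET_FLOAT"
  )
  if (ext == "mha") {
    hdr <- c(hdr, "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(x$values), con, size = 4L, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c(hdr, paste("ElementDataFile =", rawname))
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x$values), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed MetaImage header: ", path)
    hdr <- c(hdr, line)
    if (grepl("^\\s*ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  shape <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  etype <- get("ElementType", "MET_FLOAT")
  if (!is.null(get("CompressedData")) &&
      tolower(get("CompressedData")) == "true")
    stop("compressed MetaImage not supported")
  n <- prod(shape)
  readers <- list(
    MET_UCHAR  = function(c) as.numeric(readBin(c, "integer", n, size = 1L, signed = FALSE)),
    MET_SHORT  = function(c) as.numeric(readBin(c, "integer", n, size = 2L, signed = TRUE, endian = "little")),
    MET_FLOAT  = function(c) readBin(c, "numeric", n, size = 4L, endian = "little"),
    MET_DOUBLE = function(c) readBin(c, "numeric", n, size = 8L, endian = "little")
  )
  if (is.null(readers[[etype]])) stop("unsupported ElementType: ", etype)
  datafile <- get("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    vals <- readers[[etype]](con)
  } else {
    con2 <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(con2), add = TRUE)
    vals <- readers[[etype]](con2)
  }
  volume_grid(array(vals, shape), spacing)
}
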