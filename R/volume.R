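#' CT volume container
#'
#' A minimal in-memory container for a 3-D CT volume: a numeric array of
#' Hounsfield units plus the physical voxel spacing along each array axis.
#' Axis semantics are purely positional ("ijk"): masks produced by the
#' segmentation stages share the volume's grid exactly, and physical
#' coordinates are `index * spacing`.
#'
#' @param data 3-D numeric array of HU values (finite).
#' @param spacing numeric length-3, mm per voxel along each array axis
#'   (all > 0).
#' @param axes axis-order convention tag recorded with the volume;
#'   positional by default.
#' @return An object of class `ct_volume` with elements `data`, `spacing`
#'   and `axes`.
#' @export
ct_volume <- function(data, spacing, axes = "ijk") {
  if (length(dim(data)) != 3L)
    fl_input_error("volume data must be a 3-D array, got %d dims",
                   length(dim(data)))
  if (!all(is.finite(data)))
    fl_input_error("volume contains non-finite HU values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    fl_input_error("spacing must be three positive numbers (mm)")
  structure(list(data = data, spacing = spacing, axes = axes),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary mask aligned to a CT volume
#'
#' @param data logical array (2-D or 3-D).
#' @param role free-text role tag, e.g. `"lung"`, `"airway"`,
#'   `"refined-lung"`.
#' @param spacing optional voxel spacing carried along for physically
#'   scaled operations.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, role = "mask", spacing = NULL) {
  if (!is.logical(data) || is.null(dim(data)))
    fl_input_error("mask data must be a logical array")
  structure(list(data = data, role = role, spacing = spacing),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask role=%s> %s voxels, %d foreground\n", x$role,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

as_mask_array <- function(x) {
  if (inherits(x, "binary_mask")) x$data
  else if (is.logical(x) && !is.null(dim(x))) x
  else fl_input_error("expected a binary_mask or logical array")
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(as_mask_array(mask))))
    fl_input_error("mask shape %s does not match volume shape %s",
                   paste(dim(as_mask_array(mask)), collapse = "x"),
                   paste(dim(volume$data), collapse = "x"))
  invisible(TRUE)
}

#' Read a CT volume from disk
#'
#' Reads NIfTI (`.nii`, `.nii.gz`; primary format) or MetaImage
#' (`.mhd` + raw). Voxel spacing is taken from the header and must be
#' present and positive -- there is no silent 1 mm fallback. DICOM series
#' are not supported; pointing at one raises an explicit error.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.mhd` file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) fl_input_error("file not found: %s", path)
  lower <- tolower(path)
  if (dir.exists(path) || grepl("\\.dcm$", lower))
    fl_input_error(paste0("DICOM input is not supported; convert the series",
                          " to NIfTI first: %s"), path)
  if (grepl("\\.mhd$", lower)) return(read_metaimage(path))
  if (!grepl("\\.nii(\\.gz)?$", lower))
    fl_input_error("unrecognised volume format (expected .nii/.nii.gz/.mhd): %s",
                   path)
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")
  if (is.null(spacing)) spacing <- RNifti::pixdim(img)
  spacing <- as.numeric(spacing)[seq_len(3)]
  if (length(spacing) < 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    fl_input_error("NIfTI header of %s carries no usable voxel spacing", path)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  ct_volume(arr, spacing)
}

#' Write a CT volume or mask as NIfTI
#'
#' Volumes are written as float32 HU, masks as uint8, with voxel spacing
#' in the header.
#'
#' @param x a [ct_volume()] or [binary_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing spacing override for masks lacking one.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "ct_volume")) {
    arr <- x$data
    spacing <- x$spacing
    dtype <- "float"
  } else if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$data), dim = dim(x$data))
    spacing <- spacing %||% x$spacing
    if (is.null(spacing))
      fl_input_error("mask has no spacing; pass `spacing` explicitly")
    dtype <- "uint8"
  } else {
    fl_input_error("write_volume() expects a ct_volume or binary_mask")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

# Minimal MetaImage (.mhd + detached raw) reader: text header of
# `Key = value` lines plus a flat binary voxel file.
read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  need <- function(key) {
    if (is.null(kv[[key]]))
      fl_input_error("MetaImage header %s is missing required key %s",
                     path, key)
    kv[[key]]
  }
  ndims <- as.integer(need("NDims"))
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  if (length(dims) != ndims) fl_input_error("DimSize does not match NDims")
  spacing <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    fl_input_error("MetaImage header of %s has invalid ElementSpacing", path)
  etype <- need("ElementType")
  spec <- switch(etype,
    "MET_UCHAR"  = list(what = "integer", size = 1L, signed = FALSE),
    "MET_SHORT"  = list(what = "integer", size = 2L, signed = TRUE),
    "MET_FLOAT"  = list(what = "double",  size = 4L, signed = TRUE),
    "MET_DOUBLE" = list(what = "double",  size = 8L, signed = TRUE),
    fl_input_error("unsupported MetaImage ElementType: %s", etype))
  datafile <- need("ElementDataFile")
  datapath <- file.path(dirname(path), datafile)
  if (!file.exists(datapath))
    fl_input_error("MetaImage data file not found: %s", datapath)
  big <- identical(tolower(kv[["BinaryDataByteOrderMSB"]] %||% "false"), "true")
  n <- prod(dims)
  raw <- readBin(datapath, what = spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = if (big) "big" else "little")
  if (length(raw) < n)
    fl_input_error("MetaImage data file %s is truncated", datapath)
  arr <- array(as.numeric(raw), dim = dims)
  if (ndims == 2L) {
    arr <- array(arr, dim = c(dims, 1L))
    spacing <- c(spacing, 1)
  }
  ct_volume(arr, spacing)
}
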