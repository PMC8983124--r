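#' Crofton perimeter of a binary region
#'
#' Four-direction Crofton intercept estimator with direction weights
#' calibrated so the estimate is exact for axis-aligned rectangles and
#' for disks in the continuum limit (uniform weights systematically
#' underestimate rectilinear boundaries by ~5%). Transitions are counted
#' along rows, columns and both diagonals of the zero-padded image;
#' diagonal counts enter with line spacing `1/sqrt(2)`.
#'
#' @param mask logical matrix (foreground = region).
#' @param pixel_size physical size of a pixel edge (default 1).
#' @return Estimated perimeter in physical units.
#' @export
crofton_perimeter <- function(mask, pixel_size = 1) {
  if (!is.matrix(mask)) fl_input_error("mask must be a matrix")
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  nr <- nrow(m); nc <- ncol(m)
  ch <- sum(m[, -1L] != m[, -nc])
  cv <- sum(m[-1L, ] != m[-nr, ])
  cd1 <- sum(m[-1L, -1L] != m[-nr, -nc])
  cd2 <- sum(m[-1L, -nc] != m[-nr, -1L])
  beta <- (1 - pi / 4) / (pi * (sqrt(2) - 1))
  alpha <- 0.25 - beta
  pi * (alpha * (ch + cv) + beta * (cd1 + cd2) / sqrt(2)) * pixel_size
}

#' Label candidate airspaces in a histology-like image
#'
#' Binarizes the image (Otsu by default for grayscale input; identity for
#' logical input), labels 8-connected foreground regions, removes any
#' region overlapping the airway-exclusion mask by even one pixel
#' (conservative stand-in for the investigator who removes
#' pseudostratified-epithelium airways by hand), removes specks below
#' `min_size_px`, and flags regions touching the image border (incomplete
#' airspaces bias SA/P upward and are excluded from metrics by default).
#'
#' @param image logical or numeric matrix, or an object from
#'   [make_airspace_image()]. Airspaces are the low-stain (bright)
#'   phase of a grayscale image.
#' @param binarize `"auto"` (Otsu), `"fixed"` (use `threshold`), or
#'   `"none"` (input already binary).
#' @param threshold fixed binarization threshold for `binarize =
#'   "fixed"`.
#' @param foreground whether airspaces are the `"bright"` or `"dark"`
#'   phase of a grayscale image.
#' @param min_size_px minimum region size kept, in pixels.
#' @param exclusion optional logical matrix (TRUE = exclude) of the same
#'   shape.
#' @return A list of class `airspace_label_map`: `labels` (integer
#'   matrix, labels contiguous from 1), `n`, `min_size_px`,
#'   `border_labels` (labels touching the image border).
#' @export
label_airspaces <- function(image, binarize = c("auto", "fixed", "none"),
                            threshold = NULL,
                            foreground = c("bright", "dark"),
                            min_size_px = 10L, exclusion = NULL) {
  binarize <- match.arg(binarize)
  foreground <- match.arg(foreground)
  if (inherits(image, "airspace_image")) image <- image$image
  if (!is.matrix(image)) fl_input_error("image must be a matrix")
  if (is.logical(image)) {
    fg <- image
  } else if (binarize == "none") {
    fg <- image != 0
  } else {
    rng <- range(image)
    if (diff(rng) == 0)
      fl_degenerate_error("flat image: no foreground after binarization")
    scaled <- (image - rng[1]) / diff(rng)
    thr <- if (binarize == "fixed") {
      if (is.null(threshold))
        fl_input_error("binarize = 'fixed' needs a threshold")
      (threshold - rng[1]) / diff(rng)
    } else {
      EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    }
    fg <- if (foreground == "bright") scaled > thr else scaled < thr
  }
  if (!is.null(exclusion)) {
    if (!identical(dim(exclusion), dim(fg)))
      fl_input_error("exclusion mask shape does not match the image")
    exclusion <- exclusion != 0
  }
  if (!any(fg)) fl_degenerate_error("empty foreground after binarization")
  lab <- label_components(fg, connectivity = 26)  # 8-connectivity in 2-D
  sizes <- component_sizes(lab)
  drop <- which(sizes < min_size_px)
  if (!is.null(exclusion) && any(exclusion))
    drop <- union(drop, setdiff(unique(lab[exclusion]), 0L))
  keep <- setdiff(seq_along(sizes), drop)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- relabel[lab[nz]]
  border <- unique(c(out[c(1, nrow(out)), ], out[, c(1, ncol(out))]))
  structure(list(labels = out, n = length(keep),
                 min_size_px = as.integer(min_size_px),
                 border_labels = sort(border[border > 0L])),
            class = "airspace_label_map")
}

#' Per-airspace area, perimeter and SA/P
#'
#' Area is the pixel count scaled by the squared pixel size; perimeter is
#' the calibrated Crofton estimate ([crofton_perimeter()]); SA/P is their
#' ratio, one value per airspace. Border-touching regions are dropped
#' unless `include_border = TRUE`.
#'
#' @param label_map an [label_airspaces()] result.
#' @param pixel_size_um physical pixel size (um/px, > 0).
#' @param include_border include regions flagged as border-touching.
#' @param image,lobe optional identifiers copied onto every row.
#' @return A data frame of class `morphometry_result`: `image`, `lobe`,
#'   `label`, `area_um2`, `perimeter_um`, `sa_p_um`, `border`.
#' @export
airspace_metrics <- function(label_map, pixel_size_um,
                             include_border = FALSE,
                             image = NA_character_, lobe = NA_character_) {
  if (!inherits(label_map, "airspace_label_map"))
    fl_input_error("airspace_metrics() expects an airspace_label_map")
  if (pixel_size_um <= 0) fl_input_error("pixel size must be > 0")
  lab <- label_map$labels
  if (label_map$n < 1L) fl_degenerate_error("label map has no airspaces")
  rows <- vector("list", label_map$n)
  for (l in seq_len(label_map$n)) {
    idx <- which(lab == l, arr.ind = TRUE)
    rb <- range(idx[, 1]); cb <- range(idx[, 2])
    sub <- lab[rb[1]:rb[2], cb[1]:cb[2], drop = FALSE] == l
    area <- nrow(idx) * pixel_size_um^2
    perim <- crofton_perimeter(sub, pixel_size_um)
    if (perim <= 0) {
      warning(sprintf("skipping degenerate region %d (zero perimeter)", l))
      next
    }
    rows[[l]] <- data.frame(image = image, lobe = lobe, label = l,
                            area_um2 = area, perimeter_um = perim,
                            sa_p_um = area / perim,
                            border = l %in% label_map$border_labels)
  }
  out <- do.call(rbind, rows)
  if (!include_border) out <- out[!out$border, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("morphometry_result", "data.frame"))
}

#' Lobe and animal SA/P summaries
#'
#' The lobe mean is the unweighted mean of per-airspace SA/P over every
#' airspace measured in that lobe (all images pooled); the animal mean is
#' the unweighted mean of its lobe means. A pooled alternative (total
#' area / total perimeter per lobe) is available via `method`.
#'
#' @param per_region a [airspace_metrics()] result (or several
#'   `rbind`-ed), with a `lobe` column.
#' @param method `"per_airspace"` (mean of ratios; default) or `"pooled"`
#'   (ratio of sums).
#' @return A list of class `morphometry_summary`: `lobe_means` (data
#'   frame `lobe`, `sa_p_um`, `n_airspaces`) and `animal_mean_um`.
#' @export
summarize_lobes <- function(per_region,
                            method = c("per_airspace", "pooled")) {
  method <- match.arg(method)
  df <- as.data.frame(per_region)
  df <- df[!is.na(df$sa_p_um), , drop = FALSE]
  if (!nrow(df)) fl_degenerate_error("no lobes with measured airspaces")
  by_lobe <- split(df, df$lobe, drop = TRUE)
  lobe_means <- do.call(rbind, lapply(by_lobe, function(g) {
    sap <- if (method == "per_airspace") mean(g$sa_p_um)
           else sum(g$area_um2) / sum(g$perimeter_um)
    data.frame(lobe = g$lobe[1], sa_p_um = sap, n_airspaces = nrow(g))
  }))
  rownames(lobe_means) <- NULL
  structure(list(lobe_means = lobe_means,
                 animal_mean_um = mean(lobe_means$sa_p_um),
                 method = method),
            class = "morphometry_summary")
}

#' Read a grayscale histology image
#'
#' TIFF/PNG via EBImage; multichannel images are averaged to one channel.
#'
#' @param path image path.
#' @return numeric matrix of intensities.
#' @export
read_airspace_image <- function(path) {
  if (!file.exists(path)) fl_input_error("file not found: %s", path)
  img <- EBImage::readImage(path)
  arr <- EBImage::imageData(img)
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  as.matrix(arr)
}
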