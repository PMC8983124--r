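# R-facing wrappers around the compiled binary-image primitives.

#' Label connected components of a binary array
#'
#' @param mask logical 2-D or 3-D array.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners); on 2-D input
#'   these reduce to 4- and 8-connectivity.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask, connectivity = 26) {
  .cc_label_cpp(as_mask_array(mask), as.integer(connectivity))
}

# Structuring-element offsets for an ellipsoid of the given per-axis
# radius in voxels (a "ball" of physical radius r becomes an ellipsoid
# once anisotropic spacing is divided out).  Includes the origin.
ball_offsets <- function(radius_vox) {
  radius_vox <- pmax(as.numeric(radius_vox), 0)
  if (length(radius_vox) == 1L) radius_vox <- rep(radius_vox, 3L)
  r <- ceiling(radius_vox)
  grid <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- with(grid, (dx / max(radius_vox[1], .Machine$double.eps))^2 +
                 (dy / max(radius_vox[2], .Machine$double.eps))^2 +
                 (dz / max(radius_vox[3], .Machine$double.eps))^2 <= 1 + 1e-9)
  keep[grid$dx == 0 & grid$dy == 0 & grid$dz == 0] <- TRUE
  as.matrix(grid[keep, , drop = FALSE])
}

storage_mode_int <- function(m) { storage.mode(m) <- "integer"; m }

#' Binary dilation / erosion / closing with an ellipsoidal element
#'
#' `binary_closing()` pads the array by the element radius before the
#' dilation so structures near the border are not clipped against it.
#'
#' @param mask logical array.
#' @param radius_vox per-axis radius in voxels (scalar or length 3); radius
#'   0 is the identity.
#' @return logical array of the same shape.
#' @export
binary_dilate <- function(mask, radius_vox) {
  m <- as_mask_array(mask)
  if (all(radius_vox <= 0)) return(m)
  .dilate_cpp(m, storage_mode_int(ball_offsets(radius_vox)))
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius_vox) {
  m <- as_mask_array(mask)
  if (all(radius_vox <= 0)) return(m)
  .erode_cpp(m, storage_mode_int(ball_offsets(radius_vox)))
}

#' @rdname binary_dilate
#' @export
binary_closing <- function(mask, radius_vox) {
  m <- as_mask_array(mask)
  if (all(radius_vox <= 0)) return(m)
  r <- ceiling(rep(as.numeric(radius_vox), length.out = 3L))
  d <- dim(m)
  flat <- length(d) == 2L
  if (flat) { d <- c(d, 1L); dim(m) <- d; r[3] <- 0 }
  padded <- array(FALSE, dim = d + 2L * r)
  idx <- lapply(seq_len(3L), function(a) seq_len(d[a]) + r[a])
  padded[idx[[1]], idx[[2]], idx[[3]]] <- m
  off <- storage_mode_int(ball_offsets(radius_vox))
  closed <- .erode_cpp(.dilate_cpp(padded, off), off)
  out <- closed[idx[[1]], idx[[2]], idx[[3]]]
  if (flat) dim(out) <- d[1:2] else dim(out) <- d
  out
}

#' Fill enclosed cavities in a binary array
#'
#' Background is flooded from the array border (face connectivity);
#' anything not reached is an enclosed hole and becomes foreground.
#'
#' @param mask logical array.
#' @return logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  .fill_holes_cpp(as_mask_array(mask))
}

# component sizes of a label array, as a named integer vector
component_sizes <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}
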