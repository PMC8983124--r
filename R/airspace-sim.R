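#' Simulate a binary airspace image with analytic truth
#'
#' Places non-overlapping squares and disks (airspace = foreground) on a
#' background canvas and returns the image together with a truth table of
#' analytic area and perimeter per shape, for validating the morphometry
#' estimators.
#'
#' @param shapes list of shape descriptors, each a list with `kind`
#'   (`"square"` or `"disk"`), `at` (centre, pixel coordinates) and
#'   `side` (squares, px) or `radius` (disks, px).
#' @param canvas integer length-2 image size in pixels.
#' @param pixel_size_um physical pixel size (um/px).
#' @return A list of class `airspace_image` with elements `image` (logical
#'   matrix), `pixel_size_um`, and `truth` (data frame: `shape`, `kind`,
#'   `area_um2`, `perimeter_um`, `sa_p_um` -- analytic values).
#' @export
make_airspace_image <- function(shapes = list(), canvas = c(256L, 256L),
                                pixel_size_um = 1) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 2L || any(canvas <= 0))
    fl_input_error("canvas must be two positive integers")
  if (pixel_size_um <= 0) fl_input_error("pixel size must be > 0")
  img <- matrix(FALSE, canvas[1], canvas[2])
  rows <- list()
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    m <- matrix(FALSE, canvas[1], canvas[2])
    if (identical(s$kind, "square")) {
      half <- s$side / 2
      xr <- round(s$at[1] - half + 1):round(s$at[1] + half)
      yr <- round(s$at[2] - half + 1):round(s$at[2] + half)
      if (min(xr) < 1 || max(xr) > canvas[1] ||
          min(yr) < 1 || max(yr) > canvas[2])
        fl_input_error("shape %d exceeds the canvas", i)
      m[xr, yr] <- TRUE
      area <- s$side^2 * pixel_size_um^2
      perim <- 4 * s$side * pixel_size_um
    } else if (identical(s$kind, "disk")) {
      x <- seq_len(canvas[1]) - s$at[1]
      y <- seq_len(canvas[2]) - s$at[2]
      m <- outer(x^2, y^2, `+`) <= s$radius^2
      if (s$at[1] - s$radius < 1 || s$at[1] + s$radius > canvas[1] ||
          s$at[2] - s$radius < 1 || s$at[2] + s$radius > canvas[2])
        fl_input_error("shape %d exceeds the canvas", i)
      area <- pi * s$radius^2 * pixel_size_um^2
      perim <- 2 * pi * s$radius * pixel_size_um
    } else {
      fl_input_error("unknown shape kind: %s", s$kind %||% "<missing>")
    }
    if (any(m & img))
      fl_input_error("shape %d overlaps a previously placed shape", i)
    img <- img | m
    rows[[i]] <- data.frame(shape = i, kind = s$kind, area_um2 = area,
                            perimeter_um = perim, sa_p_um = area / perim)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(shape = integer(0), kind = character(0),
               area_um2 = numeric(0), perimeter_um = numeric(0),
               sa_p_um = numeric(0))
  structure(list(image = img, pixel_size_um = pixel_size_um, truth = truth),
            class = "airspace_image")
}
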