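#' Threshold-based lung segmentation
#'
#' Candidate voxels are those at or below `lung_threshold` HU. Any
#' low-attenuation connected component touching the grid border is
#' exterior air (or an airway lumen opening onto it) and is discarded;
#' of the remaining components, the largest `keep_components` are kept.
#' In a ferret the left and right lungs may or may not fuse at the
#' carina, so up to two components are retained by default. The airway
#' lumen may still be included at this stage; it is removed later by
#' [refine_lung_mask()].
#'
#' @param volume a [ct_volume()].
#' @param lung_threshold HU threshold separating aerated lung from soft
#'   tissue; -320 HU default.
#' @param keep_components maximum number of lung components to keep.
#' @return A [binary_mask()] with role `"lung"`.
#' @export
segment_lungs <- function(volume, lung_threshold = -320,
                          keep_components = 2L) {
  if (!inherits(volume, "ct_volume"))
    fl_input_error("segment_lungs() expects a ct_volume")
  cand <- volume$data <= lung_threshold
  if (!any(cand))
    fl_degenerate_error("no lung found: no voxel at or below %g HU",
                        lung_threshold)
  lab <- label_components(cand, connectivity = 26)
  d <- dim(lab)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  sizes <- component_sizes(lab)
  if (length(border_labels)) sizes[border_labels] <- 0L
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(keep_components,
                                                      sum(sizes > 0)))]
  keep <- keep[sizes[keep] > 0]
  if (!length(keep))
    fl_degenerate_error(paste0("no lung found: every low-attenuation",
                               " component touches the grid border"))
  binary_mask(array(lab %in% keep, dim = d), "lung", volume$spacing)
}

# Auto-seed for airway growing: on the top slice (last index of axis 3),
# find low-attenuation 2-D components that do not touch the slice edge
# (exterior air does), pick the darkest, and seed at the in-component
# voxel nearest its centroid.
auto_airway_seed <- function(volume, grow_threshold) {
  d <- dim(volume$data)
  top <- volume$data[, , d[3]]
  m <- top <= grow_threshold
  if (!any(m)) fl_degenerate_error("no airway opening on the top face")
  lab <- label_components(m, connectivity = 26)
  edge <- unique(c(lab[c(1, d[1]), ], lab[, c(1, d[2])]))
  interior <- setdiff(unique(lab[lab > 0L]), edge[edge > 0L])
  if (!length(interior))
    fl_degenerate_error(paste0("no interior low-attenuation component on",
                               " the top face; supply a seed voxel"))
  means <- vapply(interior, function(l) mean(top[lab == l]), numeric(1))
  pick <- interior[which.min(means)]
  ij <- which(lab == pick, arr.ind = TRUE)
  ctr <- colMeans(ij)
  best <- ij[which.min((ij[, 1] - ctr[1])^2 + (ij[, 2] - ctr[2])^2), ]
  c(best[1], best[2], d[3])
}

#' Region-growing airway segmentation with leak control
#'
#' Grows a 26-connected region from a seed in the tracheal lumen over
#' voxels at or below the growth threshold. The threshold starts
#' conservative and is relaxed stepwise; if relaxing by one step inflates
#' the region volume by more than `leak_factor`, the growth has breached
#' the airway wall into parenchyma and the pre-leak region is returned.
#'
#' @param volume a [ct_volume()].
#' @param seed_voxel integer length-3 voxel index of a lumen voxel, or
#'   `NULL` for automatic seeding (darkest interior low-attenuation
#'   component on the top face, centroid voxel).
#' @param grow_threshold initial HU growth threshold (-950 default).
#' @param leak_factor volume-jump ratio that triggers leak detection
#'   (2 = stop when the region doubles in one step).
#' @param step HU increment per relaxation step.
#' @param max_threshold last threshold attempted.
#' @return A [binary_mask()] with role `"airway"`; attribute
#'   `final_threshold` records the last accepted threshold and
#'   `leak_detected` whether relaxation was stopped by the leak rule.
#' @export
segment_airways <- function(volume, seed_voxel = NULL,
                            grow_threshold = -950, leak_factor = 2,
                            step = 10, max_threshold = -400) {
  if (!inherits(volume, "ct_volume"))
    fl_input_error("segment_airways() expects a ct_volume")
  d <- dim(volume$data)
  if (is.null(seed_voxel)) {
    seed_voxel <- auto_airway_seed(volume, grow_threshold)
  } else {
    seed_voxel <- as.integer(seed_voxel)
    if (length(seed_voxel) != 3L || any(seed_voxel < 1) ||
        any(seed_voxel > d))
      fl_input_error("seed voxel %s lies outside the volume",
                     paste(seed_voxel, collapse = ","))
  }
  seed_hu <- volume$data[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  if (seed_hu > grow_threshold)
    fl_input_error("seed voxel HU (%g) exceeds the growth threshold (%g)",
                   seed_hu, grow_threshold)
  seed0 <- (seed_voxel[3] - 1) * d[1] * d[2] + (seed_voxel[2] - 1) * d[1] +
    (seed_voxel[1] - 1)
  region <- .region_grow_cpp(volume$data, seed0, grow_threshold)
  vol_prev <- sum(region)
  thr <- grow_threshold
  leak <- FALSE
  while (thr + step <= max_threshold) {
    cand <- .region_grow_cpp(volume$data, seed0, thr + step)
    if (sum(cand) > leak_factor * vol_prev) { leak <- TRUE; break }
    thr <- thr + step
    region <- cand
    vol_prev <- sum(cand)
  }
  out <- binary_mask(region, "airway", volume$spacing)
  attr(out, "final_threshold") <- thr
  attr(out, "leak_detected") <- leak
  out
}

#' Refine the lung mask: remove airways, smooth, fill holes
#'
#' Subtracts the airway mask from the lung mask, smooths mediastinal
#' concavities with a 3-D morphological closing (ball of the given
#' physical radius, converted to a per-axis voxel radius), fills enclosed
#' cavities, and subtracts the airway once more so the result is
#' guaranteed disjoint from it. The closing-fill core is idempotent, so
#' applying the refinement twice at the same radius changes nothing.
#'
#' @param lung lung [binary_mask()] (or logical array).
#' @param airway airway [binary_mask()] (or logical array).
#' @param close_radius_mm closing-ball radius in mm (0 = no smoothing).
#' @param spacing voxel spacing in mm; taken from the lung mask when
#'   omitted.
#' @return A [binary_mask()] with role `"refined-lung"`.
#' @export
refine_lung_mask <- function(lung, airway, close_radius_mm = 2,
                             spacing = NULL) {
  l <- as_mask_array(lung)
  a <- as_mask_array(airway)
  if (!identical(dim(l), dim(a)))
    fl_input_error("lung and airway masks have different shapes")
  spacing <- spacing %||%
    (if (inherits(lung, "binary_mask")) lung$spacing else NULL)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  m <- l & !a
  radius_vox <- close_radius_mm / spacing
  m <- binary_closing(m, radius_vox)
  m <- fill_holes(m)
  binary_mask(m & !a, "refined-lung", spacing)
}

#' Percent low-attenuation area profile
#'
#' For each HU threshold, the percentage of refined-lung voxels with HU at
#' or below it (inclusive comparison). By construction the profile is
#' non-decreasing in the threshold.
#'
#' @param volume a [ct_volume()].
#' @param refined_lung the refined lung [binary_mask()].
#' @param thresholds HU thresholds; defaults to the four used for
#'   emphysema scoring.
#' @param subject optional subject id carried into the profile.
#' @return A data frame of class `laa_profile` with columns `subject`,
#'   `threshold_hu`, `percent`, `n_lung` (denominator voxel count).
#' @export
laa_profile <- function(volume, refined_lung,
                        thresholds = c(-950, -910, -900, -870),
                        subject = NA_character_) {
  if (!inherits(volume, "ct_volume"))
    fl_input_error("laa_profile() expects a ct_volume")
  check_aligned(volume, refined_lung)
  m <- as_mask_array(refined_lung)
  n <- sum(m)
  if (n == 0L) fl_degenerate_error("empty lung mask")
  hu <- volume$data[m]
  thresholds <- sort(thresholds)
  pct <- vapply(thresholds, function(th) 100 * sum(hu <= th) / n, numeric(1))
  structure(data.frame(subject = subject, threshold_hu = thresholds,
                       percent = pct, n_lung = n),
            class = c("laa_profile", "data.frame"))
}

#' Slope of %LAA against airflow obstruction across subjects
#'
#' Per HU threshold, an ordinary least-squares fit of %LAA on the
#' FEV_x:FVC ratio across subjects. A more negative slope means the
#' low-attenuation burden grows as airflow obstruction worsens.
#'
#' @param records data frame with columns `subject`, `threshold_hu`,
#'   `percent` and `fev_ratio` (one row per subject x threshold), e.g.
#'   stacked [laa_profile()]s merged with per-subject spirometry ratios.
#' @return A data frame of class `emphysema_fit` with columns
#'   `threshold_hu`, `slope`, `intercept`, `r_squared`, `n`.
#' @export
laa_function_slope <- function(records) {
  need <- c("subject", "threshold_hu", "percent", "fev_ratio")
  miss <- setdiff(need, names(records))
  if (length(miss))
    fl_input_error("records is missing column(s): %s",
                   paste(miss, collapse = ", "))
  fits <- lapply(split(records, records$threshold_hu), function(df) {
    if (nrow(df) < 2L)
      fl_degenerate_error("fewer than 2 subjects at threshold %g HU",
                          df$threshold_hu[1])
    if (diff(range(df$fev_ratio)) == 0)
      fl_degenerate_error(paste0("all FEV ratios identical at threshold",
                                 " %g HU; slope undefined"),
                          df$threshold_hu[1])
    fit <- lm(percent ~ fev_ratio, data = df)
    r2 <- if (diff(range(df$percent)) == 0) 1 else summary(fit)$r.squared
    data.frame(threshold_hu = df$threshold_hu[1],
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = r2, n = nrow(df))
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  structure(out[order(out$threshold_hu), ],
            class = c("emphysema_fit", "data.frame"))
}
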