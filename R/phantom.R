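#' Specification for a synthetic chest-CT phantom
#'
#' Describes a digital thorax used to exercise the QCT pipeline with known
#' ground truth: an elliptic soft-tissue body spanning the full
#' craniocaudal axis, two ellipsoidal lungs, and a bifurcating airway tree
#' whose trachea opens on the top face of the grid (collared by soft
#' tissue, so the lumen is never connected to the exterior air that
#' surrounds the body). A tunable fraction of lung voxels is re-labelled
#' emphysematous and drawn from a lower-attenuation HU distribution.
#'
#' HU mixture defaults place the usual low-attenuation thresholds
#' (-950 ... -870) between the normal-parenchyma and emphysema modes:
#' parenchyma N(-700, 60), emphysema N(-930, 30), airway lumen N(-1000, 5)
#' truncated at 2 SD (so every lumen voxel is at most -990 HU and region
#' growing at -950 recovers the full lumen), soft tissue N(+40, 20),
#' exterior air -1000 exactly.
#'
#' @param shape integer length-3 grid shape in voxels.
#' @param spacing voxel spacing in mm (length 3, > 0).
#' @param emphysema_fraction fraction `f` of lung voxels drawn from the
#'   emphysema HU distribution, in `[0, 1]`.
#' @param hu named list of HU mixture parameters: `parenchyma`,
#'   `emphysema`, `airway`, `soft_tissue` as `c(mean, sd)` and scalar
#'   `exterior`.
#' @param airway_depth branching depth of the airway tree (1 = trachea
#'   only, 2 = + main bronchi, 3 = + one segmental generation).
#' @param emphysema_mode `"bernoulli"` (voxelwise, exact expected
#'   fraction) or `"blobs"` (union of random spheres, spatially coherent).
#' @param seed integer RNG seed; identical spec + seed give identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L),
                         spacing = c(0.5, 0.5, 0.5),
                         emphysema_fraction = 0,
                         hu = list(parenchyma = c(-700, 60),
                                   emphysema = c(-930, 30),
                                   airway = c(-1000, 5),
                                   soft_tissue = c(40, 20),
                                   exterior = -1000),
                         airway_depth = 3L,
                         emphysema_mode = c("bernoulli", "blobs"),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape <= 0))
    fl_input_error("phantom shape must be three positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    fl_input_error("phantom spacing must be three positive numbers")
  if (!is.finite(emphysema_fraction) ||
      emphysema_fraction < 0 || emphysema_fraction > 1)
    fl_input_error("emphysema_fraction must lie in [0, 1]")
  defaults <- list(parenchyma = c(-700, 60), emphysema = c(-930, 30),
                   airway = c(-1000, 5), soft_tissue = c(40, 20),
                   exterior = -1000)
  hu <- modifyList(defaults, hu)
  for (comp in c("parenchyma", "emphysema", "airway", "soft_tissue")) {
    if (length(hu[[comp]]) != 2L || hu[[comp]][2] < 0)
      fl_input_error("hu$%s must be c(mean, sd) with sd >= 0", comp)
  }
  structure(list(shape = shape, spacing = spacing,
                 emphysema_fraction = emphysema_fraction, hu = hu,
                 airway_depth = as.integer(airway_depth),
                 emphysema_mode = match.arg(emphysema_mode),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rasterize a cylindrical tube from p0 to p1 (voxel coordinates): mark
# centres sampled every half voxel along the segment, then dilate by a
# ball of the tube radius.
tube_mask <- function(shape, p0, p1, radius) {
  len <- sqrt(sum((p1 - p0)^2))
  ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.5) + 1L))
  centres <- unique(round(cbind(p0[1] + ts * (p1[1] - p0[1]),
                                p0[2] + ts * (p1[2] - p0[2]),
                                p0[3] + ts * (p1[3] - p0[3]))))
  centres <- centres[centres[, 1] >= 1 & centres[, 1] <= shape[1] &
                     centres[, 2] >= 1 & centres[, 2] <= shape[2] &
                     centres[, 3] >= 1 & centres[, 3] <= shape[3], ,
                     drop = FALSE]
  m <- array(FALSE, dim = shape)
  m[centres] <- TRUE
  binary_dilate(m, radius)
}

ellipsoid_mask <- function(shape, centre, semi) {
  x <- (seq_len(shape[1]) - centre[1]) / semi[1]
  y <- (seq_len(shape[2]) - centre[2]) / semi[2]
  z <- (seq_len(shape[3]) - centre[3]) / semi[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d2 <= 1
}

rnorm_trunc2 <- function(n, mean, sd) {
  pmin(pmax(rnorm(n, mean, sd), mean - 2 * sd), mean + 2 * sd)
}

#' Generate a CT phantom with ground-truth masks
#'
#' Draws voxel HU values per compartment from the spec's distributions and
#' returns the volume together with aligned boolean truth masks (`lung`,
#' `airway`, `emphysema`). Invariants by construction: the emphysema mask
#' is a subset of the lung mask; the airway lumen is disjoint from the
#' lung (a 2-voxel soft-tissue wall sleeves every tube); exterior air
#' touches the grid border on all sides.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `ct_phantom` with elements `volume`
#'   ([ct_volume()]), `truth` (list of [binary_mask()]: `lung`, `airway`,
#'   `emphysema`) and `spec`.
#' @export
make_ct_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    fl_input_error("make_ct_phantom() expects a phantom_spec")
  shape <- spec$shape
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2

  # body: elliptic cylinder over the full z extent, exterior air outside
  xb <- ((seq_len(nx) - cx) / (0.42 * nx))^2
  yb <- ((seq_len(ny) - cy) / (0.42 * ny))^2
  body2d <- outer(xb, yb, `+`) <= 1
  core2d <- outer(((seq_len(nx) - cx) / (0.42 * nx - 3))^2,
                  ((seq_len(ny) - cy) / (0.42 * ny - 3))^2, `+`) <= 1
  body <- array(body2d, dim = shape)
  body_core <- array(core2d, dim = shape)

  # lungs sit either side of a mediastinal gap that is wider than twice
  # the default 2 mm closing radius, so mask refinement cannot bridge it
  lung_semi <- c(0.13 * nx, 0.25 * ny, 0.37 * nz)
  lungs <- ellipsoid_mask(shape, c(cx - 0.19 * nx, cy, 0.45 * nz), lung_semi) |
    ellipsoid_mask(shape, c(cx + 0.19 * nx, cy, 0.45 * nz), lung_semi)
  lungs <- lungs & body_core

  # airway tree: trachea opens at the top face (z = nz)
  rt <- max(2, round(0.022 * nx))
  carina <- c(cx, cy, 0.62 * nz)
  lumen <- tube_mask(shape, c(cx, cy, nz), carina, rt)
  if (spec$airway_depth >= 2L) {
    r2 <- max(2, round(rt * 0.75))
    for (s in c(-1, 1)) {
      hilum <- c(cx + s * 0.19 * nx, cy, 0.48 * nz)
      lumen <- lumen | tube_mask(shape, carina, hilum, r2)
      if (spec$airway_depth >= 3L) {
        r3 <- max(1, round(r2 * 0.6))
        for (t in c(-1, 1)) {
          tip <- c(cx + s * 0.19 * nx, cy + t * 0.10 * ny, 0.34 * nz)
          lumen <- lumen | tube_mask(shape, hilum, tip, r3)
        }
      }
    }
  }
  sleeve <- binary_dilate(lumen, 2)   # lumen + 2-voxel soft-tissue wall
  lung <- lungs & !sleeve

  hu <- spec$hu
  vol <- withr::with_seed(spec$seed, {
    v <- array(hu$exterior[1], dim = shape)
    soft <- body & !lung & !lumen     # includes the airway wall
    v[soft] <- rnorm(sum(soft), hu$soft_tissue[1], hu$soft_tissue[2])
    v[lung] <- rnorm(sum(lung), hu$parenchyma[1], hu$parenchyma[2])

    emph <- array(FALSE, dim = shape)
    f <- spec$emphysema_fraction
    lung_idx <- which(lung)
    if (f > 0 && length(lung_idx) > 0) {
      if (spec$emphysema_mode == "bernoulli") {
        emph[lung_idx[runif(length(lung_idx)) < f]] <- TRUE
      } else {
        target <- f * length(lung_idx)
        guard <- 0L
        while (sum(emph) < target && guard < 10000L) {
          guard <- guard + 1L
          ctr_i <- lung_idx[sample.int(length(lung_idx), 1L)]
          ctr <- arrayInd(ctr_i, shape)
          blob <- ellipsoid_mask(shape, as.numeric(ctr),
                                 rep(runif(1, 2, 5), 3L))
          emph <- emph | (blob & lung)
        }
      }
      v[emph] <- rnorm(sum(emph), hu$emphysema[1], hu$emphysema[2])
    }
    v[lumen] <- rnorm_trunc2(sum(lumen), hu$airway[1], hu$airway[2])
    list(v = v, emph = emph)
  })

  structure(list(
    volume = ct_volume(vol$v, spec$spacing),
    truth = list(lung = binary_mask(lung, "lung", spec$spacing),
                 airway = binary_mask(lumen, "airway", spec$spacing),
                 emphysema = binary_mask(vol$emph, "emphysema", spec$spacing)),
    spec = spec), class = "ct_phantom")
}
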