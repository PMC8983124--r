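#' Longitudinal cohort presets
#'
#' Generating parameters for synthetic IC/Ln-versus-age cohorts. The three
#' built-in presets reproduce the study design of the ferret genotype
#' comparison: per-genotype age slopes of 0.000093 (PiMM wild-type
#' controls), 0.00043 (PiZZ) and 0.00036 (AAT-KO) mL/cm per day, with
#' cohort sizes of 19, 6 and 13 animals followed over roughly 6-7 visits.
#' The generating model is
#' `y = beta * age + sex intercept + animal intercept + eps`, with the
#' animal intercept drawn once per animal (`N(0, random_intercept_sd)`)
#' and `eps ~ N(0, residual_sd)` per visit.
#'
#' Noise and intercept defaults (sex intercepts 0.85/0.95 mL/cm for
#' females/males, random-intercept SD 0.15, residual SD 0.10 mL/cm) put
#' the simulated IC/Ln on the ~1 mL/cm scale of an adult ferret.
#'
#' @param genotype genotype label; `"PiMM"`, `"PiZZ"` and `"AAT-KO"`
#'   select the built-in presets.
#' @param n_animals number of animals (>= 1).
#' @param visit_ages planned visit ages in days (strictly increasing).
#' @param beta generating age slope (mL/cm per day).
#' @param sex_intercepts named numeric `c(female = ..., male = ...)`
#'   (mL/cm).
#' @param random_intercept_sd per-animal intercept SD (mL/cm, >= 0).
#' @param residual_sd visit-level residual SD (mL/cm, >= 0).
#' @param age_jitter_days half-width of the uniform jitter applied to each
#'   planned visit age per animal (days).
#' @param seed RNG seed.
#' @return An object of class `cohort_preset`.
#' @export
cohort_preset <- function(genotype = "PiMM", n_animals = NULL,
                          visit_ages = NULL, beta = NULL,
                          sex_intercepts = c(female = 0.85, male = 0.95),
                          random_intercept_sd = 0.15, residual_sd = 0.10,
                          age_jitter_days = 30, seed = 1L) {
  builtin <- list(
    "PiMM"   = list(n = 19L, ages = seq(100, 1000, length.out = 6),
                    beta = 0.000093),
    "PiZZ"   = list(n = 6L,  ages = seq(100, 700, length.out = 6),
                    beta = 0.00043),
    "AAT-KO" = list(n = 13L, ages = seq(100, 1100, length.out = 7),
                    beta = 0.00036))
  if (genotype %in% names(builtin)) {
    b <- builtin[[genotype]]
    n_animals <- n_animals %||% b$n
    visit_ages <- visit_ages %||% b$ages
    beta <- beta %||% b$beta
  }
  if (is.null(n_animals) || is.null(visit_ages) || is.null(beta))
    fl_input_error(paste0("unknown genotype '%s': supply n_animals,",
                          " visit_ages and beta explicitly"), genotype)
  if (n_animals < 1) fl_input_error("n_animals must be >= 1")
  if (length(visit_ages) < 1) fl_input_error("empty visit schedule")
  if (any(diff(visit_ages) <= 0))
    fl_input_error("visit ages must be strictly increasing")
  if (random_intercept_sd < 0 || residual_sd < 0)
    fl_input_error("SDs must be >= 0")
  if (!all(c("female", "male") %in% names(sex_intercepts)))
    fl_input_error("sex_intercepts needs named entries 'female' and 'male'")
  structure(list(genotype = genotype, n_animals = as.integer(n_animals),
                 visit_ages = as.numeric(visit_ages), beta = beta,
                 sex_intercepts = sex_intercepts,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd,
                 age_jitter_days = age_jitter_days, seed = as.integer(seed)),
            class = "cohort_preset")
}

#' Simulate a longitudinal cohort table
#'
#' One row per animal-visit, in tidy long format. Sexes alternate across
#' animals (balanced design); body length is drawn once per animal
#' (females ~ N(38, 1.5) cm, males ~ N(45, 2) cm) and carried on every
#' row; visit ages are the preset schedule plus a per-animal uniform
#' jitter, kept strictly increasing.
#'
#' @param preset a [cohort_preset()].
#' @return A data frame of class `cohort_table` with columns `animal`,
#'   `genotype`, `sex`, `age_days`, `body_length_cm`, `ic_ln` and a
#'   `generating` attribute recording the preset truth (including the
#'   generating slope `beta`).
#' @export
make_cohort <- function(preset) {
  if (!inherits(preset, "cohort_preset"))
    fl_input_error("make_cohort() expects a cohort_preset")
  withr::with_seed(preset$seed, {
    rows <- lapply(seq_len(preset$n_animals), function(a) {
      sex <- if (a %% 2L == 1L) "female" else "male"
      len <- if (sex == "female") rnorm(1, 38, 1.5) else rnorm(1, 45, 2)
      a0 <- rnorm(1, 0, preset$random_intercept_sd)
      jit <- runif(length(preset$visit_ages), -preset$age_jitter_days,
                   preset$age_jitter_days)
      ages <- sort(preset$visit_ages + jit)
      if (any(diff(ages) <= 0)) ages <- ages + seq_along(ages) * 1e-6
      y <- preset$sex_intercepts[[sex]] + preset$beta * ages + a0 +
        rnorm(length(ages), 0, preset$residual_sd)
      data.frame(animal = sprintf("%s_%02d", preset$genotype, a),
                 genotype = preset$genotype, sex = sex, age_days = ages,
                 body_length_cm = len, ic_ln = y)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("cohort_table", "data.frame"),
              generating = list(beta = preset$beta,
                                sex_intercepts = preset$sex_intercepts,
                                random_intercept_sd = preset$random_intercept_sd,
                                residual_sd = preset$residual_sd,
                                preset = preset))
  })
}

#' Simulate a protease-inhibition curve
#'
#' Residual neutrophil-elastase activity versus added sample volume,
#' normalized so the zero-volume (no-sample) well reads exactly 1. Either
#' a linear decay (`activity = max(1 - slope * volume, 0)`) or a
#' saturating decay (`activity = floor + (1 - floor) * exp(-volume/v0)`).
#' Noise is added before re-normalizing to the zero-volume well, so the
#' normalization anchor holds for noisy curves too.
#'
#' @param volumes added sample volumes (uL), non-negative, unique, must
#'   include 0.
#' @param slope linear decay slope (1/uL); used when `saturating` is NULL.
#' @param saturating list with `v0` (uL) and `floor` (residual plateau in
#'   `[0, 1]`) selecting the saturating model.
#' @param noise_sd activity noise SD.
#' @param seed RNG seed.
#' @return A data frame of class `inhibition_curve` with columns
#'   `volume_ul`, `activity` and a `truth` attribute carrying the model,
#'   its parameters and the analytic AUC over the sampled volume range.
#' @export
make_inhibition_curve <- function(volumes = c(0, 1, 3, 5, 7, 10),
                                  slope = 0.1, saturating = NULL,
                                  noise_sd = 0, seed = 1L) {
  volumes <- as.numeric(volumes)
  if (any(volumes < 0)) fl_input_error("volumes must be non-negative")
  if (anyDuplicated(volumes)) fl_input_error("duplicate volumes")
  if (!0 %in% volumes)
    fl_input_error("volumes must include the 0 uL normalization well")
  volumes <- sort(volumes)
  vmax <- max(volumes)
  if (is.null(saturating)) {
    if (slope < 0) fl_input_error("slope must be >= 0")
    act <- pmax(1 - slope * volumes, 0)
    auc <- if (slope == 0) vmax else {
      vstar <- 1 / slope
      if (vstar >= vmax) vmax - slope * vmax^2 / 2 else vstar / 2
    }
    truth <- list(model = "linear", slope = slope, auc = auc)
  } else {
    v0 <- saturating$v0; fl <- saturating$floor %||% 0
    if (is.null(v0) || v0 <= 0 || fl < 0 || fl > 1)
      fl_input_error("saturating model needs v0 > 0 and floor in [0, 1]")
    act <- fl + (1 - fl) * exp(-volumes / v0)
    auc <- fl * vmax + (1 - fl) * v0 * (1 - exp(-vmax / v0))
    truth <- list(model = "saturating", v0 = v0, floor = fl, auc = auc)
  }
  if (noise_sd > 0) {
    act <- withr::with_seed(seed, {
      noisy <- act + rnorm(length(act), 0, noise_sd)
      noisy[volumes == 0] <- pmax(noisy[volumes == 0], 0.5)  # keep anchor sane
      noisy / noisy[volumes == 0]
    })
  }
  structure(data.frame(volume_ul = volumes, activity = act),
            class = c("inhibition_curve", "data.frame"), truth = truth)
}
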