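#' Longitudinal random-intercept model of lung function versus age
#'
#' Fits `response ~ sex + genotype:age + (1 | animal)` by REML: a
#' genotype-specific fixed age slope, a separate intercept for each sex,
#' and a random intercept per animal absorbing repeated measures. No
#' random slope is included (cohorts of this size cannot identify one).
#' Slope standard errors, Satterthwaite degrees of freedom and p-values
#' come from the lmerTest machinery; with more than one genotype, all
#' pairwise slope contrasts are tested as well.
#'
#' @param cohort a `cohort_table` data frame (columns `animal`,
#'   `genotype`, `sex`, `age_days` and the response).
#' @param response name of the response column (default `"ic_ln"`,
#'   inspiratory capacity per cm body length).
#' @param reml fit by REML (default) or ML.
#' @return A list of class `mixed_model_fit`: `slopes` (data frame
#'   `genotype`, `slope`, `se`, `df`, `p_value`; mL/cm per day),
#'   `sex_intercepts` (named numeric), `random_intercept_sd`,
#'   `residual_sd`, `contrasts` (pairwise slope differences, or NULL),
#'   and the underlying `fit`.
#' @export
fit_longitudinal <- function(cohort, response = "ic_ln", reml = TRUE) {
  df <- as.data.frame(cohort)
  need <- c("animal", "genotype", "sex", "age_days", response)
  miss <- setdiff(need, names(df))
  if (length(miss))
    fl_input_error("cohort is missing column(s): %s",
                   paste(miss, collapse = ", "))
  df$animal <- factor(df$animal)
  df$genotype <- factor(df$genotype)
  df$sex <- factor(df$sex)
  if (any(df$age_days < 0)) fl_input_error("ages must be >= 0")
  per_animal <- vapply(split(df, df$animal),
                       function(g) c(nrow(g), length(unique(g$genotype)),
                                     length(unique(g$sex))),
                       numeric(3))
  if (any(per_animal[2, ] > 1) || any(per_animal[3, ] > 1))
    fl_input_error("each animal must have a single genotype and sex")
  if (nlevels(df$animal) < 2L)
    fl_input_error("need at least 2 animals")
  if (all(per_animal[1, ] < 2))
    fl_degenerate_error(paste0("every animal has a single observation;",
                               " the random intercept is unidentifiable"))
  df$.y <- df[[response]]
  multi_g <- nlevels(df$genotype) > 1L
  multi_s <- nlevels(df$sex) > 1L
  rhs <- paste(c(if (multi_s) "sex",
                 if (multi_g) "genotype:age_days" else "age_days",
                 "(1 | animal)"), collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- lmerTest::lmer(form, data = df, REML = reml)
  sm <- summary(fit)$coefficients
  cn <- rownames(sm)
  if (multi_g) {
    idx <- grep(":age_days$|^age_days:", cn)
    genos <- sub(":?age_days:?", "", sub("genotype", "", cn[idx]))
  } else {
    idx <- which(cn == "age_days")
    genos <- levels(df$genotype)
  }
  slopes <- data.frame(genotype = genos, slope = sm[idx, "Estimate"],
                       se = sm[idx, "Std. Error"], df = sm[idx, "df"],
                       p_value = sm[idx, "Pr(>|t|)"])
  rownames(slopes) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == "animal"][1]
  res_sd <- vc$sdcor[vc$grp == "Residual"][1]
  sex_int <- setNames(numeric(0), character(0))
  if ("(Intercept)" %in% cn) {
    base <- sm["(Intercept)", "Estimate"]
    sex_int <- setNames(base, levels(df$sex)[1])
    if (multi_s) {
      for (lv in levels(df$sex)[-1]) {
        nm <- paste0("sex", lv)
        if (nm %in% cn) sex_int[lv] <- base + sm[nm, "Estimate"]
      }
    }
  }
  contrasts <- NULL
  if (multi_g && length(idx) > 1L) {
    pairs_ <- utils::combn(seq_along(idx), 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs_)), function(k) {
      i <- pairs_[1, k]; j <- pairs_[2, k]
      l <- rep(0, length(cn)); l[idx[i]] <- 1; l[idx[j]] <- -1
      ct <- lmerTest::contest1D(fit, l)
      data.frame(contrast = paste(genos[i], "-", genos[j]),
                 estimate = ct$Estimate, se = ct$`Std. Error`,
                 df = ct$df, p_value = ct$`Pr(>|t|)`)
    }))
    rownames(contrasts) <- NULL
  }
  structure(list(slopes = slopes, sex_intercepts = sex_int,
                 random_intercept_sd = ri_sd, residual_sd = res_sd,
                 contrasts = contrasts, response = response, fit = fit),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("<mixed_model_fit> age slopes (per day):\n")
  print(x$slopes, row.names = FALSE)
  cat(sprintf("random intercept SD %.4g, residual SD %.4g\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' Paired ratios compared with unity
#'
#' Per-pair case/control ratios are log-transformed and their mean is
#' tested against 0 (one-sample two-sided t test), i.e. the geometric
#' mean ratio is compared with 1. Repeated measures should be collapsed
#' to per-animal means before pairing.
#'
#' @param case,control positive paired values (same length >= 2); `case`
#'   may also be a 2-column matrix or data frame of (case, control)
#'   pairs.
#' @return A list of class `paired_ratio_result`: `ratios`,
#'   `mean_log_ratio`, `geometric_mean`, `statistic`, `df`, `p_value`.
#' @export
paired_ratio_vs_unity <- function(case, control = NULL) {
  if (is.null(control)) {
    m <- as.matrix(case)
    if (ncol(m) != 2L)
      fl_input_error("supply case and control vectors or a 2-column matrix")
    control <- m[, 2]; case <- m[, 1]
  }
  if (length(case) != length(control))
    fl_input_error("case and control must have the same length")
  if (length(case) < 2L) fl_input_error("need at least 2 pairs")
  if (any(case <= 0) || any(control <= 0))
    fl_input_error("ratios require strictly positive values")
  lr <- log(case / control)
  n <- length(lr)
  s <- sd(lr)
  if (s == 0) {
    stat <- 0
    p <- if (mean(lr) == 0) 1 else 0
    if (mean(lr) != 0) stat <- sign(mean(lr)) * Inf
  } else {
    tt <- t.test(lr, mu = 0)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(ratios = case / control, mean_log_ratio = mean(lr),
                 geometric_mean = exp(mean(lr)), statistic = stat,
                 df = n - 1L, p_value = p),
            class = "paired_ratio_result")
}

#' Trapezoidal AUC of a protease-inhibition curve
#'
#' Area under residual activity versus added sample volume; a lower AUC
#' means greater inhibitory (antiprotease) capacity. The trapezoid rule
#' handles the unevenly spaced assay volumes directly. With activity in
#' `[0, 1]` the AUC is bounded by the maximum volume.
#'
#' @param curve an `inhibition_curve` data frame (columns `volume_ul`,
#'   `activity`); unsorted rows are sorted, duplicate volumes are an
#'   error, and the 0 uL normalization well must be present.
#' @return A list of class `inhibition_auc`: `auc_ul`, `n_points`,
#'   `max_volume_ul`.
#' @export
inhibition_auc <- function(curve) {
  df <- as.data.frame(curve)
  if (is.null(df$volume_ul) || is.null(df$activity))
    fl_input_error("curve needs columns volume_ul and activity")
  if (anyDuplicated(df$volume_ul)) fl_input_error("duplicate volumes")
  df <- df[order(df$volume_ul), ]
  if (nrow(df) < 2L) fl_input_error("need at least 2 points")
  if (!0 %in% df$volume_ul)
    fl_input_error("curve must include the 0 uL normalization well")
  structure(list(auc_ul = pracma::trapz(df$volume_ul, df$activity),
                 n_points = nrow(df), max_volume_ul = max(df$volume_ul)),
            class = "inhibition_auc")
}

#' Compare inhibition AUCs between two groups
#'
#' Ratio of mean AUCs (case over control) with a Welch two-sample test.
#'
#' @param case_aucs,control_aucs numeric vectors of per-subject AUCs.
#' @return A list: `ratio` (mean case AUC / mean control AUC),
#'   `statistic`, `p_value`.
#' @export
compare_inhibition_auc <- function(case_aucs, control_aucs) {
  if (length(case_aucs) < 2L || length(control_aucs) < 2L)
    fl_input_error("need at least 2 AUCs per group")
  tt <- t.test(case_aucs, control_aucs)
  list(ratio = mean(case_aucs) / mean(control_aucs),
       statistic = unname(tt$statistic), p_value = tt$p.value)
}
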