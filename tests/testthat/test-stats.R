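test_that("noise-free cohorts return the generating slopes exactly", {
  co <- make_cohort(cohort_preset("PiZZ", random_intercept_sd = 0,
                                  residual_sd = 0))
  fit <- quiet_lmer(fit_longitudinal(co))
  expect_equal(fit$slopes$slope, 0.00043, tolerance = 1e-8)
  expect_equal(unname(fit$sex_intercepts["female"]), 0.85, tolerance = 1e-6)
  expect_equal(unname(fit$sex_intercepts["male"]), 0.95, tolerance = 1e-6)
})

test_that("multi-genotype fits give one slope per genotype plus contrasts", {
  zz <- make_cohort(cohort_preset("PiZZ", random_intercept_sd = 0,
                                  residual_sd = 0, seed = 1L))
  mm <- make_cohort(cohort_preset("PiMM", random_intercept_sd = 0,
                                  residual_sd = 0, seed = 2L))
  both <- rbind(as.data.frame(zz), as.data.frame(mm))
  fit <- quiet_lmer(fit_longitudinal(both))
  expect_setequal(fit$slopes$genotype, c("PiMM", "PiZZ"))
  got <- setNames(fit$slopes$slope, fit$slopes$genotype)
  expect_equal(unname(got["PiZZ"]), 0.00043, tolerance = 1e-7)
  expect_equal(unname(got["PiMM"]), 0.000093, tolerance = 1e-7)
  expect_equal(nrow(fit$contrasts), 1L)
  expect_equal(abs(fit$contrasts$estimate), 0.00043 - 0.000093,
               tolerance = 1e-6)
})

test_that("slope recovery is unbiased across replicate cohorts", {
  est <- vapply(1:40, function(i) {
    co <- make_cohort(cohort_preset("PiZZ", seed = 4000L + i))
    quiet_lmer(fit_longitudinal(co))$slopes$slope
  }, numeric(1))
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.00043), 4 * mcse)
})

test_that("slope differences are centred at zero under label permutation", {
  co <- make_cohort(cohort_preset("PiMM", seed = 31L))
  animals <- unique(co$animal)
  diffs <- vapply(1:12, function(i) {
    fake <- withr::with_seed(i, sample(c("G1", "G2"), length(animals),
                                       replace = TRUE))
    if (length(unique(fake)) < 2) fake[1] <- setdiff(c("G1", "G2"), fake[1])
    df <- as.data.frame(co)
    df$genotype <- fake[match(df$animal, animals)]
    quiet_lmer(fit_longitudinal(df))$contrasts$estimate
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se)
})

test_that("responses scale equivariantly", {
  co <- make_cohort(cohort_preset("PiZZ", seed = 8L))
  f1 <- quiet_lmer(fit_longitudinal(co))
  co2 <- as.data.frame(co)
  co2$ic_ln <- co2$ic_ln * 10
  f2 <- quiet_lmer(fit_longitudinal(co2))
  expect_equal(f2$slopes$slope, 10 * f1$slopes$slope, tolerance = 1e-6)
  expect_equal(f2$residual_sd, 10 * f1$residual_sd, tolerance = 1e-6)
})

test_that("degenerate longitudinal designs are rejected", {
  co <- as.data.frame(make_cohort(cohort_preset("PiZZ")))
  one_visit <- co[!duplicated(co$animal), ]
  expect_error(fit_longitudinal(one_visit), class = "fl_degenerate_error")
  expect_error(fit_longitudinal(co[, -which(names(co) == "sex")]),
               class = "fl_input_error")
  expect_error(fit_longitudinal(co[co$animal == co$animal[1], ]),
               class = "fl_input_error")
  mixed_up <- co
  mixed_up$sex[1] <- setdiff(c("male", "female"), mixed_up$sex[1])
  expect_error(fit_longitudinal(mixed_up), class = "fl_input_error")
})

test_that("paired ratios against unity behave like a one-sample log test", {
  unity <- paired_ratio_vs_unity(rep(2, 5), rep(2, 5))
  expect_equal(unity$geometric_mean, 1)
  expect_equal(unity$statistic, 0)
  expect_equal(unity$p_value, 1)

  set.seed(2)
  case <- 1.16 * exp(rnorm(13, 0, 0.01))
  res <- paired_ratio_vs_unity(case, rep(1, 13))
  expect_equal(res$geometric_mean, 1.16, tolerance = 0.02)
  expect_lt(res$p_value, 0.05)
  # oracle: plain one-sample t on the log ratios
  tt <- t.test(log(case), mu = 0)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)

  # invariant to a common rescaling of both members of each pair
  scaled <- paired_ratio_vs_unity(case * 7, rep(7, 13))
  expect_equal(scaled$geometric_mean, res$geometric_mean, tolerance = 1e-12)
  expect_equal(scaled$p_value, res$p_value, tolerance = 1e-9)

  expect_error(paired_ratio_vs_unity(1.2, 1), class = "fl_input_error")
  expect_error(paired_ratio_vs_unity(c(1, -1), c(1, 1)),
               class = "fl_input_error")
})

test_that("inhibition AUC reproduces analytic areas and stays bounded", {
  tri <- make_inhibition_curve(volumes = 0:5, slope = 0.2)
  expect_equal(inhibition_auc(tri)$auc_ul, 2.5)
  flat <- make_inhibition_curve(volumes = 0:5, slope = 0)
  expect_equal(inhibition_auc(flat)$auc_ul, 5)
  # unsorted input is sorted, duplicates rejected
  shuffled <- as.data.frame(tri)[sample(6), ]
  expect_equal(inhibition_auc(shuffled)$auc_ul, 2.5)
  expect_error(inhibition_auc(rbind(as.data.frame(tri),
                                    data.frame(volume_ul = 5, activity = 0))),
               class = "fl_input_error")
  expect_error(inhibition_auc(as.data.frame(tri)[3:4, ]),
               class = "fl_input_error")
  # property: activity in [0, 1] bounds the AUC by the max volume
  for (s in c(0, 0.05, 0.1, 0.3)) {
    a <- inhibition_auc(make_inhibition_curve(volumes = c(0, 1, 3, 5, 7, 10),
                                              slope = s))$auc_ul
    expect_gte(a, 0)
    expect_lte(a, 10)
  }
})

test_that("a constructed 4x AUC ratio is recovered from noisy curves", {
  # flat cases (AUC 10) vs controls decaying to zero at 5 uL (AUC 2.5):
  # an exact 4x ratio by construction, blurred only by assay noise
  vols <- c(0, 1, 3, 5, 7, 10)
  case_aucs <- vapply(1:6, function(i)
    inhibition_auc(make_inhibition_curve(volumes = vols, slope = 0,
                                         noise_sd = 0.01, seed = i))$auc_ul,
    numeric(1))
  ctrl_aucs <- vapply(1:6, function(i)
    inhibition_auc(make_inhibition_curve(volumes = vols, slope = 0.2,
                                         noise_sd = 0.01,
                                         seed = 100 + i))$auc_ul,
    numeric(1))
  cmp <- compare_inhibition_auc(case_aucs, ctrl_aucs)
  expect_equal(cmp$ratio, 4, tolerance = 0.05)
  expect_lt(cmp$p_value, 0.01)
})
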