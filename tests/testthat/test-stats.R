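# Group statistics: ANOVA, random-intercept mixed models, V-on-D slopes.

two_group_spec <- function(effect = 0, sigma_b = 0.05, sigma_e = 0.15,
                           n = 40, vessels = 12) {
  cohort_spec(
    group_n = c(C = n, NDR = n),
    mu = list(d_um = c(C = 18, NDR = 18),
              v_mm_s = c(C = 0.70, NDR = 0.70 - effect)),
    sigma_b = c(d_um = 1.5, v_mm_s = sigma_b),
    sigma_e = c(d_um = 4, v_mm_s = sigma_e),
    vessels_per_subject = c(mean = vessels, sd = 0)
  )
}

test_that("ANOVA validates its inputs", {
  co <- simulate_cohort(cohort_spec(group_n = c(C = 10)), seed = 1)
  expect_error(group_anova(co$vessels, co$subjects), "two groups")
  co2 <- simulate_cohort(cohort_spec(group_n = c(C = 10, NDR = 1)), seed = 1)
  expect_error(group_anova(co2$vessels, co2$subjects), "NDR")
  expect_error(group_anova(co$vessels, co$subjects, "nope"), "not found")
})

test_that("ANOVA has calibrated type-I error under the null", {
  p <- vapply(1:300, function(s) {
    co <- simulate_cohort(two_group_spec(effect = 0, n = 25, vessels = 6),
                          seed = s)
    group_anova(co$vessels, co$subjects, "v_mm_s")$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
})

test_that("ANOVA detects the printed arteriolar velocity deficit with power", {
  # group means 0.70 vs 0.54 at n = 34/47 subjects
  spec <- cohort_spec(
    group_n = c(C = 34, NDR = 47),
    mu = list(d_um = c(C = 18, NDR = 19),
              v_mm_s = c(C = 0.70, NDR = 0.54)),
    sigma_b = c(d_um = 1.5, v_mm_s = 0.08),
    sigma_e = c(d_um = 4, v_mm_s = 0.20),
    vessels_per_subject = c(mean = 12, sd = 5)
  )
  rejections <- vapply(1:200, function(s) {
    co <- simulate_cohort(spec, seed = s)
    group_anova(co$vessels, co$subjects, "v_mm_s")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

test_that("mixed model recovers zero and injected group effects", {
  co <- simulate_cohort(two_group_spec(effect = 0), seed = 11)
  m <- fit_mixed_model(co$vessels, co$subjects, "v_mm_s")
  eff <- m$group_effects
  expect_equal(nrow(eff), 1)  # C is the reference level, no C row
  expect_lt(abs(eff$estimate / eff$se), 3)
  expect_true(eff$ci_lo < eff$estimate && eff$estimate < eff$ci_hi)
  expect_gte(m$sigma_b2, 0)

  co2 <- simulate_cohort(two_group_spec(effect = 0.16), seed = 12)
  m2 <- fit_mixed_model(co2$vessels, co2$subjects, "v_mm_s")
  expect_lt(abs(m2$group_effects$estimate - (-0.16)), 3 * m2$group_effects$se)
  expect_lt(m2$group_effects$p_value, 0.001)
})

test_that("with no subject-level variance the fit matches OLS closely", {
  co <- simulate_cohort(two_group_spec(effect = 0.1, sigma_b = 0), seed = 13)
  m <- fit_mixed_model(co$vessels, co$subjects, "v_mm_s")
  df <- merge(co$vessels, co$subjects, by = "subject_id")
  df$group <- factor(df$group, levels = c("C", "NDR"))
  ols <- lm(v_mm_s ~ group, data = df)
  expect_lt(m$sigma_b2, 1e-3)
  expect_lt(abs(m$group_effects$estimate - coef(ols)[["groupNDR"]]), 1e-6)
})

test_that("one vessel per subject falls back to ordinary regression", {
  co <- simulate_cohort(two_group_spec(vessels = 3), seed = 14)
  one <- co$vessels[!duplicated(co$vessels$subject_id), ]
  expect_warning(m <- fit_mixed_model(one, co$subjects, "v_mm_s"),
                 "ordinary regression")
  expect_true(m$ols_fallback)
  df <- merge(one, co$subjects, by = "subject_id")
  df$group <- factor(df$group, levels = c("C", "NDR"))
  ols <- lm(v_mm_s ~ group, data = df)
  expect_equal(m$group_effects$estimate, unname(coef(ols)["groupNDR"]),
               tolerance = 1e-9)
})

test_that("fixed effects are invariant to row order", {
  co <- simulate_cohort(two_group_spec(effect = 0.1), seed = 15)
  m1 <- fit_mixed_model(co$vessels, co$subjects, "v_mm_s")
  perm <- sample(nrow(co$vessels))
  m2 <- fit_mixed_model(co$vessels[perm, ], co$subjects, "v_mm_s")
  expect_equal(m1$group_effects$estimate, m2$group_effects$estimate,
               tolerance = 1e-8)
})

test_that("adjusted models drop incomplete rows and report the count", {
  co <- simulate_cohort(two_group_spec(), seed = 16)
  co$subjects$hba1c[3] <- NA
  m <- fit_mixed_model(co$vessels, co$subjects, "v_mm_s", adjusted = TRUE)
  expect_gt(m$n_dropped, 0)
  for (cov in c("age", "map", "hr", "hct", "hba1c")) {
    expect_true(any(grepl(cov, m$coefficients$term)))
  }
})

test_that("slope model recovers common and differing V-on-D slopes", {
  spec <- cohort_spec(slope_per_group = c(C = 18, NDR = 18, NPDR = 18,
                                          PDR = 18))
  co <- simulate_cohort(spec, seed = 17)
  s <- velocity_diameter_slopes(co$vessels, co$subjects)
  expect_true(all(s$ci_lo < 18 & 18 < s$ci_hi))
  expect_true(all(s$p_slope < 0.001))
  expect_true(is.na(s$p_vs_control[s$group == "C"]))

  spec2 <- cohort_spec(group_n = c(C = 40, NDR = 40),
                       slope_per_group = c(C = 14, NDR = 24))
  co2 <- simulate_cohort(spec2, seed = 18)
  s2 <- velocity_diameter_slopes(co2$vessels, co2$subjects)
  expect_lt(s2$p_vs_control[s2$group == "NDR"], 0.05)

  flat <- co$vessels
  flat$d_um <- 18
  expect_error(velocity_diameter_slopes(flat, co$subjects),
               "no diameter variation")
})
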