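# Derived descriptors: formulas, units, viscosity law, de-duplication.

test_that("worked formula examples evaluate exactly", {
  expect_equal(cross_section_velocity(0.8, 20), 0.5)
  expect_equal(cross_section_velocity(0.8, 20, k = 1), 0.8)
  expect_equal(blood_flow(0.5, 20), 0.5 * 1000 * pi * 400 / 4 * 1e-3)
  expect_equal(blood_flow(0.5, 20), 157.0796, tolerance = 1e-6)
  expect_equal(wall_shear_rate(0.5, 20), 200)
  expect_equal(wall_shear_rate(0.45, 18), 200)
  expect_equal(wall_shear_stress(2.4, 200), 4.8)
  expect_equal(compute_map(120, 80), 280 / 3)
  expect_equal(compute_map(90, 90), 90)
})

test_that("formula preconditions reject invalid inputs", {
  expect_error(cross_section_velocity(0, 20), "positive")
  expect_error(cross_section_velocity(0.5, 5), "6-75")
  expect_error(wall_shear_stress(2.4, 0), "positive")
  expect_error(compute_map(80, 90), ">= DBP")
  expect_error(blood_viscosity(0, 20), "\\(0, 1\\)")
  expect_error(blood_viscosity(1.2, 20), "\\(0, 1\\)")
})

test_that("scaling laws hold", {
  expect_equal(blood_flow(0.5, 40), 4 * blood_flow(0.5, 20))
  expect_equal(wall_shear_rate(0.5, 40), wall_shear_rate(0.5, 20) / 2)
  expect_equal(wall_shear_stress(4.8, 200), 2 * wall_shear_stress(2.4, 200))
})

test_that("formula identities hold to 1e-9 for random admissible inputs", {
  set.seed(99)
  n <- 1000
  vs <- runif(n, 0.05, 3)
  d <- runif(n, 6, 75)
  hct <- runif(n, 0.2, 0.6)
  q <- blood_flow(vs, d)
  wsr <- wall_shear_rate(vs, d)
  eta <- blood_viscosity(hct, d)
  wss <- wall_shear_stress(eta, wsr)
  expect_lt(max(abs(q - vs * 1000 * pi * d^2 / 4 * 1e-3) / q), 1e-9)
  expect_lt(max(abs(wsr - 8 * vs * 1000 / d) / wsr), 1e-9)
  expect_lt(max(abs(wss - eta * wsr * 0.01) / wss), 1e-9)
})

test_that("viscosity law matches its closed form at the reference hematocrit", {
  # at HCT = 0.45 the interpolation collapses to eta*_0.45
  for (d in c(6, 10, 20, 40, 75)) {
    eta45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
    expect_equal(relative_viscosity(0.45, d), eta45, tolerance = 1e-12)
  }
  # hand-evaluated value at D = 20 um
  expect_equal(relative_viscosity(0.45, 20), 1.5876, tolerance = 1e-3)
  expect_equal(blood_viscosity(0.45, 20), 1.2 * 1.5876, tolerance = 1e-3)
})

test_that("viscosity increases with hematocrit at fixed diameter", {
  for (d in c(8, 20, 50)) {
    hct <- seq(0.1, 0.6, by = 0.01)
    eta <- blood_viscosity(hct, d)
    expect_true(all(diff(eta) > 0))
  }
})

test_that("de-duplication keeps the longest centerline with tie-breaks", {
  rec <- data.frame(
    vessel_id = c(1, 1, 1, 2),
    segment_id = c(1, 2, 3, 4),
    length_um = c(80, 120, 95, 70),
    n_stations = c(10, 15, 12, 8)
  )
  out <- dedupe_longest(rec)
  expect_equal(out$segment_id[out$vessel_id == 1], 2)
  expect_equal(out$segment_id[out$vessel_id == 2], 4)

  tie <- data.frame(vessel_id = 1, segment_id = c(1, 2),
                    length_um = c(100, 100), n_stations = c(12, 18))
  expect_equal(dedupe_longest(tie)$segment_id, 2)
  tie2 <- data.frame(vessel_id = 1, segment_id = c(7, 3),
                     length_um = c(100, 100), n_stations = c(12, 12))
  expect_equal(dedupe_longest(tie2)$segment_id, 3)
})

test_that("de-duplication agrees with a brute-force oracle on random sets", {
  set.seed(7)
  brute <- function(df) {
    vapply(split(df, df$vessel_id), function(s) {
      best <- s[order(-s$length_um, -s$n_stations, s$segment_id), ][1, ]
      best$segment_id
    }, numeric(1))
  }
  for (i in 1:1000) {
    df <- data.frame(
      vessel_id = sample(1:4, 8, replace = TRUE),
      segment_id = sample(1:99, 8),
      length_um = sample(seq(60, 120, by = 10), 8, replace = TRUE),
      n_stations = sample(5:12, 8, replace = TRUE)
    )
    out <- dedupe_longest(df)
    expect_equal(sort(as.numeric(out$segment_id)),
                     sort(unname(brute(df))))
  }
})

test_that("hemodynamics table recomputes from stored columns exactly", {
  co <- simulate_cohort(cohort_spec(group_n = c(C = 6, NDR = 6)), seed = 3)
  v <- co$vessels
  expect_lt(max(abs(v$q_pl_s - v$vs_mm_s * 1000 * pi * v$d_um^2 / 4e3) /
                  v$q_pl_s), 1e-9)
  expect_lt(max(abs(v$wsr_s - 8000 * v$vs_mm_s / v$d_um) / v$wsr_s), 1e-9)
  expect_lt(max(abs(v$wss_dyn_cm2 - v$eta_mpas * v$wsr_s / 100) /
                  v$wss_dyn_cm2), 1e-9)
  expect_true(all(v[, c("d_um", "v_mm_s", "vs_mm_s", "q_pl_s", "wsr_s",
                        "eta_mpas", "wss_dyn_cm2")] > 0))
})
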