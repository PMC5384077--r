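# Synthetic scene renderer and cohort generator.

test_that("static scene renders identical frames with zero temporal variance", {
  sc <- straight_scene(d_um = 20, v_mm_s = 0, noise_sd = 0, n_frames = 10)
  r <- render_sequence(sc, seed = 1)
  f <- r$sequence$frames
  for (t in 2:10) expect_identical(f[, , t], f[, , 1])
  tvar <- apply(f, c(1, 2), var)
  expect_equal(max(tvar), 0)
})

test_that("texture advects at the exact pixel displacement per frame", {
  # 0.625 mm/s at 50 fps and 1.25 um/px must displace 10 px/frame;
  # static background texture off so only the advected pattern remains
  sc <- straight_scene(d_um = 20, v_mm_s = 0.625, noise_sd = 0,
                       background_texture = 0)
  r <- render_sequence(sc, seed = 2)
  expect_equal(r$truth$displacement_px_per_frame, 10)
  f <- r$sequence$frames
  y <- sc$height / 2
  a <- f[y, 40:260, 1]
  b <- f[y, 40:260, 2]
  lags <- 0:20
  cc <- vapply(lags, function(l) {
    cor(a[seq_len(221 - l)], b[seq_len(221 - l) + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 10)
  expect_gt(max(cc), 0.999)
})

test_that("rendering is bit-identical under a fixed seed", {
  sc <- straight_scene(noise_sd = 0.02, jitter_amplitude_px = 1.5)
  r1 <- render_sequence(sc, seed = 77)
  r2 <- render_sequence(sc, seed = 77)
  expect_identical(r1$sequence$frames, r2$sequence$frames)
  expect_identical(r1$jitter, r2$jitter)
  r3 <- render_sequence(sc, seed = 78)
  expect_false(identical(r1$sequence$frames, r3$sequence$frames))
})

test_that("blink frames are rendered as near-uniform dark frames", {
  sc <- straight_scene(blink_frames = c(13, 14), noise_sd = 0)
  r <- render_sequence(sc, seed = 3)
  means <- apply(r$sequence$frames, 3, mean)
  expect_equal(unname(means[13]), 0.1 * sc$background, tolerance = 1e-10)
  expect_equal(unname(means[14]), 0.1 * sc$background, tolerance = 1e-10)
  expect_true(all(means[-c(13, 14)] > 0.5 * sc$background))
})

test_that("invalid vessels are rejected with informative errors", {
  off_field <- vessel_spec(cbind(c(-40, 100), c(50, 50)), 20, 0.5)
  sc <- scene_spec(200, 100, vessels = list(off_field))
  expect_error(render_sequence(sc, 1), "outside the field")

  # displacement per frame >= half segment length -> aliasing error
  fast <- vessel_spec(cbind(c(20, 120), c(50, 50)), 20, 4)  # 64 px/frame, 100 px long
  sc2 <- scene_spec(200, 100, vessels = list(fast))
  expect_error(render_sequence(sc2, 1), "displacement")

  expect_error(vessel_spec(cbind(c(1, 50), c(5, 5)), diameter_um = 4),
               "6-75")
  expect_error(vessel_spec(cbind(c(1, 50), c(5, 5)), diameter_um = 80),
               "6-75")
})

test_that("total texture displacement equals velocity times duration", {
  # frame 1 vs frame 41: 40 frames at 2 px/frame -> 80 px, within 0.1 px
  sc <- straight_scene(d_um = 14, v_mm_s = 0.125, len_px = 300, noise_sd = 0,
                       background_texture = 0)
  r <- render_sequence(sc, seed = 9)
  f <- r$sequence$frames
  y <- sc$height / 2
  a <- f[y, 25:315, 1] - mean(f[y, 25:315, 1])
  b <- f[y, 25:315, 41] - mean(f[y, 25:315, 41])
  # sub-pixel lag via parabolic refinement of the cross-correlation peak
  lags <- 70:90
  cc <- vapply(lags, function(l) {
    sum(a[seq_len(291 - l)] * b[seq_len(291 - l) + l])
  }, numeric(1))
  pk <- which.max(cc)
  den <- cc[pk - 1] - 2 * cc[pk] + cc[pk + 1]
  lag <- lags[pk] + 0.5 * (cc[pk - 1] - cc[pk + 1]) / den
  expect_equal(lag, 2 * 40, tolerance = 0.1 / 80)
})

test_that("cohort generator honours degenerate and invalid specs", {
  spec <- cohort_spec(
    group_n = c(C = 5, NDR = 5),
    sigma_b = c(d_um = 0, v_mm_s = 0),
    sigma_e = c(d_um = 0, v_mm_s = 0),
    vessels_per_subject = c(mean = 4, sd = 0)
  )
  co <- simulate_cohort(spec, seed = 1)
  expect_equal(as.numeric(tapply(co$vessels$d_um,
                                 co$subjects$group[match(co$vessels$subject_id,
                                                         co$subjects$subject_id)],
                                 sd)), c(0, 0))
  mu <- tapply(co$vessels$v_mm_s,
               co$subjects$group[match(co$vessels$subject_id,
                                       co$subjects$subject_id)], mean)
  expect_equal(unname(mu["C"]), 0.70)
  expect_equal(unname(mu["NDR"]), 0.54)

  expect_error(cohort_spec(group_n = c(C = 0, NDR = 5)), "positive")
  expect_error(cohort_spec(group_n = c(C = 5, XDR = 5)),
               "C, NDR, NPDR, PDR")
  expect_error(cohort_spec(sigma_b = c(d_um = -1, v_mm_s = 0.1)), ">= 0")
})

test_that("cohort sample means converge to specified group means", {
  # law of large numbers at ~10^4 vessels per group
  spec <- cohort_spec(
    group_n = c(C = 250, NDR = 250),
    sigma_b = c(d_um = 1.5, v_mm_s = 0.05),
    sigma_e = c(d_um = 4, v_mm_s = 0.15),
    vessels_per_subject = c(mean = 40, sd = 0)
  )
  co <- simulate_cohort(spec, seed = 5)
  g <- co$subjects$group[match(co$vessels$subject_id, co$subjects$subject_id)]
  for (grp in c("C", "NDR")) {
    n <- sum(g == grp)
    expect_gte(n, 9000)
    # subject-level intercepts dominate the SE of the grand mean
    se <- sqrt(0.05^2 / 250 + 0.15^2 / n)
    expect_lt(abs(mean(co$vessels$v_mm_s[g == grp]) -
                    spec$mu$v_mm_s[grp]), 3 * se)
  }
})

test_that("simulated group-mean difference matches the injected effect", {
  # two groups, effect 0.16 mm/s; Monte-Carlo over 100 seeds
  spec <- cohort_spec(
    group_n = c(C = 40, NDR = 40),
    mu = list(d_um = c(C = 18, NDR = 18),
              v_mm_s = c(C = 0.70, NDR = 0.54)),
    sigma_b = c(d_um = 1.5, v_mm_s = 0.05),
    sigma_e = c(d_um = 4, v_mm_s = 0.15),
    vessels_per_subject = c(mean = 12, sd = 0)
  )
  diffs <- vapply(1:100, function(s) {
    co <- simulate_cohort(spec, seed = s)
    g <- co$subjects$group[match(co$vessels$subject_id,
                                 co$subjects$subject_id)]
    mean(co$vessels$v_mm_s[g == "C"]) - mean(co$vessels$v_mm_s[g == "NDR"])
  }, numeric(1))
  se <- sqrt(2 * (0.05^2 / 40 + 0.15^2 / 480))
  expect_lt(abs(mean(diffs) - 0.16), 3 * se / sqrt(100))
})
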