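# Frame screening, run selection and translational registration.

test_that("identical frames all pass screening; single frame is valid", {
  f <- matrix(0.7, 80, 80) + outer(sin(1:80 / 7), cos(1:80 / 9)) * 0.05
  seq10 <- image_sequence(replicate(10, f, simplify = FALSE))
  q <- score_frame_quality(seq10)
  expect_true(all(q$valid))

  seq1 <- image_sequence(list(f))
  q1 <- score_frame_quality(seq1)
  expect_true(q1$valid)
})

test_that("blink frames are flagged at exactly the injected indices", {
  sc <- straight_scene(blink_frames = c(12, 13), noise_sd = 0.01)
  r <- render_sequence(sc, seed = 4)
  q <- score_frame_quality(r$sequence)
  expect_identical(which(q$criterion == "blink"), c(12L, 13L))
  expect_true(all(q$valid[-c(12, 13)]))
})

test_that("an all-invalid sequence raises a no-usable-frames error", {
  sc <- straight_scene(blink_frames = 1:50, noise_sd = 0)
  r <- render_sequence(sc, seed = 4)
  expect_error(score_frame_quality(r$sequence), "no usable frames")
  expect_error(longest_valid_run(rep(FALSE, 10)), "no usable frames")
})

test_that("longest_valid_run matches enumerated examples and tie-break", {
  V <- TRUE; I <- FALSE
  expect_equal(unname(longest_valid_run(c(V, V, V, I, V, V))), c(1, 3))
  expect_equal(unname(longest_valid_run(c(I, V, V, I, V, V, V))), c(5, 7))
  # two runs of equal length 3: the earlier one wins
  expect_equal(unname(longest_valid_run(c(V, V, V, I, V, V, V))), c(1, 3))
})

test_that("longest_valid_run agrees with brute force on random flags", {
  set.seed(42)
  for (i in 1:1000) {
    flags <- runif(sample(1:20, 1)) > 0.4
    if (!any(flags)) flags[sample(length(flags), 1)] <- TRUE
    expect_identical(unname(longest_valid_run(flags)),
                     brute_longest_run(flags))
  }
})

test_that("registration of a jitter-free scene estimates near-zero shifts", {
  sc <- straight_scene(v_mm_s = 0.5, noise_sd = 0)
  r <- render_sequence(sc, seed = 6)
  reg <- register(r$sequence)
  expect_lt(max(abs(reg$translations)), 0.05)
  expect_equal(unname(reg$translations[reg$reference, ]), c(0, 0))
})

test_that("injected whole-frame jitter is recovered within 0.5 px", {
  jp <- rbind(c(0, 0), c(3, -2), c(1, 1))
  sc <- straight_scene(v_mm_s = 0.4, noise_sd = 0, n_frames = 3,
                       jitter_path = jp)
  r <- render_sequence(sc, seed = 8)
  reg <- register(r$sequence)
  rel_inj <- sweep(jp, 2, jp[reg$reference, ])
  expect_lt(max(abs(reg$translations - rel_inj)), 0.5)

  sc2 <- straight_scene(v_mm_s = 0.8, noise_sd = 0.02,
                        jitter_amplitude_px = 2)
  r2 <- render_sequence(sc2, seed = 9)
  reg2 <- register(r2$sequence)
  rel2 <- sweep(r2$jitter, 2, r2$jitter[reg2$reference, ])
  expect_lt(max(abs(reg2$translations - rel2)), 0.5)
})

test_that("time-average of a static scene approaches the noise-free scene", {
  sc <- straight_scene(v_mm_s = 0, noise_sd = 0.02)
  r <- render_sequence(sc, seed = 10)
  clean <- straight_scene(v_mm_s = 0, noise_sd = 0)
  rc <- render_sequence(clean, seed = 10)
  reg <- register(r$sequence)
  # averaging n frames shrinks the sensor noise by sqrt(n)
  resid <- reg$average - rc$sequence$frames[, , 1]
  expect_lt(sd(resid[reg$mask]), 2 * 0.02 / sqrt(50))
})

test_that("time-averaged image is invariant to frame order", {
  sc <- straight_scene(v_mm_s = 0.5, noise_sd = 0.01)
  r <- render_sequence(sc, seed = 11)
  fr <- r$sequence$frames
  perm <- sample(dim(fr)[3])
  s1 <- image_sequence(fr, source = "a")
  s2 <- image_sequence(fr[, , perm], source = "b")
  # same frames, any order: identical mean image (registration shifts are
  # all ~0 here, so compare plain stack means)
  expect_equal(rowMeans(s1$frames, dims = 2), rowMeans(s2$frames, dims = 2),
               tolerance = 1e-12)
})

test_that("registered jittered static scene restores the noise floor", {
  noise <- 0.02
  sc <- straight_scene(v_mm_s = 0, noise_sd = noise, jitter_amplitude_px = 2)
  r <- render_sequence(sc, seed = 12)
  reg <- register(r$sequence)
  m <- rowMeans(reg$frames, dims = 2)
  tsd <- sqrt(pmax(rowMeans(reg$frames^2, dims = 2) - m^2, 0))
  # bilinear resampling at fractional shifts attenuates white noise by a
  # known factor (the root sum of squared interpolation weights); the
  # expected residual sd uses the per-frame factors of the estimated shifts
  att <- vapply(seq_len(nrow(reg$translations)), function(k) {
    fx <- abs(reg$translations[k, 1]) %% 1
    fy <- abs(reg$translations[k, 2]) %% 1
    wx <- c(1 - fx, fx); wy <- c(1 - fy, fy)
    sum(outer(wy, wx)^2)
  }, numeric(1))
  expected <- noise * sqrt(mean(att))
  expect_lt(abs(median(tsd[reg$mask]) - expected) / expected, 0.2)
})
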