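# Segmentation, centerline extraction, splitting, diametry, flow filter.

test_that("a clean vessel is segmented with high coverage and little background", {
  sc <- straight_scene(d_um = 20, v_mm_s = 0.5, noise_sd = 0, len_px = 240,
                       height = 160)
  r <- render_sequence(sc, seed = 21)
  avg <- rowMeans(r$sequence$frames, dims = 2)
  mask <- segment_vessels(avg)
  d_px <- 20 / 1.25
  y <- sc$height / 2
  # tube interior: strictly inside the half-maximum width, clear of the
  # tapered tube ends (pixel-resolution footprint)
  foot <- matrix(FALSE, sc$height, sc$width)
  foot[round(y - d_px / 2 + 1):round(y + d_px / 2 - 1), 26:254] <- TRUE
  expect_gte(mean(mask[foot]), 0.95)
  expect_lte(mean(mask[!foot]), 0.05)
})

test_that("a blank image yields an empty mask", {
  blank <- matrix(0.8, 100, 100)
  expect_warning(mask <- segment_vessels(blank), "empty")
  expect_false(any(mask))
})

test_that("two crossing vessels are both covered by the mask", {
  v1 <- vessel_spec(cbind(c(20, 230), c(60, 140)), 16, 0.3)
  v2 <- vessel_spec(cbind(c(20, 230), c(140, 60)), 16, 0.3)
  sc <- scene_spec(250, 200, vessels = list(v1, v2), noise_sd = 0)
  r <- render_sequence(sc, seed = 22)
  avg <- rowMeans(r$sequence$frames, dims = 2)
  mask <- segment_vessels(avg)
  for (v in list(v1, v2)) {
    fine <- conjflow:::resample_polyline(v$points, step = 1)
    # interior footprint: within 40% of the radius of the centerline
    inside <- unique(round(cbind(
      rep(fine[, 2], 5) + rep(seq(-2.5, 2.5, length.out = 5), each = nrow(fine)),
      rep(fine[, 1], 5)
    )))
    inside <- inside[inside[, 1] >= 1 & inside[, 1] <= 200 &
                       inside[, 2] >= 1 & inside[, 2] <= 250, ]
    expect_gte(mean(mask[inside]), 0.90)
  }
})

test_that("thinning a wide bar yields its single middle row", {
  mask <- matrix(FALSE, 60, 120)
  mask[23:38, 10:110] <- TRUE  # 16 px wide bar centred on rows 30/31
  sk <- thin_mask(mask)
  idx <- which(sk)
  ys <- (idx - 1) %% 60 + 1
  xs <- (idx - 1) %/% 60 + 1
  core <- ys[xs > 15 & xs < 105]
  expect_lte(diff(range(core)), 1)
  expect_true(all(core >= 29 & core <= 32))
  expect_false(any(thin_mask(matrix(FALSE, 20, 20))))
})

test_that("a Y-shaped mask produces exactly one bifurcation cluster", {
  mask <- matrix(FALSE, 150, 150)
  for (t in 0:60) {
    mask[do.call(rbind, lapply(-3:3, function(o) c(75 + o, 5 + t)))] <- TRUE
    y1 <- round(75 - t * 0.6); y2 <- round(75 + t * 0.6)
    mask[do.call(rbind, lapply(-3:3, function(o) c(y1 + o, 66 + t)))] <- TRUE
    mask[do.call(rbind, lapply(-3:3, function(o) c(y2 + o, 66 + t)))] <- TRUE
  }
  sk <- conjflow::prune_skeleton(thin_mask(mask))
  bif <- find_bifurcations(sk)
  # brute-force neighbor count agrees
  nb <- conjflow:::neighbor_count(sk)
  expect_identical(bif, sk & nb >= 3)
  lab <- conjflow:::label8(bif)
  expect_equal(max(lab), 1)
  segs <- split_segments(sk, 1.25)$segments
  expect_equal(length(segs), 3)
})

test_that("segment arc length and the 50-um filter follow the path metric", {
  sk <- matrix(FALSE, 40, 120)
  sk[20, 11:110] <- TRUE   # 100 px -> 99 steps -> 123.75 um
  out <- split_segments(sk, 1.25)
  expect_equal(length(out$segments), 1)
  expect_equal(out$segments[[1]]$length_um, 123.75)

  sk2 <- matrix(FALSE, 40, 60)
  sk2[20, 11:40] <- TRUE   # 30 px -> 36.25 um <= 50 -> discarded
  out2 <- split_segments(sk2, 1.25)
  expect_equal(length(out2$segments), 0)
  expect_equal(out2$n_discarded_short, 1L)

  # a segment of exactly 50 um is excluded (strict inequality)
  sk3 <- matrix(FALSE, 40, 60)
  sk3[20, 11:51] <- TRUE   # 41 px -> 40 steps -> 50.00 um
  expect_equal(length(split_segments(sk3, 1.25)$segments), 0)
})

test_that("arc length is invariant under image translation", {
  # translate the rendered scene (image and all) so the only difference
  # downstream is pixel position
  sc <- straight_scene(d_um = 16, v_mm_s = 0.4, noise_sd = 0, len_px = 200,
                       height = 140, margin = 40)
  r <- render_sequence(sc, seed = 23)
  avg <- rowMeans(r$sequence$frames, dims = 2)
  avg_shift <- conjflow:::shift_image(avg, 12, 9)
  lens <- vapply(list(avg, avg_shift), function(img) {
    segs <- extract_centerlines(segment_vessels(img), 1.25)$segments
    max(vapply(segs, function(s) s$length_um, numeric(1)))
  }, numeric(1))
  expect_lt(abs(lens[1] - lens[2]), 3 * 1.25)
})

test_that("FWHM diametry recovers true diameters within one pixel", {
  for (d in c(6, 20)) {
    sc <- straight_scene(d_um = d, v_mm_s = 0.4, noise_sd = 0, len_px = 220,
                         height = 160)
    r <- render_sequence(sc, seed = 24)
    avg <- rowMeans(r$sequence$frames, dims = 2)
    seg <- measure_diameter(straight_segment(sc), avg, 1.25)
    expect_null(seg$rejected)
    expect_lt(abs(seg$diameter_um - d), 1.25)
    expect_gte(seg$n_stations, 3)
    # stations are spaced 5 px along the resampled centerline
    expect_true(all(diff(seg$stations) %% 5 == 0))
  }
})

test_that("a featureless image rejects the segment with a diametry reason", {
  flat <- matrix(0.8, 140, 320)
  seg <- straight_segment(straight_scene())
  out <- measure_diameter(seg, flat, 1.25)
  expect_identical(out$rejected, "diametry failed")
})

test_that("temporal-variance filter separates flowing from static vessels", {
  sc_flow <- straight_scene(d_um = 18, v_mm_s = 0.5, noise_sd = 0.005)
  r <- render_sequence(sc_flow, seed = 25)
  reg <- register(r$sequence)
  mask <- segment_vessels(reg$average) & reg$mask
  segs <- filter_by_variance(list(straight_segment(sc_flow)), reg, mask)
  expect_true(segs[[1]]$flow_detected)

  sc_static <- straight_scene(d_um = 18, v_mm_s = 0, noise_sd = 0.005)
  r2 <- render_sequence(sc_static, seed = 25)
  reg2 <- register(r2$sequence)
  mask2 <- segment_vessels(reg2$average) & reg2$mask
  segs2 <- filter_by_variance(list(straight_segment(sc_static)), reg2, mask2)
  expect_false(segs2[[1]]$flow_detected)
})

test_that("pure-noise scenes rarely trigger false flow detections", {
  # Monte-Carlo calibration of the default 2x background-variance factor
  false_pos <- vapply(1:40, function(s) {
    set.seed(s)
    fr <- array(0.8 + rnorm(64 * 64 * 12, 0, 0.01), dim = c(64, 64, 12))
    reg <- list(frames = fr, mask = matrix(TRUE, 64, 64))
    seg <- structure(list(id = 1L, path = cbind(x = 5:60, y = rep(32, 56))),
                     class = "vessel_segment")
    mask <- matrix(FALSE, 64, 64); mask[30:34, 5:60] <- TRUE
    filter_by_variance(list(seg), reg, mask)[[1]]$flow_detected
  }, logical(1))
  expect_lte(mean(false_pos), 0.05)
})

test_that("vessel type labels pass through and unknown labels error", {
  seg <- structure(list(id = 1L), class = "vessel_segment")
  expect_identical(label_vessel_type(seg, "arteriole")$type, "arteriole")
  expect_identical(label_vessel_type(seg, NA)$type, "unlabeled")
  expect_error(label_vessel_type(seg, "capillary"), "unknown vessel type")

  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(segment_id = 1:2, type = c("arteriole", "venule")),
            path, row.names = FALSE)
  ann <- read_annotations(path)
  expect_identical(unname(ann["2"]), "venule")
  write.csv(data.frame(segment_id = 1, type = "artery"), path,
            row.names = FALSE)
  expect_error(read_annotations(path), "unknown vessel type")
})
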