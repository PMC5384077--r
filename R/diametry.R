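# Full-width-at-half-maximum diametry. At stations every 5 px along the
# resampled centerline, an intensity profile is sampled perpendicular to
# the local tangent; the diameter is the distance between the two
# half-maximum crossings of the background-subtracted inverted profile.

# Tangent directions from a 7-point local quadratic fit of the resampled
# centerline (raw skeleton steps are 8-connected and too noisy for
# perpendiculars).
centerline_tangents <- function(pts, half_window = 3L) {
  n <- nrow(pts)
  tx <- numeric(n); ty <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - half_window); b <- min(n, i + half_window)
    t <- (a:b) - i
    if (length(t) >= 3) {
      X <- cbind(1, t, t^2)
      cx <- qr.coef(qr(X), pts[a:b, 1])
      cy <- qr.coef(qr(X), pts[a:b, 2])
      tx[i] <- cx[2]; ty[i] <- cy[2]
    } else {
      tx[i] <- pts[min(n, i + 1), 1] - pts[max(1, i - 1), 1]
      ty[i] <- pts[min(n, i + 1), 2] - pts[max(1, i - 1), 2]
    }
    nrm <- sqrt(tx[i]^2 + ty[i]^2)
    if (nrm < 1e-9) nrm <- 1
    tx[i] <- tx[i] / nrm; ty[i] <- ty[i] / nrm
  }
  cbind(tx = tx, ty = ty)
}

# Locate the FWHM of one inverted, background-subtracted profile.
# `p` is sampled at spacing `step_px`; returns width in px or NA.
# The local background is the brightest (least inverted) smoothed point on
# each side of the central peak rather than the tail median: in densely
# vascularised fields the profile tails cross neighbouring vessels, while
# the gap between vessels still reaches true background.
fwhm_width <- function(p, step_px) {
  n <- length(p)
  ok <- which(!is.na(p))
  if (length(ok) < 8) return(NA_real_)
  ps <- p
  ps[ok] <- smooth_ma(p[ok], 5)
  core <- seq.int(max(1L, floor(n * 0.25)), min(n, ceiling(n * 0.75)))
  pk <- core[which.max(p[core])]
  if (is.na(p[pk])) return(NA_real_)
  bg <- (min(ps[seq_len(pk)], na.rm = TRUE) +
           min(ps[pk:n], na.rm = TRUE)) / 2
  q <- p - bg
  if (!is.finite(q[pk]) || q[pk] <= 0) return(NA_real_)
  half <- q[pk] / 2
  li <- NA_real_; ri <- NA_real_
  for (i in pk:2) {
    if (is.na(q[i - 1])) break
    if (q[i - 1] < half && q[i] >= half) {
      li <- (i - 1) + (half - q[i - 1]) / (q[i] - q[i - 1])
      break
    }
  }
  for (i in pk:(n - 1)) {
    if (is.na(q[i + 1])) break
    if (q[i + 1] < half && q[i] >= half) {
      ri <- i + (q[i] - half) / (q[i] - q[i + 1])
      break
    }
  }
  if (is.na(li) || is.na(ri)) return(NA_real_)
  (ri - li) * step_px
}

#' Measure vessel diameter by FWHM profiling
#'
#' Samples the time-averaged image perpendicular to the centerline at
#' stations every \code{station_spacing_px} pixels of resampled arc length,
#' inverts each profile, subtracts the local background (median of the
#' profile tails) and takes the distance between the two half-maximum
#' crossings (linear interpolation) as the station diameter. Stations
#' without two crossings are dropped; fewer than three valid stations
#' rejects the segment.
#'
#' @param segment a \code{vessel_segment} from \code{\link{split_segments}}.
#' @param avg_image time-averaged image.
#' @param pixel_size_um pixel size (um/px).
#' @param station_spacing_px spacing between diametry stations (pixels of
#'   arc length; the protocol value is 5).
#' @param profile_half_um half-length of the perpendicular profile (um).
#' @param profile_step_px sampling step along the profile (px).
#' @return the segment with fields added: \code{stations} (arc-length
#'   positions, px), \code{diameters_um}, \code{diameter_um} (mean over
#'   valid stations), \code{n_stations}, \code{boundaries} (list of left /
#'   right crossing coordinates); or, when diametry fails, the segment with
#'   \code{rejected = "diametry failed"}.
#' @export
measure_diameter <- function(segment, avg_image, pixel_size_um,
                             station_spacing_px = 5, profile_half_um = 60,
                             profile_step_px = 0.5) {
  pts <- resample_polyline(segment$path, step = 1)
  pts[, 1] <- smooth_ma(pts[, 1], 7)
  pts[, 2] <- smooth_ma(pts[, 2], 7)
  n <- nrow(pts)
  st <- seq(1L, n, by = station_spacing_px)
  tg <- centerline_tangents(pts)

  half_px <- profile_half_um / pixel_size_um
  offs <- seq(-half_px, half_px, by = profile_step_px)
  diam <- rep(NA_real_, length(st))
  bl <- matrix(NA_real_, length(st), 2)
  br <- matrix(NA_real_, length(st), 2)
  for (k in seq_along(st)) {
    i <- st[k]
    nx <- -tg[i, 2]; ny <- tg[i, 1]
    xs <- pts[i, 1] + offs * nx
    ys <- pts[i, 2] + offs * ny
    prof <- bilinear(avg_image, xs, ys)
    if (mean(is.na(prof)) > 0.2) next
    wpx <- fwhm_width(-prof, profile_step_px)
    if (!is.na(wpx)) {
      diam[k] <- wpx * pixel_size_um
      bl[k, ] <- c(pts[i, 1] - wpx / 2 * nx, pts[i, 2] - wpx / 2 * ny)
      br[k, ] <- c(pts[i, 1] + wpx / 2 * nx, pts[i, 2] + wpx / 2 * ny)
    }
  }

  ok <- !is.na(diam)
  if (sum(ok) < 3) {
    segment$rejected <- "diametry failed"
    return(segment)
  }
  segment$stations <- (st - 1)[ok]
  segment$diameters_um <- diam[ok]
  segment$diameter_um <- mean(diam[ok])
  segment$n_stations <- sum(ok)
  segment$boundaries <- list(left = bl[ok, , drop = FALSE],
                             right = br[ok, , drop = FALSE])
  segment$centerline <- pts
  segment
}

#' Flag segments with detectable blood flow by temporal variance
#'
#' Moving blood modulates the intensity along the centerline from frame to
#' frame; a segment is flagged flow-detected when the mean temporal
#' variance over its centerline pixels exceeds the background variance
#' (estimated from non-vessel pixels inside the registration mask) by
#' \code{factor}.
#'
#' @param segments list of \code{vessel_segment}s.
#' @param reg a \code{registered_sequence}.
#' @param mask logical vessel mask used to define background pixels.
#' @param factor multiple of the background variance required.
#' @return the segments with \code{flow_detected} and
#'   \code{variance_ratio} fields set.
#' @export
filter_by_variance <- function(segments, reg, mask, factor = 2) {
  h <- dim(reg$frames)[1]; w <- dim(reg$frames)[2]
  m <- rowMeans(reg$frames, dims = 2)
  m2 <- rowMeans(reg$frames^2, dims = 2)
  tvar <- pmax(m2 - m^2, 0)

  bg <- !mask & reg$mask
  bg_var <- if (any(bg)) mean(tvar[bg]) else 0
  for (i in seq_along(segments)) {
    pts <- round(resample_polyline(segments[[i]]$path, step = 1))
    keep <- pts[, 1] >= 1 & pts[, 1] <= w & pts[, 2] >= 1 & pts[, 2] <= h
    idx <- (pts[keep, 1] - 1) * h + pts[keep, 2]
    v <- mean(tvar[idx])
    segments[[i]]$variance_ratio <- if (bg_var > 0) v / bg_var else
      ifelse(v > 0, Inf, 0)
    segments[[i]]$flow_detected <- v > factor * bg_var
  }
  segments
}

#' Attach an arteriole/venule label to a segment
#'
#' Vessel typing follows the observed direction of blood flow (divergence
#' into branches for arterioles, collection into larger vessels for
#' venules); this is a manual or ground-truth annotation, not an automatic
#' classifier. Unlabeled segments are excluded from type-stratified
#' statistics.
#'
#' @param segment a \code{vessel_segment}.
#' @param label one of "arteriole", "venule", "unlabeled", or \code{NA}.
#' @return the segment with \code{type} set.
#' @export
label_vessel_type <- function(segment, label) {
  if (is.null(label) || is.na(label) || !nzchar(label)) label <- "unlabeled"
  if (!label %in% c("arteriole", "venule", "unlabeled")) {
    stop(sprintf("unknown vessel type label '%s'", label))
  }
  segment$type <- label
  segment
}
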