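# Spatio-temporal image (kymograph) velocimetry. The STI collects the
# intensity along a vessel centerline over the registered frames; moving
# red-blood-cell / plasma-gap texture forms oblique bands whose slope (in
# pixels of arc length per frame) is the axial speed.

#' Build the spatio-temporal image of a segment
#'
#' Entry (s, t) is the bilinearly interpolated intensity at centerline
#' station s (1-px arc-length steps) in registered frame t. Stations that
#' leave the registration validity mask are truncated; rows and columns are
#' then mean-subtracted (detrending) so that static structure — the vessel
#' itself — does not contribute to the band-slope search.
#'
#' @param reg a \code{registered_sequence}.
#' @param segment a \code{vessel_segment} (must be flow-detected for the
#'   pipeline, though this function does not enforce it).
#' @param min_stations minimum number of usable stations; shorter
#'   centerlines are rejected for velocimetry.
#' @return an \code{sti} object: \code{values} (stations x frames matrix,
#'   detrended), \code{raw}, \code{arc_step_um}, \code{frame_interval_s};
#'   or a list with \code{rejected = "too short for velocimetry"}.
#' @export
build_sti <- function(reg, segment, min_stations = 20) {
  pts <- resample_polyline(segment$path, step = 1)
  pts[, 1] <- smooth_ma(pts[, 1], 7)
  pts[, 2] <- smooth_ma(pts[, 2], 7)
  h <- dim(reg$frames)[1]; w <- dim(reg$frames)[2]
  xi <- round(clamp(pts[, 1], 1, w)); yi <- round(clamp(pts[, 2], 1, h))
  inside <- reg$mask[cbind(yi, xi)] &
    pts[, 1] >= 1 & pts[, 1] <= w & pts[, 2] >= 1 & pts[, 2] <= h
  # keep the longest run of in-mask stations so arc spacing stays uniform
  if (!all(inside)) {
    r <- rle(inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ok <- which(r$values)
    if (!length(ok)) return(list(rejected = "too short for velocimetry"))
    b <- ok[which.max(r$lengths[ok])]
    pts <- pts[starts[b]:ends[b], , drop = FALSE]
  }
  ns <- nrow(pts)
  if (ns < min_stations) return(list(rejected = "too short for velocimetry"))

  nt <- dim(reg$frames)[3]
  vals <- matrix(0, ns, nt)
  for (t in seq_len(nt)) {
    vals[, t] <- bilinear(reg$frames[, , t], pts[, 1], pts[, 2])
  }
  raw <- vals
  vals <- vals - rowMeans(vals)
  vals <- sweep(vals, 2, colMeans(vals))
  structure(
    list(
      values = vals, raw = raw,
      arc_step_um = reg$pixel_size_um,
      frame_interval_s = reg$frame_interval_s,
      segment_id = segment$id
    ),
    class = "sti"
  )
}

# Score one candidate slope m (arc px / frame): shear the STI so that bands
# of slope m become horizontal lines, then compute the one-way variance
# ratio (between-line mean square over within-line mean square) of the
# sheared samples. At the true slope the frozen texture aligns: within-line
# variance collapses to noise and the ratio peaks; at wrong slopes the
# ratio stays near 1 regardless of how many samples each line collects,
# which keeps the criterion unbiased at steep shears.
shear_score <- function(vals, m) {
  ns <- nrow(vals); nt <- ncol(vals)
  tind <- rep(seq_len(nt) - 1, each = ns)
  line <- rep(seq_len(ns), nt) - m * tind          # s - m*t, continuous
  lo <- floor(line)
  f <- line - lo
  v <- as.vector(vals)
  # linear split of every sample between two integer line bins
  wts <- c(1 - f, f)
  samp <- c(v * (1 - f), v * f)
  samp2 <- c(v^2 * (1 - f), v^2 * f)
  ki <- c(lo, lo + 1L) + 1L - min(lo)
  s0 <- unname(rowsum(wts, ki, reorder = TRUE))[, 1]
  s1 <- unname(rowsum(samp, ki, reorder = TRUE))[, 1]
  s2 <- unname(rowsum(samp2, ki, reorder = TRUE))[, 1]
  keep <- s0 >= 2.5
  k <- sum(keep)
  if (k < 5) return(0)
  s0 <- s0[keep]; s1 <- s1[keep]; s2 <- s2[keep]
  n_eff <- sum(s0)
  grand <- sum(s1) / n_eff
  ssb <- sum(s1^2 / s0) - n_eff * grand^2
  ssw <- sum(s2) - sum(s1^2 / s0)
  msb <- ssb / (k - 1)
  msw <- ssw / max(n_eff - k, 1)
  if (msw <= 1e-300) return(Inf)
  msb / msw
}

#' Estimate the band slope and axial velocity of an STI
#'
#' Orientation search with a Radon-style criterion: for candidate band
#' slopes, the detrended STI is sheared so candidate bands become
#' horizontal and scored by the one-way variance ratio of the projection
#' (between-line over within-line mean square); the maximizing slope wins.
#'
#' The score peaks very sharply in slope — the peak width is roughly the
#' texture correlation length divided by the frame count — so the search
#' is hierarchical: a coarse slope scan on a short central time window
#' (few frames, hence a wide peak), then two refinement passes on the full
#' STI with parabolic interpolation. The measurable-slope ceiling
#' |m| <= (stations - 1)/3 per frame guarantees every band line is sampled
#' in at least three frames; steeper bands on a short segment are not
#' measurable.
#'
#' @param sti an \code{sti} from \code{\link{build_sti}}.
#' @param quality_floor minimum quality score — the contrast
#'   (max - median)/median of the orientation criterion over a global
#'   reference slope grid — below which the estimate is flagged unreliable.
#' @return the \code{sti} with \code{slope_px_per_frame} (signed),
#'   \code{velocity_mm_s} (magnitude), \code{quality} and \code{reliable}
#'   set.
#' @export
estimate_band_slope <- function(sti, quality_floor = 2) {
  stopifnot(inherits(sti, "sti"))
  vals <- sti$values
  ns <- nrow(vals); nt <- ncol(vals)
  if (ns < 20 || nt < 10) stop("STI too small for slope estimation")
  if (max(abs(vals)) < 1e-10) stop("no detectable bands (all-zero STI)")

  m_max <- (ns - 1) / 3

  # coarse scan on a short central window: with few frames the score peak
  # is wide enough for a 0.25 px/frame grid to catch
  wlen <- min(nt, 12L)
  wstart <- (nt - wlen) %/% 2L
  short <- vals[, wstart + seq_len(wlen), drop = FALSE]
  short <- short - rowMeans(short)
  coarse <- seq(-m_max, m_max, by = 0.25)
  cs <- vapply(coarse, function(m) shear_score(short, m), numeric(1))
  slope <- coarse[which.max(cs)]

  # refinement passes on the full STI; the first pass spans wider than the
  # worst-case coarse-scan error
  for (res in c(0.2, 0.03, 0.005)) {
    grid <- slope + seq(-8 * res, 8 * res, by = res)
    grid <- grid[abs(grid) <= m_max]
    fs <- vapply(grid, function(m) shear_score(vals, m), numeric(1))
    fb <- which.max(fs)
    slope <- grid[fb]
    if (fb > 1 && fb < length(grid)) {
      den <- fs[fb - 1] - 2 * fs[fb] + fs[fb + 1]
      if (abs(den) > 1e-15) {
        slope <- slope + clamp(0.5 * (fs[fb - 1] - fs[fb + 1]) / den,
                               -0.5, 0.5) * res
      }
    }
  }

  # quality: peak contrast of the full-STI criterion over a global
  # reference grid (plus the refined optimum)
  refg <- seq(-m_max, m_max, length.out = 101)
  rs <- vapply(refg, function(m) shear_score(vals, m), numeric(1))
  peak <- max(shear_score(vals, slope), max(rs))
  med <- median(rs)
  quality <- if (med > 1e-15) (peak - med) / med else Inf

  sti$slope_px_per_frame <- slope
  sti$velocity_mm_s <- abs(slope) * sti$arc_step_um /
    sti$frame_interval_s / 1000
  sti$quality <- quality
  sti$reliable <- is.finite(quality) && quality >= quality_floor
  sti
}

#' @export
print.sti <- function(x, ...) {
  cat(sprintf("sti: %d stations x %d frames", nrow(x$values), ncol(x$values)))
  if (!is.null(x$velocity_mm_s)) {
    cat(sprintf(", slope %.2f px/frame, V %.3f mm/s (%s)",
                x$slope_px_per_frame, x$velocity_mm_s,
                if (isTRUE(x$reliable)) "reliable" else "unreliable"))
  }
  cat("\n")
  invisible(x)
}

# Independent cross-check used in tests: average 1-d cross-correlation
# shift between consecutive STI columns, exhaustive over integer lags with
# parabolic refinement.
xcorr_slope <- function(vals, max_lag = NULL) {
  ns <- nrow(vals); nt <- ncol(vals)
  if (is.null(max_lag)) max_lag <- ns %/% 2 - 1
  lags <- -max_lag:max_lag
  total <- numeric(length(lags))
  for (t in seq_len(nt - 1)) {
    a <- vals[, t]; b <- vals[, t + 1]
    for (i in seq_along(lags)) {
      l <- lags[i]
      if (l >= 0) {
        sa <- a[seq_len(ns - l)]; sb <- b[seq_len(ns - l) + l]
      } else {
        sa <- a[seq_len(ns + l) - l]; sb <- b[seq_len(ns + l)]
      }
      total[i] <- total[i] + sum(sa * sb) / length(sa)
    }
  }
  pk <- which.max(total)
  lag <- lags[pk]
  if (pk > 1 && pk < length(lags)) {
    den <- total[pk - 1] - 2 * total[pk] + total[pk + 1]
    if (abs(den) > 1e-15) {
      lag <- lag + clamp(0.5 * (total[pk - 1] - total[pk + 1]) / den, -0.5, 0.5)
    }
  }
  lag
}
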