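# Frame screening and translational registration. The acquisition protocol
# asks subjects to suspend blinking for the one-second capture, but blinks,
# saccades and illumination artifacts still occur; affected frames are
# rejected, the longest consecutive clean run is kept, and that run is
# registered by a single sub-pixel translation per frame before
# time-averaging.
#
# Registration is intensity-based cross-correlation against the evolving
# time-averaged image rather than against a single reference frame: moving
# blood texture averages out of the mean image, so the estimator locks onto
# static tissue (scleral mottle, the vessel walls themselves) instead of
# tracking flow. A final refinement masks out high-temporal-variance
# (moving) pixels entirely, which removes the residual along-vessel pull
# the flowing texture exerts on frames far from the temporal centre.

#' Screen frames for blinks, motion and illumination artifacts
#'
#' A frame is flagged invalid when (a) its mean intensity deviates from the
#' sequence's median mean-intensity by more than \code{blink_z} robust
#' standard deviations (blinks darken the whole field), (b) its normalized
#' cross-correlation with the preceding valid frame falls below
#' \code{min_correlation} (large eye motion), or (c) the peak-to-peak
#' amplitude of a least-squares planar fit to the frame exceeds
#' \code{max_gradient} times the median intensity (illumination artifact).
#'
#' @param seq an \code{\link{image_sequence}}.
#' @param blink_z robust z-score threshold on frame mean intensity.
#' @param min_correlation minimum normalized cross-correlation with the
#'   previous valid frame. Moving blood texture decorrelates consecutive
#'   frames even without eye motion, so this threshold must sit below the
#'   flow-induced decorrelation floor (around 0.6 in synthetic scenes);
#'   genuine saccades push the correlation far lower.
#' @param max_gradient maximum planar illumination amplitude, as a fraction
#'   of the median frame intensity.
#' @param blink_floor absolute mean-intensity floor (on the [0, 1] scale):
#'   frames darker than this are blinks regardless of the z-score, which
#'   catches sequences where blinks are the majority and the median itself
#'   is dark.
#' @return data frame with one row per frame: \code{frame} (1-based index),
#'   \code{valid}, and \code{criterion} ("ok", "blink", "motion" or
#'   "illumination"; the first failing criterion is recorded).
#' @export
score_frame_quality <- function(seq, blink_z = 4, min_correlation = 0.4,
                                max_gradient = 0.2, blink_floor = 0.15) {
  stopifnot(inherits(seq, "image_sequence"))
  nf <- n_frames(seq)
  if (nf < 1) stop("no usable frames: empty sequence")

  means <- vapply(seq_len(nf), function(t) mean(seq$frames[, , t]), numeric(1))
  med <- median(means)
  scale <- max(mad(means, center = med), 0.005 * abs(med), 1e-9)
  z <- abs(means - med) / scale

  criterion <- rep("ok", nf)
  criterion[z > blink_z | means < blink_floor] <- "blink"

  # planar illumination fit on a subsampled grid
  h <- dim(seq$frames)[1]; w <- dim(seq$frames)[2]
  ri <- unique(round(seq(1, h, length.out = min(h, 40))))
  ci <- unique(round(seq(1, w, length.out = min(w, 40))))
  X <- cbind(1, rep(ci, each = length(ri)) / w, rep(ri, times = length(ci)) / h)
  XtXi <- solve(crossprod(X))
  for (t in seq_len(nf)) {
    if (criterion[t] != "ok") next
    y <- as.vector(seq$frames[ri, ci, t])
    beta <- XtXi %*% crossprod(X, y)
    amp <- abs(beta[2]) + abs(beta[3])  # peak-to-peak of the plane over the field
    if (amp > max_gradient * max(median(y), 1e-6)) criterion[t] <- "illumination"
  }

  # motion: NCC against the previous frame that passed all criteria so far
  prev <- NA_integer_
  for (t in seq_len(nf)) {
    if (criterion[t] != "ok") next
    if (!is.na(prev)) {
      a <- as.vector(seq$frames[ri, ci, t]); b <- as.vector(seq$frames[ri, ci, prev])
      sa <- sd(a); sb <- sd(b)
      ncc <- if (sa < 1e-9 || sb < 1e-9) 1 else
        sum((a - mean(a)) * (b - mean(b))) / ((length(a) - 1) * sa * sb)
      if (ncc < min_correlation) {
        criterion[t] <- "motion"
        next
      }
    }
    prev <- t
  }

  flags <- data.frame(frame = seq_len(nf), valid = criterion == "ok",
                      criterion = criterion)
  if (!any(flags$valid)) stop("no usable frames: every frame failed screening")
  flags
}

#' Longest run of consecutive valid frames
#'
#' @param valid logical vector of per-frame validity (or the data frame
#'   returned by \code{\link{score_frame_quality}}).
#' @return integer vector \code{c(first, last)} of 1-based frame indices of
#'   the maximal-length consecutive valid run; ties broken by earliest start.
#' @export
longest_valid_run <- function(valid) {
  if (is.data.frame(valid)) valid <- valid$valid
  if (!any(valid)) stop("no usable frames: no valid frames to select from")
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]  # which.max takes the earliest maximum
  c(first = starts[best], last = ends[best])
}

# Windowed phase correlation with parabolic sub-pixel refinement. Spectral
# whitening makes the estimate reflect the fraction of coherently shifted
# pixels, which rejects the spatially confined flow texture; it is noise
# sensitive, so it serves only short runs where no stable time-average
# exists as an anchor.
phase_translation <- function(ref, mov) {
  h <- nrow(ref); w <- ncol(ref)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  win <- outer(hann(h), hann(w))
  Fa <- fft((ref - mean(ref)) * win)
  Fb <- fft((mov - mean(mov)) * win)
  R <- Fb * Conj(Fa)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(fft(R, inverse = TRUE)) / (h * w)
  pk <- which.max(r)
  py <- (pk - 1) %% h + 1
  px <- (pk - 1) %/% h + 1
  wrap <- function(i, n) if (i > n / 2) i - n else i
  at <- function(y, x) r[(y - 1) %% h + 1, (x - 1) %% w + 1]
  sub <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (abs(den) < 1e-12) 0 else clamp(0.5 * (cm1 - cp1) / den, -0.5, 0.5)
  }
  c(dx = wrap(px, w) - 1 + sub(at(py, px - 1), at(py, px), at(py, px + 1)),
    dy = wrap(py, h) - 1 + sub(at(py - 1, px), at(py, px), at(py + 1, px)))
}

# Sub-pixel translation of `mov` relative to `ref` by cross-correlation
# with local DFT upsampling of the peak (no spectral whitening: whitening
# boosts the high frequencies where moving blood texture lives and makes
# the estimator track flow instead of tissue). Returns c(dx, dy) such that
# mov ~ shift_image(ref, dx, dy).
estimate_translation <- function(ref, mov, upsample = 20, halfwin = 1.5) {
  h <- nrow(ref); w <- ncol(ref)
  a <- ref - mean(ref)
  b <- mov - mean(mov)
  FF <- fft(b) * Conj(fft(a))
  r <- Re(fft(FF, inverse = TRUE)) / (h * w)
  if (max(abs(r)) < 1e-12) return(c(dx = 0, dy = 0))
  pk <- which.max(r)
  py <- (pk - 1) %% h + 1
  px <- (pk - 1) %/% h + 1
  wrap <- function(i, n) if (i > n / 2) i - n else i
  dy0 <- wrap(py, h) - 1
  dx0 <- wrap(px, w) - 1

  fy <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1)) / h
  fx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1)) / w
  dys <- dy0 + seq(-halfwin, halfwin, by = 1 / upsample)
  dxs <- dx0 + seq(-halfwin, halfwin, by = 1 / upsample)
  cc <- Re(exp(2i * pi * outer(dys, fy)) %*% FF %*% exp(2i * pi * outer(fx, dxs)))
  pk2 <- which.max(cc)
  iy <- (pk2 - 1) %% length(dys) + 1
  ix <- (pk2 - 1) %/% length(dys) + 1
  # parabolic sub-grid refinement on the upsampled surface
  step <- 1 / upsample
  sub <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (abs(den) < 1e-12) 0 else clamp(0.5 * (cm1 - cp1) / den, -0.5, 0.5)
  }
  ddx <- if (ix > 1 && ix < length(dxs)) {
    sub(cc[iy, ix - 1], cc[iy, ix], cc[iy, ix + 1]) * step
  } else 0
  ddy <- if (iy > 1 && iy < length(dys)) {
    sub(cc[iy - 1, ix], cc[iy, ix], cc[iy + 1, ix]) * step
  } else 0
  c(dx = dxs[ix] + ddx, dy = dys[iy] + ddy)
}

#' Register a run of frames by translation and time-average
#'
#' Aligns every frame of the selected run by a single sub-pixel 2-d
#' translation and computes the pixel-wise mean image. Translations are
#' estimated by cross-correlation against the evolving time-averaged image
#' (two passes), then refined with moving pixels masked out (two passes);
#' see the source header for why this is preferred over frame-to-frame
#' phase correlation in microvascular sequences. Translations are reported
#' relative to the middle frame of the run, whose translation is exactly
#' (0, 0). Borders invalidated by shifting are filled by edge replication
#' and excluded from the returned validity mask.
#'
#' @param seq an \code{\link{image_sequence}}.
#' @param run integer \code{c(first, last)} (1-based, inclusive), e.g. from
#'   \code{\link{longest_valid_run}}; default is the full sequence.
#' @param max_shift_frac frames whose estimated shift exceeds this fraction
#'   of the frame width are reported in \code{oversized_shifts}.
#' @return a \code{registered_sequence}: registered frames (H x W x T
#'   array), \code{run}, per-frame \code{translations} (T x 2, dx/dy px),
#'   \code{reference} (frame index in the original sequence),
#'   \code{average} image, logical \code{mask} of pixels valid in every
#'   frame, and acquisition constants inherited from \code{seq}.
#' @export
register <- function(seq, run = NULL, max_shift_frac = 0.1) {
  stopifnot(inherits(seq, "image_sequence"))
  nf <- n_frames(seq)
  if (is.null(run)) run <- c(1L, nf)
  if (run[1] > run[2] || run[1] < 1 || run[2] > nf) {
    stop("invalid frame run")
  }
  idx <- run[1]:run[2]
  nr <- length(idx)
  h <- dim(seq$frames)[1]; w <- dim(seq$frames)[2]
  stack <- seq$frames[, , idx, drop = FALSE]

  tr <- matrix(0, nr, 2, dimnames = list(NULL, c("dx", "dy")))
  aligned <- stack
  realign <- function() {
    for (k in seq_len(nr)) {
      aligned[, , k] <<- if (all(tr[k, ] == 0)) stack[, , k] else
        shift_image(stack[, , k], -tr[k, 1], -tr[k, 2])
    }
  }

  ref_local <- (nr + 1L) %/% 2L
  if (nr > 1 && nr < 8) {
    # too few frames for the mean image to be a usable anchor: align each
    # frame to the reference frame directly by phase correlation
    for (k in seq_len(nr)) {
      if (k == ref_local) next
      tr[k, ] <- phase_translation(stack[, , ref_local], stack[, , k])
    }
    realign()
  } else if (nr > 1) {
    for (pass in 1:2) {
      avg <- rowMeans(aligned, dims = 2)
      for (k in seq_len(nr)) {
        tr[k, ] <- tr[k, ] + estimate_translation(avg, aligned[, , k])
      }
      realign()
    }
    # masked refinement: suppress moving pixels so flow cannot bias shifts
    for (pass in 1:2) {
      avg <- rowMeans(aligned, dims = 2)
      tvar <- rowMeans(aligned^2, dims = 2) - avg^2
      # relative to the background variance, with an absolute floor of 1%
      # intensity fluctuation so noise-free scenes don't flag everything
      moving <- tvar > max(3 * median(tvar), 1e-4)
      moving <- EBImage::dilate(moving, EBImage::makeBrush(13, "disc")) > 0
      if (mean(moving) >= 0.7) break  # nothing static enough to mask against
      fill <- mean(avg[!moving])
      avg_m <- avg; avg_m[moving] <- fill
      for (k in seq_len(nr)) {
        fr <- aligned[, , k]
        fr[moving] <- mean(fr[!moving])
        tr[k, ] <- tr[k, ] + estimate_translation(avg_m, fr)
      }
      realign()
    }
  }

  # anchor on the middle frame of the run
  tr <- sweep(tr, 2, tr[ref_local, ])
  realign()

  mask <- matrix(TRUE, h, w)
  oversized <- integer(0)
  for (k in seq_len(nr)) {
    if (max(abs(tr[k, ])) > max_shift_frac * w) oversized <- c(oversized, idx[k])
    mask <- mask & shift_valid_mask(h, w, -tr[k, 1], -tr[k, 2])
  }

  structure(
    list(
      frames = aligned,
      run = c(first = run[1], last = run[2]),
      translations = tr,
      reference = idx[ref_local],
      average = rowMeans(aligned, dims = 2),
      mask = mask,
      oversized_shifts = oversized,
      pixel_size_um = seq$pixel_size_um,
      frame_interval_s = seq$frame_interval_s
    ),
    class = "registered_sequence"
  )
}

#' @export
print.registered_sequence <- function(x, ...) {
  cat(sprintf(
    "registered_sequence: frames %d-%d (reference %d), max |shift| %.2f px\n",
    x$run[1], x$run[2], x$reference, max(abs(x$translations))
  ))
  invisible(x)
}
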