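# Internal helpers shared across modules. Images are numeric matrices indexed
# [row, col] (row = y, col = x); intensities live in [0, 1]. Coordinates in
# exported tables are 0-based with x = column, y = row, origin top-left.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear interpolation of matrix `img` at continuous positions (x, y),
# 1-based, x = column, y = row. Points outside the image return NA.
bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= w & y >= 1 & y <= h & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + (x0 - 1) * h
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + h] +
    (1 - fx) * fy * img[i00 + 1] +
    fx * fy * img[i00 + h + 1]
  out[ok] <- v
  out
}

# Translate an image by (dx, dy) pixels (content moves right/down for
# positive values), sub-pixel via bilinear resampling, edges replicated.
shift_image <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  xs <- clamp(rep(seq_len(w), each = h) - dx, 1, w)
  ys <- clamp(rep(seq_len(h), times = w) - dy, 1, h)
  matrix(bilinear(img, xs, ys), h, w)
}

# Logical mask of pixels unaffected by edge replication after shift_image().
shift_valid_mask <- function(h, w, dx, dy) {
  xs <- rep(seq_len(w), each = h) - dx
  ys <- rep(seq_len(h), times = w) - dy
  matrix(xs >= 1 & xs <= w & ys >= 1 & ys <= h, h, w)
}

# Replicate-pad a matrix by `p` pixels on every side.
pad_replicate <- function(img, p) {
  ri <- c(rep(1L, p), seq_len(nrow(img)), rep(nrow(img), p))
  ci <- c(rep(1L, p), seq_len(ncol(img)), rep(ncol(img), p))
  img[ri, ci, drop = FALSE]
}

# Polynomial string hash (mod 2^31 - 1), hex string; config provenance
# only, not cryptographic. All arithmetic stays exact in doubles.
string_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Resample an ordered polyline (n x 2 matrix, columns x/y) to a fixed
# arc-length step. Returns a matrix with attribute "arclen" (total, px).
resample_polyline <- function(pts, step = 1) {
  if (nrow(pts) < 2) stop("polyline needs at least 2 points")
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  keep <- c(TRUE, d > 1e-12)
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  si <- seq(0, total, by = step)
  if (si[length(si)] < total - 1e-9) si <- c(si, total)
  out <- cbind(
    x = approx_fast(s, pts[, 1], si),
    y = approx_fast(s, pts[, 2], si)
  )
  attr(out, "arclen") <- total
  attr(out, "s") <- si
  out
}

approx_fast <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# Centered moving-average smoothing with edge shrinkage.
smooth_ma <- function(v, window = 5) {
  n <- length(v)
  if (n < 3 || window < 3) return(v)
  half <- window %/% 2
  out <- v
  cs <- cumsum(c(0, v))
  for (i in seq_len(n)) {
    a <- max(1, i - half); b <- min(n, i + half)
    out[i] <- (cs[b + 1] - cs[a]) / (b - a + 1)
  }
  out
}
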