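# Centerline extraction: Zhang-Suen thinning of the binary vessel mask to a
# 1-px 8-connected skeleton, bifurcation detection by neighbor counting,
# and cutting of the skeleton into individual vessel-segment centerlines.

shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
  oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# Count of 8-neighbors that are TRUE, for every pixel.
neighbor_count <- function(m) {
  n <- matrix(0L, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    n <- n + shift_mat(m, dy, dx)
  }
  n
}

#' Thin a binary mask to a one-pixel skeleton
#'
#' Zhang-Suen iterative thinning; the result is an 8-connected, 1-px-wide
#' skeleton that preserves the topology of the mask.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
thin_mask <- function(mask) {
  m <- mask
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors P2..P9 clockwise from north
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # cleanup: Zhang-Suen can leave staircase bulge pixels that mimic
  # bifurcations (>= 3 neighbors) although they lie on a simple path
  # (crossing number 1); removing them preserves topology
  h <- nrow(m); w <- ncol(m)
  at <- function(y, x) y >= 1 && y <= h && x >= 1 && x <= w && m[y, x]
  ring_of <- function(y, x) {
    c(at(y - 1, x), at(y - 1, x + 1), at(y, x + 1), at(y + 1, x + 1),
      at(y + 1, x), at(y + 1, x - 1), at(y, x - 1), at(y - 1, x - 1))
  }
  ring_dy <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  ring_dx <- c(0, 1, 1, 1, 0, -1, -1, -1)
  repeat {
    changed <- FALSE
    nc <- neighbor_count(m)
    for (p in which(m & nc >= 2)) {
      y <- (p - 1L) %% h + 1L
      x <- (p - 1L) %/% h + 1L
      ring <- ring_of(y, x)
      a <- sum(!ring & c(ring[-1], ring[1]))
      b <- sum(ring)
      drop <- FALSE
      if (b >= 3 && a == 1) {
        drop <- TRUE
      } else if (b == 2) {
        # staircase corner: two mutually adjacent neighbors (so removal
        # keeps them connected), one of which looks like a junction only
        # because of this redundant pixel
        i2 <- which(ring)
        ny <- y + ring_dy[i2]; nx <- x + ring_dx[i2]
        if (max(abs(ny[1] - ny[2]), abs(nx[1] - nx[2])) <= 1 &&
            max(nc[cbind(ny, nx)]) >= 3) {
          drop <- TRUE
        }
      }
      if (drop) {
        m[p] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Prune short terminal spurs from a skeleton
#'
#' Thinning a wide tube leaves short side branches at blunt ends and mask
#' irregularities; these spurs create spurious bifurcations that would cut
#' the true centerline. Any branch from an endpoint that reaches a
#' bifurcation within \code{max_spur_px} pixels is removed (iterated until
#' stable). Genuine vessel segments are unaffected: at 1.25 um/px the
#' shortest admissible centerline (50 um) is 40 px.
#'
#' @param skel logical skeleton matrix.
#' @param max_spur_px maximum spur length to remove (px).
#' @return pruned skeleton.
#' @export
prune_skeleton <- function(skel, max_spur_px = 20) {
  h <- nrow(skel); w <- ncol(skel)
  step_nbrs <- function(cur, exclude) {
    cy <- (cur - 1L) %% h + 1L; cx <- (cur - 1L) %/% h + 1L
    out <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      y <- cy + dy; x <- cx + dx
      if (y < 1L || y > h || x < 1L || x > w) next
      p <- (x - 1L) * h + y
      if (skel[p] && !(p %in% exclude)) out <- c(out, p)
    }
    out
  }
  repeat {
    nc <- neighbor_count(skel)
    ends <- which(skel & nc == 1)
    removed <- FALSE
    for (e in ends) {
      path <- e
      cur <- e
      hit_branch <- FALSE
      for (s in seq_len(max_spur_px)) {
        nxt <- step_nbrs(cur, path)
        if (!length(nxt)) break
        if (any(nc[nxt] >= 3)) {
          hit_branch <- TRUE
          break
        }
        cur <- nxt[1]
        path <- c(path, cur)
      }
      if (hit_branch) {
        skel[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Find skeleton bifurcation points
#'
#' A bifurcation is a skeleton pixel with three or more skeleton neighbors
#' under 8-connectivity.
#'
#' @param skel logical skeleton matrix.
#' @return logical matrix marking bifurcation pixels.
#' @export
find_bifurcations <- function(skel) {
  skel & neighbor_count(skel) >= 3
}

# Order the pixels of a simple 8-connected path component. `coords` is an
# n x 2 matrix of (row, col). Returns ordered indices, or NULL for cycles.
order_path <- function(coords) {
  n <- nrow(coords)
  if (n == 1) return(1L)
  key <- coords[, 1] * 1e6 + coords[, 2]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  nbrs <- function(i) {
    out <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      k <- as.character((coords[i, 1] + dy) * 1e6 + coords[i, 2] + dx)
      j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  deg <- vapply(seq_len(n), function(i) length(nbrs(i)), integer(1))
  ends <- which(deg <= 1)
  start <- if (length(ends)) ends[1] else return(NULL)
  visited <- rep(FALSE, n)
  path <- integer(n); path[1] <- start; visited[start] <- TRUE
  len <- 1L
  cur <- start
  repeat {
    nx <- nbrs(cur)
    nx <- nx[!visited[nx]]
    if (!length(nx)) break
    # prefer 4-connected continuation so diagonals don't skip pixels
    if (length(nx) > 1) {
      d4 <- abs(coords[nx, 1] - coords[cur, 1]) +
        abs(coords[nx, 2] - coords[cur, 2]) == 1
      if (any(d4)) nx <- nx[d4]
    }
    cur <- nx[1]
    len <- len + 1L
    path[len] <- cur
    visited[cur] <- TRUE
  }
  path[seq_len(len)]
}

# 8-connected component labels over TRUE pixels of a logical matrix.
# Skeletons are sparse, so a simple stack-based flood fill suffices.
label8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nextlab <- 0L
  for (p in which(m)) {
    if (lab[p] != 0L) next
    nextlab <- nextlab + 1L
    stack <- p
    lab[p] <- nextlab
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      qy <- (q - 1L) %% h + 1L
      qx <- (q - 1L) %/% h + 1L
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        ry <- qy + dy; rx <- qx + dx
        if (ry < 1L || ry > h || rx < 1L || rx > w) next
        r <- (rx - 1L) * h + ry
        if (m[r] && lab[r] == 0L) {
          lab[r] <- nextlab
          stack <- c(stack, r)
        }
      }
    }
  }
  lab
}

#' Cut a skeleton at bifurcations into vessel-segment centerlines
#'
#' Bifurcation pixels are removed, each remaining 8-connected component is
#' traced into an ordered centerline path, and segments with arc length at
#' or below \code{min_length_um} are discarded (the sampling-reliability
#' rule: only centerlines longer than 50 um enter hemodynamic analysis).
#' Arc length is the sum of inter-pixel steps (1 or sqrt(2) px) times the
#' pixel size.
#'
#' @param skel logical skeleton matrix.
#' @param pixel_size_um pixel size (um/px).
#' @param min_length_um segments must be strictly longer than this.
#' @return a list with \code{segments} (list of \code{vessel_segment}
#'   objects with \code{id}, \code{path} n x 2 matrix of x/y pixel
#'   coordinates, \code{length_um}, \code{parent} component id) and
#'   \code{n_discarded_short}.
#' @export
split_segments <- function(skel, pixel_size_um, min_length_um = 50) {
  if (!any(skel)) {
    return(list(segments = list(), n_discarded_short = 0L))
  }
  comp <- label8(skel)           # parent vessel = pre-cut component
  bif <- find_bifurcations(skel)
  cut <- skel & !bif
  lab <- label8(cut)
  segs <- list()
  discarded <- 0L
  id <- 0L
  for (l in seq_len(max(lab))) {
    pix <- which(lab == l)
    coords <- cbind(row = (pix - 1) %% nrow(skel) + 1,
                    col = (pix - 1) %/% nrow(skel) + 1)
    ord <- order_path(coords)
    if (is.null(ord)) next  # closed loop: no endpoints, not a vessel segment
    coords <- coords[ord, , drop = FALSE]
    if (nrow(coords) < 2) {
      discarded <- discarded + 1L
      next
    }
    steps <- sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)
    len_um <- sum(steps) * pixel_size_um
    if (len_um <= min_length_um) {
      discarded <- discarded + 1L
      next
    }
    id <- id + 1L
    segs[[id]] <- structure(
      list(
        id = id,
        path = cbind(x = coords[, 2], y = coords[, 1]),
        length_um = len_um,
        parent = comp[pix[1]]
      ),
      class = "vessel_segment"
    )
  }
  list(segments = segs, n_discarded_short = discarded)
}

#' Extract centerline segments from a vessel mask
#'
#' Convenience composition of \code{\link{thin_mask}},
#' \code{\link{prune_skeleton}} and \code{\link{split_segments}}.
#'
#' @inheritParams split_segments
#' @param mask logical vessel mask.
#' @param max_spur_px passed to \code{\link{prune_skeleton}}.
#' @return as \code{\link{split_segments}}.
#' @export
extract_centerlines <- function(mask, pixel_size_um, min_length_um = 50,
                                max_spur_px = 20) {
  split_segments(prune_skeleton(thin_mask(mask), max_spur_px),
                 pixel_size_um, min_length_um)
}
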