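# Low-level image utilities shared across modules.
#
# Conventions used throughout the package:
#  * an RGB image is a numeric H x W x 3 array with 8-bit values in [0, 255]
#  * a grayscale map is a numeric H x W matrix
#  * a mask is a logical H x W matrix
#  * points and paths are (row, col) matrices, 1-based

.local_seed <- function(seed, envir = parent.frame()) {
  # set the RNG inside a function, restoring the caller's stream on exit
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  do.call(on.exit, list(quote({
    if (!is.null(.ttc_old_seed)) assign(".Random.seed", .ttc_old_seed, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }), add = TRUE), envir = envir)
  assign(".ttc_old_seed", old, envir = envir)
  set.seed(seed)
  invisible(NULL)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.as_ebi <- function(m) EBImage::Image(t(m))
.from_ebi <- function(img) t(as.matrix(EBImage::imageData(img)))

.disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' @noRd
.dilate_disk <- function(mask, radius) {
  if (radius < 1) return(mask)
  .from_ebi(EBImage::dilate(.as_ebi(mask * 1), .disc_brush(radius))) > 0.5
}

#' @noRd
.erode_disk <- function(mask, radius) {
  if (radius < 1) return(mask)
  .from_ebi(EBImage::erode(.as_ebi(mask * 1), .disc_brush(radius))) > 0.5
}

.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  .from_ebi(EBImage::gblur(.as_ebi(m), sigma = sigma))
}

.blur_rgb <- function(img, sigma) {
  if (sigma <= 0) return(img)
  for (ch in 1:3) img[, , ch] <- .gauss_blur(img[, , ch], sigma)
  img
}

# contrast-limited adaptive histogram equalization; the tiled implementation
# requires dimensions divisible by the tile counts, so pad by edge
# replication and crop back
.clahe <- function(m, nx = 4, ny = 4) {
  H <- nrow(m); W <- ncol(m)
  H2 <- ceiling(H / ny) * ny; W2 <- ceiling(W / nx) * nx
  mp <- m[c(seq_len(H), rep(H, H2 - H)), c(seq_len(W), rep(W, W2 - W)), drop = FALSE]
  out <- .from_ebi(EBImage::clahe(.as_ebi(mp), nx = nx, ny = ny))
  out[seq_len(H), seq_len(W), drop = FALSE]
}

# shift a matrix by (dr, dc) with replicated borders
.shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- .clip(seq_len(H) - dr, 1L, H)
  ci <- .clip(seq_len(W) - dc, 1L, W)
  m[ri, ci, drop = FALSE]
}

# central-difference gradient with replicated borders (spacing 1)
.gradient2d <- function(m) {
  gx <- (.shift_mat(m, 0, -1) - .shift_mat(m, 0, 1)) / 2   # d/dcol
  gy <- (.shift_mat(m, -1, 0) - .shift_mat(m, 1, 0)) / 2   # d/drow
  list(gr = gy, gc = gx)
}

# 5-point Laplacian with replicated (Neumann) borders
.laplacian <- function(m) {
  .shift_mat(m, 1, 0) + .shift_mat(m, -1, 0) +
    .shift_mat(m, 0, 1) + .shift_mat(m, 0, -1) - 4 * m
}

# Sobel gradient magnitude, optionally normalized to [0, 1]
.sobel_mag <- function(m, normalize = TRUE) {
  sx <- function(m) {
    a <- .shift_mat(m, 0, -1) - .shift_mat(m, 0, 1)
    b <- .shift_mat(m, -1, -1) - .shift_mat(m, -1, 1)
    d <- .shift_mat(m, 1, -1) - .shift_mat(m, 1, 1)
    2 * a + b + d
  }
  gx <- sx(m)
  gy <- sx(t(m))
  mag <- sqrt(gx^2 + t(gy)^2)
  if (normalize && max(mag) > 0) mag <- mag / max(mag)
  mag
}

# vectorized bilinear interpolation of matrix m at fractional (r, c)
.interp_bilinear <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- .clip(r, 1, H); c <- .clip(c, 1, W)
  r0 <- .clip(floor(r), 1, H - 1); c0 <- .clip(floor(c), 1, W - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * m[i00] + fr * (1 - fc) * m[i10] +
    (1 - fr) * fc * m[i01] + fr * fc * m[i11]
}

#' Connected-component labelling
#'
#' Labels connected foreground components of a binary mask.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 is background, components are numbered from 1.
#' @keywords internal
.cc_label <- function(mask, connectivity = 4L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  .cc_label_cpp(mask, as.integer(connectivity))
}

# rotate points (r, c) about pivot by angle theta (radians, CCW in
# row/col coordinates); exact analytic mapping, invertible with -theta
.rotate_points <- function(pts, theta, pivot) {
  dr <- pts[, 1] - pivot[1]; dc <- pts[, 2] - pivot[2]
  cbind(pivot[1] + cos(theta) * dr - sin(theta) * dc,
        pivot[2] + sin(theta) * dr + cos(theta) * dc)
}

# rotate a mask by theta about pivot (nearest neighbour, same frame)
.rotate_mask <- function(mask, theta, pivot) {
  H <- nrow(mask); W <- ncol(mask)
  grid <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))
  src <- .rotate_points(grid, -theta, pivot)
  sr <- round(src[, 1]); sc <- round(src[, 2])
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out <- matrix(FALSE, H, W)
  out[grid[ok, , drop = FALSE]] <- mask[cbind(sr[ok], sc[ok])]
  out
}

# rotate a grayscale map (bilinear)
.rotate_gray <- function(m, theta, pivot, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  grid <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))
  src <- .rotate_points(grid, -theta, pivot)
  out <- matrix(fill, H, W)
  ok <- src[, 1] >= 1 & src[, 1] <= H & src[, 2] >= 1 & src[, 2] <= W
  out[grid[ok, , drop = FALSE]] <- .interp_bilinear(m, src[ok, 1], src[ok, 2])
  out
}

# principal-axis orientation of a mask: angle (radians) of the major
# axis measured from the column axis (0 = horizontal major axis)
.mask_orientation <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1] - mean(idx[, 1]); c <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(c^2); mu02 <- mean(r^2); mu11 <- mean(c * r)
  0.5 * atan2(2 * mu11, mu20 - mu02)
}

# rasterize an ordered polyline of fractional (r, c) points into an
# 8-connected single-pixel chain
.rasterize_polyline <- function(pts) {
  if (nrow(pts) < 2) return(round(pts))
  segs <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1, ]
    n <- max(2, ceiling(max(abs(p1 - p0)) * 3) + 1)
    segs[[i]] <- cbind(seq(p0[1], p1[1], length.out = n),
                       seq(p0[2], p1[2], length.out = n))
  }
  dense <- do.call(rbind, segs)
  px <- round(dense)
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px <- px[keep, , drop = FALSE]
  # prune chain pixels whose neighbours are themselves 8-adjacent
  repeat {
    n <- nrow(px)
    if (n < 3) break
    drop <- rep(FALSE, n)
    i <- 2
    while (i < n) {
      if (!drop[i - 1] &&
          max(abs(px[i + 1, ] - px[i - 1, ])) <= 1) drop[i] <- TRUE
      i <- i + if (drop[i]) 2 else 1
    }
    if (!any(drop)) break
    px <- px[!drop, , drop = FALSE]
  }
  px
}

# scanline fill of a closed polygon given by vertices (r, c)
.polygon_fill <- function(xy, dim) {
  H <- dim[1]; W <- dim[2]
  out <- matrix(FALSE, H, W)
  ys <- xy[, 1]; xs <- xy[, 2]
  n <- length(ys)
  j <- n
  for (r in seq_len(H)) {
    # horizontal scanline at row r: find crossings of edges
    cross <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      y1 <- ys[j]; y2 <- ys[i]
      if ((y1 <= r && y2 > r) || (y2 <= r && y1 > r)) {
        x <- xs[j] + (r - y1) / (y2 - y1) * (xs[i] - xs[j])
        cross <- c(cross, x)
      }
      j <- i
    }
    if (length(cross) >= 2) {
      cross <- sort(cross)
      for (k in seq(1, length(cross) - 1, by = 2)) {
        c0 <- max(1L, ceiling(cross[k])); c1 <- min(W, floor(cross[k + 1]))
        if (c0 <= c1) out[r, c0:c1] <- TRUE
      }
    }
  }
  out
}

# Zhang-Suen two-subiteration thinning to unit width
.thin_mask <- function(mask) {
  m <- mask
  nbrs <- function(m) {
    list(p2 = .shift_mat(m, -1, 0), p3 = .shift_mat(m, -1, 1),
         p4 = .shift_mat(m, 0, 1),  p5 = .shift_mat(m, 1, 1),
         p6 = .shift_mat(m, 1, 0),  p7 = .shift_mat(m, 1, -1),
         p8 = .shift_mat(m, 0, -1), p9 = .shift_mat(m, -1, -1))
  }
  # zero-pad borders so shifts see background outside
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  m <- pad
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- nbrs(m)
      B <- Reduce(`+`, nb)
      seq9 <- nb[c("p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9", "p2")]
      A <- 0
      for (i in 1:8) A <- A + (!seq9[[i]] & seq9[[i + 1]])
      if (pass == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(H + 1), 2:(W + 1)]
}

# longest 8-connected simple chain through a thinned curve mask,
# found by the double-BFS diameter heuristic; returns ordered (r, c)
.longest_chain <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) return(pts)
  key <- pts[, 1] + nrow(mask) * pts[, 2]
  idx <- seq_len(nrow(pts))
  lookup <- new.env(hash = TRUE)
  for (i in idx) assign(as.character(key[i]), i, envir = lookup)
  nbr_of <- function(i) {
    r <- pts[i, 1]; c <- pts[i, 2]
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask)) next
      k <- as.character(rr + nrow(mask) * cc)
      j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  bfs <- function(start) {
    prev <- rep(NA_integer_, length(idx))
    seen <- rep(FALSE, length(idx)); seen[start] <- TRUE
    q <- c(start); last <- start
    while (length(q)) {
      cur <- q[1]; q <- q[-1]; last <- cur
      for (j in nbr_of(cur)) if (!seen[j]) { seen[j] <- TRUE; prev[j] <- cur; q <- c(q, j) }
    }
    list(last = last, prev = prev)
  }
  a <- bfs(1L)
  b <- bfs(a$last)
  chain <- b$last
  while (!is.na(b$prev[chain[1]])) chain <- c(b$prev[chain[1]], chain)
  pts[chain, , drop = FALSE]
}
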