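# Final brain segmentation: hole filling, red-dominance colour transform,
# gradient external energy, closed-snake boundary refinement and per-slice
# cropping.

#' Fill interior holes of a binary mask
#'
#' A hole is a connected component of the mask complement (4-connectivity,
#' matching conditional dilation with a 3 x 3 cross) that does not touch the
#' image border. The filled mask is the union of the input mask and all
#' holes; the operation is idempotent and never removes foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix with all interior holes filled.
#' @export
#' @examples
#' m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE; m[5, 5] <- FALSE
#' sum(fill_holes(m)) - sum(m)  # the punched pixel is restored
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  lab <- .cc_label(!mask, 4L)
  if (max(lab) == 0) return(mask)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0]
  hole <- lab > 0 & !(lab %in% border_labs)
  dim(hole) <- dim(mask)
  mask | hole
}

#' Red-dominance colour transform
#'
#' Converts an RGB crop to the grayscale map used for the external energy:
#' \code{2R - G - B} where the red and blue channels are close (the blurred
#' brain boundary and neutral background), otherwise \code{2R - G + B}
#' (strongly red tissue); the result is clipped to [0, 255]. Neutral pixels
#' map to ~0 while stained tissue saturates, so specular highlights and
#' background vanish and the tissue boundary dominates the gradient.
#'
#' @param image H x W x 3 array in [0, 255].
#' @param Ts branch threshold on |R - B| (8-bit units).
#' @return H x W numeric matrix in [0, 255].
#' @export
transform_color <- function(image, Ts = 50) {
  stopifnot(length(dim(image)) == 3, Ts >= 0, Ts <= 255)
  H <- dim(image)[1]; W <- dim(image)[2]
  R <- matrix(image[, , 1], H, W); G <- matrix(image[, , 2], H, W)
  B <- matrix(image[, , 3], H, W)
  out <- ifelse(abs(R - B) <= Ts, 2 * R - G - B, 2 * R - G + B)
  .clip(out, 0, 255)
}

#' Gradient-magnitude external energy
#'
#' \code{Eext = -gamma * |grad(G_sigma * I)|^2}: the negated squared gradient
#' magnitude of the Gaussian-smoothed input, attracting a snake to strong
#' edges.
#'
#' @param gray grayscale matrix (any intensity scale).
#' @param gamma energy weight.
#' @param sigma Gaussian smoothing standard deviation (px), > 0.
#' @return object of class \code{ttc_energy}: list with \code{E} (matrix,
#'   nonpositive), \code{gamma}, \code{sigma}.
#' @export
external_energy <- function(gray, gamma = 1, sigma = 2) {
  stopifnot(is.matrix(gray), sigma > 0)
  sm <- .gauss_blur(gray, sigma)
  g <- .gradient2d(sm)
  structure(list(E = -gamma * (g$gr^2 + g$gc^2), gamma = gamma, sigma = sigma),
            class = "ttc_energy")
}

#' Contour constructor
#'
#' @param xy n x 2 matrix of (row, col) snaxel positions.
#' @param closed logical; closed contours are treated cyclically.
#' @return object of class \code{ttc_contour}.
#' @export
contour <- function(xy, closed = TRUE) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 2, all(is.finite(xy)))
  if (closed && nrow(xy) < 3) stop("closed contour needs at least 3 snaxels")
  structure(list(xy = unname(xy), closed = closed), class = "ttc_contour")
}

# ordered boundary of a mask component by Moore neighbour tracing
.trace_boundary <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  start <- idx[order(idx[, 1], idx[, 2])[1], ]
  # Moore neighbourhood in clockwise order starting from west
  moore <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  H <- nrow(mask); W <- ncol(mask)
  inside <- function(p) p[1] >= 1 && p[1] <= H && p[2] >= 1 && p[2] <= W && mask[p[1], p[2]]
  bnd <- list(start)
  cur <- start
  enter <- 1L   # index of the neighbour we came from (backtrack direction)
  repeat {
    found <- FALSE
    for (k in 0:7) {
      dir <- ((enter - 1L + k) %% 8L) + 1L
      cand <- cur + moore[dir, ]
      if (inside(cand)) {
        bnd[[length(bnd) + 1L]] <- cand
        # new backtrack: the neighbour just before cand in the scan
        prevdir <- ((dir - 2L) %% 8L) + 1L
        back <- cur + moore[prevdir, ] - cand
        enter <- which(moore[, 1] == back[1] & moore[, 2] == back[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break                      # isolated pixel
    if (all(cur == start) && length(bnd) > 2) break
  }
  do.call(rbind, bnd[-length(bnd)])
}

# resample a polyline/polygon to n points at uniform arclength
.resample_curve <- function(xy, n, closed = TRUE) {
  pts <- if (closed) rbind(xy, xy[1, ]) else xy
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= 0) stop("contour collapse: zero-length contour")
  s <- if (closed) seq(0, L, length.out = n + 1)[-(n + 1)] else seq(0, L, length.out = n)
  r <- stats::approx(cum, pts[, 1], xout = s, ties = "ordered")$y
  c_ <- stats::approx(cum, pts[, 2], xout = s, ties = "ordered")$y
  cbind(r, c_)
}

#' Initial snake from a mask boundary
#'
#' Traces the outer boundary of the largest component of \code{mask} and
#' resamples it to \code{n} snaxels at uniform arclength.
#'
#' @param mask logical matrix.
#' @param n snaxel count.
#' @return closed \code{\link{contour}}.
#' @export
contour_from_mask <- function(mask, n = 200L) {
  lab <- .cc_label(mask, 8L)
  if (max(lab) == 0) stop("empty mask")
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  bnd <- .trace_boundary(comp)
  if (nrow(bnd) < 3) stop("component too small to trace")
  contour(.resample_curve(bnd, n, closed = TRUE), closed = TRUE)
}

# discrete snake energy (tension + rigidity + external), for bookkeeping
.snake_energy <- function(xy, closed, alpha, beta, field = NULL) {
  n <- nrow(xy)
  nxt <- if (closed) c(2:n, 1) else c(2:n, n)
  prv <- if (closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  d1 <- xy[nxt, ] - xy
  d2 <- xy[nxt, ] - 2 * xy + xy[prv, ]
  if (!closed) { d1[n, ] <- 0; d2[c(1, n), ] <- 0 }
  e <- alpha * sum(d1^2) + beta * sum(d2^2)
  if (!is.null(field)) e <- e + sum(.interp_bilinear(field$E, xy[, 1], xy[, 2]))
  e
}

# (I - tau*A)^-1 for the semi-implicit snake update
.snake_matrix <- function(n, closed, alpha, beta, tau) {
  D2 <- matrix(0, n, n); D4 <- matrix(0, n, n)
  at <- function(i) if (closed) ((i - 1) %% n) + 1 else .clip(i, 1, n)
  for (i in seq_len(n)) {
    D2[i, at(i - 1)] <- D2[i, at(i - 1)] + 1
    D2[i, i] <- D2[i, i] - 2
    D2[i, at(i + 1)] <- D2[i, at(i + 1)] + 1
    D4[i, at(i - 2)] <- D4[i, at(i - 2)] + 1
    D4[i, at(i - 1)] <- D4[i, at(i - 1)] - 4
    D4[i, i] <- D4[i, i] + 6
    D4[i, at(i + 1)] <- D4[i, at(i + 1)] - 4
    D4[i, at(i + 2)] <- D4[i, at(i + 2)] + 1
  }
  A <- alpha * D2 - beta * D4
  solve(diag(n) - tau * A)
}

#' Evolve a closed parametric snake
#'
#' Minimizes the tension + rigidity + external energy with a semi-implicit
#' (banded implicit internal, explicit external) scheme. The external force
#' is the negative gradient of the energy field, bilinearly interpolated at
#' the snaxels and clamped to \code{max_step} pixels per iteration. A
#' damped step (successive halving) is used whenever a full step would
#' increase the discrete energy, which keeps the energy trace non-increasing;
#' the contour is resampled to uniform arclength periodically when doing so
#' does not increase the energy.
#'
#' @param init closed \code{\link{contour}}.
#' @param field a \code{\link{external_energy}} result (or NULL for internal
#'   energy only).
#' @param alpha,beta tension and rigidity weights (>= 0).
#' @param tau time step.
#' @param max_iters iteration cap.
#' @param tol convergence threshold on the maximum snaxel displacement (px).
#' @param resample_every uniform-arclength resampling period (iterations).
#' @param max_step external force clamp (px per iteration).
#' @return evolved \code{ttc_contour} with attributes \code{energy_trace},
#'   \code{iterations} and \code{converged}.
#' @export
evolve_snake <- function(init, field = NULL, alpha = 1.4, beta = 1.4,
                         tau = 1, max_iters = 300L, tol = 0.1,
                         resample_every = 10L, max_step = 2) {
  stopifnot(inherits(init, "ttc_contour"), init$closed, alpha >= 0, beta >= 0)
  xy <- init$xy
  n <- nrow(xy)
  if (n < 3) stop("contour collapse: fewer than 3 snaxels")
  Minv <- .snake_matrix(n, TRUE, alpha, beta, tau)
  Hf <- if (!is.null(field)) .gradient2d(field$E) else NULL
  energy <- .snake_energy(xy, TRUE, alpha, beta, field)
  trace <- energy
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iters)) {
    iters <- it
    F <- matrix(0, n, 2)
    if (!is.null(Hf)) {
      F[, 1] <- -.interp_bilinear(Hf$gr, xy[, 1], xy[, 2])
      F[, 2] <- -.interp_bilinear(Hf$gc, xy[, 1], xy[, 2])
      nrm <- sqrt(rowSums(F^2))
      sc <- ifelse(nrm > max_step, max_step / nrm, 1)
      F <- F * sc
    }
    prop <- Minv %*% (xy + tau * F)
    # damped acceptance: guarantee non-increasing discrete energy
    s <- 1
    repeat {
      cand <- xy + s * (prop - xy)
      e <- .snake_energy(cand, TRUE, alpha, beta, field)
      if (e <= energy + 1e-12 || s < 1 / 64) break
      s <- s / 2
    }
    if (e > energy + 1e-12) { converged <- TRUE; break }
    disp <- max(sqrt(rowSums((cand - xy)^2)))
    xy <- cand; energy <- e; trace <- c(trace, energy)
    if (it %% resample_every == 0L) {
      res <- .resample_curve(xy, n, closed = TRUE)
      er <- .snake_energy(res, TRUE, alpha, beta, field)
      if (er <= energy + 1e-12) { xy <- res; energy <- er }
    }
    if (disp < tol) { converged <- TRUE; break }
  }
  if (nrow(unique(round(xy, 6))) < 3) stop("contour collapse during evolution")
  out <- contour(xy, closed = TRUE)
  attr(out, "energy_trace") <- trace
  attr(out, "iterations") <- iters
  attr(out, "converged") <- converged
  out
}

#' Rasterize a closed contour to a filled mask
#'
#' @param ctr closed \code{ttc_contour}.
#' @param dim c(rows, cols) of the output mask.
#' @return logical matrix.
#' @export
contour_to_mask <- function(ctr, dim) {
  stopifnot(inherits(ctr, "ttc_contour"), ctr$closed)
  .polygon_fill(ctr$xy, dim)
}

# moment eccentricity of a pixel set: 0 round, -> 1 elongated
.mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1] - mean(idx[, 1]); c <- idx[, 2] - mean(idx[, 2])
  cv <- stats::cov(cbind(r, c))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(1 - max(ev[2], 0) / ev[1])
}

#' Extract individual brain slices from a segmented compound image
#'
#' Splits the refined binary mask into connected components, discards
#' clutter (small components, components touching the image border, and
#' highly elongated components such as a scale bar), orders the survivors
#' row-major by centroid and crops each one, centered, into a fixed-size
#' frame.
#'
#' @param image compound H x W x 3 array.
#' @param mask refined binary mask of the same size.
#' @param config a \code{\link{ttc_config}} (A_min, crop_size).
#' @param max_eccentricity clutter gate on component elongation.
#' @return list of \code{ttc_brain_slice} objects, each with \code{image}
#'   and \code{mask} crops, \code{index} and \code{offset} (crop origin,
#'   c(row, col), 1-based) in the compound frame.
#' @export
extract_slices <- function(image, mask, config = ttc_config(),
                           max_eccentricity = 0.95) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- .cc_label(mask, 8L)
  n <- max(lab)
  if (n == 0) stop("no components in mask")
  keep <- integer(0)
  cent <- NULL
  # clutter gate: a real slice occupies a few percent of the photograph,
  # while reflections and labels are far smaller
  a_min <- max(config$A_min, 0.01 * H * W)
  for (l in seq_len(n)) {
    comp <- lab == l
    area <- sum(comp)
    if (area < a_min) next
    idx <- which(comp, arr.ind = TRUE)
    if (min(idx) <= 1 || max(idx[, 1]) >= H || max(idx[, 2]) >= W) next
    if (.mask_eccentricity(comp) > max_eccentricity) next
    keep <- c(keep, l)
    cent <- rbind(cent, colMeans(idx))
  }
  if (!length(keep)) stop("no surviving components after clutter gating")
  # row-major ordering: group centroids into rows, then sort by column
  ord <- order(cent[, 1])
  heights <- vapply(keep, function(l) diff(range(which(lab == l, arr.ind = TRUE)[, 1])), 0)
  band_h <- stats::median(heights)
  band <- integer(length(keep))
  bid <- 1L; last_r <- cent[ord[1], 1]
  for (k in seq_along(ord)) {
    if (cent[ord[k], 1] - last_r > band_h) { bid <- bid + 1L; last_r <- cent[ord[k], 1] }
    band[ord[k]] <- bid
  }
  final_ord <- order(band, cent[, 2])
  ch <- config$crop_size[1]; cw <- config$crop_size[2]
  out <- vector("list", length(final_ord))
  for (j in seq_along(final_ord)) {
    l <- keep[final_ord[j]]
    ct <- cent[final_ord[j], ]
    r0 <- round(ct[1] - ch / 2); c0 <- round(ct[2] - cw / 2)
    r0 <- .clip(r0, 1, max(1, H - ch + 1)); c0 <- .clip(c0, 1, max(1, W - cw + 1))
    rr <- r0:min(H, r0 + ch - 1); cc <- c0:min(W, c0 + cw - 1)
    crop_img <- array(0, c(ch, cw, 3))
    crop_img[seq_along(rr), seq_along(cc), ] <- image[rr, cc, ]
    crop_mask <- matrix(FALSE, ch, cw)
    crop_mask[seq_along(rr), seq_along(cc)] <- (lab == l)[rr, cc]
    out[[j]] <- structure(list(image = crop_img, mask = crop_mask,
                               index = j, offset = c(r0, c0)),
                          class = "ttc_brain_slice")
  }
  out
}

#' Snake refinement of one extracted slice
#'
#' Applies the red-dominance transform and the gradient external energy to
#' the slice crop, initializes a closed snake at the boundary of the current
#' mask and evolves it; the refined mask is the filled evolved contour.
#'
#' @param slice a \code{ttc_brain_slice}.
#' @param config a \code{\link{ttc_config}}.
#' @param n_snaxels snaxel count.
#' @return the slice with its \code{mask} replaced by the refined mask.
#' @export
refine_slice <- function(slice, config = ttc_config(), n_snaxels = 200L,
                         corridor = 2, corridor_weight = 2) {
  stopifnot(inherits(slice, "ttc_brain_slice"))
  ihat <- transform_color(slice$image, Ts = config$Ts)
  field <- external_energy(ihat, gamma = config$gamma, sigma = config$sigma_ext)
  init <- contour_from_mask(slice$mask, n = n_snaxels)
  if (corridor_weight > 0) {
    # local-refinement corridor: quadratic penalty on straying far from the
    # initial boundary, so the snake smooths the border instead of sliding
    # to stronger interior edges (e.g. the tissue/infarct transition)
    bnd <- slice$mask & !.erode_disk(slice$mask, 1)
    D <- .from_ebi(EBImage::distmap(.as_ebi(!bnd)))
    field$E <- field$E + corridor_weight * pmax(D - corridor, 0)^2
  }
  ev <- evolve_snake(init, field, alpha = config$alpha, beta = config$beta)
  refined <- contour_to_mask(ev, dim(slice$mask))
  refined <- fill_holes(refined)
  lab <- .cc_label(refined, 8L)
  if (max(lab) >= 1) {
    sizes <- tabulate(lab[lab > 0])
    refined <- lab == which.max(sizes)
  }
  slice$mask <- refined
  slice$contour <- ev
  slice
}
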