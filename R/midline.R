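# Hemisphere segmentation: medial subimage, groove/concave endpoint
# detection, GVF open-curve midline evolution and mask splitting.

#' Extract the medial subimage of a brain slice
#'
#' Deskews the slice by its mask principal axis (so the interhemispheric
#' midline is near vertical), then cuts a vertical strip of width \code{w}
#' centered on the mass-centre column and spanning the mask's row extent.
#' The strip's red channel, its contrast-limited adaptive histogram
#' equalization and its Sobel edge map are returned together with the exact
#' (invertible) deskew transform.
#'
#' @param slice a \code{ttc_brain_slice}.
#' @param w strip width in pixels (default 36). If the deskewed mask is
#'   narrower than \code{w} the strip is clamped to the mask width with a
#'   warning.
#' @return object of class \code{ttc_medial_subimage}: \code{Sr} (red
#'   channel), \code{Sc} (enhanced), \code{Se} (Sobel edge map, [0,1]),
#'   \code{mask} (strip mask), \code{w}, \code{offset} (strip origin in the
#'   deskewed frame), \code{angle} (deskew rotation, radians), \code{pivot},
#'   \code{dim} (slice dimensions).
#' @export
medial_subimage <- function(slice, w = 36L) {
  stopifnot(inherits(slice, "ttc_brain_slice"))
  mask <- slice$mask
  if (!any(mask)) stop("empty slice mask")
  idx <- which(mask, arr.ind = TRUE)
  pivot <- colMeans(idx)
  ang <- .mask_orientation(mask)        # major-axis angle from column axis
  # rotating the content by ang brings the major axis horizontal, hence the
  # midline near vertical
  dmask <- .rotate_mask(mask, ang, pivot)
  red <- .rotate_gray(slice$image[, , 1], ang, pivot)
  didx <- which(dmask, arr.ind = TRUE)
  c_center <- round(mean(didx[, 2]))
  rr <- range(didx[, 1])
  half <- floor(w / 2)
  c0 <- c_center - half; c1 <- c0 + w - 1L
  mask_cols <- range(didx[, 2])
  if (c0 < mask_cols[1] || c1 > mask_cols[2]) {
    if (diff(mask_cols) + 1 < w) {
      warning("mask narrower than requested strip width; clamping")
      c0 <- mask_cols[1]; c1 <- mask_cols[2]
    }
  }
  c0 <- max(1L, c0); c1 <- min(ncol(mask), c1)
  rows <- rr[1]:rr[2]; cols <- c0:c1
  Sr <- red[rows, cols, drop = FALSE]
  Sc <- .clip(.clahe(.clip(Sr, 0, 255) / 255, nx = 4, ny = 4), 0, 1)
  Se <- .sobel_mag(Sc, normalize = TRUE)
  structure(list(Sr = Sr, Sc = Sc, Se = Se,
                 mask = dmask[rows, cols, drop = FALSE],
                 w = length(cols), offset = c(rows[1], cols[1]),
                 angle = ang, pivot = pivot, dim = dim(mask)),
            class = "ttc_medial_subimage")
}

#' Map strip coordinates back to slice coordinates
#'
#' Applies the strip offset and the inverse deskew rotation; the mapping is
#' the exact analytic inverse of the transform used by
#' \code{\link{medial_subimage}}.
#'
#' @param sub a \code{ttc_medial_subimage}.
#' @param pts n x 2 matrix of (row, col) strip coordinates (fractional
#'   allowed).
#' @return n x 2 matrix of slice coordinates.
#' @export
strip_to_slice <- function(sub, pts) {
  pts <- as.matrix(pts)
  full <- cbind(pts[, 1] + sub$offset[1] - 1, pts[, 2] + sub$offset[2] - 1)
  .rotate_points(full, -sub$angle, sub$pivot)
}

#' Detect the superior groove and inferior concave points
#'
#' On the deskewed medial strip, the groove is the deepest point of the
#' superior boundary between the two lobe peaks (largest top-boundary row
#' flanked on both sides by higher lobes) and the concave point is the
#' deepest upward indentation of the inferior boundary near the groove's
#' vertical. For single-lobe masks without a detectable notch both points
#' fall back to the mass-centre column extremes and are flagged.
#'
#' @param sub a \code{ttc_medial_subimage}.
#' @param min_depth minimum notch depth (px) to accept a groove.
#' @return list with \code{groove} and \code{concave} (strip (row, col)),
#'   and \code{fallback} (logical).
#' @export
detect_endpoints <- function(sub, min_depth = 3) {
  m <- sub$mask
  W <- ncol(m)
  top <- apply(m, 2, function(col) if (any(col)) which(col)[1] else NA_integer_)
  bot <- apply(m, 2, function(col) if (any(col)) max(which(col)) else NA_integer_)
  ok <- which(!is.na(top))
  fallback <- TRUE
  gc_ <- NA_integer_
  if (length(ok) >= 3) {
    inner <- ok[ok > min(ok) & ok < max(ok)]
    if (length(inner)) {
      cand <- inner[which.max(top[inner])]
      left_min <- min(top[ok[ok < cand]])
      right_min <- min(top[ok[ok > cand]])
      depth <- top[cand] - max(left_min, right_min)
      if (is.finite(depth) && depth >= min_depth) { gc_ <- cand; fallback <- FALSE }
    }
  }
  if (fallback) {
    idx <- which(m, arr.ind = TRUE)
    gc_ <- round(mean(idx[, 2]))
    if (is.na(top[gc_])) gc_ <- ok[which.min(abs(ok - gc_))]
    groove <- c(top[gc_], gc_)
    concave <- c(bot[gc_], gc_)
    return(list(groove = groove, concave = concave, fallback = TRUE))
  }
  groove <- c(top[gc_], gc_)
  # concave: deepest upward indentation of the inferior boundary within
  # the strip, i.e. the smallest bottom-boundary row near the groove column
  cc_ <- ok[which.min(bot[ok])]
  concave <- c(bot[cc_], cc_)
  list(groove = groove, concave = concave, fallback = FALSE)
}

#' Straight initial midline
#'
#' @param groove,concave distinct (row, col) endpoints.
#' @param n_points snaxel count (>= 2).
#' @return open \code{\link{contour}} with \code{n_points} equally spaced
#'   snaxels whose first and last points equal the inputs exactly.
#' @export
initial_midline <- function(groove, concave, n_points = 60L) {
  if (all(groove == concave)) stop("groove and concave points coincide")
  if (n_points < 2) stop("need at least 2 points")
  t <- seq(0, 1, length.out = n_points)
  contour(cbind(groove[1] + t * (concave[1] - groove[1]),
                groove[2] + t * (concave[2] - groove[2])), closed = FALSE)
}

#' Gradient vector flow field
#'
#' Solves the GVF Euler equations by explicit gradient-descent iteration:
#' the field is initialized at the edge-map gradient and diffused under the
#' Laplacian regularizer weighted by \code{mu}, while the data term anchors
#' it to the gradient where the edge response is strong.
#'
#' @param Sg edge map (matrix, typically normalized to [0, 1]).
#' @param mu regularization weight (> 0), default 0.2.
#' @param n_iters fixed iteration count (used when \code{tol} is NULL).
#' @param dt time step; defaults to the stability limit
#'   \code{spacing^2 / (4 mu)}. Requesting a larger step is an error.
#' @param tol if non-NULL, iterate until the discrete Euler-equation
#'   residual sup-norm falls below \code{tol} (up to \code{max_iters}).
#' @param max_iters iteration cap in tolerance mode.
#' @return object of class \code{ttc_gvf}: \code{u}, \code{v} (column/row
#'   displacement components... u is the column component, v the row
#'   component), \code{mu}, \code{Sg}, \code{residual} (final sup-norm of
#'   the discrete Euler residual), \code{iters}.
#' @export
gvf_field <- function(Sg, mu = 0.2, n_iters = 80L, dt = NULL, tol = NULL,
                      max_iters = 20000L) {
  stopifnot(is.matrix(Sg), mu > 0)
  g <- .gradient2d(Sg)
  fx <- g$gc; fy <- g$gr
  b <- fx^2 + fy^2
  # explicit scheme stability: the diffusion limit spacing^2/(4 mu) and the
  # data-term decay limit 1/max|grad Sg|^2
  dt_max <- min(1 / (4 * mu), 1 / max(max(b), 1e-12))
  if (is.null(dt)) dt <- dt_max
  if (dt > dt_max + 1e-12)
    stop("unstable time step: dt must be <= min(1/(4*mu), 1/max|grad Sg|^2)")
  u <- fx; v <- fy
  resid <- function(u, v) {
    ru <- mu * .laplacian(u) - (u - fx) * b
    rv <- mu * .laplacian(v) - (v - fy) * b
    max(abs(ru), abs(rv))
  }
  iters <- 0L
  if (is.null(tol)) {
    for (i in seq_len(n_iters)) {
      u <- u + dt * (mu * .laplacian(u) - (u - fx) * b)
      v <- v + dt * (mu * .laplacian(v) - (v - fy) * b)
    }
    iters <- n_iters
  } else {
    repeat {
      u <- u + dt * (mu * .laplacian(u) - (u - fx) * b)
      v <- v + dt * (mu * .laplacian(v) - (v - fy) * b)
      iters <- iters + 1L
      if (iters %% 25L == 0L && resid(u, v) < tol) break
      if (iters >= max_iters) break
    }
  }
  structure(list(u = u, v = v, mu = mu, Sg = Sg,
                 residual = resid(u, v), iters = iters),
            class = "ttc_gvf")
}

#' Evolve the open midline snake in a GVF field
#'
#' Advects the interior snaxels by the GVF force with tension/rigidity
#' regularization (semi-implicit update). The endpoints keep their rows
#' (the superior/inferior boundary rows) and slide laterally only under the
#' external field, so with a zero field the curve straightens between its
#' endpoints. All snaxels are clamped to the subimage domain.
#'
#' @param init open \code{\link{contour}} inside the field domain.
#' @param field a \code{\link{gvf_field}} result.
#' @param alpha,beta tension and rigidity weights.
#' @param tau time step.
#' @param max_iters iteration cap.
#' @param tol convergence threshold on maximum displacement (px).
#' @param force_floor regularizer of the force normalization: the advection
#'   force is the GVF vector scaled to \code{|v| / (|v| + force_floor)}
#'   pixels, so displacements approach one pixel per step wherever the field
#'   is appreciable while decaying linearly (and stably) near field zeros.
#'   Set to NULL to use the raw field.
#' @return evolved open \code{ttc_contour} with attributes
#'   \code{iterations}, \code{converged}.
#' @export
evolve_midline <- function(init, field, alpha = 1.4, beta = 1.4, tau = 1,
                           max_iters = 400L, tol = 0.05, force_floor = 0.02) {
  stopifnot(inherits(init, "ttc_contour"), !init$closed,
            inherits(field, "ttc_gvf"))
  xy <- init$xy
  n <- nrow(xy)
  H <- nrow(field$u); W <- ncol(field$u)
  if (any(xy[, 1] < 1 | xy[, 1] > H | xy[, 2] < 1 | xy[, 2] > W)) {
    warning("initial contour partially outside the subimage; clamping")
    xy[, 1] <- .clip(xy[, 1], 1, H); xy[, 2] <- .clip(xy[, 2], 1, W)
  }
  Minv <- .snake_matrix(n, FALSE, alpha, beta, tau)
  end_rows <- xy[c(1, n), 1]
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iters)) {
    iters <- it
    Fr <- .interp_bilinear(field$v, xy[, 1], xy[, 2])
    Fc <- .interp_bilinear(field$u, xy[, 1], xy[, 2])
    F <- cbind(Fr, Fc)
    if (!is.null(force_floor)) {
      nrm <- sqrt(rowSums(F^2))
      F <- F / (nrm + force_floor)
    }
    new_xy <- Minv %*% (xy + tau * F)
    # endpoints: lateral slide under the external field only, rows pinned
    for (e in c(1L, n)) {
      new_xy[e, 1] <- end_rows[if (e == 1L) 1L else 2L]
      new_xy[e, 2] <- xy[e, 2] + tau * F[e, 2]
    }
    new_xy[, 1] <- .clip(new_xy[, 1], 1, H)
    new_xy[, 2] <- .clip(new_xy[, 2], 1, W)
    disp <- max(sqrt(rowSums((new_xy - xy)^2)))
    xy <- new_xy
    if (disp < tol) { converged <- TRUE; break }
  }
  out <- contour(xy, closed = FALSE)
  attr(out, "iterations") <- iters
  attr(out, "converged") <- converged
  out
}

#' Split a brain slice into hemispheres along a midline curve
#'
#' Maps the evolved strip-frame curve back to slice coordinates, rasterizes
#' and thins it to a one-pixel 8-connected chain, extends it along its end
#' tangents so it fully transects the mask, and splits the mask into left
#' and right hemispheres.
#'
#' @param slice a \code{ttc_brain_slice}.
#' @param curve open \code{ttc_contour}; coordinates are interpreted in the
#'   strip frame when \code{sub} is given, otherwise in slice coordinates.
#' @param sub optional \code{ttc_medial_subimage} providing the deskew
#'   transform.
#' @return object of class \code{ttc_midline_result}: \code{path} (ordered
#'   (row, col) chain), \code{left_mask}, \code{right_mask},
#'   \code{path_mask}; left/right/path partition the slice mask exactly.
#' @export
split_hemispheres <- function(slice, curve, sub = NULL) {
  stopifnot(inherits(slice, "ttc_brain_slice"), inherits(curve, "ttc_contour"))
  mask <- slice$mask
  H <- nrow(mask); W <- ncol(mask)
  pts <- curve$xy
  if (!is.null(sub)) pts <- strip_to_slice(sub, pts)
  # extend along end tangents until clear of the mask bounding box
  ext_len <- max(H, W)
  t1 <- pts[1, ] - pts[2, ]; t1 <- t1 / max(sqrt(sum(t1^2)), 1e-9)
  t2 <- pts[nrow(pts), ] - pts[nrow(pts) - 1, ]
  t2 <- t2 / max(sqrt(sum(t2^2)), 1e-9)
  pts_ext <- rbind(pts[1, ] + t1 * ext_len, pts, pts[nrow(pts), ] + t2 * ext_len)
  px <- .rasterize_polyline(pts_ext)
  px <- px[px[, 1] >= 1 & px[, 1] <= H & px[, 2] >= 1 & px[, 2] <= W, , drop = FALSE]
  raster <- matrix(FALSE, H, W)
  raster[px] <- TRUE
  thin <- .thin_mask(raster)
  if (!any(thin)) thin <- raster
  chain <- .longest_chain(thin)
  path_mask <- matrix(FALSE, H, W)
  path_mask[chain] <- TRUE
  rest <- mask & !path_mask
  lab <- .cc_label(rest, 4L)
  ncomp <- max(lab)
  if (ncomp < 2)
    stop("midline path fails to transect the mask (components: ", ncomp,
         "; path pixels in mask: ", sum(path_mask & mask), ")")
  sizes <- tabulate(lab[lab > 0], ncomp)
  main2 <- order(sizes, decreasing = TRUE)[1:2]
  ccol <- vapply(main2, function(l) mean(which(lab == l, arr.ind = TRUE)[, 2]), 0)
  left <- lab == main2[which.min(ccol)]
  right <- lab == main2[which.max(ccol)]
  if (ncomp > 2) {
    for (l in setdiff(seq_len(ncomp), main2)) {
      cl <- mean(which(lab == l, arr.ind = TRUE)[, 2])
      if (abs(cl - min(ccol)) < abs(cl - max(ccol))) left <- left | lab == l
      else right <- right | lab == l
    }
  }
  inmask <- chain[mask[chain], , drop = FALSE]
  structure(list(path = inmask, left_mask = left, right_mask = right,
                 path_mask = path_mask & mask),
            class = "ttc_midline_result")
}

#' Full hemisphere segmentation of one slice
#'
#' Runs the three hemisphere-segmentation phases: medial subimage
#' extraction, groove/concave endpoint detection with straight-midline
#' initialization, and GVF open-curve evolution; finally splits the mask.
#'
#' @param slice a \code{ttc_brain_slice}.
#' @param config a \code{\link{ttc_config}}.
#' @return a \code{ttc_midline_result} with additional fields \code{sub},
#'   \code{curve}, \code{endpoints}.
#' @export
segment_hemispheres <- function(slice, config = ttc_config()) {
  sub <- medial_subimage(slice, w = config$w)
  ep <- detect_endpoints(sub)
  init <- initial_midline(ep$groove, ep$concave, n_points = 60L)
  sg <- .gauss_blur(.sobel_mag(sub$Sc, normalize = TRUE), 1)
  field <- gvf_field(sg, mu = config$mu_g, n_iters = 80L)
  curve <- evolve_midline(init, field, alpha = config$alpha, beta = config$beta)
  res <- split_hemispheres(slice, curve, sub = sub)
  res$sub <- sub
  res$curve <- curve
  res$endpoints <- ep
  res
}
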