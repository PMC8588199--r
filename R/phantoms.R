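# Synthetic TTC phantom generator.
#
# Produces camera-like compound photographs (several stained slices plus a
# scale bar, a label and specular reflections on a slowly varying background)
# and single two-lobed slice images with a dark midline band, together with
# exact ground-truth masks and midline paths. All geometry is evaluated
# analytically per pixel so that truth masks are registered to the image by
# construction and output is byte-identical for a fixed (spec, seed).

.COL_HEALTHY <- c(200, 60, 70)
.COL_INFARCT <- c(235, 225, 215)
.COL_BACKGROUND <- c(90, 95, 105)
.COL_REFLECTION <- c(250, 250, 250)
.COL_CLUTTER <- c(235, 235, 230)
.MIDLINE_DARKEN <- 0.6

#' Phantom specification
#'
#' Parameter set describing one synthetic TTC phantom. Defaults emulate the
#' acquisition conditions of camera-based TTC imaging: a 900 x 1600 photograph
#' holding eight coronal slices, moderate sensor noise, specular reflections
#' and an uneven background.
#'
#' @param image_size c(rows, cols) of the generated image.
#' @param n_slices number of brain slices.
#' @param slice_axes optional n_slices x 2 matrix of per-slice ellipse
#'   semi-axes (rows, cols); autoderived from the layout when NULL.
#' @param infarct_fraction fraction of each slice area covered by a pale
#'   infarct patch, in [0, 1].
#' @param reflection_count number of specular highlight disks (half placed
#'   on slices, half on the background).
#' @param reflection_radius_px radius of each highlight disk.
#' @param boundary_blur_sigma Gaussian sigma (px) of the boundary softening
#'   applied around every drawn object.
#' @param background_gradient_amp amplitude (8-bit units) of the linear
#'   background intensity ramp.
#' @param midline_curvature_amp lateral bow of the midline (px), zero at
#'   both endpoints and maximal mid-course.
#' @param midline_tilt_deg in-plane rotation of the slice geometry (degrees).
#' @param noise_sigma Gaussian pixel noise sigma (8-bit units).
#' @param seed integer seed; identical (spec, seed) gives identical output.
#' @return object of class \code{ttc_phantom_spec}.
#' @export
phantom_spec <- function(image_size = c(900L, 1600L), n_slices = 8L,
                         slice_axes = NULL, infarct_fraction = 0.15,
                         reflection_count = 6L, reflection_radius_px = 10L,
                         boundary_blur_sigma = 1.0,
                         background_gradient_amp = 25,
                         midline_curvature_amp = 2,
                         midline_tilt_deg = 5,
                         noise_sigma = 3, seed = 1L) {
  spec <- list(image_size = as.integer(image_size), n_slices = as.integer(n_slices),
               slice_axes = slice_axes, infarct_fraction = infarct_fraction,
               reflection_count = as.integer(reflection_count),
               reflection_radius_px = as.integer(reflection_radius_px),
               boundary_blur_sigma = boundary_blur_sigma,
               background_gradient_amp = background_gradient_amp,
               midline_curvature_amp = midline_curvature_amp,
               midline_tilt_deg = midline_tilt_deg,
               noise_sigma = noise_sigma, seed = as.integer(seed))
  class(spec) <- "ttc_phantom_spec"
  .validate_phantom_spec(spec)
  spec
}

.validate_phantom_spec <- function(spec) {
  chk <- function(ok, msg) if (!ok) stop("invalid phantom spec: ", msg)
  chk(length(spec$image_size) == 2 && all(spec$image_size >= 64),
      "image_size must be two values >= 64")
  chk(spec$n_slices >= 1, "n_slices must be >= 1")
  chk(spec$infarct_fraction >= 0 && spec$infarct_fraction <= 1,
      "infarct_fraction must be in [0, 1]")
  chk(spec$reflection_count >= 0, "reflection_count must be >= 0")
  chk(spec$reflection_radius_px >= 1, "reflection_radius_px must be >= 1")
  chk(spec$boundary_blur_sigma >= 0, "boundary_blur_sigma must be >= 0")
  chk(spec$background_gradient_amp >= 0, "background_gradient_amp must be >= 0")
  chk(spec$noise_sigma >= 0, "noise_sigma must be >= 0")
  invisible(spec)
}

# analytic ellipse membership on the pixel grid, optional rotation theta
.ellipse_mask <- function(dim, center, semi_r, semi_c, theta = 0) {
  H <- dim[1]; W <- dim[2]
  dr <- matrix(seq_len(H) - center[1], H, W)
  dc <- matrix(seq_len(W) - center[2], H, W, byrow = TRUE)
  if (theta != 0) {
    u <- cos(theta) * dr + sin(theta) * dc
    v <- -sin(theta) * dr + cos(theta) * dc
  } else { u <- dr; v <- dc }
  (u / semi_r)^2 + (v / semi_c)^2 <= 1
}

.disk_mask <- function(dim, center, radius) {
  .ellipse_mask(dim, center, radius, radius)
}

.paint <- function(img, mask, col) {
  for (ch in 1:3) {
    m <- img[, , ch]; m[mask] <- col[ch]; img[, , ch] <- m
  }
  img
}

# background plane: base colour plus linear ramp
.background_image <- function(dim, amp) {
  H <- dim[1]; W <- dim[2]
  ramp <- matrix(seq_len(H) - 1, H, W) / max(1, H - 1) +
    matrix(seq_len(W) - 1, H, W, byrow = TRUE) / max(1, W - 1) - 1
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- .COL_BACKGROUND[ch] + amp * ramp
  img
}

# soften object boundaries: blend the blurred rendering back in only
# within a band around drawn objects, so far-field background is untouched
.soften <- function(img, object_mask, sigma) {
  if (sigma <= 0) return(img)
  band <- .dilate_disk(object_mask, ceiling(3 * sigma))
  blurred <- .blur_rgb(img, sigma)
  for (ch in 1:3) {
    m <- img[, , ch]; b <- blurred[, , ch]
    m[band] <- b[band]; img[, , ch] <- m
  }
  img
}

.finalize_image <- function(img, spec) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (spec$noise_sigma > 0)
    img <- img + array(stats::rnorm(H * W * 3, 0, spec$noise_sigma), c(H, W, 3))
  img <- round(.clip(img, 0, 255))
  storage.mode(img) <- "double"
  img
}

# vertical straight midline chain of a single-ellipse slice
.vertical_midline <- function(mask, col) {
  rows <- which(mask[, col])
  cbind(row = rows, col = rep(col, length(rows)))
}

#' Generate a compound TTC phantom photograph
#'
#' Renders \code{n_slices} reddish elliptical slices on a grid together with
#' a scale bar, a label patch, specular reflection disks, a background ramp
#' and Gaussian noise, and returns exact ground truth for every object.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return a list of class \code{ttc_phantom} with elements \code{image}
#'   (H x W x 3, 8-bit values) and \code{truth} (class
#'   \code{ttc_phantom_truth}: \code{slice_masks}, \code{midline_paths},
#'   \code{left_masks}, \code{right_masks}, \code{clutter_mask}).
#' @export
#' @examples
#' ph <- make_compound_phantom(phantom_spec(image_size = c(240, 400),
#'                                          n_slices = 4, seed = 2))
#' length(ph$truth$slice_masks)
make_compound_phantom <- function(spec) {
  stopifnot(inherits(spec, "ttc_phantom_spec"))
  .local_seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  n <- spec$n_slices

  grid_rows <- if (n > 4) 2L else 1L
  grid_cols <- as.integer(ceiling(n / grid_rows))
  usable_h <- floor(0.88 * H)
  cell_h <- floor(usable_h / grid_rows)
  cell_w <- floor(W / grid_cols)

  if (is.null(spec$slice_axes)) {
    ax <- cbind(rep(0.33 * cell_h, n), rep(0.36 * cell_w, n)) *
      matrix(stats::runif(2 * n, 0.95, 1.05), n, 2)
  } else {
    ax <- matrix(spec$slice_axes, n, 2)
  }
  if (any(2 * ax[, 1] + 8 > cell_h) || any(2 * ax[, 2] + 8 > cell_w))
    stop("slice layout overflow: slices would overlap or leave the frame")

  img <- .background_image(c(H, W), spec$background_gradient_amp)
  slice_masks <- vector("list", n)
  midline_paths <- vector("list", n)
  left_masks <- vector("list", n)
  right_masks <- vector("list", n)

  centers <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    gr <- (i - 1) %/% grid_cols; gc <- (i - 1) %% grid_cols
    centers[i, ] <- c(gr * cell_h + cell_h / 2 + stats::runif(1, -3, 3),
                      gc * cell_w + cell_w / 2 + stats::runif(1, -3, 3))
  }

  object_mask <- matrix(FALSE, H, W)
  for (i in seq_len(n)) {
    m <- .ellipse_mask(c(H, W), centers[i, ], ax[i, 1], ax[i, 2])
    slice_masks[[i]] <- m
    object_mask <- object_mask | m
    base <- .COL_HEALTHY + stats::runif(3, -8, 8)
    # slight radial darkening towards the boundary
    dr <- matrix(seq_len(H) - centers[i, 1], H, W)
    dc <- matrix(seq_len(W) - centers[i, 2], H, W, byrow = TRUE)
    rho2 <- (dr / ax[i, 1])^2 + (dc / ax[i, 2])^2
    shade <- 1 - 0.12 * .clip(rho2, 0, 1)
    for (ch in 1:3) {
      mm <- img[, , ch]
      mm[m] <- (base[ch] * shade)[m]
      img[, , ch] <- mm
    }
    # infarct patch inside one hemisphere
    if (spec$infarct_fraction > 0) {
      s <- sqrt(spec$infarct_fraction)
      side <- sample(c(-1, 1), 1)
      ic <- centers[i, ] + c(stats::runif(1, -0.2, 0.2) * ax[i, 1],
                             side * 0.45 * ax[i, 2])
      inf <- .ellipse_mask(c(H, W), ic, 0.85 * s * ax[i, 1], 0.85 * s * ax[i, 2]) & m
      img <- .paint(img, inf, .COL_INFARCT + stats::runif(3, -5, 5))
    }
    # straight vertical midline band and truth path
    c0 <- round(centers[i, 2])
    band <- m & abs(matrix(seq_len(W), H, W, byrow = TRUE) - c0) <= 1
    for (ch in 1:3) {
      mm <- img[, , ch]
      mm[band] <- mm[band] * .MIDLINE_DARKEN
      img[, , ch] <- mm
    }
    midline_paths[[i]] <- .vertical_midline(m, c0)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    left_masks[[i]] <- m & cols < c0
    right_masks[[i]] <- m & cols > c0
  }

  # clutter: scale bar and label in the bottom band, clear of the slices
  bar <- matrix(FALSE, H, W)
  bar_rows <- max(1, round(0.945 * H)):min(H, round(0.97 * H))
  bar[bar_rows, round(0.08 * W):round(0.45 * W)] <- TRUE
  lab <- matrix(FALSE, H, W)
  side <- max(8L, round(0.06 * H))
  lab[(H - round(0.03 * H) - side):(H - round(0.03 * H)),
      (W - round(0.05 * W) - side):(W - round(0.05 * W))] <- TRUE
  clutter <- (bar | lab) & !object_mask
  img <- .paint(img, clutter, .COL_CLUTTER)
  object_mask <- object_mask | clutter

  # specular reflections: half inside random slices, half on background
  n_ref <- spec$reflection_count
  if (n_ref > 0) {
    for (k in seq_len(n_ref)) {
      if (k <= ceiling(n_ref / 2)) {
        i <- sample(n, 1)
        ctr <- centers[i, ] + stats::runif(2, -0.4, 0.4) * ax[i, ]
      } else {
        ctr <- c(stats::runif(1, 0.05 * H, 0.85 * H), stats::runif(1, 0.05 * W, 0.95 * W))
      }
      d <- .disk_mask(c(H, W), ctr, spec$reflection_radius_px)
      img <- .paint(img, d, .COL_REFLECTION)
      object_mask <- object_mask | d
    }
  }

  img <- .soften(img, object_mask, spec$boundary_blur_sigma)
  img <- .finalize_image(img, spec)

  truth <- structure(list(slice_masks = slice_masks,
                          midline_paths = midline_paths,
                          left_masks = left_masks, right_masks = right_masks,
                          clutter_mask = clutter),
                     class = "ttc_phantom_truth")
  structure(list(image = img, truth = truth, spec = spec), class = "ttc_phantom")
}

#' Generate a single two-lobed slice phantom
#'
#' Renders one brain slice as the union of two ellipses (leaving a superior
#' groove notch and an inferior concavity) with a dark midline band of given
#' curvature and tilt inside a 320 x 480 frame, plus exact midline and
#' hemisphere ground truth.
#'
#' @param spec a \code{\link{phantom_spec}} with \code{n_slices = 1}. The
#'   \code{image_size} is fixed at c(320, 480); \code{slice_axes} defaults to
#'   lobe semi-axes c(130, 110).
#' @return a \code{ttc_phantom} list as in \code{\link{make_compound_phantom}};
#'   \code{truth$slice_masks[[1]]} is the slice, \code{truth$midline_paths[[1]]}
#'   the ordered superior-to-inferior one-pixel chain.
#' @export
make_slice_phantom <- function(spec) {
  stopifnot(inherits(spec, "ttc_phantom_spec"))
  if (spec$n_slices != 1) stop("make_slice_phantom requires n_slices = 1")
  .local_seed(spec$seed)
  H <- 320L; W <- 480L
  ax <- if (is.null(spec$slice_axes)) c(130, 110) else as.numeric(spec$slice_axes)
  b <- ax[1]; a <- ax[2]
  d <- 0.45 * a                       # half lobe-centre offset
  theta <- spec$midline_tilt_deg * pi / 180
  A <- spec$midline_curvature_amp
  ctr <- c(H / 2 + 0.5, W / 2 + 0.5)

  dr <- matrix(seq_len(H) - ctr[1], H, W)
  dc <- matrix(seq_len(W) - ctr[2], H, W, byrow = TRUE)
  u <- cos(theta) * dr + sin(theta) * dc     # along-midline coordinate
  v <- -sin(theta) * dr + cos(theta) * dc    # across-midline coordinate
  lobeL <- (u / b)^2 + ((v + d) / a)^2 <= 1
  lobeR <- (u / b)^2 + ((v - d) / a)^2 <= 1
  mask <- lobeL | lobeR

  img <- .background_image(c(H, W), spec$background_gradient_amp)
  base <- .COL_HEALTHY + stats::runif(3, -8, 8)
  rho2 <- pmin((u / b)^2 + ((abs(v) - d) / a)^2, 1)
  shade <- 1 - 0.12 * rho2
  for (ch in 1:3) {
    mm <- img[, , ch]; mm[mask] <- (base[ch] * shade)[mask]; img[, , ch] <- mm
  }

  if (spec$infarct_fraction > 0) {
    s <- sqrt(spec$infarct_fraction)
    side <- sample(c(-1, 1), 1)
    icu <- stats::runif(1, -0.25, 0.25) * b
    icv <- side * d
    inf <- ((u - icu) / (1.1 * s * b))^2 + ((v - icv) / (1.1 * s * a))^2 <= 1
    inf <- inf & mask
    img <- .paint(img, inf, .COL_INFARCT + stats::runif(3, -5, 5))
  }

  # midline band: lateral bow A*sin(.) vanishing at both extremities
  vm <- A * sin(pi * (u + b) / (2 * b))
  band <- mask & abs(v - vm) <= 1.2
  for (ch in 1:3) {
    mm <- img[, , ch]; mm[band] <- mm[band] * .MIDLINE_DARKEN; img[, , ch] <- mm
  }

  object_mask <- mask
  if (spec$reflection_count > 0) {
    for (k in seq_len(spec$reflection_count)) {
      if (k <= ceiling(spec$reflection_count / 2)) {
        ctr_k <- ctr + c(stats::runif(1, -0.5, 0.5) * b, stats::runif(1, -1.2, 1.2) * d)
      } else {
        ctr_k <- c(stats::runif(1, 10, H - 10), stats::runif(1, 10, W - 10))
      }
      dmask <- .disk_mask(c(H, W), ctr_k, spec$reflection_radius_px)
      img <- .paint(img, dmask, .COL_REFLECTION)
      object_mask <- object_mask | dmask
    }
  }

  img <- .soften(img, object_mask, spec$boundary_blur_sigma)
  img <- .finalize_image(img, spec)

  # truth midline: dense samples of the analytic curve, rasterized to an
  # 8-connected chain and clipped to the mask
  us <- seq(-b, b, by = 0.25)
  vs <- A * sin(pi * (us + b) / (2 * b))
  pr <- ctr[1] + cos(theta) * us - sin(theta) * vs
  pc <- ctr[2] + sin(theta) * us + cos(theta) * vs
  chain <- .rasterize_polyline(cbind(pr, pc))
  inside <- mask[chain]
  chain <- chain[inside, , drop = FALSE]
  colnames(chain) <- c("row", "col")

  path_mask <- matrix(FALSE, H, W)
  path_mask[chain] <- TRUE
  rest <- mask & !path_mask
  lab <- .cc_label(rest, 4L)
  ncomp <- max(lab)
  if (ncomp < 2) stop("phantom midline failed to split the slice")
  sizes <- tabulate(lab[lab > 0], ncomp)
  main2 <- order(sizes, decreasing = TRUE)[1:2]
  ccol <- vapply(main2, function(l) mean(which(lab == l, arr.ind = TRUE)[, 2]), 0)
  left_l <- main2[which.min(ccol)]; right_l <- main2[which.max(ccol)]
  left <- lab == left_l; right <- lab == right_l
  if (ncomp > 2) {
    for (l in setdiff(seq_len(ncomp), main2)) {
      cl <- mean(which(lab == l, arr.ind = TRUE)[, 2])
      if (abs(cl - ccol[which.min(ccol)]) < abs(cl - ccol[which.max(ccol)]))
        left <- left | (lab == l) else right <- right | (lab == l)
    }
  }

  truth <- structure(list(slice_masks = list(mask),
                          midline_paths = list(chain),
                          left_masks = list(left), right_masks = list(right),
                          clutter_mask = matrix(FALSE, H, W)),
                     class = "ttc_phantom_truth")
  structure(list(image = img, truth = truth, spec = spec), class = "ttc_phantom")
}

#' Build a superpixel training set from synthetic phantoms
#'
#' Generates \code{n_images} compound phantoms, oversegments each one,
#' computes the four saliency features per superpixel and labels superpixels
#' by ground-truth purity: foreground when at least 80\% of their pixels lie
#' inside a slice mask, background when at most 20\% do; impure superpixels
#' are dropped.
#'
#' @param n_images number of phantoms to generate.
#' @param seed integer seed; per-image seeds are derived from it.
#' @param spec_template optional \code{\link{phantom_spec}} whose fields
#'   (except the seed) are reused for every image.
#' @param config a \code{\link{ttc_config}}.
#' @param purity c(fg, bg) purity thresholds, defaults c(0.8, 0.2).
#' @return list with \code{features} (data frame of gcs, lcs, chc, scd),
#'   \code{labels} (factor fg/bg), \code{fg_fraction} (truth overlap of each
#'   kept superpixel) and \code{image} (index of origin).
#' @export
make_training_set <- function(n_images, seed, spec_template = NULL,
                              config = ttc_config(), purity = c(0.8, 0.2)) {
  stopifnot(n_images >= 1)
  feats <- list(); labs <- list(); imgid <- list()
  for (i in seq_len(n_images)) {
    si <- as.integer((as.numeric(seed) + i * 9973) %% 2147483647)
    spec <- if (is.null(spec_template)) phantom_spec(seed = si) else {
      s <- spec_template; s$seed <- si; .validate_phantom_spec(s); s
    }
    ph <- make_compound_phantom(spec)
    part <- oversegment(ph$image, K = config$K,
                        compactness = config$slic_compactness)
    fg_union <- Reduce(`|`, ph$truth$slice_masks)
    stats_i <- superpixel_stats(ph$image, part, B = config$B)
    f <- saliency_features(stats_i, sigma_p = config$sigma_p,
                           sigma_c = config$sigma_c)
    frac <- vapply(seq_len(part$K), function(k)
      mean(fg_union[part$labels == k]), 0)
    keep_fg <- frac >= purity[1]; keep_bg <- frac <= purity[2]
    if (!any(keep_bg))
      stop("degenerate phantom: no background superpixels (image ", i, ")")
    keep <- keep_fg | keep_bg
    feats[[i]] <- cbind(f[keep, , drop = FALSE], fg_fraction = frac[keep])
    labs[[i]] <- ifelse(keep_fg[keep], "fg", "bg")
    imgid[[i]] <- rep(i, sum(keep))
  }
  all_f <- do.call(rbind, feats)
  list(features = all_f[, c("gcs", "lcs", "chc", "scd"), drop = FALSE],
       fg_fraction = all_f$fg_fraction,
       labels = factor(unlist(labs), levels = c("bg", "fg")),
       image = unlist(imgid))
}
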