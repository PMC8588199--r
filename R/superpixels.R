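# SLIC superpixel oversegmentation and per-superpixel statistics.

#' Oversegment an RGB image into SLIC superpixels
#'
#' Runs simple linear iterative clustering (k-means in CIELab + position
#' space) and enforces spatial connectivity of every superpixel. The default
#' superpixel count is 65.
#'
#' @param image H x W x 3 array, 8-bit values in [0, 255].
#' @param K requested superpixel count (>= 2); the realised count may differ
#'   moderately after connectivity enforcement.
#' @param compactness SLIC compactness weight in Lab units (default 10).
#' @param iters k-means passes (default 10).
#' @return object of class \code{ttc_superpixels}: list with \code{labels}
#'   (H x W integer matrix, values 1..K) and \code{K} (realised count).
#' @export
#' @examples
#' img <- array(runif(40 * 60 * 3, 0, 255), c(40, 60, 3))
#' sp <- oversegment(img, K = 12)
#' sp$K
oversegment <- function(image, K = 65L, compactness = 10, iters = 10L) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (K < 2) stop("K must be >= 2")
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H * W < K) stop("image smaller than K pixels")
  rgb01 <- matrix(c(image) / 255, ncol = 3)
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1], H, W); A <- matrix(lab[, 2], H, W)
  B <- matrix(lab[, 3], H, W)
  labels <- .slic_cpp(L, A, B, as.integer(K), compactness, as.integer(iters)) + 1L
  structure(list(labels = labels, K = max(labels)), class = "ttc_superpixels")
}

#' Per-superpixel colour, position and histogram statistics
#'
#' Computes, for each superpixel, a 6-D colour vector (channel-normalized
#' mean RGB concatenated with range-normalized mean CIELab), the mean pixel
#' position in normalized [0,1]^2 coordinates, and a normalized quantized
#' RGB colour histogram.
#'
#' @param image H x W x 3 array in [0, 255].
#' @param partition a \code{ttc_superpixels} object for this image.
#' @param B histogram bins; must be a perfect cube of levels per channel
#'   (default 64 = 4 levels per channel).
#' @return object of class \code{ttc_spstats}: list with \code{K},
#'   \code{color} (K x 6), \code{pos} (K x 2), \code{hist} (K x B),
#'   \code{size} (pixel counts) and the label matrix.
#' @export
superpixel_stats <- function(image, partition, B = 64L) {
  stopifnot(inherits(partition, "ttc_superpixels"))
  H <- dim(image)[1]; W <- dim(image)[2]
  lv <- round(B^(1 / 3))
  if (lv^3 != B) stop("B must be a cube of the per-channel level count")
  labels <- partition$labels
  K <- partition$K
  lv_idx <- function(ch) pmin(floor(ch / (256 / lv)), lv - 1)
  f <- factor(labels, levels = seq_len(K))
  size <- as.integer(table(f))
  mr <- tapply(image[, , 1], f, mean)
  mg <- tapply(image[, , 2], f, mean)
  mb <- tapply(image[, , 3], f, mean)
  rgb_mean <- cbind(mr, mg, mb)
  lab_mean <- grDevices::convertColor(rgb_mean / 255, from = "sRGB", to = "Lab")
  color <- cbind(rgb_mean / 255,
                 lab_mean[, 1] / 100,
                 (lab_mean[, 2] + 128) / 255,
                 (lab_mean[, 3] + 128) / 255)
  colnames(color) <- c("r", "g", "b", "l_", "a_", "b_")
  rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  pos <- cbind(tapply(rows, f, mean) / H, tapply(cols, f, mean) / W)
  colnames(pos) <- c("r", "c")
  bin <- lv_idx(image[, , 1]) * lv^2 + lv_idx(image[, , 2]) * lv + lv_idx(image[, , 3]) + 1
  hist <- matrix(0, K, B)
  tab <- table(f, factor(bin, levels = seq_len(B)))
  hist[] <- as.numeric(tab)
  hist <- hist / pmax(size, 1)
  structure(list(K = K, color = color, pos = pos, hist = hist,
                 size = size, labels = labels),
            class = "ttc_spstats")
}

#' Export a superpixel partition as a 16-bit label PNG
#'
#' @param partition a \code{ttc_superpixels} object (labels 1..K).
#' @param path output PNG file; label values are stored in the 16-bit
#'   gray channel (0-based).
#' @return the path, invisibly.
#' @export
write_labels_png <- function(partition, path) {
  stopifnot(inherits(partition, "ttc_superpixels"))
  png::writePNG((partition$labels - 1L) / 65535, path)
  invisible(path)
}

#' Construct superpixel statistics directly from components
#'
#' Convenience constructor used by tests and oracles: wraps explicit colour,
#' position and histogram matrices as a \code{ttc_spstats} object without an
#' image.
#'
#' @param color K x 6 matrix, \code{pos} K x 2 matrix in [0,1]^2,
#'   \code{hist} K x B nonnegative matrix with unit row sums (optional).
#' @param pos,hist see above.
#' @return a \code{ttc_spstats} object.
#' @export
spstats <- function(color, pos, hist = NULL) {
  color <- as.matrix(color); pos <- as.matrix(pos)
  K <- nrow(color)
  stopifnot(nrow(pos) == K, ncol(pos) == 2)
  if (!is.null(hist)) {
    hist <- as.matrix(hist)
    stopifnot(nrow(hist) == K, all(hist >= 0),
              all(abs(rowSums(hist) - 1) < 1e-9))
  }
  structure(list(K = K, color = color, pos = pos, hist = hist,
                 size = rep(1L, K), labels = NULL),
            class = "ttc_spstats")
}
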