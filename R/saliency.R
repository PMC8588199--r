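# Per-superpixel colour saliency features.
#
# Four features describe how much each superpixel stands out from the rest
# of the image: global colour saliency (GCS), proximity-weighted local
# colour saliency (LCS), chi-square colour histogram contrast (CHC) and the
# spatial spread of each superpixel's colour (SCD). Foreground tissue is
# rare, strongly coloured and spatially concentrated, so it scores high on
# the contrast features and low on the spread feature.

#' Colour distance between two superpixels
#'
#' Euclidean distance over the 6-D colour vector that concatenates
#' normalized RGB and normalized CIELab coordinates.
#'
#' @param ci,cj numeric 6-vectors (rows of \code{ttc_spstats$color}).
#' @return nonnegative scalar; zero iff the vectors are equal.
#' @export
color_distance <- function(ci, cj) {
  stopifnot(length(ci) == length(cj), all(is.finite(ci)), all(is.finite(cj)))
  sqrt(sum((ci - cj)^2))
}

# K x K Euclidean distance matrix of rows of x
.pairdist <- function(x) {
  g <- tcrossprod(x)
  n2 <- diag(g)
  d2 <- outer(n2, n2, `+`) - 2 * g
  sqrt(pmax(d2, 0))
}

#' Global colour saliency
#'
#' For each superpixel, the sum of its colour distance to all other
#' superpixels.
#'
#' @param stats a \code{\link{spstats}} / \code{\link{superpixel_stats}} object.
#' @return numeric vector of length K, all values >= 0.
#' @export
global_color_saliency <- function(stats) {
  stopifnot(inherits(stats, "ttc_spstats"), stats$K >= 2)
  D <- .pairdist(stats$color)
  rowSums(D)
}

#' Local colour saliency
#'
#' Proximity-weighted colour contrast: colour distances to the other
#' superpixels are averaged under a Gaussian weight of the position distance,
#' normalized to unit sum over the neighbours of each superpixel.
#'
#' @param stats a \code{ttc_spstats} object.
#' @param sigma_p Gaussian bandwidth in normalized image coordinates.
#' @return numeric vector of length K.
#' @export
local_color_saliency <- function(stats, sigma_p = 0.25) {
  stopifnot(inherits(stats, "ttc_spstats"), sigma_p > 0)
  D <- .pairdist(stats$color)
  P <- .pairdist(stats$pos)
  Wm <- exp(-P^2 / (2 * sigma_p^2))
  diag(Wm) <- 0
  rs <- rowSums(Wm)
  rs[rs == 0] <- 1
  rowSums(Wm * D) / rs
}

#' Colour histogram contrast
#'
#' Sum over all other superpixels of the chi-square distance between
#' normalized quantized-colour histograms.
#'
#' @param stats a \code{ttc_spstats} object with histograms.
#' @param eps guard added to the chi-square denominator.
#' @return numeric vector of length K.
#' @export
color_histogram_contrast <- function(stats, eps = 1e-12) {
  stopifnot(inherits(stats, "ttc_spstats"), !is.null(stats$hist))
  h <- stats$hist
  K <- nrow(h)
  out <- numeric(K)
  for (i in seq_len(K)) {
    num <- sweep(h, 2, h[i, ], `-`)^2
    den <- sweep(h, 2, h[i, ], `+`) + eps
    out[i] <- sum(num / den)
  }
  out
}

#' Spatial colour distribution
#'
#' Colour-affinity-weighted spatial variance of each superpixel's colour:
#' positions of similarly coloured superpixels are averaged under a Gaussian
#' colour affinity (normalized to unit sum), and the feature is the weighted
#' squared spread around that mean position. Concentrated (foreground)
#' colours score low, dispersed background colours score high.
#'
#' @param stats a \code{ttc_spstats} object.
#' @param sigma_c Gaussian bandwidth in normalized colour units.
#' @return numeric vector of length K.
#' @export
spatial_color_distribution <- function(stats, sigma_c = 0.2) {
  stopifnot(inherits(stats, "ttc_spstats"), sigma_c > 0)
  Dc <- .pairdist(stats$color)
  Bw <- exp(-Dc^2 / (2 * sigma_c^2))
  Bw <- Bw / rowSums(Bw)
  mu <- Bw %*% stats$pos                 # weighted mean position, K x 2
  p <- stats$pos
  d2 <- outer(mu[, 1], p[, 1], `-`)^2 + outer(mu[, 2], p[, 2], `-`)^2
  rowSums(Bw * d2)
}

#' All four saliency features, min-max scaled per image
#'
#' @param stats a \code{ttc_spstats} object.
#' @param sigma_p,sigma_c bandwidths of the proximity and colour-affinity
#'   weights.
#' @param scale if TRUE (default) each feature is min-max scaled to [0, 1]
#'   across the image's superpixels, which makes features comparable across
#'   images of different contrast.
#' @return data frame with columns \code{gcs}, \code{lcs}, \code{chc},
#'   \code{scd}, one row per superpixel.
#' @export
saliency_features <- function(stats, sigma_p = 0.25, sigma_c = 0.2,
                              scale = TRUE) {
  f <- data.frame(gcs = global_color_saliency(stats),
                  lcs = local_color_saliency(stats, sigma_p),
                  chc = color_histogram_contrast(stats),
                  scd = spatial_color_distribution(stats, sigma_c))
  if (scale) {
    for (j in seq_along(f)) {
      rng <- range(f[[j]])
      f[[j]] <- if (diff(rng) > 0) (f[[j]] - rng[1]) / diff(rng) else 0 * f[[j]]
    }
  }
  f
}
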