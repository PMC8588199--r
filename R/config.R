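#' Pipeline configuration
#'
#' Bundles every tunable of the brain-extraction and hemisphere-segmentation
#' pipelines with validated defaults. Values not overridden keep their
#' defaults; unknown names are rejected.
#'
#' @param ... named overrides of the default values. Recognised fields:
#' \describe{
#'   \item{K}{superpixel count for the oversegmentation (default 65).}
#'   \item{Tf, Tb}{foreground / background score thresholds of the saliency
#'     trimap (defaults 0.7 and 0.3).}
#'   \item{alpha, beta}{snake tension and rigidity weights (default 1.4 each).}
#'   \item{gamma}{external-energy weight (default 1).}
#'   \item{mu_g}{GVF regularization weight (default 0.2).}
#'   \item{Ts}{red/blue branch threshold of the colour transform, 8-bit units
#'     (default 50).}
#'   \item{w}{medial subimage width in pixels (default 36).}
#'   \item{sigma_ext}{Gaussian blur of the external-energy image (default 2).}
#'   \item{sigma_p}{proximity-weight bandwidth in normalized image
#'     coordinates (default 0.25).}
#'   \item{sigma_c}{colour-affinity bandwidth in normalized colour units
#'     (default 0.2).}
#'   \item{B}{quantized-colour histogram bins (default 64 = 4 levels per
#'     channel).}
#'   \item{n_trees}{random-forest size (default 200).}
#'   \item{slic_compactness}{SLIC compactness in Lab units (default 10).}
#'   \item{grabcut_lambda}{pairwise smoothness weight of the graph cut
#'     (default 50).}
#'   \item{grabcut_components}{GMM components per side (default 5).}
#'   \item{grabcut_inner}{GMM refit iterations per outer pass (default 5).}
#'   \item{grabcut_outer}{maximum outer refinement passes (default 4).}
#'   \item{band_px}{dilation/erosion radius of the adaptive unknown band
#'     (default 10).}
#'   \item{A_min}{minimum component area kept as a slice (default 500).}
#'   \item{crop_size}{per-slice crop (rows, cols), default c(320, 480).}
#'   \item{seed}{base seed for all stochastic steps (default 1).}
#' }
#' @return an object of class \code{ttc_config} (a validated named list).
#' @export
#' @examples
#' cfg <- ttc_config(K = 80, Tf = 0.8)
#' cfg$K
ttc_config <- function(...) {
  defaults <- list(
    K = 65L, Tf = 0.7, Tb = 0.3,
    alpha = 1.4, beta = 1.4, gamma = 1.0, mu_g = 0.2,
    Ts = 50, w = 36L, sigma_ext = 2.0,
    sigma_p = 0.25, sigma_c = 0.2, B = 64L,
    n_trees = 200L, slic_compactness = 10,
    grabcut_lambda = 50, grabcut_components = 5L,
    grabcut_inner = 5L, grabcut_outer = 4L,
    band_px = 10L, A_min = 500L, crop_size = c(320L, 480L),
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  .validate_config(cfg)
  structure(cfg, class = "ttc_config")
}

.validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$K >= 2, "K must be >= 2")
  chk(cfg$Tb >= 0 && cfg$Tf <= 1 && cfg$Tb <= cfg$Tf, "need 0 <= Tb <= Tf <= 1")
  chk(cfg$alpha >= 0 && cfg$beta >= 0, "alpha, beta must be >= 0")
  chk(cfg$mu_g > 0, "mu_g must be > 0")
  chk(cfg$Ts >= 0 && cfg$Ts <= 255, "Ts must be in [0, 255]")
  chk(cfg$w >= 4, "w must be >= 4")
  chk(cfg$sigma_ext > 0 && cfg$sigma_p > 0 && cfg$sigma_c > 0,
      "bandwidths must be > 0")
  chk(cfg$B >= 2, "B must be >= 2")
  chk(cfg$n_trees >= 1, "n_trees must be >= 1")
  chk(length(cfg$crop_size) == 2 && all(cfg$crop_size > 0),
      "crop_size must be two positive integers")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with a flat mapping of configuration fields.
#'   Unknown keys are rejected.
#' @return a \code{ttc_config} object.
#' @export
read_ttc_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("configuration file must contain a mapping")
  do.call(ttc_config, vals)
}

#' @export
print.ttc_config <- function(x, ...) {
  cat("TTC segmentation pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}
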