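# Saliency trimap classification and iterative GrabCut-style refinement.

#' Train the superpixel saliency classifier
#'
#' Fits a random forest mapping the four saliency features to a foreground
#' score, defined as the fraction of trees voting foreground.
#'
#' @param features data frame / matrix with columns gcs, lcs, chc, scd.
#' @param labels factor or character vector with levels "bg"/"fg"; both
#'   classes must be present.
#' @param n_trees forest size (default 200).
#' @param seed RNG seed for the forest construction.
#' @return object of class \code{ttc_saliency_model}.
#' @export
train_saliency_model <- function(features, labels, n_trees = 200L, seed = 0L) {
  labels <- factor(as.character(labels), levels = c("bg", "fg"))
  if (any(is.na(labels))) stop("labels must be 'bg' or 'fg'")
  if (nlevels(droplevels(labels)) < 2)
    stop("both classes must be present in the training labels")
  stopifnot(all(is.finite(as.matrix(features))))
  .local_seed(seed)
  rf <- randomForest::randomForest(x = as.data.frame(features), y = labels,
                                   ntree = as.integer(n_trees))
  structure(list(rf = rf, n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "ttc_saliency_model")
}

#' Foreground saliency scores
#'
#' @param model a \code{ttc_saliency_model}.
#' @param features feature rows as in \code{\link{train_saliency_model}}.
#' @return numeric vector of scores in [0, 1] (fg vote fractions).
#' @export
predict_saliency <- function(model, features) {
  stopifnot(inherits(model, "ttc_saliency_model"))
  v <- stats::predict(model$rf, newdata = as.data.frame(features), type = "vote",
                      norm.votes = TRUE)
  as.numeric(v[, "fg"])
}

#' Three-class saliency trimap
#'
#' Thresholds superpixel saliency scores into foreground (score > Tf),
#' background (score < Tb) and unknown (in between).
#'
#' @param model a \code{ttc_saliency_model}, or a numeric score vector.
#' @param features feature rows (ignored when \code{model} is numeric).
#' @param Tf,Tb foreground / background thresholds, 0 <= Tb <= Tf <= 1.
#' @return object of class \code{ttc_trimap}: list with \code{class}
#'   (factor fg/unknown/bg per superpixel) and \code{score}.
#' @export
predict_trimap <- function(model, features = NULL, Tf = 0.7, Tb = 0.3) {
  if (Tb > Tf) stop("Tb must not exceed Tf")
  score <- if (is.numeric(model)) model else predict_saliency(model, features)
  # bg is inclusive at Tb so the unknown band (Tb, Tf] is empty when Tf = Tb
  cls <- ifelse(score > Tf, "fg", ifelse(score <= Tb, "bg", "unknown"))
  structure(list(class = factor(cls, levels = c("fg", "unknown", "bg")),
                 score = score, Tf = Tf, Tb = Tb),
            class = "ttc_trimap")
}

# ---- Gaussian mixture colour models (GrabCut style) ----

# fit a G-component full-covariance mixture by k-means initialization
# followed by hard assign / refit passes
.fit_gmm <- function(X, G = 5L, iters = 5L, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X)
  G <- min(G, max(1L, nrow(unique(X))))
  .local_seed(seed)
  assign <- if (G == 1L) rep(1L, n) else {
    km <- suppressWarnings(stats::kmeans(X, centers = G, nstart = 1, iter.max = 20))
    km$cluster
  }
  comp <- NULL
  for (it in seq_len(iters)) {
    comp <- lapply(seq_len(G), function(g) {
      idx <- which(assign == g)
      if (length(idx) < 4)
        return(list(w = 1e-8, mu = colMeans(X), sigma = diag(ncol(X)) * 1e4))
      mu <- colMeans(X[idx, , drop = FALSE])
      sg <- stats::cov(X[idx, , drop = FALSE]) + diag(ncol(X)) * 1.0
      list(w = length(idx) / n, mu = mu, sigma = sg)
    })
    ll <- .gmm_comp_loglik(comp, X)
    assign <- max.col(ll)
  }
  structure(list(comp = comp), class = "ttc_gmm")
}

# n x G matrix of log(w_g) + log N(x; mu_g, Sigma_g)
.gmm_comp_loglik <- function(comp, X) {
  out <- matrix(-Inf, nrow(X), length(comp))
  for (g in seq_along(comp)) {
    cg <- comp[[g]]
    ch <- tryCatch(chol(cg$sigma), error = function(e) NULL)
    if (is.null(ch)) next
    z <- forwardsolve(t(ch), t(sweep(X, 2, cg$mu)))
    q <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    out[, g] <- log(max(cg$w, 1e-12)) -
      0.5 * (q + logdet + ncol(X) * log(2 * pi))
  }
  out
}

# negative log-likelihood under the full mixture
.gmm_neg_loglik <- function(gmm, X) {
  ll <- .gmm_comp_loglik(gmm$comp, X)
  m <- apply(ll, 1, max)
  -(m + log(rowSums(exp(ll - m))))
}

# contrast-modulated Potts edge system of the pixel grid (computed once
# per image; reused across the outer refinement passes)
.grabcut_edges <- function(X, H, W, lambda = 50) {
  n <- H * W
  idx <- matrix(seq_len(n), H, W)
  fr <- c(as.vector(idx[, -W]), as.vector(idx[-H, ]))
  to <- c(as.vector(idx[, -1]), as.vector(idx[-1, ]))
  d2 <- rowSums((X[fr, , drop = FALSE] - X[to, , drop = FALSE])^2)
  beta <- 1 / max(2 * mean(d2), 1e-9)
  list(fr = fr, to = to, cap = lambda * exp(-beta * d2))
}

# one graph-cut pass: unary terms from the two mixtures, hard constraints
.grabcut_cut <- function(X, H, W, gmm_fg, gmm_bg, hard_fg, hard_bg, edges) {
  n <- H * W
  Dfg <- .gmm_neg_loglik(gmm_fg, X)   # cost of labelling fg
  Dbg <- .gmm_neg_loglik(gmm_bg, X)
  INF <- 1e9
  src <- Dbg                           # capacity to source = cost of bg label
  snk <- Dfg
  src[hard_bg] <- 0;  snk[hard_bg] <- INF
  src[hard_fg] <- INF; snk[hard_fg] <- 0
  res <- .bk_maxflow_cpp(n, src, snk, edges$fr, edges$to, edges$cap)
  matrix(res$source_side == 1L, H, W)
}

#' Iterative salient region extraction (GrabCut with trimap refitting)
#'
#' Converts a superpixel saliency trimap into a pixel-level binary brain
#' mask. The trimap's background superpixels form a hard background
#' constraint while foreground and unknown superpixels initialize the
#' foreground colour model; each outer pass fits 5-component Gaussian
#' mixtures to both sides, solves a graph cut, and re-derives the trimap
#' from the new mask (eroded core as hard foreground, dilated band as
#' unknown) until the mask is stable.
#'
#' @param image H x W x 3 array in [0, 255].
#' @param partition \code{ttc_superpixels} for the image.
#' @param trimap \code{ttc_trimap} over the same superpixels.
#' @param config a \code{\link{ttc_config}} (lambda, component count, inner
#'   and outer iteration counts, band width).
#' @param max_iters maximum outer passes; defaults to
#'   \code{config$grabcut_outer}.
#' @return logical H x W mask with attributes \code{iterations} (outer
#'   passes used), \code{converged} (mask stabilised before the pass cap)
#'   and \code{final_trimap} (pixel map, values "fg", "unknown", "bg").
#' @export
saliency_cut <- function(image, partition, trimap, config = ttc_config(),
                         max_iters = config$grabcut_outer) {
  stopifnot(inherits(partition, "ttc_superpixels"), inherits(trimap, "ttc_trimap"))
  H <- dim(image)[1]; W <- dim(image)[2]
  cls <- as.character(trimap$class)[partition$labels]  # per-pixel class
  dim(cls) <- c(H, W)
  # a background region fully enclosed by salient superpixels is presumably
  # part of the object (e.g. a pale infarct patch): demote it to unknown so
  # it is not used as a hard constraint or background colour evidence
  bg_map <- cls == "bg"
  enclosed <- fill_holes(!bg_map) & bg_map
  cls[enclosed] <- "unknown"
  if (!any(cls != "bg")) {
    warning("empty initialization: trimap has no non-background superpixels")
    out <- matrix(FALSE, H, W)
    attr(out, "iterations") <- 0L
    attr(out, "final_trimap") <- cls
    return(out)
  }
  if (all(cls == "fg")) {
    # no background evidence at all: degenerate all-foreground result
    out <- matrix(TRUE, H, W)
    attr(out, "iterations") <- 0L
    attr(out, "final_trimap") <- cls
    return(out)
  }
  X <- matrix(c(image), ncol = 3)
  edges <- .grabcut_edges(X, H, W, lambda = config$grabcut_lambda)
  # first pass: the trimap seeds the colour models (bg superpixels as
  # background evidence, everything else as probable foreground) but is not
  # a hard constraint, so isolated classifier errors remain recoverable;
  # hard constraints enter through the adaptive bands of later passes
  hard_bg <- rep(FALSE, H * W)
  hard_fg <- rep(FALSE, H * W)
  mask <- matrix(cls != "bg", H, W)     # high-recall initial foreground
  iters_used <- 0L
  stable <- FALSE
  stable_tol <- 5e-4 * H * W            # "stable" when the mask change is tiny
  samp <- function(idx, nmax = 5000L) {
    if (length(idx) <= nmax) idx else idx[round(seq(1, length(idx), length.out = nmax))]
  }
  for (it in seq_len(max_iters)) {
    fg_idx <- which(c(mask) & !hard_bg)
    bg_idx <- which(!c(mask) | hard_bg)
    if (!length(fg_idx) || !length(bg_idx)) break
    gmm_fg <- .fit_gmm(X[samp(fg_idx), , drop = FALSE],
                       G = config$grabcut_components,
                       iters = config$grabcut_inner, seed = config$seed + it)
    gmm_bg <- .fit_gmm(X[samp(bg_idx), , drop = FALSE],
                       G = config$grabcut_components,
                       iters = config$grabcut_inner, seed = config$seed + 100 + it)
    new_mask <- .grabcut_cut(X, H, W, gmm_fg, gmm_bg,
                             hard_fg = hard_fg, hard_bg = hard_bg,
                             edges = edges)
    iters_used <- it
    changed <- sum(xor(new_mask, mask))
    mask <- new_mask
    if (changed <= stable_tol) { stable <- TRUE; break }
    # adaptive refitting: re-derive the trimap from the segmentation
    core <- .erode_disk(mask, config$band_px)
    reach <- .dilate_disk(mask, config$band_px)
    hard_fg <- c(core)
    hard_bg <- c(!reach)
  }
  # final trimap: the adaptive re-derivation of the final segmentation
  cls_final <- matrix("unknown", H, W)
  cls_final[.erode_disk(mask, config$band_px)] <- "fg"
  cls_final[!.dilate_disk(mask, config$band_px)] <- "bg"
  attr(mask, "iterations") <- iters_used
  attr(mask, "converged") <- stable
  attr(mask, "final_trimap") <- cls_final
  mask
}
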