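# End-to-end pipelines and file-level entry points.

#' Read an RGB PNG image as an 8-bit array
#' @param path PNG file.
#' @return H x W x 3 numeric array with values in [0, 255].
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write an RGB array to PNG
#' @param image H x W x 3 array in [0, 255].
#' @param path output file.
#' @export
write_image_rgb <- function(image, path) {
  png::writePNG(.clip(image, 0, 255) / 255, path)
  invisible(path)
}

#' Write a binary mask to an 8-bit PNG (0/255)
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG file; nonzero pixels are foreground.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

#' Train the saliency model on synthetic phantoms
#'
#' Convenience wrapper: builds a phantom training set and fits the random
#' forest.
#'
#' @param n_images phantom count (default 20).
#' @param seed training-set seed (default 7).
#' @param config a \code{\link{ttc_config}}.
#' @param spec_template optional \code{\link{phantom_spec}} template.
#' @return a \code{ttc_saliency_model}.
#' @export
train_synthetic_model <- function(n_images = 20L, seed = 7L,
                                  config = ttc_config(),
                                  spec_template = NULL) {
  ts <- make_training_set(n_images, seed, spec_template = spec_template,
                          config = config)
  train_saliency_model(ts$features, ts$labels, n_trees = config$n_trees,
                       seed = config$seed)
}

#' Extract all brain slices from a compound image
#'
#' Runs the five brain-extraction phases: superpixel oversegmentation,
#' saliency feature computation, random-forest trimap, iterative salient
#' region extraction, hole filling, and per-slice snake refinement.
#'
#' @param image compound H x W x 3 array in [0, 255].
#' @param model a trained \code{ttc_saliency_model}.
#' @param config a \code{\link{ttc_config}}.
#' @param refine apply the per-slice snake refinement (default TRUE).
#' @param verbose log per-stage timings via \code{message()}.
#' @return list with \code{slices} (list of \code{ttc_brain_slice}),
#'   \code{mask} (refined compound mask), \code{raw_mask} (pre-refinement),
#'   \code{trimap}, \code{partition}.
#' @export
extract_brains <- function(image, model, config = ttc_config(),
                           refine = TRUE, verbose = FALSE) {
  stage <- function(what, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    if (verbose)
      message(sprintf("%-22s %6.2f s", what,
                      as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  part <- stage("oversegmentation", oversegment(image, K = config$K,
                                                compactness = config$slic_compactness))
  st <- stage("superpixel stats", superpixel_stats(image, part, B = config$B))
  feats <- stage("saliency features",
                 saliency_features(st, sigma_p = config$sigma_p,
                                   sigma_c = config$sigma_c))
  tri <- stage("trimap", predict_trimap(model, feats, Tf = config$Tf, Tb = config$Tb))
  ms <- stage("salient region cut", saliency_cut(image, part, tri, config = config))
  mh <- stage("hole filling", fill_holes(ms))
  slices <- stage("slice extraction", extract_slices(image, mh, config = config))
  if (refine)
    slices <- stage("snake refinement",
                    lapply(slices, refine_slice, config = config))
  full <- matrix(FALSE, nrow(mh), ncol(mh))
  for (s in slices) {
    rr <- s$offset[1]:(s$offset[1] + nrow(s$mask) - 1)
    cc <- s$offset[2]:(s$offset[2] + ncol(s$mask) - 1)
    ok_r <- rr <= nrow(full); ok_c <- cc <= ncol(full)
    full[rr[ok_r], cc[ok_c]] <- full[rr[ok_r], cc[ok_c]] | s$mask[ok_r, ok_c]
  }
  list(slices = slices, mask = full, raw_mask = mh, trimap = tri,
       partition = part)
}

#' File-level brain extraction
#'
#' Reads a compound PNG, extracts the slices and writes one image and one
#' mask PNG per slice plus a CSV manifest of crop offsets.
#'
#' @param image_path input PNG.
#' @param out_dir output directory (created if missing).
#' @param model a \code{ttc_saliency_model}, or NULL to train one on
#'   synthetic phantoms.
#' @param config a \code{\link{ttc_config}}.
#' @param verbose log per-stage timings.
#' @return invisibly, the manifest data frame.
#' @export
run_extract <- function(image_path, out_dir, model = NULL,
                        config = ttc_config(), verbose = FALSE) {
  img <- read_image_rgb(image_path)
  if (is.null(model)) model <- train_synthetic_model(config = config)
  res <- extract_brains(img, model, config = config, verbose = verbose)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.png$", "", basename(image_path), ignore.case = TRUE)
  rows <- lapply(res$slices, function(s) {
    imgf <- file.path(out_dir, sprintf("%s_slice%d.png", stem, s$index))
    maskf <- file.path(out_dir, sprintf("%s_slice%d_mask.png", stem, s$index))
    write_image_rgb(s$image, imgf)
    write_mask_png(s$mask, maskf)
    data.frame(slice = s$index, image = basename(imgf), mask = basename(maskf),
               offset_row = s$offset[1], offset_col = s$offset[2],
               area = sum(s$mask))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, sprintf("%s_manifest.csv", stem)),
                   row.names = FALSE)
  invisible(manifest)
}

#' File-level hemisphere segmentation
#'
#' Reads a slice PNG and its mask, computes the midline and writes the
#' left/right hemisphere masks, the midline path CSV and a QC overlay with
#' the midline drawn in green.
#'
#' @param slice_path slice image PNG.
#' @param mask_path slice mask PNG (same dimensions).
#' @param out_dir output directory.
#' @param config a \code{\link{ttc_config}}.
#' @return invisibly, the \code{ttc_midline_result}.
#' @export
run_hemispheres <- function(slice_path, mask_path, out_dir,
                            config = ttc_config()) {
  img <- read_image_rgb(slice_path)
  mask <- read_mask_png(mask_path)
  if (!all(dim(mask) == dim(img)[1:2])) stop("slice and mask dimensions differ")
  if (!any(mask)) stop("empty mask")
  slice <- structure(list(image = img, mask = mask, index = 1L,
                          offset = c(1L, 1L)),
                     class = "ttc_brain_slice")
  res <- segment_hemispheres(slice, config = config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.png$", "", basename(slice_path), ignore.case = TRUE)
  write_mask_png(res$left_mask, file.path(out_dir, paste0(stem, "_left.png")))
  write_mask_png(res$right_mask, file.path(out_dir, paste0(stem, "_right.png")))
  utils::write.csv(data.frame(row = res$path[, 1], col = res$path[, 2]),
                   file.path(out_dir, paste0(stem, "_midline.csv")),
                   row.names = FALSE)
  overlay <- img
  ch2 <- overlay[, , 2]; ch1 <- overlay[, , 1]; ch3 <- overlay[, , 3]
  ch1[res$path] <- 0; ch2[res$path] <- 255; ch3[res$path] <- 0
  overlay[, , 1] <- ch1; overlay[, , 2] <- ch2; overlay[, , 3] <- ch3
  write_image_rgb(overlay, file.path(out_dir, paste0(stem, "_overlay.png")))
  invisible(res)
}

#' @export
print.ttc_phantom <- function(x, ...) {
  cat(sprintf("TTC phantom: %d x %d, %d slice(s), seed %d\n",
              dim(x$image)[1], dim(x$image)[2],
              length(x$truth$slice_masks), x$spec$seed))
  invisible(x)
}

#' @export
print.ttc_brain_slice <- function(x, ...) {
  cat(sprintf("Brain slice %d: %d x %d crop at (%d, %d), area %d px\n",
              x$index, nrow(x$mask), ncol(x$mask),
              x$offset[1], x$offset[2], sum(x$mask)))
  invisible(x)
}

#' @export
print.ttc_midline_result <- function(x, ...) {
  cat(sprintf("Midline result: path %d px, left %d px, right %d px\n",
              nrow(x$path), sum(x$left_mask), sum(x$right_mask)))
  invisible(x)
}
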