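# Shared fixtures, built lazily and cached for the whole test run.
#
# Study-scale phantoms are generated at 450 x 800 so the full pipeline runs
# many times within the suite; all geometry scales with the frame.

.fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

test_compound_spec <- function(seed = 1L, ...) {
  phantom_spec(image_size = c(450L, 800L), seed = seed, ...)
}

fixture_compound <- function() {
  .fixture("compound", function() make_compound_phantom(test_compound_spec(seed = 1L)))
}

fixture_partition <- function() {
  .fixture("partition", function() oversegment(fixture_compound()$image, K = 65))
}

fixture_spstats <- function() {
  .fixture("spstats", function()
    superpixel_stats(fixture_compound()$image, fixture_partition()))
}

# the saliency model used by every pipeline-level test: trained on 20
# synthetic phantoms with seed 7
fixture_model <- function() {
  .fixture("model", function() {
    ts <- fixture_training_set()
    train_saliency_model(ts$features, ts$labels)
  })
}

fixture_training_set <- function() {
  .fixture("training_set", function()
    make_training_set(20, seed = 7, spec_template = test_compound_spec()))
}

# extraction of the seed-101 compound phantom, with and without snake
# refinement (shared by refinement-safety and acceptance checks)
fixture_extraction <- function() {
  .fixture("extraction", function() {
    ph <- make_compound_phantom(test_compound_spec(seed = 101L))
    raw <- extract_brains(ph$image, fixture_model(), refine = FALSE)
    refined <- list(slices = lapply(raw$slices, refine_slice))
    list(phantom = ph, raw = raw, refined = refined)
  })
}

# Dice in [0, 1] between two masks
dice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# truth mask cropped to a slice's frame
crop_truth <- function(slice, truth_mask) {
  rr <- slice$offset[1]:(slice$offset[1] + nrow(slice$mask) - 1)
  cc <- slice$offset[2]:(slice$offset[2] + ncol(slice$mask) - 1)
  truth_mask[rr, cc]
}

# best Dice of a slice against any truth slice mask
best_truth_dice <- function(slice, truth) {
  max(vapply(truth$slice_masks, function(tm) dice(slice$mask, crop_truth(slice, tm)), 0))
}

# mean distance from each path pixel to the nearest truth-path pixel
path_mean_dist <- function(path, truth_path) {
  mean(vapply(seq_len(nrow(path)), function(i)
    min(sqrt((truth_path[, 1] - path[i, 1])^2 +
             (truth_path[, 2] - path[i, 2])^2)), 0))
}

make_test_slice <- function(ph) {
  structure(list(image = ph$image, mask = ph$truth$slice_masks[[1]],
                 index = 1L, offset = c(1L, 1L)),
            class = "ttc_brain_slice")
}

# random blob mask: union of a few disks, for hole-filling and metric tests
random_blob <- function(dim, n_disks = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- dim[1]; W <- dim[2]
  m <- matrix(FALSE, H, W)
  for (i in seq_len(n_disks)) {
    ctr <- c(runif(1, H * 0.2, H * 0.8), runif(1, W * 0.2, W * 0.8))
    r <- runif(1, min(H, W) / 8, min(H, W) / 4)
    rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    m <- m | ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2)
  }
  m
}
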