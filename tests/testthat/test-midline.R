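# Medial subimage, endpoint detection, GVF and open-curve midline.

sym_slice <- function(seed = 2, tilt = 0, curv = 0) {
  make_slice_phantom(phantom_spec(n_slices = 1, seed = seed,
                                  midline_tilt_deg = tilt,
                                  midline_curvature_amp = curv))
}

test_that("the medial strip is centred on the midline with default width 36", {
  expect_identical(eval(formals(medial_subimage)$w), 36L)
  ph <- sym_slice()
  sub <- medial_subimage(make_test_slice(ph))
  expect_identical(ncol(sub$Sr), 36L)
  truth_col <- unique(ph$truth$midline_paths[[1]][, 2])
  strip_center <- sub$offset[2] + sub$w / 2 - 0.5
  expect_lte(abs(strip_center - truth_col), 1.5)
  # dimensions consistent
  expect_identical(dim(sub$Sc), dim(sub$Sr))
  expect_identical(dim(sub$Se), dim(sub$Sr))
})

test_that("strip-to-slice mapping is exactly invertible", {
  ph <- sym_slice(seed = 3, tilt = 8)
  sub <- medial_subimage(make_test_slice(ph))
  pts <- cbind(runif(50, 1, nrow(sub$Sr)), runif(50, 1, ncol(sub$Sr)))
  fwd <- strip_to_slice(sub, pts)
  # invert: rotate by +angle about pivot, subtract offset
  back <- ttcseg:::.rotate_points(fwd, sub$angle, sub$pivot)
  back <- cbind(back[, 1] - sub$offset[1] + 1, back[, 2] - sub$offset[2] + 1)
  expect_equal(back, pts, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("groove and concave endpoints land on the true notches", {
  ph <- sym_slice(seed = 4)
  sub <- medial_subimage(make_test_slice(ph))
  ep <- detect_endpoints(sub)
  expect_false(ep$fallback)
  truth_col_strip <- unique(ph$truth$midline_paths[[1]][, 2]) - sub$offset[2] + 1
  expect_lte(abs(ep$groove[2] - truth_col_strip), 2)
  expect_lte(abs(ep$concave[2] - truth_col_strip), 2)
  # groove above concave, both on the mask boundary
  expect_lt(ep$groove[1], ep$concave[1])
  expect_true(sub$mask[ep$groove[1], ep$groove[2]])
  expect_true(sub$mask[ep$concave[1], ep$concave[2]])

  # curved phantom: concave point near the truth path's inferior end
  phc <- sym_slice(seed = 5, curv = 4)
  subc <- medial_subimage(make_test_slice(phc))
  epc <- detect_endpoints(subc)
  tp <- phc$truth$midline_paths[[1]]
  inf_end <- tp[which.max(tp[, 1]), ]
  con_slice <- strip_to_slice(subc, rbind(epc$concave))
  expect_lte(sqrt(sum((con_slice - inf_end)^2)), 3)
})

test_that("a notch-free elliptical mask falls back to the mass-centre column", {
  H <- 200; W <- 300
  rr <- matrix(1:H, H, W); cc <- matrix(1:W, H, W, byrow = TRUE)
  img <- array(120, c(H, W, 3))
  ellipse <- ((rr - 100) / 70)^2 + ((cc - 150) / 120)^2 <= 1
  slice <- structure(list(image = img, mask = ellipse, index = 1L,
                          offset = c(1L, 1L)), class = "ttc_brain_slice")
  sub <- medial_subimage(slice)
  ep <- detect_endpoints(sub)
  expect_true(ep$fallback)
  expect_identical(ep$groove[2], ep$concave[2])
  expect_lt(ep$groove[1], ep$concave[1])
})

test_that("the initial midline is a straight, endpoint-exact polyline", {
  ml <- initial_midline(c(10, 5), c(40, 5), n_points = 31)
  expect_false(ml$closed)
  expect_equal(nrow(ml$xy), 31)
  expect_true(all(ml$xy[, 2] == 5))
  expect_equal(ml$xy[, 1], seq(10, 40, length.out = 31))
  expect_equal(ml$xy[1, ], c(10, 5)); expect_equal(ml$xy[31, ], c(40, 5))
  two <- initial_midline(c(1, 2), c(9, 7), n_points = 2)
  expect_equal(two$xy, rbind(c(1, 2), c(9, 7)), ignore_attr = TRUE)
  expect_error(initial_midline(c(3, 3), c(3, 3)), "coincide")
})

test_that("GVF of a constant edge map is identically zero and dt is guarded", {
  f <- gvf_field(matrix(1, 20, 20), mu = 0.2, n_iters = 50)
  expect_true(all(f$u == 0) && all(f$v == 0))
  expect_identical(eval(formals(gvf_field)$mu), 0.2)
  expect_error(gvf_field(matrix(1, 5, 5), mu = 0.2, dt = 10), "unstable")
})

test_that("the converged GVF field satisfies the discrete Euler equations", {
  set.seed(8)
  sg <- matrix(0, 40, 40)
  sg[, 18:22] <- 1
  sg <- ttcseg:::.gauss_blur(sg, 1.5)
  f <- gvf_field(sg, mu = 0.2, tol = 1e-3)
  expect_lt(f$residual, 1e-3)
  # where the edge response dominates the regularizer, the field stays
  # close to the raw edge gradient
  g <- ttcseg:::.gradient2d(sg * 20)         # strong-edge variant
  f2 <- gvf_field(sg * 20, mu = 0.2, tol = 1e-3)
  b <- g$gc^2 + g$gr^2
  strong <- which(b > 50 * 0.2)
  rel <- abs(f2$u[strong] - g$gc[strong]) /
    pmax(sqrt(g$gc[strong]^2 + g$gr[strong]^2), 1e-9)
  expect_lt(max(rel), 0.05)
})

test_that("the open snake finds an offset dark band and straightens under zero field", {
  # synthetic strip: dark vertical band at column 24, init offset 5 px
  H <- 120; W <- 40
  img <- matrix(1, H, W)
  img[, 23:25] <- 0.2
  sg <- ttcseg:::.gauss_blur(ttcseg:::.sobel_mag(img, TRUE), 1)
  field <- gvf_field(sg, mu = 0.2, n_iters = 80)
  init <- initial_midline(c(5, 19), c(116, 19), n_points = 40)
  ev <- evolve_midline(init, field)
  expect_lte(mean(abs(ev$xy[, 2] - 24)), 1)

  zero <- gvf_field(matrix(0.5, H, W), mu = 0.2, n_iters = 10)
  bent <- contour(cbind(seq(5, 116, length.out = 40),
                        19 + 6 * sin(seq(0, pi, length.out = 40))),
                  closed = FALSE)
  st <- evolve_midline(bent, zero, max_iters = 5000, tol = 1e-3)
  # straight chord between the (unmoved) endpoints
  expect_lt(max(abs(st$xy[, 2] - 19)), 0.5)
  expect_equal(st$xy[1, ], bent$xy[1, ], tolerance = 1e-6)
  expect_equal(st$xy[40, ], bent$xy[40, ], tolerance = 1e-6)
})

test_that("hemisphere splitting partitions the mask exactly", {
  ph <- sym_slice(seed = 6)
  slice <- make_test_slice(ph)
  res <- segment_hemispheres(slice)
  pm <- res$path_mask
  union <- res$left_mask | res$right_mask | pm
  expect_identical(union, slice$mask)
  expect_false(any(res$left_mask & res$right_mask))
  expect_false(any(res$left_mask & pm))
  expect_false(any(res$right_mask & pm))
  # balanced split of a symmetric phantom
  imbalance <- abs(sum(res$left_mask) - sum(res$right_mask)) / sum(slice$mask)
  expect_lte(imbalance, 0.02)
  # left truly left of right
  expect_lt(mean(which(res$left_mask, arr.ind = TRUE)[, 2]),
            mean(which(res$right_mask, arr.ind = TRUE)[, 2]))
})

test_that("the thinned midline path is a unit-width chain", {
  ph <- sym_slice(seed = 7, tilt = 6, curv = 3)
  res <- segment_hemispheres(make_test_slice(ph))
  pm <- matrix(FALSE, 320, 480)
  pm[res$path] <- TRUE
  # every path pixel has at most two 8-connected path neighbours
  for (i in seq_len(nrow(res$path))) {
    r <- res$path[i, 1]; c <- res$path[i, 2]
    nb <- pm[max(1, r - 1):min(320, r + 1), max(1, c - 1):min(480, c + 1)]
    expect_lte(sum(nb) - 1, 2)
  }
})

test_that("a non-transecting curve is rejected with diagnostics", {
  ph <- sym_slice(seed = 8)
  slice <- make_test_slice(ph)
  # a curve lying entirely lateral to the brain cannot split it
  stub <- contour(cbind(c(100, 220), c(5, 5)), closed = FALSE)
  expect_error(split_hemispheres(slice, stub), "transect")
})

test_that("deskew-based splitting is rotation equivariant", {
  ph <- sym_slice(seed = 9, curv = 2)
  slice <- make_test_slice(ph)
  res0 <- segment_hemispheres(slice)
  d0 <- dice(res0$left_mask, ph$truth$left_masks[[1]])

  theta <- 8 * pi / 180
  pivot <- c(160.5, 240.5)
  rimg <- ph$image
  for (ch in 1:3) rimg[, , ch] <- ttcseg:::.rotate_gray(ph$image[, , ch], theta, pivot,
                                                        fill = 95)
  rmask <- ttcseg:::.rotate_mask(ph$truth$slice_masks[[1]], theta, pivot)
  rleft <- ttcseg:::.rotate_mask(ph$truth$left_masks[[1]], theta, pivot)
  rslice <- structure(list(image = rimg, mask = rmask, index = 1L,
                           offset = c(1L, 1L)), class = "ttc_brain_slice")
  res1 <- segment_hemispheres(rslice)
  d1 <- dice(res1$left_mask, rleft)
  expect_lt(abs(d1 - d0), 0.01)
})
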