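# Hole filling, colour transform, external energy, closed snake and slice
# extraction.

# independent oracle for hole filling: conditional dilation of the
# border-touching complement (morphological reconstruction); holes are the
# complement pixels never reached
oracle_fill <- function(mask) {
  comp <- !mask
  reached <- comp
  reached[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] <- FALSE  # border seed
  cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3)
  repeat {
    grown <- ttcseg:::.from_ebi(EBImage::dilate(ttcseg:::.as_ebi(reached * 1),
                                                cross)) > 0.5
    grown <- grown & comp
    if (identical(grown, reached)) break
    reached <- grown
  }
  mask | (comp & !reached)
}

test_that("hole filling matches the conditional-dilation oracle on random masks", {
  set.seed(21)
  for (k in 1:100) {
    m <- random_blob(c(32, 32), n_disks = sample(1:3, 1))
    # punch holes
    for (h in seq_len(sample(0:3, 1))) {
      ctr <- which(m, arr.ind = TRUE)
      if (nrow(ctr) == 0) next
      p <- ctr[sample(nrow(ctr), 1), ]
      rr <- pmax(1, p[1] - 2):pmin(32, p[1] + 2)
      cc <- pmax(1, p[2] - 2):pmin(32, p[2] + 2)
      m[rr, cc] <- FALSE
    }
    expect_identical(fill_holes(m), oracle_fill(m))
  }
})

test_that("hole filling is idempotent, monotone and fills an annulus", {
  annulus <- matrix(FALSE, 21, 21)
  rr <- matrix(1:21, 21, 21); cc <- t(rr)
  d2 <- (rr - 11)^2 + (cc - 11)^2
  annulus[d2 <= 64 & d2 >= 16] <- TRUE
  filled <- fill_holes(annulus)
  expect_identical(filled, d2 <= 64)           # annulus becomes a full disk
  expect_identical(fill_holes(filled), filled) # idempotent
  expect_true(all(filled[annulus]))            # never removes foreground
})

test_that("colour transform branch arithmetic is exact", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(transform_color(px(100, 100, 100), Ts = 50)[1, 1], 0)
  expect_equal(transform_color(px(255, 0, 0), Ts = 50)[1, 1], 255)   # clipped 510
  expect_equal(transform_color(px(200, 40, 160), Ts = 50)[1, 1], 200)
  # branch boundary: |R - B| exactly Ts stays in branch one
  expect_equal(transform_color(px(150, 0, 100), Ts = 50)[1, 1], 200)
  expect_true(all(transform_color(array(runif(300, 0, 255), c(10, 10, 3))) >= 0))
})

test_that("external energy is nonpositive, linear in gamma, and peaked on edges", {
  flat <- external_energy(matrix(5, 30, 30), gamma = 1, sigma = 2)
  expect_true(all(flat$E == 0))

  step <- matrix(0, 40, 60); step[, 31:60] <- 1
  e1 <- external_energy(step, gamma = 1, sigma = 2)
  e2 <- external_energy(step, gamma = 2, sigma = 2)
  expect_equal(e2$E, 2 * e1$E, tolerance = 1e-12)
  expect_true(all(e1$E <= 0))
  argmin <- apply(e1$E[5:35, ], 1, which.min)
  expect_true(all(abs(argmin - 30.5) <= 1.5))  # on the edge column +/- 1
})

test_that("with zero external energy a tension-only snake shrinks strictly", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- contour(cbind(50 + 20 * sin(th), 50 + 20 * cos(th)))
  per <- function(xy) sum(sqrt(rowSums((xy[c(2:nrow(xy), 1), ] - xy)^2)))
  cur <- circ
  p_prev <- per(cur$xy)
  for (i in 1:10) {
    cur <- evolve_snake(cur, field = NULL, alpha = 1, beta = 0, tau = 0.5,
                        max_iters = 1, resample_every = 100)
    p_new <- per(cur$xy)
    expect_lt(p_new, p_prev)
    p_prev <- p_new
  }
})

test_that("a snake converges onto a disk edge with non-increasing energy", {
  H <- 101; W <- 101; r0 <- 30
  rr <- matrix(1:H, H, W); cc <- matrix(1:W, H, W, byrow = TRUE)
  disk <- ((rr - 51)^2 + (cc - 51)^2 <= r0^2) * 1
  field <- external_energy(disk, gamma = 200, sigma = 2)
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  init <- contour(cbind(51 + (r0 + 5) * sin(th), 51 + (r0 + 5) * cos(th)))
  ev <- evolve_snake(init, field, alpha = 0.2, beta = 0.2, max_iters = 200)
  radii <- sqrt(rowSums(sweep(ev$xy, 2, c(51, 51))^2))
  expect_true(all(abs(radii - r0) <= 1))
  tr <- attr(ev, "energy_trace")
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("slice extraction crops, orders and gates components", {
  ph <- fixture_compound()
  fg_union <- Reduce(`|`, ph$truth$slice_masks)
  slices <- extract_slices(ph$image, fg_union)
  expect_length(slices, 8)
  centers <- t(vapply(ph$truth$slice_masks, function(m)
    colMeans(which(m, arr.ind = TRUE)), numeric(2)))
  ord <- order(centers[, 1] > 225, centers[, 2])   # row-major truth order
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    expect_identical(dim(s$mask), c(320L, 480L))
    expect_identical(dim(s$image), c(320L, 480L, 3L))
    expect_identical(max(ttcseg:::.cc_label(s$mask, 8L)), 1L)
    # centroid of the crop content matches the i-th truth slice centroid
    ctr <- colMeans(which(s$mask, arr.ind = TRUE)) + s$offset - 1
    expect_lt(sqrt(sum((ctr - centers[ord[i], ])^2)), 5)
  }
  # a mask holding only clutter-like content errors out
  empty <- matrix(FALSE, 100, 100)
  expect_error(extract_slices(array(0, c(100, 100, 3)), empty), "no components")
  tiny <- empty; tiny[50:52, 50:52] <- TRUE
  expect_error(extract_slices(array(0, c(100, 100, 3)), tiny), "no surviving")
})

test_that("snake refinement never degrades phantom slices appreciably", {
  ex <- fixture_extraction()
  for (i in seq_along(ex$raw$slices)) {
    d_raw <- best_truth_dice(ex$raw$slices[[i]], ex$phantom$truth)
    d_ref <- best_truth_dice(ex$refined$slices[[i]], ex$phantom$truth)
    expect_gte(d_ref, d_raw - 0.01)
  }
})
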