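# Saliency features against brute-force oracles and closed-form examples.

# O(K^2) / O(K^2 B) reference implementations, written as literal loops
oracle_gcs <- function(st) {
  K <- st$K
  out <- numeric(K)
  for (i in 1:K) for (j in 1:K) if (i != j)
    out[i] <- out[i] + sqrt(sum((st$color[i, ] - st$color[j, ])^2))
  out
}

oracle_lcs <- function(st, sigma_p) {
  K <- st$K
  out <- numeric(K)
  for (i in 1:K) {
    w <- numeric(K)
    for (j in 1:K) if (i != j)
      w[j] <- exp(-sum((st$pos[i, ] - st$pos[j, ])^2) / (2 * sigma_p^2))
    w <- w / sum(w)
    for (j in 1:K) if (i != j)
      out[i] <- out[i] + w[j] * sqrt(sum((st$color[i, ] - st$color[j, ])^2))
  }
  out
}

oracle_chc <- function(st, eps = 1e-12) {
  K <- st$K; B <- ncol(st$hist)
  out <- numeric(K)
  for (i in 1:K) for (j in 1:K) for (k in 1:B)
    out[i] <- out[i] + (st$hist[i, k] - st$hist[j, k])^2 /
      (st$hist[i, k] + st$hist[j, k] + eps)
  out
}

oracle_scd <- function(st, sigma_c) {
  K <- st$K
  out <- numeric(K)
  for (i in 1:K) {
    w <- numeric(K)
    for (j in 1:K)
      w[j] <- exp(-sum((st$color[i, ] - st$color[j, ])^2) / (2 * sigma_c^2))
    w <- w / sum(w)
    mu <- c(sum(w * st$pos[, 1]), sum(w * st$pos[, 2]))
    for (j in 1:K)
      out[i] <- out[i] + w[j] * sum((st$pos[j, ] - mu)^2)
  }
  out
}

random_stats <- function(K, B = 16, seed) {
  set.seed(seed)
  h <- matrix(rexp(K * B), K)
  h <- h / rowSums(h)
  spstats(color = matrix(runif(K * 6), K),
          pos = matrix(runif(K * 2), K), hist = h)
}

test_that("colour distance is a 6-D Euclidean metric", {
  c1 <- c(1, 0, 0, 0, 0, 0); c2 <- c(0, 1, 0, 0, 0, 0)
  expect_equal(color_distance(c1, c2), sqrt(2))
  expect_equal(color_distance(c1, c1), 0)
  c3 <- runif(6); c4 <- runif(6)
  expect_equal(color_distance(c3, c4), color_distance(c4, c3))
  expect_gte(color_distance(c3, c4), 0)
})

test_that("all four features match their brute-force oracles to 1e-9", {
  for (K in c(5, 10, 12)) {
    st <- random_stats(K, seed = K)
    expect_equal(global_color_saliency(st), oracle_gcs(st), tolerance = 1e-9)
    expect_equal(local_color_saliency(st, 0.25), oracle_lcs(st, 0.25), tolerance = 1e-9)
    expect_equal(color_histogram_contrast(st), oracle_chc(st), tolerance = 1e-9)
    expect_equal(spatial_color_distribution(st, 0.2), oracle_scd(st, 0.2), tolerance = 1e-9)
  }
})

test_that("degenerate colour configurations give zero contrast", {
  K <- 6
  same <- spstats(color = matrix(0.4, K, 6), pos = matrix(runif(K * 2), K),
                  hist = matrix(1 / 8, K, 8))
  expect_equal(global_color_saliency(same), rep(0, K))
  expect_equal(local_color_saliency(same, 0.25), rep(0, K))
  expect_equal(color_histogram_contrast(same), rep(0, K), tolerance = 1e-9)
})

test_that("two- and three-superpixel closed forms hold", {
  # colours {A, A, B}: GCS of B is twice the pair distance, GCS of A once
  A <- rep(0.2, 6); B <- c(0.9, rep(0.2, 5))
  st <- spstats(color = rbind(A, A, B), pos = matrix(runif(6), 3))
  d <- color_distance(A, B)
  expect_equal(global_color_saliency(st), c(d, d, 2 * d), tolerance = 1e-12,
               ignore_attr = TRUE)

  # two superpixels: the single proximity weight normalizes to one
  st2 <- spstats(color = rbind(A, B), pos = rbind(c(0.1, 0.1), c(0.8, 0.4)))
  expect_equal(local_color_saliency(st2, 0.25), c(d, d), tolerance = 1e-12,
               ignore_attr = TRUE)

  # the near neighbour's colour distance receives the larger weight
  C <- c(0.2, 0.9, rep(0.2, 4))
  st3 <- spstats(color = rbind(A, B, C),
                 pos = rbind(c(0.5, 0.1), c(0.5, 0.2), c(0.5, 0.9)))
  lcs <- local_color_saliency(st3, 0.1)
  w12 <- exp(-0.1^2 / (2 * 0.01)); w13 <- exp(-0.8^2 / (2 * 0.01))
  dAB <- color_distance(A, B); dAC <- color_distance(A, C)
  expect_equal(unname(lcs[1]), (w12 * dAB + w13 * dAC) / (w12 + w13),
               tolerance = 1e-12)
  expect_gt(w12 / (w12 + w13), 0.99)   # proximity weighting is decisive

  # disjoint single-bin histograms: pairwise chi-square term is 2
  h <- rbind(c(1, 0), c(0, 1))
  st4 <- spstats(color = matrix(runif(12), 2), pos = matrix(runif(4), 2), hist = h)
  expect_equal(color_histogram_contrast(st4), c(2, 2), tolerance = 1e-9)

  # same-colour pair: weighted mean is the midpoint, spread is |p1-p2|^2/4
  p1 <- c(0.2, 0.3); p2 <- c(0.6, 0.7)
  st5 <- spstats(color = matrix(0.5, 2, 6), pos = rbind(p1, p2))
  expect_equal(spatial_color_distribution(st5, 0.2),
               rep(sum((p1 - p2)^2) / 4, 2), tolerance = 1e-12)
})

test_that("spatial colour distribution is translation invariant and zero for a point mass", {
  st <- random_stats(8, seed = 99)
  shifted <- spstats(color = st$color, pos = sweep(st$pos, 2, c(0.07, -0.04), `+`),
                     hist = st$hist)
  expect_equal(spatial_color_distribution(st, 0.2),
               spatial_color_distribution(shifted, 0.2), tolerance = 1e-12)

  pt <- spstats(color = matrix(0.3, 4, 6),
                pos = matrix(rep(c(0.4, 0.6), each = 4), 4))
  expect_equal(spatial_color_distribution(pt, 0.2), rep(0, 4), tolerance = 1e-12)
})

test_that("features are equivariant under superpixel relabelling", {
  st <- random_stats(9, seed = 5)
  perm <- sample(9)
  stp <- spstats(color = st$color[perm, ], pos = st$pos[perm, ],
                 hist = st$hist[perm, ])
  f <- saliency_features(st, scale = FALSE)
  fp <- saliency_features(stp, scale = FALSE)
  expect_equal(as.matrix(fp), as.matrix(f)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("foreground superpixels are more spatially concentrated on phantoms", {
  ph <- fixture_compound()
  part <- fixture_partition()
  st <- fixture_spstats()
  f <- saliency_features(st)
  fg_union <- Reduce(`|`, ph$truth$slice_masks)
  frac <- vapply(seq_len(part$K), function(k) mean(fg_union[part$labels == k]), 0)
  expect_lt(mean(f$scd[frac >= 0.8]), mean(f$scd[frac <= 0.2]))
})
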