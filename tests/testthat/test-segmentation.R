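test_that("moving-average denoising is the truncated box mean", {
  img <- matrix(rnorm(30), 5, 6)
  expect_identical(moving_average_denoise(img, 1), img)
  flat <- matrix(5, 4, 4)
  expect_equal(moving_average_denoise(flat, 3), flat)
  centre <- matrix(0, 3, 3); centre[2, 2] <- 9
  expect_equal(moving_average_denoise(centre, 3)[2, 2], 1)
  # output range never exceeds the input range
  den <- moving_average_denoise(img, 3)
  expect_gte(min(den), min(img))
  expect_lte(max(den), max(img))
  expect_error(moving_average_denoise(img, 2), "odd")
})

test_that("membership update reproduces hand-computed values and its limiting conventions", {
  expect_identical(fcm_update_memberships(c(0.3, 0.9, 0.1), 0.5),
                   matrix(1, 1, 3))
  # equidistant pixel splits evenly regardless of fuzziness
  for (p in c(1.5, 2, 3)) {
    u <- fcm_update_memberships(5, c(0, 10), p)
    expect_equal(as.numeric(u), c(0.5, 0.5))
  }
  # hand evaluation: p = 2, i = 1, v = (0, 10); mu ∝ (1, 1/81)
  u <- fcm_update_memberships(1, c(0, 10), 2)
  expect_equal(as.numeric(u), c(81 / 82, 1 / 82), tolerance = 1e-12)
  expect_equal(round(as.numeric(u), 5), c(0.98780, 0.01220))
  # pixel coincident with a centroid is hard-assigned
  u0 <- fcm_update_memberships(c(0, 1), c(0, 10), 2)
  expect_identical(u0[, 1], c(1, 0))
})

test_that("centroid update reproduces hand-computed values and stays within the intensity range", {
  x <- c(0, 0, 10, 10)
  u_eq <- matrix(0.5, 2, 4)
  expect_equal(fcm_update_centroids(x, u_eq, 2), c(5, 5))
  u_hard <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(fcm_update_centroids(x, u_hard, 2), c(0, 10))
  # hand evaluation: p = 2, pixels (0, 1), mu = (0.8, 0.2)
  v <- fcm_update_centroids(c(0, 1), rbind(c(0.8, 0.2), c(0.2, 0.8)), 2)
  expect_equal(v[1], 0.04 / 0.68, tolerance = 1e-12)
  expect_equal(round(v[1], 5), 0.05882)

  set.seed(4)
  x <- runif(50)
  u <- fcm_update_memberships(x, c(0.2, 0.8), 2)
  v <- fcm_update_centroids(x, u, 2)
  expect_true(all(v >= min(x) & v <= max(x)))
})

test_that("spatial regularisation reproduces hand-computed values and repairs isolated pixels", {
  # equal memberships across clusters are a fixed point (h cancels)
  u_eq <- matrix(0.5, 2, 9)
  out_eq <- spatial_regularise(u_eq, c(3, 3), 3)
  expect_equal(out_eq$memberships, u_eq, tolerance = 1e-12)
  # spatially uniform but unequal memberships sharpen towards the
  # dominant cluster: (0.7, 0.3) -> (0.49, 0.09)/0.58 at every pixel,
  # border truncation cancelling in the normalisation
  u <- rbind(rep(0.7, 9), rep(0.3, 9))
  out <- spatial_regularise(u, c(3, 3), 3)
  expect_equal(out$memberships,
               rbind(rep(0.49, 9), rep(0.09, 9)) / 0.58,
               tolerance = 1e-12)

  # window of the pixel alone: mu = (0.8, 0.2) -> (0.64, 0.04)/0.68
  u1 <- matrix(c(0.8, 0.2), 2, 1)
  out1 <- spatial_regularise(u1, c(1, 1), 1)
  expect_equal(as.numeric(out1$memberships), c(0.64, 0.04) / 0.68,
               tolerance = 1e-9)
  expect_equal(round(as.numeric(out1$memberships), 5), c(0.94118, 0.05882))

  # a lone dissenter amid 8 confident neighbours flips its dominant label
  m1 <- matrix(0.9, 3, 3); m1[2, 2] <- 0.2
  u2 <- rbind(as.numeric(m1), 1 - as.numeric(m1))
  out2 <- spatial_regularise(u2, c(3, 3), 3)
  centre <- 5
  expect_gt(out2$memberships[1, centre], 0.5)
  expect_equal(colSums(out2$memberships), rep(1, 9), tolerance = 1e-12)
})

test_that("plain FCM matches a brute-force loop reference and its cost never increases", {
  set.seed(11)
  x <- runif(60)  # <= 64 pixels, as the oracle contract demands
  C <- 3; p <- 2
  v0 <- as.numeric(quantile(x, probs = (2 * seq_len(C) - 1) / (2 * C),
                            names = FALSE))
  ref <- fcm_oracle_iterate(x, v0, p, iterations = 15)
  v <- v0
  for (it in seq_len(15)) {
    u <- fcm_update_memberships(x, v, p)
    v <- fcm_update_centroids(x, u, p)
    expect_equal(u, ref[[it]]$memberships, tolerance = 1e-8)
    expect_equal(v, ref[[it]]$centroids, tolerance = 1e-8)
    expect_equal(fcm_cost(x, u, v, p), ref[[it]]$cost, tolerance = 1e-8)
  }
  costs <- vapply(ref, `[[`, numeric(1), "cost")
  expect_true(all(diff(costs) <= 1e-10))
})

test_that("fcm_segment recovers well-separated blocks and is deterministic", {
  img <- matrix(0, 8, 8); img[5:8, ] <- 100
  res <- fcm_segment(img, fcm_config(clusters = 2, spatial_window = 3))
  expect_true(res$state$converged)
  labs <- res$labels
  expect_identical(length(unique(as.integer(labs[1:4, ]))), 1L)
  expect_identical(length(unique(as.integer(labs[5:8, ]))), 1L)
  expect_false(labs[1, 1] == labs[8, 8])
  # centroids on the normalised scale sit at the block values within threshold
  expect_equal(sort(res$state$centroids), c(0, 1), tolerance = 0.02)

  res2 <- fcm_segment(img, fcm_config(clusters = 2, spatial_window = 3))
  expect_identical(res$state$centroids, res2$state$centroids)
  expect_identical(res$labels, res2$labels)

  res1 <- fcm_segment(img, fcm_config(clusters = 1))
  expect_identical(unique(as.integer(res1$labels)), 1L)
})

test_that("labels are invariant under increasing affine intensity rescaling", {
  set.seed(8)
  img <- matrix(runif(100), 10, 10)
  cfg <- fcm_config(clusters = 3)
  a <- fcm_segment(img, cfg)
  b <- fcm_segment(37 + 11 * img, cfg)
  expect_identical(a$labels, b$labels)
  expect_equal(a$state$centroids, b$state$centroids, tolerance = 1e-9)
})

test_that("spatial regularisation reduces isolated single-pixel label components on corrupted blocks", {
  # impulses pushed 60% towards the opposite block: wrong side of the
  # decision boundary, but fuzzy enough for one spatial pass to repair
  set.seed(13)
  img <- matrix(0, 20, 20); img[, 11:20] <- 1
  flip <- sample(length(img), 30)
  img[flip] <- img[flip] + 0.6 * (1 - 2 * img[flip])
  img <- img + rnorm(length(img), sd = 0.05)

  count_specks <- function(labels) {
    total <- 0
    for (lab in unique(as.integer(labels))) {
      cc <- EBImage::bwlabel(matrix(as.numeric(labels == lab),
                                    nrow(labels), ncol(labels)))
      sizes <- tabulate(as.integer(cc)[as.integer(cc) > 0])
      total <- total + sum(sizes == 1)
    }
    total
  }
  plain <- fcm_segment(img, fcm_config(clusters = 2, spatial_window = 0))
  spatial <- fcm_segment(img, fcm_config(clusters = 2, spatial_window = 3))
  expect_lt(count_specks(spatial$labels), count_specks(plain$labels))
})

test_that("morphological cleanup removes specks, fills pinholes, and leaves solid regions alone", {
  lab <- matrix(1L, 12, 12)
  lab[3:12, 2:11] <- 2L   # solid block (cluster 2)
  lab[1, 1] <- 2L          # isolated speck
  lab[7, 7] <- 1L          # interior pinhole
  m <- morphological_cleanup(lab, 2, open_radius = 1, close_radius = 1)
  expect_s3_class(m, "lesion_mask")
  expect_false(m$mask[1, 1])
  expect_true(m$mask[7, 7])
  expect_true(all(m$mask[4:11, 3:10]))

  solid <- matrix(1L, 10, 10); solid[3:8, 3:8] <- 2L
  m2 <- morphological_cleanup(solid, 2, open_radius = 1, close_radius = 0)
  expect_identical(m2$mask, solid == 2L)
  # radius 0 everywhere is the identity on the selected-cluster mask
  m3 <- morphological_cleanup(lab, 2, open_radius = 0, close_radius = 0)
  expect_identical(m3$mask, lab == 2L)
})

test_that("membership columns sum to one after both update stages on random images", {
  for (s in 1:25) {
    set.seed(s)
    img <- matrix(runif(64), 8, 8)
    v <- sort(runif(3))
    u <- fcm_update_memberships(img, v, 2)
    expect_equal(colSums(u), rep(1, 64), tolerance = 1e-9)
    u2 <- spatial_regularise(u, c(8, 8), 3)$memberships
    expect_equal(colSums(u2), rep(1, 64), tolerance = 1e-9)
  }
})
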