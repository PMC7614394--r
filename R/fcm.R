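#' Fuzzy c-means configuration
#'
#' @param clusters Number of clusters C (>= 1). Default 3: background /
#'   coupling fluid, normal tissue, high-echogenicity lesion.
#' @param fuzziness Fuzziness exponent p (> 1). Default 2.
#' @param spatial_window Odd edge length (pixels) of the spatial
#'   regularisation window; `0` disables the spatial step (plain FCM).
#'   Note a window of 1 is not the identity: it re-weights each pixel by
#'   its own membership. Default 3.
#' @param threshold Convergence threshold on the maximum centroid change
#'   between iterations, on the min-max normalised intensity scale.
#'   Default 0.02.
#' @param max_iterations Iteration cap. Default 100.
#' @param rng_seed Reserved for optional random restarts; initialisation
#'   is deterministic (intensity quantiles).
#' @return An object of class `fcm_config`.
#' @export
fcm_config <- function(clusters = 3, fuzziness = 2, spatial_window = 3,
                       threshold = 0.02, max_iterations = 100,
                       rng_seed = NULL) {
  stopifnot(clusters >= 1, fuzziness > 1, threshold > 0, max_iterations >= 1)
  if (spatial_window < 0 || (spatial_window > 0 && spatial_window %% 2 == 0))
    stop("spatial_window must be 0 (disabled) or an odd positive integer")
  structure(list(clusters = as.integer(clusters), fuzziness = fuzziness,
                 spatial_window = as.integer(spatial_window),
                 threshold = threshold,
                 max_iterations = as.integer(max_iterations),
                 rng_seed = rng_seed),
            class = "fcm_config")
}

# Windowed sums with border truncation: entry (i, j) is the sum of m over
# the k x k window centred there, clipped to the matrix. Summed-area
# construction, O(N).
box_sum <- function(m, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  r <- (k - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  i0 <- pmax(seq_len(nr) - r, 1L); i1 <- pmin(seq_len(nr) + r, nr)
  rows <- cs[i1 + 1L, , drop = FALSE] - cs[i0, , drop = FALSE]
  cs2 <- cbind(0, t(apply(rows, 1, cumsum)))
  j0 <- pmax(seq_len(nc) - r, 1L); j1 <- pmin(seq_len(nc) + r, nc)
  cs2[, j1 + 1L, drop = FALSE] - cs2[, j0, drop = FALSE]
}

# Number of in-image pixels in each truncated k x k window.
box_count <- function(nr, nc, k) {
  box_sum(matrix(1, nr, nc), k)
}

#' Moving-average denoising
#'
#' Uniform box filter with border truncation (each pixel is averaged over
#' the in-image part of its window), so a constant image is a fixed point
#' and the output range stays within the input range.
#'
#' @param image Numeric matrix.
#' @param kernel_edge Odd window edge length in pixels. `1` is the
#'   identity. Default 3.
#' @return Denoised matrix, same dimensions.
#' @export
moving_average_denoise <- function(image, kernel_edge = 3) {
  if (kernel_edge < 1 || kernel_edge %% 2 == 0)
    stop("configuration error: kernel_edge must be an odd integer >= 1")
  if (kernel_edge == 1) return(image)
  box_sum(image, kernel_edge) / box_count(nrow(image), ncol(image),
                                          kernel_edge)
}

#' FCM membership update
#'
#' For each pixel n and cluster m,
#' `mu_mn = |i_n - v_m|^(-2/(p-1)) / sum_k |i_n - v_k|^(-2/(p-1))`.
#' A pixel exactly equal to a centroid is hard-assigned to it (membership
#' 1, shared equally if several centroids coincide there), the limiting
#' convention of the update.
#'
#' @param image Numeric vector or matrix of pixel intensities.
#' @param centroids Numeric vector of cluster centroids (length C).
#' @param p Fuzziness exponent (> 1).
#' @return C x N membership matrix; every column sums to 1.
#' @export
fcm_update_memberships <- function(image, centroids, p = 2) {
  x <- as.numeric(image)
  C <- length(centroids)
  if (C == 1) return(matrix(1, 1, length(x)))
  d <- abs(outer(centroids, x, "-"))
  zero <- d == 0
  zero_col <- colSums(zero) > 0
  w <- d^(-2 / (p - 1))
  u <- sweep(w, 2, colSums(w), "/")
  if (any(zero_col)) {
    u[, zero_col] <- sweep(zero[, zero_col, drop = FALSE] * 1, 2,
                           colSums(zero[, zero_col, drop = FALSE]), "/")
  }
  u
}

#' FCM centroid update
#'
#' `v_m = sum_n mu_mn^p i_n / sum_n mu_mn^p`. A cluster whose total
#' p-weighted membership vanishes has no defined centroid; it is re-seeded
#' at the pixel intensity farthest from its nearest surviving centroid.
#'
#' @param image Numeric vector or matrix of pixel intensities.
#' @param memberships C x N membership matrix.
#' @param p Fuzziness exponent (> 1).
#' @return Numeric vector of C centroids, each within the intensity range.
#' @export
fcm_update_centroids <- function(image, memberships, p = 2) {
  x <- as.numeric(image)
  up <- memberships^p
  denom <- rowSums(up)
  v <- as.numeric(up %*% x) / denom
  dead <- denom < .Machine$double.eps * length(x)
  if (any(dead)) {
    for (m in which(dead)) {
      alive <- v[!dead]
      if (!length(alive)) alive <- mean(x)
      nearest <- vapply(x, function(xx) min(abs(xx - alive)), numeric(1))
      v[m] <- x[which.max(nearest)]
    }
  }
  v
}

#' Spatial membership regularisation
#'
#' Each pixel's memberships are re-weighted by the summed memberships of
#' its spatial neighbours: `h_mn = sum_{k in N_n} mu_mk` over the window
#' centred on pixel n (truncated at image borders), then
#' `mu'_mn = mu_mn h_mn / sum_k mu_kn h_kn`. Isolated misclassified pixels
#' are pulled towards the label of their neighbourhood; spatially uniform
#' memberships are unchanged.
#'
#' @param memberships C x N membership matrix.
#' @param image_dim `c(rows, cols)` of the underlying image.
#' @param spatial_window Odd window edge length in pixels.
#' @return List with `memberships` (the regularised C x N matrix, columns
#'   summing to 1) and `spatial_weights` (the C x N matrix of `h_mn`).
#' @export
spatial_regularise <- function(memberships, image_dim, spatial_window = 3) {
  stopifnot(spatial_window >= 1, spatial_window %% 2 == 1)
  C <- nrow(memberships)
  h <- memberships
  for (m in seq_len(C)) {
    h[m, ] <- as.numeric(box_sum(matrix(memberships[m, ], image_dim[1],
                                        image_dim[2]), spatial_window))
  }
  u <- memberships * h
  u <- sweep(u, 2, colSums(u), "/")
  list(memberships = u, spatial_weights = h)
}

#' FCM cost function
#'
#' `J = sum_n sum_m mu_mn^p |i_n - v_m|^2`, the p-weighted within-cluster
#' distance minimised by the alternating updates.
#'
#' @inheritParams fcm_update_centroids
#' @param centroids Numeric vector of C centroids.
#' @return Scalar cost.
#' @export
fcm_cost <- function(image, memberships, centroids, p = 2) {
  x <- as.numeric(image)
  d2 <- outer(centroids, x, "-")^2
  sum(memberships^p * d2)
}

#' Segment an image by spatially regularised fuzzy c-means
#'
#' Min-max normalises the image (so the convergence threshold is
#' scale-free), initialises centroids at evenly spaced intensity quantiles
#' (deterministic), then alternates membership update, spatial
#' regularisation (when enabled) and centroid update until the maximum
#' centroid change drops below the threshold or the iteration cap is hit.
#' Each pixel is finally labelled with its maximal (regularised)
#' membership.
#'
#' @param image Numeric matrix (typically the denoised dB M-mode image).
#' @param config An [fcm_config()].
#' @param normalise Min-max normalise intensities to `[0, 1]` before
#'   clustering (default `TRUE`); the threshold is interpreted on this
#'   scale.
#' @return A list with `state` (class `fcm_state`: `centroids` on the
#'   working intensity scale, `memberships`, `spatial_weights`, `cost`
#'   trajectory, `iterations`, `converged`) and `labels` (integer matrix
#'   of cluster assignments; clusters are ordered by increasing centroid
#'   at initialisation).
#' @export
fcm_segment <- function(image, config = fcm_config(), normalise = TRUE) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  x <- image
  if (normalise) {
    rng <- range(image)
    if (diff(rng) == 0) {
      # degenerate flat image: single effective cluster
      state <- structure(list(centroids = rep(0, config$clusters),
                              memberships = matrix(1 / config$clusters,
                                                   config$clusters,
                                                   length(image)),
                              spatial_weights = NULL, cost = 0,
                              iterations = 0L, converged = TRUE),
                         class = "fcm_state")
      return(list(state = state,
                  labels = matrix(1L, nrow(image), ncol(image))))
    }
    x <- (image - rng[1]) / diff(rng)
  }
  xv <- as.numeric(x)
  C <- config$clusters
  p <- config$fuzziness
  v <- as.numeric(stats::quantile(xv, probs = (2 * seq_len(C) - 1) / (2 * C),
                                  names = FALSE))
  # coincident centroids stall the membership update; nudge them apart
  eps <- 1e-6 * diff(range(xv))
  while (anyDuplicated(v)) v <- v + eps * (seq_len(C) - 1)

  cost <- numeric(0)
  u <- NULL; h <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    u <- fcm_update_memberships(xv, v, p)
    if (config$spatial_window > 0) {
      sp <- spatial_regularise(u, dim(image), config$spatial_window)
      u <- sp$memberships
      h <- sp$spatial_weights
    }
    v_new <- fcm_update_centroids(xv, u, p)
    cost <- c(cost, fcm_cost(xv, u, v_new, p))
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < config$threshold) {
      converged <- TRUE
      break
    }
  }

  labels <- matrix(max.col(t(u), ties.method = "first"),
                   nrow(image), ncol(image))
  state <- structure(list(centroids = v, memberships = u,
                          spatial_weights = h, cost = cost,
                          iterations = iter, converged = converged),
                     class = "fcm_state")
  list(state = state, labels = labels)
}

#' Morphological cleanup of a cluster label map
#'
#' Binary mask of the selected cluster(s), opened then closed with a
#' square structuring element: opening removes components smaller than the
#' element, closing fills comparably small holes.
#'
#' @param label_map Integer matrix of cluster labels.
#' @param selected_clusters Cluster label(s) forming the ablation region
#'   (typically the highest-centroid cluster).
#' @param open_radius,close_radius Structuring-element radii in pixels
#'   (edge `2 r + 1`); `0` skips the operation. Defaults 1.
#' @return An object of class `lesion_mask`: `mask` (logical matrix) and
#'   `cluster_label_map`.
#' @export
morphological_cleanup <- function(label_map, selected_clusters,
                                  open_radius = 1, close_radius = 1) {
  stopifnot(open_radius >= 0, close_radius >= 0)
  mask <- matrix(as.numeric(label_map %in% selected_clusters),
                 nrow(label_map), ncol(label_map))
  if (open_radius > 0) {
    mask <- EBImage::opening(mask,
                             EBImage::makeBrush(2 * open_radius + 1, "box"))
  }
  if (close_radius > 0) {
    mask <- EBImage::closing(mask,
                             EBImage::makeBrush(2 * close_radius + 1, "box"))
  }
  structure(list(mask = matrix(as.numeric(mask) > 0.5,
                               nrow(label_map), ncol(label_map)),
                 cluster_label_map = label_map),
            class = "lesion_mask")
}

#' Segment the ablation lesion on an M-mode image
#'
#' The full segmentation chain: moving-average denoising, spatially
#' regularised FCM, selection of the highest-centroid (most echogenic)
#' cluster, and morphological opening/closing.
#'
#' @param mmode An `mmode_image` from [process_sequence()].
#' @param config An [fcm_config()].
#' @param denoise_kernel Moving-average kernel edge (odd). Default 3.
#' @param open_radius,close_radius See [morphological_cleanup()].
#' @return A list with `mask` (a `lesion_mask`), `fcm` (the
#'   [fcm_segment()] result) and `lesion_cluster` (the selected label).
#' @export
segment_lesion <- function(mmode, config = fcm_config(),
                           denoise_kernel = 3,
                           open_radius = 1, close_radius = 1) {
  den <- moving_average_denoise(mmode$image, denoise_kernel)
  res <- fcm_segment(den, config)
  lesion_cluster <- which.max(res$state$centroids)
  mask <- morphological_cleanup(res$labels, lesion_cluster,
                                open_radius, close_radius)
  list(mask = mask, fcm = res, lesion_cluster = lesion_cluster)
}
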