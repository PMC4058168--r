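#' Spatial texture features of a grayscale frame
#'
#' Computes three per-pixel texture features over a square neighborhood:
#' the mean, the population standard deviation, and the Shannon entropy
#' (in bits, over a fixed 16-bin intensity histogram of the window).
#' Borders are handled by symmetric (reflected) padding.
#'
#' @param frame Numeric matrix with values in `[0, 1]`.
#' @param window Odd window side length in pixels (>= 3).
#' @return A `height x width x 3` array with slices `"mean"`, `"sd"` and
#'   `"entropy"`.
#' @export
#' @examples
#' f <- matrix(0.5, 32, 32)
#' sf <- compute_spatial_features(f, window = 9)
#' range(sf[, , "sd"])
compute_spatial_features <- function(frame, window = 9L) {
  stopifnot(is.matrix(frame))
  window <- as.integer(window)
  if (window < 3L || !is_odd(window))
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  if (min(frame) < 0 || max(frame) > 1)
    stop("`frame` values must lie in [0, 1]", call. = FALSE)
  H <- nrow(frame); W <- ncol(frame)
  p <- (window - 1L) %/% 2L
  if (p >= H || p >= W)
    stop("`window` is too large for the frame", call. = FALSE)
  P <- pad_symmetric(frame, p)
  n <- window^2
  s1 <- box_sum(P, window, H, W)
  s2 <- box_sum(P^2, window, H, W)
  mu <- s1 / n
  v <- pmax(s2 / n - mu^2, 0)
  sdv <- sqrt(v)

  # 16-bin histogram entropy per window
  bins <- pmin(floor(P * 16) + 1L, 16L)
  ent <- matrix(0, H, W)
  for (bnum in 1:16) {
    cnt <- box_sum((bins == bnum) * 1, window, H, W)
    pr <- cnt / n
    nz <- pr > 0
    ent[nz] <- ent[nz] - pr[nz] * log2(pr[nz])
  }
  array(c(mu, sdv, ent), dim = c(H, W, 3),
        dimnames = list(NULL, NULL, c("mean", "sd", "entropy")))
}

#' Per-pixel temporal standard deviation of a sequence
#'
#' The population standard deviation of each pixel's intensity across all
#' frames — the temporal feature that singles out the moving vessel wall
#' among otherwise similar-looking static structures.
#'
#' @param sequence An [ultrasound_sequence()] or a 3D array
#'   `height x width x n_frames`.
#' @return Numeric matrix `height x width`.
#' @export
compute_temporal_std <- function(sequence) {
  frames <- if (inherits(sequence, "ultrasound_sequence")) sequence$frames
            else sequence
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  d <- dim(frames)
  if (d[3] < 2)
    stop("temporal standard deviation needs at least 2 frames", call. = FALSE)
  m <- matrix(frames, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  v <- pmax(rowMeans(m^2) - mu^2, 0)
  matrix(sqrt(v), d[1], d[2])
}

# Pixel-wise temporal median frame, used as the sequence's reference frame.
temporal_median <- function(sequence) {
  frames <- if (inherits(sequence, "ultrasound_sequence")) sequence$frames
            else sequence
  d <- dim(frames)
  m <- matrix(frames, d[1] * d[2], d[3])
  matrix(apply(m, 1, median), d[1], d[2])
}

#' K-means segmentation of a per-pixel feature image
#'
#' Z-scores each feature channel, then clusters pixels with k-means
#' (multiple restarts, best within-cluster sum of squares kept). The result
#' is deterministic for a given seed.
#'
#' @param features Array `height x width x n_features` (or a matrix for a
#'   single feature).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart Number of random restarts.
#' @return Integer label matrix `height x width` with values in `1:k`.
#' @export
kmeans_segment <- function(features, k = 3L, seed = 1L, nstart = 10L) {
  if (is.matrix(features)) features <- array(features, c(dim(features), 1))
  stopifnot(is.array(features), length(dim(features)) == 3)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  d <- dim(features)
  X <- matrix(features, d[1] * d[2], d[3])
  for (j in seq_len(ncol(X))) {
    s <- sd(X[, j])
    X[, j] <- if (s > 0) (X[, j] - mean(X[, j])) / s else X[, j] - mean(X[, j])
  }
  if (nrow(unique(X)) < k)
    stop("fewer distinct feature vectors than clusters", call. = FALSE)
  if (k == 1L) return(matrix(1L, d[1], d[2]))
  km <- with_seed(seed,
                  kmeans(X, centers = k, nstart = nstart, iter.max = 100))
  matrix(as.integer(km$cluster), d[1], d[2])
}

#' Select the moving vessel-wall cluster
#'
#' Among clusters whose mean intensity feature exceeds the global median
#' (the visibility guard — the wall is the *most visible* structure), picks
#' the one with the largest mean temporal standard deviation (the *most
#' dynamic* structure). The selected cluster is morphologically closed and
#' reduced to its largest 4-connected component.
#'
#' @param labels Integer label matrix from [kmeans_segment()].
#' @param temporal_std Matrix from [compute_temporal_std()], same shape.
#' @param intensity Matrix of the mean-intensity feature channel, same
#'   shape (slice `"mean"` of [compute_spatial_features()]).
#' @param min_dynamism Minimum mean temporal standard deviation of the
#'   winning cluster; below it the scene is considered static and a
#'   `cartwave_no_wall` error is raised.
#' @return Logical wall mask matrix.
#' @export
select_wall <- function(labels, temporal_std, intensity,
                        min_dynamism = 1e-3) {
  stopifnot(is.matrix(labels),
            all(dim(labels) == dim(temporal_std)),
            all(dim(labels) == dim(intensity)))
  ks <- sort(unique(as.vector(labels)))
  mtsd <- vapply(ks, function(kk) mean(temporal_std[labels == kk]), 0)
  mint <- vapply(ks, function(kk) mean(intensity[labels == kk]), 0)
  visible <- mint > median(intensity)
  if (!any(visible))
    stop_cartwave("no cluster passes the visibility guard; no wall found",
                  "cartwave_no_wall")
  cand <- ks[visible]
  pick <- cand[which.max(mtsd[visible])]
  if (mtsd[match(pick, ks)] < min_dynamism)
    stop_cartwave("scene appears static (temporal variation below threshold); no wall found",
                  "cartwave_no_wall")
  mask <- labels == pick
  mask <- close_mask(mask, 3L)
  largest_component4(mask)
}

# Refine a temporally-derived wall mask to the reference frame. The cluster
# mask covers the whole region swept by the moving wall; the wall band *at
# the reference frame* is its bright core. Otsu-threshold the reference
# intensities inside the mask, then fill each column between its outermost
# bright rows (the band is vertically contiguous, so this bridges the darker
# media line between the intima and adventitia echoes). Falls back to the
# unrefined mask when thresholding keeps too little of it to be credible.
refine_wall_mask <- function(mask, reference, min_keep = 0.25) {
  vals <- reference[mask]
  if (length(vals) == 0) return(mask)
  th <- otsu_threshold(clamp01(vals))
  bright <- mask & (reference >= th)
  if (sum(bright) < min_keep * sum(mask)) return(mask)
  filled <- matrix(FALSE, nrow(mask), ncol(mask))
  for (j in seq_len(ncol(mask))) {
    r <- which(bright[, j])
    if (length(r)) filled[r[1]:r[length(r)], j] <- TRUE
  }
  filled <- filled & mask
  largest_component4(filled)
}

#' Segment the moving vessel wall of a sequence
#'
#' Full segmentation stage: computes the three spatial texture features on
#' the temporal-median reference frame, adds the per-pixel temporal standard
#' deviation as a fourth feature, clusters with k-means (`k = 3` by
#' default), and selects the most visible, most dynamic cluster as the wall.
#' Because the temporal features mark the whole region swept by the moving
#' wall, the selected cluster is finally refined to the wall band at the
#' reference frame by intensity thresholding within the cluster.
#'
#' @param sequence An [ultrasound_sequence()].
#' @param window Odd spatial feature window (pixels).
#' @param k Number of k-means classes.
#' @param seed Integer seed for k-means restarts.
#' @param min_dynamism Passed to [select_wall()].
#' @return An object of class `wall_segmentation` with elements `labels`,
#'   `wall_mask`, `k`, `cluster_dynamism` (per-cluster mean temporal
#'   standard deviation), `reference` (the median frame), `temporal_std`
#'   and `window`.
#' @export
segment_wall <- function(sequence, window = 9L, k = 3L, seed = 1L,
                         min_dynamism = 1e-3) {
  stopifnot(inherits(sequence, "ultrasound_sequence"))
  reference <- temporal_median(sequence)
  spatial <- compute_spatial_features(reference, window = window)
  tstd <- compute_temporal_std(sequence)
  feats <- array(c(spatial, tstd), dim = c(dim(reference), 4),
                 dimnames = list(NULL, NULL,
                                 c("mean", "sd", "entropy", "temporal_std")))
  labels <- kmeans_segment(feats, k = k, seed = seed)
  ks <- sort(unique(as.vector(labels)))
  dyn <- vapply(ks, function(kk) mean(tstd[labels == kk]), 0)
  wall <- select_wall(labels, tstd, spatial[, , "mean"],
                      min_dynamism = min_dynamism)
  wall <- refine_wall_mask(wall, reference)
  structure(list(labels = labels, wall_mask = wall, k = k,
                 cluster_dynamism = stats::setNames(dyn, ks),
                 reference = reference, temporal_std = tstd,
                 window = window),
            class = "wall_segmentation")
}

#' @export
print.wall_segmentation <- function(x, ...) {
  cat(sprintf("<wall_segmentation> %d classes; wall mask %d px (%.1f%% of frame)\n",
              x$k, sum(x$wall_mask),
              100 * mean(x$wall_mask)))
  invisible(x)
}
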