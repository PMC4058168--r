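# Internal helpers shared across the pipeline.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Error with a condition class so callers can distinguish pipeline failures
# (e.g. no moving wall found) from programming errors.
stop_cartwave <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cartwave_error")))
}

is_odd <- function(x) (x %% 2) == 1

# Label 4-connected foreground components of a logical matrix.
# Returns an integer matrix (0 = background).
label_components4 <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  visited <- !mask  # treat background as visited
  seeds <- which(mask)
  cur <- 0L
  for (s in seeds) {
    if (visited[s]) next
    cur <- cur + 1L
    frontier <- s
    visited[s] <- TRUE
    lab[s] <- cur
    while (length(frontier)) {
      r <- ((frontier - 1L) %% H) + 1L
      up    <- frontier[r > 1L] - 1L
      down  <- frontier[r < H] + 1L
      left  <- frontier[frontier > H] - H
      right <- frontier[frontier <= (W - 1L) * H] + H
      cand <- c(up, down, left, right)
      cand <- cand[!visited[cand]]
      cand <- unique(cand)
      if (length(cand)) {
        visited[cand] <- TRUE
        lab[cand] <- cur
        frontier <- cand
      } else {
        frontier <- integer(0)
      }
    }
  }
  lab
}

largest_component4 <- function(mask) {
  lab <- label_components4(mask)
  if (!any(lab > 0L)) return(mask & FALSE)
  tab <- tabulate(lab)
  lab == which.max(tab)
}

# Morphological closing of a binary mask with a square box brush.
close_mask <- function(mask, size = 3L) {
  out <- EBImage::closing(mask * 1, EBImage::makeBrush(size, shape = "box"))
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

# Box-filter statistics over a square window with symmetric (reflected edge)
# padding, computed with integral images.
pad_symmetric <- function(mat, p) {
  H <- nrow(mat); W <- ncol(mat)
  ri <- c(p:1, 1:H, H:(H - p + 1))
  ci <- c(p:1, 1:W, W:(W - p + 1))
  mat[ri, ci, drop = FALSE]
}

box_sum <- function(padded, window, H, W) {
  # padded is (H + window - 1) x (W + window - 1)
  I <- apply(padded, 2, cumsum)
  I <- t(apply(I, 1, cumsum))
  I <- rbind(0, cbind(0, I))
  w <- window
  I[(1:H) + w, (1:W) + w, drop = FALSE] -
    I[1:H, (1:W) + w, drop = FALSE] -
    I[(1:H) + w, 1:W, drop = FALSE] +
    I[1:H, 1:W, drop = FALSE]
}

# Otsu's threshold of a numeric vector of intensities in [0, 1]: the 256-bin
# histogram cut maximizing the between-class variance (lowest cut on ties).
otsu_threshold <- function(x, levels = 256L) {
  stopifnot(length(x) > 0, min(x) >= 0, max(x) <= 1)
  bins <- pmin(floor(x * levels) + 1L, levels)
  h <- tabulate(bins, nbins = levels)
  p <- h / sum(h)
  centers <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)
  m0 <- cumsum(p * centers)
  mt <- m0[levels]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, levels)
  bc[ok] <- (mt * w0[ok] - m0[ok])^2 / (w0[ok] * w1[ok])
  centers[which.max(bc)] + 0.5 / levels
}
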