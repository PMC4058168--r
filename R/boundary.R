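#' Boundary track constructor
#'
#' Low-level constructor for a per-frame, per-column track of the inner
#' (lumen-facing) wall boundary. Rows are continuous coordinates: the value
#' `v` marks the interface between pixel rows `v` and `v + 1`.
#'
#' @param rows Numeric matrix `n_frames x n_columns` of boundary rows.
#' @param columns Integer vector of absolute image column indices
#'   (contiguous), one per column of `rows`.
#' @param lumen_side `"above"` or `"below"`: which side of the wall the
#'   lumen lies on.
#' @param valid_range Length-2 integer vector: first and last index (into
#'   `columns`) of the contiguous run of reliable columns. Defaults to the
#'   full range.
#' @param detected_rate Optional per-column fraction of frames in which the
#'   boundary was located directly (not interpolated).
#' @return An object of class `boundary_track`.
#' @export
boundary_track <- function(rows, columns = seq_len(ncol(rows)),
                           lumen_side = c("above", "below"),
                           valid_range = c(1L, ncol(rows)),
                           detected_rate = NULL) {
  stopifnot(is.matrix(rows), length(columns) == ncol(rows))
  lumen_side <- match.arg(lumen_side)
  if (valid_range[1] > valid_range[2])
    stop_cartwave("boundary track has no valid columns", "cartwave_no_boundary")
  if (any(!is.finite(rows[, valid_range[1]:valid_range[2]])))
    stop("boundary rows must be finite within the valid range", call. = FALSE)
  structure(list(rows = rows, columns = as.integer(columns),
                 lumen_side = lumen_side,
                 valid_range = as.integer(valid_range),
                 detected_rate = detected_rate),
            class = "boundary_track")
}

#' @export
print.boundary_track <- function(x, ...) {
  cat(sprintf("<boundary_track> %d frames x %d columns (lumen %s), %d valid columns\n",
              nrow(x$rows), ncol(x$rows), x$lumen_side,
              diff(x$valid_range) + 1L))
  invisible(x)
}

valid_length <- function(track) diff(track$valid_range) + 1L

#' Track the inner wall boundary with sub-pixel precision
#'
#' Isolates the section of the vessel wall in contact with the blood flow.
#' The lumen side is the side of the wall mask with the lower mean intensity
#' in the reference frame. Per frame and column, the boundary is located as
#' the half-maximum crossing of the intensity profile moving from lumen into
#' wall, searched within one wall-thickness of the reference mask edge;
#' sub-pixel position comes from linear interpolation between pixel centers.
#' Columns (or frames) with no crossing are filled by linear interpolation
#' from their neighbors. The valid region is the largest contiguous run of
#' columns in which at least `min_detect` of the frames gave a direct
#' detection.
#'
#' @param wall_mask Logical wall mask (e.g. from [segment_wall()]).
#' @param sequence The [ultrasound_sequence()].
#' @param reference Optional reference frame (defaults to the temporal
#'   median of the sequence).
#' @param min_detect Minimum direct-detection fraction for a valid column.
#' @return A [boundary_track()].
#' @export
extract_inner_boundary <- function(wall_mask, sequence, reference = NULL,
                                   min_detect = 0.9) {
  stopifnot(is.matrix(wall_mask))
  if (!any(wall_mask))
    stop("`wall_mask` is empty", call. = FALSE)
  stopifnot(inherits(sequence, "ultrasound_sequence"),
            all(dim(wall_mask) == dim(sequence$frames)[1:2]))
  if (is.null(reference)) reference <- temporal_median(sequence)
  H <- nrow(wall_mask); W <- ncol(wall_mask)
  Tn <- n_frames(sequence)

  colHas <- which(colSums(wall_mask) > 0)
  j1 <- min(colHas); j2 <- max(colHas)
  cols <- j1:j2
  nc <- length(cols)

  top <- rep(NA_real_, nc); bot <- rep(NA_real_, nc)
  for (i in seq_len(nc)) {
    r <- which(wall_mask[, cols[i]])
    if (length(r)) { top[i] <- min(r); bot[i] <- max(r) }
  }

  # lumen side: lower mean reference intensity above vs below the mask band
  rtop <- floor(min(top, na.rm = TRUE)); rbot <- ceiling(max(bot, na.rm = TRUE))
  above <- if (rtop > 1) mean(reference[1:(rtop - 1), cols]) else Inf
  below <- if (rbot < H) mean(reference[(rbot + 1):H, cols]) else Inf
  lumen_side <- if (above <= below) "above" else "below"

  wt <- max(3, round(median(bot - top + 1, na.rm = TRUE)))
  r0 <- if (lumen_side == "above") top else bot
  if (anyNA(r0)) {
    known <- which(!is.na(r0))
    r0 <- approx(known, r0[known], xout = seq_len(nc), rule = 2)$y
  }
  r0 <- round(r0)

  # oriented sample rows: first row is at the lumen end of the search window
  offs <- -wt:wt
  dir <- if (lumen_side == "above") 1 else -1
  rowIdx <- outer(dir * offs, r0, "+")       # (2wt+1) x nc
  rowIdx <- pmin(pmax(rowIdx, 1L), H)
  nr <- nrow(rowIdx)
  colIdx <- matrix(cols, nr, nc, byrow = TRUE)
  flat <- cbind(as.vector(rowIdx), as.vector(colIdx))

  rows <- matrix(NA_real_, Tn, nc)
  detected <- matrix(FALSE, Tn, nc)
  for (f in seq_len(Tn)) {
    fr <- sequence$frames[, , f]
    P <- matrix(fr[flat], nr, nc)
    i_lum <- colMeans(P[1:3, , drop = FALSE])
    i_wall <- do.call(pmax, c(lapply(seq_len(nr), function(i) P[i, ]),
                              list(na.rm = TRUE)))
    half <- (i_lum + i_wall) / 2
    belowH <- sweep(P, 2, half, "<")
    crossing <- belowH[-nr, , drop = FALSE] & !belowH[-1, , drop = FALSE]
    pos <- which(crossing, arr.ind = TRUE)
    if (nrow(pos)) {
      o <- order(pos[, 2], pos[, 1])
      keep <- !duplicated(pos[o, 2])
      jj <- pos[o, 2][keep]
      i0 <- pos[o, 1][keep]
      p0 <- P[cbind(i0, jj)]
      p1 <- P[cbind(i0 + 1L, jj)]
      den <- p1 - p0
      fracs <- ifelse(den > 1e-12, (half[jj] - p0) / den, 0.5)
      # continuous image row (pixel-center units) of the half-max crossing;
      # the interface coordinate is 0.5 below it for either scan direction
      rc <- rowIdx[cbind(i0, jj)] + dir * fracs
      rows[f, jj] <- rc - 0.5
      detected[f, jj] <- TRUE
    }
    # fill gaps within this frame by linear interpolation across columns
    miss <- is.na(rows[f, ])
    if (any(miss)) {
      known <- which(!miss)
      if (length(known) >= 2) {
        rows[f, miss] <- approx(known, rows[f, known],
                                xout = which(miss), rule = 2)$y
      } else if (length(known) == 1) {
        rows[f, miss] <- rows[f, known]
      } else {
        rows[f, ] <- r0[1]  # degenerate frame: fall back to reference edge
      }
    }
  }

  rate <- colMeans(detected)
  ok <- rate >= min_detect
  vr <- longest_true_run(ok)
  if (is.null(vr))
    stop_cartwave("no contiguous run of reliably detected boundary columns",
                  "cartwave_no_boundary")
  boundary_track(rows, columns = cols, lumen_side = lumen_side,
                 valid_range = vr, detected_rate = rate)
}

# First and last index of the longest run of TRUE values, or NULL.
longest_true_run <- function(x) {
  r <- rle(x)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  c(starts[i], ends[i])
}

#' Assign midway-overlapping ROIs along the wall
#'
#' Places regions of interest of width `w` columns along the valid part of a
#' boundary track such that consecutive ROIs overlap by half their width
#' ("midway"). The number of ROIs is `R = floor((L - w) / (w / 2)) + 1` for
#' a usable length of `L` columns; trailing columns that do not fill a whole
#' ROI are dropped.
#'
#' @param track A [boundary_track()].
#' @param roi_width Even ROI width in columns (`4 <= w <= L`). `NULL`
#'   chooses the largest even width yielding about `target_rois` ROIs.
#' @param target_rois Desired ROI count used when `roi_width` is `NULL`.
#' @return An object of class `roi_set` with elements `width`, `starts`
#'   (indices into the track's valid columns, 1-based), `starts_abs`
#'   (absolute image columns) and `n_rois`.
#' @export
#' @examples
#' tr <- boundary_track(matrix(10, 16, 100))
#' assign_rois(tr, roi_width = 20)$n_rois  # 9
assign_rois <- function(track, roi_width = NULL, target_rois = 16L) {
  stopifnot(inherits(track, "boundary_track"))
  L <- valid_length(track)
  if (is.null(roi_width)) {
    roi_width <- max(4L, 2L * (L %/% (target_rois + 1L)))
    roi_width <- min(roi_width, 2L * (L %/% 2L))
  }
  w <- as.integer(roi_width)
  if (w %% 2L != 0L) stop("`roi_width` must be even", call. = FALSE)
  if (w < 4L) stop("`roi_width` must be at least 4", call. = FALSE)
  if (w > L)
    stop("`roi_width` exceeds the number of valid columns", call. = FALSE)
  starts <- seq.int(1L, L - w + 1L, by = w %/% 2L)
  abs_start <- track$columns[track$valid_range[1]] + starts - 1L
  structure(list(width = w, starts = as.integer(starts),
                 starts_abs = as.integer(abs_start),
                 n_rois = length(starts)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs of width %d columns (midway overlap)\n",
              x$n_rois, x$width))
  invisible(x)
}

#' Extract per-ROI radial distension signals
#'
#' For each ROI and frame, the radial distension is the mean boundary row
#' over the ROI's columns, sign-oriented so that motion toward the lumen is
#' positive, with the per-ROI temporal mean removed.
#'
#' @param track A [boundary_track()].
#' @param rois A [roi_set()][assign_rois()].
#' @return Numeric matrix `n_frames x n_rois` of class `radial_signals`
#'   (zero temporal mean per column), with the ROI set and lumen side kept
#'   as attributes.
#' @export
extract_radial_signals <- function(track, rois) {
  stopifnot(inherits(track, "boundary_track"), inherits(rois, "roi_set"))
  v0 <- track$valid_range[1]
  sgn <- if (track$lumen_side == "above") -1 else 1
  sig <- vapply(rois$starts, function(s) {
    idx <- (v0 + s - 1L):(v0 + s + rois$width - 2L)
    rowMeans(track$rows[, idx, drop = FALSE])
  }, numeric(nrow(track$rows)))
  sig <- sgn * sig
  sig <- sweep(sig, 2, colMeans(sig))
  structure(sig, class = c("radial_signals", "matrix"),
            rois = rois, lumen_side = track$lumen_side)
}
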