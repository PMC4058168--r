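#' Analyze carotid wall motion in an ultrasound sequence
#'
#' The end-to-end pipeline: wall segmentation (texture + temporal features,
#' k-means), sub-pixel inner-boundary tracking, assignment of
#' midway-overlapping ROIs, radial-distension signal extraction, assembly of
#' the spatiotemporal and spatiospectral 2D maps, spectral homogeneity
#' feature computation and (optionally) the threshold-based class call.
#'
#' @param x An [ultrasound_sequence()], a `cartwave_phantom` from
#'   [generate_phantom()], or a path accepted by [read_sequence()].
#' @param ecg Optional `ecg_trace` (taken from the phantom automatically).
#' @param window Spatial feature window (odd pixels).
#' @param k Number of k-means classes.
#' @param roi_width Even ROI width in columns; `NULL` for automatic.
#' @param seed Integer seed driving k-means restarts.
#' @param config `NULL` to skip classification, or a [classifier_config()].
#' @param verbose Print per-stage progress.
#' @return An object of class `cartwave_case` bundling all stage outputs:
#'   `segmentation`, `track`, `rois`, `signals`, `st_map`, `ss_map`,
#'   `features`, `call` (or `NULL`), `params` and `provenance`.
#' @export
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_config("young", seed = 1))
#' res <- cartwave(ph)
#' res$features$ft2_area
#' }
cartwave <- function(x, ecg = NULL, window = 9L, k = 3L, roi_width = NULL,
                     seed = 1L, config = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  if (is.character(x)) x <- read_sequence(x)
  if (inherits(x, "cartwave_phantom")) {
    if (is.null(ecg)) ecg <- x$ecg
    x <- x$sequence
  }
  stopifnot(inherits(x, "ultrasound_sequence"))
  stage <- function(name, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    if (verbose)
      message(sprintf("[%s] %.2fs", name,
                      as.numeric(Sys.time() - st, units = "secs")))
    out
  }
  seg <- stage("segment", segment_wall(x, window = window, k = k, seed = seed))
  track <- stage("boundary",
                 extract_inner_boundary(seg$wall_mask, x,
                                        reference = seg$reference))
  rois <- stage("rois", assign_rois(track, roi_width = roi_width))
  sig <- stage("signals", extract_radial_signals(track, rois))
  st_map <- stage("st_map",
                  build_spatiotemporal(sig, frame_rate = x$frame_rate,
                                       ecg = ecg))
  ss_map <- stage("ss_map", build_spatiospectral(st_map))
  feats <- stage("features", case_features(ss_map))
  call_ <- if (!is.null(config)) stage("classify", call_case(feats, config))
           else NULL
  params <- list(window = window, k = k,
                 roi_width = rois$width, seed = seed)
  structure(list(segmentation = seg, track = track, rois = rois,
                 signals = sig, st_map = st_map, ss_map = ss_map,
                 features = feats, call = call_,
                 params = params,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("cartwave")),
                   params_hash = params_hash(params),
                   elapsed_s = as.numeric(Sys.time() - t0, units = "secs"),
                   timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))),
            class = "cartwave_case")
}

# MD5 of the canonical JSON encoding of the parameter list.
params_hash <- function(params) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(params, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' @export
print.cartwave_case <- function(x, ...) {
  cat("<cartwave_case>\n")
  cat(sprintf("  %d frames, %d ROIs (width %d)\n",
              nrow(x$st_map$values), x$rois$n_rois, x$rois$width))
  cat(sprintf("  ft2_area %.3f | ramp_feature %.3f\n",
              x$features$ft2_area, x$features$ramp_feature))
  if (!is.null(x$call)) cat(sprintf("  call: %s\n", x$call$label))
  invisible(x)
}

#' @export
summary.cartwave_case <- function(object, ...) {
  x <- object
  cat("Carotid wall motion analysis\n")
  cat(sprintf("  wall mask: %d px; boundary valid columns: %d (lumen %s)\n",
              sum(x$segmentation$wall_mask), valid_length(x$track),
              x$track$lumen_side))
  cat(sprintf("  ROIs: %d of width %d columns, midway overlap\n",
              x$rois$n_rois, x$rois$width))
  print(x$features)
  if (!is.null(x$call)) print(x$call)
  invisible(x)
}

#' @export
plot.cartwave_case <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(x$st_map)
  plot(x$ss_map)
  invisible(x)
}
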