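#' Read an ultrasound sequence from disk
#'
#' Reads either a directory of same-shaped grayscale PNG frames (in
#' lexicographic order) or a multi-page TIFF. Multi-channel frames are
#' averaged to grayscale; 8-bit intensities are scaled to `[0, 1]` by the
#' PNG/TIFF readers. The frame rate is taken from a `meta.json` sidecar
#' (key `frame_rate`) when present.
#'
#' @param path Directory of PNG frames or path to a multi-page TIFF.
#' @param frame_rate Frame rate override; `NULL` uses the sidecar or 30.
#' @return An [ultrasound_sequence()].
#' @export
read_sequence <- function(path, frame_rate = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 8)
      stop("fewer than 8 PNG frames found", call. = FALSE)
    imgs <- lapply(files, png::readPNG)
    meta <- file.path(path, "meta.json")
    if (is.null(frame_rate) && file.exists(meta)) {
      m <- jsonlite::read_json(meta)
      if (!is.null(m$frame_rate)) frame_rate <- m$frame_rate
    }
  } else if (file.exists(path)) {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    if (length(imgs) < 8)
      stop("fewer than 8 TIFF pages found", call. = FALSE)
  } else {
    stop(sprintf("'%s' does not exist", path), call. = FALSE)
  }
  imgs <- lapply(imgs, function(im) {
    if (length(dim(im)) == 3) {
      nch <- min(dim(im)[3], 3)
      im <- apply(im[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
    }
    im
  })
  d1 <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(im) identical(dim(im), d1), TRUE)))
    stop_cartwave("frames have mixed shapes", "cartwave_format_error")
  frames <- array(unlist(imgs), dim = c(d1, length(imgs)))
  ultrasound_sequence(frames, frame_rate = frame_rate %||% 30)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ultrasound sequence (and phantom sidecars) to a directory
#'
#' Writes frames as `frame_%04d.png` plus `meta.json`. For a phantom,
#' `ecg.csv` (frame, amplitude), `truth_boundary.csv` (frame, column, row)
#' and `config.json` are written alongside.
#'
#' @param x An [ultrasound_sequence()] or a `cartwave_phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqn <- if (inherits(x, "cartwave_phantom")) x$sequence else x
  stopifnot(inherits(seqn, "ultrasound_sequence"))
  Tn <- n_frames(seqn)
  for (f in seq_len(Tn)) {
    png::writePNG(seqn$frames[, , f],
                  target = file.path(dir, sprintf("frame_%04d.png", f)))
  }
  jsonlite::write_json(list(frame_rate = seqn$frame_rate),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  if (inherits(x, "cartwave_phantom")) {
    write.csv(data.frame(frame = seq_len(Tn), amplitude = x$ecg$samples),
              file.path(dir, "ecg.csv"), row.names = FALSE)
    b <- x$truth$boundary
    write.csv(data.frame(frame = rep(seq_len(nrow(b)), ncol(b)),
                         column = rep(seq_len(ncol(b)), each = nrow(b)),
                         row = as.vector(b)),
              file.path(dir, "truth_boundary.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(x$config),
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

# Matrix <-> CSV helpers (rows = time or frequency, columns = ROIs).
write_map_csv <- function(map, file) {
  v <- if (is.matrix(map)) map else map$values
  colnames(v) <- sprintf("roi_%d", seq_len(ncol(v)))
  write.csv(v, file, row.names = FALSE)
  invisible(file)
}

read_map_csv <- function(file) {
  as.matrix(read.csv(file, check.names = FALSE))
}
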