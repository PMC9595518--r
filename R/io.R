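#' Write / read a confocal image with voxel geometry
#'
#' Images are stored as TIFF with a JSON sidecar (`<path>.json`) holding
#' the voxel geometry and the intensity scale.  Integer-valued images in
#' `[0, 65535]` round-trip losslessly through 16-bit storage; other
#' images are stored as 32-bit float scaled to `[0, 1]`.
#'
#' @param image Numeric matrix or 3D array (x, y\[, z\]), values >= 0.
#' @param path Output TIFF path.
#' @param geometry A [voxel_geometry()].
#' @return `write_image` returns `path` invisibly; `read_image` returns
#'   a list with `image` and `geometry`.
#' @export
write_image <- function(image, path, geometry = voxel_geometry()) {
  stopifnot(is.numeric(image), inherits(geometry, "voxel_geometry"))
  if (any(image < 0)) stop_param("image values must be >= 0")
  is_int16 <- all(image == round(image)) && max(image) <= 65535
  scale <- if (is_int16) 65535 else max(image, 1e-300)
  bits <- if (is_int16) 16L else 32L
  slices <- if (length(dim(image)) == 3L)
    lapply(seq_len(dim(image)[3]), function(z) image[, , z] / scale)
  else list(image / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = bits)
  jsonlite::write_json(
    list(dx = geometry$dx, dy = geometry$dy, dz = geometry$dz,
         scale = scale, mode = if (is_int16) "uint16" else "float",
         n_slices = length(slices)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @param geometry_override Optional [voxel_geometry()] taking precedence
#'   over sidecar metadata (logged with a warning when both exist).
#' @export
read_image <- function(path, geometry_override = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (is.null(meta) && is.null(geometry_override))
    stop_param("no voxel geometry: sidecar ", sidecar,
               " missing and no override given")
  geometry <- if (!is.null(geometry_override)) {
    stopifnot(inherits(geometry_override, "voxel_geometry"))
    if (!is.null(meta))
      warning("voxel geometry override takes precedence over sidecar metadata")
    geometry_override
  } else {
    voxel_geometry(meta$dx, meta$dy, meta$dz)
  }
  scale <- if (!is.null(meta)) meta$scale else 1
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  img <- if (length(slices) == 1L) slices[[1]] * scale
  else {
    a <- array(0, c(dim(slices[[1]]), length(slices)))
    for (z in seq_along(slices)) a[, , z] <- slices[[z]] * scale
    a
  }
  if (!is.null(meta) && identical(meta$mode, "uint16")) img <- round(img)
  list(image = img, geometry = geometry)
}

#' Write / read particle tracks as tabular text
#'
#' Comma-separated tables in the TrackMate dialect: columns `TRACK_ID`,
#' `FRAME` (0-based), `POSITION_X`, `POSITION_Y` in um.
#'
#' @param tracks A `track_set` or list of [new_track()] objects.
#' @param path CSV path.
#' @return `write_tracks` returns `path` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  d <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(TRACK_ID = tr$track_id, FRAME = tr$frames,
               POSITION_X = tr$positions[, 1],
               POSITION_Y = tr$positions[, 2])))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param dt Frame interval, s.
#' @param pixel_size Declared pixel size in um when positions are in
#'   pixel units; positions are converted to um on read (`NULL` = already
#'   in um).
#' @export
read_tracks <- function(path, dt = 1, pixel_size = NULL) {
  d <- read.csv(path)
  req <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop(errorCondition(
      paste0("missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = c("condensorheo_schema_error", "error", "condition")))
  if (anyDuplicated(d[c("TRACK_ID", "FRAME")]))
    stop(errorCondition("duplicate (TRACK_ID, FRAME) rows",
                        class = c("condensorheo_schema_error",
                                  "error", "condition")))
  if (!is.null(pixel_size)) {
    check_scalar(pixel_size, "pixel_size", positive = TRUE)
    d$POSITION_X <- d$POSITION_X * pixel_size
    d$POSITION_Y <- d$POSITION_Y * pixel_size
  }
  tracks <- lapply(split(d, d$TRACK_ID), function(g) {
    g <- g[order(g$FRAME), ]
    new_track(g$TRACK_ID[1], g$FRAME, cbind(g$POSITION_X, g$POSITION_Y),
              dt)
  })
  names(tracks) <- NULL
  structure(tracks, class = "track_set", dt = dt)
}

#' Write / read an intensity trace as tabular text
#'
#' Columns `time_s`, `counts`.
#'
#' @param trace An [intensity_trace()].
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fcs_trace"))
  write.csv(data.frame(time_s = trace$times, counts = trace$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "counts") %in% names(d)))
    stop(errorCondition("trace file needs columns time_s, counts",
                        class = c("condensorheo_schema_error",
                                  "error", "condition")))
  dtimes <- diff(d$time_s)
  bw <- stats::median(dtimes)
  if (any(abs(dtimes - bw) > 1e-9 * max(abs(d$time_s), bw)))
    stop_param("trace times must be uniformly spaced")
  intensity_trace(d$counts, bw, t0 = d$time_s[1])
}

#' Write a correlation curve as tabular text
#'
#' Columns `lag_s`, `G`, `n_pairs`.
#'
#' @param curve An `fcs_correlation`.
#' @param path CSV path.
#' @export
write_correlation <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_correlation"))
  write.csv(data.frame(lag_s = curve$lag, G = curve$G,
                       n_pairs = curve$n_pairs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @param base_frequency Base frequency to attach (Hz).
#' @export
read_correlation <- function(path, base_frequency = NA_real_) {
  d <- read.csv(path)
  if (!all(c("lag_s", "G") %in% names(d)))
    stop(errorCondition("curve file needs columns lag_s, G",
                        class = c("condensorheo_schema_error",
                                  "error", "condition")))
  if (is.null(d$n_pairs)) d$n_pairs <- 1
  structure(data.frame(lag = d$lag_s, G = d$G, n_pairs = d$n_pairs),
            class = c("fcs_correlation", "data.frame"),
            base_frequency = base_frequency, mean_rate = NA_real_)
}

#' Write an analysis result as JSON
#'
#' Serializes fit results and summaries (lists, data frames) to pretty
#' JSON with full numeric precision, embedding provenance when present.
#'
#' @param x List-like result.
#' @param path Output path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}
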