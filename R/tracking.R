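#' Detect spots in a single frame by Laplacian-of-Gaussian filtering
#'
#' Convolves the frame with a negated LoG kernel matched to the expected
#' spot size, takes local maxima of the response above `threshold`, and
#' refines each candidate to subpixel precision with an
#' intensity-weighted centroid in a window of radius `2 sigma`.
#'
#' @param image Numeric matrix.
#' @param sigma Expected spot scale in pixels.
#' @param threshold Minimum LoG response for a detection.
#' @return Data frame with columns `x`, `y` (pixel units, subpixel,
#'   1-based) and `response`; zero rows when nothing is detected.
#' @export
detect_spots <- function(image, sigma = 2, threshold) {
  stopifnot(is.matrix(image))
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(threshold, "threshold")
  half <- max(2L, ceiling(3 * sigma))
  ax <- (-half):half
  g <- expand.grid(x = ax, y = ax)
  r2 <- g$x^2 + g$y^2
  # negated LoG: positive response on bright blobs
  kern <- matrix(-(r2 - 2 * sigma^2) / sigma^4 *
                   exp(-r2 / (2 * sigma^2)), length(ax))
  kern <- kern - mean(kern)
  resp <- conv2_cpp(image, kern)
  nr <- nrow(image); nc <- ncol(image)
  win <- max(1L, ceiling(2 * sigma))
  cand <- which(resp > threshold, arr.ind = TRUE)
  cand <- cand[cand[, 1] > win & cand[, 1] <= nr - win &
               cand[, 2] > win & cand[, 2] <= nc - win, , drop = FALSE]
  spots <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c_ <- cand[i, 2]
    nb <- resp[(r - 1):(r + 1), (c_ - 1):(c_ + 1)]
    if (resp[r, c_] < max(nb)) next          # not a local maximum
    rr <- (r - win):(r + win); cc <- (c_ - win):(c_ + win)
    w <- image[rr, cc] - min(image[rr, cc])
    if (sum(w) == 0) next
    spots[[length(spots) + 1L]] <- data.frame(
      x = sum(outer(rr, rep(1, length(cc))) * w) / sum(w),
      y = sum(outer(rep(1, length(rr)), cc) * w) / sum(w),
      response = resp[r, c_])
  }
  if (!length(spots))
    return(data.frame(x = numeric(), y = numeric(), response = numeric()))
  out <- do.call(rbind, spots)
  # merge duplicate maxima refined to (nearly) the same centroid
  out <- out[order(-out$response), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    d <- sqrt((out$x - out$x[i])^2 + (out$y - out$y[i])^2)
    dup <- which(d < sigma & seq_len(nrow(out)) > i)
    keep[dup] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link per-frame spots into tracks
#'
#' Frame-to-frame one-to-one assignment: candidate links within
#' `max_disp` are sorted by displacement and assigned greedily (shortest
#' first), so no spot is linked twice and no link exceeds `max_disp`.
#' Consecutive frames only — no gap closing.  Unmatched spots start new
#' tracks.
#'
#' @param spots_by_frame List of data frames with columns `x`, `y`
#'   (um), one per frame, in frame order.
#' @param max_disp Maximum displacement per frame, um.
#' @param dt Frame interval, s.
#' @return A `track_set` of [new_track()] objects (0-based frames).
#' @export
link_tracks <- function(spots_by_frame, max_disp, dt = 1) {
  stopifnot(is.list(spots_by_frame), length(spots_by_frame) >= 1L)
  check_scalar(max_disp, "max_disp", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  next_id <- 0L
  active <- list()   # open tracks: list(id, frames, xs, ys)
  done <- list()
  for (f in seq_along(spots_by_frame)) {
    sp <- spots_by_frame[[f]]
    n_sp <- if (is.null(sp)) 0L else nrow(sp)
    assigned_track <- integer(0)
    assigned_spot <- integer(0)
    if (length(active) && n_sp) {
      last <- t(vapply(active, function(a)
        c(tail(a$xs, 1), tail(a$ys, 1)), numeric(2)))
      dmat <- sqrt(outer(last[, 1], sp$x, "-")^2 +
                   outer(last[, 2], sp$y, "-")^2)
      cand <- which(dmat <= max_disp, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand])
        used_t <- logical(length(active)); used_s <- logical(n_sp)
        for (ci in ord) {
          ti <- cand[ci, 1]; si <- cand[ci, 2]
          if (used_t[ti] || used_s[si]) next
          used_t[ti] <- TRUE; used_s[si] <- TRUE
          assigned_track <- c(assigned_track, ti)
          assigned_spot <- c(assigned_spot, si)
        }
      }
    }
    # extend matched tracks
    for (j in seq_along(assigned_track)) {
      ti <- assigned_track[j]; si <- assigned_spot[j]
      active[[ti]]$frames <- c(active[[ti]]$frames, f - 1L)
      active[[ti]]$xs <- c(active[[ti]]$xs, sp$x[si])
      active[[ti]]$ys <- c(active[[ti]]$ys, sp$y[si])
    }
    # close unmatched tracks (no gap closing)
    unmatched <- setdiff(seq_along(active), assigned_track)
    done <- c(done, active[unmatched])
    active <- active[setdiff(seq_along(active), unmatched)]
    # open new tracks for unmatched spots
    new_spots <- setdiff(seq_len(n_sp), assigned_spot)
    for (si in new_spots) {
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <- list(id = next_id,
                                            frames = f - 1L,
                                            xs = sp$x[si], ys = sp$y[si])
    }
  }
  done <- c(done, active)
  tracks <- lapply(done, function(a)
    if (length(a$frames) >= 2L)
      new_track(a$id, a$frames, cbind(a$xs, a$ys), dt) else NULL)
  tracks <- Filter(Negate(is.null), tracks)
  tracks <- tracks[order(vapply(tracks, function(tr) tr$track_id, 1L))]
  structure(tracks, class = "track_set", dt = dt)
}
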