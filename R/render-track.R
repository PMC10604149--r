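#' Channel region of interest in a rendered or recorded stack
#'
#' @param row_span Integer range `c(first, last)` of image rows covering
#'   the channel interior.
#' @param column_origin Column index (0-based offset in pixels) where the
#'   channel inlet sits; positions are measured from here.
#' @param scale Metres per pixel (> 0).
#' @param wet_is_dark `TRUE` if the water-filled region is darker than the
#'   dry channel.
#' @return A `channel_roi` object.
#' @export
channel_roi <- function(row_span, column_origin = 0L, scale,
                        wet_is_dark = TRUE) {
  if (!is.numeric(row_span) || length(row_span) != 2L ||
      row_span[1] > row_span[2] || row_span[1] < 1) {
    abort_invalid_parameter("`row_span` must be c(first, last) with first <= last")
  }
  check_scalar(scale, "scale", lower = 0, strict_lower = TRUE)
  structure(
    list(row_span = as.integer(row_span),
         column_origin = as.integer(column_origin),
         scale = scale, wet_is_dark = isTRUE(wet_is_dark)),
    class = "channel_roi")
}

#' Render a dual-channel filling sequence as a synthetic image stack
#'
#' Produces, per time sample, a top-view grayscale frame of the two
#' channels: channel interiors are light (1) where dry and dark (0) where
#' wet (x < S_i), the PDMS background is light. Wall waviness is drawn
#' from [wall_profile()], so the channel silhouette narrows and widens
#' along x. The returned stack carries the ROI pair (the central band of
#' guaranteed interior, of half-width (h0 - A)/2 around each centreline),
#' the pixel scale and the frame times as attributes, which
#' [track_fronts()] picks up for the round trip.
#'
#' @param trace A [dual_trace()]; one frame is rendered per sample (thin
#'   it first for long runs).
#' @param geometry1,geometry2 The channel geometries.
#' @param resolution Pixel size, m; must be finer than the nominal width.
#' @return A numeric array `[rows, cols, frames]` with values in `[0, 1]`
#'   and attributes `rois` (list of two [channel_roi()]), `scale`,
#'   `times`.
#' @export
render_frames <- function(trace, geometry1, geometry2, resolution = 2.5e-5) {
  assert_dual_trace(trace)
  for (g in list(geometry1, geometry2)) {
    if (!inherits(g, "channel_geometry")) {
      abort_invalid_parameter("geometries must be `channel_geometry` objects")
    }
  }
  check_scalar(resolution, "resolution", lower = 0, strict_lower = TRUE)
  if (resolution >= min(geometry1$nominal_width, geometry2$nominal_width)) {
    abort_invalid_parameter("`resolution` must be finer than the nominal channel width")
  }
  L <- max(geometry1$total_length, geometry2$total_length)
  n_cols <- ceiling(L / resolution)
  margin_px <- ceiling(0.5e-3 / resolution)
  band_px <- function(g) ceiling((g$nominal_width + g$amplitude) / resolution)
  b1 <- band_px(geometry1); b2 <- band_px(geometry2)
  n_rows <- margin_px + b1 + margin_px + b2 + margin_px
  # centreline y (m) of each channel band
  yc <- c(margin_px + b1 / 2, 2 * margin_px + b1 + b2 / 2) * resolution
  x <- (seq_len(n_cols) - 0.5) * resolution
  y <- (seq_len(n_rows) - 0.5) * resolution
  geoms <- list(geometry1, geometry2)
  interior <- vector("list", 2L)
  for (i in 1:2) {
    xg <- pmin(x, geoms[[i]]$total_length)
    half <- wall_profile(geoms[[i]], xg) / 2
    interior[[i]] <- outer(abs(y - yc[i]), half, `<=`) &
      matrix(x <= geoms[[i]]$total_length, n_rows, n_cols, byrow = TRUE)
  }
  n_frames <- nrow(trace)
  stack <- array(1, dim = c(n_rows, n_cols, n_frames))
  S <- cbind(trace$s1, trace$s2)
  for (k in seq_len(n_frames)) {
    frame <- matrix(1, n_rows, n_cols)
    for (i in 1:2) {
      wet_cols <- x <= S[k, i]
      if (any(wet_cols)) {
        wet <- interior[[i]] & matrix(wet_cols, n_rows, n_cols, byrow = TRUE)
        frame[wet] <- 0
      }
    }
    stack[, , k] <- frame
  }
  rois <- lapply(1:2, function(i) {
    g <- geoms[[i]]
    half_safe <- (g$nominal_width - g$amplitude) / 2
    rows <- which(abs(y - yc[i]) <= half_safe)
    channel_roi(row_span = range(rows), column_origin = 0L,
                scale = resolution, wet_is_dark = TRUE)
  })
  structure(stack, rois = rois, scale = resolution, times = trace$times)
}

# front position (m) from one frame and ROI; returns NA when no threshold
# crossing is found in an otherwise active frame
frame_front <- function(frame, roi, threshold) {
  rows <- roi$row_span[1]:roi$row_span[2]
  profile <- colMeans(frame[rows, , drop = FALSE])
  rng <- range(profile)
  if (diff(rng) < 1e-12) {
    # featureless frame: no front in view. Disambiguate fully dry from
    # fully wet by the absolute level (stacks are normalized to [0, 1]).
    wet_level <- if (roi$wet_is_dark) mean(profile) < 0.5 else mean(profile) > 0.5
    return(if (wet_level) length(profile) * roi$scale else 0)
  }
  wet <- if (roi$wet_is_dark) (rng[2] - profile) / diff(rng)
         else (profile - rng[1]) / diff(rng)
  above <- which(wet >= threshold)
  if (length(above) == 0L) return(0)
  j <- max(above)
  n <- length(wet)
  j_sub <- if (j < n && wet[j] > wet[j + 1]) {
    j + (wet[j] - threshold) / (wet[j] - wet[j + 1])
  } else j + 0.5
  max(j_sub - 0.5 - roi$column_origin, 0) * roi$scale
}

#' Track the two fronts through an image stack
#'
#' Per frame and channel, rows of the ROI are averaged into an intensity
#' profile, normalized to the per-frame range (guarding against
#' illumination drift), and the front is the largest column where the
#' wet-side profile crosses `threshold`, refined to sub-pixel by linear
#' interpolation between the straddling columns. Frames without a
#' crossing carry the previous position forward and are flagged; more
#' than 20 percent flagged frames aborts with a tracking failure. A
#' width-3 running median over time removes single-frame outliers.
#'
#' @param stack Numeric array `[rows, cols, frames]`, e.g. from
#'   [render_frames()] or [read_stack()].
#' @param rois List of two [channel_roi()] objects; defaults to the
#'   stack's `rois` attribute.
#' @param times Frame times, s; defaults to the stack's `times` attribute.
#' @param threshold Intensity fraction in (0, 1), default 0.5.
#' @return A [dual_trace()]; attribute `flagged` gives the per-channel
#'   count of carried-forward frames.
#' @export
track_fronts <- function(stack, rois = attr(stack, "rois"),
                         times = attr(stack, "times"), threshold = 0.5) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    abort_invalid_input("`stack` must be a [rows, cols, frames] array")
  }
  if (is.null(rois) || length(rois) != 2L ||
      !all(vapply(rois, inherits, logical(1), "channel_roi"))) {
    abort_invalid_parameter("`rois` must be a list of two `channel_roi` objects")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort_invalid_parameter("`threshold` must lie in (0, 1)")
  }
  n_frames <- dim(stack)[3]
  if (is.null(times)) abort_invalid_parameter("`times` must be supplied")
  if (length(times) != n_frames) {
    abort_invalid_input("`times` length must match the frame count")
  }
  pos <- matrix(0, n_frames, 2L)
  flagged <- integer(2L)
  for (i in 1:2) {
    prev <- 0
    for (k in seq_len(n_frames)) {
      p <- frame_front(stack[, , k], rois[[i]], threshold)
      if (is.na(p) || (p == 0 && prev > rois[[i]]$scale)) {
        # lost the front: carry forward and flag
        p <- prev
        flagged[i] <- flagged[i] + 1L
      }
      pos[k, i] <- p
      prev <- p
    }
  }
  if (any(flagged > 0.2 * n_frames)) {
    abort_tracking_failure(sprintf(
      "front lost in %d/%d frames", max(flagged), n_frames))
  }
  if (n_frames >= 3L) {
    pos[, 1] <- stats::runmed(pos[, 1], 3, endrule = "keep")
    pos[, 2] <- stats::runmed(pos[, 2], 3, endrule = "keep")
  }
  # enforce monotone fronts: tracking jitter must not read as retreat
  pos[, 1] <- cummax(pos[, 1])
  pos[, 2] <- cummax(pos[, 2])
  tr <- dual_trace(times = times, s1 = pos[, 1], s2 = pos[, 2],
                   label = "tracked",
                   monotone_tol = rois[[1]]$scale)
  attr(tr, "flagged") <- flagged
  tr
}

#' Write / read a multi-page TIFF image stack
#'
#' Thin wrappers over the tiff package storing the `[rows, cols, frames]`
#' array as one grayscale page per frame. ROI and timing metadata are not
#' stored in the TIFF; keep them in the run's config/manifest.
#'
#' @param stack Numeric array `[rows, cols, frames]` with values in
#'   `[0, 1]`.
#' @param path File path.
#' @return `read_stack()` returns the array; `write_stack()` returns the
#'   path invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    abort_invalid_input("`stack` must be a [rows, cols, frames] array")
  }
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- dim(pages[[1]])
  arr <- array(0, dim = c(dims[1], dims[2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[, , k] <- pg
  }
  arr
}
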