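# Toy movie rendering and spot extraction, to exercise the trace-from-image
# round trip. Each ROI is a fixed Gaussian spot whose integrated intensity
# per frame equals its trace value.

#' Render a synthetic movie from ground truth
#'
#' Places one Gaussian spot per ROI on a regular grid and scales it each
#' frame so the spot's integrated intensity equals the ROI's trace value.
#'
#' @param truth a `ground_truth` object.
#' @param frame_shape length-2 integer `(height, width)` in pixels.
#' @param roi_sigma_px Gaussian spot SD in pixels (default 2).
#' @return list with `stack` (array height x width x frames), `centers`
#'   (data.frame roi_id, y, x), `traces` (the rendered `trace_set`).
#' @export
render_movie <- function(truth, frame_shape = c(64, 64), roi_sigma_px = 2) {
  stopifnot(inherits(truth, "ground_truth"))
  traces <- render_traces(truth)
  n_rois <- nrow(traces$fluorescence)
  h <- frame_shape[1]; w <- frame_shape[2]
  margin <- ceiling(4 * roi_sigma_px)
  spacing <- 2 * margin
  per_row <- max(0L, (w - 2 * margin) %/% spacing + 1L)
  n_rows <- max(0L, (h - 2 * margin) %/% spacing + 1L)
  if (per_row * n_rows < n_rois)
    stop("frame too small for ", n_rois, " non-overlapping spots; ",
         "use a larger frame_shape", call. = FALSE)
  idx <- seq_len(n_rois) - 1L
  cy <- margin + (idx %/% per_row) * spacing
  cx <- margin + (idx %% per_row) * spacing
  n_frames <- ncol(traces$fluorescence)
  stack <- array(0, dim = c(h, w, n_frames))
  ys <- matrix(rep(seq_len(h), w), nrow = h)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  for (r in seq_len(n_rois)) {
    g <- exp(-((ys - cy[r])^2 + (xs - cx[r])^2) / (2 * roi_sigma_px^2))
    g <- g / sum(g) # unit integral: spot sum per frame = trace value
    for (f in seq_len(n_frames))
      stack[, , f] <- stack[, , f] + g * traces$fluorescence[r, f]
  }
  list(stack = stack,
       centers = data.frame(roi_id = traces$roi_ids, y = cy, x = cx),
       traces = traces)
}

#' Extract spot traces from a movie
#'
#' Sums pixel intensities in a square patch around each ROI center per
#' frame — the inverse of [render_movie()] for well-separated spots.
#'
#' @param stack array height x width x frames.
#' @param centers data.frame with `roi_id`, `y`, `x`.
#' @param frame_rate_hz frames per second of the stack.
#' @param radius_px half-width of the extraction patch (default 8).
#' @return a `trace_set` of the extracted traces.
#' @export
extract_spot_traces <- function(stack, centers, frame_rate_hz,
                                radius_px = 8) {
  stopifnot(length(dim(stack)) == 3)
  h <- dim(stack)[1]; w <- dim(stack)[2]; n_frames <- dim(stack)[3]
  mat <- matrix(0, nrow = nrow(centers), ncol = n_frames)
  for (r in seq_len(nrow(centers))) {
    ys <- max(1, centers$y[r] - radius_px):min(h, centers$y[r] + radius_px)
    xs <- max(1, centers$x[r] - radius_px):min(w, centers$x[r] + radius_px)
    mat[r, ] <- apply(stack[ys, xs, , drop = FALSE], 3, sum)
  }
  trace_set(mat, frame_rate_hz, roi_ids = as.character(centers$roi_id))
}

#' Write a movie stack as multi-page TIFF
#'
#' @param stack array height x width x frames, non-negative.
#' @param path output file.
#' @export
write_movie_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks", call. = FALSE)
  mx <- max(stack)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
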