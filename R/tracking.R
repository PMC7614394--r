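#' Detect the tissue surface from the pre-ablation window
#'
#' The surface appears as the brightest boundary in the quiet pre-ablation
#' frames: for each pre-window column the row of maximum intensity is
#' taken, and the per-column rows are aggregated by median so isolated
#' noise peaks cannot displace the estimate.
#'
#' @param mmode An `mmode_image` (or a bare matrix of envelope/dB values).
#' @param pre_window_frames Number of leading pre-ablation frames to use
#'   (>= 1).
#' @return Surface row index (1-based matrix row).
#' @export
detect_surface <- function(mmode, pre_window_frames) {
  img <- if (inherits(mmode, "mmode_image")) mmode$image else mmode
  if (is.null(pre_window_frames) || pre_window_frames < 1)
    stop("no pre-ablation window available: supply surface_row explicitly")
  pre_window_frames <- min(as.integer(pre_window_frames), ncol(img))
  pre <- img[, seq_len(pre_window_frames), drop = FALSE]
  if (diff(range(pre)) == 0)
    stop("pre-ablation window is featureless (constant); cannot detect a surface")
  rows <- apply(pre, 2, which.max)
  as.integer(round(stats::median(rows)))
}

#' Trace per-frame lesion depth from a lesion mask
#'
#' Pixels at or above the frozen surface row are discarded first (this
#' rejects contact-regime ejecta echoes), then the largest connected
#' sub-surface component is kept to suppress stray masked pixels. In every
#' frame the depth is the time-of-flight depth of the deepest remaining
#' masked row minus the surface depth; frames with no sub-surface mask
#' pixels read 0.
#'
#' @param mask A `lesion_mask` (or a logical matrix).
#' @param surface_row Surface row index from [detect_surface()].
#' @param config An [acquisition_config()] for the depth conversion.
#' @param frame_times Optional per-frame acquisition times (s).
#' @return An object of class `depth_trace`: `depth_mm` per frame,
#'   `surface_row`, `surface_depth_mm`, `frame_times`.
#' @export
trace_depth <- function(mask, surface_row, config, frame_times = NULL) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  if (surface_row < 1 || surface_row > nrow(m))
    stop("surface_row outside the image")
  sub <- m
  sub[seq_len(surface_row), ] <- FALSE
  if (any(sub)) {
    lab <- EBImage::bwlabel(matrix(as.numeric(sub), nrow(m), ncol(m)))
    lab <- matrix(as.integer(lab), nrow(m), ncol(m))
    sizes <- tabulate(lab[lab > 0])
    sub <- lab == which.max(sizes)
  }
  depth_mm <- apply(sub, 2, function(col) {
    rows <- which(col)
    if (!length(rows)) return(0)
    max(rows) - surface_row
  }) * config$speed_of_sound / (2 * config$sample_rate) * 1000
  structure(list(depth_mm = as.numeric(depth_mm),
                 surface_row = as.integer(surface_row),
                 surface_depth_mm = sample_to_depth(surface_row - 1L, config),
                 frame_times = frame_times),
            class = "depth_trace")
}

#' Final (post-ablation) lesion depth
#'
#' Median of the traced depth over the trailing post-laser window, where
#' the echogenic region and image contrast have stabilised.
#'
#' @param trace A `depth_trace` (or a numeric depth vector).
#' @param post_window_frames Number of trailing frames forming the
#'   post-laser window (>= 1).
#' @return Final lesion depth in mm.
#' @export
final_depth <- function(trace, post_window_frames) {
  d <- if (inherits(trace, "depth_trace")) trace$depth_mm else trace
  n <- length(d)
  if (is.null(post_window_frames) || post_window_frames < 1 || n < 1)
    stop("post-laser window is empty")
  post_window_frames <- min(as.integer(post_window_frames), n)
  stats::median(d[(n - post_window_frames + 1L):n])
}

#' Track the lesion on an M-mode image end to end
#'
#' Convenience wrapper: detect the surface from the pre-ablation window,
#' trace the per-frame depth from the mask, and summarise the final depth
#' over the post-laser window.
#'
#' @param mmode An `mmode_image`.
#' @param mask A `lesion_mask` (e.g. from [segment_lesion()]).
#' @param pre_window_frames,post_window_frames Frame counts of the quiet
#'   windows at the start and end of the acquisition.
#' @return A `depth_trace` with an additional `final_depth_mm` element.
#' @export
track_lesion <- function(mmode, mask, pre_window_frames,
                         post_window_frames) {
  surface_row <- detect_surface(mmode, pre_window_frames)
  trace <- trace_depth(mask, surface_row, mmode$config, mmode$time_axis)
  trace$final_depth_mm <- final_depth(trace, post_window_frames)
  trace
}

#' Write a depth trace to CSV
#'
#' Columns `frame_time_s`, `depth_mm`.
#'
#' @param trace A `depth_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_depth_trace <- function(trace, path) {
  times <- trace$frame_times
  if (is.null(times)) times <- seq_along(trace$depth_mm) - 1
  utils::write.csv(data.frame(frame_time_s = times,
                              depth_mm = trace$depth_mm),
                   path, row.names = FALSE)
  invisible(path)
}
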