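## Temporal alignment: every stream is placed on a single camera-anchored
## timeline, with 0 s at the first recorded camera frame.
##
## Camera frames get regenerated timestamps from the known frame rate.
## Touch-device timestamps are regenerated from the device millisecond
## counter after estimating its drift against the host clock from the
## first/last frame pairs; the difference between recorded and regenerated
## host times is the USB transport latency, kept as a diagnostic only.
## MIDI host times are never regenerated (the host clock is their only
## source); camera/MIDI alignment adds the mean of per-note offsets from a
## small set of visually identified anchor notes to all MIDI and touch
## timestamps.

#' Regenerate camera timestamps from the known frame rate
#'
#' @param frames marker data.frame with `frame_index`.
#' @param camera_fps frames per second (> 0).
#' @return the data.frame with a `time_s` column;
#'   `time_s = (frame_index - frame_index[first]) / camera_fps`, so the
#'   first recorded frame sits at exactly 0 s.
#' @export
regenerate_camera_timestamps <- function(frames, camera_fps) {
  kf_assert(is.numeric(camera_fps) && camera_fps > 0, "camera_fps must be > 0")
  kf_assert("frame_index" %in% names(frames), "frame_index column required")
  idx <- unique(frames$frame_index)
  kf_assert(!is.unsorted(idx, strictly = TRUE),
            "frame_index must be strictly increasing")
  frames$time_s <- (frames$frame_index - idx[1]) / camera_fps
  frames
}

#' Estimate the touch-device clock against the host clock
#'
#' The first and last device frame counters and the first and last host
#' timestamps give the actual device rate:
#' `factor = (host_last - host_first) / ((device_last - device_first)/1000)`
#' (host seconds per device second). The epoch is the first recorded host
#' timestamp.
#'
#' @param touches touch data.frame with `device_ms` and `host_s`.
#' @param method `"endpoints"` (default) uses only the first and last
#'   frame pairs; `"least_squares"` regresses host time on device time
#'   over all frames (more noise-resistant, but the endpoint rule is the
#'   reference behaviour).
#' @return list(touch_rate_factor, touch_epoch, device_origin_ms).
#' @export
estimate_touch_clock <- function(touches,
                                 method = c("endpoints", "least_squares")) {
  method <- match.arg(method)
  kf_assert(nrow(touches) >= 2L, "need at least 2 touch frames")
  ord <- order(touches$device_ms)
  dev <- touches$device_ms[ord]; host <- touches$host_s[ord]
  span_ms <- dev[length(dev)] - dev[1]
  kf_assert(span_ms > 0, "degenerate device-time span (all device_ms equal)")
  factor <- if (method == "least_squares") {
    unname(stats::coef(stats::lm(host ~ I(dev / 1000)))[2])
  } else {
    (host[length(host)] - host[1]) / (span_ms / 1000)
  }
  list(touch_rate_factor = factor,
       touch_epoch = host[1],
       device_origin_ms = dev[1])
}

#' Regenerate touch timestamps on the host clock
#'
#' `t_i = epoch + factor * (device_i - device_0) / 1000`. The recorded host
#' time minus the regenerated time is the per-frame USB latency, returned
#' as a diagnostic; regenerated times always replace host times downstream.
#'
#' @param touches touch data.frame.
#' @param clock result of [estimate_touch_clock()].
#' @return the data.frame with `regen_host_s` and `latency_s` columns.
#' @export
regenerate_touch_timestamps <- function(touches, clock) {
  touches$regen_host_s <- clock$touch_epoch +
    clock$touch_rate_factor * (touches$device_ms - clock$device_origin_ms) / 1000
  touches$latency_s <- touches$host_s - touches$regen_host_s
  touches
}

#' Mean camera/MIDI offset from anchor notes
#'
#' The onset times of a few notes (normally the first three) are
#' identified visually in the camera stream and paired with their MIDI
#' onset times; the mean of `camera - midi` is the offset added to all
#' MIDI and touch timestamps.
#'
#' @param anchors data.frame with `camera_onset_s` and `midi_onset_s`.
#' @param min_anchors minimum number of pairs required (default 3).
#' @return midi_offset in seconds.
#' @export
align_midi_to_camera <- function(anchors, min_anchors = 3L) {
  kf_assert(nrow(anchors) >= min_anchors,
            "need at least %d anchor pairs, got %d", min_anchors, nrow(anchors))
  mean(anchors$camera_onset_s - anchors$midi_onset_s)
}

#' Align a full recording bundle onto the camera timeline
#'
#' Runs the three alignment stages and stamps every stream with
#' `unified_s`. Raw columns (`frame_index`, `device_ms`, `host_s`) are
#' never modified, so alignment is idempotent: re-running it on an aligned
#' bundle recomputes identical values.
#'
#' @param bundle a `recording_bundle`.
#' @param camera_fps camera frame rate in Hz (default 117).
#' @param anchors anchor data.frame; defaults to `bundle$anchors`.
#' @param min_anchors minimum anchor pairs (default 3).
#' @return the bundle with `unified_s` columns, segmented `notes`, and an
#'   `alignment` record (class `alignment_result`).
#' @export
align_bundle <- function(bundle, camera_fps = 117, anchors = bundle$anchors,
                         min_anchors = 3L) {
  kf_assert(!is.null(anchors), "anchor pairs required for camera/MIDI alignment")
  bundle$markers <- regenerate_camera_timestamps(bundle$markers, camera_fps)
  clock <- estimate_touch_clock(bundle$touches)
  bundle$touches <- regenerate_touch_timestamps(bundle$touches, clock)
  offset <- align_midi_to_camera(anchors, min_anchors)
  bundle$touches$unified_s <- bundle$touches$regen_host_s + offset
  bundle$midi$unified_s <- bundle$midi$host_s + offset
  bundle$alignment <- structure(list(
    camera_fps = camera_fps,
    touch_rate_factor = clock$touch_rate_factor,
    touch_epoch = clock$touch_epoch,
    midi_offset = offset,
    per_frame_latency = bundle$touches$latency_s
  ), class = "alignment_result")
  bundle$notes <- segment_notes(bundle$midi, "unified_s")
  bundle
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result>\n")
  cat(sprintf("  camera_fps:        %.6g Hz\n", x$camera_fps))
  cat(sprintf("  touch_rate_factor: %.8f\n", x$touch_rate_factor))
  cat(sprintf("  touch_epoch:       %.6f s (host clock)\n", x$touch_epoch))
  cat(sprintf("  midi_offset:       %.6f s\n", x$midi_offset))
  cat(sprintf("  usb latency:       mean %.4g s, max %.4g s\n",
              mean(x$per_frame_latency), max(x$per_frame_latency)))
  invisible(x)
}
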