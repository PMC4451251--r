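## The three analyses: finger curvature index, touch-vs-MIDI contact
## timing, and transition windows with quantity-of-motion indices and
## lift/fall/slide classification.

#' Curvature index
#'
#' Ratio of an instantaneous marker-pair (or marker-touch) planar
#' distance to the same distance in a flat-hand calibration pose:
#' `CI = d / d_ref`. 1 is a fully extended finger lying flat along the
#' key; 0 is a fully vertical posture with the distal marker directly
#' above the touch.
#'
#' @param d distance at time t (>= 0), pixels.
#' @param d_ref flat-hand reference distance (> 0), pixels.
#' @return dimensionless CI.
#' @export
curvature_index <- function(d, d_ref) {
  if (any(!is.finite(d_ref)) || any(d_ref <= 0)) {
    kf_stop("calibration error: d_ref must be > 0")
  }
  d / d_ref
}

#' Capture flat-hand reference distances
#'
#' From one designated calibration frame in which all fingers are laid
#' flat on the keys (and touching), measures per finger the distal
#' reference distance (distal marker to pixel-mapped touch; the thumb's
#' IP marker to its touch) and the proximal reference distance (distal to
#' proximal marker).
#'
#' @param bundle aligned, pixel-mapped bundle.
#' @param calibration_frame camera `frame_index` of the flat-hand pose.
#' @param window_s touch frames within this window of the calibration
#'   frame are candidates (default 0.5 s).
#' @return data.frame: hand, finger, phalanx, d_ref.
#' @export
calibrate_reference <- function(bundle, calibration_frame, window_s = 0.5) {
  mk <- bundle$markers
  kf_assert("time_s" %in% names(mk), "bundle must be aligned")
  fr <- mk[mk$frame_index == calibration_frame & mk$visible, , drop = FALSE]
  kf_assert(nrow(fr) > 0, "calibration frame %d not found", calibration_frame)
  t0 <- fr$time_s[1]
  touches <- bundle$touches
  if (!"x_px" %in% names(touches)) {
    touches <- touch_to_pixels(touches, bundle$polygons)
  }
  tw <- touches[abs(touches$unified_s - t0) <= window_s, , drop = FALSE]
  out <- list()
  for (h in intersect(KF_HANDS, unique(fr$hand))) {
    for (f in 1:5) {
      distal <- fr[fr$hand == h & fr$finger %in% f &
                   fr$landmark == (if (f == 1L) "IP" else "DIP"), , drop = FALSE]
      if (!nrow(distal)) next
      # the finger's own touch: nearest in X among calibration-window touches
      if (nrow(tw)) {
        j <- which.min(abs(tw$x_px - distal$x_px[1]))
        d_touch <- sqrt((tw$x_px[j] - distal$x_px[1])^2 +
                        (tw$y_px[j] - distal$y_px[1])^2)
        out[[length(out) + 1L]] <- data.frame(
          hand = h, finger = f,
          phalanx = if (f == 1L) "proximal" else "distal", d_ref = d_touch)
      }
      if (f != 1L) {
        pip <- fr[fr$hand == h & fr$finger %in% f & fr$landmark == "PIP", ,
                  drop = FALSE]
        if (nrow(pip)) {
          out[[length(out) + 1L]] <- data.frame(
            hand = h, finger = f, phalanx = "proximal",
            d_ref = sqrt((pip$x_px[1] - distal$x_px[1])^2 +
                         (pip$y_px[1] - distal$y_px[1])^2))
        }
      }
    }
  }
  kf_assert(length(out) > 0, "no calibration distances could be measured")
  do.call(rbind, out)
}

#' Curvature-index time series
#'
#' For every camera frame falling inside a fingered note's touch block,
#' computes the distal CI (distal marker to the pixel-mapped touch
#' nearest in time; the thumb reports its proximal-touch CI instead) and
#' the proximal CI (distal to proximal marker), normalised by the
#' calibration distances. Frames with occluded markers are skipped and
#' counted in the `coverage` attribute.
#'
#' @param bundle aligned, fingered bundle.
#' @param calibration data.frame from [calibrate_reference()], or a
#'   calibration `frame_index`.
#' @param signed when TRUE, a marker-touch CI is negated while the distal
#'   marker sits on the player side of the touch location (the finger
#'   bent past the contact point); the default is the plain unsigned
#'   ratio.
#' @return data.frame: time_s, note_id, hand, finger, phalanx, d, d_ref,
#'   ci; attribute `coverage` = list(n_samples, n_skipped_occluded).
#' @export
ci_series <- function(bundle, calibration, signed = FALSE) {
  if (is.numeric(calibration) && length(calibration) == 1L) {
    calibration <- calibrate_reference(bundle, calibration)
  }
  if (!is_fingered(bundle)) kf_stop("bundle must be fingered")
  touches <- bundle$touches
  kf_assert("x_px" %in% names(touches), "touches must be pixel-mapped")
  mk <- bundle$markers
  notes <- bundle$notes[!is.na(bundle$notes$finger) &
                        !is.na(bundle$notes$block_id), , drop = FALSE]
  refs <- function(h, f, ph) {
    r <- calibration$d_ref[calibration$hand == h & calibration$finger == f &
                           calibration$phalanx == ph]
    if (length(r)) r[1] else NA_real_
  }
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(notes))) {
    h <- notes$hand[i]; f <- notes$finger[i]
    distal_lm <- if (f == 1L) "IP" else "DIP"
    frames <- mk[mk$hand == h & mk$finger %in% f & mk$landmark == distal_lm &
                 mk$time_s >= notes$block_start[i] &
                 mk$time_s <= notes$block_end[i], , drop = FALSE]
    if (!nrow(frames)) next
    tb <- touches[!is.na(touches$block_id) &
                  touches$block_id == notes$block_id[i], , drop = FALSE]
    tb <- tb[order(tb$unified_s), , drop = FALSE]
    pip <- mk[mk$hand == h & mk$finger %in% f & mk$landmark == "PIP", , drop = FALSE]
    dref_t <- refs(h, f, if (f == 1L) "proximal" else "distal")
    dref_p <- refs(h, f, "proximal")
    for (k in seq_len(nrow(frames))) {
      if (!frames$visible[k]) { skipped <- skipped + 1L; next }
      # nearest-in-time touch sample within the block
      j <- nearest_index(frames$time_s[k], tb$unified_s)
      d_t <- sqrt((frames$x_px[k] - tb$x_px[j])^2 + (frames$y_px[k] - tb$y_px[j])^2)
      if (is.finite(dref_t) && dref_t > 0) {
        ci_t <- curvature_index(d_t, dref_t)
        if (signed && frames$y_px[k] < tb$y_px[j]) ci_t <- -ci_t
        out[[length(out) + 1L]] <- data.frame(
          time_s = frames$time_s[k], note_id = notes$note_id[i], hand = h,
          finger = f, phalanx = if (f == 1L) "proximal" else "distal",
          d = d_t, d_ref = dref_t, ci = ci_t)
      }
      if (f != 1L && nrow(pip)) {
        pk <- pip[pip$frame_index == frames$frame_index[k], , drop = FALSE]
        if (nrow(pk) && pk$visible[1]) {
          d_p <- sqrt((frames$x_px[k] - pk$x_px[1])^2 + (frames$y_px[k] - pk$y_px[1])^2)
          if (is.finite(dref_p) && dref_p > 0) {
            out[[length(out) + 1L]] <- data.frame(
              time_s = frames$time_s[k], note_id = notes$note_id[i], hand = h,
              finger = f, phalanx = "proximal",
              d = d_p, d_ref = dref_p, ci = curvature_index(d_p, dref_p))
          }
        } else {
          skipped <- skipped + 1L
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(time_s = numeric(0), note_id = integer(0), hand = character(0),
               finger = integer(0), phalanx = character(0), d = numeric(0),
               d_ref = numeric(0), ci = numeric(0))
  attr(res, "coverage") <- list(n_samples = nrow(res), n_skipped_occluded = skipped)
  res
}

#' Anticipatory and release contact timing
#'
#' Per note: `anticipatory = block_start - onset` (negative when the
#' finger contacts the key before the press registers) and
#' `release_time = block_end - release` (positive when the finger lingers
#' after the key has risen). The first and last notes per finger are
#' excluded, as are notes without an associated touch block (counted in
#' the `excluded` attribute).
#'
#' @param notes fingered note table with block associations.
#' @return data.frame: note_id, midi_note, hand, finger, anticipatory_s,
#'   release_time_s.
#' @export
contact_timing <- function(notes) {
  ok <- !is.na(notes$finger) & !is.na(notes$block_id)
  n_noblock <- sum(!is.na(notes$finger) & is.na(notes$block_id))
  keep <- rep(FALSE, nrow(notes))
  for (h in unique(notes$hand[ok])) {
    for (f in unique(notes$finger[ok & notes$hand == h])) {
      idx <- which(ok & notes$hand == h & notes$finger == f)
      idx <- idx[order(notes$onset[idx])]
      if (length(idx) > 2L) keep[idx[-c(1L, length(idx))]] <- TRUE
    }
  }
  sub <- notes[keep, , drop = FALSE]
  res <- data.frame(note_id = sub$note_id, midi_note = sub$midi_note,
                    hand = sub$hand, finger = sub$finger,
                    anticipatory_s = sub$block_start - sub$onset,
                    release_time_s = sub$block_end - sub$release)
  attr(res, "excluded") <- list(first_last_per_finger = sum(ok) - nrow(res),
                                no_block = n_noblock)
  res
}

## --- quantity of motion ------------------------------------------------

# path length of a sampled 2D trajectory over [t0, t1], with linearly
# interpolated positions at the segment boundaries so that path lengths
# are exactly additive over adjacent segments
path_length_window <- function(ts, xs, ys, t0, t1) {
  if (t1 <= t0 || length(ts) < 2L) return(0)
  sel <- ts > t0 & ts < t1
  tt <- c(t0, ts[sel], t1)
  xx <- c(approx(ts, xs, t0, rule = 2)$y, xs[sel], approx(ts, xs, t1, rule = 2)$y)
  yy <- c(approx(ts, ys, t0, rule = 2)$y, ys[sel], approx(ts, ys, t1, rule = 2)$y)
  sum(sqrt(diff(xx)^2 + diff(yy)^2))
}

#' Quantity of motion index
#'
#' `QMI_seg = (QoM_seg / QoM_transition) * (t_transition / t_seg)`: the
#' time-normalised fraction of a transition's motion occurring in one
#' segment. 1 means the motion is uniformly distributed over the window.
#' Undefined cases (zero total motion or zero segment span) return NA.
#'
#' @param qom_seg,qom_transition path lengths (same units).
#' @param t_seg,t_transition segment and window durations (same units).
#' @return dimensionless QMI, or NA when undefined.
#' @export
qmi <- function(qom_seg, qom_transition, t_seg, t_transition) {
  ifelse(is.na(qom_transition) | qom_transition <= 0 | is.na(t_seg) | t_seg <= 0,
         NA_real_,
         (qom_seg / qom_transition) * (t_transition / t_seg))
}

#' Classify touch-surface motion at a key release or press
#'
#' Negligible travel along the key surface is a `lift` (release) or
#' `fall` (press); travel of at least `slide_threshold_mm` is a `slide`.
#'
#' @param path_mm touch path length along the key surface, millimetres.
#' @param kind `"release"` or `"press"`.
#' @param slide_threshold_mm slide threshold (default 1 mm); a path
#'   exactly at the threshold is a slide.
#' @return `"lift"`, `"fall"`, `"slide"`, or NA when no touch path.
#' @export
classify_touch_motion <- function(path_mm, kind = c("release", "press"),
                                  slide_threshold_mm = 1) {
  kind <- match.arg(kind)
  ifelse(is.na(path_mm), NA_character_,
         ifelse(path_mm >= slide_threshold_mm, "slide",
                if (kind == "release") "lift" else "fall"))
}

#' Build transition windows between consecutive same-finger notes
#'
#' For every pair of consecutive notes played by the same finger, the
#' window runs from the midpoint of the first note to the midpoint of the
#' second and is partitioned into a release segment (to the end of the
#' first note's touch block), a no-touch segment, and a press segment
#' (from the start of the second note's block). Per segment: the finger's
#' distal-marker path length (QoM, with boundary interpolation so that
#' segment QoMs sum exactly to the window QoM), the touch path along the
#' key surface (release/press only), both QMIs, and the lift/fall/slide
#' label. Same-finger notes whose blocks leave no touch gap are flagged
#' with a zero-span no-touch segment.
#'
#' @param bundle aligned, fingered bundle.
#' @param slide_threshold_mm slide classification threshold.
#' @return data.frame, three rows (segments) per window.
#' @export
build_transitions <- function(bundle, slide_threshold_mm = 1) {
  if (!is_fingered(bundle)) kf_stop("bundle must be fingered")
  notes <- bundle$notes[!is.na(bundle$notes$finger) &
                        !is.na(bundle$notes$block_id), , drop = FALSE]
  touches <- bundle$touches
  mk <- bundle$markers
  mmpx <- mm_per_px(bundle$polygons)
  out <- list()
  wid <- 0L
  for (h in unique(notes$hand)) {
    for (f in unique(notes$finger[notes$hand == h])) {
      idx <- which(notes$hand == h & notes$finger == f)
      idx <- idx[order(notes$onset[idx])]
      if (length(idx) < 2L) next
      lm <- if (f == 1L) "IP" else "DIP"
      traj <- mk[mk$hand == h & mk$finger %in% f & mk$landmark == lm & mk$visible, ,
                 drop = FALSE]
      traj <- traj[order(traj$time_s), , drop = FALSE]
      for (k in seq_len(length(idx) - 1L)) {
        ni <- notes[idx[k], ]; nj <- notes[idx[k + 1L], ]
        t_start <- (ni$onset + ni$release) / 2
        t_end <- (nj$onset + nj$release) / 2
        if (t_end <= t_start) next
        b1 <- min(max(ni$block_end, t_start), t_end)
        b2 <- min(max(nj$block_start, b1), t_end)
        no_gap <- b2 <= b1
        t_trans <- t_end - t_start
        seg <- data.frame(segment = c("release", "no_touch", "press"),
                          seg_start = c(t_start, b1, b2),
                          seg_end = c(b1, b2, t_end))
        seg$t_span <- seg$seg_end - seg$seg_start
        seg$qom_marker_px <- vapply(seq_len(3), function(s) {
          path_length_window(traj$time_s, traj$x_px, traj$y_px,
                             seg$seg_start[s], seg$seg_end[s])
        }, numeric(1))
        qom_trans <- sum(seg$qom_marker_px)
        seg$qmi_marker <- qmi(seg$qom_marker_px, qom_trans, seg$t_span, t_trans)
        # touch path along the key surface for release / press segments
        touch_path <- function(block_id, t0, t1) {
          tb <- touches[!is.na(touches$block_id) & touches$block_id == block_id, ,
                        drop = FALSE]
          tb <- tb[order(tb$unified_s), , drop = FALSE]
          if (nrow(tb) < 2L) return(NA_real_)
          path_length_window(tb$unified_s, tb$x_px, tb$y_px, t0, t1)
        }
        seg$qom_touch_px <- c(touch_path(ni$block_id, seg$seg_start[1], seg$seg_end[1]),
                              NA_real_,
                              touch_path(nj$block_id, seg$seg_start[3], seg$seg_end[3]))
        seg$qom_touch_mm <- seg$qom_touch_px * mmpx
        qom_touch_trans <- sum(seg$qom_touch_px, na.rm = TRUE)
        seg$qmi_touch <- qmi(seg$qom_touch_px, qom_touch_trans, seg$t_span, t_trans)
        seg$label <- c(
          classify_touch_motion(seg$qom_touch_mm[1], "release", slide_threshold_mm),
          NA_character_,
          classify_touch_motion(seg$qom_touch_mm[3], "press", slide_threshold_mm))
        wid <- wid + 1L
        seg <- data.frame(window_id = wid, hand = h, finger = f,
                          note_i = ni$note_id, note_j = nj$note_id,
                          t_start = t_start, t_end = t_end,
                          no_touch_gap_zero = no_gap, seg, row.names = NULL)
        out[[length(out) + 1L]] <- seg
      }
    }
  }
  if (!length(out)) {
    return(data.frame(window_id = integer(0), hand = character(0),
                      finger = integer(0), note_i = integer(0),
                      note_j = integer(0), t_start = numeric(0),
                      t_end = numeric(0), no_touch_gap_zero = logical(0),
                      segment = character(0), seg_start = numeric(0),
                      seg_end = numeric(0), t_span = numeric(0),
                      qom_marker_px = numeric(0), qmi_marker = numeric(0),
                      qom_touch_px = numeric(0), qom_touch_mm = numeric(0),
                      qmi_touch = numeric(0), label = character(0)))
  }
  do.call(rbind, out)
}

#' Run all three analyses on a fingered bundle
#'
#' @param bundle aligned, fingered bundle.
#' @param calibration_frame camera frame index of the flat-hand pose.
#' @param slide_threshold_mm slide classification threshold.
#' @return list(ci, timing, transitions, calibration).
#' @export
analyze_bundle <- function(bundle, calibration_frame = 0L,
                           slide_threshold_mm = 1) {
  calib <- calibrate_reference(bundle, calibration_frame)
  list(ci = ci_series(bundle, calib),
       timing = contact_timing(bundle$notes),
       transitions = build_transitions(bundle, slide_threshold_mm),
       calibration = calib)
}
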