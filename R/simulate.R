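## Deterministic, seeded synthetic-performance simulator.
##
## Emulates the statistical structure the pipeline assumes: a camera at a
## fixed frame rate anchoring the unified timeline; a touch device whose
## millisecond counter drifts against the host clock and whose frames
## suffer USB transport latency; MIDI events on the host clock of a second
## computer offset from the camera computer; finger-key contacts that lead
## MIDI onsets and linger past releases; small-area moisture artifacts;
## marker jitter and occlusion. Every random draw comes from a named
## sub-stream of the base seed (seed + a fixed per-source increment), so
## enabling one noise source never perturbs the draws of another.

#' Clock model for the simulator
#'
#' @param camera_fps camera frame rate, Hz (default 117).
#' @param touch_rate_hz touch sensor sampling rate per key (default 200,
#'   i.e. one frame every 5 ms).
#' @param drift_factor host seconds per touch-device second; the device
#'   clock is specified accurate to within 0.01%, so realistic values lie
#'   in [0.999, 1.001].
#' @param inter_computer_offset_s camera-computer time minus MIDI/touch
#'   host time.
#' @param usb_latency_mean_s mean USB transport latency added to recorded
#'   host timestamps.
#' @param usb_tail_prob probability of a latency spike on a touch frame.
#' @param usb_tail_s maximum spike magnitude (uniform), default 0.4 s.
#' @return list of class `clock_model`.
#' @export
clock_model <- function(camera_fps = 117, touch_rate_hz = 200,
                        drift_factor = 1.0, inter_computer_offset_s = 0,
                        usb_latency_mean_s = 0, usb_tail_prob = 0,
                        usb_tail_s = 0.4) {
  kf_assert(drift_factor >= 0.999 && drift_factor <= 1.001,
            "drift_factor must lie in [0.999, 1.001]")
  kf_assert(usb_latency_mean_s >= 0 && usb_tail_prob >= 0 && usb_tail_s >= 0,
            "latency magnitudes must be >= 0")
  structure(list(camera_fps = camera_fps, touch_rate_hz = touch_rate_hz,
                 drift_factor = drift_factor,
                 inter_computer_offset_s = inter_computer_offset_s,
                 usb_latency_mean_s = usb_latency_mean_s,
                 usb_tail_prob = usb_tail_prob, usb_tail_s = usb_tail_s),
            class = "clock_model")
}

#' Noise and contact-behaviour configuration for the simulator
#'
#' @param touch_lead_s mean time the finger contacts the key before the
#'   MIDI onset (default 0.030 s; anticipatory time is its negative).
#' @param touch_lag_s mean time the finger lingers after MIDI release
#'   (default 0.050 s).
#' @param lead_jitter_s,lag_jitter_s s.d. of per-note lead/lag jitter.
#' @param marker_jitter_frac s.d. of marker X jitter as a fraction of the
#'   white-key width.
#' @param occlusion_prob per marker-frame probability of being occluded.
#' @param moisture_frac moisture-artifact touch frames as a fraction of
#'   genuine frames; artifact areas are drawn uniformly in
#'   (0, 0.15 x nominal], below the 20% spurious-touch cut.
#' @param slide_mm along-key surface travel per contact (0 = stationary
#'   touches, giving pure lifts and falls).
#' @return list of class `noise_config`.
#' @export
noise_config <- function(touch_lead_s = 0.030, touch_lag_s = 0.050,
                         lead_jitter_s = 0, lag_jitter_s = 0,
                         marker_jitter_frac = 0, occlusion_prob = 0,
                         moisture_frac = 0, slide_mm = 0) {
  structure(as.list(environment()), class = "noise_config")
}

#' Performance scripts
#'
#' A performance script is a table of notes (midi_note, onset, release,
#' hand, finger) with times in seconds from the start of the musical
#' material. Notes of the same finger must not overlap (the fingering
#' algorithm does not handle substitutions on a held key).
#'
#' @param notes data.frame with columns midi_note, onset, release, hand,
#'   finger.
#' @param pattern label: scale, broken_chord, held_chord_plus_melody or
#'   custom.
#' @return data.frame of class `performance_script`.
#' @export
performance_script <- function(notes, pattern = "custom") {
  kf_assert(all(c("midi_note", "onset", "release", "hand", "finger") %in%
                names(notes)), "script missing columns")
  kf_assert(all(notes$finger %in% 1:5), "fingers must be 1-5")
  kf_assert(all(notes$onset < notes$release), "onset must precede release")
  for (h in unique(notes$hand)) {
    for (f in unique(notes$finger[notes$hand == h])) {
      sub <- notes[notes$hand == h & notes$finger == f, , drop = FALSE]
      sub <- sub[order(sub$onset), , drop = FALSE]
      if (nrow(sub) > 1L &&
          any(sub$onset[-1] < sub$release[-nrow(sub)] - 1e-12)) {
        kf_validation_error("infeasible script: finger %s%d has overlapping notes",
                            h, f)
      }
    }
  }
  structure(notes[order(notes$onset), , drop = FALSE],
            class = c("performance_script", "data.frame"),
            pattern = pattern)
}

#' @rdname performance_script
#' @param hand `"left"` or `"right"`.
#' @param start_note first white key of the run.
#' @param n_notes number of notes.
#' @param note_dur,ioi note duration and inter-onset interval, seconds.
#' @param fingers fingering cycle applied to the run.
#' @export
script_scale <- function(hand = "right", start_note = 60L, n_notes = 16L,
                         note_dur = 0.18, ioi = 0.25,
                         fingers = c(1L, 2L, 3L, 4L, 5L)) {
  whites <- unlist(Filter(function(n) !is_black_key(n),
                          start_note:(start_note + 60L)))
  # triangle wave over m white keys with no immediate key repeats
  m <- min(8L, max(3L, n_notes))
  p <- (seq_len(n_notes) - 1L) %% (2L * m - 2L)
  steps <- ifelse(p < m, p + 1L, 2L * m - 1L - p)
  notes <- data.frame(
    midi_note = whites[steps],
    onset = (seq_len(n_notes) - 1L) * ioi,
    release = (seq_len(n_notes) - 1L) * ioi + note_dur,
    hand = hand,
    finger = rep_len(fingers, n_notes))
  performance_script(notes, "scale")
}

#' @rdname performance_script
#' @param finger the single finger playing every note.
#' @param span alternate between `start_note` and the white key `span`
#'   white keys above it.
#' @export
script_same_finger <- function(hand = "right", finger = 2L, start_note = 60L,
                               n_notes = 8L, note_dur = 0.2, ioi = 0.5,
                               span = 2L) {
  whites <- Filter(function(n) !is_black_key(n), start_note:(start_note + 30L))
  keys <- rep(c(whites[[1]], whites[[span + 1L]]), length.out = n_notes)
  notes <- data.frame(
    midi_note = as.integer(keys),
    onset = (seq_len(n_notes) - 1L) * ioi,
    release = (seq_len(n_notes) - 1L) * ioi + note_dur,
    hand = hand, finger = finger)
  performance_script(notes, "broken_chord")
}

#' @rdname performance_script
#' @param n_bars bars of held chord (fingers 1-2) plus melody (fingers
#'   3-5).
#' @export
script_chord_melody <- function(hand = "right", start_note = 60L, n_bars = 4L,
                                bar_dur = 1.0) {
  whites <- vapply(Filter(function(n) !is_black_key(n),
                          start_note:(start_note + 40L)), identity, integer(1))
  out <- list()
  for (b in seq_len(n_bars) - 1L) {
    t0 <- b * bar_dur
    base <- 1L + (b %% 2L)
    # held chord: thumb and index
    out[[length(out) + 1L]] <- data.frame(
      midi_note = whites[c(base, base + 2L)],
      onset = t0, release = t0 + bar_dur * 0.9,
      hand = hand, finger = c(1L, 2L))
    # melody: middle, ring, little
    mel <- whites[base + c(4L, 5L, 6L, 5L)]
    out[[length(out) + 1L]] <- data.frame(
      midi_note = mel,
      onset = t0 + (0:3) * bar_dur / 4,
      release = t0 + (0:3) * bar_dur / 4 + bar_dur / 5,
      hand = hand, finger = c(3L, 4L, 5L, 4L))
  }
  performance_script(do.call(rbind, out), "held_chord_plus_melody")
}

# flat-hand vertical marker offsets (keyboard-frame px, +Y toward fallboard:
# joints sit behind the touch point as seen from above)
marker_offsets_px <- function() {
  list(finger = c(DIP = 20, PIP = 42, MCP = 66),   # cumulative from touch
       thumb = c(IP = 18, MCP = 44))
}

# home keys (flat-hand rest position): five consecutive white keys per hand,
# placed outside the played range so a resting finger never sits over a key
# another finger is playing (left hand below, right hand above the material)
home_keys <- function(hands, played_notes, map) {
  avail <- as.integer(names(map))
  whites <- sort(avail[!is_black_key(avail)])
  out <- list()
  for (h in hands) {
    if (h == "right") {
      above <- whites[whites > max(played_notes) + 2L]
      keys <- if (length(above) >= 5L) above[1:5] else tail(whites, 5)
      out$right <- setNames(keys, 1:5)            # thumb on the lowest
    } else {
      below <- whites[whites < min(played_notes) - 2L]
      keys <- if (length(below) >= 5L) tail(below, 5) else head(whites, 5)
      out$left <- setNames(rev(keys), 1:5)        # thumb on the highest
    }
  }
  out
}

# minimum-jerk interpolation between hold targets; vectorised over t
min_jerk_pos <- function(t, holds) {
  # holds: data.frame(start, end, x, y), sorted, non-overlapping
  n <- nrow(holds)
  x <- rep(holds$x[1], length(t)); y <- rep(holds$y[1], length(t))
  for (i in seq_len(n)) {
    m <- t >= holds$start[i] & t <= holds$end[i]
    x[m] <- holds$x[i]; y[m] <- holds$y[i]
    if (i < n) {
      g <- t > holds$end[i] & t < holds$start[i + 1L]
      if (any(g)) {
        u <- (t[g] - holds$end[i]) / (holds$start[i + 1L] - holds$end[i])
        s <- 10 * u^3 - 15 * u^4 + 6 * u^5
        x[g] <- holds$x[i] + (holds$x[i + 1L] - holds$x[i]) * s
        y[g] <- holds$y[i] + (holds$y[i + 1L] - holds$y[i]) * s
      }
    }
  }
  after <- t > holds$end[n]
  x[after] <- holds$x[n]; y[after] <- holds$y[n]
  data.frame(x = x, y = y)
}

# nominal touch location on a key, in normalised and pixel coordinates
key_touch_point <- function(map, note) {
  key <- map[[as.character(note)]]
  yn <- if (key$color == "black") 0.3 else 0.2
  tp <- touch_to_pixels(data.frame(midi_note = note, x_norm = 0.5, y_norm = yn),
                        map)
  list(x_norm = 0.5, y_norm = yn, x_px = tp$x_px[1], y_px = tp$y_px[1])
}

#' Simulate a recording bundle with ground truth
#'
#' Writes `markers.csv`, `touch.csv`, `midi.csv`, `midi.mid`,
#' `polygons.json`, `anchors.csv` and `ground_truth.json` into `out_dir`.
#' The recording opens with a flat-hand calibration segment (all fingers
#' resting on their home keys and touching them), followed by the
#' scripted material. Identical `(script, clock, noise, seed)` give
#' byte-identical bundles.
#'
#' @param script a `performance_script`.
#' @param out_dir output directory.
#' @param seed base RNG seed.
#' @param clock a `clock_model`.
#' @param noise a `noise_config`.
#' @param map key polygon map (default: full 88-key idealised keyboard).
#' @param cal_dur_s flat-hand calibration hold, seconds (default 1).
#' @param music_start_s unified time at which script time 0 falls
#'   (default 1.5).
#' @return invisibly, the ground-truth list.
#' @export
simulate_bundle <- function(script, out_dir, seed = 1L,
                            clock = clock_model(), noise = noise_config(),
                            map = NULL, cal_dur_s = 1.0, music_start_s = 1.5) {
  if (is.null(map)) map <- standard_keyboard_polygons()
  kf_assert(music_start_s > cal_dur_s, "music must start after calibration")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fps <- clock$camera_fps
  O <- clock$inter_computer_offset_s
  hands <- sort(unique(script$hand))
  homes <- home_keys(hands, script$midi_note, map)
  offs <- marker_offsets_px()
  ppm <- attr(map, "px_per_mm"); if (is.na(ppm)) ppm <- 2
  ww_px <- 23.5 * ppm
  wl_mm <- attr(map, "white_length_mm"); if (is.na(wl_mm)) wl_mm <- 150

  notes <- as.data.frame(script)
  notes$onset <- notes$onset + music_start_s
  notes$release <- notes$release + music_start_s

  # per-note contact lead/lag (sub-stream 6)
  set.seed(seed + 6L)
  lead <- pmax(0.005, noise$touch_lead_s + rnorm(nrow(notes), 0, noise$lead_jitter_s))
  lag <- pmax(0.005, noise$touch_lag_s + rnorm(nrow(notes), 0, noise$lag_jitter_s))
  notes$contact_start <- notes$onset - lead
  notes$contact_end <- notes$release + lag

  total_dur <- max(notes$contact_end) + 0.3
  n_frames <- ceiling(total_dur * fps) + 1L
  frame_t <- (seq_len(n_frames) - 1L) / fps
  calibration_frame <- round(cal_dur_s / 2 * fps)

  ## ---- marker stream -------------------------------------------------
  marker_rows <- list()
  hand_mcp <- list()   # per hand: matrix frames x (x of each finger MCP)
  for (h in hands) {
    mcp_x <- matrix(0, n_frames, 5); mcp_y <- matrix(0, n_frames, 5)
    for (f in 1:5) {
      tp_home <- key_touch_point(map, homes[[h]][[as.character(f)]])
      holds <- data.frame(start = -1, end = cal_dur_s,
                          x = tp_home$x_px, y = tp_home$y_px)
      sub <- notes[notes$hand == h & notes$finger == f, , drop = FALSE]
      if (nrow(sub)) {
        for (i in order(sub$contact_start)) {
          tp <- key_touch_point(map, sub$midi_note[i])
          holds <- rbind(holds, data.frame(start = sub$contact_start[i],
                                           end = sub$contact_end[i],
                                           x = tp$x_px, y = tp$y_px))
        }
      }
      # after its last note the finger retreats to its home rest position
      holds <- rbind(holds, data.frame(start = max(holds$end) + 0.4,
                                       end = total_dur + 1,
                                       x = tp_home$x_px, y = tp_home$y_px))
      holds <- holds[order(holds$start), , drop = FALSE]
      pos <- min_jerk_pos(frame_t, holds)
      lms <- if (f == 1L) offs$thumb else offs$finger
      for (lm in names(lms)) {
        marker_rows[[length(marker_rows) + 1L]] <- data.frame(
          frame_index = seq_len(n_frames) - 1L, hand = h, finger = f,
          landmark = lm, x_px = pos$x, y_px = pos$y + lms[[lm]])
      }
      mcp_x[, f] <- pos$x
      mcp_y[, f] <- pos$y + lms[["MCP"]]
    }
    cx <- rowMeans(mcp_x); cy <- rowMeans(mcp_y)
    for (w in c("wrist1", "wrist2")) {
      dx <- if (w == "wrist1") -12 else 12
      marker_rows[[length(marker_rows) + 1L]] <- data.frame(
        frame_index = seq_len(n_frames) - 1L, hand = h, finger = NA_integer_,
        landmark = w, x_px = cx + dx, y_px = cy - 40)
    }
  }
  markers <- do.call(rbind, marker_rows)
  # marker X jitter (sub-stream 2)
  if (noise$marker_jitter_frac > 0) {
    set.seed(seed + 2L)
    markers$x_px <- markers$x_px +
      rnorm(nrow(markers), 0, noise$marker_jitter_frac * ww_px)
  }
  # occlusion (sub-stream 3)
  markers$visible <- TRUE
  if (noise$occlusion_prob > 0) {
    set.seed(seed + 3L)
    markers$visible <- runif(nrow(markers)) >= noise$occlusion_prob
  }
  markers <- markers[order(markers$frame_index, markers$hand,
                           ifelse(is.na(markers$finger), 0L, markers$finger),
                           markers$landmark), , drop = FALSE]

  ## ---- touch stream --------------------------------------------------
  drift <- clock$drift_factor
  u0_dev <- -10                       # unified time at device counter zero
  set.seed(seed + 1L)                 # per-key sampling phase (sub-stream 1)
  played <- sort(unique(c(unlist(lapply(homes, unname)), notes$midi_note)))
  period_ms <- 1000 / clock$touch_rate_hz
  # the device stamps frames from its integer-ms counter, so per-key phases
  # are whole milliseconds and device timestamps are exact counter values
  phase_ms <- setNames(sample.int(max(1L, floor(period_ms)),
                                  length(played), replace = TRUE) - 1L, played)

  contacts <- data.frame(midi_note = notes$midi_note, start = notes$contact_start,
                         end = notes$contact_end, slide = noise$slide_mm)
  for (h in hands) {
    for (f in 1:5) {
      contacts <- rbind(contacts, data.frame(
        midi_note = homes[[h]][[as.character(f)]], start = 0.02,
        end = cal_dur_s, slide = 0))
    }
  }
  touch_rows <- list()
  for (i in seq_len(nrow(contacts))) {
    nt <- contacts$midi_note[i]
    tp <- key_touch_point(map, nt)
    phi <- phase_ms[[as.character(nt)]]
    # device milliseconds (true, real-valued) covering the contact
    d0 <- (contacts$start[i] - u0_dev) / drift * 1000
    d1 <- (contacts$end[i] - u0_dev) / drift * 1000
    k_lo <- ceiling((d0 - phi) / period_ms)
    k_hi <- floor((d1 - phi) / period_ms)
    if (k_lo > k_hi) next
    k <- k_lo:k_hi
    d_true <- phi + k * period_ms
    u <- u0_dev + d_true / 1000 * drift
    w <- if (length(u) > 1L) (u - u[1]) / (u[length(u)] - u[1]) else 0.5
    area <- round(180 * (0.6 + 0.4 * sin(pi * w)))
    yn <- tp$y_norm + contacts$slide[i] / wl_mm * w
    touch_rows[[length(touch_rows) + 1L]] <- data.frame(
      midi_note = nt, device_true_ms = d_true, unified_true_s = u,
      slot = 0L, y_norm = yn, x_norm = tp$x_norm, area = area,
      genuine = TRUE)
  }
  touches <- do.call(rbind, touch_rows)

  # moisture artifacts (sub-stream 4)
  n_moist <- round(noise$moisture_frac * nrow(touches))
  if (n_moist > 0) {
    set.seed(seed + 4L)
    keys <- sample(unique(notes$midi_note), n_moist, replace = TRUE)
    u <- runif(n_moist, cal_dur_s, total_dur - 0.1)
    moist <- data.frame(
      midi_note = keys,
      device_true_ms = (u - u0_dev) / drift * 1000,
      unified_true_s = u, slot = 0L,
      y_norm = runif(n_moist, 0.05, 0.38),
      x_norm = runif(n_moist, 0.2, 0.8),
      area = runif(n_moist, 1, 0.15 * 180),
      genuine = FALSE)
    touches <- rbind(touches, moist)
  }
  touches <- touches[order(touches$device_true_ms, touches$midi_note), , drop = FALSE]
  touches$device_ms <- floor(touches$device_true_ms)
  # recorded host timestamps: emission time plus USB latency (sub-stream 5)
  set.seed(seed + 5L)
  latency <- rep(clock$usb_latency_mean_s, nrow(touches))
  if (clock$usb_tail_prob > 0) {
    spikes <- runif(nrow(touches)) < clock$usb_tail_prob
    latency[spikes] <- latency[spikes] + runif(sum(spikes), 0, clock$usb_tail_s)
  }
  touches$host_s <- touches$unified_true_s - O + latency

  ## ---- MIDI ----------------------------------------------------------
  ev <- rbind(
    data.frame(kind = "note_on", id = notes$midi_note, host_s = notes$onset - O,
               velocity = 64L),
    data.frame(kind = "note_off", id = notes$midi_note, host_s = notes$release - O,
               velocity = 0L))
  ev <- ev[order(ev$host_s, ev$kind, ev$id), , drop = FALSE]

  ## ---- anchors: first three notes, camera onset at the nearest frame --
  first3 <- notes[order(notes$onset), ][1:min(3L, nrow(notes)), ]
  anchors <- data.frame(camera_onset_s = round(first3$onset * fps) / fps,
                        midi_onset_s = first3$onset - O)

  ## ---- write ---------------------------------------------------------
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
    df
  }
  utils::write.csv(fmt(markers[, c("frame_index", "hand", "finger", "landmark",
                                   "x_px", "y_px", "visible")]),
                   file.path(out_dir, "markers.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  tdf <- touches[, c("midi_note", "device_ms", "host_s", "slot", "y_norm",
                     "x_norm", "area")]
  utils::write.csv(fmt(tdf), file.path(out_dir, "touch.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(fmt(ev), file.path(out_dir, "midi.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  write_midi_smf(data.frame(kind = ev$kind, midi_note = as.integer(ev$id),
                            pedal_id = NA_integer_, host_s = ev$host_s,
                            velocity = ev$velocity), file.path(out_dir, "midi.mid"))
  write_polygon_map(map, file.path(out_dir, "polygons.json"))
  utils::write.csv(fmt(anchors), file.path(out_dir, "anchors.csv"),
                   row.names = FALSE, quote = FALSE)

  truth <- list(
    seed = seed,
    pattern = attr(script, "pattern"),
    clock = unclass(clock),
    noise = unclass(noise),
    device_origin_unified_s = u0_dev,
    calibration_frame = calibration_frame,
    cal_dur_s = cal_dur_s,
    music_start_s = music_start_s,
    marker_offsets_px = lapply(offs, as.list),
    home_keys = lapply(homes, as.list),
    notes = data.frame(midi_note = notes$midi_note, onset = notes$onset,
                       release = notes$release, hand = notes$hand,
                       finger = notes$finger, lead_s = lead, lag_s = lag,
                       contact_start = notes$contact_start,
                       contact_end = notes$contact_end),
    n_moisture_rows = if (n_moist > 0) n_moist else 0L,
    n_genuine_rows = sum(touches$genuine)
  )
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(truth)
}

#' Render a synthetic hands-free keyboard image
#'
#' Gray-level raster of a polygon map (white keys light, black keys dark,
#' uniform background), with known boundary rows and blob centroids
#' returned as ground truth. Rendered in image convention (row 1 at the
#' fallboard side); the detection frame maps back via
#' `x_det = x_kb + dx`, `y_det = y_kb + dy`.
#'
#' @param map a `key_polygon_map`.
#' @param margin_px background margin around the keyboard.
#' @param bg,white,black gray levels.
#' @param noise_sd additive Gaussian pixel noise s.d.
#' @param seed RNG seed for the noise.
#' @return list(image, truth) where truth holds boundaries, black-key
#'   centroids (detection frame) and the keyboard-to-detection offsets.
#' @export
render_keyboard_image <- function(map, margin_px = 20, bg = 0.45, white = 0.9,
                                  black = 0.1, noise_sd = 0, seed = 1L) {
  xs <- unlist(lapply(map, function(k) k$vertices[, 1]))
  ys <- unlist(lapply(map, function(k) k$vertices[, 2]))
  xmin <- min(xs); xmax <- max(xs); ymin <- min(ys); ymax <- max(ys)
  W <- ceiling(xmax - xmin) + 2L * margin_px
  H <- ceiling(ymax - ymin) + 2L * margin_px
  dx <- margin_px - xmin; dy <- margin_px - ymin
  img <- matrix(bg, H, W)
  fill <- function(x0, x1, y0, y1, val) {
    cs <- max(1L, ceiling(x0 + 0.5)):min(W, floor(x1 + 0.5))
    rs <- max(1L, ceiling(H - y1 + 0.5)):min(H, floor(H - y0 + 0.5))
    img[rs, cs] <<- val
  }
  for (k in map) {
    if (k$color == "white") {
      v <- k$vertices
      fill(min(v[, 1]) + dx, max(v[, 1]) + dx,
           min(v[, 2]) + dy, max(v[, 2]) + dy, white)
    }
  }
  cent <- list()
  for (nm in names(map)) {
    k <- map[[nm]]
    if (k$color == "black") {
      v <- k$vertices
      fill(min(v[, 1]) + dx, max(v[, 1]) + dx,
           min(v[, 2]) + dy, max(v[, 2]) + dy, black)
      cent[[length(cent) + 1L]] <- data.frame(
        midi_note = as.integer(nm),
        cx = mean(range(v[, 1])) + dx, cy = mean(range(v[, 2])) + dy)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  whites <- Filter(function(k) k$color == "white", map)
  blacks <- Filter(function(k) k$color == "black", map)
  truth <- list(
    y_white_bottom = min(vapply(whites, function(k) min(k$vertices[, 2]), numeric(1))) + dy,
    y_black_bottom = min(vapply(blacks, function(k) min(k$vertices[, 2]), numeric(1))) + dy,
    y_top = ymax + dy,
    black_centroids = do.call(rbind, cent),
    offset = c(dx = dx, dy = dy))
  list(image = img, truth = truth)
}
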