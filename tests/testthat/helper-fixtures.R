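# Shared fixtures. Expensive simulated bundles are built once per test run
# and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# simulate a bundle into a session temp dir and return its path + truth
sim_fixture <- function(name, script, seed, clock = clock_model(),
                        noise = noise_config(), map = NULL) {
  cached(name, {
    dir <- file.path(tempdir(), paste0("kf_", name))
    truth <- simulate_bundle(script, dir, seed = seed, clock = clock,
                             noise = noise, map = map)
    list(dir = dir, truth = truth)
  })
}

truth_notes <- function(fx) {
  df <- as.data.frame(fx$truth$notes)
  df[order(df$onset), , drop = FALSE]
}

# 60 s recording with an injected touch-clock drift factor
drift_fixture <- function(f) {
  sim_fixture(sprintf("drift_%d", round(f * 1e4)),
              script_scale(n_notes = 8, ioi = 7.3, note_dur = 6.5),
              seed = 41,
              clock = clock_model(drift_factor = f,
                                  inter_computer_offset_s = 0.25))
}

# independent point-in-polygon oracle: winding number by signed angle
# summation (different algorithm from the ray-crossing implementation)
winding_inside <- function(px, py, verts, eps = 1e-9) {
  n <- nrow(verts)
  vapply(seq_along(px), function(i) {
    dx <- verts[, 1] - px[i]; dy <- verts[, 2] - py[i]
    # on-edge check
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      cr <- dx[j] * dy[k] - dy[j] * dx[k]
      dt <- dx[j] * (px[i] - verts[k, 1]) + dy[j] * (py[i] - verts[k, 2])
      seglen <- sqrt((verts[k, 1] - verts[j, 1])^2 + (verts[k, 2] - verts[j, 2])^2)
      if (abs(cr) <= eps * (seglen + 1) &&
          px[i] >= min(verts[c(j, k), 1]) - eps && px[i] <= max(verts[c(j, k), 1]) + eps &&
          py[i] >= min(verts[c(j, k), 2]) - eps && py[i] <= max(verts[c(j, k), 2]) + eps) {
        return(TRUE)
      }
    }
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi            # |winding| >= 2*pi means inside
  }, logical(1))
}

# minimal in-memory aligned+fingered bundle for metric unit tests:
# one finger, two notes on two keys, fully scripted trajectories
tiny_metric_bundle <- function() {
  map <- standard_keyboard_polygons(55L, 65L, px_per_mm = 2)
  # notes: [0,1] on key 60, [2,3] on key 62; blocks [-0.1,0.9], [2.1,3.05]
  notes <- data.frame(note_id = 1:2, midi_note = c(60L, 62L),
                      onset = c(0, 2), release = c(1, 3),
                      hand = "right", finger = 2L, n_touch = 10L,
                      block_id = 1:2, block_start = c(-0.1, 2.1),
                      block_end = c(0.9, 3.05))
  tp1 <- touch_to_pixels(data.frame(midi_note = 60L, x_norm = 0.5, y_norm = 0.2), map)
  tp2 <- touch_to_pixels(data.frame(midi_note = 62L, x_norm = 0.5, y_norm = 0.2), map)
  mk_touch <- function(block, note, t, x, y) {
    data.frame(midi_note = note, device_ms = round(t * 1000), host_s = t,
               slot = 0L, y_norm = 0.2, x_norm = 0.5, area = 180,
               block_id = block, unified_s = t, x_px = x, y_px = y,
               hand = "right", finger = 2L, tf_hand = "right", tf_finger = 2L)
  }
  t1 <- seq(-0.1, 0.9, by = 0.005)
  t2 <- seq(2.1, 3.05, by = 0.005)
  touches <- rbind(mk_touch(1L, 60L, t1, tp1$x_px, tp1$y_px),
                   mk_touch(2L, 62L, t2, tp2$x_px, tp2$y_px))
  # distal marker: constant speed along X across the whole span
  ft <- seq(-0.2, 3.2, by = 0.01)
  markers <- data.frame(frame_index = seq_along(ft) - 1L, hand = "right",
                        finger = 2L, landmark = "DIP",
                        x_px = tp1$x_px + 30 * (ft + 0.2),
                        y_px = tp1$y_px + 20, visible = TRUE, time_s = ft)
  structure(list(markers = markers, touches = touches, midi = NULL,
                 polygons = map, notes = notes,
                 alignment = structure(list(camera_fps = 100,
                                            touch_rate_factor = 1,
                                            touch_epoch = 0, midi_offset = 0,
                                            per_frame_latency = 0),
                                       class = "alignment_result"),
                 blocks = data.frame(block_id = 1:2, midi_note = c(60L, 62L),
                                     start = c(-0.1, 2.1), end = c(0.9, 3.05),
                                     n_frames = c(length(t1), length(t2)))),
            class = "recording_bundle")
}
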