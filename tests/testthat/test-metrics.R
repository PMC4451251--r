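test_that("curvature index is the calibrated distance ratio", {
  expect_equal(curvature_index(30, 30), 1)      # fully extended (flat)
  expect_equal(curvature_index(0, 30), 0)       # fully vertical
  expect_equal(curvature_index(15, 30), 0.5)
  expect_error(curvature_index(10, 0), "calibration")
  expect_error(curvature_index(10, -2), "calibration")
  # monotone in d; invariant under global scaling
  d <- seq(0, 50, by = 5)
  expect_true(all(diff(curvature_index(d, 40)) > 0))
  expect_equal(curvature_index(d * 2, 40 * 2), curvature_index(d, 40))
})

test_that("a flat simulated performance yields CI of 1 everywhere", {
  fx <- sim_fixture("small", script_scale(n_notes = 8), seed = 3,
                    clock = clock_model(inter_computer_offset_s = 1.234,
                                        drift_factor = 1.0001))
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  ci <- ci_series(b, calibration = 0L)
  expect_gt(nrow(ci), 100)
  expect_equal(ci$ci, rep(1, nrow(ci)), tolerance = 1e-6)
  # thumbs report the proximal-touch relation only
  expect_true(all(ci$phalanx[ci$finger == 1L] == "proximal"))
  expect_true(all(c("distal", "proximal") %in% ci$phalanx[ci$finger != 1L]))
})

test_that("a curled finger drives the distal CI toward zero", {
  b <- tiny_metric_bundle()
  # distal marker directly above the touch point for note 1's frames
  tp <- touch_to_pixels(data.frame(midi_note = 60L, x_norm = 0.5, y_norm = 0.2),
                        b$polygons)
  curl <- b$markers$time_s >= -0.1 & b$markers$time_s <= 0.9
  b$markers$x_px[curl] <- tp$x_px
  b$markers$y_px[curl] <- tp$y_px
  calib <- data.frame(hand = "right", finger = 2L,
                      phalanx = c("distal", "proximal"), d_ref = c(20, 22))
  ci <- ci_series(b, calib)
  d1 <- ci[ci$note_id == 1L & ci$phalanx == "distal", ]
  expect_equal(d1$ci, rep(0, nrow(d1)), tolerance = 1e-9)
})

test_that("the signed CI variant flips sign past the touch point", {
  b <- tiny_metric_bundle()
  # distal marker bent past the touch: on the player side (lower Y)
  tp <- touch_to_pixels(data.frame(midi_note = 60L, x_norm = 0.5, y_norm = 0.2),
                        b$polygons)
  bent <- b$markers$time_s >= -0.1 & b$markers$time_s <= 0.9
  b$markers$x_px[bent] <- tp$x_px
  b$markers$y_px[bent] <- tp$y_px - 10
  calib <- data.frame(hand = "right", finger = 2L,
                      phalanx = c("distal", "proximal"), d_ref = c(20, 22))
  plain <- ci_series(b, calib)
  signed <- ci_series(b, calib, signed = TRUE)
  d_plain <- plain$ci[plain$note_id == 1L & plain$phalanx == "distal"]
  d_signed <- signed$ci[signed$note_id == 1L & signed$phalanx == "distal"]
  expect_true(all(d_plain > 0))
  expect_equal(d_signed, -d_plain)
})

test_that("CI series is invariant under uniform coordinate scaling", {
  fx <- sim_fixture("small", script_scale(n_notes = 8), seed = 3,
                    clock = clock_model(inter_computer_offset_s = 1.234,
                                        drift_factor = 1.0001))
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  ci1 <- ci_series(b, 0L)
  b2 <- b
  b2$markers$x_px <- b2$markers$x_px * 2
  b2$markers$y_px <- b2$markers$y_px * 2
  b2$touches$x_px <- b2$touches$x_px * 2
  b2$touches$y_px <- b2$touches$y_px * 2
  calib2 <- calibrate_reference(b2, 0L)
  ci2 <- ci_series(b2, calib2)
  expect_equal(ci2$ci, ci1$ci, tolerance = 1e-9)
})

test_that("contact timing signs follow the block/note offsets", {
  mk_note <- function(id, on, off, bs, be, f = 2L) {
    data.frame(note_id = id, midi_note = 60L, onset = on, release = off,
               hand = "right", finger = f, block_id = id,
               block_start = bs, block_end = be)
  }
  # five notes so the middle ones survive the first/last exclusion
  notes <- rbind(mk_note(1L, 0, 1, -0.02, 1.0),
                 mk_note(2L, 2, 3, 1.97, 3.05),   # 30 ms lead, 50 ms lag
                 mk_note(3L, 4, 5, 4.0, 5.0),     # exact span
                 mk_note(4L, 6, 7, 5.99, 7.01),
                 mk_note(5L, 8, 9, 7.98, 9.02))
  tm <- contact_timing(notes)
  expect_equal(tm$note_id, 2:4)
  expect_equal(tm$anticipatory_s[1], -0.030)
  expect_equal(tm$release_time_s[1], 0.050)
  expect_equal(tm$anticipatory_s[2], 0)
  expect_equal(tm$release_time_s[2], 0)
  ex <- attr(tm, "excluded")
  expect_equal(ex$first_last_per_finger, 2L)
})

test_that("configured lead and lag are recovered within one sample period", {
  fx <- cached("leadlag", {
    dir <- file.path(tempdir(), "kf_leadlag")
    truth <- simulate_bundle(
      script_scale(n_notes = 30), dir, seed = 29,
      clock = clock_model(inter_computer_offset_s = 0.9,
                          drift_factor = 1.0002),
      noise = noise_config(touch_lead_s = 0.030, touch_lag_s = 0.050,
                           lead_jitter_s = 0.008, lag_jitter_s = 0.008))
    list(dir = dir, truth = truth)
  })
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  tm <- contact_timing(b$notes)
  tn <- truth_notes(fx)
  tn$note_id <- seq_len(nrow(tn))
  m <- merge(tm, tn[, c("note_id", "lead_s", "lag_s")], by = "note_id")
  expect_gte(nrow(m), 20L)
  expect_true(all(abs(m$anticipatory_s - (-m$lead_s)) < 0.005))
  expect_true(all(abs(m$release_time_s - m$lag_s) < 0.005))
})

test_that("transition windows partition midpoint-to-midpoint", {
  b <- tiny_metric_bundle()
  tw <- build_transitions(b)
  expect_equal(nrow(tw), 3L)
  expect_equal(unique(tw$t_start), 0.5)
  expect_equal(unique(tw$t_end), 2.5)
  expect_equal(tw$seg_start, c(0.5, 0.9, 2.1))
  expect_equal(tw$seg_end, c(0.9, 2.1, 2.5))
  expect_equal(tw$segment, c("release", "no_touch", "press"))
  # abutting blocks give a zero-span flagged no-touch segment
  b2 <- b
  b2$notes$block_end[1] <- 1.6
  b2$notes$block_start[2] <- 1.6
  tw2 <- build_transitions(b2)
  expect_equal(tw2$t_span[tw2$segment == "no_touch"], 0)
})

test_that("uniform-speed motion gives QMI of 1 in every segment", {
  b <- tiny_metric_bundle()       # marker moves at constant velocity
  tw <- build_transitions(b)
  expect_equal(tw$qmi_marker, rep(1, 3), tolerance = 1e-9)
})

test_that("QoM is additive and QMI identities hold on simulated windows", {
  fx <- cached("samefinger", {
    dir <- file.path(tempdir(), "kf_samefinger")
    truth <- simulate_bundle(script_same_finger(n_notes = 8), dir, seed = 31,
                             clock = clock_model(inter_computer_offset_s = 0.7))
    list(dir = dir, truth = truth)
  })
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  tw <- build_transitions(b)
  expect_equal(length(unique(tw$window_id)), 7L)     # n - 1 windows
  for (w in unique(tw$window_id)) {
    seg <- tw[tw$window_id == w, ]
    expect_true(all(seg$qom_marker_px >= 0))
    t_trans <- seg$t_end[1] - seg$t_start[1]
    # sum of segment QoM equals the whole-window path length exactly
    qom_trans <- sum(seg$qom_marker_px)
    ok <- !is.na(seg$qmi_marker)
    if (any(ok)) {
      expect_equal(sum(seg$qmi_marker[ok] * seg$t_span[ok] / t_trans) +
                     sum(seg$qom_marker_px[!ok]) / qom_trans,
                   1, tolerance = 1e-9)
    }
  }
})

test_that("QoM never undercuts the straight-line displacement", {
  fx <- cached("samefinger", {
    dir <- file.path(tempdir(), "kf_samefinger")
    truth <- simulate_bundle(script_same_finger(n_notes = 8), dir, seed = 31,
                             clock = clock_model(inter_computer_offset_s = 0.7))
    list(dir = dir, truth = truth)
  })
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  tw <- build_transitions(b)
  mk <- b$markers[b$markers$landmark == "DIP" & b$markers$finger == 2L, ]
  for (i in seq_len(nrow(tw))) {
    xs <- approx(mk$time_s, mk$x_px, c(tw$seg_start[i], tw$seg_end[i]), rule = 2)$y
    ys <- approx(mk$time_s, mk$y_px, c(tw$seg_start[i], tw$seg_end[i]), rule = 2)$y
    disp <- sqrt(diff(xs)^2 + diff(ys)^2)
    expect_gte(tw$qom_marker_px[i] + 1e-9, disp)
  }
})

test_that("the QMI formula is unit-invariant and handles degenerate inputs", {
  expect_equal(qmi(10, 40, 0.25, 1), 1)            # uniform speed
  expect_equal(qmi(40, 40, 0.25, 1), 4)            # all motion in 1/4 window
  expect_equal(qmi(10, 40, 250, 1000), qmi(10, 40, 0.25, 1))  # s -> ms
  expect_true(is.na(qmi(0, 0, 0.25, 1)))
  expect_true(is.na(qmi(1, 10, 0, 1)))
})

test_that("surface motion classifies as lift, fall, or slide", {
  expect_equal(classify_touch_motion(0, "release"), "lift")
  expect_equal(classify_touch_motion(0, "press"), "fall")
  expect_equal(classify_touch_motion(5, "release"), "slide")
  expect_equal(classify_touch_motion(1, "press"), "slide")   # >= convention
  expect_true(is.na(classify_touch_motion(NA_real_, "press")))
  # stationary simulated touches label every segment lift/fall
  fx <- cached("samefinger", {
    dir <- file.path(tempdir(), "kf_samefinger")
    truth <- simulate_bundle(script_same_finger(n_notes = 8), dir, seed = 31,
                             clock = clock_model(inter_computer_offset_s = 0.7))
    list(dir = dir, truth = truth)
  })
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  tw <- build_transitions(b)
  expect_true(all(tw$label[tw$segment == "release"] == "lift", na.rm = TRUE))
  expect_true(all(tw$label[tw$segment == "press"] == "fall", na.rm = TRUE))
})
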