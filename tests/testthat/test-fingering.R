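mk_touches <- function(t, note = 60L, area = 180, y = 0.2, x = 0.5) {
  empty <- !length(t)
  if (empty) t <- 0
  out <- data.frame(midi_note = note, device_ms = round(t * 1000), host_s = t,
                    slot = 0L, y_norm = y, x_norm = x, area = area,
                    unified_s = t)
  if (empty) out[0, ] else out
}

test_that("touch blocks split at gaps larger than gap_max", {
  t <- seq(0, by = 0.005, length.out = 10)
  seg <- segment_touch_blocks(mk_touches(t), gap_max_s = 0.0125)
  expect_equal(nrow(seg$blocks), 1L)
  expect_equal(seg$blocks$start, 0)
  expect_equal(seg$blocks$end, 0.045)
  # a 50 ms hole splits the run
  t2 <- c(t[1:5], t[6:10] + 0.050)
  seg2 <- segment_touch_blocks(mk_touches(t2), gap_max_s = 0.0125)
  expect_equal(nrow(seg2$blocks), 2L)
  # empty stream: zero blocks
  seg0 <- segment_touch_blocks(mk_touches(numeric(0)), gap_max_s = 0.0125)
  expect_equal(nrow(seg0$blocks), 0L)
})

test_that("spurious touches are removed by the 20% area rule", {
  tc <- mk_touches(c(0, 0.005, 0.010), area = c(100, 15, 30))
  out <- filter_spurious(tc)
  expect_equal(out$area, c(100, 30))            # 15 < 20% of 100
  # equal areas all survive
  tc2 <- mk_touches(c(0, 0.005), area = c(50, 50))
  expect_equal(nrow(filter_spurious(tc2)), 2L)
  # idempotence
  expect_identical(filter_spurious(filter_spurious(tc)), filter_spurious(tc))
})

test_that("the filter never removes a block's maximum-area frame", {
  fx <- cached("moist", {
    dir <- file.path(tempdir(), "kf_moist")
    truth <- simulate_bundle(script_scale(n_notes = 16), dir, seed = 23,
                             clock = clock_model(inter_computer_offset_s = 0.4),
                             noise = noise_config(moisture_frac = 0.05))
    list(dir = dir, truth = truth)
  })
  b <- align_bundle(read_bundle_dir(fx$dir))
  seg <- segment_touch_blocks(b$touches)
  kept <- filter_spurious(seg$touches)
  # blocks carrying a note's contact (moisture-only blocks are wholly spurious)
  for (i in seq_len(nrow(b$notes))) {
    bl <- seg$blocks[seg$blocks$midi_note == b$notes$midi_note[i] &
                     seg$blocks$start <= b$notes$release[i] &
                     seg$blocks$end >= b$notes$onset[i], ]
    for (bid in bl$block_id) {
      rows <- seg$touches[seg$touches$block_id == bid, ]
      top <- rows$device_ms[which.max(rows$area)]
      expect_true(top %in% kept$device_ms[kept$midi_note == rows$midi_note[1]])
    }
  }
  # all simulated moisture rows (area <= 15% of nominal) are gone
  expect_equal(sum(kept$area < 0.2 * 180),
               0L)
})

test_that("per-touch fingers follow the nearest distal marker in X", {
  markers <- data.frame(frame_index = 0L, hand = "right", finger = c(2L, 3L),
                        landmark = "DIP", x_px = c(298, 320), y_px = 100,
                        visible = TRUE, time_s = 0)
  tc <- mk_touches(0)
  tc$x_px <- 300; tc$y_px <- 90
  out <- assign_touch_finger(tc, markers)
  expect_equal(out$tf_finger, 2L)
  # exact tie in |dX| goes to the lower finger number
  markers$x_px <- c(305, 295)
  expect_equal(assign_touch_finger(tc, markers)$tf_finger, 2L)
  # no visible distal marker: unassigned
  markers$visible <- FALSE
  expect_true(is.na(assign_touch_finger(tc, markers)$tf_finger))
})

test_that("per-touch assignment matches the script on a noise-free simulation", {
  fx <- sim_fixture("small", script_scale(n_notes = 8), seed = 3,
                    clock = clock_model(inter_computer_offset_s = 1.234,
                                        drift_factor = 1.0001))
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  tn <- truth_notes(fx)
  for (i in seq_len(nrow(tn))) {
    sel <- b$touches$midi_note == tn$midi_note[i] &
      b$touches$unified_s >= tn$onset[i] & b$touches$unified_s <= tn$release[i]
    expect_true(all(b$touches$tf_finger[sel] == tn$finger[i]),
                label = sprintf("note %d touches match script finger", i))
  }
})

test_that("note fingering is a plurality vote with documented tie-breaks", {
  notes <- data.frame(note_id = 1L, midi_note = 60L, onset = 0, release = 1)
  tc <- mk_touches(seq(0, 0.12, by = 0.01))
  tc$tf_hand <- "right"
  tc$tf_finger <- c(rep(1L, 10), rep(2L, 3))
  out <- assign_note_fingering(notes, tc)
  expect_equal(out$finger, 1L)
  # tie: finger of the temporally later touches wins
  tc2 <- mk_touches(seq(0, 0.05, by = 0.01))
  tc2$tf_hand <- "right"
  tc2$tf_finger <- c(3L, 3L, 3L, 4L, 4L, 4L)
  expect_equal(assign_note_fingering(notes, tc2)$finger, 4L)
  # counting is order-free
  perm <- tc2[sample.int(nrow(tc2)), ]
  expect_equal(assign_note_fingering(notes, perm)$finger, 4L)
  # zero touches: unfingered with a warning
  expect_warning(out0 <- assign_note_fingering(notes, tc2[0, ]), "unfingered")
  expect_true(is.na(out0$finger))
})

test_that("second pass corrects strays and resolves bridging blocks", {
  notes <- data.frame(note_id = 1:2, midi_note = 60L,
                      onset = c(0, 1.5), release = c(1.0, 2.5),
                      hand = "right", finger = c(3L, 1L))
  # one stray f2 frame inside note 1 (a finger passing above the key)
  tc <- mk_touches(seq(0.1, 0.9, by = 0.1))
  tc$block_id <- 1L
  tc$tf_hand <- "right"
  tc$tf_finger <- c(3L, 3L, 3L, 2L, 3L, 3L, 3L, 3L, 3L)
  out <- second_pass_correct(tc, notes)
  expect_equal(out$finger, rep(3L, 9))
  # pre-onset block contiguous with the following note inherits its finger
  pre <- mk_touches(seq(1.42, 1.55, by = 0.01))
  pre$block_id <- 2L
  pre$tf_hand <- "right"; pre$tf_finger <- 5L
  out2 <- second_pass_correct(pre, notes)
  expect_equal(unique(out2$finger), 1L)
  # block bridging release of note 1 (t=1.0) and onset of note 2 (t=1.5):
  # frame at t=1.1 is closer to note 1
  bridge <- mk_touches(seq(0.9, 1.6, by = 0.05))
  bridge$block_id <- 3L
  bridge$tf_hand <- "right"; bridge$tf_finger <- 5L
  out3 <- second_pass_correct(bridge, notes)
  expect_equal(out3$finger[abs(out3$unified_s - 1.1) < 1e-9], 3L)
  expect_equal(out3$finger[abs(out3$unified_s - 1.4) < 1e-9], 1L)
  # an unconnected block keeps its first-pass fingers
  lone <- mk_touches(seq(5, 5.1, by = 0.05), note = 64L)
  lone$block_id <- 4L
  lone$tf_hand <- "right"; lone$tf_finger <- 4L
  expect_equal(unique(second_pass_correct(lone, notes)$finger), 4L)
})

test_that("noise-free fingering matches ground truth on every note", {
  fx <- cached("sim100", {
    dir <- file.path(tempdir(), "kf_sim100")
    truth <- simulate_bundle(script_scale(n_notes = 100), dir, seed = 19,
                             clock = clock_model(inter_computer_offset_s = 0.5))
    list(dir = dir, truth = truth)
  })
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  tn <- truth_notes(fx)
  expect_equal(b$notes$finger, tn$finger)
  expect_equal(b$notes$hand, tn$hand)
})
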