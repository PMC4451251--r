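test_that("a simulated bundle reads back with identical record counts", {
  fx <- sim_fixture("small", script_scale(n_notes = 8), seed = 3,
                    clock = clock_model(inter_computer_offset_s = 1.234,
                                        drift_factor = 1.0001))
  b <- read_bundle_dir(fx$dir)
  mk <- utils::read.csv(file.path(fx$dir, "markers.csv"))
  tc <- utils::read.csv(file.path(fx$dir, "touch.csv"))
  expect_equal(nrow(b$markers), nrow(mk))
  expect_equal(nrow(b$touches), nrow(tc))
  expect_equal(nrow(b$midi), 16L)            # 8 notes on + off
  expect_length(b$polygons, 88L)
  expect_null(b$alignment)
  expect_false("unified_s" %in% names(b$touches))
})

test_that("validation rejects exactly the offending records", {
  tf <- data.frame(midi_note = c(60L, 60L), device_ms = c(0, 5),
                   host_s = c(0, 0.005), slot = 0L,
                   y_norm = c(0.5, 1.2), x_norm = 0.5, area = 100)
  err <- expect_error(validate_touches(tf), class = "keyfusion_validation_error")
  expect_match(conditionMessage(err), "y_norm")
  expect_match(conditionMessage(err), "rows 2")
  expect_silent(validate_touches(tf[1, , drop = FALSE]))

  mk <- data.frame(frame_index = 0L, hand = "right", finger = 1L,
                   landmark = "DIP", x_px = 0, y_px = 0, visible = TRUE)
  expect_error(validate_markers(mk), "thumb")
  mk$landmark <- "IP"
  expect_silent(validate_markers(mk))

  ev <- data.frame(kind = c("note_on", "note_on"), midi_note = 60L,
                   pedal_id = NA_integer_, host_s = c(0, 1), velocity = 64L)
  expect_error(validate_midi(ev), "alternate")
})

test_that("an empty MIDI stream loads with zero notes and a warning", {
  fx <- sim_fixture("small", script_scale(n_notes = 8), seed = 3,
                    clock = clock_model(inter_computer_offset_s = 1.234,
                                        drift_factor = 1.0001))
  dir <- withr::local_tempdir()
  file.copy(list.files(fx$dir, full.names = TRUE), dir)
  writeLines("kind,id,host_s,velocity", file.path(dir, "midi.csv"))
  expect_warning(b <- read_bundle_dir(dir), "zero notes")
  b <- align_bundle(b)
  expect_equal(nrow(b$notes), 0L)
})

test_that("polygon map invariants are enforced", {
  map <- standard_keyboard_polygons(48L, 72L)
  expect_silent(validate_polygon_map(map))
  blacks <- vapply(map, function(k) k$color == "black", logical(1))
  expect_true(all(vapply(map[blacks], function(k) nrow(k$vertices) == 4L,
                         logical(1))))
  nverts <- vapply(map[!blacks], function(k) nrow(k$vertices), integer(1))
  expect_true(all(nverts >= 4L & nverts <= 8L))
  # a black key with 5 vertices is rejected
  bad <- unclass(map)
  nm <- names(which(blacks))[1]
  bad[[nm]]$vertices <- rbind(bad[[nm]]$vertices, bad[[nm]]$vertices[1, ] + 1)
  expect_error(key_polygon_map(bad), "4 vertices")
  # overlapping keys are rejected
  bad2 <- unclass(map)
  bad2[[nm]]$vertices <- bad2[[nm]]$vertices + c(30, 30, 30, 30, 0, 0, 0, 0)
  expect_error(key_polygon_map(bad2), "overlap")
})

test_that("polygon map JSON roundtrips exactly", {
  map <- standard_keyboard_polygons(60L, 72L, px_per_mm = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_polygon_map(map, path)
  map2 <- read_polygon_map(path)
  expect_equal(names(map2), names(map))
  for (nm in names(map)) {
    expect_equal(map2[[nm]]$vertices, map[[nm]]$vertices)
    expect_equal(map2[[nm]]$color, map[[nm]]$color)
  }
  expect_equal(attr(map2, "px_per_mm"), 3)
})

test_that("SMF write/read roundtrips events and honours the tempo map", {
  ev <- data.frame(kind = c("note_on", "note_off", "note_on", "pedal_on",
                            "note_off", "pedal_off"),
                   midi_note = c(60L, 60L, 64L, NA, 64L, NA),
                   pedal_id = c(NA, NA, NA, 64L, NA, 64L),
                   host_s = c(0.25, 0.75, 1.0, 1.1, 1.5, 1.9),
                   velocity = c(80L, 0L, 64L, 127L, 0L, 0L))
  path <- withr::local_tempfile(fileext = ".mid")
  write_midi_smf(ev, path)
  expect_true(is_smf(path))
  back <- read_midi_smf(path)
  expect_equal(back$kind, ev$kind)
  expect_equal(back$midi_note, ev$midi_note)
  expect_equal(back$pedal_id, ev$pedal_id)
  # writer re-zeroes at the first event; tick resolution is 960/s
  expect_equal(back$host_s, ev$host_s - 0.25, tolerance = 1e-3)
})

test_that("SMF reader handles a hand-assembled file with a tempo change", {
  # 120 bpm for one quarter (480 ticks), then 60 bpm for one quarter
  track <- as.raw(c(
    0x00, 0xFF, 0x51, 0x03, 0x07, 0xA1, 0x20,   # tempo 500000
    0x00, 0x90, 0x3C, 0x40,                     # C4 on at 0
    0x83, 0x60, 0xFF, 0x51, 0x03, 0x0F, 0x42, 0x40,  # +480 ticks: tempo 1000000
    0x83, 0x60, 0x80, 0x3C, 0x40,               # +480 ticks: C4 off
    0x00, 0xFF, 0x2F, 0x00))
  bytes <- c(charToRaw("MThd"), as.raw(c(0, 0, 0, 6, 0, 0, 0, 1, 1, 0xE0)),
             charToRaw("MTrk"),
             as.raw(c(0, 0, 0, length(track))), track)
  path <- withr::local_tempfile(fileext = ".mid")
  writeBin(bytes, path)
  ev <- read_midi_smf(path)
  expect_equal(ev$kind, c("note_on", "note_off"))
  # 480 ticks at 0.5 s/quarter, then 480 ticks at 1.0 s/quarter
  expect_equal(ev$host_s, c(0, 1.5))
})

test_that("note segmentation pairs alternating on/off per pitch", {
  ev <- data.frame(kind = rep(c("note_on", "note_off"), 3),
                   midi_note = c(60L, 60L, 62L, 62L, 60L, 60L),
                   pedal_id = NA_integer_,
                   host_s = c(0, 0.5, 0.25, 0.6, 1.0, 1.4),
                   velocity = 64L)
  notes <- segment_notes(ev, "host_s")
  expect_equal(nrow(notes), 3L)
  expect_equal(notes$midi_note, c(60L, 62L, 60L))
  expect_equal(notes$onset, c(0, 0.25, 1.0))
  expect_equal(notes$release, c(0.5, 0.6, 1.4))
})

test_that("write_annotated roundtrips and rejects unprocessed bundles", {
  fx <- sim_fixture("small", script_scale(n_notes = 8), seed = 3,
                    clock = clock_model(inter_computer_offset_s = 1.234,
                                        drift_factor = 1.0001))
  raw <- read_bundle_dir(fx$dir)
  expect_error(write_annotated(raw, tempfile()), "aligned")
  b <- finger_bundle(align_bundle(raw))
  tr <- build_transitions(b)
  out <- withr::local_tempdir()
  write_annotated(b, out, transitions = tr)
  notes2 <- utils::read.csv(file.path(out, "notes.csv"))
  expect_equal(nrow(notes2), nrow(b$notes))
  expect_identical(notes2$midi_note, b$notes$midi_note)
  expect_identical(notes2$finger, b$notes$finger)
  expect_equal(notes2$onset, b$notes$onset, tolerance = 1e-10)
  expect_equal(notes2$release, b$notes$release, tolerance = 1e-10)
  touch2 <- utils::read.csv(file.path(out, "touch_annotated.csv"))
  expect_equal(nrow(touch2), nrow(b$touches))
  expect_equal(touch2$unified_s, b$touches$unified_s, tolerance = 1e-10)
  tr2 <- utils::read.csv(file.path(out, "transitions.csv"))
  expect_equal(nrow(tr2), nrow(tr))
})

test_that("transitions rows equal the count of consecutive same-finger pairs", {
  fx <- cached("sim100", {
    dir <- file.path(tempdir(), "kf_sim100")
    truth <- simulate_bundle(script_scale(n_notes = 100), dir, seed = 19,
                             clock = clock_model(inter_computer_offset_s = 0.5))
    list(dir = dir, truth = truth)
  })
  b <- finger_bundle(align_bundle(read_bundle_dir(fx$dir)))
  tw <- build_transitions(b)
  tn <- truth_notes(fx)
  expected <- sum(vapply(split(tn, paste(tn$hand, tn$finger)),
                         function(d) nrow(d) - 1L, integer(1)))
  expect_equal(length(unique(tw$window_id)), expected)
})
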