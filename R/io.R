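## Readers, writers and validation for every table the pipeline touches.
## All CSV dialects: UTF-8, comma-separated, header row, times in decimal
## seconds except device_ms (integer milliseconds on the touch device clock).

KF_HANDS <- c("left", "right")
KF_LANDMARKS <- c("wrist1", "wrist2", "MCP", "PIP", "DIP", "IP")
KF_MIDI_KINDS <- c("note_on", "note_off", "pedal_on", "pedal_off")

#' Read and validate a marker-track CSV
#'
#' Columns: `frame_index, hand, finger, landmark, x_px, y_px, visible`.
#' One row per marker per camera frame; positions are keyboard-frame
#' pixels. Wrist rows carry landmark `wrist1`/`wrist2` and an empty finger
#' field; the thumb carries `MCP` and `IP` (its interphalangeal joint,
#' reported as "proximal"), other fingers `MCP`, `PIP`, `DIP`.
#'
#' @param path CSV file.
#' @return data.frame of marker rows.
#' @export
read_markers <- function(path) {
  kf_assert(file.exists(path), "marker file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "hand", "finger", "landmark", "x_px", "y_px", "visible")
  kf_assert(all(need %in% names(df)), "%s: missing columns: %s", path,
            paste(setdiff(need, names(df)), collapse = ", "))
  df$frame_index <- as.integer(df$frame_index)
  df$finger <- suppressWarnings(as.integer(df$finger))
  df$visible <- as.logical(df$visible)
  validate_markers(df, file = path)
  df
}

#' @rdname read_markers
#' @param df marker data.frame.
#' @param file label used in error messages.
#' @export
validate_markers <- function(df, file = "markers") {
  bad <- function(rows, why) {
    if (any(rows)) {
      kf_validation_error("%s: %s (rows %s)", file, why,
                          paste(utils::head(which(rows), 10), collapse = ", "))
    }
  }
  bad(is.na(df$frame_index) | df$frame_index < 0L, "frame_index must be >= 0")
  bad(!(df$hand %in% KF_HANDS), "hand must be left/right")
  bad(!(df$landmark %in% KF_LANDMARKS), "unknown landmark")
  is_wrist <- df$landmark %in% c("wrist1", "wrist2")
  bad(!is_wrist & (is.na(df$finger) | df$finger < 1L | df$finger > 5L),
      "finger must be 1-5 for joint markers")
  bad(df$finger %in% 1L & df$landmark %in% c("PIP", "DIP"),
      "thumb carries MCP and IP only")
  bad(!(df$finger %in% 1L) & df$landmark == "IP",
      "IP landmark is thumb-only")
  key <- paste(df$frame_index, df$hand, df$finger, df$landmark)
  bad(duplicated(key), "duplicate (frame, hand, finger, landmark)")
  frames <- unique(df$frame_index)
  kf_assert(!is.unsorted(frames, strictly = FALSE),
            "%s: frame_index must be non-decreasing in file order", file)
  invisible(df)
}

#' Read and validate a touch-frame CSV
#'
#' Columns: `midi_note, device_ms, host_s, slot, y_norm, x_norm, area`.
#' One row per touch slot (0--2) per sensor frame. `y_norm` runs 0 at the
#' key front edge (player side) to 1 at the fallboard end; `x_norm` runs 0
#' at the bass-side edge and is empty on the rear part of white keys, which
#' senses Y only. `area` is the raw 8-bit contact area.
#'
#' @param path CSV file.
#' @return data.frame of touch rows.
#' @export
read_touches <- function(path) {
  kf_assert(file.exists(path), "touch file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("midi_note", "device_ms", "host_s", "slot", "y_norm", "x_norm", "area")
  kf_assert(all(need %in% names(df)), "%s: missing columns: %s", path,
            paste(setdiff(need, names(df)), collapse = ", "))
  df$midi_note <- as.integer(df$midi_note)
  df$device_ms <- as.numeric(df$device_ms)
  df$slot <- as.integer(df$slot)
  df$x_norm <- suppressWarnings(as.numeric(df$x_norm))
  validate_touches(df, file = path)
  df
}

#' @rdname read_touches
#' @param df touch data.frame.
#' @param file label used in error messages.
#' @export
validate_touches <- function(df, file = "touches") {
  bad <- function(rows, why) {
    rows[is.na(rows)] <- FALSE
    if (any(rows)) {
      kf_validation_error("%s: %s (rows %s)", file, why,
                          paste(utils::head(which(rows), 10), collapse = ", "))
    }
  }
  bad(is.na(df$midi_note) | df$midi_note < 21L | df$midi_note > 108L,
      "midi_note must be 21-108")
  bad(is.na(df$slot) | df$slot < 0L | df$slot > 2L, "slot must be 0-2")
  bad(df$y_norm < 0 | df$y_norm > 1 | is.na(df$y_norm), "y_norm must be in [0,1]")
  bad(!is.na(df$x_norm) & (df$x_norm < 0 | df$x_norm > 1), "x_norm must be in [0,1]")
  bad(is.na(df$area) | df$area < 0, "area must be >= 0")
  nslot <- table(paste(df$midi_note, df$device_ms))
  kf_assert(all(nslot <= 3L), "%s: more than 3 touches in one frame", file)
  invisible(df)
}

#' Read MIDI events from a 4-column CSV
#'
#' Columns: `kind, id, host_s, velocity` with kind in
#' `note_on`/`note_off`/`pedal_on`/`pedal_off`; `id` is the MIDI note
#' number for notes and the controller number for pedals.
#'
#' @param path CSV file.
#' @return data.frame with columns kind, midi_note, pedal_id, host_s,
#'   velocity.
#' @export
read_midi_csv <- function(path) {
  kf_assert(file.exists(path), "MIDI file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "id", "host_s", "velocity")
  kf_assert(all(need %in% names(df)), "%s: missing columns: %s", path,
            paste(setdiff(need, names(df)), collapse = ", "))
  is_note <- df$kind %in% c("note_on", "note_off")
  out <- data.frame(kind = df$kind,
                    midi_note = ifelse(is_note, as.integer(df$id), NA_integer_),
                    pedal_id = ifelse(is_note, NA_integer_, as.integer(df$id)),
                    host_s = as.numeric(df$host_s),
                    velocity = as.integer(df$velocity),
                    stringsAsFactors = FALSE)
  validate_midi(out, file = path)
  out
}

#' @rdname read_midi_csv
#' @param df MIDI event data.frame.
#' @param file label used in error messages.
#' @export
validate_midi <- function(df, file = "midi") {
  kf_assert(all(df$kind %in% KF_MIDI_KINDS), "%s: unknown event kind", file)
  notes <- df[df$kind %in% c("note_on", "note_off"), ]
  if (nrow(notes)) {
    kf_assert(all(notes$midi_note >= 0L & notes$midi_note <= 127L),
              "%s: note number out of range", file)
    for (nt in unique(notes$midi_note)) {
      kinds <- notes$kind[notes$midi_note == nt]
      expect <- rep(c("note_on", "note_off"), length.out = length(kinds))
      kf_assert(all(kinds == expect),
                "%s: note %d on/off events do not alternate", file, nt)
    }
  }
  invisible(df)
}

#' Read anchor pairs for camera/MIDI alignment
#'
#' Columns: `camera_onset_s, midi_onset_s` -- one row per visually
#' identified note onset (normally the first three notes).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_anchors <- function(path) {
  kf_assert(file.exists(path), "anchors file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("camera_onset_s", "midi_onset_s")
  kf_assert(all(need %in% names(df)), "%s: missing columns: %s", path,
            paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Read a full recording bundle
#'
#' Loads and validates the four input files; unified timestamps are left
#' unset (alignment is a separate step). A recording with no MIDI note
#' events loads with zero notes and a warning.
#'
#' @param marker_path,touch_path,midi_path,polygon_path input files; MIDI
#'   may be a 4-column CSV or a Standard MIDI File (detected by the `MThd`
#'   magic).
#' @param anchors_path optional anchors CSV.
#' @return a `recording_bundle`.
#' @export
read_recording <- function(marker_path, touch_path, midi_path, polygon_path,
                           anchors_path = NULL) {
  midi <- if (is_smf(midi_path)) read_midi_smf(midi_path) else read_midi_csv(midi_path)
  if (!any(midi$kind == "note_on")) {
    warning(sprintf("%s: no MIDI note events; recording loads with zero notes",
                    midi_path), call. = FALSE)
  }
  bundle <- structure(list(
    markers = read_markers(marker_path),
    touches = read_touches(touch_path),
    midi = midi,
    polygons = read_polygon_map(polygon_path),
    anchors = if (!is.null(anchors_path)) read_anchors(anchors_path) else NULL,
    alignment = NULL, notes = NULL, blocks = NULL
  ), class = "recording_bundle")
  bundle
}

#' Read a bundle directory written by the simulator or pipeline
#'
#' Expects `markers.csv`, `touch.csv`, `midi.csv` (or `midi.mid`),
#' `polygons.json` and optionally `anchors.csv`.
#'
#' @param dir bundle directory.
#' @param prefer_smf read `midi.mid` instead of `midi.csv` when both exist.
#' @return a `recording_bundle`.
#' @export
read_bundle_dir <- function(dir, prefer_smf = FALSE) {
  p <- function(f) file.path(dir, f)
  midi_path <- if (prefer_smf && file.exists(p("midi.mid"))) p("midi.mid") else p("midi.csv")
  anchors <- if (file.exists(p("anchors.csv"))) p("anchors.csv") else NULL
  read_recording(p("markers.csv"), p("touch.csv"), midi_path, p("polygons.json"),
                 anchors_path = anchors)
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat("<recording_bundle>\n")
  cat(sprintf("  markers: %d rows, %d frames\n", nrow(x$markers),
              length(unique(x$markers$frame_index))))
  cat(sprintf("  touches: %d rows on %d keys\n", nrow(x$touches),
              length(unique(x$touches$midi_note))))
  cat(sprintf("  midi:    %d events\n", nrow(x$midi)))
  cat(sprintf("  keys:    %d polygons\n", length(x$polygons)))
  cat(sprintf("  aligned: %s; fingered: %s\n",
              !is.null(x$alignment), !is.null(x$notes) && !is.null(x$notes$finger)))
  invisible(x)
}

is_aligned <- function(bundle) !is.null(bundle$alignment)
is_fingered <- function(bundle) !is.null(bundle$notes) && "finger" %in% names(bundle$notes)

#' Write the annotated bundle tables
#'
#' Emits `notes.csv` (onset, release, note, finger and contact timing),
#' `touch_annotated.csv` (touch rows with unified time, block id and
#' finger) and `transitions.csv`. Reading the files back reproduces the
#' in-memory values bit-for-bit for integers and to better than 1e-9 s for
#' times.
#'
#' @param bundle an aligned, fingered `recording_bundle`.
#' @param out_dir output directory (created if needed).
#' @param transitions optional transitions table from [build_transitions()].
#' @return invisibly, the paths written.
#' @export
write_annotated <- function(bundle, out_dir, transitions = NULL) {
  if (!is_aligned(bundle)) kf_stop("bundle must be aligned before writing")
  if (!is_fingered(bundle)) kf_stop("bundle must be fingered before writing")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    path
  }
  paths <- c(paths, wr(bundle$notes, "notes.csv"))
  paths <- c(paths, wr(bundle$touches, "touch_annotated.csv"))
  if (!is.null(transitions)) paths <- c(paths, wr(transitions, "transitions.csv"))
  if (!is.null(bundle$alignment)) {
    al <- bundle$alignment
    path <- file.path(out_dir, "alignment.json")
    jsonlite::write_json(list(
      camera_fps = al$camera_fps, touch_rate_factor = al$touch_rate_factor,
      touch_epoch = al$touch_epoch, midi_offset = al$midi_offset,
      per_frame_latency = al$per_frame_latency
    ), path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}
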