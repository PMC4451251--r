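## Standard MIDI File (SMF) support and note segmentation.
##
## A deliberately small SMF 1.0 codec: type 0/1, tempo map honoured on
## read, note on/off and the sustain (CC 64) / soft (CC 67) pedals mapped
## to the event table; everything else skipped. Times in an SMF are
## relative to the first event; the alignment offset later absorbs the
## missing absolute epoch.

#' Does a file look like a Standard MIDI File?
#' @param path file path.
#' @return logical.
#' @export
is_smf <- function(path) {
  if (!file.exists(path)) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  identical(rawToChar(magic), "MThd")
}

read_varlen <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- as.integer(bytes[pos]); pos <- pos + 1L
    val <- val * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

encode_varlen <- function(val) {
  out <- as.raw(val %% 128L)
  val <- val %/% 128L
  while (val > 0) {
    out <- c(as.raw(128L + val %% 128L), out)
    val <- val %/% 128L
  }
  out
}

be_int <- function(bytes) Reduce(function(a, b) a * 256 + as.integer(b), bytes, 0)

#' Read MIDI events from a Standard MIDI File
#'
#' Parses a type 0 or type 1 SMF, converts delta ticks to seconds through
#' the file's tempo map, and returns note and pedal events in the same
#' table layout as [read_midi_csv()]. `host_s` is relative to the start of
#' the file.
#'
#' @param path SMF path.
#' @return data.frame with columns kind, midi_note, pedal_id, host_s,
#'   velocity.
#' @export
read_midi_smf <- function(path) {
  kf_assert(file.exists(path), "MIDI file not found: %s", path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  kf_assert(identical(rawToChar(bytes[1:4]), "MThd"), "%s: not an SMF", path)
  division <- be_int(bytes[13:14])
  kf_assert(division < 32768L, "%s: SMPTE time division unsupported", path)
  ntrks <- be_int(bytes[11:12])
  pos <- 15L
  ev <- list()
  for (trk in seq_len(ntrks)) {
    kf_assert(identical(rawToChar(bytes[pos:(pos + 3L)]), "MTrk"),
              "%s: malformed track header", path)
    tlen <- be_int(bytes[(pos + 4L):(pos + 7L)])
    pos <- pos + 8L
    end <- pos + tlen
    tick <- 0
    status <- 0L
    while (pos < end) {
      d <- read_varlen(bytes, pos); pos <- d$pos
      tick <- tick + d$value
      b <- as.integer(bytes[pos])
      if (b >= 128L) { status <- b; pos <- pos + 1L } # else running status
      hi <- status %/% 16L
      if (status == 255L) {                     # meta
        type <- as.integer(bytes[pos]); pos <- pos + 1L
        l <- read_varlen(bytes, pos); pos <- l$pos
        if (type == 81L) {                      # tempo, microseconds per quarter
          ev[[length(ev) + 1L]] <- list(tick = tick, kind = "tempo",
                                        value = be_int(bytes[pos:(pos + 2L)]))
        }
        pos <- pos + l$value
      } else if (hi == 9L || hi == 8L) {        # note on/off
        note <- as.integer(bytes[pos]); vel <- as.integer(bytes[pos + 1L])
        pos <- pos + 2L
        kind <- if (hi == 9L && vel > 0L) "note_on" else "note_off"
        ev[[length(ev) + 1L]] <- list(tick = tick, kind = kind, note = note,
                                      velocity = vel)
      } else if (hi == 11L) {                   # control change
        cc <- as.integer(bytes[pos]); val <- as.integer(bytes[pos + 1L])
        pos <- pos + 2L
        if (cc %in% c(64L, 67L)) {
          ev[[length(ev) + 1L]] <- list(tick = tick,
                                        kind = if (val >= 64L) "pedal_on" else "pedal_off",
                                        pedal = cc, velocity = val)
        }
      } else if (hi %in% c(12L, 13L)) {         # program change / channel pressure
        pos <- pos + 1L
      } else if (status == 240L || status == 247L) {  # sysex
        l <- read_varlen(bytes, pos); pos <- l$pos + l$value
      } else {                                  # other 2-byte channel messages
        pos <- pos + 2L
      }
    }
    pos <- end
  }
  if (!length(ev)) {
    return(data.frame(kind = character(0), midi_note = integer(0),
                      pedal_id = integer(0), host_s = numeric(0),
                      velocity = integer(0), stringsAsFactors = FALSE))
  }
  ticks <- vapply(ev, `[[`, numeric(1), "tick")
  ord <- order(ticks)
  ev <- ev[ord]; ticks <- ticks[ord]
  # tempo map: piecewise-constant microseconds per quarter note
  tempo_ticks <- c(0, ticks[vapply(ev, function(e) e$kind == "tempo", logical(1))])
  tempo_vals <- c(500000, vapply(ev[vapply(ev, function(e) e$kind == "tempo", logical(1))],
                                 `[[`, numeric(1), "value"))
  tick_to_s <- function(t) {
    s <- 0
    for (i in seq_along(tempo_ticks)) {
      t0 <- tempo_ticks[i]
      t1 <- if (i < length(tempo_ticks)) min(tempo_ticks[i + 1], t) else t
      if (t1 > t0) s <- s + (t1 - t0) * tempo_vals[i] / 1e6 / division
      if (t1 >= t) break
    }
    s
  }
  keep <- vapply(ev, function(e) e$kind != "tempo", logical(1))
  ev <- ev[keep]; ticks <- ticks[keep]
  out <- data.frame(
    kind = vapply(ev, `[[`, character(1), "kind"),
    midi_note = vapply(ev, function(e) if (!is.null(e$note)) e$note else NA_integer_,
                       integer(1)),
    pedal_id = vapply(ev, function(e) if (!is.null(e$pedal)) e$pedal else NA_integer_,
                      integer(1)),
    host_s = vapply(ticks, tick_to_s, numeric(1)),
    velocity = vapply(ev, function(e) if (!is.null(e$velocity)) e$velocity else NA_integer_,
                      integer(1)),
    stringsAsFactors = FALSE)
  validate_midi(out, file = path)
  out
}

#' Write MIDI events to a type-0 Standard MIDI File
#'
#' Events are written on channel 0 at a fixed tempo of 500000 microseconds
#' per quarter note with 480 ticks per quarter (960 ticks per second);
#' times are taken relative to the earliest event.
#'
#' @param events event data.frame as returned by [read_midi_csv()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_midi_smf <- function(events, path) {
  division <- 480L; tempo <- 500000L
  t0 <- if (nrow(events)) min(events$host_s) else 0
  ticks <- round((events$host_s - t0) * 1e6 / tempo * division)
  ord <- order(ticks)
  body <- c(encode_varlen(0), as.raw(c(0xFF, 0x51, 0x03)),
            as.raw(c(tempo %/% 65536L, (tempo %/% 256L) %% 256L, tempo %% 256L)))
  last <- 0
  for (i in ord) {
    delta <- ticks[i] - last; last <- ticks[i]
    kind <- events$kind[i]
    msg <- switch(kind,
      note_on = as.raw(c(0x90, events$midi_note[i],
                         max(1L, min(127L, events$velocity[i], na.rm = TRUE)))),
      note_off = as.raw(c(0x80, events$midi_note[i], 0x40)),
      pedal_on = as.raw(c(0xB0, events$pedal_id[i], 0x7F)),
      pedal_off = as.raw(c(0xB0, events$pedal_id[i], 0x00)))
    body <- c(body, encode_varlen(delta), msg)
  }
  body <- c(body, encode_varlen(0), as.raw(c(0xFF, 0x2F, 0x00)))  # end of track
  u32 <- function(x) as.raw(c(x %/% 16777216L, (x %/% 65536L) %% 256L,
                              (x %/% 256L) %% 256L, x %% 256L))
  u16 <- function(x) as.raw(c(x %/% 256L, x %% 256L))
  out <- c(charToRaw("MThd"), u32(6L), u16(0L), u16(1L), u16(division),
           charToRaw("MTrk"), u32(length(body)), body)
  writeBin(out, path)
  invisible(path)
}

#' Segment MIDI note events into notes
#'
#' Pairs alternating note_on/note_off events per note number into notes
#' with onset and release times.
#'
#' @param midi event data.frame.
#' @param time_col which time column to use (`"unified_s"` once aligned,
#'   else `"host_s"`).
#' @return data.frame: note_id, midi_note, onset, release.
#' @export
segment_notes <- function(midi, time_col = c("unified_s", "host_s")) {
  time_col <- time_col[time_col %in% names(midi)][1]
  kf_assert(!is.na(time_col), "no usable time column in MIDI table")
  notes <- midi[midi$kind %in% c("note_on", "note_off"), , drop = FALSE]
  out <- list()
  for (nt in sort(unique(notes$midi_note))) {
    sub <- notes[notes$midi_note == nt, , drop = FALSE]
    sub <- sub[order(sub[[time_col]]), , drop = FALSE]
    ons <- sub[[time_col]][sub$kind == "note_on"]
    offs <- sub[[time_col]][sub$kind == "note_off"]
    n <- min(length(ons), length(offs))
    if (n > 0) {
      out[[length(out) + 1L]] <- data.frame(midi_note = nt, onset = ons[seq_len(n)],
                                            release = offs[seq_len(n)])
    }
  }
  if (!length(out)) {
    return(data.frame(note_id = integer(0), midi_note = integer(0),
                      onset = numeric(0), release = numeric(0)))
  }
  res <- do.call(rbind, out)
  kf_assert(all(res$onset < res$release), "note with onset >= release")
  res <- res[order(res$onset, res$midi_note), , drop = FALSE]
  res <- data.frame(note_id = seq_len(nrow(res)), res, row.names = NULL)
  res
}
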