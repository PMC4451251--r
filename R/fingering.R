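## Touch segmentation, spurious-touch filtering, and the two-pass
## automatic fingering assignment.
##
## Pass one: each touch frame is assigned the finger whose distal marker
## (the DIP joint; the thumb's IP) is nearest in X in the temporally
## closest camera frame, and each MIDI note takes the plurality finger of
## the touches made while it is active. Pass two: touches inside a note
## inherit that note's finger; touches outside a note inherit the finger
## of the MIDI note their contiguous touch block connects to, taking the
## temporally closer event when a block bridges two notes.

#' Segment touch frames into contiguous blocks
#'
#' Maximal runs of touch frames per key whose consecutive gaps do not
#' exceed `gap_max_s`. The default of 12.5 ms is 2.5 sample periods at
#' the sensors' 200 Hz rate, so a single dropped frame never splits a
#' block.
#'
#' @param touches touch data.frame with `unified_s`.
#' @param gap_max_s maximum within-block gap in seconds.
#' @return list(touches = rows with a `block_id` column, blocks =
#'   data.frame block_id, midi_note, start, end, n_frames).
#' @export
segment_touch_blocks <- function(touches, gap_max_s = 0.0125) {
  kf_assert("unified_s" %in% names(touches), "touches must be aligned first")
  touches$block_id <- rep(NA_integer_, nrow(touches))
  blocks <- list()
  next_id <- 1L
  for (nt in sort(unique(touches$midi_note))) {
    rows <- which(touches$midi_note == nt)
    rows <- rows[order(touches$unified_s[rows])]
    t <- touches$unified_s[rows]
    ft <- sort(unique(t))                       # frame times (slots collapse)
    brk <- c(0L, which(diff(ft) > gap_max_s), length(ft))
    for (b in seq_len(length(brk) - 1L)) {
      span <- ft[(brk[b] + 1L):brk[b + 1L]]
      in_block <- rows[t >= span[1] & t <= span[length(span)]]
      touches$block_id[in_block] <- next_id
      blocks[[next_id]] <- data.frame(block_id = next_id, midi_note = nt,
                                      start = span[1], end = span[length(span)],
                                      n_frames = length(span))
      next_id <- next_id + 1L
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = integer(0), midi_note = integer(0),
               start = numeric(0), end = numeric(0), n_frames = integer(0))
  list(touches = touches, blocks = blocks)
}

#' Remove spurious (moisture) touches
#'
#' Touch rows whose contact area falls below `area_fraction` of the
#' maximum area observed for that MIDI note are discarded regardless of
#' their location. With `marker_check = TRUE`, a small-area row is instead
#' kept when it lies within `dist_max_px` of some visible distal marker in
#' the temporally closest camera frame (camera confirmation of a genuine
#' touch). The filter is idempotent and never removes the maximum-area
#' frame of any note's block.
#'
#' @param touches touch data.frame (pixel-mapped when `marker_check`).
#' @param area_fraction fraction of the per-note maximum area (default
#'   0.2).
#' @param marker_check confirm small-area touches against marker
#'   positions instead of dropping them outright.
#' @param markers aligned marker data.frame (required for
#'   `marker_check`).
#' @param dist_max_px marker-distance bound; defaults to one white-key
#'   width when a map is supplied.
#' @param map polygon map (to default `dist_max_px`).
#' @return the filtered touch data.frame.
#' @export
filter_spurious <- function(touches, area_fraction = 0.2, marker_check = FALSE,
                            markers = NULL, dist_max_px = NULL, map = NULL) {
  kf_assert(area_fraction >= 0 && area_fraction <= 1,
            "area_fraction must be in [0, 1]")
  if (!nrow(touches)) return(touches)
  max_area <- tapply(touches$area, touches$midi_note, max)
  thr <- area_fraction * as.numeric(max_area[as.character(touches$midi_note)])
  small <- touches$area < thr
  if (marker_check && any(small)) {
    kf_assert(!is.null(markers), "marker_check requires marker data")
    if (is.null(dist_max_px)) {
      kf_assert(!is.null(map), "dist_max_px or map required for marker_check")
      whites <- Filter(function(k) k$color == "white", map)
      dist_max_px <- median(vapply(whites, function(k) {
        v <- k$vertices; diff(range(v[abs(v[, 2] - min(v[, 2])) < 1e-9, 1]))
      }, numeric(1)))
    }
    kf_assert(all(c("x_px", "y_px") %in% names(touches)),
              "marker_check requires pixel-mapped touches")
    near <- nearest_distal_distance(touches[small, , drop = FALSE], markers)
    small[small] <- !(near <= dist_max_px)      # confirmed touches survive
  }
  touches[!small, , drop = FALSE]
}

# distal marker subset (DIP joints; the thumb's IP)
distal_markers <- function(markers) {
  markers[markers$visible &
          (markers$landmark == "DIP" | (markers$landmark == "IP" & markers$finger == 1L)), ,
          drop = FALSE]
}

# for each touch row: distance to the nearest visible distal marker in
# the temporally closest camera frame
nearest_distal_distance <- function(touches, markers) {
  dm <- distal_markers(markers)
  if (!nrow(dm)) return(rep(Inf, nrow(touches)))
  ft <- sort(unique(dm$time_s))
  out <- rep(Inf, nrow(touches))
  ni <- nearest_index(touches$unified_s, ft)
  for (f in unique(ni)) {
    sub <- dm[dm$time_s == ft[f], , drop = FALSE]
    rows <- which(ni == f)
    for (r in rows) {
      out[r] <- sqrt(min((sub$x_px - touches$x_px[r])^2 +
                         (sub$y_px - touches$y_px[r])^2))
    }
  }
  out
}

# index of the element of sorted vector `grid` nearest to each x
nearest_index <- function(x, grid) {
  i <- findInterval(x, grid, all.inside = TRUE)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(grid))
  ifelse(abs(x - grid[lo]) <= abs(grid[hi] - x), lo, hi)
}

#' First-pass per-touch finger assignment
#'
#' For every touch row, finds the temporally closest camera frame and
#' assigns the (hand, finger) of the visible distal marker with the
#' smallest X distance from the pixel-mapped touch. Exact ties go to the
#' lower finger number (left hand before right). Rows with no visible
#' distal marker in the nearest frame stay unassigned.
#'
#' @param touches pixel-mapped, aligned touch data.frame.
#' @param markers aligned marker data.frame (with `time_s`).
#' @return touches with `tf_hand` and `tf_finger` columns.
#' @export
assign_touch_finger <- function(touches, markers, map = NULL) {
  kf_assert(all(c("x_px", "unified_s") %in% names(touches)),
            "touches must be aligned and pixel-mapped")
  kf_assert("time_s" %in% names(markers), "markers must carry time_s")
  dm <- distal_markers(markers)
  touches$tf_hand <- NA_character_
  touches$tf_finger <- NA_integer_
  if (!nrow(dm) || !nrow(touches)) return(touches)
  ft <- sort(unique(dm$time_s))
  ni <- nearest_index(touches$unified_s, ft)
  # deterministic tie-break order: left hand, then finger number
  for (f in unique(ni)) {
    sub <- dm[dm$time_s == ft[f], , drop = FALSE]
    ord <- order(match(sub$hand, c("left", "right")), sub$finger)
    sub <- sub[ord, , drop = FALSE]
    rows <- which(ni == f)
    dx <- abs(outer(touches$x_px[rows], sub$x_px, "-"))
    best <- apply(dx, 1L, which.min)             # first minimum = tie-break
    touches$tf_hand[rows] <- sub$hand[best]
    touches$tf_finger[rows] <- sub$finger[best]
  }
  touches
}

#' Note fingering by plurality vote
#'
#' While a MIDI note is active, the fingers assigned to each touch row on
#' that key are counted (multi-touch rows count once per slot); at
#' release, the plurality finger becomes the note's finger. Ties go to
#' the finger of the temporally later touches (the one whose last touch
#' is closest to the release). Notes with zero touches stay unfingered
#' with a warning.
#'
#' @param notes note table from [segment_notes()].
#' @param touches touch rows with `tf_hand`/`tf_finger`.
#' @return notes with `hand`, `finger` and `n_touch` columns.
#' @export
assign_note_fingering <- function(notes, touches) {
  notes$hand <- NA_character_
  notes$finger <- NA_integer_
  notes$n_touch <- 0L
  for (i in seq_len(nrow(notes))) {
    sel <- touches$midi_note == notes$midi_note[i] &
      touches$unified_s >= notes$onset[i] & touches$unified_s <= notes$release[i] &
      !is.na(touches$tf_finger)
    if (!any(sel)) next
    sub <- touches[sel, , drop = FALSE]
    keyv <- paste(sub$tf_hand, sub$tf_finger)
    cnt <- table(keyv)
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) > 1L) {
      last_t <- vapply(top, function(k) max(sub$unified_s[keyv == k]), numeric(1))
      top <- top[order(-last_t, top)][1]
    }
    hf <- strsplit(top, " ")[[1]]
    notes$hand[i] <- hf[1]
    notes$finger[i] <- as.integer(hf[2])
    notes$n_touch[i] <- sum(sel)
  }
  if (any(notes$n_touch == 0L)) {
    warning(sprintf("%d note(s) had no touches and remain unfingered",
                    sum(notes$n_touch == 0L)), call. = FALSE)
  }
  notes
}

#' Associate each note with its touch block
#'
#' Picks, per note, the touch block on the same key with the largest
#' overlap with the note interval (anticipatory and lingering contact
#' make the block extend beyond the note on both sides).
#'
#' @param notes note table.
#' @param blocks block table from [segment_touch_blocks()].
#' @return notes with `block_id`, `block_start`, `block_end`.
#' @export
associate_note_blocks <- function(notes, blocks) {
  notes$block_id <- NA_integer_
  notes$block_start <- NA_real_
  notes$block_end <- NA_real_
  for (i in seq_len(nrow(notes))) {
    cand <- blocks[blocks$midi_note == notes$midi_note[i], , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, notes$release[i]) - pmax(cand$start, notes$onset[i])
    j <- which.max(ov)
    if (ov[j] >= 0) {
      notes$block_id[i] <- cand$block_id[j]
      notes$block_start[i] <- cand$start[j]
      notes$block_end[i] <- cand$end[j]
    }
  }
  notes
}

#' Second-pass touch fingering correction
#'
#' Touches during a held note take that note's finger. Touches outside
#' any note take the finger of the MIDI note their contiguous block
#' connects to; when a block bridges the release of one note and the
#' onset of the next, each frame takes the temporally closer event.
#' Blocks connecting to no note keep their first-pass fingers.
#'
#' @param touches touch rows with `block_id` and first-pass fingers.
#' @param notes fingered note table.
#' @return touches with final `hand` and `finger` columns.
#' @export
second_pass_correct <- function(touches, notes) {
  touches$hand <- touches$tf_hand
  touches$finger <- touches$tf_finger
  fingered <- notes[!is.na(notes$finger), , drop = FALSE]
  if (!nrow(fingered)) return(touches)
  for (b in unique(touches$block_id[!is.na(touches$block_id)])) {
    rows <- which(touches$block_id == b)
    nt <- touches$midi_note[rows[1]]
    b_start <- min(touches$unified_s[rows]); b_end <- max(touches$unified_s[rows])
    conn <- fingered[fingered$midi_note == nt &
                     fingered$onset <= b_end & fingered$release >= b_start, ,
                     drop = FALSE]
    if (!nrow(conn)) next
    t <- touches$unified_s[rows]
    for (k in seq_along(rows)) {
      inside <- which(conn$onset <= t[k] & conn$release >= t[k])
      if (length(inside)) {
        j <- inside[1]
      } else {
        prev <- which(conn$release < t[k])
        nxt <- which(conn$onset > t[k])
        if (length(prev) && length(nxt)) {
          p <- prev[which.max(conn$release[prev])]
          q <- nxt[which.min(conn$onset[nxt])]
          j <- if ((t[k] - conn$release[p]) <= (conn$onset[q] - t[k])) p else q
        } else if (length(prev)) {
          j <- prev[which.max(conn$release[prev])]
        } else {
          j <- nxt[which.min(conn$onset[nxt])]
        }
      }
      touches$hand[rows[k]] <- conn$hand[j]
      touches$finger[rows[k]] <- conn$finger[j]
    }
  }
  touches
}

#' Run the full fingering stage on an aligned bundle
#'
#' Pixel-maps the touches, removes spurious touches, segments blocks,
#' assigns per-touch fingers from the camera, votes note fingerings, and
#' applies the second-pass correction.
#'
#' @param bundle an aligned `recording_bundle`.
#' @param gap_max_s block segmentation gap (s).
#' @param area_fraction spurious-touch area threshold.
#' @param marker_check confirm small-area touches against markers.
#' @return the bundle with fingered `notes`, `blocks`, and annotated
#'   `touches`.
#' @export
finger_bundle <- function(bundle, gap_max_s = 0.0125, area_fraction = 0.2,
                          marker_check = FALSE) {
  if (!is_aligned(bundle)) kf_stop("bundle must be aligned before fingering")
  touches <- touch_to_pixels(bundle$touches, bundle$polygons)
  touches <- filter_spurious(touches, area_fraction = area_fraction,
                             marker_check = marker_check,
                             markers = bundle$markers, map = bundle$polygons)
  seg <- segment_touch_blocks(touches, gap_max_s = gap_max_s)
  touches <- assign_touch_finger(seg$touches, bundle$markers)
  notes <- assign_note_fingering(bundle$notes, touches)
  notes <- associate_note_blocks(notes, seg$blocks)
  touches <- second_pass_correct(touches, notes)
  bundle$touches <- touches
  bundle$blocks <- seg$blocks
  bundle$notes <- notes
  bundle
}
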