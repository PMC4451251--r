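## Spatial registration between marker pixels, key polygons and the
## normalised key-surface coordinates reported by the touch sensors.

#' Assign points to keys through the polygon map
#'
#' Each point is assigned the key whose polygon contains it. A point on a
#' shared edge belongs to the lower-numbered key (deterministic
#' tie-break). Points in front of the keyboard (Y below the white-key
#' front boundary) are assigned the white key whose front centreline is
#' nearest in X, provided they lie within the keyboard's X extent; points
#' beyond the keyboard ends or above the fallboard edge get no key.
#'
#' @param xs,ys point coordinates in keyboard-frame pixels.
#' @param map a `key_polygon_map`.
#' @return data.frame with `midi_note` (NA when unassigned) and `rule`
#'   (`inside_polygon`, `front_by_x` or `none`).
#' @export
assign_points_to_keys <- function(xs, ys, map) {
  n <- length(xs)
  note <- rep(NA_integer_, n)
  rule <- rep("none", n)
  notes <- as.integer(names(map))
  for (i in order(notes)) {           # ascending notes: first hit = lowest key
    v <- map[[i]]$vertices
    open <- is.na(note)
    if (!any(open)) break
    cand <- open &
      xs >= min(v[, 1]) & xs <= max(v[, 1]) &
      ys >= min(v[, 2]) & ys <= max(v[, 2])
    if (any(cand)) {
      hit <- point_in_polygon(xs[cand], ys[cand], v, boundary = TRUE)
      idx <- which(cand)[hit]
      note[idx] <- notes[i]
      rule[idx] <- "inside_polygon"
    }
  }
  y_front <- white_front_y(map)
  whites <- which(vapply(map, function(k) k$color == "white", logical(1)))
  wnotes <- notes[whites]
  cx <- vapply(map[whites], key_centerline_x, numeric(1))
  xmin <- min(vapply(map, function(k) min(k$vertices[, 1]), numeric(1)))
  xmax <- max(vapply(map, function(k) max(k$vertices[, 1]), numeric(1)))
  front <- is.na(note) & ys < y_front & xs >= xmin & xs <= xmax
  if (any(front)) {
    for (j in which(front)) {
      d <- abs(cx - xs[j])
      best <- which(d == min(d))          # ties -> lower-numbered key
      note[j] <- wnotes[min(best)]
      rule[j] <- "front_by_x"
    }
  }
  data.frame(midi_note = note, rule = rule, stringsAsFactors = FALSE)
}

#' @rdname assign_points_to_keys
#' @param point length-2 numeric (x, y).
#' @return `assign_point_to_key`: list(midi_note, rule) for one point.
#' @export
assign_point_to_key <- function(point, map) {
  res <- assign_points_to_keys(point[1], point[2], map)
  list(midi_note = res$midi_note[1], rule = res$rule[1])
}

# y at which a notched white key narrows; NA for plain rectangles
key_notch_y <- function(v) {
  ys <- sort(unique(round(v[, 2], 9)))
  if (length(ys) >= 3) ys[2] else NA_real_
}

# x-range of a key at height y (axis-aligned keys)
key_xrange_at <- function(key, y) {
  v <- key$vertices
  y_front <- min(v[, 2]); y_top <- max(v[, 2])
  yn <- key_notch_y(v)
  if (!is.na(yn) && y > yn + 1e-9) {
    range(v[abs(v[, 2] - y_top) < 1e-9, 1])
  } else {
    range(v[abs(v[, 2] - y_front) < 1e-9, 1])
  }
}

#' Map normalised touch coordinates to keyboard-frame pixels
#'
#' `y_norm` (0 at the key front edge, 1 at the fallboard end) maps
#' linearly along the key's Y extent. `x_norm` maps across the key's
#' X-range at that height -- for notched white keys this is a piecewise
#' bilinear map over the wide front and narrow rear sub-rectangles; for
#' 4-vertex black keys it is the plain bilinear map of the quadrilateral,
#' so the four corner coordinates (0,0), (1,0), (0,1), (1,1) land on the
#' four polygon vertices. A missing `x_norm` (rear of a white key, where
#' only Y is sensed) falls back to the key's centreline at that height.
#'
#' @param touches touch data.frame (needs midi_note, x_norm, y_norm).
#' @param map a `key_polygon_map`.
#' @return the data.frame with `x_px`, `y_px` columns.
#' @export
touch_to_pixels <- function(touches, map) {
  miss <- setdiff(unique(touches$midi_note), as.integer(names(map)))
  if (length(miss)) {
    kf_stop("touch notes missing from polygon map: %s",
            paste(miss, collapse = ", "))
  }
  x_px <- numeric(nrow(touches)); y_px <- numeric(nrow(touches))
  for (nt in unique(touches$midi_note)) {
    key <- map[[as.character(nt)]]
    v <- key$vertices
    rows <- which(touches$midi_note == nt)
    y_front <- min(v[, 2]); y_top <- max(v[, 2])
    yy <- y_front + touches$y_norm[rows] * (y_top - y_front)
    xx <- numeric(length(rows))
    for (k in seq_along(rows)) {
      xr <- key_xrange_at(key, yy[k])
      u <- touches$x_norm[rows[k]]
      if (is.na(u)) u <- 0.5                       # centreline fallback
      xx[k] <- xr[1] + u * (xr[2] - xr[1])
    }
    x_px[rows] <- xx; y_px[rows] <- yy
  }
  touches$x_px <- x_px; touches$y_px <- y_px
  touches
}

#' Invert the touch pixel mapping
#'
#' For a point inside (or on) a key's polygon, recover the normalised
#' coordinates that [touch_to_pixels()] would map back onto it.
#'
#' @param x_px,y_px pixel coordinates.
#' @param midi_note the key.
#' @param map a `key_polygon_map`.
#' @return data.frame with x_norm, y_norm.
#' @export
pixels_to_touch_norms <- function(x_px, y_px, midi_note, map) {
  key <- map[[as.character(midi_note)]]
  kf_assert(!is.null(key), "note %s missing from polygon map", midi_note)
  v <- key$vertices
  y_front <- min(v[, 2]); y_top <- max(v[, 2])
  y_norm <- (y_px - y_front) / (y_top - y_front)
  x_norm <- vapply(seq_along(x_px), function(i) {
    xr <- key_xrange_at(key, y_px[i])
    (x_px[i] - xr[1]) / (xr[2] - xr[1])
  }, numeric(1))
  data.frame(x_norm = x_norm, y_norm = y_norm)
}

#' Annotate every visible marker with the key beneath it
#'
#' Each visible marker in each frame is assigned independently through
#' [assign_points_to_keys()]; no hand-level consistency is imposed, so the
#' distal and proximal markers of an angled finger may legitimately map to
#' different keys.
#'
#' @param markers marker data.frame.
#' @param map a `key_polygon_map`.
#' @return the visible marker rows with `midi_note` and `rule` columns.
#' @export
marker_key_annotation <- function(markers, map) {
  vis <- markers[markers$visible, , drop = FALSE]
  ann <- assign_points_to_keys(vis$x_px, vis$y_px, map)
  vis$midi_note <- ann$midi_note
  vis$rule <- ann$rule
  vis
}
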