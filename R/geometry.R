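#' @section Keyboard frame:
#' All geometry lives in the keyboard frame: X in pixels growing bass to
#' treble, Y in pixels growing from the player toward the fallboard. Key
#' polygons are simple (non-self-intersecting) and mutually non-overlapping;
#' adjacent keys may share edges.
#' @name keyfusion-geometry
#' @keywords internal
NULL

KF_BLACK_PCS <- c(1L, 3L, 6L, 8L, 10L)

#' Is a MIDI note a black key?
#' @param note integer MIDI note number(s).
#' @return logical vector.
#' @export
is_black_key <- function(note) (as.integer(note) %% 12L) %in% KF_BLACK_PCS

#' Construct a key polygon map
#'
#' A key polygon map associates each MIDI note with a key outline in
#' keyboard-frame pixels plus its colour. Black keys have exactly 4
#' vertices; white keys have 4 to 8 (they are notched around neighbouring
#' black keys).
#'
#' @param keys named list (names = MIDI note numbers) of
#'   `list(color = "white"|"black", vertices = <n x 2 matrix>)`.
#' @param px_per_mm optional pixels-per-millimetre scale, retained so touch
#'   path lengths can be expressed in physical units.
#' @param white_length_mm optional white-key visible length in millimetres.
#' @param validate run invariant checks (default TRUE).
#' @return object of class `key_polygon_map`.
#' @export
key_polygon_map <- function(keys, px_per_mm = NA_real_,
                            white_length_mm = NA_real_, validate = TRUE) {
  kf_assert(is.list(keys) && length(keys) > 0L, "polygon map must be a non-empty list")
  nms <- names(keys)
  kf_assert(!is.null(nms) && !anyNA(suppressWarnings(as.integer(nms))),
            "polygon map names must be MIDI note numbers")
  keys <- keys[order(as.integer(nms))]
  for (nm in names(keys)) {
    k <- keys[[nm]]
    k$vertices <- as.matrix(k$vertices)
    storage.mode(k$vertices) <- "double"
    keys[[nm]] <- k
  }
  obj <- structure(keys, class = "key_polygon_map",
                   px_per_mm = px_per_mm, white_length_mm = white_length_mm)
  if (validate) validate_polygon_map(obj)
  obj
}

#' Validate a key polygon map
#'
#' Checks vertex counts (black = 4, white 4--8), polygon simplicity and
#' pairwise non-overlap (shared edges allowed).
#'
#' @param map a `key_polygon_map`.
#' @return the map, invisibly; signals a validation error otherwise.
#' @export
validate_polygon_map <- function(map) {
  notes <- as.integer(names(map))
  for (i in seq_along(map)) {
    k <- map[[i]]
    kf_assert(k$color %in% c("black", "white"),
              "key %d: color must be black or white", notes[i])
    nv <- nrow(k$vertices)
    if (k$color == "black") {
      kf_assert(nv == 4L, "black key %d must have 4 vertices, has %d", notes[i], nv)
    } else {
      kf_assert(nv >= 4L && nv <= 8L,
                "white key %d must have 4-8 vertices, has %d", notes[i], nv)
    }
    kf_assert(polygon_is_simple(k$vertices),
              "key %d: polygon self-intersects", notes[i])
  }
  bb <- t(vapply(map, function(k) c(range(k$vertices[, 1]), range(k$vertices[, 2])),
                 numeric(4)))
  for (i in seq_along(map)) {
    for (j in seq_len(i - 1L)) {
      if (bb[i, 1] >= bb[j, 2] || bb[j, 1] >= bb[i, 2] ||
          bb[i, 3] >= bb[j, 4] || bb[j, 3] >= bb[i, 4]) next
      kf_assert(!polygons_interiors_overlap(map[[i]]$vertices, map[[j]]$vertices),
                "keys %d and %d overlap", notes[i], notes[j])
    }
  }
  invisible(map)
}

## --- low-level polygon predicates -------------------------------------

cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)

on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-9) {
  abs(cross2(ax, ay, bx, by, px, py)) <= eps * (abs(bx - ax) + abs(by - ay) + 1) &
    px >= pmin(ax, bx) - eps & px <= pmax(ax, bx) + eps &
    py >= pmin(ay, by) - eps & py <= pmax(ay, by) + eps
}

segments_cross_properly <- function(a1, a2, b1, b2) {
  d1 <- cross2(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  d2 <- cross2(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  d3 <- cross2(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  d4 <- cross2(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  idx <- seq_len(n)
  nxt <- c(idx[-1], 1L)
  for (i in idx) {
    for (j in idx) {
      if (j <= i) next
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross_properly(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

polygons_interiors_overlap <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segments_cross_properly(a[i, ], a[if (i == na) 1L else i + 1L, ],
                                  b[j, ], b[if (j == nb) 1L else j + 1L, ])) {
        return(TRUE)
      }
    }
  }
  any(point_in_polygon(a[, 1], a[, 2], b, boundary = FALSE)) ||
    any(point_in_polygon(b[, 1], b[, 2], a, boundary = FALSE))
}

#' Even-odd point-in-polygon test
#'
#' Ray-crossing (even-odd) containment, vectorised over points. Points lying
#' on a polygon edge are counted inside when `boundary = TRUE`.
#'
#' @param px,py point coordinates (equal-length vectors).
#' @param verts n x 2 vertex matrix (closed implicitly).
#' @param boundary treat boundary points as inside.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, verts, boundary = TRUE) {
  n <- nrow(verts)
  xs <- verts[, 1]; ys <- verts[, 2]
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    onedge <- onedge | on_segment(px, py, xi, yi, xj, yj)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  if (boundary) inside | onedge else inside & !onedge
}

## --- standard keyboard construction -----------------------------------

#' Build an idealised keyboard polygon map
#'
#' Generates key polygons for a contiguous note range in keyboard-frame
#' pixels. White keys are uniform-width rectangles notched around the black
#' keys; each black key is a rectangle centred on the boundary between its
#' two neighbouring white keys, occupying the rear part of the keyboard.
#'
#' Default physical dimensions: white keys 23.5 mm wide and 150 mm long,
#' black keys 13.5 mm wide and 100 mm long, so the wide front part of a
#' white key is 50 mm deep.
#'
#' @param note_lo,note_hi inclusive MIDI note range (default full 88-key
#'   compass, 21--108); both ends must be white keys.
#' @param px_per_mm image scale.
#' @param white_width_mm,white_length_mm,black_width_mm,black_length_mm key
#'   dimensions in millimetres.
#' @param origin_px (x, y) pixel offset of the front bass corner.
#' @return a `key_polygon_map`.
#' @export
standard_keyboard_polygons <- function(note_lo = 21L, note_hi = 108L,
                                       px_per_mm = 2,
                                       white_width_mm = 23.5,
                                       white_length_mm = 150,
                                       black_width_mm = 13.5,
                                       black_length_mm = 100,
                                       origin_px = c(0, 0)) {
  note_lo <- as.integer(note_lo); note_hi <- as.integer(note_hi)
  kf_assert(note_lo < note_hi, "note range empty")
  kf_assert(!is_black_key(note_lo) && !is_black_key(note_hi),
            "keyboard must start and end on white keys")
  notes <- note_lo:note_hi
  whites <- notes[!is_black_key(notes)]
  ww <- white_width_mm * px_per_mm
  wl <- white_length_mm * px_per_mm
  bw <- black_width_mm * px_per_mm
  bl <- black_length_mm * px_per_mm
  y0 <- origin_px[2]
  y_notch <- y0 + (wl - bl)   # bottom of the black keys
  y_top <- y0 + wl
  # white key index -> left edge
  wx <- function(i) origin_px[1] + (i - 1) * ww
  white_index <- setNames(seq_along(whites), whites)

  keys <- list()
  for (nt in notes) {
    if (is_black_key(nt)) {
      # centred on the boundary between the white neighbours nt-1, nt+1
      i <- white_index[[as.character(nt - 1L)]]
      cx <- wx(i + 1L)
      keys[[as.character(nt)]] <- list(
        color = "black",
        vertices = rbind(c(cx - bw / 2, y_notch), c(cx + bw / 2, y_notch),
                         c(cx + bw / 2, y_top), c(cx - bw / 2, y_top)))
    } else {
      i <- white_index[[as.character(nt)]]
      xl <- wx(i); xr <- wx(i + 1L)
      has_l <- (nt - 1L) >= note_lo && is_black_key(nt - 1L)
      has_r <- (nt + 1L) <= note_hi && is_black_key(nt + 1L)
      rl <- if (has_l) xl + bw / 2 else xl   # rear-left edge
      rr <- if (has_r) xr - bw / 2 else xr   # rear-right edge
      v <- rbind(c(xl, y0), c(xr, y0), c(xr, y_notch), c(rr, y_notch),
                 c(rr, y_top), c(rl, y_top), c(rl, y_notch), c(xl, y_notch))
      v <- v[!duplicated(round(v, 9)), , drop = FALSE]
      keys[[as.character(nt)]] <- list(color = "white", vertices = v)
    }
  }
  key_polygon_map(keys, px_per_mm = px_per_mm,
                  white_length_mm = white_length_mm)
}

## --- polygon map I/O ---------------------------------------------------

#' Read / write a key polygon map as JSON
#'
#' Schema: `{"<note>": {"color": "white", "vertices": [[x, y], ...]}, ...}`
#' with an optional `"meta"` entry carrying `px_per_mm` and
#' `white_length_mm`.
#'
#' @param path JSON file path.
#' @return `read_polygon_map`: a `key_polygon_map`.
#' @export
read_polygon_map <- function(path) {
  kf_assert(file.exists(path), "polygon file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  meta <- raw[["meta"]]
  raw[["meta"]] <- NULL
  keys <- lapply(raw, function(k) {
    list(color = k$color,
         vertices = do.call(rbind, lapply(k$vertices, function(v) as.numeric(v))))
  })
  key_polygon_map(keys,
                  px_per_mm = if (!is.null(meta$px_per_mm)) meta$px_per_mm else NA_real_,
                  white_length_mm = if (!is.null(meta$white_length_mm)) meta$white_length_mm else NA_real_)
}

#' @rdname read_polygon_map
#' @param map a `key_polygon_map`.
#' @export
write_polygon_map <- function(map, path) {
  out <- lapply(map, function(k) {
    list(color = k$color,
         vertices = lapply(seq_len(nrow(k$vertices)),
                           function(i) as.numeric(k$vertices[i, ])))
  })
  if (!is.na(attr(map, "px_per_mm"))) {
    out$meta <- list(px_per_mm = attr(map, "px_per_mm"),
                     white_length_mm = attr(map, "white_length_mm"))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## --- derived geometry helpers -----------------------------------------

# y of the white-key front boundary (lowest y over white keys)
white_front_y <- function(map) {
  ys <- vapply(map, function(k) if (k$color == "white") min(k$vertices[, 2]) else Inf,
               numeric(1))
  min(ys)
}

# x centre of a white key's wide front part (or black key centre)
key_centerline_x <- function(key) {
  v <- key$vertices
  yb <- min(v[, 2])
  front <- v[abs(v[, 2] - yb) < 1e-9, 1, drop = TRUE]
  if (length(front) >= 2) mean(range(front)) else mean(range(v[, 1]))
}

# millimetres per pixel, from stored scale or white key length
mm_per_px <- function(map) {
  s <- attr(map, "px_per_mm")
  if (!is.null(s) && !is.na(s)) return(1 / s)
  wl <- attr(map, "white_length_mm")
  if (is.null(wl) || is.na(wl)) wl <- 150
  whites <- Filter(function(k) k$color == "white", map)
  ylen <- median(vapply(whites, function(k) diff(range(k$vertices[, 2])), numeric(1)))
  wl / ylen
}
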