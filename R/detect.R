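## Keyboard detection from a hands-free grayscale image.
##
## Image convention: a plain R matrix of gray values in [0, 1], row 1 at
## the top of the frame. After orientation normalisation the fallboard is
## at the top, so image rows increase toward the player. Detected geometry
## is reported in the *detection frame*: x = image column centre,
## y = nrow - row + 0.5, which restores the keyboard-frame orientation
## (+Y toward the fallboard).
##
## Horizontal boundaries are found as gradient peaks of the row-mean
## intensity profile (the contract is the three boundaries, not the
## algorithm used to find them); black keys by automatic (Otsu)
## thresholding and connected-component labelling within the black-key
## band.

#' Keyboard boundary rows
#'
#' @param y_top,y_black_bottom,y_white_bottom detection-frame y of the
#'   fallboard edge, the bottom of the black keys and the bottom (front
#'   edge) of the white keys; `y_top > y_black_bottom > y_white_bottom`.
#' @return object of class `keyboard_boundaries`.
#' @export
keyboard_boundaries <- function(y_top, y_black_bottom, y_white_bottom) {
  kf_assert(y_top > y_black_bottom && y_black_bottom > y_white_bottom,
            "boundaries must satisfy y_top > y_black_bottom > y_white_bottom")
  structure(list(y_top = y_top, y_black_bottom = y_black_bottom,
                 y_white_bottom = y_white_bottom),
            class = "keyboard_boundaries")
}

load_gray_image <- function(image) {
  if (is.character(image)) {
    img <- png::readPNG(image)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else {
    as.matrix(image)
  }
}

#' Normalise keyboard image orientation
#'
#' Flips the image vertically if the black-key band sits below the
#' white-only band (i.e. the keyboard was photographed upside-down). The
#' black-key band is located as the rows with the highest across-column
#' intensity variance (dark keys alternating with white key rears); the
#' white-only band as the brightest rows.
#'
#' @param image gray matrix or PNG path.
#' @return list(image, flipped).
#' @export
normalize_keyboard_orientation <- function(image) {
  img <- load_gray_image(image)
  m <- rowMeans(img)
  v <- rowMeans(img^2) - m^2
  flipped <- which.max(v) > which.max(m)
  if (flipped) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  list(image = img, flipped = flipped)
}

#' Detect the three horizontal keyboard boundaries
#'
#' Finds the fallboard edge, the bottom of the black keys and the front
#' edge of the white keys as the three strongest gradient peaks of the
#' row-mean intensity profile.
#'
#' @param image gray matrix (normalised orientation) or PNG path.
#' @param min_gradient minimum row-mean intensity step regarded as an
#'   edge.
#' @return a `keyboard_boundaries` (detection-frame y).
#' @export
detect_boundaries <- function(image, min_gradient = 0.04) {
  img <- load_gray_image(image)
  m <- rowMeans(img)
  g <- abs(diff(m))
  # local maxima of |gradient|
  peaks <- which(g >= min_gradient &
                 g >= c(-Inf, g[-length(g)]) & g >= c(g[-1], -Inf))
  if (length(peaks) > 1L) {                 # merge adjacent peak plateaus
    keep <- c(TRUE, diff(peaks) > 3L)
    peaks <- peaks[keep]
  }
  if (length(peaks) < 3L) {
    kf_stage_error("keyboard boundary detection failed: %d edge(s) found, need 3",
                   length(peaks))
  }
  rows <- sort(peaks[order(g[peaks], decreasing = TRUE)][1:3])
  ys <- nrow(img) - rows                     # boundary between rows r, r+1
  keyboard_boundaries(y_top = ys[1], y_black_bottom = ys[2],
                      y_white_bottom = ys[3])
}

#' Detect black keys within the boundary band
#'
#' Thresholds the black-key band automatically (Otsu) and labels
#' connected dark components; small specks below a fifth of the median
#' blob area are discarded.
#'
#' @param image gray matrix (normalised orientation) or PNG path.
#' @param boundaries a `keyboard_boundaries`.
#' @return data.frame, one row per black key left to right: `cx, cy`
#'   (detection-frame centroid) and `x0, x1, y0, y1` (bounding
#'   quadrilateral).
#' @export
detect_black_keys <- function(image, boundaries) {
  img <- load_gray_image(image)
  H <- nrow(img)
  r0 <- max(1L, floor(H - boundaries$y_top) + 2L)
  r1 <- min(H, ceiling(H - boundaries$y_black_bottom) - 2L)
  kf_assert(r1 > r0, "black-key band is empty")
  ext <- detect_x_extent(img, boundaries)        # exclude background margins
  c0 <- max(1L, ceiling(ext[1] + 0.5) + 2L)
  c1 <- min(ncol(img), floor(ext[2] + 0.5) - 2L)
  band <- img[r0:r1, c0:c1, drop = FALSE]
  thr <- EBImage::otsu(EBImage::Image(band), range = c(0, 1))
  mask <- band < thr
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  if (n < 2L) kf_stage_error("black-key detection found %d blob(s)", n)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area <- tabulate(lab, n)
  keep <- which(area >= 0.2 * median(area))
  if (length(keep) < 2L) kf_stage_error("black-key blobs inconsistent")
  rows_mean <- tapply(idx[, 1], lab, mean)
  cols_mean <- tapply(idx[, 2], lab, mean)
  rows_min <- tapply(idx[, 1], lab, min); rows_max <- tapply(idx[, 1], lab, max)
  cols_min <- tapply(idx[, 2], lab, min); cols_max <- tapply(idx[, 2], lab, max)
  to_y <- function(r) H - (r0 - 1 + r) + 0.5     # band row -> detection y
  to_x <- function(c) c0 - 1 + c                 # band col -> image col
  out <- data.frame(
    cx = to_x(as.numeric(cols_mean[keep])) - 0.5,
    cy = to_y(as.numeric(rows_mean[keep])),
    x0 = to_x(as.numeric(cols_min[keep])) - 1, x1 = to_x(as.numeric(cols_max[keep])),
    y0 = to_y(as.numeric(rows_max[keep])) - 0.5,
    y1 = to_y(as.numeric(rows_min[keep])) + 0.5)
  out <- out[order(out$cx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# keyboard x extent from the white-only band
detect_x_extent <- function(img, boundaries) {
  H <- nrow(img)
  r0 <- max(1L, floor(H - boundaries$y_black_bottom) + 2L)
  r1 <- min(H, ceiling(H - boundaries$y_white_bottom) - 2L)
  cm <- colMeans(img[r0:r1, , drop = FALSE])
  thr <- (max(cm) + min(cm)) / 2
  cols <- range(which(cm > thr))
  c(cols[1] - 1, cols[2])
}

KF_WHITE_PCS <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)

# MIDI note of the white key `offset` white-keys away from C4 (midi 60)
white_note_from_c4 <- function(offset) {
  oct <- floor(offset / 7)
  pc <- KF_WHITE_PCS[(offset %% 7) + 1L]
  as.integer(60L + 12L * oct + pc)
}

#' Synthesise key polygons from detected geometry
#'
#' Reconstructs the white-key grid from the detected black keys, anchors
#' note numbers at the user-identified C4 key, and emits a full
#' `key_polygon_map`: 4-vertex rectangles for black keys, white keys
#' notched around their black neighbours (4--8 vertices).
#'
#' @param boundaries a `keyboard_boundaries`.
#' @param black_keys data.frame from [detect_black_keys()].
#' @param c4_click (x, y) detection-frame coordinates of a click inside
#'   the C4 key area.
#' @param x_extent keyboard (x_left, x_right); taken from the white band
#'   when called through [detect_keyboard()].
#' @return a `key_polygon_map` in detection-frame coordinates.
#' @export
synthesize_polygons <- function(boundaries, black_keys, c4_click, x_extent) {
  cx <- black_keys$cx
  inside_blob <- c4_click[1] >= black_keys$x0 & c4_click[1] <= black_keys$x1 &
    c4_click[2] >= black_keys$y0 & c4_click[2] <= black_keys$y1
  if (any(inside_blob)) kf_validation_error("C4 click falls inside a black key")
  kf_assert(c4_click[1] >= x_extent[1] && c4_click[1] <= x_extent[2] &&
            c4_click[2] >= boundaries$y_white_bottom &&
            c4_click[2] <= boundaries$y_top,
            "C4 click outside the key area")
  gaps <- diff(cx)
  ww0 <- median(gaps[gaps < 1.5 * min(gaps)])
  nw <- round((x_extent[2] - x_extent[1]) / ww0)
  ww <- (x_extent[2] - x_extent[1]) / nw
  bx <- function(i) x_extent[1] + i * ww           # boundary i (between whites i-1, i)
  # boundary index of each black key; must land near a boundary
  bidx <- round((cx - x_extent[1]) / ww)
  if (any(abs(cx - bx(bidx)) > 0.35 * ww) || any(bidx < 1L) || any(bidx > nw - 1L)) {
    kf_stage_error("black keys inconsistent with the white-key grid")
  }
  # white key index (0-based) holding the C4 click
  i_c4 <- floor((c4_click[1] - x_extent[1]) / ww)
  notes_white <- vapply(seq_len(nw) - 1L, function(i) white_note_from_c4(i - i_c4),
                        integer(1))
  # layout check: every detected black must sit on a boundary whose
  # left-neighbour white is C, D, F, G or A
  left_pc <- notes_white[bidx] %% 12L
  if (!all(left_pc %in% c(0L, 2L, 5L, 7L, 9L))) {
    kf_stage_error("detected black keys contradict the C4 anchor")
  }
  bw <- median(black_keys$x1 - black_keys$x0)
  bl_len <- median(black_keys$y1 - black_keys$y0)
  y_notch <- boundaries$y_top - bl_len
  keys <- list()
  has_black_at <- logical(nw + 1L)
  has_black_at[bidx + 1L] <- TRUE                  # boundary i -> index i+1
  for (i in seq_len(nw) - 1L) {
    nt <- notes_white[i + 1L]
    xl <- bx(i); xr <- bx(i + 1L)
    has_l <- i >= 1L && has_black_at[i + 1L]
    has_r <- (i + 1L) <= (nw - 1L) && has_black_at[i + 2L]
    rl <- if (has_l) xl + bw / 2 else xl
    rr <- if (has_r) xr - bw / 2 else xr
    v <- rbind(c(xl, boundaries$y_white_bottom), c(xr, boundaries$y_white_bottom),
               c(xr, y_notch), c(rr, y_notch), c(rr, boundaries$y_top),
               c(rl, boundaries$y_top), c(rl, y_notch), c(xl, y_notch))
    v <- v[!duplicated(round(v, 9)), , drop = FALSE]
    keys[[as.character(nt)]] <- list(color = "white", vertices = v)
  }
  for (k in seq_along(bidx)) {
    nt <- notes_white[bidx[k]] + 1L
    cxk <- bx(bidx[k])
    keys[[as.character(nt)]] <- list(
      color = "black",
      vertices = rbind(c(cxk - bw / 2, y_notch), c(cxk + bw / 2, y_notch),
                       c(cxk + bw / 2, boundaries$y_top),
                       c(cxk - bw / 2, boundaries$y_top)))
  }
  key_polygon_map(keys)
}

#' Detect a keyboard and build its polygon map
#'
#' Orientation normalisation, boundary detection, black-key detection and
#' polygon synthesis in one call.
#'
#' @param image gray matrix or PNG path.
#' @param c4_click (x, y) detection-frame coordinates of the C4 key (the
#'   one manual step).
#' @return list(map, boundaries, black_keys, flipped).
#' @export
detect_keyboard <- function(image, c4_click) {
  norm <- normalize_keyboard_orientation(image)
  img <- norm$image
  boundaries <- detect_boundaries(img)
  blacks <- detect_black_keys(img, boundaries)
  extent <- detect_x_extent(img, boundaries)
  map <- synthesize_polygons(boundaries, blacks, c4_click, extent)
  list(map = map, boundaries = boundaries, black_keys = blacks,
       flipped = norm$flipped)
}
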