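test_that("points are assigned to the containing key polygon", {
  map <- standard_keyboard_polygons(48L, 72L)
  c4 <- map[["60"]]$vertices
  centroid <- c(mean(c4[, 1]), mean(c4[, 2]))
  res <- assign_point_to_key(centroid, map)
  expect_equal(res$midi_note, 60L)
  expect_equal(res$rule, "inside_polygon")
  # above the fallboard edge: no key
  top <- max(vapply(map, function(k) max(k$vertices[, 2]), numeric(1)))
  expect_equal(assign_point_to_key(c(centroid[1], top + 5), map)$rule, "none")
})

test_that("points in front of the keyboard go to the nearest white key by X", {
  map <- standard_keyboard_polygons(48L, 72L)
  d4 <- map[["62"]]$vertices
  cx <- mean(range(d4[abs(d4[, 2] - min(d4[, 2])) < 1e-9, 1]))
  y_front <- min(d4[, 2])
  res <- assign_point_to_key(c(cx, y_front - 3), map)
  expect_equal(res$midi_note, 62L)
  expect_equal(res$rule, "front_by_x")
  # beyond the keyboard ends: none
  xmax <- max(vapply(map, function(k) max(k$vertices[, 1]), numeric(1)))
  expect_equal(assign_point_to_key(c(xmax + 10, y_front - 3), map)$rule, "none")
})

test_that("assignment agrees with an independent winding-number oracle", {
  map <- standard_keyboard_polygons(60L, 72L)
  xs <- seq(-10, 320, length.out = 100)
  ys <- seq(-10, 320, length.out = 60)
  grid <- expand.grid(x = xs, y = ys)
  got <- assign_points_to_keys(grid$x, grid$y, map)
  inside_any <- rep(FALSE, nrow(grid))
  oracle <- rep(NA_integer_, nrow(grid))
  for (nm in names(map)) {        # ascending notes: first hit = tie-break
    hit <- winding_inside(grid$x, grid$y, map[[nm]]$vertices)
    new <- hit & !inside_any
    oracle[new] <- as.integer(nm)
    inside_any <- inside_any | hit
  }
  poly_rows <- got$rule == "inside_polygon"
  expect_identical(poly_rows, inside_any)
  expect_identical(got$midi_note[poly_rows], oracle[poly_rows])
})

test_that("shared-edge points belong to the lower-numbered key only", {
  map <- standard_keyboard_polygons(60L, 72L)
  # boundary between C4 (60) and C#4 (61)
  cs <- map[["61"]]$vertices
  x_edge <- min(cs[, 1])
  y_mid <- mean(range(cs[, 2]))
  res <- assign_point_to_key(c(x_edge, y_mid), map)
  expect_equal(res$midi_note, 60L)
  # a point is never in two keys: per-point assignment is single-valued
  got <- assign_points_to_keys(rep(x_edge, 3), y_mid + c(-1, 0, 1), map)
  expect_true(all(!is.na(got$midi_note)))
})

test_that("touch coordinates map into key polygons", {
  # plain rectangular white key spanning x in [100,120], front edge y=400
  rect <- key_polygon_map(list(`60` = list(
    color = "white",
    vertices = rbind(c(100, 400), c(120, 400), c(120, 700), c(100, 700)))))
  tp <- touch_to_pixels(data.frame(midi_note = 60L, x_norm = 0.5, y_norm = 0), rect)
  expect_equal(c(tp$x_px, tp$y_px), c(110, 400))
  # black key corner identity: norms (0,0),(1,0),(0,1),(1,1) -> vertices
  map <- standard_keyboard_polygons(60L, 72L)
  bk <- map[["61"]]$vertices
  tp2 <- touch_to_pixels(data.frame(midi_note = 61L,
                                    x_norm = c(0, 1, 0, 1),
                                    y_norm = c(0, 0, 1, 1)), map)
  expect_equal(tp2$x_px, c(min(bk[, 1]), max(bk[, 1]), min(bk[, 1]), max(bk[, 1])))
  expect_equal(tp2$y_px, c(min(bk[, 2]), min(bk[, 2]), max(bk[, 2]), max(bk[, 2])))
  expect_error(touch_to_pixels(data.frame(midi_note = 100L, x_norm = 0.5,
                                          y_norm = 0.5), map), "missing")
})

test_that("null x_norm falls back to the key centreline", {
  map <- standard_keyboard_polygons(60L, 72L)
  # rear of white key D4: narrow part between C#4 and D#4
  tp <- touch_to_pixels(data.frame(midi_note = 62L, x_norm = NA_real_,
                                   y_norm = 0.9), map)
  d4 <- map[["62"]]$vertices
  y_top <- max(d4[, 2])
  rear_x <- range(d4[abs(d4[, 2] - y_top) < 1e-9, 1])
  expect_equal(tp$x_px, mean(rear_x))
})

test_that("pixel mapping roundtrips norms to 1e-6 px", {
  map <- standard_keyboard_polygons(60L, 72L)
  set.seed(7)
  for (nt in c(60L, 61L, 62L, 66L)) {
    norms <- data.frame(midi_note = nt, x_norm = runif(20, 0.01, 0.99),
                        y_norm = runif(20, 0.01, 0.99))
    px <- touch_to_pixels(norms, map)
    back <- pixels_to_touch_norms(px$x_px, px$y_px, nt, map)
    px2 <- touch_to_pixels(cbind(midi_note = nt, back), map)
    expect_equal(px2$x_px, px$x_px, tolerance = 1e-6)
    expect_equal(px2$y_px, px$y_px, tolerance = 1e-6)
  }
})

test_that("marker annotation is per-marker, with occlusion skipped", {
  map <- standard_keyboard_polygons(48L, 72L)
  tp <- function(nt) touch_to_pixels(data.frame(midi_note = nt, x_norm = 0.5,
                                                y_norm = 0.2), map)
  # a hand flat over five white keys; ring finger occluded
  notes5 <- c(60L, 62L, 64L, 65L, 67L)
  mk <- do.call(rbind, lapply(1:5, function(f) {
    p <- tp(notes5[f])
    data.frame(frame_index = 0L, hand = "right", finger = f,
               landmark = if (f == 1L) "IP" else "DIP",
               x_px = p$x_px, y_px = p$y_px, visible = f != 4L)
  }))
  ann <- marker_key_annotation(mk, map)
  expect_equal(nrow(ann), 4L)                   # occluded marker dropped
  expect_equal(sort(ann$midi_note), sort(notes5[-4]))
  # a finger angled across two keys: distal and proximal notes differ
  p60 <- tp(60L)
  angled <- data.frame(frame_index = 0L, hand = "right", finger = 2L,
                       landmark = c("DIP", "PIP"),
                       x_px = c(p60$x_px, p60$x_px + 47),
                       y_px = c(p60$y_px, p60$y_px + 30), visible = TRUE)
  ann2 <- marker_key_annotation(angled, map)
  expect_false(ann2$midi_note[1] == ann2$midi_note[2])
})
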