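# Shared generators and the raster-oracle comparison used by both the unit
# and the acceptance property tests.

# Random integer-coordinate drawing set on the [0, plane)^2 plane:
# up to max_participants participants, up to max_rects rectangles, every
# footprint contained in the plane so the pixel oracle can cover it.
random_drawing_set <- function(seed, max_participants = 10L,
                               max_rects = 100L, plane = 200L) {
  set.seed(seed)
  n_p <- sample.int(max_participants, 1)
  n_r <- sample.int(max_rects, 1)
  who <- sprintf("P%02d", sample.int(n_p, n_r, replace = TRUE))
  x <- sample.int(plane - 1L, n_r, replace = TRUE) - 1L
  y <- sample.int(plane - 1L, n_r, replace = TRUE) - 1L
  w <- pmin(sample.int(40L, n_r, replace = TRUE), plane - x)
  h <- pmin(sample.int(40L, n_r, replace = TRUE), plane - y)
  drawing_set(pain_recordings(who, x = x, y = y, width = w, height = h),
              total_drawings = n_p)
}

# Paint output rectangles onto a pixel grid; errors if two rectangles claim
# the same pixel. Returns an integer matrix of rect row indices (0 = bare).
fill_rect_ids <- function(rects, bbox) {
  nx <- bbox[3] - bbox[1]
  ny <- bbox[4] - bbox[2]
  ids <- matrix(0L, nx, ny)
  for (k in seq_len(nrow(rects))) {
    i0 <- rects$x[k] - bbox[1] + 1L
    i1 <- rects$x[k] + rects$width[k] - bbox[1]
    j0 <- rects$y[k] - bbox[2] + 1L
    j1 <- rects$y[k] + rects$height[k] - bbox[2]
    patch <- ids[i0:i1, j0:j1]
    if (any(patch != 0L)) stop("output rectangles overlap at the pixel level")
    ids[i0:i1, j0:j1] <- k
  }
  ids
}

# Per-pixel equivalence between compute_overlap() output and the brute-force
# raster oracle: identical coverage, identical participant set everywhere,
# hence identical per-overlap-set areas. Returns TRUE or stops.
expect_oracle_equivalent <- function(ds, fm, bbox = c(0, 0, 200, 200)) {
  keys <- rasterize_oracle(ds$recordings, bbox = bbox)
  ids <- fill_rect_ids(fm$rects, bbox)
  covered <- keys != ""
  expect_identical(ids != 0L, covered)
  expect_identical(fm$rects$overlap[ids[covered]],
                   as.vector(keys[covered]))
  # conservation: total output area equals the rasterized union area
  expect_equal(sum(fm$rects$area), sum(covered))
  invisible(TRUE)
}

# Per-overlap-set total areas, for layout/permutation invariance checks.
area_by_set <- function(fm) {
  a <- tapply(fm$rects$area, fm$rects$overlap, sum)
  a[order(names(a))]
}

# No two rectangles with identical overlap sets may still satisfy either
# merge-eligibility rule (same cross band and adjacent along the layout
# axis; same layout extent and adjacent on the cross axis). Checked by
# hashing each rectangle's left/top faces against every right/bottom face
# within the same overlap set.
expect_maximal <- function(fm) {
  r <- fm$rects
  if (fm$layout == "vertical") {
    r <- data.frame(x = r$y, y = r$x, width = r$height, height = r$width,
                    overlap = r$overlap)
  }
  rule1_rhs <- paste(r$overlap, r$y, r$height, r$x + r$width)
  rule1_lhs <- paste(r$overlap, r$y, r$height, r$x)
  rule2_rhs <- paste(r$overlap, r$x, r$width, r$y + r$height)
  rule2_lhs <- paste(r$overlap, r$x, r$width, r$y)
  expect_length(intersect(rule1_rhs, rule1_lhs), 0)
  expect_length(intersect(rule2_rhs, rule2_lhs), 0)
  invisible(TRUE)
}

# Write a small SVG drawing document for I/O tests.
write_svg_drawing <- function(path, rects_txt) {
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"200\" height=\"200\">",
    rects_txt,
    "</svg>"), path)
  path
}
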