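test_that("edge decomposition collects sorted, deduplicated boundaries", {
  one <- pain_recordings("a", x = 5, y = 0, width = 20, height = 10)
  expect_identical(rect_boundaries(one, "x"), c(5, 25))
  expect_identical(rect_boundaries(one, "y"), c(0, 10))

  three <- pain_recordings("a", x = c(0, 20, 10), y = 0,
                           width = 30, height = 5)
  expect_identical(rect_boundaries(three, "x"),
                   c(0, 10, 20, 30, 40, 50))

  abutting <- pain_recordings(c("a", "b"), x = c(0, 10), y = 0,
                              width = 10, height = 10)
  expect_identical(rect_boundaries(abutting, "x"), c(0, 10, 20))

  empty <- pain_recordings(character(0), numeric(0), numeric(0),
                           numeric(0), numeric(0))
  expect_identical(rect_boundaries(empty, "x"), numeric(0))

  bad <- data.frame(participant = "a", x = 0, y = 0, width = 0, height = 5)
  expect_error(rect_boundaries(bad, "x"), "strictly positive")
})

test_that("partitions tile the boundary range with half-open windows", {
  w <- rect_partitions(c(0, 10, 20))
  expect_identical(w$start, c(0, 10))
  expect_identical(w$end, c(10, 20))
  expect_identical(nrow(rect_partitions(c(5, 25))), 1L)
  expect_identical(nrow(rect_partitions(numeric(0))), 0L)

  b <- sort(runif(8))
  w <- rect_partitions(b)
  expect_identical(nrow(w), 7L)
  expect_identical(w$end[-7], w$start[-1])   # no gaps, no overlap

  expect_error(rect_partitions(c(10, 0)), "sorted")
  expect_error(rect_partitions(c(0, 10, 10)), "sorted")
})

test_that("grid cells carry distinct-participant overlap sets", {
  ts <- pain_fixture("two_square")
  g <- overlap_grid(ts$recordings)
  expect_identical(dim(g$set_id), c(3L, 3L))
  expect_identical(sum(g$set_id != 0), 7L)
  centre <- g$set_id[2, 2]                   # x [10,20) x y [10,20)
  expect_identical(g$sets[[centre]], c("a", "b"))
  others <- g$set_id[g$set_id != 0 & g$set_id != centre]
  expect_true(all(lengths(g$sets[others]) == 1))

  # one participant drawing twice: every nonempty cell is a singleton {a}
  same <- pain_recordings("a", x = c(0, 10), y = c(0, 10),
                          width = 20, height = 20)
  g2 <- overlap_grid(same)
  expect_true(all(lengths(g2$sets[g2$set_id[g2$set_id != 0]]) == 1))

  # disjoint rects, distinct participants: no cell set exceeds size 1
  disj <- pain_recordings(c("a", "b"), x = c(0, 50), y = 0,
                          width = 10, height = 10)
  g3 <- overlap_grid(disj)
  expect_true(all(lengths(g3$sets) == 1))
})

test_that("two-pass merging reproduces the nested-squares decompositions", {
  conc <- pain_fixture("concentric3")
  for (layout in c("horizontal", "vertical")) {
    m <- merge_cells(overlap_grid(conc$recordings), layout)
    expect_identical(nrow(m), 9L)
    sets <- attr(m, "sets")
    sizes <- lengths(sets)[m$set_id]
    expect_identical(sum(sizes == 3), 1L)    # 1 centre
    expect_identical(sum(sizes == 2), 4L)    # 4 per ring
    expect_identical(sum(sizes == 1), 4L)
  }

  nested <- pain_fixture("nested_single")
  m1 <- merge_cells(overlap_grid(nested$recordings), "horizontal")
  expect_identical(nrow(m1), 1L)
  expect_identical(m1[1, c("x", "y", "width", "height")],
                   data.frame(x = 20, y = 20, width = 60, height = 60))

  ts <- pain_fixture("two_square")
  m2 <- merge_cells(overlap_grid(ts$recordings), "horizontal")
  expect_identical(nrow(m2), 5L)
  both <- m2[lengths(attr(m2, "sets"))[m2$set_id] == 2, ]
  expect_identical(nrow(both), 1L)
  expect_identical(as.numeric(both[1, c("x", "y", "width", "height")]),
                   c(10, 10, 10, 10))
})

test_that("compute_overlap annotates frequency and proportion over T", {
  # complete overlay: identical rects from two participants
  ident <- drawing_set(pain_recordings(c("a", "b"), x = 0, y = 0,
                                       width = 20, height = 20))
  fm <- compute_overlap(ident)
  expect_identical(nrow(fm$rects), 1L)
  expect_identical(fm$rects$overlap_frequency, 2L)
  expect_identical(fm$rects$overlap_proportion, 1)

  # three mutually overlapping squares: proportions k/3
  fm3 <- compute_overlap(pain_fixture("venn3"))
  r <- fm3$rects
  expect_identical(sort(unique(r$overlap_proportion)), c(1, 2, 3) / 3)
  expect_true(all(r$overlap_proportion == r$overlap_frequency / 3))

  # empty drawings inflate the denominator: one rect, T = 3
  solo <- drawing_set(pain_recordings("a", 0, 0, 10, 10),
                      total_drawings = 3)
  fm1 <- compute_overlap(solo)
  expect_identical(fm1$rects$overlap_proportion, 1 / 3)
  expect_identical(compute_overlap(solo, denominator = "participants")$
                     rects$overlap_proportion, 1)

  # no recordings at all: a zero-rectangle map
  none <- drawing_set(pain_recordings(character(0), numeric(0), numeric(0),
                                      numeric(0), numeric(0)),
                      total_drawings = 2)
  fm0 <- compute_overlap(none)
  expect_identical(nrow(fm0$rects), 0L)
  expect_true(is.na(fm0$max_frequency))

  # T below the participant count violates the contract
  expect_error(drawing_set(pain_recordings(c("a", "b"), x = c(0, 5),
                                           y = 0, width = 5, height = 5),
                           total_drawings = 1),
               "smaller than the number")
})

test_that("filtering is inclusive on both ends and keeps proportions", {
  fm <- compute_overlap(pain_fixture("two_square"))
  top <- filter_map(fm, min_freq = 2)
  expect_identical(nrow(top$rects), 1L)
  expect_identical(top$rects$overlap, "a;b")
  expect_identical(top$rects$overlap_proportion, 1)   # denominator still T

  expect_identical(filter_map(fm)$rects, fm$rects)    # identity filter
  expect_identical(nrow(filter_map(fm, min_width = 100)$rects), 0L)
  expect_error(filter_map(fm, min_freq = 3, max_freq = 1), "min_freq")
})

test_that("null-drawing masking keeps within-template overlap only", {
  rec <- pain_recordings(c("N", "A"), x = c(0, 10), y = c(0, 10),
                         width = c(100, 10), height = c(100, 10))
  fm <- compute_overlap(drawing_set(rec, total_drawings = 2))
  masked <- apply_null_mask(fm, "N")
  expect_true(all(masked$rects$overlap == "A"))
  expect_identical(sum(masked$rects$area), 100)
  expect_identical(masked$rects$overlap_frequency, 1L)
  expect_identical(masked$rects$overlap_proportion, 1)  # denominator T - 1

  # no actual drawing overlaps the template: an empty map
  apart <- pain_recordings(c("N", "A"), x = c(0, 200), y = c(0, 0),
                           width = c(100, 10), height = c(100, 10))
  fma <- compute_overlap(drawing_set(apart, total_drawings = 2))
  expect_identical(nrow(apply_null_mask(fma, "N")$rects), 0L)

  expect_error(apply_null_mask(fm, "nobody"), "mask mismatch")
})

test_that("raster oracle matches hand-countable cases", {
  one <- pain_recordings("a", x = 0, y = 0, width = 2, height = 2)
  keys <- rasterize_oracle(one)
  expect_identical(dim(keys), c(2L, 2L))
  expect_true(all(keys == "a"))

  ts <- pain_fixture("two_square")
  keys <- rasterize_oracle(ts$recordings)
  expect_identical(sum(keys == "a"), 300L)
  expect_identical(sum(keys == "a;b"), 100L)
  expect_identical(sum(keys == "b"), 300L)

  empty <- pain_recordings(character(0), numeric(0), numeric(0),
                           numeric(0), numeric(0))
  expect_true(all(rasterize_oracle(empty, bbox = c(0, 0, 4, 4)) == ""))
})

test_that("decomposition properties hold on random integer instances", {
  for (seed in 1:25) {
    ds <- random_drawing_set(seed)
    fm <- compute_overlap(ds)
    # disjointness + conservation + per-pixel oracle equivalence
    expect_oracle_equivalent(ds, fm)
    expect_maximal(fm)

    # frequency bounds and exact proportion arithmetic
    expect_true(all(fm$rects$overlap_frequency >= 1))
    expect_true(all(fm$rects$overlap_frequency <=
                      length(ds$participants)))
    expect_identical(fm$rects$overlap_proportion * ds$total_drawings,
                     as.numeric(fm$rects$overlap_frequency))

    # layout invariance of per-overlap-set areas
    fmv <- compute_overlap(ds, layout = "vertical")
    expect_maximal(fmv)
    expect_identical(area_by_set(fm), area_by_set(fmv))

    # permutation invariance of the (overlap set, area) decomposition
    perm <- ds$recordings[sample.int(nrow(ds$recordings)), , drop = FALSE]
    fmp <- compute_overlap(drawing_set(perm,
                                       total_drawings = ds$total_drawings))
    expect_identical(area_by_set(fm), area_by_set(fmp))
  }
})

test_that("a single participant's nested rectangles collapse to one", {
  set.seed(99)
  for (k in 1:10) {
    depth <- sample(2:6, 1)
    x0 <- sort(sample(0:40, depth))          # strictly nested chain
    side <- 100 - 2 * x0
    rec <- pain_recordings("solo", x = x0, y = x0,
                           width = side, height = side)
    fm <- compute_overlap(drawing_set(rec))
    expect_identical(nrow(fm$rects), 1L)
    expect_identical(fm$rects$width, max(side))
  }
})
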