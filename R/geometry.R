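#' Decompose recordings into edge coordinates along one axis
#'
#' The first stage of the overlap computation: every rectangle contributes
#' its two edge coordinates along the chosen axis (`x` and `x + width`, or
#' `y` and `y + height`). The sorted, deduplicated union of these edges
#' defines the interval partition for that axis.
#'
#' @param recordings a recordings data frame (see [pain_recordings()]).
#' @param axis `"x"` or `"y"`.
#' @return a sorted numeric vector of distinct edge coordinates (empty for
#'   empty input).
#' @examples
#' rec <- pain_recordings("a", x = 5, y = 0, width = 20, height = 10)
#' rect_boundaries(rec, "x")  # 5 25
#' @export
rect_boundaries <- function(recordings, axis = c("x", "y")) {
  axis <- match.arg(axis)
  rec <- validate_recordings(recordings)
  if (nrow(rec) == 0) return(numeric(0))
  edges <- if (axis == "x") c(rec$x, rec$x + rec$width)
           else c(rec$y, rec$y + rec$height)
  sort(unique(edges))
}

#' Turn sorted edge coordinates into half-open interval windows
#'
#' Consecutive pairs of distinct edge coordinates become half-open windows
#' `[start, end)`; n coordinates yield n - 1 windows tiling
#' `[min, max)` exactly.
#'
#' @param bounds sorted, duplicate-free numeric vector of edge coordinates.
#' @return a data.frame with columns `start` and `end`, one row per window.
#' @examples
#' rect_partitions(c(0, 10, 20))
#' @export
rect_partitions <- function(bounds) {
  bounds <- as.numeric(bounds)
  if (length(bounds) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  if (is.unsorted(bounds, strictly = TRUE)) {
    stop("bounds must be sorted and free of duplicates", call. = FALSE)
  }
  if (length(bounds) == 1) {
    stop("at least two bounds are needed to form a window", call. = FALSE)
  }
  n <- length(bounds)
  data.frame(start = bounds[-n], end = bounds[-1])
}

# Map each rectangle to its 1-based inclusive range of window indices along
# one axis. Edges are reproduced by the same arithmetic that built the
# bounds, so findInterval matches exactly (no tolerance needed).
window_range <- function(lo, hi, bounds) {
  i0 <- findInterval(lo, bounds)
  i1 <- findInterval(hi, bounds) - 1L
  list(lo = as.integer(i0), hi = as.integer(i1))
}

#' Label grid cells with their participant overlap sets
#'
#' Crossing the x- and y-interval windows yields a grid of cells; each cell
#' is labeled with the set of *distinct* participants owning at least one
#' recording whose footprint contains the cell. Multiple rectangles from the
#' same participant count once (set semantics). Cells covered by no
#' recording carry set id 0.
#'
#' @param recordings a recordings data frame.
#' @param xwin,ywin interval windows from [rect_partitions()]; if `NULL`
#'   they are derived from `recordings`.
#' @return an object of class `overlap_grid`: a list with `set_id` (an
#'   `nx x ny` integer matrix over (x window, y window) cells), `sets`
#'   (list of sorted participant-id character vectors, indexed by set id),
#'   `xbounds`, `ybounds`.
#' @examples
#' rec <- pain_recordings(c("a", "b"), x = c(0, 10), y = c(0, 10),
#'                        width = 20, height = 20)
#' g <- overlap_grid(rec)
#' sum(g$set_id != 0)  # 7 nonempty cells of the 3 x 3 grid
#' @export
overlap_grid <- function(recordings, xwin = NULL, ywin = NULL) {
  rec <- validate_recordings(recordings)
  xb <- if (is.null(xwin)) rect_boundaries(rec, "x")
        else unique(c(xwin$start, xwin$end))
  yb <- if (is.null(ywin)) rect_boundaries(rec, "y")
        else unique(c(ywin$start, ywin$end))
  participants <- sort(unique(rec$participant), method = "radix")
  if (nrow(rec) == 0) {
    return(structure(list(set_id = matrix(integer(0), 0, 0), sets = list(),
                          xbounds = xb, ybounds = yb),
                     class = "overlap_grid"))
  }
  rx <- window_range(rec$x, rec$x + rec$width, xb)
  ry <- window_range(rec$y, rec$y + rec$height, yb)
  pid <- match(rec$participant, participants)
  lab <- grid_label_cpp(rx$lo, rx$hi, ry$lo, ry$hi, pid,
                        length(xb) - 1L, length(yb) - 1L)
  sets <- lapply(lab$sets, function(codes) participants[codes])
  structure(list(set_id = lab$set_id, sets = sets,
                 xbounds = xb, ybounds = yb),
            class = "overlap_grid")
}

# Merge a set-id matrix into maximal rectangles. M is indexed (layout axis,
# cross axis); lb/cb are the bound vectors for the two axes. Pass 1 takes
# maximal constant-set runs along the layout axis within each cross band
# (rle is maximal by construction); pass 2 chain-merges runs with identical
# set id and identical layout extent that are edge-adjacent on the cross
# axis. Cross bands are single windows, so adjacency is consecutive band
# index, and chain merging reaches the fixpoint in one sorted sweep.
merge_axis <- function(M, lb, cb) {
  nband <- ncol(M)
  sid <- integer(0); llo <- integer(0); lhi <- integer(0); band <- integer(0)
  acc <- vector("list", nband)
  for (j in seq_len(nband)) {
    r <- rle(M[, j])
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    keep <- r$values != 0L
    if (any(keep)) {
      acc[[j]] <- cbind(r$values[keep], lo[keep], hi[keep], j)
    }
  }
  runs <- do.call(rbind, acc)
  if (is.null(runs)) {
    return(data.frame(lx = numeric(0), cx = numeric(0),
                      lext = numeric(0), cext = numeric(0),
                      set_id = integer(0)))
  }
  sid <- runs[, 1]; llo <- runs[, 2]; lhi <- runs[, 3]; band <- runs[, 4]
  ord <- order(sid, llo, lhi, band)
  sid <- sid[ord]; llo <- llo[ord]; lhi <- lhi[ord]; band <- band[ord]
  n <- length(sid)
  same_group <- c(FALSE, sid[-1] == sid[-n] & llo[-1] == llo[-n] &
                         lhi[-1] == lhi[-n])
  new_chain <- !(same_group & c(FALSE, band[-1] == band[-n] + 1L))
  chain <- cumsum(new_chain)
  first <- !duplicated(chain)
  last <- !duplicated(chain, fromLast = TRUE)
  data.frame(
    lx = lb[llo[first]],
    cx = cb[band[first]],
    lext = lb[lhi[last] + 1L] - lb[llo[first]],
    cext = cb[band[last] + 1L] - cb[band[first]],
    set_id = sid[first]
  )
}

#' Merge grid cells into maximal nonoverlapping rectangles
#'
#' Adjoining cells with identical overlap sets are merged in two passes so
#' that the output rectangles are as wide (horizontal layout) or as long
#' (vertical layout) as possible: pass 1 merges maximal runs of adjacent
#' cells with identical overlap sets along the layout axis within each cross
#' band; pass 2 merges results with identical overlap sets and identical
#' layout-axis extent that abut on the cross axis, repeated to fixpoint.
#' The output rectangles are pairwise disjoint and tile exactly the cells
#' covered by at least one recording.
#'
#' @param grid an `overlap_grid`.
#' @param layout `"horizontal"` (wider rectangles) or `"vertical"` (longer
#'   rectangles).
#' @return a data.frame with columns `x`, `y`, `width`, `height`, `set_id`,
#'   sorted by (y, x), with the participant sets in `attr(, "sets")`.
#' @export
merge_cells <- function(grid, layout = c("horizontal", "vertical")) {
  layout <- match.arg(layout)
  if (length(grid$set_id) == 0) {
    out <- data.frame(x = numeric(0), y = numeric(0), width = numeric(0),
                      height = numeric(0), set_id = integer(0))
    attr(out, "sets") <- grid$sets
    return(out)
  }
  if (layout == "horizontal") {
    m <- merge_axis(grid$set_id, grid$xbounds, grid$ybounds)
    out <- data.frame(x = m$lx, y = m$cx, width = m$lext, height = m$cext,
                      set_id = m$set_id)
  } else {
    m <- merge_axis(t(grid$set_id), grid$ybounds, grid$xbounds)
    out <- data.frame(x = m$cx, y = m$lx, width = m$cext, height = m$lext,
                      set_id = m$set_id)
  }
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sets") <- grid$sets
  out
}

#' Compute the pain frequency map from a drawing set
#'
#' The end-to-end overlap computation: rectangle edges are decomposed into
#' interval partitions along both axes ([rect_boundaries()],
#' [rect_partitions()]), the crossed grid cells are labeled with participant
#' overlap sets ([overlap_grid()]), and adjoining cells with identical sets
#' are merged into maximal nonoverlapping rectangles ([merge_cells()]).
#' Each output rectangle represents a unique location on the body template
#' and carries its overlap set, overlap frequency (number of distinct
#' participants covering it) and overlap proportion (frequency divided by
#' the total number of drawings T, which may include empty submissions).
#'
#' @param x a [drawing_set()], or a recordings data frame (coerced with
#'   `total_drawings` defaulting to the number of distinct participants).
#' @param layout merge direction: `"horizontal"` (wider rectangles, suits
#'   wide regions like the abdomen) or `"vertical"` (longer rectangles,
#'   suits the legs).
#' @param denominator `"drawings"` divides frequencies by T (the default,
#'   counting empty drawings); `"participants"` divides by the number of
#'   participants with at least one recording.
#' @return an object of class [pain_freqmap].
#' @examples
#' ds <- pain_fixture("concentric3")
#' fm <- compute_overlap(ds)
#' fm                       # 9 nonoverlapping rectangles
#' as.data.frame(fm)
#' @export
compute_overlap <- function(x, layout = c("horizontal", "vertical"),
                            denominator = c("drawings", "participants")) {
  layout <- match.arg(layout)
  denominator <- match.arg(denominator)
  ds <- if (inherits(x, "drawing_set")) x else drawing_set(x)
  grid <- overlap_grid(ds$recordings)
  merged <- merge_cells(grid, layout)
  sets <- attr(merged, "sets")
  denom <- if (denominator == "drawings") ds$total_drawings
           else max(length(ds$participants), 1L)
  freq <- if (nrow(merged) > 0) lengths(sets)[merged$set_id] else integer(0)
  rects <- data.frame(
    x = merged$x, y = merged$y,
    width = merged$width, height = merged$height,
    area = merged$width * merged$height,
    overlap = if (nrow(merged) > 0)
      vapply(sets, paste, "", collapse = ";")[merged$set_id]
      else character(0),
    overlap_frequency = as.integer(freq),
    overlap_proportion = if (nrow(merged) > 0) freq / denom else numeric(0),
    stringsAsFactors = FALSE
  )
  new_pain_freqmap(rects, region = ds$region,
                   total_drawings = ds$total_drawings,
                   layout = layout, denominator = denominator,
                   denom = denom)
}

#' Filter a pain frequency map
#'
#' Retains rectangles whose overlap frequency lies in
#' `[min_freq, max_freq]` (inclusive on both ends) and whose width and
#' height meet the thresholds. Proportions are unchanged: the denominator
#' stays the total number of drawings of the unfiltered map.
#'
#' @param fm a [pain_freqmap].
#' @param min_freq,max_freq inclusive overlap-frequency range.
#' @param min_width,min_height minimum rectangle dimensions (>= 0).
#' @return a filtered [pain_freqmap].
#' @export
filter_map <- function(fm, min_freq = 1L, max_freq = Inf,
                       min_width = 0, min_height = 0) {
  stopifnot(inherits(fm, "pain_freqmap"))
  if (min_freq > max_freq) {
    stop("min_freq must not exceed max_freq", call. = FALSE)
  }
  if (min_width < 0 || min_height < 0) {
    stop("width/height thresholds must be nonnegative", call. = FALSE)
  }
  r <- fm$rects
  keep <- r$overlap_frequency >= min_freq & r$overlap_frequency <= max_freq &
          r$width >= min_width & r$height >= min_height
  fm$rects <- r[keep, , drop = FALSE]
  rownames(fm$rects) <- NULL
  fm$max_frequency <- if (any(keep)) max(fm$rects$overlap_frequency)
                      else NA_integer_
  fm
}

#' Mask a frequency map with a null drawing
#'
#' A *null drawing* is a synthetic drawing (participant id `null_id`) that
#' tiles the body template's regions exactly. Running the overlap
#' computation on actual drawings plus the null drawing and then applying
#' this mask retains only the rectangles common to the null drawing and at
#' least one actual drawing — discarding the parts of actual drawings that
#' overflow the region outline, and the null-only remainder (frequency 1).
#' The null id is removed from each surviving overlap set, the frequency is
#' decremented, and the proportion is recomputed with a denominator that
#' excludes the null drawing.
#'
#' @param fm a [pain_freqmap] computed on a drawing set that included the
#'   null drawing.
#' @param null_id participant id of the null drawing.
#' @return the masked [pain_freqmap].
#' @export
apply_null_mask <- function(fm, null_id) {
  stopifnot(inherits(fm, "pain_freqmap"))
  r <- fm$rects
  members <- strsplit(r$overlap, ";", fixed = TRUE)
  has_null <- vapply(members, function(s) null_id %in% s, TRUE)
  if (!any(has_null)) {
    stop("null drawing id '", null_id,
         "' appears in no overlap set; mask mismatch", call. = FALSE)
  }
  keep <- has_null & r$overlap_frequency >= 2L
  r <- r[keep, , drop = FALSE]
  members <- members[keep]
  denom <- max(fm$denom - 1L, 1L)
  r$overlap <- vapply(members, function(s)
    paste(setdiff(s, null_id), collapse = ";"), "")
  r$overlap_frequency <- r$overlap_frequency - 1L
  r$overlap_proportion <- r$overlap_frequency / denom
  rownames(r) <- NULL
  fm$rects <- r
  fm$total_drawings <- fm$total_drawings - 1L
  fm$denom <- denom
  fm$max_frequency <- if (nrow(r) > 0) max(r$overlap_frequency)
                      else NA_integer_
  fm
}
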