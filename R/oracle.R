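#' Brute-force raster oracle for overlap validation
#'
#' Rasterizes recordings onto a grid of square cells and records, for every
#' cell, the set of distinct participants covering it. This is the naive
#' per-pixel computation that the grid-free overlap algorithm replaces; it
#' is retained purely as an independent oracle for testing (per-pixel set
#' equality and per-overlap-set area equality against [compute_overlap()]).
#'
#' @param recordings a recordings data frame with integer coordinates.
#' @param bbox `c(xmin, ymin, xmax, ymax)`; default is the integer bounding
#'   box of the recordings.
#' @param resolution cell side length, a positive integer that divides all
#'   coordinates relative to the bounding box.
#' @return a character matrix (rows = x cells, columns = y cells); entry
#'   `[i, j]` is the cell's overlap set serialized as sorted participant
#'   ids joined with `";"`, `""` where no recording covers the cell.
#'   The bounding box and resolution are attached as attributes.
#' @examples
#' rec <- pain_recordings("a", x = 0, y = 0, width = 2, height = 2)
#' rasterize_oracle(rec)  # 4 cells, each "a"
#' @export
rasterize_oracle <- function(recordings, bbox = NULL, resolution = 1L) {
  rec <- validate_recordings(recordings)
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 1) {
    stop("resolution must be a positive integer", call. = FALSE)
  }
  coords <- c(rec$x, rec$y, rec$x + rec$width, rec$y + rec$height)
  if (any(coords != round(coords))) {
    stop("the raster oracle requires integer-coordinate recordings",
         call. = FALSE)
  }
  if (is.null(bbox)) {
    if (nrow(rec) == 0) bbox <- c(0, 0, resolution, resolution)
    else bbox <- c(min(rec$x), min(rec$y),
                   max(rec$x + rec$width), max(rec$y + rec$height))
  }
  rel <- c(rec$x - bbox[1], rec$y - bbox[2],
           rec$x + rec$width - bbox[1], rec$y + rec$height - bbox[2],
           bbox[3] - bbox[1], bbox[4] - bbox[2])
  if (any(rel %% resolution != 0)) {
    stop("resolution must divide all coordinates relative to the bounding ",
         "box", call. = FALSE)
  }
  nx <- as.integer((bbox[3] - bbox[1]) / resolution)
  ny <- as.integer((bbox[4] - bbox[2]) / resolution)
  keys <- matrix("", nx, ny)
  for (p in sort(unique(rec$participant), method = "radix")) {
    mask <- matrix(FALSE, nx, ny)
    rows <- rec[rec$participant == p, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      i0 <- (rows$x[k] - bbox[1]) / resolution + 1L
      i1 <- (rows$x[k] + rows$width[k] - bbox[1]) / resolution
      j0 <- (rows$y[k] - bbox[2]) / resolution + 1L
      j1 <- (rows$y[k] + rows$height[k] - bbox[2]) / resolution
      i0 <- max(i0, 1L); j0 <- max(j0, 1L)
      i1 <- min(i1, nx); j1 <- min(j1, ny)
      if (i0 <= i1 && j0 <= j1) mask[i0:i1, j0:j1] <- TRUE
    }
    keys[mask] <- ifelse(keys[mask] == "", p, paste(keys[mask], p, sep = ";"))
  }
  attr(keys, "bbox") <- bbox
  attr(keys, "resolution") <- resolution
  keys
}
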