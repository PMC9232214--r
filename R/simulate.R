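#' Simulated single-click drawings (one rectangle per participant)
#'
#' Generates the first benchmark workload: every participant's drawing is a
#' single rectangle (one mouse click) on an XY plane of the given
#' dimensions with the origin at (0, 0). Rectangle origins are integer
#' ordered pairs sampled *without* replacement from the plane; widths and
#' heights are sampled *with* replacement from `dims` (10 to 100 in steps
#' of 10). Rectangles may extend past the plane's right/bottom edge and are
#' recorded as drawn. The single region is labeled `"xy-plane"`.
#'
#' @param n_rects number of rectangles (= participants).
#' @param seed integer seed for reproducibility (identical seed, identical
#'   rows); `NULL` uses the current RNG state.
#' @param plane `c(width, height)` of the plane (default 1000 x 1000).
#' @param dims candidate rectangle dimensions.
#' @return a data.frame in the input CSV schema
#'   (`participant,x,y,width,height,region`).
#' @examples
#' head(simulate_single_click(100, seed = 1))
#' @export
simulate_single_click <- function(n_rects, seed = NULL,
                                  plane = c(1000, 1000),
                                  dims = seq(10, 100, by = 10)) {
  n_rects <- as.integer(n_rects)
  n_pairs <- as.numeric(plane[1]) * as.numeric(plane[2])
  if (n_rects > n_pairs) {
    stop("n_rects exceeds the number of ordered pairs on the plane",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n_pairs, n_rects) - 1
  data.frame(
    participant = sprintf("p%06d", seq_len(n_rects)),
    x = idx %% plane[1],
    y = idx %/% plane[1],
    width = sample(dims, n_rects, replace = TRUE),
    height = sample(dims, n_rects, replace = TRUE),
    region = "xy-plane",
    stringsAsFactors = FALSE
  )
}

#' Simulated multi-click participant drawings
#'
#' Generates the second benchmark workload: a typical participant drawing
#' consists of `clicks` rectangles (default 100 mouse clicks). Origins are
#' sampled without replacement — by default across the whole dataset, or
#' per participant with `origin_unique = "participant"` (so two
#' participants may then click the same spot). Dimensions are sampled with
#' replacement from `dims`.
#'
#' @param n_participants number of participants.
#' @param clicks rectangles per participant (default 100).
#' @param origin_unique `"dataset"` or `"participant"`: the scope within
#'   which origins are unique.
#' @inheritParams simulate_single_click
#' @return a data.frame in the input CSV schema; `n_participants * clicks`
#'   rows.
#' @export
simulate_participants <- function(n_participants, clicks = 100L,
                                  seed = NULL, plane = c(1000, 1000),
                                  dims = seq(10, 100, by = 10),
                                  origin_unique = c("dataset",
                                                    "participant")) {
  origin_unique <- match.arg(origin_unique)
  n_participants <- as.integer(n_participants)
  clicks <- as.integer(clicks)
  n <- n_participants * clicks
  n_pairs <- as.numeric(plane[1]) * as.numeric(plane[2])
  need <- if (origin_unique == "dataset") n else clicks
  if (need > n_pairs) {
    stop("requested origins exceed the number of ordered pairs on the plane",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- if (origin_unique == "dataset") {
    sample.int(n_pairs, n) - 1
  } else {
    unlist(lapply(seq_len(n_participants),
                  function(i) sample.int(n_pairs, clicks) - 1))
  }
  data.frame(
    participant = rep(sprintf("p%06d", seq_len(n_participants)),
                      each = clicks),
    x = idx %% plane[1],
    y = idx %/% plane[1],
    width = sample(dims, n, replace = TRUE),
    height = sample(dims, n, replace = TRUE),
    region = "xy-plane",
    stringsAsFactors = FALSE
  )
}

#' Deterministic worked-example drawing sets
#'
#' Small fixed geometries used throughout the documentation and tests:
#'
#' * `"concentric3"` — three strictly nested squares (sides 60, 40, 20,
#'   centered at (50, 50)) drawn by participants A, B and C (A outermost);
#'   the overlap computation decomposes them into 9 nonoverlapping
#'   rectangles (1 center + 4 per ring) in either layout.
#' * `"nested_single"` — the same squares all drawn by one participant,
#'   which collapse to a single rectangle equal to the outermost square
#'   (this happens when an individual switches pencil-tip size).
#' * `"venn3"` — three mutually overlapping squares from three
#'   participants with a nonempty triple intersection, exercising
#'   proportions 1/3, 2/3 and 3/3.
#' * `"two_square"` — the worked pair (0,0,20,20) by `a` and
#'   (10,10,20,20) by `b`, which decomposes into 5 rectangles
#'   (horizontal layout).
#'
#' @param name fixture name.
#' @return a [drawing_set()].
#' @examples
#' compute_overlap(pain_fixture("two_square"))
#' @export
pain_fixture <- function(name = c("concentric3", "nested_single", "venn3",
                                  "two_square")) {
  name <- match.arg(name)
  rec <- switch(name,
    concentric3 = pain_recordings(
      c("A", "B", "C"), x = c(20, 30, 40), y = c(20, 30, 40),
      width = c(60, 40, 20), height = c(60, 40, 20)),
    nested_single = pain_recordings(
      "A", x = c(20, 30, 40), y = c(20, 30, 40),
      width = c(60, 40, 20), height = c(60, 40, 20)),
    venn3 = pain_recordings(
      c("A", "B", "C"), x = c(0, 20, 10), y = c(0, 10, 20),
      width = 40, height = 40),
    two_square = pain_recordings(
      c("a", "b"), x = c(0, 10), y = c(0, 10), width = 20, height = 20)
  )
  drawing_set(rec)
}
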