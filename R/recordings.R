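#' Construct a table of pain recordings
#'
#' A pain recording is one pencil mark: an axis-aligned rectangle drawn by a
#' participant on the body template. Recordings are kept in an ordinary data
#' frame with columns `participant`, `x`, `y`, `width`, `height`, `region`,
#' `visibility` and `order` (insertion index, used by eraser/duplicate
#' semantics).
#'
#' @param participant character vector of participant identifiers.
#' @param x,y numeric top-left corner, template pixels (y increases
#'   downward).
#' @param width,height numeric, strictly positive.
#' @param region region label on the body template (e.g. `"front"`,
#'   `"back"`); recycled.
#' @param visibility `"visible"` or `"hidden"` (hidden means erased);
#'   recycled.
#' @param order integer insertion index; defaults to row order.
#' @return a `data.frame` of recordings.
#' @examples
#' pain_recordings(c("a", "b"), x = c(0, 10), y = c(0, 10),
#'                 width = 20, height = 20)
#' @export
pain_recordings <- function(participant, x, y, width, height,
                            region = "front", visibility = "visible",
                            order = NULL) {
  n <- max(length(participant), length(x), length(y),
           length(width), length(height))
  rec <- data.frame(
    participant = as.character(rep_len(participant, n)),
    x = as.numeric(rep_len(x, n)), y = as.numeric(rep_len(y, n)),
    width = as.numeric(rep_len(width, n)),
    height = as.numeric(rep_len(height, n)),
    region = as.character(rep_len(region, n)),
    visibility = as.character(rep_len(visibility, n)),
    order = if (is.null(order)) seq_len(n) else as.integer(order),
    stringsAsFactors = FALSE
  )
  validate_recordings(rec)
}

# Coerce + validate a recordings data frame; the single ingest gate for
# geometry: degenerate (zero or negative area) recordings are rejected here.
validate_recordings <- function(rec, require_visibility = FALSE) {
  if (!is.data.frame(rec)) {
    stop("recordings must be a data.frame", call. = FALSE)
  }
  needed <- c("participant", "x", "y", "width", "height")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols) > 0) {
    stop("recordings are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"region" %in% names(rec)) rec$region <- "front"
  if (!"visibility" %in% names(rec)) rec$visibility <- "visible"
  rec$order <- if ("order" %in% names(rec)) as.integer(rec$order)
               else seq_len(nrow(rec))
  rec$participant <- as.character(rec$participant)
  for (col in c("x", "y", "width", "height")) {
    rec[[col]] <- as.numeric(rec[[col]])
    if (anyNA(rec[[col]])) {
      stop("recordings column '", col, "' contains missing values",
           call. = FALSE)
    }
  }
  if (any(rec$width <= 0) || any(rec$height <= 0)) {
    stop("invalid recording: width and height must be strictly positive",
         call. = FALSE)
  }
  if (!all(rec$visibility %in% c("visible", "hidden"))) {
    stop("visibility must be 'visible' or 'hidden'", call. = FALSE)
  }
  rec[c("participant", "x", "y", "width", "height", "region",
        "visibility", "order")]
}

#' Bundle recordings into a drawing set
#'
#' A drawing set holds all visible, unique recordings for one region of the
#' body template together with the total number of drawings T (which may
#' include empty submissions from participants who had no pain to record)
#' and the set of participants with at least one recording. The overlap
#' proportion reported by [compute_overlap()] uses T as its denominator.
#'
#' @param recordings data.frame of recordings (see [pain_recordings()]);
#'   only visible rows are kept.
#' @param total_drawings integer T >= 1; defaults to the number of distinct
#'   participants (i.e. no empty drawings).
#' @param region region label; defaults to the recordings' single region
#'   (an error if mixed and not supplied).
#' @return an object of class `drawing_set` with elements `recordings`,
#'   `total_drawings`, `participants`, `region`.
#' @examples
#' rec <- pain_recordings(c("a", "b"), x = c(0, 10), y = c(0, 10),
#'                        width = 20, height = 20)
#' drawing_set(rec, total_drawings = 3)
#' @export
drawing_set <- function(recordings, total_drawings = NULL, region = NULL) {
  rec <- validate_recordings(recordings)
  rec <- rec[rec$visibility == "visible", , drop = FALSE]
  participants <- sort(unique(rec$participant), method = "radix")
  if (is.null(total_drawings)) total_drawings <- length(participants)
  total_drawings <- as.integer(total_drawings)
  if (is.na(total_drawings) || total_drawings < 1) {
    stop("total_drawings must be a positive integer", call. = FALSE)
  }
  if (length(participants) > total_drawings) {
    stop("total_drawings (", total_drawings, ") is smaller than the number ",
         "of distinct participants (", length(participants), ")",
         call. = FALSE)
  }
  if (is.null(region)) {
    regs <- unique(rec$region)
    if (length(regs) > 1) {
      stop("recordings span several regions (", paste(regs, collapse = ", "),
           "); supply `region` or filter first", call. = FALSE)
    }
    region <- if (length(regs) == 1) regs else "front"
  }
  structure(
    list(recordings = rec, total_drawings = total_drawings,
         participants = participants, region = region),
    class = "drawing_set"
  )
}

#' @export
print.drawing_set <- function(x, ...) {
  cat("Drawing set: region '", x$region, "'\n", sep = "")
  cat("  ", nrow(x$recordings), " visible recordings from ",
      length(x$participants), " participants (T = ", x$total_drawings,
      " drawings)\n", sep = "")
  invisible(x)
}

#' Read and write the recordings CSV schema
#'
#' The input schema has columns `participant,x,y,width,height,region` with
#' an optional `visibility` column (as written by the `extract` stage);
#' UTF-8, `.` decimal separator.
#'
#' @param path file path, or `"-"` for the standard input/output stream.
#' @return `read_recordings_csv()` returns a validated recordings data
#'   frame; `write_recordings_csv()` returns `path` invisibly.
#' @export
read_recordings_csv <- function(path) {
  con <- if (identical(path, "-")) file("stdin") else path
  # everything is read as text so ids like "007" keep their digits; the
  # numeric columns are coerced (and checked) by validate_recordings()
  rec <- utils::read.csv(con, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character")
  validate_recordings(rec)
}

#' @param recordings a recordings data frame.
#' @param visibility whether to include the `visibility` column.
#' @rdname read_recordings_csv
#' @export
write_recordings_csv <- function(recordings, path, visibility = TRUE) {
  rec <- validate_recordings(recordings)
  cols <- c("participant", "x", "y", "width", "height", "region")
  if (visibility) cols <- c(cols, "visibility")
  con <- if (identical(path, "-")) stdout() else path
  utils::write.csv(rec[cols], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
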