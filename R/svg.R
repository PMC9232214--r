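#' Extract pain recordings from an SVG drawing document
#'
#' The drawing tool records each pencil click as an SVG `<rect>` element
#' whose width and height are equal (the pencil tip is square). Only such
#' square rects are pain recordings; rects with differing width and height
#' belong to the template geometry and are skipped. Visibility is read from
#' the `visibility` attribute (`"hidden"` means erased); the region is read
#' from the `data-region` attribute, falling back to `default_region`.
#' Document order is preserved as the insertion index, which the eraser
#' semantics of [dedupe_recordings()] rely on.
#'
#' @param path path to an SVG file, or an `xml2` document.
#' @param participant participant id; defaults to the file name without
#'   extension (the capture tool stores one file per participant).
#' @param default_region region assigned to rects lacking `data-region`.
#' @return a recordings data frame (possibly 0 rows for an empty drawing).
#' @export
parse_svg_drawing <- function(path, participant = NULL,
                              default_region = "front") {
  if (inherits(path, "xml_document")) {
    doc <- path
    if (is.null(participant)) participant <- "drawing"
  } else {
    doc <- xml2::read_xml(path)
    if (is.null(participant)) {
      participant <- tools::file_path_sans_ext(basename(path))
    }
  }
  xml2::xml_ns_strip(doc)
  rects <- xml2::xml_find_all(doc, ".//rect")
  if (length(rects) == 0) {
    return(pain_recordings(character(0), numeric(0), numeric(0),
                           numeric(0), numeric(0)))
  }
  w <- xml2::xml_attr(rects, "width")
  h <- xml2::xml_attr(rects, "height")
  x <- xml2::xml_attr(rects, "x")
  y <- xml2::xml_attr(rects, "y")
  square <- !is.na(w) & !is.na(h) & suppressWarnings(
    as.numeric(w) == as.numeric(h))
  square[is.na(square)] <- FALSE
  if (!any(square)) {
    return(pain_recordings(character(0), numeric(0), numeric(0),
                           numeric(0), numeric(0)))
  }
  idx <- which(square)
  if (any(is.na(x[idx])) || any(is.na(y[idx]))) {
    stop("square <rect> element missing x/y attribute in drawing '",
         participant, "'", call. = FALSE)
  }
  vis <- xml2::xml_attr(rects[idx], "visibility")
  vis[is.na(vis)] <- "visible"
  region <- xml2::xml_attr(rects[idx], "data-region")
  region[is.na(region)] <- default_region
  pain_recordings(
    participant = participant,
    x = as.numeric(x[idx]), y = as.numeric(y[idx]),
    width = as.numeric(w[idx]), height = as.numeric(h[idx]),
    region = region, visibility = vis, order = idx
  )
}

#' Resolve duplicate and erased recordings
#'
#' Scribbling in one spot creates identical recordings (complete overlay:
#' exactly equal participant, x, y, width and height), and the eraser hides
#' a previously inserted recording. Each identical group is reduced to one
#' instance whose visibility is that of the *last* occurrence in insertion
#' order; recordings whose final status is hidden (erased) are excluded.
#' The result contains only visible, unique recordings.
#'
#' @param recordings a recordings data frame carrying insertion `order`.
#' @return the deduplicated recordings, in first-occurrence order.
#' @export
dedupe_recordings <- function(recordings) {
  rec <- validate_recordings(recordings)
  if (nrow(rec) == 0) return(rec)
  key <- paste(rec$participant, rec$x, rec$y, rec$width, rec$height,
               sep = "\r")
  ord <- order(rec$order)
  rec <- rec[ord, , drop = FALSE]
  key <- key[ord]
  last_vis <- tapply(rec$visibility, key, function(v) v[length(v)])
  first <- !duplicated(key)
  out <- rec[first, , drop = FALSE]
  out$visibility <- as.character(last_vis[key[first]])
  out <- out[out$visibility == "visible", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a drawing set from SVG files or a CSV table
#'
#' Builds the [drawing_set()] for one region from per-participant SVG
#' drawing documents, a recordings CSV, or an in-memory recordings data
#' frame. Eraser/duplicate semantics ([dedupe_recordings()]) are applied,
#' so the set holds only visible, unique recordings. Empty drawings
#' (documents with no square rect, or participants with no surviving
#' recording) contribute to the total drawing count T iff `include_empty`.
#'
#' @param x character vector of SVG file paths, a single CSV path, or a
#'   recordings data frame.
#' @param region_filter keep only recordings with this region label
#'   (`NULL` keeps all; the set's region is then the recordings' region).
#' @param include_empty count empty drawings in `total_drawings`.
#' @param default_region region for SVG rects lacking `data-region`.
#' @param total_drawings explicit T, overriding the count derived from the
#'   input (needed for CSV input when empty drawings are not representable
#'   as rows).
#' @return a [drawing_set()].
#' @export
load_drawing_set <- function(x, region_filter = NULL, include_empty = TRUE,
                             default_region = "front",
                             total_drawings = NULL) {
  if (is.data.frame(x)) {
    rec <- validate_recordings(x)
    n_drawings <- length(unique(rec$participant))
  } else if (is.character(x) && length(x) == 1 &&
             grepl("\\.csv$", x, ignore.case = TRUE) || identical(x, "-")) {
    rec <- read_recordings_csv(x)
    n_drawings <- length(unique(rec$participant))
  } else if (is.character(x)) {
    per_file <- lapply(x, parse_svg_drawing, default_region = default_region)
    empty <- vapply(per_file, function(d) nrow(d) == 0, TRUE)
    rec <- do.call(rbind, per_file)
    rec$order <- seq_len(nrow(rec))
    n_drawings <- if (include_empty) length(x) else sum(!empty)
  } else {
    stop("x must be SVG paths, a CSV path, or a recordings data frame",
         call. = FALSE)
  }
  rec <- dedupe_recordings(rec)
  region <- NULL
  if (!is.null(region_filter)) {
    rec <- rec[rec$region %in% region_filter, , drop = FALSE]
    region <- region_filter
  } else if (nrow(rec) > 0 && length(unique(rec$region)) > 1) {
    region <- "all"
  }
  if (is.null(total_drawings)) total_drawings <- max(n_drawings, 1L)
  drawing_set(rec, total_drawings = total_drawings, region = region)
}
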