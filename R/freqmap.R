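#' Pain frequency map objects
#'
#' A `pain_freqmap` is the result of [compute_overlap()]: a collection of
#' pairwise disjoint rectangles for one body region, each carrying the set
#' of participants whose drawings cover it (serialized as participant ids
#' sorted lexicographically and joined with `";"`), the overlap frequency
#' and the overlap proportion. `max_frequency` is the largest frequency in
#' the map (`NA` for an empty map).
#'
#' @param rects data.frame with columns `x`, `y`, `width`, `height`,
#'   `area`, `overlap`, `overlap_frequency`, `overlap_proportion`.
#' @param region region label.
#' @param total_drawings total number of drawings T.
#' @param layout `"horizontal"` or `"vertical"`.
#' @param denominator `"drawings"` or `"participants"`.
#' @param denom the numeric denominator actually used for proportions.
#' @return an object of class `pain_freqmap`.
#' @name pain_freqmap
#' @keywords internal
new_pain_freqmap <- function(rects, region, total_drawings, layout,
                             denominator = "drawings",
                             denom = total_drawings) {
  structure(
    list(rects = rects, region = region,
         total_drawings = as.integer(total_drawings),
         layout = layout, denominator = denominator,
         denom = as.integer(denom),
         max_frequency = if (nrow(rects) > 0)
           max(rects$overlap_frequency) else NA_integer_),
    class = "pain_freqmap"
  )
}

#' @export
print.pain_freqmap <- function(x, ...) {
  cat("Pain frequency map: region '", x$region, "', ", x$layout,
      " layout\n", sep = "")
  cat("  ", nrow(x$rects), " nonoverlapping rectangles",
      if (nrow(x$rects) > 0)
        paste0(", overlap frequency ", min(x$rects$overlap_frequency),
               "-", x$max_frequency),
      "\n", sep = "")
  cat("  T = ", x$total_drawings, " drawings (proportion denominator ",
      x$denom, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.pain_freqmap <- function(object, ...) {
  r <- object$rects
  freq_tab <- if (nrow(r) > 0) table(r$overlap_frequency) else table(integer(0))
  area_tab <- if (nrow(r) > 0)
    tapply(r$area, r$overlap_frequency, sum) else numeric(0)
  out <- list(region = object$region, layout = object$layout,
              n_rects = nrow(r), total_drawings = object$total_drawings,
              max_frequency = object$max_frequency,
              rects_by_frequency = freq_tab,
              area_by_frequency = area_tab,
              total_area = sum(r$area))
  class(out) <- "summary.pain_freqmap"
  out
}

#' @export
print.summary.pain_freqmap <- function(x, ...) {
  cat("Pain frequency map summary (region '", x$region, "', ", x$layout,
      " layout)\n", sep = "")
  cat("  rectangles:", x$n_rects, " total area:", x$total_area, "\n")
  cat("  drawings T:", x$total_drawings,
      " max overlap frequency:", x$max_frequency, "\n")
  if (x$n_rects > 0) {
    cat("  rectangles per overlap frequency:\n")
    print(x$rects_by_frequency)
  }
  invisible(x)
}

#' @export
as.data.frame.pain_freqmap <- function(x, ...) {
  x$rects
}

#' Plot a pain frequency map with base graphics
#'
#' Draws the nonoverlapping rectangles shaded by overlap frequency (the same
#' opacity coding used by the SVG renderer); darker/denser color means more
#' participants drew pain at that location. The y axis is flipped so the
#' template's downward y matches screen orientation.
#'
#' @param x a [pain_freqmap].
#' @param color fill color (default `"#ff0000"`).
#' @param border rectangle border color, `NA` for none.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pain_freqmap <- function(x, color = "#ff0000", border = NA, ...) {
  r <- x$rects
  if (nrow(r) == 0) {
    graphics::plot(0, 0, type = "n", xlab = "x", ylab = "y",
                   main = "pain frequency map (empty)", ...)
    return(invisible(x))
  }
  xr <- range(c(r$x, r$x + r$width))
  yr <- range(c(r$y, r$y + r$height))
  graphics::plot(NA, xlim = xr, ylim = rev(yr), xlab = "x", ylab = "y",
                 asp = 1, main = paste0("pain frequency map (", x$region,
                                        ")"), ...)
  alpha <- heat_opacity(r$overlap_frequency, x$max_frequency)
  fill <- grDevices::adjustcolor(color, alpha.f = 1)
  cols <- vapply(alpha, function(a) grDevices::adjustcolor(fill, alpha.f = a),
                 "")
  graphics::rect(r$x, r$y + r$height, r$x + r$width, r$y,
                 col = cols, border = border)
  invisible(x)
}

#' Read and write the frequency-map CSV schema
#'
#' The output schema has columns
#' `x,y,width,height,area,overlap,overlap_frequency,overlap_proportion`
#' plus an optional trailing `region` column; overlap sets are participant
#' ids sorted lexicographically, joined with `";"`; proportions are printed
#' with 4 decimals.
#'
#' @param fm a [pain_freqmap].
#' @param path file path, or `"-"` for the standard output/input stream.
#' @param region whether to append the `region` column.
#' @return `write_freqmap_csv()` returns `path` invisibly;
#'   `read_freqmap_csv()` returns a [pain_freqmap] (`total_drawings`
#'   inferred from frequency/proportion pairs unless supplied).
#' @export
write_freqmap_csv <- function(fm, path, region = FALSE) {
  stopifnot(inherits(fm, "pain_freqmap"))
  r <- fm$rects
  out <- data.frame(
    x = r$x, y = r$y, width = r$width, height = r$height, area = r$area,
    overlap = r$overlap, overlap_frequency = r$overlap_frequency,
    overlap_proportion = sprintf("%.4f", r$overlap_proportion),
    stringsAsFactors = FALSE
  )
  if (region) out$region <- rep_len(fm$region, nrow(out))
  con <- if (identical(path, "-")) stdout() else path
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param total_drawings denominator T; if `NULL`, inferred as
#'   `round(frequency / proportion)` from the rows (1 for an empty map).
#' @param layout,region_label metadata to attach to the reconstructed map.
#' @rdname write_freqmap_csv
#' @export
read_freqmap_csv <- function(path, total_drawings = NULL,
                             layout = "horizontal", region_label = NULL) {
  con <- if (identical(path, "-")) file("stdin") else path
  r <- utils::read.csv(con, stringsAsFactors = FALSE,
                       colClasses = c(overlap = "character"))
  needed <- c("x", "y", "width", "height", "area", "overlap",
              "overlap_frequency", "overlap_proportion")
  missing_cols <- setdiff(needed, names(r))
  if (length(missing_cols) > 0) {
    stop("frequency-map CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("x", "y", "width", "height", "area",
                "overlap_proportion")) {
    r[[col]] <- as.numeric(r[[col]])
  }
  r$overlap_frequency <- as.integer(r$overlap_frequency)
  region <- if (!is.null(region_label)) region_label
            else if ("region" %in% names(r) && nrow(r) > 0) r$region[1]
            else "front"
  if (is.null(total_drawings)) {
    total_drawings <- if (nrow(r) > 0)
      max(round(r$overlap_frequency / r$overlap_proportion)) else 1L
  }
  new_pain_freqmap(r[needed], region = region,
                   total_drawings = total_drawings, layout = layout)
}
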