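#' Opacity coding for the pain frequency map
#'
#' The shade of an output rectangle encodes its overlap frequency through
#' the SVG `opacity` attribute, which must be strictly between 0 and 1.
#' The map `opacity = frequency / (max_frequency + 1)` is strictly
#' increasing in frequency and stays inside the open interval (0, 1) for
#' every valid frequency, so rectangles drawn by more participants are
#' always visibly denser and none is fully transparent or fully opaque.
#'
#' @param frequency integer overlap frequency, `1 <= frequency <=
#'   max_frequency` (vectorized).
#' @param max_frequency the map's maximum overlap frequency.
#' @return opacities in (0, 1).
#' @examples
#' heat_opacity(3, 3)  # 0.75
#' heat_opacity(1, 1)  # 0.5
#' @export
heat_opacity <- function(frequency, max_frequency) {
  if (length(max_frequency) != 1 || is.na(max_frequency) ||
      max_frequency < 1) {
    stop("max_frequency must be a single integer >= 1", call. = FALSE)
  }
  if (any(frequency < 1) || any(frequency > max_frequency)) {
    stop("frequency must lie in [1, max_frequency]", call. = FALSE)
  }
  frequency / (max_frequency + 1)
}

#' Rendering configuration
#'
#' @param color heat color, a CSS color name or `#rrggbb` hex code
#'   (default `#ff0000`, red).
#' @param mask optional data.frame of region outlines (columns `x`, `y`,
#'   `width`, `height`) used as an SVG clip path so rectangles overflowing
#'   the region are hidden; `NULL` (default) renders unclipped.
#' @return a list of class `render_config`.
#' @export
render_config <- function(color = "#ff0000", mask = NULL) {
  is_hex <- grepl("^#[0-9a-fA-F]{6}$", color)
  is_name <- color %in% grDevices::colors()
  if (length(color) != 1 || (!is_hex && !is_name)) {
    stop("color must be a CSS color name or a #rrggbb hex code",
         call. = FALSE)
  }
  if (!is.null(mask)) {
    stopifnot(is.data.frame(mask),
              all(c("x", "y", "width", "height") %in% names(mask)))
  }
  structure(list(color = color, mask = mask), class = "render_config")
}

#' Render a frequency map onto a body-template SVG
#'
#' Adds one `<rect>` element per output rectangle to the template, filled
#' with the configured color at an opacity encoding its overlap frequency
#' (see [heat_opacity()]). Untouched template areas remain blank. When the
#' configuration carries region mask shapes, the heat rectangles are
#' clipped to them so parts overflowing the region outline are hidden.
#'
#' @param fm a [pain_freqmap].
#' @param template path to the body-template SVG, or an `xml2` document;
#'   the default is the synthetic body outline shipped with the package.
#' @param config a [render_config()].
#' @return the rendered SVG as an `xml2` document.
#' @export
render_svg <- function(fm, template = NULL, config = render_config()) {
  stopifnot(inherits(fm, "pain_freqmap"), inherits(config, "render_config"))
  if (is.null(template)) {
    template <- system.file("extdata", "body_template_synthetic.svg",
                            package = "painmap")
  }
  doc <- if (inherits(template, "xml_document")) template
         else xml2::read_xml(template)
  root <- xml2::xml_root(doc)
  grp <- xml2::xml_add_child(root, "g", id = "painmap-heatmap")
  if (!is.null(config$mask)) {
    defs <- xml2::xml_add_child(root, "defs")
    clip <- xml2::xml_add_child(defs, "clipPath", id = "painmap-mask")
    for (k in seq_len(nrow(config$mask))) {
      xml2::xml_add_child(clip, "rect",
                          x = as.character(config$mask$x[k]),
                          y = as.character(config$mask$y[k]),
                          width = as.character(config$mask$width[k]),
                          height = as.character(config$mask$height[k]))
    }
    xml2::xml_set_attr(grp, "clip-path", "url(#painmap-mask)")
  }
  r <- fm$rects
  if (nrow(r) > 0) {
    alpha <- heat_opacity(r$overlap_frequency, fm$max_frequency)
    for (k in seq_len(nrow(r))) {
      xml2::xml_add_child(grp, "rect",
                          x = as.character(r$x[k]),
                          y = as.character(r$y[k]),
                          width = as.character(r$width[k]),
                          height = as.character(r$height[k]),
                          fill = config$color,
                          opacity = as.character(alpha[k]),
                          `data-frequency` = as.character(
                            r$overlap_frequency[k]),
                          `data-proportion` = sprintf(
                            "%.6f", r$overlap_proportion[k]))
    }
  }
  doc
}

#' Wrap a rendered frequency map in a standalone HTML page
#'
#' Produces a self-contained HTML5 document embedding the rendered SVG and
#' a threshold slider: sliding the control hides rectangles whose overlap
#' proportion exceeds the chosen cutoff (rectangles with proportion less
#' than or equal to the cutoff stay visible). At the maximum position every
#' rectangle is visible.
#'
#' @param svg a rendered SVG document from [render_svg()].
#' @param fm the [pain_freqmap] that was rendered.
#' @param title page title.
#' @return the HTML document as a single character string.
#' @export
render_html <- function(svg, fm, title = "Pain frequency map") {
  stopifnot(inherits(fm, "pain_freqmap"))
  svg_txt <- as.character(svg)
  svg_txt <- sub("^<\\?xml[^>]*\\?>\\s*", "", svg_txt)
  props <- sort(unique(fm$rects$overlap_proportion))
  step <- if (fm$denom > 0) 1 / fm$denom else 1
  maxv <- if (length(props) > 0) max(props) else 1
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>", title, "</title>\n</head>\n<body>\n",
    "<h1>", title, "</h1>\n",
    "<p>Region: ", fm$region, " &mdash; ", nrow(fm$rects),
    " nonoverlapping rectangles, T = ", fm$total_drawings,
    " drawings.</p>\n",
    "<label>Overlap proportion threshold (&le;): ",
    "<input type=\"range\" id=\"painmap-threshold\" min=\"0\" max=\"",
    sprintf("%.6f", maxv), "\" step=\"", sprintf("%.6f", step),
    "\" value=\"", sprintf("%.6f", maxv), "\"/>",
    " <span id=\"painmap-threshold-value\">", sprintf("%.4f", maxv),
    "</span></label>\n",
    "<div id=\"painmap-svg\">\n", svg_txt, "\n</div>\n",
    "<script>\n",
    "var slider = document.getElementById('painmap-threshold');\n",
    "var label = document.getElementById('painmap-threshold-value');\n",
    "function painmapApply() {\n",
    "  var v = parseFloat(slider.value);\n",
    "  label.textContent = v.toFixed(4);\n",
    "  var rects = document.querySelectorAll(",
    "'#painmap-heatmap rect[data-proportion]');\n",
    "  rects.forEach(function (r) {\n",
    "    var p = parseFloat(r.getAttribute('data-proportion'));\n",
    "    r.style.display = (p <= v + 1e-9) ? '' : 'none';\n",
    "  });\n",
    "}\n",
    "if (slider) { slider.addEventListener('input', painmapApply); ",
    "painmapApply(); }\n",
    "</script>\n</body>\n</html>\n"
  )
}
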