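test_that("opacity coding is strictly monotone inside (0, 1)", {
  expect_identical(heat_opacity(3, 3), 0.75)
  expect_identical(heat_opacity(1, 1), 0.5)
  for (fmax in c(1, 2, 5, 21)) {
    o <- heat_opacity(seq_len(fmax), fmax)
    expect_true(all(o > 0 & o < 1))
    expect_true(all(diff(o) > 0))
  }
  expect_error(heat_opacity(0, 3), "frequency")
  expect_error(heat_opacity(4, 3), "frequency")
})

test_that("render configuration validates colors and masks", {
  expect_identical(render_config()$color, "#ff0000")
  expect_identical(render_config("tomato")$color, "tomato")
  expect_error(render_config("#ff00"), "color")
  expect_error(render_config("notacolor"), "color")
})

test_that("rendered SVG carries one faithful rect per output rectangle", {
  fm <- compute_overlap(pain_fixture("concentric3"))
  svg <- render_svg(fm)
  added <- xml2::xml_find_all(svg, "//g[@id='painmap-heatmap']/rect")
  expect_length(added, 9)
  expect_identical(unique(xml2::xml_attr(added, "fill")), "#ff0000")
  expect_length(unique(xml2::xml_attr(added, "opacity")), 3)

  # geometry fidelity: attributes equal the fields as decimal strings
  expect_identical(xml2::xml_attr(added, "x"), as.character(fm$rects$x))
  expect_identical(xml2::xml_attr(added, "y"), as.character(fm$rects$y))
  expect_identical(xml2::xml_attr(added, "width"),
                   as.character(fm$rects$width))
  expect_identical(xml2::xml_attr(added, "height"),
                   as.character(fm$rects$height))

  # the template outline is untouched (template nodes live in the SVG
  # namespace, the heat layer is appended alongside them)
  expect_length(xml2::xml_find_all(
    svg, "//*[local-name()='g'][@id='body-template']"), 1)

  # empty map: template plus an empty heat group
  none <- compute_overlap(drawing_set(
    pain_recordings(character(0), numeric(0), numeric(0), numeric(0),
                    numeric(0)), total_drawings = 1))
  svg0 <- render_svg(none)
  expect_length(xml2::xml_find_all(svg0, "//g[@id='painmap-heatmap']/rect"),
                0)
})

test_that("region masks clip the heat layer when configured", {
  fm <- compute_overlap(pain_fixture("two_square"))
  cfg <- render_config(mask = data.frame(x = 0, y = 0, width = 15,
                                         height = 30))
  svg <- render_svg(fm, config = cfg)
  grp <- xml2::xml_find_first(svg, "//g[@id='painmap-heatmap']")
  expect_identical(xml2::xml_attr(grp, "clip-path"), "url(#painmap-mask)")
  expect_length(xml2::xml_find_all(svg, "//clipPath/rect"), 1)
})

test_that("the HTML wrapper embeds the SVG and a threshold slider", {
  fm <- compute_overlap(pain_fixture("venn3"))
  html <- render_html(render_svg(fm), fm)
  expect_match(html, "<!DOCTYPE html>", fixed = TRUE)
  expect_match(html, "id=\"painmap-threshold\"", fixed = TRUE)
  expect_identical(lengths(regmatches(html, gregexpr("data-proportion",
                                                     html))),
                   nrow(fm$rects) + 2L)      # rects + 2 JS references
  # slider covers the proportions; cutoff comparison is <=
  expect_match(html, "p <= v", fixed = TRUE)
  expect_match(html, sprintf("value=\"%.6f\"", max(fm$rects$overlap_proportion)),
               fixed = TRUE)

  none <- compute_overlap(drawing_set(
    pain_recordings(character(0), numeric(0), numeric(0), numeric(0),
                    numeric(0)), total_drawings = 1))
  html0 <- render_html(render_svg(none), none)
  expect_match(html0, "</html>", fixed = TRUE)
})
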