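# painmap

Pain frequency maps from grid-free freehand pain drawings.

## The problem

Clinicians and researchers record where people hurt by letting them draw
freehand on a 2D body template (a manikin). On *grid-free* templates — no
predefined cells, no anatomical parcellation — every pencil click lands at an
arbitrary coordinate, which makes drawings unbiased and paper-like but leaves
no obvious way to count, across participants, how often each body location
was drawn. painmap solves exactly that: given any number of drawings captured
as overlapping axis-aligned squares (SVG `<rect>` elements with equal width
and height — the pencil tip is square, and the intersection of two rectangles
is always a rectangle), it produces a set of **nonoverlapping rectangles**,
each a unique body location annotated with how many participants drew there,
and renders the result as a **pain frequency map**.

## The algorithm

Let T be the total number of drawings (empty submissions included), P the set
of participants with at least one recording, and R the set of visible, unique
rectangles, each with attributes (x, y, w, h) and an owning participant
(a surjection from rectangles to participants). The overlap computation runs
in four stages:

1. **Decomposition** — collect every rectangle's edge coordinates
   {x, x + w} and {y, y + h} along each axis.
2. **Partitions** — sorted distinct edges become half-open interval windows
   `[b_i, b_i+1)`; rectangle footprints are half-open boxes
   `[x, x + w) × [y, y + h)`, so abutting marks neither overlap nor gap.
3. **Overlap sets** — crossing the x- and y-windows yields grid cells; each
   cell is labeled with its overlap set o ∈ O: the set of *distinct*
   participants covering it (drawing twice in one spot counts once).
4. **Maximal merging** — adjoining cells with identical overlap sets are
   merged in two passes (maximal runs along the layout axis, then chains of
   equal-extent neighbors across it), giving rectangles as wide
   (*horizontal* layout) or as long (*vertical* layout) as possible.

Each output rectangle carries its overlap frequency |o| and overlap
proportion |o| / T, and the map colors it with opacity |o| / (max|o| + 1),
strictly inside (0, 1).

## Worked example

Three strictly nested squares (sides 60, 40, 20, centered at (50, 50)) drawn
by participants A, B and C:

```r
library(painmap)
ds <- pain_fixture("concentric3")
fm <- compute_overlap(ds)
fm
#> Pain frequency map: region 'front', horizontal layout
#>   9 nonoverlapping rectangles, overlap frequency 1-3
#>   T = 3 drawings (proportion denominator 3)
as.data.frame(fm)
#>    x  y width height area overlap overlap_frequency overlap_proportion
#> 1 20 20    60     10  600       A                 1          0.3333333
#> 2 20 30    10     40  400       A                 1          0.3333333
#> 3 30 30    40     10  400     A;B                 2          0.6666667
#> 4 70 30    10     40  400       A                 1          0.3333333
#> 5 30 40    10     20  200     A;B                 2          0.6666667
#> 6 40 40    20     20  400   A;B;C                 3          1.0000000
#> 7 60 40    10     20  200     A;B                 2          0.6666667
#> 8 30 60    40     10  400     A;B                 2          0.6666667
#> 9 20 70    60     10  600       A                 1          0.3333333
```

The nested input decomposes into 9 disjoint rectangles: the center square
covered by all three participants (proportion 3/3), four rectangles per ring
(proportions 2/3 and 1/3). Had one participant drawn all three squares, the
output would collapse to a single rectangle equal to the outermost square.
`render_svg(fm)` places these rectangles on a body-template SVG with
opacities 0.25 / 0.5 / 0.75, and `render_html()` wraps the map with a
proportion-threshold slider.

The same pipeline runs from a shell, chainable through pipes:

```sh
painmap simulate --n 1000 --seed 7 \
  | painmap overlap --layout horizontal \
  | painmap heatmap -o map.html
```

(`painmap` is the installed `exec/painmap` script.)

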