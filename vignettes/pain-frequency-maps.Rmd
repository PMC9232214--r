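---
title: "Quantifying grid-free pain drawings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying grid-free pain drawings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmap)
```

## The measurement model

A freehand pain drawing on a grid-free 2D body template is a set of
overlapping axis-aligned squares: each pencil click inserts one square
(an SVG `<rect>` with equal `width` and `height`) at an arbitrary pixel
coordinate. Square tips are essential — the intersection of two axis-aligned
rectangles is again an axis-aligned rectangle, which is what lets the whole
analysis stay in rectangle space rather than pixel space.

The quantity of interest is spatial: for every location on the template, how
many distinct participants drew pain there. painmap computes this exactly,
with no rasterization, by decomposing the union of all rectangles into
**nonoverlapping rectangles of constant overlap set**. The overlap set *o*
of a location is the set of distinct participants covering it;
`overlap_frequency` is |o| and `overlap_proportion` is |o| / T where T is
the total number of drawings.

Assumptions the model makes:

* recordings are axis-aligned rectangles with strictly positive width and
  height (zero-area recordings are rejected at ingest);
* participant identity is what matters — a participant scribbling
  repeatedly over one spot contributes once to that spot's overlap set;
* regions of the template ("front", "back", ...) are analyzed
  independently, and a recording's region label is authoritative — no
  geometric inference is attempted.

## The decomposition, step by step

1. `rect_boundaries()` collects each rectangle's edge coordinates along one
   axis; the sorted distinct union defines that axis's partition.
2. `rect_partitions()` turns n distinct edges into n − 1 half-open interval
   windows `[b_i, b_{i+1})`. Footprints are half-open boxes
   `[x, x + w) × [y, y + h)`: abutting rectangles neither overlap nor leave
   gaps, and every coordinate stays a real number — nothing is rounded.
3. `overlap_grid()` crosses the two partitions into grid cells and labels
   each with its overlap set. Cost is the total number of
   (rectangle, cell) incidences; this inner loop is the one piece of
   compiled code in the package (an Rcpp kernel), because it is executed
   around 10^8 times at the benchmark workloads below.
4. `merge_cells()` merges adjoining cells with identical overlap sets into
   maximal rectangles (next section).

`compute_overlap()` chains the four stages and returns a classed
`pain_freqmap` with `print`, `summary`, `plot` and `as.data.frame` methods.

## Merge rules (an open design point)

Many equivalent-area decompositions exist; the package commits to a two-pass
scheme per layout:

* **Pass 1** — within each cross-axis band (one interval window wide), merge
  maximal runs of adjacent cells with identical overlap sets along the
  layout axis. `rle()` semantics make these runs maximal by construction.
* **Pass 2** — merge results that have identical overlap sets, identical
  layout-axis extent, and abut on the cross axis, repeating to fixpoint.
  Because such merges form chains along one axis, the relation is confluent
  and a single sorted sweep reaches the fixpoint; the output is independent
  of input order.

This is the simplest scheme that reproduces the canonical nested-squares
behavior: three strictly concentric squares from three participants yield
exactly 9 rectangles (1 center + 4 per ring) in *both* layouts, and the same
squares from a single participant collapse to exactly 1 rectangle. The
`horizontal` layout produces rectangles as wide as possible (suited to wide
regions such as the abdomen), `vertical` as long as possible (suited to the
legs). Whether the original analysis also re-merged along the layout axis
after pass 2 is unknowable from the published description; our fixpoint
choice is conservative in that per-overlap-set areas are provably identical
across layouts (a tested invariant), only rectangle counts may differ.

Note the output is *maximal under these two merge rules*, not a
minimum-cardinality rectangle partition — no optimality is claimed.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `layout` | `compute_overlap()` | `"horizontal"` | wider rectangles; purely presentational, areas invariant |
| `denominator` | `compute_overlap()` | `"drawings"` (T) | proportions count empty submissions, so a location drawn by 1 of 3 enrollees scores 1/3 even if two submitted blank templates; `"participants"` gives the \|o\|/\|P\| reading |
| `min_freq`/`max_freq`, `min_width`/`min_height` | `filter_map()` | 1/Inf, 0/0 | inclusive bounds on frequency and size; proportions keep denominator T |
| `color` | `render_config()` | `#ff0000` | CSS name or hex; red is the conventional heat color |
| opacity | `heat_opacity()` | f / (F_max + 1) | strictly increasing, strictly inside (0, 1) for every valid frequency; the published expression is not recoverable, so this monotone form is the package's own choice |

## Eraser and duplicate semantics

The capture tool's eraser *hides* a previously inserted rect rather than
deleting it, and scribbling yields exactly identical rects (complete
overlay). `dedupe_recordings()` therefore groups recordings by exact
(participant, x, y, width, height) equality — no tolerance — and keeps one
instance per group whose visibility is the **last** occurrence's; a final
status of hidden means erased and the recording is dropped. Identical
geometry from *different* participants is kept: deduplication is
per participant.

## The null-drawing mask

The decomposition knows nothing about region outlines, so output rectangles
can overflow the template borders when people draw near them. For frequency
maps this is cosmetic (the SVG renderer can clip to region outlines via
`render_config(mask = ...)`). For analyses that need strictly within-region
output, `apply_null_mask()` implements the null-drawing approach: add a
synthetic drawing that tiles the template exactly, recompute, then keep only
rectangles common to the null drawing and at least one actual drawing. The
null participant is removed from each surviving overlap set, frequencies are
decremented and proportions recomputed excluding the null drawing. The same
trick makes undrawn within-template locations representable. The null
drawing is template-specific and reusable across datasets captured on the
same template.

## The simulation module

`simulate_single_click()` and `simulate_participants()` generate the two
benchmark regimes on a 1000×1000 plane with origin (0, 0): integer origins
sampled *without* replacement from the plane's ordered pairs, and dimensions
sampled *with* replacement from {10, 20, ..., 100}; rectangles may extend
past the right/bottom edge and are recorded as drawn. The single-click
regime gives every participant exactly one rectangle; the participant regime
gives each participant 100 clicks by default. Origin uniqueness in the
participant regime is dataset-wide by default, with
`origin_unique = "participant"` for the per-participant reading — the
published description is ambiguous between the two. Seeds are caller-chosen;
identical seeds reproduce identical rows byte for byte.

What the simulations emulate is *load*, not anatomy: uniformly scattered
squares have no body-shaped spatial structure, no regions, no erasures and
no duplicates. Passing tests on simulated data therefore demonstrate
geometric correctness and scaling, not clinical validity of any particular
map.

## Validation strategy and problem sizes

The decomposition is validated against an independent brute-force oracle,
`rasterize_oracle()`, which computes per-pixel participant sets directly.
The test suite checks, on 200 random integer-coordinate drawing sets (up to
10 participants, up to 100 rectangles on a `[0, 200)²` plane):

* per-pixel set equality between the oracle and the containing output
  rectangle;
* pairwise disjointness and exact conservation of the union area;
* merge maximality (no two same-set rectangles remain mergeable under
  either rule);
* layout invariance of per-overlap-set areas, and permutation invariance
  under input row shuffling.

Exactness is meaningful here: on integer instances every comparison is an
integer comparison, so the tests assert equality, not approximate equality.
With real coordinates the same arithmetic applies (edges are reproduced by
the identical floating-point expression on both sides of `findInterval`),
so no epsilon is needed anywhere in the pipeline.

Scaling is checked on single-click workloads of 10,000 / 20,000 / 40,000
rectangles — sizes chosen so the full suite completes comfortably on one
CPU while still spanning a 4× range; the assertion is a ratio bound (time at
4× input must stay far below the quadratic factor), never a wall-clock
target, since absolute timings are hardware-dependent.

## Known limitations

* Rectangle counts (not areas) depend on the layout and on the merge-rule
  choice; comparisons across tools should use per-overlap-set areas.
* The pipeline is 2D and rectangle-native: circular or polygonal pencil
  tips, and 3D manikins, are out of scope.
* Without a null drawing the output covers only drawn locations; inferential
  statistics over the whole template require the mask workflow above.
* CSV input cannot represent empty drawings as rows; supply
  `total_drawings` explicitly when empty submissions should inflate T.
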