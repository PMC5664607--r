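---
title: "Methods: site suitability, buffer scenarios and availability accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site suitability, buffer scenarios and availability accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvcapacity)
```

## The question and the modeling chain

US consumers fall short of recommended fruit and vegetable (F&V) intakes.
If demand rose, domestic production would have to expand, and because F&V
supply chains co-locate with existing areas of concentrated production, the
most plausible place for expansion is *in and around current production
centers*. This package estimates that capacity for a set of nutrient-dense
crops by chaining five stages:

1. **Crop screening** — nutrient-density scoring plus consumption and
   production trend filters;
2. **Production centers** — counties holding ≥ 10% of mean national
   harvested acreage, with abutting eligible counties merged;
3. **Site suitability** — a strictly boolean overlay of monthly climate,
   soil and land-use conditions on a common raster grid;
4. **Expansion scenarios** — Euclidean dilation of center footprints by
   0/5/10/15/20 km;
5. **Availability** — suitable area × yield, adjusted down a farm → retail
   → consumer loss chain, converted to cup-equivalents and divided over the
   population.

Each stage is an exported function group; `run_pipeline()` binds them.

## The suitability model and its assumptions

The overlay is deliberately boolean, not a weighted score: a cell is
suitable for a crop iff *every* active condition holds. Comparisons against
bounds are inclusive (`low ≤ x ≤ high`) because bounds derived from a
zone's observed extrema must leave the zone itself suitable. Nodata in any
active layer fails the cell — a conservative choice consistent with
requiring all conditions to be demonstrably satisfied. Each call logs a
*filter cascade*, the surviving cell count after each condition, so users
can audit which constraint binds.

Two provenances of bounds coexist. Published growing requirements are
passed directly into `crop_requirement()`. Where data resolution cannot
support a published value, `derive_bounds()` adopts the zonal min/max of
the variable over the crop's production center, or — where high-resolution
crop-specific land cover is available — over the connected clusters in
which at least 95% of the crop is cultivated (`crop_clusters()`, largest
clusters first, ties broken in scan order). The choice is per crop and per
variable; the default is published-where-supplied, derived otherwise.
Because a production center trivially satisfies its own derived bounds,
derived-only models measure *land-use and soil* constraints inside the
center and *climate similarity* outside it — which is exactly the intended
reading of "expand near where the crop already grows".

Precipitation is the only water-supply test; irrigation is not modeled
(data availability), which makes suitable-area estimates conservative for
irrigated regions. Only crop-relevant conditions enter a crop's model: the
canonical example is an indoor-grown crop (Agaricus mushrooms) whose model
reduces to fallow land use inside the region, since climate and soil do not
bind in climate-controlled production.

## Geometry conventions

Grids are planar projected meters, row-major, origin at the upper-left
outer corner, square cells; all layers in one analysis must be
pre-aligned (shape, cell size, origin) — reprojection is an I/O concern and
out of scope. Areas are exact cell counts × cell area (0.09 ha at 30 m);
no sub-cell integration.

Buffer expansion is morphological dilation under *cell-center* semantics: a
cell joins the region when its center lies within the buffer distance of
some center-cell's center. The alternative (any-overlap) differs by at most
half a cell diagonal — sub-cell at 30–150 m cells against 5–20 km buffers.
Dilation is implemented through an exact two-pass squared Euclidean
distance transform (per-column 1-D distances, then a lower envelope of
parabolas along rows), so buffers are exact circles in the discrete metric,
not iterated box approximations; the distance map is computed once per
center and thresholded per buffer. Buffers are not clipped at
administrative borders or coastlines by default (an optional clip mask
exists): the analysis regions are geometric neighborhoods, and the land-use
condition already excludes non-agricultural cells. County adjacency
("abutting") is rook contiguity — shared edge, not corner — matching the
common GIS contiguity reading; it can also be supplied as an explicit pair
list. When one crop has several centers whose expanded regions overlap,
cells claimed by a higher-share center are not counted again for a later
one, so crop totals never double count.

## Availability accounting

Loss-adjusted availability collapses the multi-stage federal accounting
(primary-to-retail conversion, nonedible share, retail and consumer loss)
into three multiplicative fractions plus one `cups_per_kg` factor per crop;
the structure is fixed, the factors are inputs. Each center uses its own
state's yield; a 365-day year is used (leap handling is immaterial at the
reported precision). Report tables are built at full precision — the Total
row is always the exact column sum — and rounded only for presentation
(areas to 0.1 × 10³ ha, availability to 0.1 × 10⁻³ cups, the printed
units). `percent_increase()` and `omit_crop_sensitivity()` operate on these
tables; the shipped published tables (`published_tables()`) are *inputs*
for consistency checking, not outputs of the package. One shipped value is
recorded as missing: the current per-capita availability of lima beans is
printed only as "< 0.02" in the source table and is stored as `NA`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| share threshold | 0.10 | fraction of mean national acreage | eligibility for production-center status |
| year range | 2002–2012 | years | acreage averaging window |
| buffers | 0, 5, 10, 15, 20 | km | the five expansion scenarios |
| cluster coverage | 0.95 | fraction of crop cells | clusters used for derived bounds |
| score refs | 28 g, 1300 mg, 420 mg, 4700 mg | fiber/Ca/Mg/K daily | current FDA Daily Values; fully overridable |
| score cutoff | top decile | — | the screen's "nutrient dense" line is not externally fixed; an absolute cutoff can be passed |
| trend window | 5 | years | "most recent five-year period", read as the last 5 calendar years present |
| loss fractions, cups/kg | per crop | [0,1), cups/kg | inputs, not constants |

Screening defaults that were genuinely open were fixed once: the score
aggregator is the *sum* of percent-of-reference contributions (a mean and a
custom nutrient set are available), and "most recent five year period"
means the last five calendar years present in each series.

## The synthetic-data generator

`gen_truth_case()` produces a complete input bundle *plus* its expected
outputs computed in closed form from the construction, never by running the
pipeline:

- **Counties**: a 3 × 3 tiling; the west-center tile holds a 55% share of
  national acreage (every other tile is below threshold), so center
  identification has a unique right answer. Year-to-year acreage variation
  is a seeded factor applied to all counties alike, leaving shares of means
  exactly at their designed values.
- **Climate**: monthly fields that vary along the row axis only — a linear
  ramp plus a seeded low-frequency sine, with the ramp slope dominating the
  sine. Any cell sharing the center's row band therefore satisfies bounds
  derived from the center, and any cell beyond the band fails them; this is
  what makes the expected suitable mask paintable from geometry alone.
- **Suitability geometry**: one target rectangle of fallow land inside the
  center county (suitable at no expansion); one fallow rectangle per buffer
  annulus, placed strictly between consecutive buffer fronts east of the
  county, so each enters exactly one scenario; and four distractor fallow
  rectangles that each fail exactly one condition (soil too shallow,
  disallowed texture, rows outside the climate band, beyond the largest
  buffer).
- **Economics**: yield, losses, cups/kg drawn from realistic seeded ranges
  (or pinned in the design); expected cups follow the availability formula
  by hand.

The default truth-case grid is 300 × 300 cells at 150 m (45 km × 45 km):
the stand-alone layer generators default to 30 m — the working resolution
of real land-cover data — but a 20 km buffer is 667 cells at 30 m, so the
truth case uses a coarser cell to hold the full scenario set and the
annulus placements inside one tractable grid. Grid size, cell size, buffer
list and all economics are designable.

What the generator does *not* emulate: spatially realistic (2-D,
autocorrelated, distributionally calibrated) climate fields, real county
geometries, irrigation, multi-crop landscapes with competing land uses.
Passing tests therefore demonstrate that the pipeline's geometry, overlay
logic and accounting are exact — they do not validate the realism of any
particular parameterization against field data.

## Numerical choices and degenerate inputs

- Squared cell distances in the transform are integers; the dilation
  threshold adds 1e-9 to absorb floating-point error in `(d/cell)²` at
  exact ties (e.g. buffers that are integer multiples of the cell size).
- Component labels are assigned in row-major scan order, making labeling —
  and the coverage-prefix tie-break in `crop_clusters()` — deterministic.
- Masks coerce `NA` to `FALSE`: a cell with no data cannot be asserted
  suitable, in or adjacent to anything.
- Degenerate inputs fail loudly with stage-specific errors: empty zones,
  all-identical years in a trend series, zero national acreage, loss
  fractions ≥ 1, missing crop×buffer report cells, misaligned grids.
- Scores refuse missing nutrient values rather than zero-filling them.

## Problem sizes

The test suite checks the distance transform against an O(n²) brute-force
oracle on ≤ 40 × 40 grids (50+ random cases), component labeling against a
flood-fill oracle, regression slopes against the closed form, and the full
pipeline against closed-form ground truth for 20 seeded truth cases at the
default 300 × 300 grid; the whole suite runs in well under a minute. The
acceptance script replays the report-consistency checks and five pipeline
cases.

## Known limitations

Headline national results depend on proprietary-resolution climate, soil,
land-cover and census inputs that are not redistributable; the package
ships the printed scenario tables for consistency checking and the
synthetic generator for everything else. Fallowed-because-of-drought land
is indistinguishable from available fallow land in a land-cover snapshot,
biasing suitable area upward in drought regions, while incomplete
production-center coverage biases it downward. Availability assumes equal
national distribution; no price, demand or trade response is modeled.
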