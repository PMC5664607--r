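# fvcapacity

Geospatial capacity modeling for expanding US fruit and vegetable (F&V)
production. The package asks: if consumer demand for a set of nutrient-dense
fruits and vegetables rose, how much additional cropland *in and around the
crops' existing production centers* is suitable for growing them, and how
many additional cup-equivalents per person per day would that land supply?

It is written for food-systems and agricultural-geography researchers who
want the full analysis chain — crop screening, production-center
identification, boolean raster site-suitability overlay, buffer-expansion
scenarios, and loss-adjusted availability accounting — as tested, reusable
functions rather than a one-off GIS session.

## The model

**Crop screening.** Candidate foods are scored by nutrient density over four
nutrients of public health concern (fiber, calcium, magnesium, potassium):
by default the score is Σᵢ (amountᵢ / reference-dailyᵢ) × 100 per serving.
A food is retained iff its score passes a cutoff *and* the OLS slope of both
its consumption and its production series over the most recent five years is
strictly positive.

**Production centers.** For each crop, a county is eligible when it holds at
least 10% of mean (2002–2012) national harvested acreage; abutting eligible
counties (rook contiguity) merge into a single production center.

**Site suitability.** All layers live on one planar projected grid (30 m
cells in the real analysis). A cell is suitable for a crop iff **all** of
the crop's active conditions hold simultaneously:

- monthly precipitation within [low, high] for all 12 months,
- monthly minimum and maximum surface temperature within bounds,
- soil depth ≥ a minimum, soil texture class in an allowed set,
- land use = fallow cropland,
- the cell lies in the analysis region.

Bounds come from published growing requirements where available; otherwise
they are derived as the zonal min/max of the variable over the crop's own
production center (optionally restricted to the clusters where ≥95% of the
crop is cultivated). Only the conditions relevant to a crop enter its model
— e.g. an indoor-grown crop can use land use alone. Nodata in any active
layer makes a cell unsuitable.

**Scenarios.** Each center footprint is expanded 0/5/10/15/20 km from all
sides by exact Euclidean dilation of its raster mask (cell-center
semantics), giving five nested analysis regions; results are cumulative in
buffer distance by construction.

**Availability.** Suitable area × state-level yield gives farm-weight
production; a multiplicative loss chain (farm, retail, consumer) and a
cups-per-kg factor convert it to cup-equivalents; dividing by population and
365 gives cups per person per day:

cups = area_ha × yield × (1−l_farm)(1−l_retail)(1−l_consumer) × cups_per_kg / pop / 365.

Because the national climate/soil/land-cover/acreage inputs are not
packaged, a synthetic-data module generates complete grid-aligned bundles
with *analytically known* ground truth, so the entire pipeline is testable
offline (see `gen_truth_case()`).

## Worked example

```r
library(fvcapacity)
tc  <- gen_truth_case(truth_design(), seed = 1)   # synthetic input bundle
res <- run_pipeline(tc$inputs, tc$params)
res$results
#>   crop_id buffer_km suitable_area_ha production_kg_farm cups_per_capita_day
#> 1 crop_a          0          1350.00           11086359          0.07178487
#> 2 crop_a          5          1572.75           12915608          0.08362937
#> 3 crop_a         10          1894.50           15557857          0.10073810
#> 4 crop_a         15          2115.00           17368629          0.11246296
#> 5 crop_a         20          2259.00           18551174          0.12012001
```

One county holding 55% of national acreage becomes the single production
center; 1350 ha of fallow land inside it passes every growing condition
(suitable area, cumulative), rising to 2259 ha at a 20 km expansion, which
after yield, losses and cup conversion is worth 0.072–0.120 cup-equivalents
per person per day. Every number equals the bundle's closed-form expectation
(`tc$expected`) to floating-point precision.

The report-side functions work directly on scenario tables. Summing the
shipped per-crop cumulative area table and taking its 10 km Total:

```r
pub <- published_tables()
t2  <- scenario_table(...)            # see analysis/04_report_consistency.R
t2$km_10[t2$crop == "Total"]          # 280.7 (10^3 ha)
percent_increase(43.6e-3, 2.6)        # 1.68 -> "1.7%" at one decimal
```

The `analysis/` directory holds four numbered drivers narrating the full
sequence (screening → bundle simulation → pipeline → report consistency);
each writes its tables under `results/`.

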