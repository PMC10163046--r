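---
title: "Methods: species-NCP relationship tables and the per-pixel NCP index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-NCP relationship tables and the per-pixel NCP index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncplinkr)
```

## The model

`ncplinkr` operates on a two-way contingency table linking species to
Nature's Contributions to People (NCPs). Each cell holds one of three signed
values — `+1` (the species contributes positively to the NCP), `0`
(documented as neutral), `−1` (documented detriment) — or `NA`. The signed
three-valued scheme is deliberately coarse: it records the *existence and
direction* of a documented relationship, not its intensity. All downstream
statistics are sums and counts over these values.

Two assumptions shape everything else:

1. **Applicability is a lineage property.** Whether an NCP can apply to a
   species is decided at the lineage level (tracheophyte vs vertebrate) in
   the catalog, not per species. Of the 17 built-in NCPs, 16 apply to
   tracheophytes and 9 to vertebrates (8 to both). A cell under an
   inapplicable NCP is structurally `NA` and any non-`NA` value there is a
   validation error.
2. **Two NA flavours, one storage.** `NA` means either *no information
   found* (the cell was a candidate but the evidence search came up empty)
   or *not applicable* (the lineage rule above). Because the flavour is
   fully determined by the catalog, the package stores a plain integer
   matrix and recovers the flavour on demand (`na_flavor()`). Both flavours
   contribute 0 to every sum; only no-information cells count as "missing"
   in `count_relationships()` and in the per-species `n_na` columns (the
   not-applicable count is a lineage constant carrying no information about
   the species).

Sign permissions are also catalog properties: for solid wood, burned wood,
mellifera use, decontamination, hedge for crop yield and all non-material
NCPs, a negative relationship is not meaningful (a species cannot
"negatively" provide firewood) and `−1` is rejected at validation,
evidence-merge and generator level alike.

## Aggregation semantics

For species $s$ and category $c \in \{$material, non-material,
regulating$\}$:

* `positive_c` = number of `+1` cells; `negative_c` = signed sum of `−1`
  cells (so it is $\le 0$ and prints as e.g. `−1`);
* `total_c = positive_c + negative_c`; grand columns are sums over the three
  categories.

The negative column is a *signed sum*, not an absolute count: the printed
census rows render a single negative relationship as `−1`, and the identity
`total = positive + negative` then holds exactly, which the tests assert for
every species. Per-NCP summaries (`ncp_summary()`) instead report plain
counts that partition the applicable species of each group:
`n_positive + n_negative + n_neutral + n_na = n_species`.

Percentages in all reports use "round half away from zero" to one decimal
(`percent_of()`), the spreadsheet convention that reproduces the published
figures (1139/1816 → 62.7%). Base R's banker's rounding would differ on
exact halves.

Ranking (`top_scored_species()`) sorts by `grand_positive` descending, then
`grand_total` descending, then `species_id` lexicographically. The first two
keys follow how the published sample table is selected ("highest number of
reported positive relationships"); the lexicographic tail makes the order
total and the CLI outputs byte-reproducible.

## Attribution rules

Three evidence routes feed cells:

* **Membership lists** (`assign_membership()`): binary presence on a curated
  list maps to `+1` (crop wild relatives, Emerald species, wood species) or
  `−1` (toxic species under the wild-food rule); absentees get `0`.
* **Quartile thresholding** (`quartile_threshold()`): bibliometric counts
  (publications, weblinks) are converted by flagging species whose count is
  *strictly greater* than the third quartile of their group's distribution.
  "Strictly greater" follows the rule's wording ("higher than the 3rd
  quartile"); with heavy ties this can flag nobody, and it can never flag
  more than the strictly-above-median half. Q3 uses linear interpolation
  between order statistics (`stats::quantile` type 7, $h = 0.75(n-1)$) —
  the default convention of mainstream numerical environments; the source
  procedure does not state one, so the type is a parameter and is recorded
  in the output's attributes. The grouping key is likewise a parameter
  (`group=`): the source separates "by taxonomic group" without defining
  the level, so the caller chooses (per-lineage at minimum).
* **Evidence merging** (`merge_evidence()`): when several records target one
  cell, the default `"dominance"` policy resolves `−1 > +1 > 0` — any
  credible detriment outweighs positive mentions, generalising the
  toxicity rule. The alternative `"precedence"` policy lets the
  highest-ranking source win (expert > reference > analytics), reflecting
  documented cases where a national expert verdict overrode the literature;
  within the winning source, dominance applies. Neither policy is asserted
  to be *the* one used to build the original census — how
  reference-vs-expert conflicts were resolved there is not stated beyond one
  anecdote — so both are provided and the choice is recorded in run
  manifests. Both are order-invariant, which the tests check by permutation.

Cells no evidence route touches stay no-information `NA` — absence of
evidence is never coerced to neutral.

### Synonym merging

Taxonomic aggregation (`apply_synonym_map()`) combines rows cell-wise. The
default `"information"` policy keeps the unique non-`NA` value and errors on
genuinely conflicting values: aggregation is supposed to happen *before*
scoring, so a conflict means dirty input and failing loudly beats averaging.
A `"dominance"` fallback (`−1 > +1 > 0`) exists for exploratory use.
Occurrence counts of merged taxa are summed; other metadata follows the
first-listed record.

## The per-pixel NCP index

For pixel $p$ with observed species set $S(p)$ and area $a(p)$ (km²):

$$I_c(p) = \frac{\sum_{s \in S(p)} \mathrm{total}_c(s)}{|S(p)|} \times a(p)$$

Numerical and design choices:

* **Denominator.** $|S(p)|$ counts *all* species observed in the pixel,
  including species whose category cells are all `NA` (they contribute 0 to
  the numerator). They were observed, and the defining phrase ("divided by
  the number of species observed") carries no restriction. Because the
  alternative reading exists, `denominator = "scored"` restricts the count
  to species with at least one filled cell in the category.
* **Empty pixels are no-data, not zero.** $I_c$ is undefined when
  $S(p) = \emptyset$; a pixel of all-neutral species has the meaningful
  value 0 and must stay distinguishable.
* **Gridding.** Cells are half-open intervals, so a point on a cell's
  lower-left corner belongs to that cell and every point belongs to exactly
  one cell; `pixel_id` is `row_col` with row 1 northernmost. Duplicate
  records of a species in a pixel collapse (set semantics), so the index is
  invariant to resampling effort within a pixel.
* **Border pixels.** An optional WKT polygon clips per-cell areas (border
  pixels of a study region are smaller than the nominal 1 km²). With no
  geometry package in the supported stack, clipping is done in-package:
  Sutherland–Hodgman clipping of each ring against the cell rectangle plus
  shoelace areas, with holes subtracted. Coordinates are assumed planar in
  km-compatible units; no geodesic areas.
* **Raster export.** The stack has no GeoTIFF writer, so the raster format
  is the ESRI ASCII grid (`.asc`) — plain text, GDAL/QGIS-readable, with
  `NODATA_value -9999` for undefined pixels — alongside CSV. Every export
  writes a JSON sidecar recording the category, the denominator setting and
  a checksum of the relationship-table matrix, so maps remain attributable
  to the exact table that produced them.

Useful invariants (all tested): linearity in area at fixed species set;
collapse to $k \times a(p)$ when every observed species has the same
category total $k$; and adding a species whose total equals the current
pixel mean leaves the per-area index unchanged.

## The synthetic-data generator

The generator states a world and sticks to it; it is a first-class module,
not a test shim.

* **Tables** (`generate_table()`): every applicable cell is drawn i.i.d.
  from per-NCP probabilities $(p_+, p_-, p_{NA})$, remainder neutral.
  Defaults: $p_+ = 0.25$ (the third-quartile attribution rules flag about a
  quarter of a lineage), $p_- = 0.05$ (negatives are rare in the census:
  the largest negative share printed is 12.9%), $p_{NA} = 0.01$ (the census
  left 208 of 31,306 cells unfilled, ≈0.7%). A scalar `p_negative` is
  zeroed where negatives are disallowed (a convenience, since the constraint
  is structural); an *explicit per-NCP* nonzero value there is an argument
  error, because it contradicts the stated world rather than abbreviating
  it. The generator returns its planted tallies so aggregation code is
  checked against bookkeeping, not against itself.
* **The census-shaped preset** (`generate_paper_preset()`): 1816 + 250
  species, the built-in catalog, exactly 208 no-information cells placed
  uniformly at random among applicable cells — so reported/possible counts
  are (31,098, 31,306) by construction, exercising NA bookkeeping at full
  scale without any download.
* **Occurrences** (`generate_occurrences()`): per-pixel distinct-species
  richness is either fixed (uniform) or Poisson with mean increasing
  linearly along rows (gradient), species sampled without replacement and
  placed at pixel centres, years uniform in 1970–2020.
* **Reference counts** (`generate_reference_counts()`): rounded log-normal
  (meanlog 3, sdlog 1.5) for citation-like skew, or uniform integers.

What the generator does *not* emulate: spatial autocorrelation, elevation
gradients, detection bias, cross-NCP correlation within species, and the
real taxonomic composition. A green test against synthetic data therefore
establishes that the *computations* are correct under the stated sampling
model — it says nothing about ecological realism of any particular map.

Seeds are explicit arguments everywhere; no function leaves global RNG
state modified.

## Degenerate inputs and numeric conventions

* Empty catalog files, empty count tables, zero-pixel grids and richness
  exceeding the species pool are argument errors, not silent empties.
* Values outside `{−1, 0, 1, NA}` fail the CSV reader with row/column
  coordinates; the reader also refuses structurally invalid tables, while
  `validate_table()` (and the `validate` CLI command) reports violations
  without throwing, one row each.
* The occurrence filter keeps `n_occurrences >= min_occurrences`
  (inclusive, matching "at least 10") and is idempotent.
* CSV cell encoding is `1` / `0` / `-1` / empty string — a plain
  spreadsheet export round-trips.

## Known limitations

* The three-valued scheme cannot express intensity; weighting species (e.g.
  by toxicity level or abundance) is out of scope.
* Live bibliometric querying is excluded by design — reference counts enter
  as files, which keeps runs reproducible but means the package never
  re-derives counts.
* The spatial module does no species distribution modelling: indices are
  computed from observed occurrences only, inheriting their sampling bias.
* The full published relationship table is a supplementary download and is
  not redistributed here; the packaged sample covers the 11 printed rows,
  and full-scale behaviour is exercised by the census-shaped synthetic
  preset instead.
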