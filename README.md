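# ncplinkr

Species-to-NCP relationship tables and per-pixel ecosystem-service indices.

## The problem

Nature's Contributions to People (NCPs, the IPBES framing of ecosystem
services) are usually mapped from coarse land-use/land-cover units. Mapping
them directly from *species* requires a census of species-to-NCP
relationships first: for every species and every NCP, is the relationship
positive, neutral, negative — or simply undocumented? `ncplinkr` implements
that census machinery for tracheophyte (vascular plant) and vertebrate
assemblages:

* a **catalog** of 17 NCPs selected from CICES V5.1, in three categories
  (material, non-material, regulating/maintenance), with per-lineage
  applicability (16 NCPs apply to tracheophytes, 9 to vertebrates, 8 to
  both) and per-NCP sign permissions;
* a **relationship table**: a species × NCP matrix over `{+1, 0, −1, NA}`,
  where `NA` means either *no information found* or *NCP not applicable to
  this lineage* (the package distinguishes the two), with a validator for
  every structural invariant;
* **attribution rules** that turn evidence into cell values: membership
  lists (crop wild relatives → +1, toxic species → −1, Emerald list → +1),
  third-quartile thresholding of bibliometric reference counts (a species
  scores +1 iff its count is *strictly greater* than Q3 of its group's count
  distribution, Q3 by linear interpolation), and a deterministic merger of
  conflicting evidence records (negative-dominance or
  expert-over-reference-over-analytics precedence);
* **aggregation**: per-species category scores and grand totals
  (`total = positive + negative`, NA excluded), per-NCP counts by lineage or
  subgroup, reported-vs-possible relationship bookkeeping, species ranking;
* a **spatial NCP index**: for each grid pixel `p` and category `c`,

  ```
  I_c(p) = ( Σ_{s ∈ S(p)} total_c(s) ) / |S(p)| × area(p)
  ```

  the mean per-species category score of the species observed in the pixel,
  scaled by (boundary-clipped) pixel area, exported as CSV or plain-text
  ESRI ASCII rasters;
* a **synthetic-data module** that generates tables, occurrence grids and
  skewed reference counts with known ground truth, including a census-shaped
  preset (1816 + 250 species, 31,098 of 31,306 cells filled);
* a **CLI** (`ncp_cli()`: `validate` / `summarize` / `map` / `simulate`)
  driven by YAML configs, writing run manifests with input checksums.

## Worked example

The package ships the published sample of the census table (the five
top-scored tracheophytes and six top-scored vertebrates) as a fixture:

```r
library(ncplinkr)
catalog <- load_catalog()                       # the built-in 17-NCP catalog
tab <- read_relationship_table(
  system.file("extdata", "table1_sample.csv", package = "ncplinkr"), catalog)
tab
#> <ncp_table> 11 species (5 tracheophytes, 6 vertebrates) x 17 NCPs
#>   reported relationships: 131 of 134 possible

top_scored_species(tab, lineage = "tracheophyte", n = 3)[
  , c("species_id", "grand_positive", "grand_negative", "grand_total")]
#>        species_id grand_positive grand_negative grand_total
#> 1      salix_alba             12              0          12
#> 2    salix_caprea             12              0          12
#> 3 populus_tremula             11              0          11
```

The white willow has 12 positive relationships out of its 16 applicable
NCPs and no negative ones, hence a cumulated score of 12. Per-NCP counts
partition each lineage:

```r
ncp_summary(tab, "wild_food")
#>      ncp_id        group n_species n_positive n_negative n_neutral n_na pct_positive pct_negative
#> 1 wild_food tracheophyte         5          0          0         5    0            0            0
#> 2 wild_food   vertebrate         6          3          0         3    0           50            0
```

The spatial index on a toy two-pixel grid (second pixel clipped to
0.62 km²):

```r
pix <- data.frame(pixel_id = c("1_1", "1_2"), row = 1, col = 1:2,
                  area_km2 = c(1, 0.62))
g <- occurrence_grid(pix, list(`1_1` = c("salix_alba", "canis_lupus"),
                               `1_2` = "betula_pendula"))
compute_ncp_index(g, tab)
#>   pixel_id row col area_km2 n_species index_material index_non_material index_regulating
#> 1      1_1   1   1     1.00         2            3.0               2.00             2.50
#> 2      1_2   1   2     0.62         1            3.1               1.24             1.86
```

Pixel `1_1` hosts the willow (material score 6) and the wolf (material
score 0): mean 3, times area 1 km² gives a material index of 3.0. Empty
pixels get an undefined index (`NA`), not 0 — an all-neutral community has
a meaningful index of exactly 0.

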