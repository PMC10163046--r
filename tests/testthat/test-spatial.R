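test_that("points are assigned to half-open cells and deduplicated", {
  spec <- grid_spec(0, 0, 1, ncols = 2, nrows = 2)
  rec <- data.frame(
    species_id = c("a", "a", "b", "c"),
    x = c(0, 0.5, 0.5, 1),   # (0,0) is cell 2_1's lower-left corner
    y = c(0, 0.5, 0.5, 1))   # (1,1) is the shared interior corner -> cell 1_2
  g <- rasterize_occurrences(rec, spec)
  expect_equal(g$species[["2_1"]], c("a", "b"))  # duplicate 'a' counted once
  expect_equal(g$species[["1_2"]], "c")
  expect_equal(g$species[["1_1"]], character(0))
  expect_true(all(g$pixels$area_km2 == 1))

  # out-of-extent records are dropped and reported
  g2 <- rasterize_occurrences(rbind(rec, data.frame(species_id = "z", x = 5, y = 5)), spec)
  expect_equal(attr(g2, "dropped")[["out_of_extent"]], 1L)
  expect_error(grid_spec(0, 0, 0, 2, 2), "positive")
})

test_that("boundary polygons clip per-cell areas", {
  # right triangle of area 2 over a 2x2 unit grid: two half cells, one full
  spec <- grid_spec(0, 0, 1, 2, 2, boundary = "POLYGON ((0 0, 2 0, 0 2, 0 0))")
  g <- rasterize_occurrences(data.frame(species_id = "a", x = 0.25, y = 0.25), spec)
  areas <- setNames(g$pixels$area_km2, g$pixels$pixel_id)
  expect_equal(areas, c(`1_1` = 0.5, `2_1` = 1.0, `2_2` = 0.5))
  expect_equal(sum(areas), 2)
  # a hole subtracts area
  spec2 <- grid_spec(0, 0, 1, 2, 2,
                     boundary = "POLYGON ((0 0, 2 0, 2 2, 0 2, 0 0), (0.25 0.25, 0.75 0.25, 0.75 0.75, 0.25 0.75, 0.25 0.25))")
  g2 <- rasterize_occurrences(data.frame(species_id = "a", x = 1.5, y = 1.5), spec2)
  a2 <- setNames(g2$pixels$area_km2, g2$pixels$pixel_id)
  expect_equal(unname(a2["2_1"]), 1 - 0.25)
  expect_equal(unname(a2["1_1"]), 1)
})

test_that("the per-pixel index follows score-sum / n-species x area", {
  sp <- make_species(c("hi", "lo"), "tracheophyte")
  cells <- rbind(
    data.frame(species_id = "hi", ncp_id = c("wild_food", "mellifera", "solid_wood"), value = 1),
    data.frame(species_id = "lo", ncp_id = "wild_food", value = 1))
  tab <- make_table(sp, cells)  # material totals: hi = 3, lo = 1
  pix <- data.frame(pixel_id = "1_1", row = 1, col = 1, area_km2 = 1)
  g <- occurrence_grid(pix, list(`1_1` = c("hi", "lo")))
  idx <- compute_ncp_index(g, tab, "material")
  expect_equal(idx$index_material, 2)
  # linear in area
  pix$area_km2 <- 0.5
  idx2 <- compute_ncp_index(occurrence_grid(pix, list(`1_1` = c("hi", "lo"))), tab, "material")
  expect_equal(idx2$index_material, 1)
  # all-NA species: total 0, index defined
  sp3 <- make_species("ghost", "tracheophyte")
  tab3 <- make_table(sp3)
  g3 <- occurrence_grid(data.frame(pixel_id = "1_1", row = 1, col = 1, area_km2 = 1),
                        list(`1_1` = "ghost"))
  idx3 <- compute_ncp_index(g3, tab3, "material")
  expect_equal(idx3$index_material, 0)
  expect_equal(idx3$n_species, 1L)
  # empty pixel: undefined index, zero species
  g4 <- occurrence_grid(data.frame(pixel_id = c("1_1", "1_2"), row = 1, col = 1:2,
                                   area_km2 = 1),
                        list(`1_1` = c("hi", "lo")), spec = NULL)
  idx4 <- compute_ncp_index(g4, tab, "material")
  expect_true(is.na(idx4$index_material[idx4$pixel_id == "1_2"]))
  expect_equal(idx4$n_species[idx4$pixel_id == "1_2"], 0L)
  # unknown species in the grid
  g5 <- occurrence_grid(pix, list(`1_1` = c("hi", "nessie")))
  expect_error(compute_ncp_index(g5, tab), "nessie")
})

test_that("index invariants: mean collapse, duplication, mean-preserving species", {
  gen <- generate_table(table_generator_spec(10, 5, p_positive = 0.4,
                                             p_negative = 0.1, p_na = 0.1, seed = 2))
  tab <- gen$table
  ids <- tab$species$species_id
  # identical totals collapse to k x area: a table where every species is +1
  # on wild_food only has total_material = 1 for everyone
  sp <- make_species(sprintf("s%d", 1:4), "tracheophyte")
  flat <- make_table(sp, data.frame(species_id = sp$species_id,
                                    ncp_id = "wild_food", value = 1))
  pix <- data.frame(pixel_id = c("1_1", "1_2"), row = 1, col = 1:2, area_km2 = c(1, 0.7))
  g <- occurrence_grid(pix, list(`1_1` = sp$species_id[1:2], `1_2` = sp$species_id))
  idx <- compute_ncp_index(g, flat, "material")
  expect_equal(idx$index_material, 1 * pix$area_km2)

  # duplicated occurrence records do not change the index (set semantics)
  spec <- grid_spec(0, 0, 1, 2, 1)
  rec <- data.frame(species_id = ids[1:6], x = rep(c(0.5, 1.5), 3), y = 0.5)
  idx_once <- compute_ncp_index(rasterize_occurrences(rec, spec), tab)
  idx_dup <- compute_ncp_index(rasterize_occurrences(rbind(rec, rec, rec), spec), tab)
  expect_equal(idx_dup, idx_once)

  # adding a species at the pixel mean leaves the per-area index unchanged:
  # material totals planted as one = 1, three = 3, two = 2 (their mean)
  sp5 <- make_species(c("one", "three", "two"), "tracheophyte")
  tab5 <- make_table(sp5, rbind(
    data.frame(species_id = "one", ncp_id = "wild_food", value = 1),
    data.frame(species_id = "three", ncp_id = c("wild_food", "mellifera", "solid_wood"), value = 1),
    data.frame(species_id = "two", ncp_id = c("wild_food", "mellifera"), value = 1)))
  g_pair <- occurrence_grid(data.frame(pixel_id = "1_1", row = 1, col = 1, area_km2 = 1),
                            list(`1_1` = c("one", "three")))
  g_three <- occurrence_grid(data.frame(pixel_id = "1_1", row = 1, col = 1, area_km2 = 1),
                             list(`1_1` = c("one", "three", "two")))
  expect_equal(compute_ncp_index(g_three, tab5, "material")$index_material,
               compute_ncp_index(g_pair, tab5, "material")$index_material)
})

test_that("index matches the naive per-pixel loop on small random grids", {
  for (seed in 1:2) {
    gen <- generate_table(table_generator_spec(12, 6, p_positive = 0.3,
                                               p_negative = 0.1, p_na = 0.2, seed = seed))
    tab <- gen$table
    occ <- generate_occurrences(grid_generator_spec(2, 3, richness = "uniform",
                                                    richness_range = 4, seed = seed),
                                tab$species$species_id)
    g <- rasterize_occurrences(occ, attr(occ, "grid"))
    idx <- compute_ncp_index(g, tab)
    for (cc in c("material", "non_material", "regulating")) {
      expect_equal(idx[[paste0("index_", cc)]], unname(naive_index(g, tab, cc)),
                   info = paste(seed, cc))
    }
  }
})

test_that("index grids round-trip through CSV and export to ASCII rasters", {
  gen <- generate_table(table_generator_spec(8, 4, seed = 5))
  tab <- gen$table
  spec <- grid_spec(0, 0, 1, 2, 2)
  # leave pixel 2_2 empty
  rec <- data.frame(species_id = tab$species$species_id[1:6],
                    x = c(0.5, 0.5, 1.5, 1.5, 0.5, 0.5),
                    y = c(1.5, 1.5, 1.5, 1.5, 0.5, 0.5))
  idx <- compute_ncp_index(rasterize_occurrences(rec, spec), tab)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_index_grid(idx, csv, format = "csv")
  back <- read_index_grid(csv)
  for (cc in c("index_material", "index_non_material", "index_regulating")) {
    expect_equal(back[[cc]], idx[[cc]], tolerance = 1e-9)
  }
  expect_equal(attr(back, "table_checksum"), attr(idx, "table_checksum"))

  asc <- withr::local_tempfile(fileext = ".asc")
  write_index_grid(idx, asc, format = "asc", category = "material")
  lines <- readLines(asc)
  expect_equal(lines[1], "ncols 2")
  expect_equal(lines[6], "NODATA_value -9999")
  grid_vals <- do.call(rbind, lapply(lines[7:8], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  expect_equal(grid_vals[2, 2], -9999)  # the empty pixel
  expect_equal(grid_vals[1, 1], idx$index_material[idx$pixel_id == "1_1"])

  # all-zero indices stay distinct from no-data
  zero <- idx
  zero$index_material[] <- 0
  write_index_grid(zero, asc, format = "asc", category = "material")
  vals <- as.numeric(strsplit(readLines(asc)[7], " ")[[1]])
  expect_true(all(vals == 0))
})
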