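test_that("score summaries reproduce the printed sample rows", {
  tab <- table1_fixture()
  salix <- species_score_summary(tab, "salix_alba")
  expect_equal(salix$total_material, 6)
  expect_equal(salix$total_non_material, 2)
  expect_equal(salix$total_regulating, 4)
  expect_equal(salix$grand_total, 12)
  expect_equal(salix$grand_positive, 12)
  expect_equal(salix$grand_negative, 0)

  wolf <- species_score_summary(tab, "canis_lupus")
  expect_equal(wolf$grand_total, 3)
  expect_equal(wolf$grand_positive, 4)
  expect_equal(wolf$grand_negative, -1)
  expect_equal(wolf$total_regulating, 1)

  expect_error(species_score_summary(tab, "yeti"), "unknown species_id")
})

test_that("an all-NA species scores zero everywhere and counts its NA cells", {
  sp <- make_species(c("p1", "v1"), c("tracheophyte", "vertebrate"))
  tab <- make_table(sp)
  s <- species_score_summary(tab)
  expect_true(all(s$grand_total == 0))
  expect_equal(s$grand_n_na, c(16L, 9L))
  # category identity holds for every species and category
  for (cc in c("material", "non_material", "regulating")) {
    expect_equal(s[[paste0("total_", cc)]],
                 s[[paste0("positive_", cc)]] + s[[paste0("negative_", cc)]])
  }
})

test_that("ncp_summary partitions the applicable species of each group", {
  sp <- make_species(sprintf("p%d", 1:5), "tracheophyte")
  cells <- data.frame(species_id = sprintf("p%d", 1:4),
                      ncp_id = "wild_food", value = c(1, 1, -1, 0))
  tab <- make_table(sp, cells)  # p5 stays NA
  s <- ncp_summary(tab, "wild_food")
  expect_equal(s[, c("n_positive", "n_negative", "n_neutral", "n_na")],
               data.frame(n_positive = 2L, n_negative = 1L, n_neutral = 1L, n_na = 1L))
  expect_equal(s$n_species, 5L)
  expect_equal(s$pct_positive, 40.0)

  # vertebrate-only NCP against a tracheophyte-only table: empty group
  s2 <- ncp_summary(tab, "reduce_species_damage")
  expect_equal(s2$n_species, 0L)
  expect_true(is.na(s2$pct_positive))
  expect_error(ncp_summary(tab, "bogus"), "unknown ncp_id")
})

test_that("relationship counting follows NA bookkeeping exactly", {
  sp <- make_species(c("p1", "p2", "p3"), "tracheophyte")
  cat3 <- ncp_catalog(data.frame(
    ncp_id = c("a", "b"), label = c("A", "B"), category = "material",
    applicable_lineages = "tracheophyte", negative_allowed = TRUE,
    sources = "expert"))
  v <- matrix(c(1L, 0L, -1L, 0L, 1L, NA), 3, 2,
              dimnames = list(sp$species_id, c("a", "b")))
  tab <- relationship_table(sp, v, cat3)
  expect_equal(count_relationships(tab), c(n_reported = 5L, n_possible = 6L))

  v[3, 2] <- 0L
  full <- relationship_table(sp, v, cat3)
  cr <- count_relationships(full)
  expect_equal(cr[["n_reported"]], cr[["n_possible"]])
})

test_that("top_scored_species ranks by positives, then total, then id", {
  sp <- make_species(c("a", "b", "c"), "tracheophyte")
  cells <- do.call(rbind, list(
    data.frame(species_id = "a", ncp_id = c("wild_food", "mellifera", "solid_wood",
                                            "burned_wood", "potential_crop"), value = 1),
    data.frame(species_id = "b", ncp_id = c("wild_food", "mellifera"), value = 1),
    data.frame(species_id = "c", ncp_id = c("wild_food", "mellifera", "solid_wood",
                                            "burned_wood"), value = 1)))
  tab <- make_table(sp, cells)
  top <- top_scored_species(tab, n = 2)
  expect_equal(top$species_id, c("a", "c"))
  expect_equal(top$grand_positive, c(5L, 4L))
  # n beyond the table size returns everything, no error
  expect_equal(nrow(top_scored_species(tab, n = 10)), 3)
  # all-equal scores fall back to lexicographic ids
  flat <- make_table(sp, data.frame(species_id = c("c", "a", "b"),
                                    ncp_id = "wild_food", value = 1))
  expect_equal(top_scored_species(flat, n = 3)$species_id, c("a", "b", "c"))
  # tie on positives broken by grand total (a negative lowers the total)
  tied <- make_table(sp, rbind(
    data.frame(species_id = c("a", "b"), ncp_id = "wild_food", value = 1),
    data.frame(species_id = "a", ncp_id = "forage_pasture", value = -1)))
  expect_equal(top_scored_species(tied, n = 1)$species_id, "b")
})

test_that("summaries match a naive cell-by-cell recount on random tables", {
  for (seed in 1:3) {
    gen <- generate_table(table_generator_spec(
      n_tracheophytes = 30, n_vertebrates = 15,
      p_positive = 0.3, p_negative = 0.1, p_na = 0.15, seed = seed))
    tab <- gen$table
    s <- species_score_summary(tab)
    for (sid in sample(tab$species$species_id, 8)) {
      expected <- naive_score_summary(tab, sid)
      got <- s[s$species_id == sid, ]
      for (f in names(expected)) expect_equal(got[[f]], expected[[f]], info = paste(seed, sid, f))
    }
    for (ncp in sample(tab$catalog$ncp_id, 5)) {
      ns <- ncp_summary(tab, ncp)
      for (g in ns$group) {
        expected <- naive_ncp_counts(tab, ncp, g)
        got <- ns[ns$group == g, ]
        expect_equal(c(got$n_positive, got$n_negative, got$n_neutral, got$n_na),
                     unname(expected), info = paste(seed, ncp, g))
      }
    }
    # conservation: per-lineage counts over all NCPs sum to |species| x |mask|
    all_ns <- ncp_summary(tab)
    per_lineage <- tapply(
      all_ns$n_positive + all_ns$n_negative + all_ns$n_neutral + all_ns$n_na,
      all_ns$group, sum)
    for (lin in names(per_lineage)) {
      expect_equal(unname(per_lineage[[lin]]),
                   sum(tab$species$lineage == lin) *
                     length(applicability_mask(tab$catalog, lin)))
    }
    # count_relationships identity
    cr <- count_relationships(tab)
    fl <- na_flavor(tab)
    expect_equal(cr[["n_reported"]] + sum(fl == "no_info", na.rm = TRUE),
                 cr[["n_possible"]])
  }
})
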