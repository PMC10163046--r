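# Shared fixtures and naive reference implementations. The oracles here are
# deliberately dumb cell-by-cell loops, independent of the vectorised package
# code they check.

paper_catalog <- function() load_catalog()

table1_fixture <- function() {
  read_relationship_table(
    system.file("extdata", "table1_sample.csv", package = "ncplinkr"),
    paper_catalog())
}

make_species <- function(ids, lineage, subgroup = NA, n_occurrences = 100,
                         alien = FALSE) {
  data.frame(species_id = ids, lineage = lineage, subgroup = subgroup,
             n_occurrences = n_occurrences, alien = alien,
             stringsAsFactors = FALSE)
}

# Build an ncp_table from sparse cell triplets; unspecified cells stay NA.
make_table <- function(species, cells = NULL, catalog = paper_catalog()) {
  v <- matrix(NA_integer_, nrow(species), nrow(catalog),
              dimnames = list(species$species_id, catalog$ncp_id))
  if (!is.null(cells) && nrow(cells)) {
    v[cbind(match(cells$species_id, rownames(v)),
            match(cells$ncp_id, colnames(v)))] <- as.integer(cells$value)
  }
  relationship_table(species, v, catalog)
}

# --- naive oracles ----------------------------------------------------------

naive_score_summary <- function(table, sid) {
  cat <- table$catalog
  lin <- table$species$lineage[table$species$species_id == sid]
  out <- list()
  for (cc in c("material", "non_material", "regulating")) {
    pos <- 0; neg <- 0; nna <- 0
    for (i in seq_len(nrow(cat))) {
      if (cat$category[i] != cc) next
      applicable <- lin %in% strsplit(cat$applicable_lineages[i], ";")[[1]]
      if (!applicable) next
      val <- table$values[sid, cat$ncp_id[i]]
      if (is.na(val)) nna <- nna + 1
      else if (val == 1) pos <- pos + 1
      else if (val == -1) neg <- neg - 1
    }
    out[[paste0("total_", cc)]] <- pos + neg
    out[[paste0("positive_", cc)]] <- pos
    out[[paste0("negative_", cc)]] <- neg
    out[[paste0("n_na_", cc)]] <- nna
  }
  out$grand_total <- out$total_material + out$total_non_material + out$total_regulating
  out$grand_positive <- out$positive_material + out$positive_non_material + out$positive_regulating
  out$grand_negative <- out$negative_material + out$negative_non_material + out$negative_regulating
  out
}

naive_ncp_counts <- function(table, ncp, group_value, group_by = "lineage") {
  cat <- table$catalog
  i <- which(cat$ncp_id == ncp)
  lins <- strsplit(cat$applicable_lineages[i], ";")[[1]]
  n <- c(pos = 0, neg = 0, neu = 0, na = 0)
  for (k in seq_len(nrow(table$species))) {
    sp <- table$species[k, ]
    if (!identical(sp[[group_by]], group_value)) next
    if (!sp$lineage %in% lins) next
    val <- table$values[sp$species_id, ncp]
    if (is.na(val)) n["na"] <- n["na"] + 1
    else if (val == 1) n["pos"] <- n["pos"] + 1
    else if (val == -1) n["neg"] <- n["neg"] + 1
    else n["neu"] <- n["neu"] + 1
  }
  n
}

# Q3 by explicit linear interpolation between order statistics (h = .75(n-1)).
naive_q3 <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- 0.75 * (n - 1)       # 0 <= h <= n - 2 + 0.75 for n >= 2
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

naive_index <- function(grid, table, category) {
  vapply(grid$pixels$pixel_id, function(p) {
    sp <- grid$species[[p]]
    if (length(sp) == 0) return(NA_real_)
    tot <- vapply(sp, function(s) naive_score_summary(table, s)[[paste0("total_", category)]],
                  numeric(1))
    a <- grid$pixels$area_km2[grid$pixels$pixel_id == p]
    sum(tot) / length(sp) * a
  }, numeric(1))
}
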