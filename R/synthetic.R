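#' Specification for a synthetic relationship table
#'
#' Describes the stochastic world a synthetic species-by-NCP table is drawn
#' from: two lineages of configurable size and, per NCP, the probabilities
#' of a positive, negative and no-information cell (the remainder is
#' neutral). Probabilities may be scalars (applied to every NCP) or named
#' vectors keyed by `ncp_id`. A scalar `p_negative` is silently zeroed for
#' NCPs with `negative_allowed = FALSE`; an *explicit per-NCP* positive
#' `p_negative` for such an NCP is an argument error.
#'
#' Defaults emulate the statistical shape of the real census: roughly a
#' quarter of cells positive (the third-quartile attribution rules flag about
#' 25% of a lineage), negatives rare (5% where permitted), and about 1% of
#' cells left no-information (the census reports 208 of 31,306 cells
#' unfilled).
#'
#' @param n_tracheophytes,n_vertebrates lineage sizes (>= 1).
#' @param p_positive,p_negative,p_na cell-value probabilities (scalar or
#'   named per-NCP vectors).
#' @param seed integer seed; generation never touches global RNG state.
#' @return a `table_generator_spec`.
#' @export
table_generator_spec <- function(n_tracheophytes = 50, n_vertebrates = 20,
                                 p_positive = 0.25, p_negative = 0.05,
                                 p_na = 0.01, seed = 1) {
  stopifnot(n_tracheophytes >= 1, n_vertebrates >= 1)
  structure(list(n_tracheophytes = as.integer(n_tracheophytes),
                 n_vertebrates = as.integer(n_vertebrates),
                 p_positive = p_positive, p_negative = p_negative,
                 p_na = p_na, seed = seed),
            class = "table_generator_spec")
}

expand_prob <- function(p, catalog, what) {
  if (is.null(names(p))) {
    if (length(p) != 1) stop_ncp("%s must be a scalar or a named per-NCP vector", what)
    return(stats::setNames(rep(p, nrow(catalog)), catalog$ncp_id))
  }
  bad <- setdiff(names(p), catalog$ncp_id)
  if (length(bad)) stop_ncp("%s names not in catalog: %s", what, paste(bad, collapse = ", "))
  out <- stats::setNames(rep(0, nrow(catalog)), catalog$ncp_id)
  out[names(p)] <- p
  out
}

validate_generator_spec <- function(spec, catalog) {
  pp <- expand_prob(spec$p_positive, catalog, "p_positive")
  pn <- expand_prob(spec$p_negative, catalog, "p_negative")
  pna <- expand_prob(spec$p_na, catalog, "p_na")
  explicit_neg <- !is.null(names(spec$p_negative))
  disallowed <- catalog$ncp_id[!catalog$negative_allowed]
  if (explicit_neg && any(pn[disallowed] > 0)) {
    stop_ncp("p_negative > 0 for negative-disallowed NCP(s): %s",
             paste(disallowed[pn[disallowed] > 0], collapse = ", "))
  }
  pn[disallowed] <- 0
  if (any(pp < 0 | pn < 0 | pna < 0) || any(pp + pn + pna > 1 + 1e-12)) {
    stop_ncp("infeasible probabilities: need p_positive + p_negative + p_na <= 1, all >= 0")
  }
  list(p_positive = pp, p_negative = pn, p_na = pna)
}

subgroup_pool <- function(lineage) {
  switch(lineage, tracheophyte = PLANT_SUBGROUPS, vertebrate = ANIMAL_SUBGROUPS)
}

#' Generate a synthetic relationship table with known ground truth
#'
#' Draws every applicable cell independently from the per-NCP value
#' distribution of the spec and returns both the table and the exact tallies
#' that were planted, so aggregation code can be checked against the
#' generator's own bookkeeping rather than a re-count. Reproducible: the
#' same spec (same seed) yields an identical table.
#'
#' @param spec a [table_generator_spec()].
#' @param catalog an [ncp_catalog] (default: the built-in 17-NCP catalog).
#' @return list with elements `table` (an `ncp_table`) and `tallies`
#'   (data.frame `ncp_id`, `lineage`, `n_positive`, `n_negative`,
#'   `n_neutral`, `n_na`).
#' @export
generate_table <- function(spec, catalog = load_catalog()) {
  stopifnot(inherits(spec, "table_generator_spec"))
  probs <- validate_generator_spec(spec, catalog)
  n <- c(tracheophyte = spec$n_tracheophytes, vertebrate = spec$n_vertebrates)

  with_seed(spec$seed, {
    ids <- c(sprintf("trach_%04d", seq_len(n[["tracheophyte"]])),
             sprintf("vert_%04d", seq_len(n[["vertebrate"]])))
    lineage <- rep(LINEAGES, times = n)
    species <- data.frame(
      species_id = ids,
      scientific_name = paste("Species", ids),
      lineage = lineage,
      subgroup = vapply(lineage, function(l) sample(subgroup_pool(l), 1), character(1)),
      iucn_status = sample(c("LC", "NT", "VU", "EN"), length(ids), replace = TRUE,
                           prob = c(0.7, 0.15, 0.1, 0.05)),
      n_occurrences = sample(10:5000, length(ids), replace = TRUE),
      alien = FALSE,
      stringsAsFactors = FALSE)

    values <- matrix(NA_integer_, length(ids), nrow(catalog),
                     dimnames = list(ids, catalog$ncp_id))
    app <- lineage_applicability(catalog)  # ncp x lineage
    tallies <- list()
    for (ncp in catalog$ncp_id) {
      p <- c(pos = probs$p_positive[[ncp]], neg = probs$p_negative[[ncp]],
             na = probs$p_na[[ncp]])
      p <- c(p, neu = 1 - sum(p))
      for (lin in LINEAGES) {
        rows <- which(lineage == lin)
        if (app[ncp, lin] && length(rows)) {
          draw <- sample(c(1L, -1L, NA_integer_, 0L), length(rows),
                         replace = TRUE, prob = p)
          values[rows, ncp] <- draw
          tallies[[length(tallies) + 1]] <- data.frame(
            ncp_id = ncp, lineage = lin,
            n_positive = sum(draw == 1L, na.rm = TRUE),
            n_negative = sum(draw == -1L, na.rm = TRUE),
            n_neutral = sum(draw == 0L, na.rm = TRUE),
            n_na = sum(is.na(draw)),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(table = relationship_table(species, values, catalog),
         tallies = do.call(rbind, tallies))
  })
}

#' The census-shaped synthetic preset
#'
#' A synthetic table with the real census dimensions: 1816 tracheophytes and
#' 250 vertebrates against the built-in 17-NCP catalog, with exactly 208
#' no-information cells planted at random among the 31,306 applicable cells,
#' so that [count_relationships()] returns (31,098, 31,306) by construction.
#' Sign frequencies follow the generator defaults.
#'
#' @param seed integer seed.
#' @return an `ncp_table`.
#' @export
generate_paper_preset <- function(seed = 1) {
  catalog <- load_catalog()
  spec <- table_generator_spec(n_tracheophytes = 1816, n_vertebrates = 250,
                               p_positive = 0.25, p_negative = 0.05, p_na = 0,
                               seed = seed)
  tab <- generate_table(spec, catalog)$table
  with_seed(seed + 1L, {
    app <- applicability_matrix(tab)
    applicable_cells <- which(app)
    na_cells <- sample(applicable_cells, 208)
    tab$values[na_cells] <- NA_integer_
  })
  tab
}

#' Specification for a synthetic occurrence grid
#'
#' @param nrows,ncols grid dimensions (>= 1 each; a 0-pixel grid is an
#'   error).
#' @param cell_size cell edge length in km (default 1, the census pixel).
#' @param richness `"uniform"` (every pixel gets `richness_range[1]` distinct
#'   species) or `"gradient"` (expected richness increases linearly with row
#'   index from `richness_range[1]` to `richness_range[2]`; draws are
#'   Poisson, clamped to `[1, species pool]`).
#' @param richness_range one value (uniform) or `c(low, high)` (gradient).
#' @param seed integer seed.
#' @return a `grid_generator_spec`.
#' @export
grid_generator_spec <- function(nrows, ncols, cell_size = 1,
                                richness = c("uniform", "gradient"),
                                richness_range = 2, seed = 1) {
  richness <- match.arg(richness)
  if (nrows < 1 || ncols < 1) stop_ncp("grid must have at least one pixel")
  if (richness == "gradient" && length(richness_range) != 2) {
    stop_ncp("gradient richness needs richness_range = c(low, high)")
  }
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 cell_size = cell_size, richness = richness,
                 richness_range = richness_range, seed = seed),
            class = "grid_generator_spec")
}

#' Generate synthetic occurrence records
#'
#' Plants a known per-pixel richness structure: for each pixel a number of
#' distinct species is drawn per the richness model and that many species
#' are sampled (without replacement) from the pool and placed at the pixel
#' centre, with years drawn uniformly in 1970-2020. Rasterizing the records
#' on the matching grid recovers the planted per-pixel richness exactly for
#' the uniform model.
#'
#' @param spec a [grid_generator_spec()].
#' @param species_ids the species pool.
#' @return data.frame `species_id`, `x`, `y`, `year`; attribute `grid` holds
#'   the matching [grid_spec()] (origin at (0, 0)).
#' @export
generate_occurrences <- function(spec, species_ids) {
  stopifnot(inherits(spec, "grid_generator_spec"))
  if (length(species_ids) == 0) stop_ncp("species pool is empty")
  pool <- length(species_ids)
  if (spec$richness == "uniform" && spec$richness_range[1] > pool) {
    stop_ncp("requested richness %d exceeds species pool %d", spec$richness_range[1], pool)
  }
  if (spec$richness == "gradient" && max(spec$richness_range) > pool) {
    stop_ncp("gradient richness ceiling %d exceeds species pool %d",
             max(spec$richness_range), pool)
  }
  g <- grid_spec(0, 0, spec$cell_size, spec$ncols, spec$nrows)
  w <- spec$cell_size
  with_seed(spec$seed, {
    rows <- list()
    for (r in seq_len(spec$nrows)) {
      mean_k <- if (spec$richness == "uniform") {
        spec$richness_range[1]
      } else if (spec$nrows == 1) {
        mean(spec$richness_range)
      } else {
        spec$richness_range[1] + (r - 1) / (spec$nrows - 1) *
          diff(spec$richness_range)
      }
      for (cc in seq_len(spec$ncols)) {
        k <- if (spec$richness == "uniform") {
          as.integer(mean_k)
        } else {
          min(max(stats::rpois(1, mean_k), 1L), pool)
        }
        sp <- sample(species_ids, k)
        b <- cell_bounds(g, r, cc)
        rows[[length(rows) + 1]] <- data.frame(
          species_id = sp,
          x = unname((b["xmin"] + b["xmax"]) / 2),
          y = unname((b["ymin"] + b["ymax"]) / 2),
          year = sample(1970:2020, k, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "grid") <- g
    out
  })
}

#' Generate synthetic reference counts
#'
#' Stands in for bibliometric hit counts (publications per species, weblinks
#' per species) feeding [quartile_threshold()]. The `"heavy_tail"`
#' distribution (rounded log-normal, meanlog 3, sdlog 1.5) mimics real
#' citation-count skew: a few heavily documented species, a long tail of
#' barely mentioned ones, so the strictly-greater-than-Q3 rule flags close
#' to 25% of species. `"uniform"` draws integers in 0-1000.
#'
#' @param n number of species (>= 1).
#' @param distribution `"heavy_tail"` or `"uniform"`.
#' @param seed integer seed.
#' @param species_ids optional ids (default `sp_0001`...).
#' @return data.frame `species_id`, `count`.
#' @export
generate_reference_counts <- function(n, distribution = c("heavy_tail", "uniform"),
                                      seed = 1, species_ids = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 1)
  if (is.null(species_ids)) species_ids <- sprintf("sp_%04d", seq_len(n))
  stopifnot(length(species_ids) == n)
  with_seed(seed, {
    count <- switch(distribution,
      heavy_tail = as.integer(round(stats::rlnorm(n, meanlog = 3, sdlog = 1.5))),
      uniform = sample(0:1000, n, replace = TRUE))
    data.frame(species_id = species_ids, count = count, stringsAsFactors = FALSE)
  })
}
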