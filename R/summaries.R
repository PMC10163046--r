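#' Per-species NCP score summary
#'
#' Computes, for each species, the signed sum of relationship values per NCP
#' category and overall ("cumulated score"), together with the count of
#' positive cells, the signed sum of negative cells (<= 0) and the number of
#' no-information `NA` cells. Both `NA` flavours contribute 0 to every sum;
#' `n_na_<category>` counts `NA` cells among the NCPs applicable to the
#' species' lineage only (not-applicable cells are a lineage constant and are
#' not species information). For every category,
#' `total = positive + negative`, and the grand columns are the sums of the
#' category columns.
#'
#' @param table an `ncp_table`.
#' @param species_id optional single id (or vector of ids) to restrict to;
#'   unknown ids are an error.
#' @return data.frame, one row per species: `species_id`, then
#'   `total_<c>`, `positive_<c>`, `negative_<c>`, `n_na_<c>` for each
#'   category `c` in `material`, `non_material`, `regulating`, then
#'   `grand_total`, `grand_positive`, `grand_negative`, `grand_n_na`.
#' @examples
#' tab <- read_relationship_table(
#'   system.file("extdata", "table1_sample.csv", package = "ncplinkr"),
#'   load_catalog())
#' species_score_summary(tab, "salix_alba")[, c("grand_total", "grand_positive")]
#' @export
species_score_summary <- function(table, species_id = NULL) {
  stopifnot(inherits(table, "ncp_table"))
  if (!is.null(species_id)) {
    missing_ids <- setdiff(species_id, table$species$species_id)
    if (length(missing_ids)) {
      stop_ncp("unknown species_id: %s", paste(missing_ids, collapse = ", "))
    }
  }
  v <- table$values
  app <- applicability_matrix(table)
  cat_of <- table$catalog$category[match(colnames(v), table$catalog$ncp_id)]

  out <- data.frame(species_id = rownames(v), stringsAsFactors = FALSE)
  for (cc in CATEGORIES) {
    cols <- which(cat_of == cc)
    vc <- v[, cols, drop = FALSE]
    ac <- app[, cols, drop = FALSE]
    pos <- rowSums(vc == 1L, na.rm = TRUE)
    neg <- -rowSums(vc == -1L, na.rm = TRUE)
    nna <- rowSums(is.na(vc) & ac)
    out[[paste0("total_", cc)]] <- as.integer(pos + neg)
    out[[paste0("positive_", cc)]] <- as.integer(pos)
    out[[paste0("negative_", cc)]] <- as.integer(neg)
    out[[paste0("n_na_", cc)]] <- as.integer(nna)
  }
  out$grand_total <- out$total_material + out$total_non_material + out$total_regulating
  out$grand_positive <- out$positive_material + out$positive_non_material + out$positive_regulating
  out$grand_negative <- out$negative_material + out$negative_non_material + out$negative_regulating
  out$grand_n_na <- out$n_na_material + out$n_na_non_material + out$n_na_regulating
  rownames(out) <- NULL
  if (!is.null(species_id)) out <- out[match(species_id, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-NCP relationship counts by group
#'
#' For one NCP (or all of them), counts positive, negative, neutral and
#' no-information cells within each species group (lineage or subgroup).
#' Counts are restricted to species whose lineage the NCP applies to, so
#' `n_positive + n_negative + n_neutral + n_na = n_species` (the applicable
#' group size). Percentages (`pct_positive`, `pct_negative`) are relative to
#' `n_species`, rounded half-up to one decimal; they are `NA` for empty
#' groups.
#'
#' @param table an `ncp_table`.
#' @param ncp_id single ncp_id, or `NULL` for all catalog NCPs.
#' @param group_by `"lineage"` (default) or `"subgroup"`.
#' @return data.frame with columns `ncp_id`, `group`, `n_species`,
#'   `n_positive`, `n_negative`, `n_neutral`, `n_na`, `pct_positive`,
#'   `pct_negative`.
#' @export
ncp_summary <- function(table, ncp_id = NULL, group_by = c("lineage", "subgroup")) {
  stopifnot(inherits(table, "ncp_table"))
  group_by <- match.arg(group_by)
  if (is.null(ncp_id)) {
    ncp_id <- table$catalog$ncp_id
  } else if (!all(ncp_id %in% table$catalog$ncp_id)) {
    stop_ncp("unknown ncp_id: %s",
             paste(setdiff(ncp_id, table$catalog$ncp_id), collapse = ", "))
  }
  key <- table$species[[group_by]]
  key[is.na(key)] <- "<unknown>"
  groups <- unique(key)
  app <- applicability_matrix(table)

  rows <- list()
  for (ncp in ncp_id) {
    v <- table$values[, ncp]
    a <- app[, ncp]
    for (g in groups) {
      sel <- key == g & a
      n <- sum(sel)
      npos <- sum(v[sel] == 1L, na.rm = TRUE)
      nneg <- sum(v[sel] == -1L, na.rm = TRUE)
      nneu <- sum(v[sel] == 0L, na.rm = TRUE)
      nna <- sum(is.na(v[sel]))
      rows[[length(rows) + 1]] <- data.frame(
        ncp_id = ncp, group = g, n_species = n,
        n_positive = npos, n_negative = nneg, n_neutral = nneu, n_na = nna,
        pct_positive = if (n > 0) percent_of(npos, n) else NA_real_,
        pct_negative = if (n > 0) percent_of(nneg, n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count reported vs possible relationships
#'
#' A relationship is *possible* for every (species, applicable NCP) pair:
#' `n_possible = sum over lineages of |species| * |applicable NCPs|`. It is
#' *reported* when the cell is filled (not no-information `NA`). For the
#' full census (1816 tracheophytes x 16 + 250 vertebrates x 9) this gives
#' 31,306 possible relationships.
#'
#' @param table an `ncp_table`.
#' @return named integer vector `c(n_reported = , n_possible = )`.
#' @export
count_relationships <- function(table) {
  stopifnot(inherits(table, "ncp_table"))
  app <- applicability_matrix(table)
  n_possible <- sum(app)
  n_no_info <- sum(is.na(table$values) & app)
  c(n_reported = as.integer(n_possible - n_no_info),
    n_possible = as.integer(n_possible))
}

#' Top-scored species
#'
#' Ranks species by the number of reported positive relationships
#' (`grand_positive`, descending), breaking ties by `grand_total`
#' (descending) then `species_id` (lexicographic), and returns the first
#' `n` score-summary rows. Asking for more species than exist returns all.
#'
#' @param table an `ncp_table`.
#' @param lineage optional lineage to restrict to.
#' @param n number of species to return (>= 1).
#' @return data.frame of [species_score_summary()] rows, ranked.
#' @export
top_scored_species <- function(table, lineage = NULL, n = 5) {
  stopifnot(inherits(table, "ncp_table"), n >= 1)
  s <- species_score_summary(table)
  if (!is.null(lineage)) {
    if (!lineage %in% LINEAGES) stop_ncp("unknown lineage '%s'", lineage)
    s <- s[table$species$lineage == lineage, , drop = FALSE]
  }
  ord <- order(-s$grand_positive, -s$grand_total, s$species_id)
  s <- s[ord, , drop = FALSE]
  rownames(s) <- NULL
  utils::head(s, n)
}
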