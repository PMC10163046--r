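#' Species-by-NCP relationship tables
#'
#' The central container of the package: a set of species records plus a
#' species x NCP matrix of signed relationship values. Cells take values
#' `+1` (positive relationship), `0` (neutral), `-1` (negative) or `NA`.
#' An `NA` cell has one of two meanings, fully determined by lineage
#' applicability: if the NCP applies to the species' lineage the cell is
#' "no information" (`NA_no_info`); otherwise it is "not applicable"
#' (`NA_not_applicable`). The two flavours are never stored separately --
#' they are recovered from the catalog, which keeps the matrix a plain
#' integer matrix.
#'
#' @param species data.frame of species metadata. Required columns:
#'   `species_id` (unique), `lineage` (`tracheophyte`/`vertebrate`).
#'   Recognised optional columns: `scientific_name`, `vernacular_en` (and
#'   further `vernacular_*`), `subgroup`, `class`, `order`, `family`,
#'   `iucn_status`, `n_occurrences`, `alien`. Missing optional columns are
#'   filled with `NA`.
#' @param values integer matrix, one row per species (rownames =
#'   `species_id`), one column per catalog NCP (colnames = `ncp_id`),
#'   entries in `{-1, 0, 1, NA}`. Rows/columns are reordered to match
#'   `species`/`catalog`.
#' @param catalog an [ncp_catalog].
#' @return an object of class `ncp_table`: a list with elements `species`,
#'   `values`, `catalog`.
#' @seealso [read_relationship_table()], [validate_table()],
#'   [species_score_summary()]
#' @export
relationship_table <- function(species, values, catalog) {
  stopifnot(inherits(catalog, "ncp_catalog"))
  species <- as.data.frame(species)
  for (col in c("species_id", "lineage")) {
    if (!col %in% names(species)) stop_ncp("species table lacks column '%s'", col)
  }
  species$species_id <- as.character(species$species_id)
  species$lineage <- as.character(species$lineage)
  dup <- species$species_id[duplicated(species$species_id)]
  if (length(dup)) stop_ncp("duplicate species_id: %s", paste(unique(dup), collapse = ", "))
  bad_lin <- setdiff(unique(species$lineage), LINEAGES)
  if (length(bad_lin)) stop_ncp("unknown lineage value(s): %s", paste(bad_lin, collapse = ", "))

  optional <- c("scientific_name", "vernacular_en", "subgroup", "class", "order",
                "family", "iucn_status", "n_occurrences", "alien")
  for (col in optional) if (!col %in% names(species)) species[[col]] <- NA
  if (!is.logical(species$alien)) species$alien <- as.logical(species$alien)
  if (!is.numeric(species$n_occurrences)) {
    species$n_occurrences <- suppressWarnings(as.numeric(species$n_occurrences))
  }

  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_ncp("values matrix must carry species_id rownames and ncp_id colnames")
  }
  missing_sp <- setdiff(species$species_id, rownames(values))
  if (length(missing_sp)) stop_ncp("values matrix lacks rows for: %s",
                                   paste(missing_sp, collapse = ", "))
  missing_ncp <- setdiff(catalog$ncp_id, colnames(values))
  if (length(missing_ncp)) stop_ncp("values matrix lacks NCP column(s): %s",
                                    paste(missing_ncp, collapse = ", "))
  extra_ncp <- setdiff(colnames(values), catalog$ncp_id)
  if (length(extra_ncp)) stop_ncp("unknown NCP column(s): %s", paste(extra_ncp, collapse = ", "))
  values <- values[species$species_id, catalog$ncp_id, drop = FALSE]
  storage.mode(values) <- "integer"

  rownames(species) <- NULL
  structure(list(species = species, values = values, catalog = catalog),
            class = "ncp_table")
}

#' @export
print.ncp_table <- function(x, ...) {
  counts <- table(factor(x$species$lineage, levels = LINEAGES))
  rel <- count_relationships(x)
  cat(sprintf("<ncp_table> %d species (%d tracheophytes, %d vertebrates) x %d NCPs\n",
              nrow(x$species), counts[["tracheophyte"]], counts[["vertebrate"]],
              nrow(x$catalog)))
  cat(sprintf("  reported relationships: %d of %d possible\n",
              rel[["n_reported"]], rel[["n_possible"]]))
  invisible(x)
}

# species x ncp logical matrix: TRUE where the NCP applies to the row species.
applicability_matrix <- function(table) {
  app <- lineage_applicability(table$catalog)   # ncp x lineage
  m <- t(app)[table$species$lineage, , drop = FALSE]
  dimnames(m) <- dimnames(table$values)
  m
}

#' NA flavour of each cell
#'
#' @param table an `ncp_table`.
#' @return character matrix: `"no_info"` / `"not_applicable"` for `NA` cells,
#'   `NA` for filled cells.
#' @export
na_flavor <- function(table) {
  stopifnot(inherits(table, "ncp_table"))
  app <- applicability_matrix(table)
  out <- matrix(NA_character_, nrow(table$values), ncol(table$values),
                dimnames = dimnames(table$values))
  isna <- is.na(table$values)
  out[isna & app] <- "no_info"
  out[isna & !app] <- "not_applicable"
  out
}

metadata_columns <- c("species_id", "scientific_name", "vernacular_en", "lineage",
                      "subgroup", "class", "order", "family", "iucn_status",
                      "n_occurrences", "alien")

#' Read a relationship table from CSV
#'
#' The CSV carries the species metadata columns (`species_id`,
#' `scientific_name`, `vernacular_en`, `lineage`, `subgroup`, `class`,
#' `order`, `family`, `iucn_status`, `n_occurrences`, `alien`) followed by
#' one column per catalog `ncp_id`. Cell encoding: `1`, `0`, `-1`, and the
#' empty string for `NA` (no-information where the NCP is applicable,
#' not-applicable otherwise). The table is validated on read and the read
#' fails if [validate_table()] reports any violation.
#'
#' @param path CSV path.
#' @param catalog an [ncp_catalog].
#' @return an `ncp_table`.
#' @export
read_relationship_table <- function(path, catalog) {
  stopifnot(inherits(catalog, "ncp_catalog"))
  if (!file.exists(path)) stop_ncp("relationship table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  if (nrow(df) == 0) stop_ncp("relationship table %s has no rows", path)
  for (col in c("species_id", "lineage")) {
    if (!col %in% names(df)) stop_ncp("%s: missing required column '%s'", path, col)
  }
  ncp_cols <- setdiff(names(df), metadata_columns)
  unknown <- setdiff(ncp_cols, catalog$ncp_id)
  if (length(unknown)) stop_ncp("%s: unknown NCP column(s): %s", path,
                                paste(unknown, collapse = ", "))
  missing <- setdiff(catalog$ncp_id, ncp_cols)
  if (length(missing)) stop_ncp("%s: missing NCP column(s): %s", path,
                                paste(missing, collapse = ", "))

  values <- matrix(NA_integer_, nrow(df), length(catalog$ncp_id),
                   dimnames = list(df$species_id, catalog$ncp_id))
  for (ncp in catalog$ncp_id) {
    raw <- trimws(df[[ncp]])
    raw[!nzchar(raw)] <- NA
    ok <- is.na(raw) | raw %in% c("1", "+1", "0", "-1")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop_ncp("%s: row %d, column '%s': value '%s' is not one of 1/0/-1/empty",
               path, i, ncp, raw[i])
    }
    raw[raw == "+1"] <- "1"
    values[, ncp] <- as.integer(raw)
  }
  species <- df[intersect(metadata_columns, names(df))]
  if ("alien" %in% names(species)) species$alien <- toupper(species$alien) %in% c("TRUE", "T", "1")
  tab <- relationship_table(species, values, catalog)
  report <- validate_table(tab)
  if (nrow(report) > 0) {
    stop_ncp("%s: table is invalid (%d violation(s)); first: %s / %s: %s",
             path, nrow(report), report$species_id[1], report$ncp_id[1], report$problem[1])
  }
  tab
}

#' Write a relationship table to CSV
#'
#' Inverse of [read_relationship_table()]: `+1` as `1`, `-1` as `-1`, `0` as
#' `0`, both `NA` flavours as the empty string.
#'
#' @param table an `ncp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relationship_table <- function(table, path) {
  stopifnot(inherits(table, "ncp_table"))
  sp <- table$species[intersect(metadata_columns, names(table$species))]
  vals <- as.data.frame(table$values)
  vals[] <- lapply(vals, function(v) ifelse(is.na(v), "", as.character(v)))
  out <- cbind(sp, vals)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Validate a relationship table
#'
#' Checks every table invariant and returns a report, one row per violation:
#' values outside `{-1, 0, 1, NA}` (screened at construction), non-`NA`
#' values in lineage-inapplicable cells, `-1` under NCPs that disallow
#' negative values, and subgroup/lineage inconsistencies. The table is valid
#' iff the report is empty.
#'
#' @param table an `ncp_table`.
#' @return data.frame with columns `species_id`, `ncp_id`, `problem`.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "ncp_table"))
  problems <- list()
  add <- function(sp, ncp, msg) {
    problems[[length(problems) + 1]] <<- data.frame(
      species_id = sp, ncp_id = ncp, problem = msg, stringsAsFactors = FALSE)
  }
  v <- table$values
  app <- applicability_matrix(table)

  bad_val <- which(!is.na(v) & !(v %in% c(-1L, 0L, 1L)), arr.ind = TRUE)
  for (k in seq_len(nrow(bad_val))) {
    add(rownames(v)[bad_val[k, 1]], colnames(v)[bad_val[k, 2]],
        sprintf("value %d outside {-1,0,1,NA}", v[bad_val[k, , drop = FALSE]]))
  }
  not_app <- which(!is.na(v) & !app, arr.ind = TRUE)
  for (k in seq_len(nrow(not_app))) {
    add(rownames(v)[not_app[k, 1]], colnames(v)[not_app[k, 2]],
        "non-NA value for an NCP not applicable to this lineage")
  }
  neg_ok <- table$catalog$negative_allowed[match(colnames(v), table$catalog$ncp_id)]
  bad_neg <- which(!is.na(v) & v == -1L &
                     matrix(!neg_ok, nrow(v), ncol(v), byrow = TRUE), arr.ind = TRUE)
  for (k in seq_len(nrow(bad_neg))) {
    add(rownames(v)[bad_neg[k, 1]], colnames(v)[bad_neg[k, 2]],
        "negative value under an NCP with negative_allowed = FALSE")
  }
  sp <- table$species
  has_sub <- !is.na(sp$subgroup)
  for (i in which(has_sub)) {
    ok_set <- if (sp$lineage[i] == "tracheophyte") PLANT_SUBGROUPS else ANIMAL_SUBGROUPS
    if (!sp$subgroup[i] %in% ok_set) {
      add(sp$species_id[i], NA_character_,
          sprintf("subgroup '%s' inconsistent with lineage '%s'",
                  sp$subgroup[i], sp$lineage[i]))
    }
  }
  if (length(problems) == 0) {
    return(data.frame(species_id = character(), ncp_id = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, problems)
}

#' Filter species records
#'
#' Retains species with at least `min_occurrences` occurrence records
#' (inclusive bound: "at least 10 occurrences" keeps a count of exactly 10)
#' and, optionally, drops alien species. Input order is preserved and the
#' operation is idempotent.
#'
#' @param x a species data.frame (with `n_occurrences`, `alien`) or an
#'   `ncp_table` (filtered row-wise, matrix kept in step).
#' @param min_occurrences minimum occurrence count (default 10, the census
#'   selection rule for Switzerland 1970-2020).
#' @param exclude_alien drop species flagged alien (default TRUE).
#' @return object of the same class as `x`, filtered.
#' @export
filter_species <- function(x, min_occurrences = 10, exclude_alien = TRUE) {
  stopifnot(is.numeric(min_occurrences), min_occurrences >= 0)
  if (inherits(x, "ncp_table")) {
    keep <- species_keep(x$species, min_occurrences, exclude_alien)
    return(relationship_table(x$species[keep, , drop = FALSE],
                              x$values[keep, , drop = FALSE], x$catalog))
  }
  x[species_keep(x, min_occurrences, exclude_alien), , drop = FALSE]
}

species_keep <- function(sp, min_occurrences, exclude_alien) {
  n <- sp$n_occurrences
  if (is.null(n)) stop_ncp("species records lack 'n_occurrences'")
  alien <- sp$alien
  if (is.null(alien)) alien <- rep(FALSE, nrow(sp))
  alien[is.na(alien)] <- FALSE
  keep <- !is.na(n) & n >= min_occurrences
  if (exclude_alien) keep <- keep & !alien
  keep
}

#' Merge synonymous species
#'
#' Applies a synonym map (old id -> canonical id) and combines the cells of
#' merged species cell-wise. Under the default `"information"` policy a
#' non-`NA` value beats `NA` and equal non-`NA` values are kept; two
#' *different* non-`NA` values are a merge error (taxonomic aggregation is
#' performed before scoring, so conflicts signal dirty data). The
#' `"dominance"` policy instead resolves conflicts by `-1 > +1 > 0`.
#' Occurrence counts of merged taxa are summed; other metadata is taken from
#' the first (canonical-ordered) record.
#'
#' @param table an `ncp_table`.
#' @param map named character vector: `names(map)` are ids to retire,
#'   values are the canonical ids they merge into.
#' @param policy `"information"` (default) or `"dominance"`.
#' @return a merged `ncp_table` with one row per canonical id.
#' @export
apply_synonym_map <- function(table, map, policy = c("information", "dominance")) {
  stopifnot(inherits(table, "ncp_table"))
  policy <- match.arg(policy)
  ids <- table$species$species_id
  unknown <- setdiff(names(map), ids)
  if (length(unknown)) {
    warning(sprintf("synonym map names absent from table ignored: %s",
                    paste(unknown, collapse = ", ")))
    map <- map[!names(map) %in% unknown]
  }
  canonical <- ids
  canonical[match(names(map), ids)] <- unname(map)

  groups <- split(seq_along(ids), canonical)
  # keep first-appearance order of canonical ids
  groups <- groups[order(vapply(groups, min, integer(1)))]

  merged_values <- matrix(NA_integer_, length(groups), ncol(table$values),
                          dimnames = list(names(groups), colnames(table$values)))
  merged_species <- table$species[vapply(groups, min, integer(1)), , drop = FALSE]
  merged_species$species_id <- names(groups)
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    merged_species$n_occurrences[g] <- sum(table$species$n_occurrences[rows], na.rm = TRUE)
    for (j in seq_len(ncol(table$values))) {
      vals <- table$values[rows, j]
      nn <- unique(vals[!is.na(vals)])
      merged_values[g, j] <- if (length(nn) == 0) {
        NA_integer_
      } else if (length(nn) == 1) {
        nn
      } else if (policy == "dominance") {
        if (-1L %in% nn) -1L else if (1L %in% nn) 1L else 0L
      } else {
        stop_ncp("conflicting values {%s} while merging '%s' at NCP '%s'",
                 paste(sort(nn), collapse = ","), names(groups)[g],
                 colnames(table$values)[j])
      }
    }
  }
  relationship_table(merged_species, merged_values, table$catalog)
}
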