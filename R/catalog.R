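#' NCP catalogs
#'
#' An NCP catalog describes the set of Nature's Contributions to People
#' (ecosystem services in the CICES V5.1 sense) against which species are
#' scored. Each entry carries a stable `ncp_id`, a human-readable label, a
#' category (`material`, `non_material` or `regulating`), the lineages the
#' NCP applies to (`tracheophyte`, `vertebrate` or both), whether a negative
#' relationship is permitted, and the evidence sources used to document it
#' (`references`, `expert`, `analytics`; metadata only, never gating any
#' computation).
#'
#' The built-in catalog (`load_catalog("builtin")`) holds the 17 NCPs of the
#' Swiss Alps species-NCP census: 16 applicable to tracheophytes, 9 to
#' vertebrates, 8 shared. Negative values are disallowed for solid wood,
#' burned wood, mellifera use, decontamination, hedge for crop yield, and all
#' non-material NCPs.
#'
#' @param x a data.frame with columns `ncp_id`, `label`, `category`,
#'   `applicable_lineages` (semicolon-separated), `negative_allowed`
#'   (logical), `sources` (semicolon-separated).
#' @return an `ncp_catalog` object (a validated data.frame).
#' @export
ncp_catalog <- function(x) {
  required <- c("ncp_id", "label", "category", "applicable_lineages",
                "negative_allowed", "sources")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop_ncp("catalog is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[required]
  x$ncp_id <- as.character(x$ncp_id)
  x$label <- as.character(x$label)
  x$category <- as.character(x$category)
  x$applicable_lineages <- as.character(x$applicable_lineages)
  x$negative_allowed <- as.logical(x$negative_allowed)
  x$sources <- as.character(x$sources)

  if (nrow(x) == 0) stop_ncp("catalog has no rows")
  dup <- x$ncp_id[duplicated(x$ncp_id)]
  if (length(dup)) stop_ncp("duplicate ncp_id: %s", paste(unique(dup), collapse = ", "))

  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    if (is.na(row$ncp_id) || !nzchar(row$ncp_id)) {
      stop_ncp("row %d: empty ncp_id", i)
    }
    if (!row$category %in% CATEGORIES) {
      stop_ncp("row %d (%s): category '%s' is not one of %s",
               i, row$ncp_id, row$category, paste(CATEGORIES, collapse = "/"))
    }
    lin <- split_tokens(row$applicable_lineages)
    if (length(lin) == 0 || !all(lin %in% LINEAGES)) {
      stop_ncp("row %d (%s): applicable_lineages must be a non-empty subset of %s",
               i, row$ncp_id, paste(LINEAGES, collapse = "/"))
    }
    if (is.na(row$negative_allowed)) {
      stop_ncp("row %d (%s): negative_allowed must be TRUE or FALSE", i, row$ncp_id)
    }
    if (row$category == "non_material" && row$negative_allowed) {
      stop_ncp("row %d (%s): non-material NCPs cannot allow negative values",
               i, row$ncp_id)
    }
    src <- split_tokens(row$sources)
    if (!all(src %in% SOURCES)) {
      stop_ncp("row %d (%s): sources must be a subset of %s",
               i, row$ncp_id, paste(SOURCES, collapse = "/"))
    }
  }
  rownames(x) <- NULL
  class(x) <- c("ncp_catalog", "data.frame")
  x
}

split_tokens <- function(s) {
  out <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- trimws(out)
  out[nzchar(out)]
}

#' Load an NCP catalog
#'
#' @param source either the token `"builtin"` (the packaged 17-NCP catalog)
#'   or a path to a catalog CSV (columns as in [ncp_catalog()]).
#' @return an `ncp_catalog`.
#' @examples
#' cat17 <- load_catalog()
#' nrow(cat17) # 17
#' @export
load_catalog <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    source <- system.file("extdata", "ncp_catalog.csv", package = "ncplinkr")
  }
  if (!file.exists(source)) stop_ncp("catalog file not found: %s", source)
  df <- tryCatch(
    utils::read.csv(source, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_ncp("cannot parse catalog file %s: %s", source, conditionMessage(e))
  )
  if (nrow(df) == 0) stop_ncp("catalog file %s has no rows", source)
  ncp_catalog(df)
}

#' Write an NCP catalog to CSV
#'
#' Round-trips through [load_catalog()].
#'
#' @param catalog an `ncp_catalog`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "ncp_catalog"))
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' NCP ids applicable to a lineage
#'
#' @param catalog an `ncp_catalog`.
#' @param lineage `"tracheophyte"` or `"vertebrate"`.
#' @return character vector of ncp_ids, in catalog order.
#' @examples
#' length(applicability_mask(load_catalog(), "tracheophyte")) # 16
#' @export
applicability_mask <- function(catalog, lineage) {
  stopifnot(inherits(catalog, "ncp_catalog"))
  if (length(lineage) != 1 || !lineage %in% LINEAGES) {
    stop_ncp("unknown lineage '%s'; expected one of %s",
             paste(lineage, collapse = ","), paste(LINEAGES, collapse = "/"))
  }
  keep <- vapply(catalog$applicable_lineages,
                 function(s) lineage %in% split_tokens(s), logical(1))
  catalog$ncp_id[keep]
}

# Logical matrix (lineage x ncp) of applicability, used internally.
lineage_applicability <- function(catalog) {
  out <- sapply(LINEAGES, function(l) catalog$ncp_id %in% applicability_mask(catalog, l))
  rownames(out) <- catalog$ncp_id
  out
}
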