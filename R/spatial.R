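#' Regular grid specification
#'
#' Defines the analysis raster: a regular grid of square cells in a planar,
#' km-compatible projected coordinate system. Cells are half-open intervals
#' `[x0 + (c-1) w, x0 + c w) x [ ... )` so a point on a cell's lower-left
#' corner belongs to that cell. `pixel_id` is `"<row>_<col>"` with row 1 the
#' northernmost row (raster convention, top-left origin); `(x0, y0)` is the
#' lower-left corner of the whole grid.
#'
#' @param x0,y0 lower-left corner coordinates (km).
#' @param cell_size cell edge length (km); nominal cell area is
#'   `cell_size^2` km^2.
#' @param ncols,nrows grid dimensions (>= 1).
#' @param boundary optional WKT `POLYGON` string (outer ring plus optional
#'   holes) used to clip per-cell areas: border pixels get their clipped
#'   area, cells wholly outside are dropped.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(x0, y0, cell_size, ncols, nrows, boundary = NULL) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop_ncp("cell_size must be a positive number")
  }
  if (ncols < 1 || nrows < 1) stop_ncp("grid must have at least one row and column")
  if (!is.null(boundary)) boundary <- parse_wkt_polygon(boundary)
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size,
                 ncols = as.integer(ncols), nrows = as.integer(nrows),
                 boundary = boundary),
            class = "grid_spec")
}

# --- minimal planar polygon support (no geometry package in the stack) ------

# WKT "POLYGON ((x y, ...), (hole ...))" -> list of rings (2-col matrices).
parse_wkt_polygon <- function(wkt) {
  stopifnot(is.character(wkt), length(wkt) == 1)
  s <- trimws(wkt)
  if (!grepl("^POLYGON", s, ignore.case = TRUE)) stop_ncp("boundary must be a WKT POLYGON")
  body <- sub("^POLYGON\\s*\\(", "", s, ignore.case = TRUE)
  body <- sub("\\)\\s*$", "", body)
  rings_txt <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1]]
  if (length(rings_txt) == 0) stop_ncp("cannot parse WKT polygon: %s", wkt)
  lapply(rings_txt, function(r) {
    r <- gsub("[()]", "", r)
    pts <- strsplit(trimws(strsplit(r, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
    if (anyNA(m) || nrow(m) < 4) stop_ncp("malformed WKT ring: %s", r)
    m
  })
}

# Shoelace area (absolute) of a closed or open ring.
ring_area <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clip of a ring against an axis-aligned rectangle.
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  n <- nrow(ring)
  if (ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2]) ring <- ring[-n, , drop = FALSE]
  edges <- list(
    list(inside = function(p) p[1] >= xmin,
         isect = function(a, b) { t <- (xmin - a[1]) / (b[1] - a[1]); c(xmin, a[2] + t * (b[2] - a[2])) }),
    list(inside = function(p) p[1] <= xmax,
         isect = function(a, b) { t <- (xmax - a[1]) / (b[1] - a[1]); c(xmax, a[2] + t * (b[2] - a[2])) }),
    list(inside = function(p) p[2] >= ymin,
         isect = function(a, b) { t <- (ymin - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), ymin) }),
    list(inside = function(p) p[2] <= ymax,
         isect = function(a, b) { t <- (ymax - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), ymax) })
  )
  poly <- ring
  for (e in edges) {
    if (nrow(poly) == 0) return(poly)
    out <- list()
    m <- nrow(poly)
    for (i in seq_len(m)) {
      a <- poly[i, ]; b <- poly[if (i == m) 1 else i + 1, ]
      ain <- e$inside(a); bin <- e$inside(b)
      if (ain) out[[length(out) + 1]] <- a
      if (xor(ain, bin)) out[[length(out) + 1]] <- e$isect(a, b)
    }
    poly <- if (length(out)) do.call(rbind, out) else matrix(numeric(0), 0, 2)
  }
  poly
}

# Area of (polygon with holes) intersected with a rectangle.
clipped_cell_area <- function(rings, xmin, xmax, ymin, ymax) {
  outer <- ring_area(clip_ring_rect(rings[[1]], xmin, xmax, ymin, ymax))
  holes <- 0
  if (length(rings) > 1) {
    holes <- sum(vapply(rings[-1], function(r)
      ring_area(clip_ring_rect(r, xmin, xmax, ymin, ymax)), numeric(1)))
  }
  max(outer - holes, 0)
}

cell_bounds <- function(spec, row, col) {
  w <- spec$cell_size
  xmin <- spec$x0 + (col - 1) * w
  ymax <- spec$y0 + (spec$nrows - row + 1) * w
  c(xmin = xmin, xmax = xmin + w, ymin = ymax - w, ymax = ymax)
}

#' Rasterize occurrence records onto a grid
#'
#' Assigns each occurrence record to the grid cell containing its point
#' (half-open cells: a point on the lower-left corner belongs to the cell)
#' and collects the *distinct* species observed per pixel -- duplicate
#' observations of a species in a pixel count once. Records outside the grid
#' extent (or in cells clipped away by the boundary) are dropped and counted
#' in the `dropped` attribute. Cell areas are the nominal `cell_size^2`, or
#' the boundary-clipped area when the grid spec has a boundary; cells with
#' zero clipped area are removed from the grid.
#'
#' @param records data.frame with columns `species_id`, `x`, `y` and
#'   optionally `year`.
#' @param spec a [grid_spec()].
#' @param species_filter optional character vector; records of other species
#'   are dropped (counted separately in the report).
#' @param year_range optional `c(min, max)`; records outside are dropped.
#' @return an `occurrence_grid`: list with `spec`, `pixels` (data.frame
#'   `pixel_id`, `row`, `col`, `area_km2`), `species` (named list of
#'   character vectors per pixel_id), and attribute `dropped` (named counts).
#' @export
rasterize_occurrences <- function(records, spec, species_filter = NULL,
                                  year_range = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  for (col in c("species_id", "x", "y")) {
    if (!col %in% names(records)) stop_ncp("occurrence records lack column '%s'", col)
  }
  n0 <- nrow(records)
  dropped <- c(out_of_extent = 0L, filtered_species = 0L, out_of_years = 0L)
  if (!is.null(species_filter)) {
    keep <- records$species_id %in% species_filter
    dropped[["filtered_species"]] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  if (!is.null(year_range) && "year" %in% names(records)) {
    keep <- !is.na(records$year) & records$year >= year_range[1] & records$year <= year_range[2]
    dropped[["out_of_years"]] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  w <- spec$cell_size
  col <- floor((records$x - spec$x0) / w) + 1
  row_from_bottom <- floor((records$y - spec$y0) / w) + 1
  row <- spec$nrows - row_from_bottom + 1
  inside <- col >= 1 & col <= spec$ncols & row >= 1 & row <= spec$nrows

  pixels <- expand.grid(row = seq_len(spec$nrows), col = seq_len(spec$ncols))
  pixels <- pixels[order(pixels$row, pixels$col), , drop = FALSE]
  pixels$pixel_id <- paste(pixels$row, pixels$col, sep = "_")
  if (is.null(spec$boundary)) {
    pixels$area_km2 <- w^2
  } else {
    pixels$area_km2 <- vapply(seq_len(nrow(pixels)), function(i) {
      b <- cell_bounds(spec, pixels$row[i], pixels$col[i])
      clipped_cell_area(spec$boundary, b["xmin"], b["xmax"], b["ymin"], b["ymax"])
    }, numeric(1))
    pixels <- pixels[pixels$area_km2 > 0, , drop = FALSE]
  }
  pid <- ifelse(inside, paste(row, col, sep = "_"), NA)
  pid[!is.na(pid) & !(pid %in% pixels$pixel_id)] <- NA  # clipped-away cells
  dropped[["out_of_extent"]] <- sum(is.na(pid))
  keep <- !is.na(pid)

  species <- lapply(stats::setNames(pixels$pixel_id, pixels$pixel_id),
                    function(p) character(0))
  if (any(keep)) {
    by_pix <- split(records$species_id[keep], pid[keep])
    for (p in names(by_pix)) species[[p]] <- sort(unique(by_pix[[p]]))
  }
  pixels <- pixels[, c("pixel_id", "row", "col", "area_km2")]
  rownames(pixels) <- NULL
  structure(list(spec = spec, pixels = pixels, species = species),
            class = "occurrence_grid",
            dropped = dropped, n_records = n0)
}

#' Construct an occurrence grid directly
#'
#' Low-level constructor for tests and for pre-gridded data: supply the
#' pixel table and per-pixel species sets yourself.
#'
#' @param pixels data.frame `pixel_id`, `row`, `col`, `area_km2` (> 0).
#' @param species named list (by `pixel_id`) of character vectors.
#' @param spec optional [grid_spec()] (needed for raster export).
#' @return an `occurrence_grid`.
#' @export
occurrence_grid <- function(pixels, species, spec = NULL) {
  stopifnot(all(c("pixel_id", "row", "col", "area_km2") %in% names(pixels)))
  if (any(duplicated(pixels$pixel_id))) stop_ncp("duplicate pixel_id")
  if (any(pixels$area_km2 <= 0)) stop_ncp("area_km2 must be positive")
  missing_pix <- setdiff(pixels$pixel_id, names(species))
  species[missing_pix] <- list(character(0))
  structure(list(spec = spec, pixels = pixels,
                 species = species[pixels$pixel_id]),
            class = "occurrence_grid")
}

#' Per-pixel NCP index
#'
#' For each pixel and NCP category, the index is the mean per-species
#' category score of the species observed in the pixel, scaled by pixel
#' area:
#' \deqn{I_c(p) = \frac{\sum_{s \in S(p)} \mathrm{total}_c(s)}{|S(p)|} \times \mathrm{area}(p)}
#' where `total_c(s)` is the signed category score from
#' [species_score_summary()] (NA cells contribute 0). Pixels with no
#' observed species have an undefined index (`NA`, not 0 -- an all-neutral
#' community has a meaningful index of 0). By default every observed species
#' counts in the denominator, including species whose category cells are all
#' `NA`; set `denominator = "scored"` to count only species with at least one
#' filled cell in the category.
#'
#' @param grid an `occurrence_grid`.
#' @param table an `ncp_table`; every species occurring in the grid must be
#'   present in it.
#' @param category one or more of `material`, `non_material`, `regulating`
#'   (default: all three).
#' @param denominator `"observed"` (default) or `"scored"`.
#' @return data.frame `pixel_id`, `row`, `col`, `area_km2`, `n_species`,
#'   and one `index_<category>` column per requested category; attributes
#'   `categories`, `denominator`, `table_checksum` (and `spec` when the grid
#'   has one) feed the export metadata.
#' @export
compute_ncp_index <- function(grid, table, category = CATEGORIES,
                              denominator = c("observed", "scored")) {
  stopifnot(inherits(grid, "occurrence_grid"), inherits(table, "ncp_table"))
  denominator <- match.arg(denominator)
  category <- match.arg(category, CATEGORIES, several.ok = TRUE)
  observed <- unique(unlist(grid$species, use.names = FALSE))
  missing_sp <- setdiff(observed, table$species$species_id)
  if (length(missing_sp)) {
    stop_ncp("grid species absent from relationship table: %s",
             paste(missing_sp, collapse = ", "))
  }
  scores <- species_score_summary(table)
  rownames(scores) <- scores$species_id

  out <- grid$pixels
  out$n_species <- vapply(grid$species[out$pixel_id], length, integer(1))
  for (cc in category) {
    tot <- stats::setNames(scores[[paste0("total_", cc)]], scores$species_id)
    n_na <- stats::setNames(scores[[paste0("n_na_", cc)]], scores$species_id)
    n_applicable <- applicable_per_category(table)[, cc]
    idx <- vapply(seq_len(nrow(out)), function(i) {
      sp <- grid$species[[out$pixel_id[i]]]
      if (length(sp) == 0) return(NA_real_)
      denom <- if (denominator == "observed") {
        length(sp)
      } else {
        sum(n_na[sp] < n_applicable[sp])
      }
      if (denom == 0) return(NA_real_)
      sum(tot[sp]) / denom * out$area_km2[i]
    }, numeric(1))
    out[[paste0("index_", cc)]] <- idx
  }
  attr(out, "categories") <- category
  attr(out, "denominator") <- denominator
  attr(out, "table_checksum") <- digest::digest(table$values)
  attr(out, "spec") <- grid$spec
  out
}

# Per-species number of applicable NCPs in each category.
applicable_per_category <- function(table) {
  app <- applicability_matrix(table)
  cat_of <- table$catalog$category[match(colnames(app), table$catalog$ncp_id)]
  out <- vapply(CATEGORIES,
                function(cc) rowSums(app[, cat_of == cc, drop = FALSE]),
                numeric(nrow(app)))
  matrix(out, nrow = nrow(app), dimnames = list(rownames(app), CATEGORIES))
}

#' Write an NCP index grid
#'
#' Two formats:
#' * `"csv"`: the full index table, plus a sidecar `<path>.meta.json`
#'   recording categories, denominator setting and the relationship-table
#'   checksum. Round-trips through [read_index_grid()].
#' * `"asc"`: one ESRI ASCII grid per call (plain-text raster readable by
#'   GDAL/QGIS), single category, `NODATA_value -9999` for undefined pixels;
#'   requires the grid to carry a [grid_spec()]. Metadata sidecar as above.
#'
#' @param index output of [compute_ncp_index()].
#' @param path output file path.
#' @param format `"csv"` or `"asc"`.
#' @param category category to write (asc only; default the first computed).
#' @return `path`, invisibly.
#' @export
write_index_grid <- function(index, path, format = c("csv", "asc"),
                             category = NULL) {
  format <- match.arg(format)
  meta <- list(categories = attr(index, "categories"),
               denominator = attr(index, "denominator"),
               table_checksum = attr(index, "table_checksum"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(index), path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    spec <- attr(index, "spec")
    if (is.null(spec)) stop_ncp("asc export needs a grid_spec attached to the index")
    category <- category %||% attr(index, "categories")[1]
    colname <- paste0("index_", category)
    if (!colname %in% names(index)) stop_ncp("category '%s' not present in index", category)
    m <- matrix(NA_real_, spec$nrows, spec$ncols)
    m[cbind(index$row, index$col)] <- index[[colname]]
    m[is.na(m)] <- -9999
    lines <- c(
      sprintf("ncols %d", spec$ncols),
      sprintf("nrows %d", spec$nrows),
      sprintf("xllcorner %.10g", spec$x0),
      sprintf("yllcorner %.10g", spec$y0),
      sprintf("cellsize %.10g", spec$cell_size),
      "NODATA_value -9999",
      apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                           digits = 15), collapse = " "))
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
    meta$category <- category
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read back a CSV index grid
#'
#' @param path CSV written by [write_index_grid()].
#' @return data.frame with metadata attributes restored from the sidecar.
#' @export
read_index_grid <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "categories") <- meta$categories
    attr(out, "denominator") <- meta$denominator
    attr(out, "table_checksum") <- meta$table_checksum
  }
  out
}
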