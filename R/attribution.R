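#' Membership-list attribution
#'
#' The simplest attribution rule: species on a curated list (e.g. the Swiss
#' crop-wild-relative list, the Emerald list, a toxic-species list) receive
#' `value_if_member` (+1 or -1), everyone else receives a neutral 0. Members
#' absent from the species set are ignored with a warning.
#'
#' @param species character vector of species ids to score.
#' @param member_list character vector of listed species ids.
#' @param value_if_member `+1` (e.g. crop wild relatives) or `-1`
#'   (e.g. toxic species under the wild-food rule).
#' @return data.frame `species_id`, `value`, one row per input species, in
#'   input order.
#' @export
assign_membership <- function(species, member_list, value_if_member = 1L) {
  stopifnot(is.character(species), length(species) > 0)
  if (!value_if_member %in% c(1L, -1L)) {
    stop_ncp("value_if_member must be +1 or -1, got %s", value_if_member)
  }
  unknown <- setdiff(member_list, species)
  if (length(unknown)) {
    warning(sprintf("member list ids absent from species set ignored: %s",
                    paste(unknown, collapse = ", ")))
  }
  data.frame(species_id = species,
             value = ifelse(species %in% member_list, as.integer(value_if_member), 0L),
             stringsAsFactors = FALSE)
}

#' Third-quartile thresholding of reference counts
#'
#' Converts reference counts (publication hits, weblink hits) into cell
#' values: species whose count is *strictly greater* than the third quartile
#' (Q3) of the count distribution receive +1, all others 0. Q3 is computed
#' by linear interpolation between order statistics
#' (`stats::quantile(type = 7)`, index `h = 0.75 * (n - 1)`); the convention
#' is configurable via `type` and recorded in the result's attributes. With
#' a strictly-greater rule, ties at Q3 are never flagged, so between 0 and
#' `ceiling(n / 2)` species are flagged for any input. An optional grouping
#' key (e.g. lineage) computes the quartile within each group separately.
#'
#' @param counts data.frame with columns `species_id` and `count`
#'   (non-negative), or a named numeric vector.
#' @param group optional vector (same length) of group labels; the threshold
#'   is computed per group.
#' @param type quantile algorithm passed to [stats::quantile()] (default 7).
#' @return data.frame `species_id`, `count`, `group` (if given), `q3`,
#'   `value` (+1 or 0), with attribute `quantile_type`.
#' @examples
#' quartile_threshold(c(a = 1, b = 2, c = 3, d = 100)) # Q3 = 27.25, only d flagged
#' @export
quartile_threshold <- function(counts, group = NULL, type = 7) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- data.frame(species_id = names(counts), count = unname(counts),
                         stringsAsFactors = FALSE)
  }
  if (!is.data.frame(counts) || !all(c("species_id", "count") %in% names(counts))) {
    stop_ncp("counts must be a data.frame with species_id and count, or a named vector")
  }
  if (nrow(counts) == 0) stop_ncp("counts table is empty")
  if (any(is.na(counts$count)) || any(counts$count < 0)) {
    stop_ncp("counts must be non-negative and non-missing")
  }
  if (is.null(group)) group <- rep("all", nrow(counts))
  if (length(group) != nrow(counts)) stop_ncp("group must match counts length")

  q3 <- ave(counts$count, group,
            FUN = function(x) stats::quantile(x, 0.75, type = type, names = FALSE))
  out <- data.frame(species_id = counts$species_id,
                    count = counts$count,
                    group = group,
                    q3 = q3,
                    value = ifelse(counts$count > q3, 1L, 0L),
                    stringsAsFactors = FALSE)
  attr(out, "quantile_type") <- type
  out
}

#' Merge evidence records into cell values
#'
#' Combines per-cell evidence from the three attribution strategies
#' (literature references, expert assessment, search-engine analytics) into
#' one relationship value per (species, NCP) cell. Two policies:
#'
#' * `"dominance"` (default): over all records of a cell, `-1` dominates
#'   `+1` dominates `0` -- any credible report of a detriment (e.g. a plant
#'   cited toxic) outweighs positive mentions.
#' * `"precedence"`: only records from the highest-ranking source present
#'   are considered (`expert` > `reference` > `analytics`), mirroring cases
#'   where a national expert verdict overrides the literature; ties within
#'   that source are then resolved by dominance.
#'
#' Cells with no records are simply absent from the output (they remain
#' no-information `NA` in a table). The result is invariant to the order of
#' the input records. A record proposing `-1` for an NCP with
#' `negative_allowed = FALSE` is rejected.
#'
#' @param records data.frame with columns `species_id`, `ncp_id`, `source`
#'   (one of `reference`, `expert`, `analytics`), `proposed_value`
#'   (-1/0/+1); an optional `note` column is carried through unchecked.
#' @param catalog an [ncp_catalog]; all `ncp_id`s must belong to it.
#' @param policy `"dominance"` or `"precedence"`.
#' @return data.frame `species_id`, `ncp_id`, `value`, sorted by
#'   (`species_id`, `ncp_id`).
#' @export
merge_evidence <- function(records, catalog, policy = c("dominance", "precedence")) {
  stopifnot(inherits(catalog, "ncp_catalog"))
  policy <- match.arg(policy)
  required <- c("species_id", "ncp_id", "source", "proposed_value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_ncp("evidence records lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) {
    return(data.frame(species_id = character(), ncp_id = character(),
                      value = integer(), stringsAsFactors = FALSE))
  }
  # precedence rank: expert outranks reference outranks analytics
  src_rank <- c(expert = 1L, reference = 2L, analytics = 3L)
  bad_src <- setdiff(unique(records$source), names(src_rank))
  if (length(bad_src)) stop_ncp("unknown evidence source(s): %s", paste(bad_src, collapse = ", "))
  if (!all(records$proposed_value %in% c(-1L, 0L, 1L))) {
    stop_ncp("proposed_value must be -1, 0 or +1")
  }
  bad_ncp <- setdiff(unique(records$ncp_id), catalog$ncp_id)
  if (length(bad_ncp)) stop_ncp("unknown ncp_id in evidence: %s", paste(bad_ncp, collapse = ", "))
  neg_ok <- stats::setNames(catalog$negative_allowed, catalog$ncp_id)
  illegal <- records$proposed_value == -1L & !neg_ok[records$ncp_id]
  if (any(illegal)) {
    i <- which(illegal)[1]
    stop_ncp("evidence proposes -1 for '%s' (species '%s') but that NCP disallows negatives",
             records$ncp_id[i], records$species_id[i])
  }

  key <- paste(records$species_id, records$ncp_id, sep = "\r")
  resolve <- function(idx) {
    vals <- records$proposed_value[idx]
    if (policy == "precedence") {
      rk <- src_rank[records$source[idx]]
      vals <- vals[rk == min(rk)]
    }
    if (-1L %in% vals) -1L else if (1L %in% vals) 1L else 0L
  }
  groups <- split(seq_len(nrow(records)), key)
  vals <- vapply(groups, resolve, integer(1))
  parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(species_id = parts[, 1], ncp_id = parts[, 2],
                    value = unname(vals), stringsAsFactors = FALSE)
  out <- out[order(out$species_id, out$ncp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write cell assignments into a relationship table
#'
#' Convenience for pushing attribution output (from [assign_membership()],
#' [quartile_threshold()] or [merge_evidence()]) into an `ncp_table`.
#'
#' @param table an `ncp_table`.
#' @param assignments data.frame with `species_id`, `value`, and either an
#'   `ncp_id` column or a single `ncp_id` argument.
#' @param ncp_id target NCP when `assignments` has no `ncp_id` column.
#' @return the updated `ncp_table` (validated).
#' @export
set_cells <- function(table, assignments, ncp_id = NULL) {
  stopifnot(inherits(table, "ncp_table"))
  if (!"ncp_id" %in% names(assignments)) {
    if (is.null(ncp_id)) stop_ncp("ncp_id must be given when assignments lack an ncp_id column")
    assignments$ncp_id <- ncp_id
  }
  v <- table$values
  bad_sp <- setdiff(assignments$species_id, rownames(v))
  if (length(bad_sp)) stop_ncp("unknown species_id: %s", paste(bad_sp, collapse = ", "))
  bad_ncp <- setdiff(assignments$ncp_id, colnames(v))
  if (length(bad_ncp)) stop_ncp("unknown ncp_id: %s", paste(bad_ncp, collapse = ", "))
  v[cbind(match(assignments$species_id, rownames(v)),
          match(assignments$ncp_id, colnames(v)))] <- as.integer(assignments$value)
  out <- relationship_table(table$species, v, table$catalog)
  report <- validate_table(out)
  if (nrow(report)) {
    stop_ncp("assignment produces an invalid table (%d violation(s)); first: %s / %s: %s",
             nrow(report), report$species_id[1], report$ncp_id[1], report$problem[1])
  }
  out
}
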