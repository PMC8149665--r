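# Demographic group construction. A grouping scheme maps raw source columns
# (as delivered by a census-style count table) to derived analysis groups by
# column addition and subtraction, e.g.
#   people_of_color = total - non_hispanic_white_alone.

#' Define a grouping scheme
#'
#' Each derived group is defined by the source columns to add and (optionally)
#' to subtract. Partitions declare sets of derived groups expected to sum to
#' a total column, so conservation can be checked downstream.
#'
#' @param name scheme label recorded in the output table.
#' @param groups named list; each element a list with character vectors
#'   `add` and optional `subtract` of source column names.
#' @param keep character vector of source columns copied through unchanged
#'   (e.g. the totals).
#' @param partitions named list mapping a kept total column to the derived
#'   group columns that partition it.
#' @return an object of class `groupScheme`.
#' @seealso [buildGroups()], [readGroupScheme()], [acsRaceScheme()]
#' @export
#' @examples
#' sc <- groupScheme("race", groups = list(
#'   people_of_color = list(add = "total", subtract = "nh_white")),
#'   keep = c("total", "nh_white"))
groupScheme <- function(name, groups, keep = character(0),
                        partitions = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.list(groups),
            length(names(groups)) == length(groups))
  groups <- lapply(groups, function(g) {
    list(add = as.character(g$add),
         subtract = as.character(if (is.null(g$subtract)) character(0)
                                 else g$subtract))
  })
  structure(list(name = name, groups = groups, keep = keep,
                 partitions = partitions), class = "groupScheme")
}

#' @export
print.groupScheme <- function(x, ...) {
  cat(sprintf("groupScheme '%s': %d derived groups\n", x$name,
              length(x$groups)))
  for (g in names(x$groups)) {
    sp <- x$groups[[g]]
    cat(sprintf("  %s = %s%s\n", g, paste(sp$add, collapse = " + "),
                if (length(sp$subtract))
                  paste0(" - ", paste(sp$subtract, collapse = " - "))
                else ""))
  }
  invisible(x)
}

#' Read a grouping scheme from a YAML file
#'
#' Expected layout:
#' ```yaml
#' name: race
#' keep: [total, nh_white]
#' groups:
#'   people_of_color: {add: [total], subtract: [nh_white]}
#' partitions:
#'   pov_total: [below_pov, pov_1_2, above_2pov]
#' ```
#'
#' @param path YAML file path.
#' @return a [groupScheme()].
#' @export
readGroupScheme <- function(path) {
  y <- yaml::read_yaml(path)
  groupScheme(y$name,
              groups = y$groups,
              keep = as.character(y$keep),
              partitions = if (is.null(y$partitions)) list() else
                lapply(y$partitions, as.character))
}

#' Census-profile race/ethnicity scheme
#'
#' The standard race/ethnicity grouping for ACS-style profile tables with
#' source columns `total`, `hispanic`, `nh_white`, `nh_black`: Hispanic of
#' any race, two non-Hispanic single-race groups (Black, white), a residual
#' non-Hispanic "other", and people of color defined as everyone except
#' non-Hispanic white alone.
#'
#' @return a [groupScheme()].
#' @export
acsRaceScheme <- function() {
  groupScheme("acs_race",
    groups = list(
      people_of_color = list(add = "total", subtract = "nh_white"),
      nh_other = list(add = "total",
                      subtract = c("hispanic", "nh_white", "nh_black"))
    ),
    keep = c("total", "hispanic", "nh_white", "nh_black"),
    partitions = list(total = c("hispanic", "nh_white", "nh_black",
                                "nh_other")))
}

#' Poverty-ratio scheme
#'
#' Income relative to the poverty line in three categories — at/below 1x,
#' 1-2x, and above 2x — partitioning the poverty-status universe.
#'
#' @return a [groupScheme()].
#' @export
acsIncomeScheme <- function() {
  groupScheme("acs_income",
    groups = list(),
    keep = c("pov_total", "below_pov", "pov_1_2", "above_2pov"),
    partitions = list(pov_total = c("below_pov", "pov_1_2", "above_2pov")))
}

#' Build derived demographic groups from a raw count table
#'
#' Applies a [groupScheme()] to a raw tract table: each derived group is the
#' row-wise sum of its `add` columns minus its `subtract` columns. A derived
#' count below zero aborts with the offending tract named (age-by-race
#' tables where Black includes Hispanic Black are supported simply by
#' pointing `add` at the all-Black column).
#'
#' @param raw data.frame (or [DemographicTable-class]) with `tract_id` and
#'   the scheme's source columns.
#' @param scheme a [groupScheme()].
#' @return a [DemographicTable-class] carrying the kept and derived columns,
#'   scheme name and partitions.
#' @export
buildGroups <- function(raw, scheme) {
  stopifnot(inherits(scheme, "groupScheme"))
  if (is(raw, "DemographicTable")) raw <- demographicCounts(raw)
  src <- unique(c(unlist(lapply(scheme$groups, unlist)), scheme$keep))
  missingCols <- setdiff(src, names(raw))
  if (length(missingCols))
    stop("raw table lacks source columns: ",
         paste(missingCols, collapse = ", "))
  out <- data.frame(tract_id = as.character(raw$tract_id),
                    stringsAsFactors = FALSE)
  for (k in scheme$keep) out[[k]] <- raw[[k]]
  for (g in names(scheme$groups)) {
    sp <- scheme$groups[[g]]
    v <- rowSums(raw[, sp$add, drop = FALSE])
    if (length(sp$subtract))
      v <- v - rowSums(raw[, sp$subtract, drop = FALSE])
    bad <- which(v < 0)
    if (length(bad))
      stop(sprintf("derived group '%s' negative for tract(s) %s", g,
                   paste(out$tract_id[bad], collapse = ", ")))
    out[[g]] <- v
  }
  demographicTable(out, scheme = scheme$name, partitions = scheme$partitions)
}

#' Check partition conservation
#'
#' Verifies, for every declared partition, that the category counts sum to
#' the total column within `tol` per tract (source tables may carry small
#' rounding discrepancies).
#'
#' @param x a [DemographicTable-class].
#' @param tol per-tract absolute tolerance (default 1e-6; raise for rounded
#'   survey tables).
#' @return `TRUE` invisibly, or a character vector describing violations.
#' @export
checkPartitions <- function(x, tol = 1e-6) {
  stopifnot(is(x, "DemographicTable"))
  df <- x@counts
  issues <- character(0)
  for (tot in names(x@partitions)) {
    parts <- x@partitions[[tot]]
    gap <- abs(rowSums(df[, parts, drop = FALSE]) - df[[tot]])
    bad <- which(gap > tol)
    if (length(bad))
      issues <- c(issues, sprintf(
        "partition of '%s' off by up to %g in tract(s) %s", tot,
        max(gap[bad]), paste(utils::head(df$tract_id[bad], 5), collapse = ", ")))
  }
  if (length(issues)) issues else invisible(TRUE)
}
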