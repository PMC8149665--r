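# Tract-level surface urban heat island intensity by the simplified urban
# extent method: SUHI_t = LST_t - LST_r, where LST_t is the tract's mean LST
# over pixels inside its urbanized area and LST_r the mean LST over the
# nonurban, nonwater pixels of that urbanized area.

#' Compute the rural reference temperature of an urbanized area
#'
#' The rural reference is the unweighted mean land surface temperature over
#' all cells of the urbanized area carrying the NONURBAN land cover label
#' (water and urban cells never qualify). Missing LST cells are excluded.
#'
#' @param x a [CityRaster-class].
#' @param ua integer urbanized-area id present in the UA grid.
#' @return list with `urbanized_area_id`, `lst_r` (degrees C) and `n_cells`.
#' @seealso [computeTractSuhi()], [computeCitySuhi()]
#' @export
#' @examples
#' lc <- matrix(2L, 4, 4); lc[2:3, 2:3] <- 1L
#' ua <- matrix(1L, 4, 4)
#' tr <- matrix(NA_integer_, 4, 4); tr[2:3, 2:3] <- 1L
#' lst <- matrix(28, 4, 4); lst[2:3, 2:3] <- 31
#' computeRuralReference(cityRaster(lst, lc, ua, tr), 1L)
computeRuralReference <- function(x, ua) {
  stopifnot(is(x, "CityRaster"), length(ua) == 1L)
  inUa <- !is.na(x@ua) & x@ua == ua
  if (!any(inUa)) stop("urbanized area ", ua, " not present in the UA grid")
  sel <- inUa & x@landcover == landCoverCodes()[["NONURBAN"]] & !is.na(x@lst)
  if (!any(sel))
    stop("no rural reference: urbanized area ", ua,
         " has no nonurban, nonwater cell with valid LST")
  list(urbanized_area_id = as.integer(ua),
       lst_r = mean(x@lst[sel]),
       n_cells = sum(sel))
}

#' Compute one tract's SUHI intensity
#'
#' LST_t is the mean of non-missing LST over the cells assigned to both the
#' tract and its urbanized area; by default water-labeled cells are excluded
#' from the tract mean, mirroring the nonwater rule on the rural side
#' (`includeWater = TRUE` keeps them). The SUHI intensity is
#' `lst_t - ref$lst_r`.
#'
#' @param x a [CityRaster-class].
#' @param ref rural reference from [computeRuralReference()]; the tract must
#'   belong to its urbanized area.
#' @param tract integer tract id.
#' @param includeWater logical; include water cells in the tract mean.
#' @return one-row data.frame (`tract_id`, `urbanized_area_id`, `lst_t`,
#'   `lst_r`, `suhi`, `n_cells`), or `NULL` (with a message) when the tract
#'   has no qualifying cell.
#' @export
computeTractSuhi <- function(x, ref, tract, includeWater = FALSE) {
  stopifnot(is(x, "CityRaster"), length(tract) == 1L)
  ua <- ref$urbanized_area_id
  sel <- !is.na(x@tract) & x@tract == tract &
    !is.na(x@ua) & x@ua == ua & !is.na(x@lst)
  if (!includeWater)
    sel <- sel & x@landcover != landCoverCodes()[["WATER"]]
  if (!any(sel)) {
    message("tract ", tract, " skipped: no valid LST cell inside urbanized area ",
            ua)
    return(NULL)
  }
  lst_t <- mean(x@lst[sel])
  data.frame(tract_id = as.character(tract),
             urbanized_area_id = as.integer(ua),
             lst_t = lst_t, lst_r = ref$lst_r,
             suhi = lst_t - ref$lst_r,
             n_cells = sum(sel))
}

#' Compute SUHI for every tract of an urbanized area
#'
#' Computes the rural reference once and applies it to each tract of the
#' urbanized area; tracts with no qualifying cell are skipped with a message
#' and listed in the `skipped` attribute of the result.
#'
#' @inheritParams computeTractSuhi
#' @param ua integer urbanized-area id.
#' @return data.frame of per-tract records (see [computeTractSuhi()]) with
#'   attributes `skipped` (character tract ids) and `include_water`.
#' @export
computeCitySuhi <- function(x, ua, includeWater = FALSE) {
  stopifnot(is(x, "CityRaster"))
  ref <- computeRuralReference(x, ua)
  inUa <- !is.na(x@ua) & x@ua == ua
  tracts <- sort(unique(x@tract[inUa & !is.na(x@tract)]))
  rows <- vector("list", length(tracts))
  skipped <- character(0)
  for (i in seq_along(tracts)) {
    rec <- computeTractSuhi(x, ref, tracts[i], includeWater = includeWater)
    if (is.null(rec)) skipped <- c(skipped, as.character(tracts[i]))
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tract_id = character(0),
                      urbanized_area_id = integer(0), lst_t = numeric(0),
                      lst_r = numeric(0), suhi = numeric(0),
                      n_cells = integer(0))
  attr(out, "skipped") <- skipped
  attr(out, "include_water") <- includeWater
  out
}

#' Compute SUHI for every urbanized area on a grid
#'
#' @inheritParams computeCitySuhi
#' @return row-bound per-tract records across all urbanized areas, with the
#'   combined `skipped` attribute.
#' @export
computeSuhi <- function(x, includeWater = FALSE) {
  stopifnot(is(x, "CityRaster"))
  uas <- sort(unique(x@ua[!is.na(x@ua)]))
  parts <- lapply(uas, function(u) computeCitySuhi(x, u,
                                                   includeWater = includeWater))
  out <- do.call(rbind, parts)
  attr(out, "skipped") <- unlist(lapply(parts, attr, "skipped"))
  attr(out, "include_water") <- includeWater
  rownames(out) <- NULL
  out
}
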