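#' @import methods
NULL

#' Land cover codes used in all grids
#'
#' Integer codes for the three-way land cover partition: urban built-up,
#' nonurban land (the rural-reference class), and water.
#'
#' @return named integer vector `c(URBAN = 1L, NONURBAN = 2L, WATER = 3L)`.
#' @export
#' @examples
#' landCoverCodes()
landCoverCodes <- function() c(URBAN = 1L, NONURBAN = 2L, WATER = 3L)

#' CityRaster: aligned LST, land cover and zone grids
#'
#' Holds the four co-registered grids the tract-level SUHI computation needs:
#' land surface temperature (LST, degrees C, `NA` = missing), categorical land
#' cover (codes of [landCoverCodes()]), and two integer zone grids assigning
#' each cell to an urbanized area and to a census tract (`NA` = unassigned).
#' Grids are row-major with origin at the top-left cell; a cell belongs to a
#' zone by center containment and is atomic (no area weighting of boundary
#' cells).
#'
#' @slot lst numeric matrix of LST in degrees C; `NA` marks missing pixels.
#' @slot landcover integer matrix with values in `landCoverCodes()`.
#' @slot ua integer matrix of urbanized-area ids (`NA` = outside any UA).
#' @slot tract integer matrix of tract ids (`NA` = no tract). A cell with a
#'   tract id must also carry a UA id, and every tract id must map to exactly
#'   one UA id.
#' @slot xll,yll numeric, coordinates of the lower-left corner.
#' @slot cellsize numeric, cell edge length (same in x and y).
#'
#' @export
setClass("CityRaster",
  representation(
    lst = "matrix",
    landcover = "matrix",
    ua = "matrix",
    tract = "matrix",
    xll = "numeric",
    yll = "numeric",
    cellsize = "numeric"
  ),
  prototype(xll = 0, yll = 0, cellsize = 1)
)

setValidity("CityRaster", function(object) {
  msgs <- character(0)
  d <- dim(object@lst)
  if (!identical(d, dim(object@landcover)) ||
      !identical(d, dim(object@ua)) ||
      !identical(d, dim(object@tract)))
    msgs <- c(msgs, "lst, landcover, ua and tract grids must share one shape")
  lc <- object@landcover
  if (anyNA(lc) || !all(lc %in% landCoverCodes()))
    msgs <- c(msgs, "landcover cells must all carry one of the codes 1/2/3")
  v <- object@lst[!is.na(object@lst)]
  if (length(v) && any(!is.finite(v)))
    msgs <- c(msgs, "non-missing LST values must be finite")
  hasTract <- !is.na(object@tract)
  if (any(hasTract & is.na(object@ua)))
    msgs <- c(msgs, "every cell with a tract id must have a UA id")
  if (any(hasTract)) {
    map <- unique(data.frame(tract = object@tract[hasTract],
                             ua = object@ua[hasTract]))
    if (anyDuplicated(map$tract))
      msgs <- c(msgs, "each tract id must map to exactly one urbanized area")
  }
  if (length(object@cellsize) != 1L || object@cellsize <= 0)
    msgs <- c(msgs, "cellsize must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CityRaster
#'
#' @param lst numeric matrix of land surface temperature (degrees C), `NA` for
#'   missing pixels.
#' @param landcover integer matrix of land cover codes (see
#'   [landCoverCodes()]).
#' @param ua integer matrix of urbanized-area ids, `NA` outside any UA.
#' @param tract integer matrix of tract ids, `NA` where no tract applies.
#' @param xll,yll lower-left corner coordinates (default 0, 0).
#' @param cellsize cell edge length (default 1).
#' @return a validated [CityRaster-class] object.
#' @export
#' @examples
#' lc <- matrix(2L, 4, 4); lc[2:3, 2:3] <- 1L
#' ua <- matrix(1L, 4, 4)
#' tr <- matrix(NA_integer_, 4, 4); tr[2:3, 2:3] <- 1L
#' cityRaster(matrix(25, 4, 4), lc, ua, tr)
cityRaster <- function(lst, landcover, ua, tract, xll = 0, yll = 0,
                       cellsize = 1) {
  storage.mode(landcover) <- "integer"
  storage.mode(ua) <- "integer"
  storage.mode(tract) <- "integer"
  new("CityRaster", lst = lst, landcover = landcover, ua = ua, tract = tract,
      xll = xll, yll = yll, cellsize = cellsize)
}

#' DemographicTable: per-tract person counts by group
#'
#' One row per census tract; numeric columns hold person counts for each
#' group of a named grouping scheme. Partitions record which group columns
#' are expected to sum to a total column (e.g., the three poverty-ratio
#' categories partitioning the poverty universe).
#'
#' @slot counts data.frame with character column `tract_id` (leading zeros
#'   preserved) and one nonnegative numeric column per group.
#' @slot scheme character scalar naming the grouping scheme.
#' @slot partitions named list; each element is a character vector of group
#'   columns, named by the total column they partition.
#'
#' @export
setClass("DemographicTable",
  representation(
    counts = "data.frame",
    scheme = "character",
    partitions = "list"
  ),
  prototype(scheme = "unspecified", partitions = list())
)

setValidity("DemographicTable", function(object) {
  msgs <- character(0)
  df <- object@counts
  if (!"tract_id" %in% names(df))
    return("counts must contain a tract_id column")
  if (!is.character(df$tract_id))
    msgs <- c(msgs, "tract_id must be character (FIPS codes keep zeros)")
  if (anyDuplicated(df$tract_id))
    msgs <- c(msgs, "duplicate tract_id values")
  num <- df[setdiff(names(df), "tract_id")]
  if (!all(vapply(num, is.numeric, logical(1))))
    msgs <- c(msgs, "all group columns must be numeric")
  else if (any(vapply(num, function(x) any(x < 0, na.rm = TRUE), logical(1))))
    msgs <- c(msgs, "group counts must be nonnegative")
  for (tot in names(object@partitions)) {
    parts <- object@partitions[[tot]]
    if (!all(c(tot, parts) %in% names(df)))
      msgs <- c(msgs, sprintf("partition of '%s' references missing columns",
                              tot))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DemographicTable
#'
#' @param counts data.frame with `tract_id` (character) plus one numeric
#'   count column per group.
#' @param scheme name of the grouping scheme the columns follow.
#' @param partitions named list mapping a total column to the character
#'   vector of group columns that partition it.
#' @return a validated [DemographicTable-class].
#' @export
#' @examples
#' demographicTable(data.frame(tract_id = c("001", "002"),
#'                             total = c(100, 200), poc = c(60, 50)),
#'                  scheme = "toy")
demographicTable <- function(counts, scheme = "unspecified",
                             partitions = list()) {
  counts$tract_id <- as.character(counts$tract_id)
  new("DemographicTable", counts = counts, scheme = scheme,
      partitions = partitions)
}

#' SyntheticCity: one generated urbanized area with recoverable truth
#'
#' Container produced by [generateCity()]. The tract table stores both the
#' realized tract SUHI (deterministic gradient + noise, computed cell by cell
#' at generation time, independently of the zonal-statistics module) and the
#' noise-free deterministic component used as ground truth for parameter
#' recovery.
#'
#' @slot cityId integer urbanized-area id.
#' @slot raster a [CityRaster-class], or `NULL` when the city was generated
#'   in tract-level mode (`cellLevel = FALSE`).
#' @slot tracts data.frame: `tract_id`, `urbanized_area_id`, `suhi`
#'   (realized, degrees C), `suhi_det` (noise-free), `n_cells`, `population`.
#' @slot demographics a [DemographicTable-class] of group counts.
#' @slot truth list of generator-side quantities (expected group gaps,
#'   Kolm-Pollak indices of the generating distribution).
#' @slot config the [syntheticConfig()] list used.
#' @slot seed integer seed the city was generated with.
#'
#' @export
setClass("SyntheticCity",
  representation(
    cityId = "integer",
    raster = "ANY",
    tracts = "data.frame",
    demographics = "DemographicTable",
    truth = "list",
    config = "list",
    seed = "integer"
  )
)

setValidity("SyntheticCity", function(object) {
  msgs <- character(0)
  tr <- object@tracts
  need <- c("tract_id", "urbanized_area_id", "suhi", "suhi_det", "n_cells",
            "population")
  if (!all(need %in% names(tr)))
    msgs <- c(msgs, "tracts table lacks required columns")
  if (!is.null(object@raster) && !is(object@raster, "CityRaster"))
    msgs <- c(msgs, "raster must be NULL or a CityRaster")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticPanel: a multi-city synthetic study region
#'
#' @slot cities list of [SyntheticCity-class] objects.
#' @slot zones data.frame with `urbanized_area_id` and `zone` (climate zone
#'   label: arid / snow / temperate / equatorial).
#' @slot config the shared [syntheticConfig()].
#' @slot seed master seed.
#'
#' @export
setClass("SyntheticPanel",
  representation(
    cities = "list",
    zones = "data.frame",
    config = "list",
    seed = "integer"
  )
)

setValidity("SyntheticPanel", function(object) {
  msgs <- character(0)
  if (!all(vapply(object@cities, is, logical(1), "SyntheticCity")))
    msgs <- c(msgs, "cities must all be SyntheticCity objects")
  if (!all(c("urbanized_area_id", "zone") %in% names(object@zones)))
    msgs <- c(msgs, "zones needs urbanized_area_id and zone columns")
  if (length(msgs)) msgs else TRUE
})
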