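# Accessors and show methods for the S4 containers.

#' @describeIn CityRaster-class grid dimensions (rows, cols).
#' @param x,object a `CityRaster`.
#' @export
setMethod("dim", "CityRaster", function(x) dim(x@lst))

#' Grid accessors
#'
#' Extract the component grids of a [CityRaster-class] without touching
#' slots directly.
#'
#' @param x a `CityRaster`.
#' @return the requested matrix.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
lstGrid <- function(x) { stopifnot(is(x, "CityRaster")); x@lst }

#' @rdname grid-accessors
#' @export
landCoverGrid <- function(x) { stopifnot(is(x, "CityRaster")); x@landcover }

#' @rdname grid-accessors
#' @export
uaGrid <- function(x) { stopifnot(is(x, "CityRaster")); x@ua }

#' @rdname grid-accessors
#' @export
tractGrid <- function(x) { stopifnot(is(x, "CityRaster")); x@tract }

setMethod("show", "CityRaster", function(object) {
  d <- dim(object)
  nua <- length(unique(stats::na.omit(as.vector(object@ua))))
  ntr <- length(unique(stats::na.omit(as.vector(object@tract))))
  cat(sprintf("CityRaster: %d x %d cells (cellsize %g)\n", d[1], d[2],
              object@cellsize))
  cat(sprintf("  urbanized areas: %d; tracts: %d; missing LST cells: %d\n",
              nua, ntr, sum(is.na(object@lst))))
  tab <- table(factor(object@landcover, levels = landCoverCodes(),
                      labels = names(landCoverCodes())))
  cat("  land cover:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

#' Accessors for DemographicTable
#'
#' @param x a [DemographicTable-class].
#' @return `demographicCounts`: the underlying data.frame;
#'   `groupNames`: character vector of group columns; `schemeName`: the
#'   scheme label.
#' @name demographic-accessors
NULL

#' @rdname demographic-accessors
#' @export
demographicCounts <- function(x) { stopifnot(is(x, "DemographicTable")); x@counts }

#' @rdname demographic-accessors
#' @export
groupNames <- function(x) {
  stopifnot(is(x, "DemographicTable"))
  setdiff(names(x@counts), "tract_id")
}

#' @rdname demographic-accessors
#' @export
schemeName <- function(x) { stopifnot(is(x, "DemographicTable")); x@scheme }

setMethod("show", "DemographicTable", function(object) {
  cat(sprintf("DemographicTable ('%s'): %d tracts, %d groups\n",
              object@scheme, nrow(object@counts), length(groupNames(object))))
  cat("  groups:", paste(groupNames(object), collapse = ", "), "\n")
  if (length(object@partitions))
    cat("  partitions:", paste(names(object@partitions), collapse = ", "), "\n")
})

#' Accessors for synthetic cities and panels
#'
#' @param x a [SyntheticCity-class] or [SyntheticPanel-class].
#' @name synthetic-accessors
NULL

#' @rdname synthetic-accessors
#' @export
cityTracts <- function(x) { stopifnot(is(x, "SyntheticCity")); x@tracts }

#' @rdname synthetic-accessors
#' @export
cityDemographics <- function(x) { stopifnot(is(x, "SyntheticCity")); x@demographics }

#' @rdname synthetic-accessors
#' @export
cityRasterOf <- function(x) { stopifnot(is(x, "SyntheticCity")); x@raster }

#' @rdname synthetic-accessors
#' @export
cityTruth <- function(x) { stopifnot(is(x, "SyntheticCity")); x@truth }

#' @rdname synthetic-accessors
#' @export
panelCities <- function(x) { stopifnot(is(x, "SyntheticPanel")); x@cities }

#' @rdname synthetic-accessors
#' @export
panelZones <- function(x) { stopifnot(is(x, "SyntheticPanel")); x@zones }

setMethod("show", "SyntheticCity", function(object) {
  cat(sprintf("SyntheticCity %d: %d tracts, %s raster, seed %d\n",
              object@cityId, nrow(object@tracts),
              if (is.null(object@raster)) "no" else
                paste(dim(object@raster), collapse = "x"),
              object@seed))
})

setMethod("show", "SyntheticPanel", function(object) {
  cat(sprintf("SyntheticPanel: %d cities, seed %d\n",
              length(object@cities), object@seed))
  print(table(object@zones$zone))
})
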