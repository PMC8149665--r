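# Plain-text raster and table I/O. Grids travel as ESRI ASCII grids (.asc),
# the standard text interchange raster format: a six-line header (ncols,
# nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of
# whitespace-separated values, top row first.

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @param integer logical; coerce cell values to integer (for land cover and
#'   zone grids).
#' @return a matrix (rows top-to-bottom) with attributes `xll`, `yll`,
#'   `cellsize`; nodata cells become `NA`.
#' @export
readAsciiGrid <- function(path, integer = FALSE) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing ncols/nrows header): ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("grid %s: expected %d values, found %d", path,
                 hdr$ncols * hdr$nrows, length(vals)))
  if (!is.null(hdr$nodata_value))
    vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (integer) storage.mode(m) <- "integer"
  attr(m, "xll") <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  attr(m, "yll") <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  attr(m, "cellsize") <- if (is.null(hdr$cellsize)) 1 else hdr$cellsize
  m
}

#' Write an ESRI ASCII grid
#'
#' @param m matrix; `NA` cells are written as the nodata value.
#' @param path output path.
#' @param xll,yll lower-left corner.
#' @param cellsize cell edge length.
#' @param nodata numeric nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(m, path, xll = 0, yll = 0, cellsize = 1,
                           nodata = -9999) {
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  mm <- m
  mm[is.na(mm)] <- nodata
  body <- apply(mm, 1L, function(r) paste(format(r, trim = TRUE,
                                                 scientific = FALSE,
                                                 digits = 10),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a CityRaster bundle to a directory
#'
#' Emits `lst.asc`, `landcover.asc`, `ua.asc`, `tract.asc` — the exact
#' formats [readCityBundle()] and the pipeline consume.
#'
#' @param x a [CityRaster-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCityRaster <- function(x, dir) {
  stopifnot(is(x, "CityRaster"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(m, f) writeAsciiGrid(m, file.path(dir, f), xll = x@xll,
                                     yll = x@yll, cellsize = x@cellsize)
  w(x@lst, "lst.asc")
  w(x@landcover, "landcover.asc")
  w(x@ua, "ua.asc")
  w(x@tract, "tract.asc")
  invisible(dir)
}

#' Read a CityRaster bundle from a directory
#'
#' @param dir directory holding `lst.asc`, `landcover.asc`, `ua.asc`,
#'   `tract.asc`.
#' @return a [CityRaster-class].
#' @export
readCityRaster <- function(dir) {
  lst <- readAsciiGrid(file.path(dir, "lst.asc"))
  lc <- readAsciiGrid(file.path(dir, "landcover.asc"), integer = TRUE)
  ua <- readAsciiGrid(file.path(dir, "ua.asc"), integer = TRUE)
  tract <- readAsciiGrid(file.path(dir, "tract.asc"), integer = TRUE)
  cityRaster(lst, lc, ua, tract, xll = attr(lst, "xll"),
             yll = attr(lst, "yll"), cellsize = attr(lst, "cellsize"))
}

#' Read a per-tract demographic count table
#'
#' Reads a CSV with a header row and one row per tract. `tract_id` is read
#' as character so 11-digit FIPS codes keep their leading zeros.
#'
#' @param path CSV path.
#' @param scheme scheme label to attach.
#' @param partitions partition list (see [demographicTable()]).
#' @return a [DemographicTable-class].
#' @export
readDemographics <- function(path, scheme = "unspecified",
                             partitions = list()) {
  df <- utils::read.csv(path, colClasses = c(tract_id = "character"),
                        check.names = FALSE)
  demographicTable(df, scheme = scheme, partitions = partitions)
}

#' Write a demographic table to CSV
#'
#' @param x a [DemographicTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDemographics <- function(x, path) {
  stopifnot(is(x, "DemographicTable"))
  utils::write.csv(x@counts, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Fixed-significant-digit CSV writer for pipeline outputs: 6 significant
# digits keeps reruns byte-identical across platforms.
writeResultCsv <- function(df, path, digits = 6) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
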