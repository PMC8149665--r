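# End-to-end orchestration: grids -> tract SUHI -> demographic groups ->
# exposure tables, per-city tests, kernel densities and Kolm-Pollak
# summaries, with a run log and bit-stable CSV outputs.

# Fill a run configuration with defaults and read it from YAML if given a
# path. A config either names input bundle directories (`input`) or asks for
# a synthetic panel (`synth`, a list of syntheticConfig overrides).
normalizeRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, out = "heatEquity-run", synth = NULL,
                   input = NULL, kappa_list = c(-0.25, -0.5, -1),
                   threshold = 2, include_water = FALSE,
                   compare = NULL, precise = FALSE)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$synth) && is.null(config$input))
    stop("config needs either 'synth' (generator settings) or 'input' ",
         "(bundle directories)")
  config
}

# Load or generate the (suhi, demo, zones) triple a run works on.
assembleInputs <- function(config) {
  if (!is.null(config$synth)) {
    sc <- do.call(syntheticConfig,
                  config$synth[setdiff(names(config$synth), "cellLevel")])
    panel <- generatePanel(sc, seed = config$seed,
                           cellLevel = isTRUE(config$synth$cellLevel) ||
                             is.null(config$synth$cellLevel))
    rasters <- !is.null(panelCities(panel)[[1]]@raster)
    suhi <- if (rasters) {
      do.call(rbind, lapply(panelCities(panel), function(ct)
        computeSuhi(cityRasterOf(ct), includeWater = config$include_water)))
    } else panelSuhiTable(panel)
    list(suhi = suhi, demo = panelDemographics(panel),
         zones = panelZones(panel), panel = panel)
  } else {
    dirs <- config$input
    parts <- lapply(dirs, function(d) {
      ras <- readCityRaster(d)
      list(suhi = computeSuhi(ras, includeWater = config$include_water),
           demo = readDemographics(file.path(d, "demographics.csv")),
           zones = utils::read.csv(file.path(d, "zones.csv")))
    })
    counts <- do.call(rbind, lapply(parts, function(p)
      demographicCounts(p$demo)))
    list(suhi = do.call(rbind, lapply(parts, `[[`, "suhi")),
         demo = demographicTable(counts, scheme = "input"),
         zones = do.call(rbind, lapply(parts, `[[`, "zones")),
         panel = NULL)
  }
}

# Default comparisons: every group against the last-listed one (for the
# synthetic scheme: poc vs nh_white), plus the age-crossed pairs if present.
defaultComparisons <- function(groups) {
  base <- setdiff(groups, grep("_u5$|_o65$|^total$", groups, value = TRUE))
  if (length(base) < 2) stop("need at least two groups to compare")
  refGroup <- base[1]
  lapply(setdiff(base, refGroup), function(g) c(g, refGroup))
}

#' Run the full exposure-disparity pipeline
#'
#' Orchestrates an end-to-end run: assemble inputs (synthetic panel or city
#' bundles), compute tract SUHI, build exposure tables (group means and
#' clustered difference tests by climate zone and nationally), per-city
#' tests with tallies, city-mean kernel densities, and Kolm-Pollak index
#' summaries over the configured kappa sweep. All outputs are CSVs with 6
#' significant digits (set `precise: true` for full-precision copies) plus
#' a `run.log`. Any stage failure removes partial outputs and aborts with a
#' stage-named error.
#'
#' @param config run configuration: a YAML path or a list with fields
#'   `seed`, `out`, `synth` or `input`, `kappa_list`, `threshold`,
#'   `include_water`, `compare` (list of c(groupA, groupB)), `precise`.
#' @return invisibly, a list with the output directory and the computed
#'   tables.
#' @export
runPipeline <- function(config) {
  config <- normalizeRunConfig(config)
  outDir <- config$out
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  created <- character(0)
  stage <- "setup"
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    writeResultCsv(df, path)
    created <<- c(created, path)
    if (isTRUE(config$precise)) {
      pp <- file.path(outDir, sub("\\.csv$", "_precise.csv", name))
      utils::write.csv(df, pp, row.names = FALSE, quote = FALSE)
      created <<- c(created, pp)
    }
    df
  }
  result <- tryCatch({
    stage <- "inputs"
    inp <- assembleInputs(config)
    suhi <- inp$suhi; demo <- inp$demo; zones <- inp$zones
    groups <- groupNames(demo)
    comparisons <- if (is.null(config$compare)) defaultComparisons(groups)
      else config$compare

    stage <- "group_means"
    meanGroups <- setdiff(groups, "total")
    t1means <- do.call(rbind, lapply(c("total", meanGroups), function(g)
      rbind(weightedGroupMean(suhi, demo, g, "zone", zones),
            weightedGroupMean(suhi, demo, g, "national"))))
    ageGroups <- grep("_u5$|_o65$", groups, value = TRUE)
    t1 <- t1means[!t1means$group %in% ageGroups, ]
    emit(t1, "table1_means.csv")

    stage <- "group_differences"
    t1d <- do.call(rbind, lapply(comparisons, function(cp)
      rbind(groupMeanDifference(suhi, demo, cp[1], cp[2], "zone", zones),
            groupMeanDifference(suhi, demo, cp[1], cp[2], "national"))))
    emit(t1d, "table1_diffs.csv")

    stage <- "kolm_pollak"
    t2 <- do.call(rbind, lapply(config$kappa_list, function(k) {
      perGroup <- lapply(setdiff(groups, c("total", ageGroups)), function(g)
        groupCityIndices(suhi, demo, g, kappa = k))
      rbind(
        do.call(rbind, lapply(perGroup, kpSummary, zones = zones)),
        NULL)
    }))
    emit(t2, "table2_kp.csv")
    t2d <- do.call(rbind, lapply(config$kappa_list, function(k)
      do.call(rbind, lapply(comparisons, function(cp)
        indexDifference(groupCityIndices(suhi, demo, cp[1], kappa = k),
                        groupCityIndices(suhi, demo, cp[2], kappa = k))))))
    emit(t2d, "table2_kp_diffs.csv")

    stage <- "age_tables"
    if (length(ageGroups)) {
      agePairs <- list()
      for (cp in comparisons) {
        for (suf in c("_u5", "_o65")) {
          a <- paste0(cp[1], suf); b <- paste0(cp[2], suf)
          if (all(c(a, b) %in% groups))
            agePairs <- c(agePairs, list(c(a, b)))
        }
      }
      t3m <- t1means[t1means$group %in% ageGroups, ]
      t3d <- do.call(rbind, lapply(agePairs, function(cp)
        rbind(groupMeanDifference(suhi, demo, cp[1], cp[2], "zone", zones),
              groupMeanDifference(suhi, demo, cp[1], cp[2], "national"))))
      emit(rbind(t3m), "table3_age.csv")
      if (!is.null(t3d)) emit(t3d, "table3_age_diffs.csv")
    }

    stage <- "city_tests"
    ct <- do.call(rbind, lapply(comparisons, function(cp) {
      tests <- cityLevelTest(suhi, demo, cp[1], cp[2])
      tests$group_a <- cp[1]; tests$group_b <- cp[2]
      tests
    }))
    emit(ct, "city_tests.csv")
    tall <- do.call(rbind, lapply(comparisons, function(cp) {
      tests <- ct[ct$group_a == cp[1] & ct$group_b == cp[2], ]
      tl <- tallyCityComparisons(tests, zones)
      tl$group_a <- cp[1]; tl$group_b <- cp[2]
      tl
    }))
    emit(tall, "city_tally.csv")

    stage <- "densities"
    dens <- do.call(rbind, lapply(setdiff(groups, "total"), function(g) {
      cm <- cityGroupMeans(suhi, demo, g)
      if (is.null(cm) || nrow(cm) < 2) return(NULL)
      d <- exposureDensity(cm$weighted_mean, nCities = nrow(cm))
      data.frame(group = g, x = d$x, density = d$density, scaled = d$scaled,
                 bw = attr(d, "bw"))
    }))
    emit(dens, "densities.csv")

    stage <- "thresholds"
    thr <- do.call(rbind, lapply(setdiff(groups, "total"), function(g) {
      cm <- cityGroupMeans(suhi, demo, g)
      data.frame(group = g, threshold = config$threshold,
                 n_cities = nrow(cm),
                 n_above = citiesAboveThreshold(cm$weighted_mean,
                                                config$threshold))
    }))
    emit(thr, "city_thresholds.csv")

    stage <- "log"
    logPath <- file.path(outDir, "run.log")
    writeLines(c(
      sprintf("heatEquity %s on R %s",
              as.character(utils::packageVersion("heatEquity")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", as.integer(config$seed)),
      sprintf("include_water: %s", config$include_water),
      sprintf("kappa_list: %s", paste(config$kappa_list, collapse = ", ")),
      sprintf("threshold: %g", config$threshold),
      sprintf("skipped tracts: %s",
              paste(attr(suhi, "skipped"), collapse = ", ")),
      "config:",
      yaml::as.yaml(config[setdiff(names(config), "panel")])), logPath)
    created <- c(created, logPath)

    list(out = outDir, means = t1, diffs = t1d, kp = t2, kp_diffs = t2d,
         city_tests = ct, tally = tall, densities = dens, thresholds = thr)
  }, error = function(e) {
    unlink(created)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Validate a run configuration's inputs
#'
#' Checks, without running the analysis: that referenced paths exist, grids
#' align (one shape, valid land cover codes, tract-UA consistency),
#' demographic tract ids are unique, the tract join between zone grids and
#' demographics covers both sides, and declared partitions sum. Hard
#' violations make `ok` FALSE.
#'
#' @param config run configuration (YAML path or list); only `input` runs
#'   are validated against files, synthetic configs are checked for
#'   feasibility.
#' @return an object of class `validationReport`: list with `ok` and a
#'   data.frame `issues` (`severity`, `stage`, `message`).
#' @export
validateInputs <- function(config) {
  config <- normalizeRunConfig(config)
  issues <- data.frame(severity = character(0), stage = character(0),
                       message = character(0))
  note <- function(severity, stage, message) {
    issues <<- rbind(issues, data.frame(severity = severity, stage = stage,
                                        message = message))
  }
  if (!is.null(config$synth)) {
    ok <- tryCatch({ do.call(syntheticConfig, config$synth); TRUE },
                   error = function(e) {
                     note("error", "synth", conditionMessage(e)); FALSE })
  } else {
    for (d in config$input) {
      if (!dir.exists(d)) { note("error", "paths", paste("missing dir:", d));
                            next }
      grids <- tryCatch({
        lst <- readAsciiGrid(file.path(d, "lst.asc"))
        lc <- readAsciiGrid(file.path(d, "landcover.asc"), integer = TRUE)
        ua <- readAsciiGrid(file.path(d, "ua.asc"), integer = TRUE)
        tract <- readAsciiGrid(file.path(d, "tract.asc"), integer = TRUE)
        shapes <- list(dim(lst), dim(lc), dim(ua), dim(tract))
        if (length(unique(shapes)) != 1L)
          stop("alignment error: grid shapes differ (",
               paste(vapply(shapes, paste, "", collapse = "x"),
                     collapse = " vs "), ")")
        cityRaster(lst, lc, ua, tract)   # runs validity checks
      }, error = function(e) {
        note("error", "grids", paste0(d, ": ", conditionMessage(e)))
        NULL
      })
      demo <- tryCatch(
        readDemographics(file.path(d, "demographics.csv")),
        error = function(e) {
          note("error", "demographics", paste0(d, ": ", conditionMessage(e)))
          NULL
        })
      if (!is.null(demo)) {
        ids <- demographicCounts(demo)$tract_id
        if (anyDuplicated(ids))
          note("error", "demographics",
               paste0(d, ": duplicate tract_ids: ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
        pc <- checkPartitions(demo)
        if (is.character(pc)) for (m in pc) note("warning", "partitions", m)
      }
      if (!is.null(grids) && !is.null(demo)) {
        gridTracts <- as.character(
          sort(unique(tractGrid(grids)[!is.na(tractGrid(grids))])))
        demoTracts <- demographicCounts(demo)$tract_id
        onlyGrid <- setdiff(gridTracts, demoTracts)
        onlyDemo <- setdiff(demoTracts, gridTracts)
        if (length(onlyGrid))
          note("warning", "join",
               paste0(d, ": tracts missing from demographics: ",
                      paste(onlyGrid, collapse = ", ")))
        if (length(onlyDemo))
          note("warning", "join",
               paste0(d, ": demographic tracts absent from grid: ",
                      paste(onlyDemo, collapse = ", ")))
      }
    }
  }
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validationReport")
}

#' @export
print.validationReport <- function(x, ...) {
  cat(if (x$ok) "inputs OK" else "validation FAILED", "\n")
  if (nrow(x$issues))
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("[%s] %s: %s\n", x$issues$severity[i], x$issues$stage[i],
                  x$issues$message[i]))
  invisible(x)
}
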