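#' Run configuration for the full analysis pipeline
#'
#' Exactly one of `raster_paths` (named by year) or `preset` must be given.
#' Every analysis default the pipeline fills in (boundary-edge handling, RID
#' annualization, significance threshold) is echoed to the run log so runs
#' are self-describing.
#'
#' @param site site name used in output file prefixes.
#' @param raster_paths named character vector, names = years, values = ESRI
#'   ASCII grid paths; or `NULL`.
#' @param preset name of a [scenario_presets()] entry; or `NULL`.
#' @param zone_path optional ESRI ASCII grid of zone codes (nonzero =
#'   conservation unit for the binary stratification) or GeoJSON polygon
#'   file; ignored when a preset supplies its own CU mask.
#' @param remap optional class-code remap passed to [read_asc()].
#' @param boundary_edge,annualize,alpha,max_order analysis options.
#' @param out_dir output directory.
#' @param seed RNG seed for preset simulation.
#' @return object of class `run_config`.
#' @export
run_config <- function(site = "site", raster_paths = NULL, preset = NULL,
                       zone_path = NULL, remap = NULL,
                       boundary_edge = FALSE, annualize = FALSE,
                       alpha = 0.05, max_order = 2,
                       out_dir = ".", seed = 1L) {
  if (is.null(raster_paths) == is.null(preset))
    stop("exactly one of `raster_paths` or `preset` must be given")
  if (!is.null(raster_paths)) {
    if (is.null(names(raster_paths)) || anyNA(as.integer(names(raster_paths))))
      stop("`raster_paths` must be named by year")
    missing <- raster_paths[!file.exists(raster_paths)]
    if (length(missing))
      stop("input raster(s) not found: ", paste(missing, collapse = ", "))
  }
  if (!is.null(preset) && !preset %in% names(scenario_presets()))
    stop("unknown preset: ", preset)
  if (!is.null(zone_path) && !file.exists(zone_path))
    stop("zone file not found: ", zone_path)
  structure(list(site = site, raster_paths = raster_paths, preset = preset,
                 zone_path = zone_path, remap = remap,
                 boundary_edge = boundary_edge, annualize = annualize,
                 alpha = alpha, max_order = max_order,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$raster_paths)) cfg$raster_paths <- unlist(cfg$raster_paths)
  do.call(run_config, cfg)
}

#' Run the full fragmentation analysis
#'
#' Loads (or simulates) the land-cover series, builds the inside/outside
#' conservation-unit zones, computes the class-metric table, the relative
#' incidence of deforestation series, and the GLS trend table, and writes
#' `<site>_metrics.csv`, `<site>_rid.csv`, `<site>_trend.csv` and
#' `<site>_run_log.json` to the output directory.  Deterministic given the
#' config (including its seed).
#'
#' @param config a [run_config()].
#' @return list with `metrics`, `rid`, `trend`, `log` (invisibly also
#'   written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$preset)) {
      scn <- scenario_presets(seed = config$seed)[[config$preset]]
      rasters <- generate_series(scn)
      cu_mask <- attr(rasters, "cu_mask")
    } else {
      years <- as.integer(names(config$raster_paths))
      ord <- order(years)
      rasters <- Map(function(p, y) read_asc(p, year = y, remap = config$remap),
                     config$raster_paths[ord], years[ord])
      cu_mask <- NULL
      if (!is.null(config$zone_path)) {
        if (grepl("\\.(geojson|json)$", config$zone_path, ignore.case = TRUE)) {
          cu_mask <- zone_from_geojson(config$zone_path, rasters[[1]],
                                       "inside_CU")$mask
        } else {
          zr <- read_asc(config$zone_path,
                         class_codes = c(CU = 1L), nodata = 0L)
          cu_mask <- zr$grid != zr$nodata
        }
      }
    }
    zones <- if (!is.null(cu_mask)) zones_from_mask(cu_mask)
             else list(zone_mask(matrix(TRUE, nrow(rasters[[1]]$grid),
                                        ncol(rasters[[1]]$grid)), "all"))
    stage <- "metrics"
    metrics <- metrics_for_series(rasters, zones,
                                  boundary_edge = config$boundary_edge)
    stage <- "rid"
    rid_tbl <- rid_series(rasters, zones, annualize = config$annualize)
    stage <- "trend"
    trend <- trend_table(metrics, rid_tbl, alpha = config$alpha,
                         max_order = config$max_order)
    list(rasters = rasters, metrics = metrics, rid = rid_tbl, trend = trend)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(config$out_dir, config$site)
  metrics_out <- cbind(site = config$site, metrics_long(result$metrics))
  write.csv(metrics_out, paste0(pre, "_metrics.csv"), row.names = FALSE)
  rid_out <- cbind(site = config$site, result$rid)
  write.csv(rid_out, paste0(pre, "_rid.csv"), row.names = FALSE)
  trend_out <- cbind(site = config$site, as.data.frame(result$trend))
  write.csv(trend_out, paste0(pre, "_trend.csv"), row.names = FALSE)
  log <- list(
    site = config$site,
    package_version = as.character(utils::packageVersion("landfrag")),
    r_version = R.version.string,
    seed = config$seed,
    input = if (!is.null(config$preset)) list(preset = config$preset)
            else list(rasters = unname(config$raster_paths),
                      zone = config$zone_path),
    defaults = list(
      patch_connectivity = 8,
      adjacency = "rook double-count, internal sides only",
      boundary_edge_in_ED = config$boundary_edge,
      deforestation = "MF->NF only; MF->SF reported as QC, excluded from D",
      rid_annualized = config$annualize,
      trend_alpha = config$alpha,
      trend_max_arma_order = config$max_order,
      trend_gaps = "annual lattice with missing years"),
    skipped_series = as.list(attr(result$trend, "skipped")))
  jsonlite::write_json(log, paste0(pre, "_run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(result[c("metrics", "rid", "trend")], list(log = log)))
}

#' Write small hand-constructed fixture rasters
#'
#' Named fixtures used in documentation and tests:
#' \describe{
#'   \item{checkerboard_8}{8 x 8 alternating MF/NF grid.}
#'   \item{square_in_matrix}{10 x 10 NF with a centred 2 x 2 MF patch.}
#'   \item{strip_patch}{10 x 10 NF with a 1 x 8 MF strip.}
#'   \item{clearing_series}{three-year 6 x 6 series with one MF -> NF
#'     clearing event and later NF -> SF regrowth.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory.
#' @return character vector of files written.
#' @export
make_fixture <- function(name, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grids <- switch(
    name,
    checkerboard_8 = list(fixture =
      matrix(rep_len(c(1L, 2L), 64), 8, 8) |>
        (\(m) { m[, seq(2, 8, 2)] <- 3L - m[, seq(2, 8, 2)]; m })()),
    square_in_matrix = {
      g <- matrix(2L, 10, 10); g[5:6, 5:6] <- 1L
      list(fixture = g)
    },
    strip_patch = {
      g <- matrix(2L, 10, 10); g[5, 2:9] <- 1L
      list(fixture = g)
    },
    clearing_series = {
      base <- matrix(1L, 6, 6)
      y2 <- base; y2[2:3, 2:4] <- 2L
      y3 <- y2; y3[2, 2:3] <- 3L
      list(y1984 = base, y1990 = y2, y1995 = y3)
    },
    stop("unknown fixture: ", name))
  files <- character()
  years <- c(y1984 = 1984L, y1990 = 1990L, y1995 = 1995L)
  for (nm in names(grids)) {
    yr <- if (nm %in% names(years)) years[[nm]] else NA_integer_
    f <- file.path(dir, paste0(name, if (nm != "fixture") paste0("_", nm),
                               ".asc"))
    write_asc(land_raster(grids[[nm]], cell_size = 30, year = yr), f)
    files <- c(files, f)
  }
  files
}
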