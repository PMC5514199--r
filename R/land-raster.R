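#' Categorical land-cover raster
#'
#' Container for one year's land-cover map: an integer matrix of class codes
#' plus the cell size (metres), the nodata code, the substantive class codes
#' (by default mature forest MF = 1, non-forest NF = 2, secondary forest
#' SF = 3) and the calendar year.  Any georeference (lower-left corner) is
#' carried through I/O untouched; all computation is in row/column space.
#'
#' @param grid integer matrix of class codes; `NA` entries are converted to
#'   `nodata`.
#' @param cell_size cell side length in metres (> 0).
#' @param year calendar year of the map, or `NA`.
#' @param class_codes named integer vector of substantive class codes; names
#'   are the class labels used in all output tables.
#' @param nodata integer code for cells outside the landscape.
#' @param origin optional list with `xll`, `yll` (lower-left corner), passed
#'   through to [write_asc()].
#' @return An object of class `land_raster`.
#' @examples
#' r <- land_raster(matrix(1L, 3, 3), cell_size = 30, year = 1984)
#' r
#' @export
land_raster <- function(grid, cell_size = 30, year = NA_integer_,
                        class_codes = c(MF = 1L, NF = 2L, SF = 3L),
                        nodata = 0L, origin = NULL) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  storage.mode(grid) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  class_codes <- as.integer(class_codes) |> setNames(names(class_codes))
  if (is.null(names(class_codes)) || anyNA(class_codes) ||
      anyDuplicated(class_codes))
    stop("`class_codes` must be a named integer vector without duplicates")
  nodata <- as.integer(nodata)
  if (nodata %in% class_codes) stop("`nodata` collides with a class code")
  grid[is.na(grid)] <- nodata
  bad <- setdiff(unique(as.vector(grid)), c(class_codes, nodata))
  if (length(bad))
    stop("grid contains codes not in class_codes/nodata: ",
         paste(bad, collapse = ", "))
  structure(
    list(grid = grid, cell_size = as.numeric(cell_size),
         year = as.integer(year), class_codes = class_codes,
         nodata = nodata, origin = origin),
    class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("<land_raster> %d x %d cells, %.0f m, year %s\n",
              nrow(x$grid), ncol(x$grid), x$cell_size,
              ifelse(is.na(x$year), "?", x$year)))
  tab <- table(factor(x$grid, levels = x$class_codes,
                      labels = names(x$class_codes)))
  print(tab)
  invisible(x)
}

#' @rdname land_raster
#' @param x object to test.
#' @export
is_land_raster <- function(x) inherits(x, "land_raster")

cell_area_ha <- function(raster) raster$cell_size^2 / 1e4

#' Total substantive (non-nodata) area of a raster in hectares
#' @param raster a [land_raster()].
#' @return area in ha.
#' @export
landscape_area_ha <- function(raster) {
  sum(raster$grid != raster$nodata) * cell_area_ha(raster)
}

#' Read an ESRI ASCII grid as a categorical raster
#'
#' Parses the standard six-line ESRI ASCII header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' whitespace-separated integer codes.  File codes that are not already the
#' package's class codes must be covered by `remap`; an unmapped code is an
#' error, never silently dropped.
#'
#' @param path path to the `.asc` file.
#' @param year calendar year to attach.
#' @param class_codes,nodata as in [land_raster()].
#' @param remap optional named integer vector mapping file codes (names) to
#'   class codes (values), e.g. `c("10" = 1, "20" = 2)`.
#' @return a [land_raster()].
#' @export
read_asc <- function(path, year = NA_integer_,
                     class_codes = c(MF = 1L, NF = 2L, SF = 3L),
                     nodata = 0L, remap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stop("ASCII grid header missing ", key)
  if (hdr$cellsize <= 0) stop("cellsize must be > 0")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = integer(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values, found ", length(vals))
  file_nodata <- if (!is.null(hdr$nodata_value)) as.integer(hdr$nodata_value)
                 else nodata
  # ASCII grids are row-major, top row first
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  grid[grid == file_nodata] <- nodata
  if (!is.null(remap)) {
    m <- setNames(as.integer(remap), names(remap))
    hit <- match(as.character(grid), names(m))
    grid[!is.na(hit)] <- m[hit[!is.na(hit)]]
  }
  bad <- setdiff(unique(as.vector(grid)), c(as.integer(class_codes), nodata))
  if (length(bad))
    stop("unmapped class code(s) in ", path, ": ", paste(bad, collapse = ", "))
  origin <- if (!is.null(hdr$xllcorner))
    list(xll = hdr$xllcorner, yll = hdr$yllcorner) else NULL
  land_raster(grid, cell_size = hdr$cellsize, year = year,
              class_codes = class_codes, nodata = nodata, origin = origin)
}

#' Write a categorical raster as an ESRI ASCII grid
#' @param raster a [land_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path) {
  stopifnot(is_land_raster(raster))
  g <- raster$grid
  xll <- if (!is.null(raster$origin)) raster$origin$xll else 0
  yll <- if (!is.null(raster$origin)) raster$origin$yll else 0
  hdr <- c(paste("ncols", ncol(g)), paste("nrows", nrow(g)),
           paste("xllcorner", xll), paste("yllcorner", yll),
           paste("cellsize", raster$cell_size),
           paste("NODATA_value", raster$nodata))
  body <- apply(g, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Zone mask aligned to a raster
#'
#' A named boolean mask selecting the cells of one analysis zone (e.g.
#' inside a conservation unit).  Zones of one stratification are expected to
#' partition the non-nodata cells.
#'
#' @param mask logical matrix.
#' @param label zone name used in output tables.
#' @return object of class `zone_mask`.
#' @export
zone_mask <- function(mask, label) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("zone '", label, "' is empty")
  structure(list(mask = mask, label = as.character(label)), class = "zone_mask")
}

#' Inside/outside zone pair from a protection mask
#' @param cu_mask logical matrix, TRUE inside the conservation unit(s).
#' @param labels length-2 character: names for the inside and outside zones.
#' @return list of two [zone_mask()] objects.
#' @export
zones_from_mask <- function(cu_mask, labels = c("inside_CU", "outside_CU")) {
  list(zone_mask(cu_mask, labels[1]), zone_mask(!cu_mask, labels[2]))
}

#' Zones from a categorical zone raster
#'
#' Each distinct non-nodata code becomes one zone, named by `labels` (a named
#' vector code -> label) or `zone_<code>`.  Mirrors per-category protected
#' area stratifications (federal / state / county / unprotected).
#'
#' @param zone_grid integer matrix of zone codes.
#' @param labels optional named character vector mapping codes to labels.
#' @param nodata code to ignore.
#' @return list of [zone_mask()] objects.
#' @export
zones_from_grid <- function(zone_grid, labels = NULL, nodata = 0L) {
  codes <- sort(setdiff(unique(as.vector(zone_grid)), nodata))
  lapply(codes, function(code) {
    lab <- if (!is.null(labels) && as.character(code) %in% names(labels))
      labels[[as.character(code)]] else paste0("zone_", code)
    zone_mask(zone_grid == code, lab)
  })
}

#' Rasterize GeoJSON polygons to a zone mask
#'
#' Reads a GeoJSON file of Polygon/MultiPolygon features and marks every cell
#' whose centre point falls inside any outer ring (centre-point containment;
#' holes are not subtracted).  The grid is pinned by the raster's lower-left
#' `origin` and `cell_size`; row 1 is the top row.
#'
#' @param path GeoJSON file path.
#' @param raster the [land_raster()] defining the grid.
#' @param label zone name.
#' @return a [zone_mask()].
#' @export
zone_from_geojson <- function(path, raster, label) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  rings <- list()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(geom$type, "Polygon")) {
      rings <- c(rings, list(geom$coordinates[[1]]))
    } else if (identical(geom$type, "MultiPolygon")) {
      for (poly in geom$coordinates) rings <- c(rings, list(poly[[1]]))
    } else stop("unsupported GeoJSON geometry: ", geom$type)
  }
  if (!length(rings)) stop("no polygon rings in ", path)
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  cs <- raster$cell_size
  xll <- if (!is.null(raster$origin)) raster$origin$xll else 0
  yll <- if (!is.null(raster$origin)) raster$origin$yll else 0
  # cell centres: row 1 is the northernmost row
  cx <- xll + (seq_len(nc) - 0.5) * cs
  cy <- yll + (nr - seq_len(nr) + 0.5) * cs
  pts <- cbind(rep(cx, each = nr), rep(cy, times = nc))
  inside <- rep(FALSE, nr * nc)
  for (ring in rings) {
    bnd <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    bnd <- list(x = bnd[, 1], y = bnd[, 2])
    inside <- inside | mgcv::in.out(cbind(bnd$x, bnd$y), pts)
  }
  zone_mask(matrix(inside, nr, nc), label)
}

#' Restrict a raster to one zone
#'
#' Cells outside the zone become nodata, so patches are clipped at the zone
#' boundary and all downstream metrics see the zone as its own landscape.
#' The zone's substantive area (ha) is recorded for density denominators.
#'
#' @param raster a [land_raster()].
#' @param zone a [zone_mask()] with matching shape.
#' @return a [land_raster()] with attribute `zone_label`.
#' @export
apply_zone <- function(raster, zone) {
  stopifnot(is_land_raster(raster), inherits(zone, "zone_mask"))
  if (!identical(dim(raster$grid), dim(zone$mask)))
    stop("zone mask shape ", paste(dim(zone$mask), collapse = "x"),
         " does not match raster ", paste(dim(raster$grid), collapse = "x"))
  out <- raster
  out$grid[!zone$mask] <- raster$nodata
  out$zone_label <- zone$label
  out
}
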