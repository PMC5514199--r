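#' Minimum raster perimeter of a patch of given area
#'
#' Number of cell sides in the most compact polyomino of `cells` cells: with
#' `n = floor(sqrt(cells))`, the minimum perimeter is `4n` for a perfect
#' square, `4n + 2` when `cells <= n(n+1)`, and `4n + 4` otherwise.
#'
#' @param cells integer vector of patch areas in cells (>= 1).
#' @return integer vector of minimum perimeters in cell sides.
#' @export
min_perimeter_sides <- function(cells) {
  stopifnot(all(cells >= 1))
  n <- floor(sqrt(cells))
  ifelse(n^2 == cells, 4 * n,
         ifelse(cells <= n * (n + 1), 4 * n + 2, 4 * n + 4))
}

#' Patch shape index
#'
#' Ratio of a patch's perimeter to the minimum perimeter achievable by any
#' patch of the same area: 1 for a solid square, increasing with boundary
#' irregularity.
#'
#' @param cells patch area in cells.
#' @param perimeter_sides patch perimeter in cell sides (cell_size cancels).
#' @return shape index (>= 1).
#' @examples
#' shape_index(8, 18)  # 1 x 8 strip -> 1.5
#' @export
shape_index <- function(cells, perimeter_sides) {
  perimeter_sides / min_perimeter_sides(cells)
}

#' Edge density of one class
#'
#' Total class edge length (m) divided by the landscape (zone) area (ha).
#' By default an edge segment is a cell side between the class and a
#' different substantive class; sides facing nodata or the grid boundary are
#' excluded (no-border convention).  `boundary_edge = TRUE` includes them.
#' A class absent from the zone has edge density 0.
#'
#' @param raster a [land_raster()] (already zone-masked if applicable).
#' @param class class label (e.g. "MF") or code.
#' @param zone_area_ha landscape area for the denominator; defaults to the
#'   raster's substantive area.
#' @param boundary_edge include nodata/boundary-facing sides as edge.
#' @return edge density in m/ha.
#' @export
edge_density <- function(raster, class, zone_area_ha = NULL,
                         boundary_edge = FALSE) {
  stopifnot(is_land_raster(raster))
  code <- resolve_class(raster, class)
  if (is.null(zone_area_ha)) zone_area_ha <- landscape_area_ha(raster)
  stopifnot(zone_area_ha > 0)
  sides <- cpp_cell_sides(raster$grid, as.integer(raster$class_codes))
  in_class <- raster$grid == code
  n_sides <- sum(sides$unlike[in_class])
  if (boundary_edge) n_sides <- n_sides + sum(sides$outside[in_class])
  n_sides * raster$cell_size / zone_area_ha
}

#' Clumpiness index of one class
#'
#' Normalised deviation of the class's like-adjacency proportion from its
#' areal proportion: -1 maximally disaggregated (checkerboard), 0
#' indistinguishable from random placement, 1 maximally clumped.  The
#' like-adjacency proportion is `G = g_ii / (sum_k g_ik - min_e)` where
#' `min_e` is the minimum perimeter (in sides) of a maximally compact patch
#' holding the whole class area; when the denominator would be <= 0 it falls
#' back to `g_ii / sum_k g_ik`.  Then
#' `CLUMPY = (G - P) / P` if `G < P` and `P < 0.5`, else `(G - P) / (1 - P)`,
#' clamped to `[-1, 1]`.  Undefined (NA) when the class is absent or fills
#' the whole landscape (`P = 1`).
#'
#' @param adj an [adjacency_table()].
#' @param class class label or code (resolved against the table's names).
#' @return clumpiness in `[-1, 1]`, or `NA`.
#' @export
clumpy <- function(adj, class) {
  stopifnot(inherits(adj, "adjacency_table"))
  lab <- if (class %in% names(adj$P)) class
         else names(adj$P)[match(class, seq_along(adj$P))]
  if (is.na(lab) || !lab %in% names(adj$P)) stop("unknown class: ", class)
  n_i <- adj$cells[[lab]]
  P <- adj$P[[lab]]
  if (n_i == 0L || P >= 1) return(NA_real_)
  g_ii <- adj$g[lab, lab]
  g_row <- sum(adj$g[lab, ])
  if (g_row == 0) return(NA_real_)
  min_e <- min_perimeter_sides(n_i)
  G <- if (g_row - min_e > 0) g_ii / (g_row - min_e) else g_ii / g_row
  val <- if (G < P && P < 0.5) (G - P) / P else (G - P) / (1 - P)
  max(-1, min(1, val))
}

#' Area-weighted mean patch size of one class
#'
#' Each patch weighted by its share of class area:
#' `AREA_AM = sum_j a_j^2 / sum_j a_j` (ha).  `NA` when the class has no
#' patch.
#'
#' @param patches a [label_patches()] result.
#' @param class class label.
#' @return area-weighted mean patch size in ha, or `NA`.
#' @export
area_am <- function(patches, class) {
  a <- patches$patches$area_ha[patches$patches$class == class]
  if (!length(a)) return(NA_real_)
  sum(a^2) / sum(a)
}

#' Area-weighted mean patch shape index of one class
#'
#' Per-patch [shape_index()] weighted by each patch's share of class area.
#' `NA` when the class has no patch.
#'
#' @inheritParams area_am
#' @return area-weighted mean shape index (>= 1), or `NA`.
#' @export
shape_am <- function(patches, class) {
  p <- patches$patches[patches$patches$class == class, ]
  if (!nrow(p)) return(NA_real_)
  si <- shape_index(p$cells, p$perimeter_m / patches$cell_size)
  sum(si * p$area_ha) / sum(p$area_ha)
}

resolve_class <- function(raster, class) {
  codes <- raster$class_codes
  if (is.character(class)) {
    if (!class %in% names(codes)) stop("unknown class label: ", class)
    codes[[class]]
  } else {
    if (!class %in% codes) stop("unknown class code: ", class)
    as.integer(class)
  }
}

#' All four class-level metrics for one raster
#'
#' One row per substantive class with edge density (ED, m/ha), clumpiness
#' (CLUMPY), area-weighted mean patch size (AREA_AM, ha) and shape index
#' (SHAPE_AM), plus class area and patch count.  Metrics that are undefined
#' for a class (absent, or the sole class for CLUMPY) are `NA`, never 0 —
#' except ED, which is 0 for an absent class by definition.
#'
#' @param raster a [land_raster()], typically the output of [apply_zone()].
#' @param boundary_edge passed to [edge_density()].
#' @return tibble with columns `year`, `zone`, `class`, `class_area_ha`,
#'   `n_patches`, `ED`, `CLUMPY`, `AREA_AM`, `SHAPE_AM`.
#' @export
class_metrics <- function(raster, boundary_edge = FALSE) {
  stopifnot(is_land_raster(raster))
  zone_area <- landscape_area_ha(raster)
  if (zone_area <= 0) stop("raster is entirely nodata")
  ps <- label_patches(raster)
  adj <- adjacency_table(raster)
  labs <- names(raster$class_codes)
  rows <- lapply(labs, function(lab) {
    p <- ps$patches[ps$patches$class == lab, ]
    tibble::tibble(
      year = raster$year,
      zone = if (!is.null(raster$zone_label)) raster$zone_label else "all",
      class = lab,
      class_area_ha = sum(p$area_ha),
      n_patches = nrow(p),
      ED = edge_density(raster, lab, zone_area, boundary_edge),
      CLUMPY = clumpy(adj, lab),
      AREA_AM = area_am(ps, lab),
      SHAPE_AM = shape_am(ps, lab))
  })
  do.call(rbind, rows)
}

#' Class metrics for a raster time series across zones
#'
#' The long-format table behind per-class metric trajectories: one record
#' per year x zone x class.  All rasters must share shape and cell size.
#'
#' @param rasters list of [land_raster()] objects (one per mapped year).
#' @param zones list of [zone_mask()] objects, or `NULL` for a single
#'   whole-landscape zone.
#' @param boundary_edge passed to [edge_density()].
#' @return tibble as in [class_metrics()], one row per year x zone x class.
#' @export
metrics_for_series <- function(rasters, zones = NULL, boundary_edge = FALSE) {
  check_aligned_series(rasters)
  if (is.null(zones)) {
    rows <- lapply(rasters, class_metrics, boundary_edge = boundary_edge)
  } else {
    rows <- lapply(rasters, function(r) {
      do.call(rbind, lapply(zones, function(z)
        class_metrics(apply_zone(r, z), boundary_edge = boundary_edge)))
    })
  }
  do.call(rbind, rows)
}

#' Pivot a metrics table to long format
#' @param metrics output of [metrics_for_series()].
#' @return tibble with columns `year`, `zone`, `class`, `metric`, `value`.
#' @export
metrics_long <- function(metrics) {
  cols <- c("ED", "CLUMPY", "AREA_AM", "SHAPE_AM")
  do.call(rbind, lapply(cols, function(m)
    tibble::tibble(year = metrics$year, zone = metrics$zone,
                   class = metrics$class, metric = m,
                   value = metrics[[m]])))
}

check_aligned_series <- function(rasters) {
  stopifnot(length(rasters) >= 1, all(vapply(rasters, is_land_raster, TRUE)))
  d1 <- dim(rasters[[1]]$grid); cs <- rasters[[1]]$cell_size
  for (r in rasters)
    if (!identical(dim(r$grid), d1) || r$cell_size != cs)
      stop("rasters of one series must share shape and cell size")
  invisible(TRUE)
}
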