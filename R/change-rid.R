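#' Per-zone class transition tally between two maps
#'
#' Cross-tabulates class transitions between two aligned maps within each
#' zone.  Deforestation `D` is the area of mature-forest cells becoming
#' non-forest (MF -> NF).  Direct MF -> SF transitions violate the
#' succession rule that secondary forest must be preceded by non-forest;
#' they are tallied in a QC column and excluded from `D` unless
#' `include_mf_to_sf = TRUE`.  SF -> NF clearing is likewise excluded from
#' `D` by default (`include_sf_clearing`).
#'
#' @param r_from,r_to aligned [land_raster()] maps, `r_from$year < r_to$year`.
#' @param zones list of [zone_mask()] objects partitioning the landscape.
#' @param include_sf_clearing count SF -> NF in `D`.
#' @param include_mf_to_sf count MF -> SF in `D` as well as in the QC column.
#' @return object of class `transition_tally`: tibble with one row per zone
#'   (`zone`, `year_from`, `year_to`, `A_ha`, `D_ha`, `qc_mf_to_sf_ha`) and
#'   attribute `matrices`, the per-zone transition count matrices over
#'   classes + nodata.
#' @export
transitions <- function(r_from, r_to, zones = NULL,
                        include_sf_clearing = FALSE,
                        include_mf_to_sf = FALSE) {
  stopifnot(is_land_raster(r_from), is_land_raster(r_to))
  if (!identical(dim(r_from$grid), dim(r_to$grid)))
    stop("rasters are not aligned")
  if (!identical(r_from$class_codes, r_to$class_codes))
    stop("rasters use different class codings")
  if (!is.na(r_from$year) && !is.na(r_to$year) && r_from$year >= r_to$year)
    stop("year_from must precede year_to")
  if (is.null(zones))
    zones <- list(zone_mask(matrix(TRUE, nrow(r_from$grid), ncol(r_from$grid)),
                            "all"))
  codes <- r_from$class_codes
  lev <- c(codes, nodata = r_from$nodata)
  ha <- cell_area_ha(r_from)
  mats <- list()
  rows <- lapply(zones, function(z) {
    if (!identical(dim(z$mask), dim(r_from$grid))) stop("zone mask misaligned")
    from <- factor(r_from$grid[z$mask], levels = lev, labels = names(lev))
    to <- factor(r_to$grid[z$mask], levels = lev, labels = names(lev))
    m <- table(from = from, to = to)
    mats[[z$label]] <<- m
    D <- m["MF", "NF"]
    if (include_sf_clearing) D <- D + m["SF", "NF"]
    if (include_mf_to_sf) D <- D + m["MF", "SF"]
    tibble::tibble(
      zone = z$label,
      year_from = r_from$year, year_to = r_to$year,
      A_ha = sum(m[names(codes), , drop = FALSE]) * ha,
      D_ha = as.numeric(D) * ha,
      qc_mf_to_sf_ha = as.numeric(m["MF", "SF"]) * ha)
  })
  out <- do.call(rbind, rows)
  attr(out, "matrices") <- mats
  class(out) <- c("transition_tally", class(out))
  out
}

#' Relative incidence of deforestation per zone
#'
#' For each zone, the ratio of its share of total deforested area to its
#' share of total landscape area:
#' `RID_i = (D_i / D_total) / (A_i / A_total)`.
#' RID = 1 means deforestation in the zone is proportional to its area;
#' below 1 less than proportional, above 1 disproportionate.  Undefined
#' (`NA`) for all zones when no deforestation occurred in the interval;
#' exactly 0 for a zone with `D_i = 0` while `D_total > 0`.
#'
#' @param tally a [transitions()] result (zones must partition the
#'   landscape for the area-weighted mean identity to hold).
#' @return the tally tibble with a `RID` column appended.
#' @export
rid <- function(tally) {
  stopifnot(inherits(tally, "transition_tally") || is.data.frame(tally))
  A_total <- sum(tally$A_ha)
  if (A_total <= 0) stop("total landscape area is zero")
  D_total <- sum(tally$D_ha)
  out <- tally
  out$RID <- if (D_total == 0) NA_real_
             else (out$D_ha / D_total) / (out$A_ha / A_total)
  out
}

#' RID over every consecutive-map interval of a series
#'
#' @param rasters list of [land_raster()] maps in year order (>= 2).
#' @param zones list of [zone_mask()] objects partitioning the landscape.
#' @param annualize divide deforested area by the interval length in years,
#'   so `D` is an annual rate; RID itself is unchanged by a common factor,
#'   but the reported `D_ha` is.
#' @param ... passed to [transitions()].
#' @return tibble with one row per interval x zone: `zone`, `year_from`,
#'   `year_to`, `interval_yr`, `A_ha`, `D_ha`, `qc_mf_to_sf_ha`, `RID`.
#' @export
rid_series <- function(rasters, zones, annualize = FALSE, ...) {
  check_aligned_series(rasters)
  if (length(rasters) < 2) stop("need at least two maps")
  rows <- lapply(seq_len(length(rasters) - 1), function(i) {
    tal <- rid(transitions(rasters[[i]], rasters[[i + 1]], zones, ...))
    tal$interval_yr <- tal$year_to - tal$year_from
    if (annualize) {
      tal$D_ha <- tal$D_ha / tal$interval_yr
      tal$qc_mf_to_sf_ha <- tal$qc_mf_to_sf_ha / tal$interval_yr
    }
    attr(tal, "matrices") <- NULL
    tal
  })
  out <- do.call(rbind, rows)
  class(out) <- setdiff(class(out), "transition_tally")
  out[c("zone", "year_from", "year_to", "interval_yr",
        "A_ha", "D_ha", "qc_mf_to_sf_ha", "RID")]
}
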