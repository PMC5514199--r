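#' Synthetic landscape-dynamics scenario
#'
#' Describes a seeded simulation of tropical land-cover change on a 30 m
#' grid: deforestation spreading contagiously from road lines, optional
#' fishbone settlement geometry, episodic irregular wildfire scars, regrowth
#' of cleared land to secondary forest after a minimum fallow, re-clearing
#' of secondary forest, and reduced clearing probability inside a
#' conservation-unit mask.  The scenario is a pure value: the same scenario
#' and seed always generate the same series.
#'
#' @param shape integer c(rows, cols).
#' @param cell_size metres per cell side.
#' @param years simulated calendar years (annual).
#' @param gap_years years simulated internally but omitted from the output,
#'   mimicking missing scenes in a mapping record.
#' @param roads list of polylines (matrices with columns row, col) or `NULL`.
#' @param road_decay e-folding scale (in cells, Chebyshev distance) of the
#'   road-proximity clearing kernel.
#' @param budget annual clearing budget in cells.
#' @param contagion fraction of clearing probability mass placed on cells
#'   adjacent to existing non-forest (vs. road-proximal seeding), in [0, 1].
#' @param cu_mask logical matrix marking conservation units, or `NULL`.
#' @param protection multiplier in [0, 1] on clearing probability inside the
#'   CU mask (0 = fully effective protection).
#' @param fires data.frame with columns `year`, `size` (cells),
#'   `irregularity` in [0, 1] (0 = compact near-disc scar, 1 = dendritic).
#' @param fallow_min minimum years a cell stays non-forest before it may
#'   regrow.
#' @param p_regrow annual NF -> SF probability once eligible.
#' @param p_reclear annual SF -> NF probability.
#' @param seed RNG seed recorded with the scenario.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(shape = c(80, 80), cell_size = 30,
                               years = 1984:2011, gap_years = integer(),
                               roads = NULL, road_decay = 6,
                               budget = 40, contagion = 0.6,
                               cu_mask = NULL, protection = 0.3,
                               fires = NULL, fallow_min = 3,
                               p_regrow = 0.2, p_reclear = 0.1,
                               seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 4), cell_size > 0,
            budget >= 0, contagion >= 0, contagion <= 1,
            protection >= 0, protection <= 1,
            p_regrow >= 0, p_regrow <= 1, p_reclear >= 0, p_reclear <= 1,
            fallow_min >= 0)
  if (!is.null(cu_mask))
    stopifnot(is.logical(cu_mask), identical(dim(cu_mask), as.integer(shape)))
  if (!is.null(fires)) {
    stopifnot(all(c("year", "size", "irregularity") %in% names(fires)),
              all(fires$year %in% years),
              all(fires$irregularity >= 0 & fires$irregularity <= 1))
  }
  stopifnot(all(gap_years %in% years))
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 years = as.integer(years),
                 gap_years = as.integer(gap_years),
                 roads = roads, road_decay = road_decay,
                 budget = as.integer(budget), contagion = contagion,
                 cu_mask = cu_mask, protection = protection,
                 fires = fires, fallow_min = as.integer(fallow_min),
                 p_regrow = p_regrow, p_reclear = p_reclear,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Fishbone road network
#'
#' One spine polyline through the grid centre plus perpendicular ribs at a
#' fixed spacing, the clearing geometry of planned colonisation settlements.
#'
#' @param shape integer c(rows, cols).
#' @param orientation `"EW"` (spine along a row) or `"NS"` (along a column).
#' @param spacing rib spacing in cells (>= 2, < the spine length).
#' @return list of polylines (2-column matrices row, col); the spine first.
#' @examples
#' length(fishbone_roads(c(40, 40), spacing = 8))  # 1 spine + 4 ribs
#' @export
fishbone_roads <- function(shape, orientation = c("EW", "NS"), spacing = 8) {
  orientation <- match.arg(orientation)
  nr <- shape[1]; nc <- shape[2]
  stopifnot(spacing >= 2)
  if (orientation == "NS") {
    # transpose of the EW construction
    roads <- fishbone_roads(c(nc, nr), "EW", spacing)
    return(lapply(roads, function(m) {
      m <- m[, 2:1, drop = FALSE]
      colnames(m) <- c("row", "col")
      m
    }))
  }
  if (spacing >= nc) stop("rib spacing exceeds grid width")
  mid <- ceiling(nr / 2)
  spine <- cbind(row = c(mid, mid), col = c(1, nc))
  ribs <- lapply(seq(spacing, nc - 1, by = spacing), function(x)
    cbind(row = c(1, nr), col = c(x, x)))
  c(list(spine), ribs)
}

# Rasterize polylines to a logical mask (Bresenham on cell centres).
rasterize_roads <- function(roads, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (line in roads) {
    for (i in seq_len(nrow(line) - 1)) {
      r0 <- line[i, 1]; c0 <- line[i, 2]
      r1 <- line[i + 1, 1]; c1 <- line[i + 1, 2]
      n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
      rr <- round(seq(r0, r1, length.out = n))
      cc <- round(seq(c0, c1, length.out = n))
      keep <- rr >= 1 & rr <= shape[1] & cc >= 1 & cc <= shape[2]
      mask[cbind(rr[keep], cc[keep])] <- TRUE
    }
  }
  mask
}

# Chebyshev distance (in cells) to the nearest TRUE cell, by iterative
# 8-neighbour dilation; Inf when mask has no TRUE cell.
chebyshev_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[mask] <- 0
  if (!any(mask)) return(d)
  repeat {
    m <- d
    sh <- function(dr, dc) {
      out <- matrix(Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs] <- d[rs - dr, cs - dc]
      out
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      m <- pmin(m, sh(dr, dc) + 1)
    }
    if (identical(m, d)) break
    d <- m
  }
  d
}

# TRUE for cells with at least one queen neighbour satisfying `mask`.
has_neighbor <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- out[rs, cs] | mask[rs - dr, cs - dc]
  }
  out
}

# Grow one connected wildfire scar of `size` cells over mature forest by
# biased accretion: low irregularity prefers frontier cells with many burnt
# rook neighbours (compact, near-disc scar), high irregularity prefers cells
# with few (dendritic scar).
grow_fire_scar <- function(mf, size, irregularity) {
  nr <- nrow(mf); nc <- ncol(mf)
  if (sum(mf) < size)
    stop("wildfire size ", size, " exceeds remaining mature forest ", sum(mf))
  idx_mf <- which(mf)
  seed_cell <- idx_mf[sample.int(length(idx_mf), 1)]
  scar <- matrix(FALSE, nr, nc)
  scar[seed_cell] <- TRUE
  beta <- 1.5 * (1 - 2 * irregularity)  # >0 compact bias, <0 dendritic
  rook <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nbrs_of <- function(cell) {
    r <- (cell - 1) %% nr + 1; c <- (cell - 1) %/% nr + 1
    rr <- r + rook[, 1]; cc <- c + rook[, 2]
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    (cc[keep] - 1) * nr + rr[keep]
  }
  frontier <- setdiff(nbrs_of(seed_cell), which(!mf))
  frontier <- frontier[mf[frontier]]
  while (sum(scar) < size) {
    if (!length(frontier)) {
      # scar boxed in by non-forest; reseed from any remaining forest cell
      rest <- which(mf & !scar)
      frontier <- rest[sample.int(length(rest), 1)]
    }
    ncount <- vapply(frontier, function(cell) sum(scar[nbrs_of(cell)]),
                     numeric(1))
    w <- exp(beta * ncount)
    pick <- frontier[sample.int(length(frontier), 1, prob = w)]
    scar[pick] <- TRUE
    frontier <- frontier[frontier != pick]
    new_nb <- nbrs_of(pick)
    new_nb <- new_nb[mf[new_nb] & !scar[new_nb]]
    frontier <- unique(c(frontier, new_nb))
  }
  scar
}

#' Generate a synthetic land-cover time series
#'
#' Starts from all mature forest (roads rendered as non-forest), then each
#' year: (1) samples `budget` clearing cells among mature forest with
#' probability proportional to a mixture of contagion (adjacency to existing
#' non-forest) and an exponential road-proximity kernel, scaled by the
#' protection factor inside conservation units, and flips them MF -> NF;
#' (2) burns any scheduled wildfire as a connected irregular scar (MF -> NF);
#' (3) regrows eligible non-forest (fallow age >= `fallow_min`, never road
#' cells) to secondary forest with probability `p_regrow`; (4) re-clears
#' secondary forest with probability `p_reclear`.  Gap years are simulated
#' but omitted from the output unless `keep_gap_years = TRUE`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param keep_gap_years return every simulated year (used to audit the
#'   succession rule on the full annual record).
#' @return named list of [land_raster()] objects, one per output year, with
#'   attributes `cu_mask` and `scenario`.
#' @export
generate_series <- function(scenario, keep_gap_years = FALSE) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  nr <- s$shape[1]; nc <- s$shape[2]
  set.seed(s$seed)
  codes <- .landfrag_default_codes
  MF <- codes[["MF"]]; NF <- codes[["NF"]]; SF <- codes[["SF"]]
  grid <- matrix(MF, nr, nc)
  road_mask <- if (!is.null(s$roads)) rasterize_roads(s$roads, s$shape)
               else matrix(FALSE, nr, nc)
  grid[road_mask] <- NF
  kern <- if (any(road_mask))
    exp(-chebyshev_distance(road_mask) / s$road_decay)
  else matrix(1, nr, nc)
  prot <- matrix(1, nr, nc)
  if (!is.null(s$cu_mask)) prot[s$cu_mask] <- s$protection
  fallow <- matrix(0L, nr, nc)  # years since clearing, NF cells only
  out <- list()
  for (year in s$years) {
    # 1. budgeted clearing
    if (s$budget > 0) {
      mf <- grid == MF
      adj_nf <- has_neighbor(grid == NF)
      w <- (s$contagion * adj_nf + (1 - s$contagion) * kern + 1e-9) * prot
      w[!mf] <- 0
      cand <- which(w > 0)
      k <- min(s$budget, length(cand))
      if (k > 0) {
        pick <- cand[sample.int(length(cand), k, prob = w[cand])]
        grid[pick] <- NF
        fallow[pick] <- 0L
      }
    }
    # 2. scheduled wildfire
    if (!is.null(s$fires) && year %in% s$fires$year) {
      for (i in which(s$fires$year == year)) {
        scar <- grow_fire_scar(grid == MF, s$fires$size[i],
                               s$fires$irregularity[i])
        grid[scar] <- NF
        fallow[scar] <- 0L
      }
    }
    # 3. regrowth NF -> SF after minimum fallow
    eligible <- grid == NF & !road_mask & fallow >= s$fallow_min
    if (any(eligible) && s$p_regrow > 0) {
      flip <- eligible & matrix(runif(nr * nc) < s$p_regrow, nr, nc)
      grid[flip] <- SF
    }
    # 4. re-clearing SF -> NF
    sf <- grid == SF
    if (any(sf) && s$p_reclear > 0) {
      flip <- sf & matrix(runif(nr * nc) < s$p_reclear, nr, nc)
      grid[flip] <- NF
      fallow[flip] <- 0L
    }
    fallow[grid == NF] <- fallow[grid == NF] + 1L
    if (keep_gap_years || !(year %in% s$gap_years)) {
      out[[as.character(year)]] <- land_raster(
        grid, cell_size = s$cell_size, year = year, class_codes = codes)
    }
  }
  attr(out, "cu_mask") <- s$cu_mask
  attr(out, "scenario") <- s
  out
}

#' Write a generated series to disk as ASCII grids plus metadata
#'
#' One ESRI ASCII grid per output year (`<prefix>_<year>.asc`), the
#' conservation-unit mask as a 0/1 grid when present, and the scenario
#' parameters (including the seed) as JSON, so a simulated run is fully
#' reproducible from its files.
#'
#' @param rasters output of [generate_series()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of files written, invisibly.
#' @export
write_series <- function(rasters, dir, prefix = "landcover") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (r in rasters) {
    f <- file.path(dir, sprintf("%s_%d.asc", prefix, r$year))
    write_asc(r, f)
    files <- c(files, f)
  }
  cu <- attr(rasters, "cu_mask")
  if (!is.null(cu)) {
    f <- file.path(dir, paste0(prefix, "_cu_mask.asc"))
    write_asc(land_raster(matrix(as.integer(cu), nrow(cu), ncol(cu)),
                          cell_size = rasters[[1]]$cell_size,
                          class_codes = c(CU = 1L)), f)
    files <- c(files, f)
  }
  scn <- attr(rasters, "scenario")
  if (!is.null(scn)) {
    f <- file.path(dir, paste0(prefix, "_scenario.json"))
    meta <- unclass(scn)
    meta$cu_mask <- NULL  # carried by the mask grid
    meta$roads <- lapply(meta$roads, function(m) { dimnames(m) <- NULL; m })
    jsonlite::write_json(meta, f, auto_unbox = TRUE, null = "null")
    files <- c(files, f)
  }
  invisible(files)
}

#' Named scenario presets
#'
#' Three contrasting dynamics regimes on an 80 x 80 grid of 30 m cells,
#' 1984-2011 with short mapping gaps and a conservation unit covering the
#' left ~38% of the landscape:
#' \describe{
#'   \item{isolated_low_pressure}{low clearing budget, no roads, no fires —
#'     a remote, lightly fragmented landscape.}
#'   \item{spontaneous_with_fires}{moderate road-driven clearing plus two
#'     large irregular wildfires (1993, 1998).}
#'   \item{planned_settlement}{fishbone road geometry with a high, strongly
#'     contagious clearing budget.}
#' }
#'
#' @param seed RNG seed stored in every preset.
#' @return named list of [synthetic_scenario()] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  shape <- c(80L, 80L)
  cu <- matrix(FALSE, shape[1], shape[2])
  cu[, 1:30] <- TRUE
  gaps <- c(1987L, 1995L, 2005L, 2006L)
  side_road <- list(cbind(row = c(5, 5), col = c(31, 80)))
  fb <- fishbone_roads(shape, "EW", spacing = 10)
  # keep planned settlement outside the CU: shift ribs/spine right of col 30
  fb <- lapply(fb, function(m) { m[, 2] <- pmax(m[, 2], 31); m })
  list(
    isolated_low_pressure = synthetic_scenario(
      shape = shape, years = 1984:2011, gap_years = gaps,
      roads = NULL, budget = 12, contagion = 0.5,
      cu_mask = cu, protection = 0.3, fires = NULL, seed = seed),
    spontaneous_with_fires = synthetic_scenario(
      shape = shape, years = 1984:2011, gap_years = gaps,
      roads = side_road, budget = 45, contagion = 0.6,
      cu_mask = cu, protection = 0.3,
      fires = data.frame(year = c(1993L, 1998L), size = c(350L, 550L),
                         irregularity = c(0.75, 0.85)),
      seed = seed),
    planned_settlement = synthetic_scenario(
      shape = shape, years = 1984:2011, gap_years = gaps,
      roads = fb, budget = 80, contagion = 0.85,
      cu_mask = cu, protection = 0.3, fires = NULL, seed = seed))
}
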