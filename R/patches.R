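#' Delineate patches by 8-neighbour connectivity
#'
#' Patches are maximal sets of equal-class cells connected under the queen
#' rule (a shared side or corner joins cells into one patch).  Per-patch
#' area is `cells * cell_size^2 / 1e4` ha; perimeter is the number of cell
#' sides adjoining a different class, nodata, or the grid boundary, times
#' `cell_size` metres.
#'
#' @param raster a [land_raster()].
#' @param connectivity 8 (default, queen) or 4 (rook).
#' @return object of class `patch_set`: list with `labels` (integer matrix,
#'   0 = background) and `patches`, a tibble with columns `id`, `class`
#'   (label), `code`, `cells`, `area_ha`, `perimeter_m`.
#' @examples
#' r <- land_raster(matrix(c(1, 2, 2, 1), 2, 2), cell_size = 30)
#' label_patches(r)$patches
#' @export
label_patches <- function(raster, connectivity = 8) {
  stopifnot(is_land_raster(raster))
  ps <- patch_stats(raster$grid, raster$class_codes, raster$cell_size,
                    connectivity)
  structure(list(labels = ps$labels,
                 patches = tibble::as_tibble(ps$patches),
                 cell_size = raster$cell_size,
                 class_codes = raster$class_codes),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches\n", nrow(x$patches)))
  print(x$patches)
  invisible(x)
}

# Low-level patch statistics on a bare integer matrix (hot path for the
# property suites).  Returns plain structures, no tibble overhead.
patch_stats <- function(grid, class_codes, cell_size, connectivity = 8) {
  labels <- cpp_label_patches(grid, as.integer(class_codes),
                              as.integer(connectivity))
  sides <- cpp_cell_sides(grid, as.integer(class_codes))
  per_cell <- sides$unlike + sides$outside
  np <- max(labels)
  if (np == 0L) {
    return(list(labels = labels,
                patches = data.frame(id = integer(), class = character(),
                                     code = integer(), cells = integer(),
                                     area_ha = numeric(),
                                     perimeter_m = numeric())))
  }
  sel <- labels > 0L
  ids <- labels[sel]
  cells <- tabulate(ids, nbins = np)
  perim <- as.vector(rowsum(as.numeric(per_cell[sel]), ids))
  # class of each patch: value of its first cell in scan order
  first <- match(seq_len(np), ids)
  code <- grid[sel][first]
  list(labels = labels,
       patches = data.frame(
         id = seq_len(np),
         class = names(class_codes)[match(code, class_codes)],
         code = code,
         cells = cells,
         area_ha = cells * cell_size^2 / 1e4,
         perimeter_m = perim * cell_size))
}

#' Rook adjacency table between classes
#'
#' Counts cell-side adjacencies between substantive classes with the
#' double-count convention: each ordered (cell, rook-neighbour) pair is one
#' tally, so a shared side between two like cells contributes 2 to
#' `g[i, i]`.  Pairs involving nodata or the grid boundary are excluded.
#' `P` is each class's proportion of the non-nodata area.
#'
#' @param raster a [land_raster()].
#' @return object of class `adjacency_table`: list with `g` (named matrix of
#'   directed tallies), `cells` (named per-class cell counts) and `P` (named
#'   areal proportions).
#' @examples
#' r <- land_raster(matrix(c(1, 1), 1, 2), cell_size = 30)
#' adjacency_table(r)$g  # g["MF","MF"] == 2
#' @export
adjacency_table <- function(raster) {
  stopifnot(is_land_raster(raster))
  codes <- raster$class_codes
  g <- cpp_adjacency(raster$grid, as.integer(codes))
  dimnames(g) <- list(names(codes), names(codes))
  cells <- vapply(codes, function(code) sum(raster$grid == code), integer(1))
  names(cells) <- names(codes)
  total <- sum(cells)
  if (total == 0L) stop("raster is entirely nodata")
  structure(list(g = g, cells = cells, P = cells / total),
            class = "adjacency_table")
}
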