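test_that("land_raster validates its invariants", {
  expect_s3_class(land_raster(matrix(1L, 3, 3)), "land_raster")
  expect_error(land_raster(matrix(1L, 3, 3), cell_size = 0), "positive")
  expect_error(land_raster(matrix(c(1L, 99L), 2, 2)), "99")
  # NA becomes nodata
  g <- matrix(c(1L, NA, 2L, 3L), 2, 2)
  expect_equal(land_raster(g)$grid[2, 1], 0L)
})

test_that("ASCII grid I/O round-trips and rejects unmapped codes", {
  d <- withr::local_tempdir()
  g <- matrix(sample(c(0:3), 30, replace = TRUE), 5, 6)
  r <- land_raster(g, cell_size = 30, year = 1999,
                   origin = list(xll = 100, yll = 200))
  f <- file.path(d, "r.asc")
  write_asc(r, f)
  r2 <- read_asc(f, year = 1999)
  expect_identical(r2$grid, r$grid)
  expect_equal(r2$cell_size, r$cell_size)
  expect_equal(r2$nodata, r$nodata)
  expect_equal(r2$origin$xll, 100)

  # 3x3 all-MF identity read
  write_asc(land_raster(matrix(1L, 3, 3)), f)
  expect_equal(sum(read_asc(f)$grid == 1L), 9)

  # unmapped code errors; remap rescues it
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "NODATA_value -9999", "99 1"), f)
  expect_error(read_asc(f), "unmapped")
  expect_equal(read_asc(f, remap = c("99" = 2))$grid[1, 1], 2L)
})

test_that("apply_zone masks, clips patches, and checks alignment", {
  g <- matrix(1L, 4, 4)
  r <- land_raster(g, cell_size = 30)
  full <- zone_mask(matrix(TRUE, 4, 4), "all")
  expect_identical(apply_zone(r, full)$grid, r$grid)

  half <- zone_mask(cbind(matrix(TRUE, 4, 2), matrix(FALSE, 4, 2)), "left")
  rz <- apply_zone(r, half)
  expect_equal(sum(rz$grid == 1L), 8)
  expect_equal(landscape_area_ha(rz), 8 * 0.09)

  # patch straddling the zone edge is clipped to its inside portion
  g2 <- matrix(2L, 4, 4); g2[2:3, 2:3] <- 1L
  rz2 <- apply_zone(land_raster(g2), half)
  ps <- label_patches(rz2)$patches
  expect_equal(ps$cells[ps$class == "MF"], 2)

  expect_error(apply_zone(r, zone_mask(matrix(TRUE, 3, 3), "bad")), "shape")
  expect_error(zone_mask(matrix(FALSE, 4, 4), "empty"), "empty")
})

test_that("zone stratifications partition and rasterize from GeoJSON", {
  zg <- matrix(rep(1:2, each = 8), 4, 4)
  zones <- zones_from_grid(zg, labels = c("1" = "CU_federal", "2" = "non_CU"))
  expect_setequal(vapply(zones, `[[`, "", "label"), c("CU_federal", "non_CU"))
  m <- Reduce(`+`, lapply(zones, function(z) z$mask))
  expect_true(all(m == 1))  # partition

  d <- withr::local_tempdir()
  gj <- file.path(d, "z.geojson")
  # square polygon covering the left half of a 4x4 grid at 30 m, origin (0,0)
  writeLines(jsonlite::toJSON(list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(list(list(0, 0), list(60, 0),
                                            list(60, 120), list(0, 120),
                                            list(0, 0))))),
    auto_unbox = TRUE), gj)
  r <- land_raster(matrix(1L, 4, 4), cell_size = 30,
                   origin = list(xll = 0, yll = 0))
  z <- zone_from_geojson(gj, r, "inside_CU")
  expect_equal(sum(z$mask), 8)
  expect_true(all(z$mask[, 1:2]))
})

test_that("patch labelling follows the queen rule on known cases", {
  # diagonal-only touch is one patch under the 8-neighbour rule
  g <- matrix(2L, 2, 2); g[1, 1] <- 1L; g[2, 2] <- 1L
  ps <- label_patches(land_raster(g))
  expect_equal(sum(ps$patches$class == "MF"), 1)
  # ... but two patches under rook connectivity
  ps4 <- label_patches(land_raster(g), connectivity = 4)
  expect_equal(sum(ps4$patches$class == "MF"), 2)

  # 3x3 solid block: one patch, 9 cells, perimeter 12 sides
  ps <- label_patches(land_raster(matrix(1L, 3, 3), cell_size = 30))
  expect_equal(nrow(ps$patches), 1)
  expect_equal(ps$patches$cells, 9)
  expect_equal(ps$patches$perimeter_m, 12 * 30)
  expect_equal(ps$patches$area_ha, 9 * 900 / 1e4)
})

test_that("labelling and patch stats match the flood-fill oracle", {
  set.seed(42)
  for (trial in 1:40) {
    nr <- sample(3:12, 1); nc <- sample(3:12, 1)
    g <- random_raster(nr, nc, codes = 0:3)
    r <- land_raster(g, cell_size = 30)
    ps <- label_patches(r)
    expect_identical(ps$labels, oracle_label(g, 1:3))
    ora <- oracle_patch_table(g, 1:3)
    expect_equal(ps$patches$cells, ora$cells)
    expect_equal(ps$patches$perimeter_m / 30, as.numeric(ora$perim))
    expect_equal(ps$patches$code, ora$code)
    # area accounting: patch cells of class i sum to the class cell count
    for (cl in 1:3)
      expect_equal(sum(ps$patches$cells[ps$patches$code == cl]),
                   sum(g == cl))
  }
})

test_that("total perimeter counts unlike sides twice and outside sides once", {
  set.seed(7)
  for (trial in 1:20) {
    g <- random_raster(6, 6, codes = 0:3)
    r <- land_raster(g)
    ps <- label_patches(r)
    # direct enumeration over all cell sides
    unlike2 <- 0L; outside1 <- 0L
    for (j in 1:6) for (i in 1:6) {
      if (!(g[i, j] %in% 1:3)) next
      for (d in 1:4) {
        ni <- i + DIRS4[d, 1]; nj <- j + DIRS4[d, 2]
        off <- ni < 1 || ni > 6 || nj < 1 || nj > 6
        if (off || !(g[ni, nj] %in% 1:3)) outside1 <- outside1 + 1L
        else if (g[ni, nj] != g[i, j]) unlike2 <- unlike2 + 1L
      }
    }
    expect_equal(sum(ps$patches$perimeter_m) / r$cell_size,
                 unlike2 + outside1)  # each unlike side seen from both cells
  }
})

test_that("masking commutes with labelling", {
  set.seed(13)
  for (trial in 1:10) {
    g <- random_raster(8, 8, codes = 1:3)
    mask <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE, c(.7, .3)), 8, 8)
    if (!any(mask)) next
    z <- zone_mask(mask, "z")
    a <- label_patches(apply_zone(land_raster(g), z))
    g2 <- g; g2[!mask] <- 0L
    b <- label_patches(land_raster(g2))
    expect_identical(a$labels, b$labels)
    expect_equal(a$patches, b$patches)
  }
})

test_that("adjacency tallies follow the double-count rook convention", {
  r2 <- function(g) land_raster(g, cell_size = 30)
  expect_equal(adjacency_table(r2(matrix(c(1L, 1L), 1)))$g["MF", "MF"], 2L)
  g <- adjacency_table(r2(matrix(c(1L, 2L), 1)))$g
  expect_equal(g["MF", "NF"], 1L)
  expect_equal(g["NF", "MF"], 1L)
  cb <- adjacency_table(r2(checkerboard(6)))$g
  expect_equal(cb["MF", "MF"], 0L)
  expect_equal(cb["NF", "NF"], 0L)
  # nodata and boundary excluded; P over non-nodata cells
  g3 <- matrix(c(1L, 0L, 2L, 2L), 2, 2)
  adj <- adjacency_table(r2(g3))
  expect_equal(sum(adj$P), 1)
  expect_equal(adj$P[["MF"]], 1 / 3)
  expect_error(adjacency_table(r2(matrix(0L, 2, 2))), "nodata")
  # randomized equivalence with the loop oracle
  set.seed(99)
  for (trial in 1:20) {
    g <- random_raster(7, 5, codes = 0:3)
    adj <- adjacency_table(land_raster(g))
    expect_equal(unname(adj$g), oracle_adjacency(g, 1:3))
  }
})
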