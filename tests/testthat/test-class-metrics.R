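test_that("minimum-perimeter rule matches exhaustive polyomino enumeration", {
  expect_equal(min_perimeter_sides(1:8), polyomino_min_perims(8))
})

test_that("shape index is 1 for squares and matches hand-enumerated shapes", {
  for (n in 1:4) {
    ps <- label_patches(land_raster(matrix(1L, n, n)))
    p <- ps$patches
    expect_equal(shape_index(p$cells, p$perimeter_m / 30), 1)
  }
  # 1x8 strip: perimeter 18 sides, min over all 8-cell polyominoes is 12
  expect_equal(shape_index(8, 18), 1.5)
})

test_that("edge density handles presence, absence and the boundary flag", {
  g <- square_in_matrix()  # 2x2 MF centred in 10x10 NF, 30 m cells
  r <- land_raster(g, cell_size = 30)
  expect_equal(edge_density(r, "MF"), 240 / 9)  # 8 sides * 30 m over 9 ha
  expect_equal(edge_density(r, "SF"), 0)        # absent class
  # class filling the zone: no unlike sides by default, boundary flag flips
  solid <- land_raster(matrix(1L, 5, 5), cell_size = 30)
  expect_equal(edge_density(solid, "MF"), 0)
  expect_equal(edge_density(solid, "MF", boundary_edge = TRUE),
               20 * 30 / (25 * 0.09))
})

test_that("clumpiness hits its analytic anchors", {
  cb <- land_raster(checkerboard(8), cell_size = 30)
  expect_equal(clumpy(adjacency_table(cb), "MF"), -1)
  expect_equal(clumpy(adjacency_table(cb), "NF"), -1)
  # compact square patch away from the boundary is maximally clumped
  adj <- adjacency_table(land_raster(square_in_matrix()))
  expect_equal(clumpy(adj, "MF"), 1)
  # single-class raster: P = 1, undefined
  solo <- land_raster(matrix(1L, 4, 4))
  expect_true(is.na(clumpy(adjacency_table(solo), "MF")))
  expect_true(is.na(clumpy(adjacency_table(solo), "NF")))
})

test_that("area-weighted means follow their closed forms", {
  # 100 m cells make 1 cell = 1 ha: patches of 1 ha and 3 ha -> (1 + 9) / 4
  g <- matrix(2L, 10, 10)
  g[2, 2] <- 1L        # 1 ha single cell
  g[5, 5:7] <- 1L      # 3 ha strip
  ps <- label_patches(land_raster(g, cell_size = 100))
  expect_equal(area_am(ps, "MF"), (1 + 9) / 4)
  expect_true(is.na(area_am(ps, "SF")))
  expect_true(is.na(shape_am(ps, "SF")))

  # m equal patches of area A -> A; all squares -> SHAPE_AM 1
  g2 <- matrix(2L, 9, 9)
  g2[c(2, 5, 8), c(2, 5, 8)] <- 1L  # nine isolated single cells
  ps2 <- label_patches(land_raster(g2, cell_size = 100))
  expect_equal(area_am(ps2, "MF"), 1)
  expect_equal(shape_am(ps2, "MF"), 1)

  # square (4 cells) and 1x8 strip: 1 * (1/3) + 1.5 * (2/3)
  g3 <- matrix(2L, 12, 12)
  g3[2:3, 2:3] <- 1L
  g3[8, 2:9] <- 1L
  ps3 <- label_patches(land_raster(g3, cell_size = 30))
  expect_equal(shape_am(ps3, "MF"), 1 / 3 + 1.5 * 2 / 3)
})

test_that("class_metrics table has sane records and missing semantics", {
  m <- class_metrics(land_raster(square_in_matrix(), cell_size = 30))
  expect_equal(nrow(m), 3)
  sf <- m[m$class == "SF", ]
  expect_equal(sf$ED, 0)
  expect_true(is.na(sf$CLUMPY) && is.na(sf$AREA_AM) && is.na(sf$SHAPE_AM))
  expect_equal(sf$n_patches, 0)
  mf <- m[m$class == "MF", ]
  expect_equal(mf$SHAPE_AM, 1)
  expect_equal(mf$AREA_AM, 4 * 0.09)
})

test_that("metrics_for_series yields year x zone x class records", {
  g <- square_in_matrix()
  r <- function(y) land_raster(g, cell_size = 30, year = y)
  zones <- zones_from_mask(cbind(matrix(TRUE, 10, 5), matrix(FALSE, 10, 5)))
  tab <- metrics_for_series(list(r(1984), r(1990), r(1995)), zones)
  expect_equal(nrow(tab), 3 * 2 * 3)
  # static series: identical metrics every year
  for (col in c("ED", "CLUMPY", "AREA_AM", "SHAPE_AM"))
    expect_true(all(tapply(tab[[col]], paste(tab$zone, tab$class),
                           function(v) length(unique(round(v, 12)))) == 1))
  long <- metrics_long(tab)
  expect_equal(nrow(long), 4 * nrow(tab))

  # clearing event strictly increases ED(MF)
  base <- matrix(1L, 6, 6)
  after <- base; after[3:4, 3:4] <- 2L
  tab2 <- metrics_for_series(list(land_raster(base, year = 2000),
                                  land_raster(after, year = 2001)))
  ed_mf <- tab2$ED[tab2$class == "MF"]
  expect_gt(ed_mf[2], ed_mf[1])
})

test_that("all four metrics match the brute-force oracle on random grids", {
  set.seed(314)
  codes <- c(MF = 1L, NF = 2L, SF = 3L)
  for (trial in 1:60) {
    g <- random_raster(10, 10, codes = if (trial %% 3) 1:3 else 0:3)
    r <- land_raster(g, cell_size = 30)
    ps <- label_patches(r)
    adj <- adjacency_table(r)
    ora <- oracle_metrics(g, 30, codes)
    for (cl in names(codes)) {
      expect_equal(edge_density(r, cl), ora[[cl]][["ED"]], tolerance = 1e-9)
      expect_equal(clumpy(adj, cl), ora[[cl]][["CLUMPY"]], tolerance = 1e-9)
      expect_equal(area_am(ps, cl), ora[[cl]][["AREA_AM"]], tolerance = 1e-9)
      expect_equal(shape_am(ps, cl), ora[[cl]][["SHAPE_AM"]], tolerance = 1e-9)
    }
  }
})

test_that("metric invariants hold on randomized landscapes", {
  set.seed(2718)
  for (trial in 1:30) {
    g <- random_raster(9, 9, codes = 1:3)
    r <- land_raster(g, cell_size = 30)
    m <- class_metrics(r)
    ok <- !is.na(m$CLUMPY)
    expect_true(all(m$CLUMPY[ok] >= -1 & m$CLUMPY[ok] <= 1))
    expect_true(all(m$SHAPE_AM[!is.na(m$SHAPE_AM)] >= 1 - 1e-12))
    expect_true(all(m$ED >= 0))
    ps <- label_patches(r)$patches
    for (cl in unique(ps$class)) {
      a <- ps$area_ha[ps$class == cl]
      am <- m$AREA_AM[m$class == cl]
      expect_gte(am, min(a) - 1e-12)
      expect_lte(am, max(a) + 1e-12)
    }
  }
})

test_that("carving holes raises ED and never raises AREA_AM", {
  g <- matrix(1L, 12, 12)
  holes <- cbind(c(3, 3, 6, 9, 9, 6), c(3, 9, 6, 3, 9, 10))
  prev_ed <- class_metrics(land_raster(g, cell_size = 30))
  prev_ed <- prev_ed$ED[prev_ed$class == "MF"]
  prev_am <- Inf
  for (k in seq_len(nrow(holes))) {
    g[holes[k, 1], holes[k, 2]] <- 2L
    m <- class_metrics(land_raster(g, cell_size = 30))
    ed <- m$ED[m$class == "MF"]; am <- m$AREA_AM[m$class == "MF"]
    expect_gt(ed, prev_ed)
    expect_lte(am, prev_am)
    prev_ed <- ed; prev_am <- am
  }
})

test_that("metrics respond to cell size exactly as dimensional analysis says", {
  set.seed(5)
  g <- random_raster(8, 8, codes = 1:3)
  m1 <- class_metrics(land_raster(g, cell_size = 30))
  m2 <- class_metrics(land_raster(g, cell_size = 60))
  expect_equal(m2$CLUMPY, m1$CLUMPY)
  expect_equal(m2$SHAPE_AM, m1$SHAPE_AM)
  expect_equal(m2$AREA_AM, 4 * m1$AREA_AM)
  expect_equal(m2$ED, m1$ED / 2)
})
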