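# Independent brute-force oracles.  Everything here is deliberately written
# as plain per-cell loops against the definitions, sharing no code with the
# package's vectorized/Rcpp implementation.

DIRS8 <- cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))
DIRS8 <- DIRS8[!(DIRS8[, 1] == 0 & DIRS8[, 2] == 0), ]
DIRS4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))

# flood-fill labelling in scan order (column-major, matching the package's
# deterministic label assignment)
oracle_label <- function(grid, classes, connectivity = 8) {
  nr <- nrow(grid); nc <- ncol(grid)
  dirs <- if (connectivity == 8) DIRS8 else DIRS4
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    v <- grid[i, j]
    if (lab[i, j] != 0L || !(v %in% classes)) next
    nxt <- nxt + 1L
    stack <- matrix(c(i, j), 1)
    lab[i, j] <- nxt
    while (nrow(stack) > 0) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (d in seq_len(nrow(dirs))) {
        ni <- cur[1] + dirs[d, 1]; nj <- cur[2] + dirs[d, 2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (lab[ni, nj] == 0L && grid[ni, nj] == v) {
          lab[ni, nj] <- nxt
          stack <- rbind(stack, c(ni, nj))
        }
      }
    }
  }
  lab
}

# per-patch cells and perimeter sides by direct side counting
oracle_patch_table <- function(grid, classes, connectivity = 8) {
  lab <- oracle_label(grid, classes, connectivity)
  nr <- nrow(grid); nc <- ncol(grid)
  np <- max(lab)
  if (np == 0) return(data.frame(id = integer(), code = integer(),
                                 cells = integer(), perim = integer()))
  cells <- integer(np); perim <- integer(np); code <- integer(np)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    id <- lab[i, j]
    if (id == 0L) next
    cells[id] <- cells[id] + 1L
    code[id] <- grid[i, j]
    for (d in 1:4) {
      ni <- i + DIRS4[d, 1]; nj <- j + DIRS4[d, 2]
      off <- ni < 1 || ni > nr || nj < 1 || nj > nc
      if (off || grid[ni, nj] != grid[i, j] || !(grid[ni, nj] %in% classes))
        perim[id] <- perim[id] + 1L
    }
  }
  data.frame(id = seq_len(np), code = code, cells = cells, perim = perim)
}

# directed rook adjacency tallies among substantive classes
oracle_adjacency <- function(grid, classes) {
  K <- length(classes)
  g <- matrix(0L, K, K)
  nr <- nrow(grid); nc <- ncol(grid)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    a <- match(grid[i, j], classes)
    if (is.na(a)) next
    for (d in 1:4) {
      ni <- i + DIRS4[d, 1]; nj <- j + DIRS4[d, 2]
      if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
      b <- match(grid[ni, nj], classes)
      if (!is.na(b)) g[a, b] <- g[a, b] + 1L
    }
  }
  g
}

# minimum raster perimeter restated from the compactness rule (the rule
# itself is validated against exhaustive polyomino enumeration elsewhere)
oracle_min_perim <- function(z) {
  n <- floor(sqrt(z))
  if (n * n == z) 4 * n else if (z <= n * (n + 1)) 4 * n + 2 else 4 * n + 4
}

# the four class-level metrics straight from their definitions
oracle_metrics <- function(grid, cell_size, classes, boundary_edge = FALSE) {
  pt <- oracle_patch_table(grid, classes)
  adj <- oracle_adjacency(grid, classes)
  nr <- nrow(grid); nc <- ncol(grid)
  n_sub <- sum(grid %in% classes)
  area_ha <- n_sub * cell_size^2 / 1e4
  out <- list()
  for (k in seq_along(classes)) {
    cl <- classes[k]
    n_i <- sum(grid == cl)
    # ED: count unlike-substantive sides cell by cell
    edges <- 0L
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      if (grid[i, j] != cl) next
      for (d in 1:4) {
        ni <- i + DIRS4[d, 1]; nj <- j + DIRS4[d, 2]
        off <- ni < 1 || ni > nr || nj < 1 || nj > nc
        if (off || !(grid[ni, nj] %in% classes)) {
          if (boundary_edge) edges <- edges + 1L
        } else if (grid[ni, nj] != cl) edges <- edges + 1L
      }
    }
    ED <- edges * cell_size / area_ha
    # CLUMPY
    P <- n_i / n_sub
    if (n_i == 0 || P >= 1 || sum(adj[k, ]) == 0) {
      CL <- NA_real_
    } else {
      g_row <- sum(adj[k, ])
      min_e <- oracle_min_perim(n_i)
      G <- if (g_row - min_e > 0) adj[k, k] / (g_row - min_e)
           else adj[k, k] / g_row
      CL <- if (G < P && P < 0.5) (G - P) / P else (G - P) / (1 - P)
      CL <- max(-1, min(1, CL))
    }
    # AREA_AM / SHAPE_AM
    p <- pt[pt$code == cl, ]
    if (nrow(p) == 0) {
      AM <- NA_real_; SH <- NA_real_
    } else {
      a <- p$cells * cell_size^2 / 1e4
      AM <- sum(a^2) / sum(a)
      si <- p$perim / vapply(p$cells, oracle_min_perim, numeric(1))
      SH <- sum(si * a) / sum(a)
    }
    out[[k]] <- c(ED = ED, CLUMPY = CL, AREA_AM = AM, SHAPE_AM = SH)
  }
  names(out) <- names(classes)
  out
}

# per-pixel transition cross-tabulation within a mask
oracle_transitions <- function(g_from, g_to, mask, levels) {
  K <- length(levels)
  m <- matrix(0L, K, K, dimnames = list(names(levels), names(levels)))
  for (idx in which(mask)) {
    a <- match(g_from[idx], levels); b <- match(g_to[idx], levels)
    m[a, b] <- m[a, b] + 1L
  }
  m
}

# exhaustive fixed-polyomino enumeration; returns the minimum perimeter (in
# sides) achievable at each size 1..nmax
polyomino_min_perims <- function(nmax) {
  canon <- function(cells) {
    cells[, 1] <- cells[, 1] - min(cells[, 1])
    cells[, 2] <- cells[, 2] - min(cells[, 2])
    paste(sort(paste(cells[, 1], cells[, 2], sep = ",")), collapse = ";")
  }
  perim <- function(cells) {
    key <- paste(cells[, 1], cells[, 2], sep = ",")
    p <- 0L
    for (k in seq_len(nrow(cells))) for (d in 1:4) {
      nb <- paste(cells[k, 1] + DIRS4[d, 1], cells[k, 2] + DIRS4[d, 2],
                  sep = ",")
      if (!(nb %in% key)) p <- p + 1L
    }
    p
  }
  mins <- integer(nmax)
  mins[1] <- 4L
  current <- list(matrix(c(0L, 0L), 1))
  for (n in 2:nmax) {
    seen <- new.env(hash = TRUE)
    nxt <- list()
    for (poly in current) {
      key <- paste(poly[, 1], poly[, 2], sep = ",")
      for (k in seq_len(nrow(poly))) for (d in 1:4) {
        cand <- c(poly[k, 1] + DIRS4[d, 1], poly[k, 2] + DIRS4[d, 2])
        if (paste(cand[1], cand[2], sep = ",") %in% key) next
        newp <- rbind(poly, cand)
        cn <- canon(newp)
        if (!exists(cn, envir = seen, inherits = FALSE)) {
          assign(cn, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- newp
        }
      }
    }
    current <- nxt
    mins[n] <- min(vapply(current, perim, integer(1)))
  }
  mins
}

# small builders used across files
checkerboard <- function(n = 8) {
  outer(seq_len(n), seq_len(n), function(i, j) ifelse((i + j) %% 2 == 0, 1L, 2L))
}

square_in_matrix <- function() {
  g <- matrix(2L, 10, 10); g[5:6, 5:6] <- 1L; g
}

random_raster <- function(nr, nc, codes = 1:3, p = NULL) {
  matrix(sample(as.integer(codes), nr * nc, replace = TRUE, prob = p), nr, nc)
}
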