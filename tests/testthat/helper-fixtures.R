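# Shared fixtures (built in code) and independent oracles.

# Axis-aligned rectangular channel polygon, metres.
rect_poly <- function(x0, x1, y0, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# Straight east-west channel mask: `len_m` long, `wid_m` wide, lower-left at
# the origin.
straight_mask <- function(len_m = 1000, wid_m = 100, cell = 50) {
  rasterize_river(rect_poly(0, len_m, 0, wid_m), cell_size_m = cell)
}

# L-shaped channel, one cell wide: horizontal arm along the bottom row plus
# vertical arm up the last column.
l_mask <- function(arm_cells = 10, cell = 50) {
  w <- matrix(FALSE, arm_cells, arm_cells)
  w[1, ] <- TRUE
  w[, arm_cells] <- TRUE
  crocspace:::new_mask(w, 0, 0, cell)
}

# A synthetic density surface from an explicit matrix (rows = y, cols = x).
make_surface <- function(dens, row0 = 0, col0 = 0, cell = 50, h = 750) {
  dens <- dens / sum(dens)
  structure(list(density = dens, row0 = row0, col0 = col0,
                 n_rows = nrow(dens), n_cols = ncol(dens),
                 cell_size_m = cell, h_m = h, n_fixes = NA_integer_),
            class = "density_surface")
}

# Independent brute-force KDE: double loop over cells and fixes.
brute_kde <- function(track, surface) {
  cell <- surface$cell_size_m; h <- surface$h_m
  out <- matrix(0, surface$n_rows, surface$n_cols)
  for (r in seq_len(surface$n_rows)) {
    yc <- (surface$row0 + r - 0.5) * cell
    for (cc in seq_len(surface$n_cols)) {
      xc <- (surface$col0 + cc - 0.5) * cell
      s <- 0
      for (i in seq_len(nrow(track)))
        s <- s + exp(-0.5 * ((track$x[i] - xc)^2 + (track$y[i] - yc)^2) / h^2)
      out[r, cc] <- s
    }
  }
  out / sum(out)
}

# Independent all-pairs shortest paths: Floyd-Warshall over the water cells
# of a mask under 8-connectivity (plain loops, no graph library).
floyd_warshall_distances <- function(mask) {
  cells <- crocspace:::water_cells(mask)
  n <- nrow(cells)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(cells$row[i] - cells$row[j]); dc <- abs(cells$col[i] - cells$col[j])
    if (i != j && dr <= 1 && dc <= 1)
      D[i, j] <- mask$cell_size_m * sqrt(dr + dc)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  rownames(D) <- colnames(D) <- cells$key
  D
}

# Straight-river helper for simulation tests.
straight_river <- function(length_km = 60, seed = 1)
  generate_river(river_spec(length_km, n_tributaries = 0, bend_amplitude_m = 0,
                            seed = seed))

# Minimal fix table builder.
fix_df <- function(id, times, x, y, sdop = 1) {
  data.frame(id = id, timestamp = as.POSIXct(times, tz = "UTC"),
             x = x, y = y, sdop = sdop)
}
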