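#' Boolean river raster on the analysis lattice
#'
#' A `river_mask` is a boolean 50 m (by default) raster of navigable water.
#' All grids in the package live on a single global lattice anchored at
#' (0, 0): cell `(row, col)` covers
#' `x in [(col-1), col) * cell`, `y in [(row-1), row) * cell` (global indices,
#' possibly negative), with its centre at `((col-0.5) * cell, (row-0.5) * cell)`.
#' A mask stores the water matrix plus the global row/col offset of its
#' lower-left corner, so any two grids agree cell-for-cell and clipping a
#' contour to the river is an exact key intersection.
#'
#' @name river_mask
NULL

new_mask <- function(water, row0, col0, cell) {
  structure(list(water = water, row0 = as.integer(row0), col0 = as.integer(col0),
                 cell_size_m = cell,
                 n_rows = nrow(water), n_cols = ncol(water),
                 origin_x = col0 * cell, origin_y = row0 * cell),
            class = "river_mask")
}

#' @export
print.river_mask <- function(x, ...) {
  cat(sprintf("<river_mask> %d x %d cells of %g m, %d water cells (%.2f km2)\n",
              x$n_rows, x$n_cols, x$cell_size_m, sum(x$water),
              sum(x$water) * (x$cell_size_m / 1000)^2))
  invisible(x)
}

# centres of all cells as vectors (x by column, y by row)
mask_centres <- function(mask) {
  list(x = (mask$col0 + seq_len(mask$n_cols) - 0.5) * mask$cell_size_m,
       y = (mask$row0 + seq_len(mask$n_rows) - 0.5) * mask$cell_size_m)
}

# data.frame of water cells: local/global indices, centre coords, key
water_cells <- function(mask) {
  idx <- which(mask$water, arr.ind = TRUE)
  ctr <- mask_centres(mask)
  data.frame(row = idx[, 1], col = idx[, 2],
             grow = idx[, 1] + mask$row0, gcol = idx[, 2] + mask$col0,
             x = ctr$x[idx[, 2]], y = ctr$y[idx[, 1]],
             key = cell_key(idx[, 1] + mask$row0, idx[, 2] + mask$col0))
}

# Adjacency among water cells under 8- (or 4-) connectivity, as an edge list
# over water-cell indices 1..n (vectorised over lattice shifts).
water_adjacency <- function(water, connectivity = 8) {
  idx <- which(water, arr.ind = TRUE)
  nid <- matrix(NA_integer_, nrow(water), ncol(water))
  nid[idx] <- seq_len(nrow(idx))
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (sh in shifts) {
    r2 <- idx[, 1] + sh[1]; c2 <- idx[, 2] + sh[2]
    ok <- r2 >= 1 & r2 <= nrow(water) & c2 >= 1 & c2 <= ncol(water)
    ok[ok] <- !is.na(nid[cbind(r2[ok], c2[ok])])
    if (!any(ok)) next
    ef <- c(ef, nid[cbind(idx[ok, 1], idx[ok, 2])])
    et <- c(et, nid[cbind(r2[ok], c2[ok])])
    ew <- c(ew, rep(sqrt(sum(sh^2)), sum(ok)))
  }
  list(idx = idx, from = ef, to = et, wmult = ew)
}

# Keep only the largest 8-connected component of water; warn if any dropped.
keep_largest_component <- function(mask) {
  if (!any(mask$water)) stopf("mask has no water cells")
  adj <- water_adjacency(mask$water, 8)
  g <- igraph::make_empty_graph(n = nrow(adj$idx), directed = FALSE)
  g <- igraph::add_edges(g, rbind(adj$from, adj$to))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    keep <- comp$membership == which.max(comp$csize)
    warnf("water cells form %d components; keeping the largest (%d of %d cells)",
          comp$no, sum(keep), nrow(adj$idx))
    w2 <- matrix(FALSE, mask$n_rows, mask$n_cols)
    w2[adj$idx[keep, , drop = FALSE]] <- TRUE
    mask$water <- w2
  }
  mask
}

#' Rasterise a river (or polygon) to a boolean water mask
#'
#' A cell is water iff its centre lies inside the channel. For a `river`
#' object the channel is the set of points within half the local width of a
#' branch centreline (an exact buffer test, evaluated segment by segment);
#' for a plain polygon (two-column matrix of vertices) containment is tested
#' by even-odd ray casting. If the water cells fall into more than one
#' 8-connected component, the largest is kept with a warning.
#'
#' @param x A `river` object or a two-column numeric matrix of polygon
#'   vertices (metres).
#' @param cell_size_m Raster cell size in metres (default 50).
#' @param bounds Optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   channel extent padded by one cell. Bounds are snapped outward to the
#'   global lattice.
#' @return A [river_mask] object.
#' @export
rasterize_river <- function(x, cell_size_m = 50, bounds = NULL) {
  if (inherits(x, "river")) rasterize_river_channel(x, cell_size_m, bounds)
  else if (is.matrix(x) && ncol(x) == 2) rasterize_polygon(x, cell_size_m, bounds)
  else stopf("x must be a river object or a two-column vertex matrix")
}

lattice_bounds <- function(bounds, cell) {
  col0 <- floor(bounds[1] / cell); col1 <- ceiling(bounds[2] / cell)
  row0 <- floor(bounds[3] / cell); row1 <- ceiling(bounds[4] / cell)
  list(row0 = row0, col0 = col0,
       n_rows = max(1, row1 - row0), n_cols = max(1, col1 - col0))
}

rasterize_river_channel <- function(river, cell_size_m, bounds) {
  allv <- do.call(rbind, lapply(river$branches, function(b) b[c("x", "y", "width")]))
  pad <- max(allv$width) / 2 + cell_size_m
  if (is.null(bounds))
    bounds <- c(min(allv$x) - pad, max(allv$x) + pad,
                min(allv$y) - pad, max(allv$y) + pad)
  lb <- lattice_bounds(bounds, cell_size_m)
  w <- matrix(FALSE, lb$n_rows, lb$n_cols)
  xc <- (lb$col0 + seq_len(lb$n_cols) - 0.5) * cell_size_m
  yc <- (lb$row0 + seq_len(lb$n_rows) - 0.5) * cell_size_m
  for (b in river$branches) {
    n <- nrow(b)
    for (k in seq_len(n - 1)) {
      x1 <- b$x[k]; y1 <- b$y[k]; x2 <- b$x[k + 1]; y2 <- b$y[k + 1]
      wid <- max(b$width[k], b$width[k + 1]) / 2
      jr <- which(xc >= min(x1, x2) - wid - cell_size_m & xc <= max(x1, x2) + wid + cell_size_m)
      ir <- which(yc >= min(y1, y2) - wid - cell_size_m & yc <= max(y1, y2) + wid + cell_size_m)
      if (!length(jr) || !length(ir)) next
      gx <- rep(xc[jr], each = length(ir)); gy <- rep(yc[ir], times = length(jr))
      vx <- x2 - x1; vy <- y2 - y1; L2 <- vx^2 + vy^2
      t <- if (L2 > 0) pmin(1, pmax(0, ((gx - x1) * vx + (gy - y1) * vy) / L2)) else 0
      d2 <- (gx - (x1 + t * vx))^2 + (gy - (y1 + t * vy))^2
      # local width at the nearest point on the segment
      wd <- (b$width[k] + t * (b$width[k + 1] - b$width[k])) / 2
      inside <- d2 <= wd^2
      if (any(inside)) {
        sub <- matrix(inside, length(ir), length(jr))
        w[ir, jr] <- w[ir, jr] | sub
      }
    }
  }
  if (!any(w)) stopf("rasterisation produced an empty mask")
  keep_largest_component(new_mask(w, lb$row0, lb$col0, cell_size_m))
}

rasterize_polygon <- function(verts, cell_size_m, bounds) {
  if (is.null(bounds))
    bounds <- c(min(verts[, 1]), max(verts[, 1]), min(verts[, 2]), max(verts[, 2]))
  lb <- lattice_bounds(bounds, cell_size_m)
  xc <- (lb$col0 + seq_len(lb$n_cols) - 0.5) * cell_size_m
  yc <- (lb$row0 + seq_len(lb$n_rows) - 0.5) * cell_size_m
  px <- verts[, 1]; py <- verts[, 2]
  n <- length(px)
  gx <- rep(xc, each = length(yc)); gy <- rep(yc, times = length(xc))
  inside <- rep(FALSE, length(gx))
  j <- n
  for (i in seq_len(n)) {  # even-odd ray casting, vectorised over cells
    cross <- ((py[i] > gy) != (py[j] > gy)) &
      (gx < (px[j] - px[i]) * (gy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  w <- matrix(inside, lb$n_rows, lb$n_cols)
  if (!any(w)) stopf("rasterisation produced an empty mask")
  keep_largest_component(new_mask(w, lb$row0, lb$col0, cell_size_m))
}

#' Build the water-cell movement graph
#'
#' Connects neighbouring water cells (8-connectivity by default) with edge
#' weights equal to the centre-to-centre Euclidean distance: `cell_size_m`
#' for rook moves and `cell_size_m * sqrt(2)` for diagonal moves. Nodes are
#' the water cells of the largest connected component (a warning reports any
#' cells dropped). Shortest paths through this graph realise the along-river
#' ("least-cost") distance used by all movement metrics.
#'
#' @param mask A [river_mask].
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `river_graph`: the igraph, the mask, a node
#'   table `cells` and a local-index lookup matrix `node_id`.
#' @export
build_graph <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "river_mask"), connectivity %in% c(4, 8))
  cells <- water_cells(mask)
  if (!nrow(cells)) stopf("mask has no water cells")
  adj <- water_adjacency(mask$water, connectivity)
  g <- igraph::make_empty_graph(n = nrow(cells), directed = FALSE)
  g <- igraph::add_edges(g, rbind(adj$from, adj$to))
  igraph::E(g)$weight <- adj$wmult * mask$cell_size_m
  igraph::V(g)$name <- cells$key
  nid <- matrix(NA_integer_, mask$n_rows, mask$n_cols)
  nid[cbind(cells$row, cells$col)] <- seq_len(nrow(cells))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    keep <- which(comp$membership == which.max(comp$csize))
    warnf("movement graph has %d components; keeping the largest (%d of %d cells)",
          comp$no, length(keep), nrow(cells))
    g <- igraph::induced_subgraph(g, keep)
    cells <- cells[keep, , drop = FALSE]
    nid[] <- NA_integer_
    nid[cbind(cells$row, cells$col)] <- seq_len(nrow(cells))
  }
  structure(list(g = g, mask = mask, cells = cells, node_id = nid,
                 connectivity = connectivity),
            class = "river_graph")
}

#' @export
print.river_graph <- function(x, ...) {
  cat(sprintf("<river_graph> %d water cells, %d edges (%d-connectivity)\n",
              igraph::vcount(x$g), igraph::ecount(x$g), x$connectivity))
  invisible(x)
}

#' Snap planar points to the nearest water cell
#'
#' GPS error puts some fixes on the bank; they are snapped (never discarded)
#' to the water cell whose centre is nearest by Euclidean distance, with a
#' deterministic (row, col) tie-break, and the snap distance is reported so
#' gross outliers can be audited.
#'
#' @param x,y Point coordinates in metres (vectors of equal length).
#' @param mask A [river_mask].
#' @return A data frame with the water cell (`row`, `col` local, `key`
#'   global), its centre (`cell_x`, `cell_y`) and `snap_m`.
#' @export
snap_to_river <- function(x, y, mask) {
  stopifnot(inherits(mask, "river_mask"), length(x) == length(y))
  cell <- mask$cell_size_m
  ctr <- mask_centres(mask)
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    c0 <- min(max(ceiling((x[i] - mask$origin_x) / cell), 1L), mask$n_cols)
    r0 <- min(max(ceiling((y[i] - mask$origin_y) / cell), 1L), mask$n_rows)
    r <- 2L
    repeat {
      rr <- max(1L, r0 - r):min(mask$n_rows, r0 + r)
      cc <- max(1L, c0 - r):min(mask$n_cols, c0 + r)
      sub <- which(mask$water[rr, cc, drop = FALSE], arr.ind = TRUE)
      if (nrow(sub)) {
        rows <- rr[sub[, 1]]; cols <- cc[sub[, 2]]
        d <- sqrt((ctr$x[cols] - x[i])^2 + (ctr$y[rows] - y[i])^2)
        dmin <- min(d)
        # guarantee: candidates within dmin of the point may lie outside the
        # window; widen once past dmin before committing
        if (dmin <= (r - 1) * cell || (length(rr) == mask$n_rows && length(cc) == mask$n_cols)) {
          sel <- which(d <= dmin + 1e-9)
          sel <- sel[order(rows[sel], cols[sel])][1]
          out[[i]] <- data.frame(row = rows[sel], col = cols[sel],
                                 key = cell_key(rows[sel] + mask$row0, cols[sel] + mask$col0),
                                 cell_x = ctr$x[cols[sel]], cell_y = ctr$y[rows[sel]],
                                 snap_m = d[sel])
          break
        }
      }
      r <- r * 2L
    }
  }
  do.call(rbind, out)
}

#' Along-river (least-cost) distance between water cells
#'
#' Shortest-path distance in metres through the water-cell graph; the
#' along-river analogue of straight-line distance for a strictly river-bound
#' animal. Symmetric, zero on the diagonal, and never less than the
#' straight-line distance between cell centres.
#'
#' @param from,to Character vectors of cell keys (as in `graph$cells$key`).
#' @param graph A [build_graph()] object.
#' @return A numeric matrix `length(from) x length(to)` of metres.
#' @export
river_distance <- function(from, to, graph) {
  stopifnot(inherits(graph, "river_graph"))
  miss <- setdiff(unique(c(from, to)), graph$cells$key)
  if (length(miss)) stopf("cells not in movement graph: %s", paste(utils::head(miss, 3), collapse = ", "))
  d <- igraph::distances(graph$g, v = from, to = to, algorithm = "dijkstra")
  if (any(!is.finite(d))) stopf("unreachable cell pair in movement graph")
  d
}

#' Write / read a mask as an ESRI ASCII grid
#'
#' Single-band plain-text grid, 1 = water, 0 = land; cell-centre registered
#' via the standard `xllcorner`/`yllcorner` header.
#'
#' @param mask A [river_mask].
#' @param path File path (`.asc`).
#' @return `read_esri_ascii` returns a [river_mask]; `write_esri_ascii`
#'   returns `path` invisibly.
#' @export
write_esri_ascii <- function(mask, path) {
  stopifnot(inherits(mask, "river_mask"))
  hdr <- sprintf(paste0("ncols %d\nnrows %d\nxllcorner %.6f\nyllcorner %.6f\n",
                        "cellsize %.6f\nNODATA_value -9999"),
                 mask$n_cols, mask$n_rows, mask$origin_x, mask$origin_y,
                 mask$cell_size_m)
  body <- apply(mask$water[rev(seq_len(mask$n_rows)), , drop = FALSE], 1,
                function(r) paste(as.integer(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) as.numeric(sub(paste0("^", key, "\\s+"), "", hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]))
  ncols <- val("ncols"); nrows <- val("nrows")
  x0 <- val("xllcorner"); y0 <- val("yllcorner"); cell <- val("cellsize")
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  w <- m[rev(seq_len(nrows)), , drop = FALSE] == 1
  new_mask(w, round(y0 / cell), round(x0 / cell), cell)
}
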