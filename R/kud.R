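#' Fixed-kernel configuration
#'
#' The utilisation distribution is estimated with the fixed-kernel method:
#' an isotropic bivariate Gaussian kernel of standard deviation `h_m` in
#' both axes, one global bandwidth for all fixes. The default `h_m = 750` m
#' trades off contiguity of the home-range boundary along the river against
#' fidelity to the outermost locations; least-squares cross-validation and
#' the reference bandwidth are available as diagnostics ([h_lscv()],
#' [h_ref()]) but are not used by default, as the former fragments a
#' river-bound range into disjunct contours and the latter inflates it far
#' beyond the outermost fixes.
#'
#' @param h_m Kernel SD (smoothing parameter) in metres, default 750.
#' @param grid_cell_m Analysis grid cell size (m), default 50, matching the
#'   river raster so clipping is cell-wise exact.
#' @param extent_pad_m Padding of the fix bounding box (default `4 * h_m`,
#'   keeping truncated tail mass below 1e-4).
#' @return An object of class `kde_config`.
#' @export
kde_config <- function(h_m = 750, grid_cell_m = 50, extent_pad_m = 4 * h_m) {
  stopifnot(h_m > 0, grid_cell_m > 0, extent_pad_m >= 0)
  structure(list(h_m = h_m, grid_cell_m = grid_cell_m, extent_pad_m = extent_pad_m),
            class = "kde_config")
}

#' Estimate a fixed-kernel utilisation distribution
#'
#' Evaluates, at every cell centre of a grid on the global analysis lattice,
#' the sum over fixes of the isotropic bivariate Gaussian kernel with SD
#' `cfg$h_m`, and normalises the surface to unit total mass. The grid covers
#' the fix bounding box padded by `cfg$extent_pad_m`. The Gaussian kernel is
#' separable, so the surface is computed as a cross-product of per-axis
#' kernel matrices rather than a double loop over cells and fixes.
#'
#' @param track Data frame of fixes (`x`, `y`); at least 5 required.
#' @param cfg A [kde_config()].
#' @return An object of class `density_surface`: `density` (rows = y,
#'   cols = x; sums to 1), `row0`/`col0` (global lattice offsets),
#'   `cell_size_m`, `h_m`, `n_fixes`.
#' @export
estimate_kde <- function(track, cfg = kde_config()) {
  stopifnot(inherits(cfg, "kde_config"))
  if (nrow(track) < 5)
    stopf("at least 5 retained fixes are required for a kernel surface (got %d)", nrow(track))
  cell <- cfg$grid_cell_m; h <- cfg$h_m; pad <- cfg$extent_pad_m
  lb <- lattice_bounds(c(min(track$x) - pad, max(track$x) + pad,
                         min(track$y) - pad, max(track$y) + pad), cell)
  xc <- (lb$col0 + seq_len(lb$n_cols) - 0.5) * cell
  yc <- (lb$row0 + seq_len(lb$n_rows) - 0.5) * cell
  # kernel matrices: fixes x grid-axis; constants cancel in the normalisation
  kx <- exp(-0.5 * (outer(track$x, xc, "-") / h)^2)
  ky <- exp(-0.5 * (outer(track$y, yc, "-") / h)^2)
  dens <- crossprod(ky, kx)            # n_rows x n_cols
  dens <- dens / sum(dens)
  structure(list(density = dens, row0 = lb$row0, col0 = lb$col0,
                 n_rows = lb$n_rows, n_cols = lb$n_cols,
                 cell_size_m = cell, h_m = h, n_fixes = nrow(track)),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("<density_surface> %d x %d cells of %g m, h = %g m, %d fixes\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$h_m, x$n_fixes))
  invisible(x)
}

#' Volume contour of a utilisation distribution
#'
#' The level-p volume contour is the smallest set of grid cells containing
#' at least a fraction `level` of the surface's mass: cells are accumulated
#' in decreasing density order (ties broken by row then column) until the
#' cumulative mass first reaches `level`. The area is the cell count times
#' the cell area.
#'
#' @param surface A [estimate_kde()] surface.
#' @param level Proportion in (0, 1); 0.50 and 0.95 are the conventional
#'   core and home-range levels.
#' @return An object of class `volume_contour`: global `rows`, `cols`,
#'   `keys`, per-cell `density`, centre `x`/`y`, `mass`, `area_km2`,
#'   `clipped`, `reduction_percent`.
#' @export
volume_contour <- function(surface, level) {
  stopifnot(inherits(surface, "density_surface"), level > 0, level < 1)
  d <- surface$density
  rows <- as.vector(row(d)); cols <- as.vector(col(d)); v <- as.vector(d)
  o <- order(-v, rows, cols)
  cum <- cumsum(v[o])
  k <- which(cum >= level)[1]
  sel <- o[seq_len(k)]
  cell <- surface$cell_size_m
  structure(list(level = level,
                 rows = rows[sel] + surface$row0, cols = cols[sel] + surface$col0,
                 keys = cell_key(rows[sel] + surface$row0, cols[sel] + surface$col0),
                 density = v[sel],
                 x = (cols[sel] + surface$col0 - 0.5) * cell,
                 y = (rows[sel] + surface$row0 - 0.5) * cell,
                 mass = cum[k], area_km2 = k * (cell / 1000)^2,
                 cell_size_m = cell, clipped = FALSE,
                 reduction_percent = NA_real_, unclipped_area_km2 = NA_real_),
            class = "volume_contour")
}

#' @export
print.volume_contour <- function(x, ...) {
  cat(sprintf("<volume_contour> KUD %d%%%s: %d cells, %.3f km2%s\n",
              round(100 * x$level), if (x$clipped) " (river-clipped)" else "",
              length(x$keys), x$area_km2,
              if (x$clipped) sprintf(" (reduction %.1f%%)", x$reduction_percent) else ""))
  invisible(x)
}

#' Clip a volume contour to the river channel
#'
#' Intersects the contour's cell set with the water cells of the river mask
#' and recomputes the area; `reduction_percent` records how much of the
#' unconstrained kernel area fell on land (habitat inaccessible to a
#' river-bound animal). Both grids live on the same lattice, so the clip is
#' an exact cell-key intersection.
#'
#' @param contour A [volume_contour()].
#' @param mask A [river_mask].
#' @return The clipped `volume_contour`.
#' @export
clip_to_river <- function(contour, mask) {
  stopifnot(inherits(contour, "volume_contour"), inherits(mask, "river_mask"))
  if (contour$cell_size_m != mask$cell_size_m)
    stopf("contour and mask cell sizes differ (%g vs %g m)",
          contour$cell_size_m, mask$cell_size_m)
  wk <- water_cells(mask)$key
  keep <- contour$keys %in% wk
  if (!any(keep)) stopf("contour does not intersect the river mask")
  out <- contour
  for (f in c("rows", "cols", "keys", "density", "x", "y"))
    out[[f]] <- contour[[f]][keep]
  out$unclipped_area_km2 <- contour$area_km2
  out$area_km2 <- sum(keep) * (contour$cell_size_m / 1000)^2
  out$reduction_percent <- 100 * (1 - out$area_km2 / contour$area_km2)
  out$mass <- sum(out$density)     # mass actually enclosed after clipping
  out$clipped <- TRUE
  out
}

#' Centroid of the core-use area
#'
#' Density-weighted mean position of the river-clipped 50% contour cells
#' (or unweighted with `geometric = TRUE`), snapped to the nearest water
#' cell so that along-river distances from the centroid are defined.
#'
#' @param contour50 A river-clipped 50% [volume_contour()].
#' @param mask A [river_mask].
#' @param geometric If `TRUE`, use the unweighted cell-centre mean.
#' @return A one-row data frame as from [snap_to_river()], plus the
#'   unsnapped mean (`mean_x`, `mean_y`).
#' @export
kud_centroid <- function(contour50, mask, geometric = FALSE) {
  stopifnot(inherits(contour50, "volume_contour"))
  if (!length(contour50$keys)) stopf("empty contour")
  w <- if (geometric) rep(1, length(contour50$x)) else contour50$density
  mx <- sum(w * contour50$x) / sum(w)
  my <- sum(w * contour50$y) / sum(w)
  out <- snap_to_river(mx, my, mask)
  out$mean_x <- mx; out$mean_y <- my
  out
}

#' Cumulative analysis windows
#'
#' Windows share a common start and have strictly increasing ends; the
#' default six are 01 September through the end of each month to 28
#' February, matching a breeding-to-nesting season of tracking.
#'
#' @param start Common start date.
#' @param ends Vector of window end dates (strictly increasing).
#' @return An object of class `analysis_windows`.
#' @export
analysis_windows <- function(start = "2010-09-01",
                             ends = c("2010-09-30", "2010-10-31", "2010-11-30",
                                      "2010-12-31", "2011-01-31", "2011-02-28")) {
  start <- as.Date(start); ends <- as.Date(ends)
  if (any(diff(ends) <= 0) || any(ends <= start))
    stopf("window ends must be strictly increasing and after the start")
  structure(list(start = start, ends = ends), class = "analysis_windows")
}

#' Cumulative monthly KUD series
#'
#' For each window, estimates the kernel surface from all fixes between the
#' common start and the window end, extracts the 95% and 50% volume
#' contours, clips them to the river and records the areas. A stabilising
#' series (areas flat as data accumulate) is the signature of site
#' fidelity; a climbing series is the signature of nomadism. Windows with
#' fewer than 5 fixes yield missing values with a warning.
#'
#' @param track Filtered fixes for one individual.
#' @param windows An [analysis_windows()].
#' @param cfg A [kde_config()].
#' @param mask A [river_mask].
#' @return Data frame: `window_end`, `n_fixes`, `kud95_km2`, `kud50_km2`
#'   (clipped), `kud95_unclipped_km2`, `kud50_unclipped_km2`,
#'   `reduction95_percent`, `reduction50_percent`.
#' @export
cumulative_kuds <- function(track, windows = analysis_windows(),
                            cfg = kde_config(), mask) {
  stopifnot(inherits(windows, "analysis_windows"))
  res <- lapply(seq_along(windows$ends), function(i) {
    end <- windows$ends[i]
    d <- as.Date(track$timestamp, tz = "UTC")
    sub <- track[d >= windows$start & d <= end, , drop = FALSE]
    if (nrow(sub) < 5) {
      warnf("window ending %s has %d fixes (< 5); emitting missing values",
            format(end), nrow(sub))
      return(data.frame(window_end = end, n_fixes = nrow(sub),
                        kud95_km2 = NA_real_, kud50_km2 = NA_real_,
                        kud95_unclipped_km2 = NA_real_, kud50_unclipped_km2 = NA_real_,
                        reduction95_percent = NA_real_, reduction50_percent = NA_real_))
    }
    surf <- estimate_kde(sub, cfg)
    c95 <- clip_to_river(volume_contour(surf, 0.95), mask)
    c50 <- clip_to_river(volume_contour(surf, 0.50), mask)
    data.frame(window_end = end, n_fixes = nrow(sub),
               kud95_km2 = c95$area_km2, kud50_km2 = c50$area_km2,
               kud95_unclipped_km2 = c95$unclipped_area_km2,
               kud50_unclipped_km2 = c50$unclipped_area_km2,
               reduction95_percent = c95$reduction_percent,
               reduction50_percent = c50$reduction_percent)
  })
  do.call(rbind, res)
}

#' Bandwidth diagnostics
#'
#' `h_ref` is the bivariate reference (normal-optimal) bandwidth
#' `0.5 * (sd_x + sd_y) * n^(-1/6)`; `h_lscv` minimises the least-squares
#' cross-validation score for the bivariate Gaussian kernel over a bracket.
#' Both are provided for diagnosis only and are deliberately not defaults:
#' on strictly river-bound ranges LSCV fragments the distribution into
#' disjunct contours and the reference bandwidth spreads mass far beyond
#' the outermost fixes.
#'
#' @param track Data frame of fixes (`x`, `y`).
#' @return Bandwidth in metres.
#' @export
h_ref <- function(track) {
  n <- nrow(track)
  0.5 * (stats::sd(track$x) + stats::sd(track$y)) * n^(-1 / 6)
}

#' @rdname h_ref
#' @param lower,upper Search bracket in metres.
#' @export
h_lscv <- function(track, lower = 25, upper = 3000) {
  d2 <- as.vector(stats::dist(cbind(track$x, track$y)))^2
  n <- nrow(track)
  score <- function(h) {
    # integral of fhat^2 minus twice the leave-one-out mean density
    int_f2 <- (n + 2 * sum(exp(-d2 / (4 * h^2)))) / (n^2 * 4 * pi * h^2)
    loo <- 2 * sum(exp(-d2 / (2 * h^2))) / (pi * h^2 * n * (n - 1))
    int_f2 - loo
  }
  stats::optimize(score, c(lower, upper))$minimum
}

#' Export contours as GeoJSON
#'
#' Writes each contour as a GeoJSON Feature whose geometry is a
#' MultiPolygon of its grid cells (adjacent cells in a row are merged into
#' rectangles), with level, clipped flag and area properties.
#'
#' @param contours Named list of [volume_contour()] objects.
#' @param path Output path.
#' @export
write_contours_geojson <- function(contours, path) {
  feat <- lapply(names(contours), function(nm) {
    ct <- contours[[nm]]
    cell <- ct$cell_size_m
    polys <- list()
    for (r in unique(ct$rows)) {
      cs <- sort(ct$cols[ct$rows == r])
      runs <- split(cs, cumsum(c(1, diff(cs) != 1)))
      for (run in runs) {
        x0 <- (min(run) - 1) * cell; x1 <- max(run) * cell
        y0 <- (r - 1) * cell; y1 <- r * cell
        polys[[length(polys) + 1]] <-
          list(list(list(x0, y0), list(x1, y0), list(x1, y1), list(x0, y1), list(x0, y0)))
      }
    }
    list(type = "Feature",
         properties = list(name = nm, level = ct$level, clipped = ct$clipped,
                           area_km2 = ct$area_km2,
                           reduction_percent = ct$reduction_percent),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
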