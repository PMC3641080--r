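#' Specification of a synthetic branching estuarine river
#'
#' Describes the geometry of a synthetic stand-in for a branching estuarine
#' river catchment: a meandering main channel plus optional tributaries, each
#' carried as a planar polyline (metres) with a channel width attached to
#' every vertex. Widths taper from `max(channel_width_m)` at the river mouth
#' to `min(channel_width_m)` at the upstream tips, mimicking an estuary.
#'
#' @param main_channel_length_km Length of the main channel centreline (km).
#' @param n_tributaries Number of tributaries branching off the main channel.
#' @param channel_width_m Length-2 numeric, `c(min, max)` channel width in
#'   metres. The minimum must be at least `2 * min_cell_size_m` so the
#'   rasterised channel cannot fall apart into disconnected cells.
#' @param bend_amplitude_m Controls meander strength (metres); larger values
#'   give a more sinuous channel.
#' @param min_cell_size_m Cell size (metres) the river is intended to be
#'   rasterised at; only used to validate `channel_width_m`.
#' @param seed Integer seed; the generated geometry is a pure function of the
#'   spec including this seed.
#' @return An object of class `river_spec`.
#' @seealso [generate_river()]
#' @export
river_spec <- function(main_channel_length_km,
                       n_tributaries = 0,
                       channel_width_m = c(150, 400),
                       bend_amplitude_m = 300,
                       min_cell_size_m = 50,
                       seed = 1) {
  stopifnot(length(main_channel_length_km) == 1, main_channel_length_km > 0,
            n_tributaries >= 0, length(channel_width_m) %in% c(1, 2),
            bend_amplitude_m >= 0)
  channel_width_m <- range(channel_width_m)
  if (channel_width_m[1] < 2 * min_cell_size_m)
    stopf("channel_width_m minimum (%g m) is below 2 x cell size (%g m); the rasterised channel could disconnect",
          channel_width_m[1], 2 * min_cell_size_m)
  structure(list(main_channel_length_km = main_channel_length_km,
                 n_tributaries = as.integer(n_tributaries),
                 channel_width_m = channel_width_m,
                 bend_amplitude_m = bend_amplitude_m,
                 min_cell_size_m = min_cell_size_m,
                 seed = as.integer(seed)),
            class = "river_spec")
}

# One meandering polyline of exactly `length_m`, starting at `start` with base
# direction `base_dir`. Headings follow an AR(1) process clamped to +/- `clamp`
# radians about base_dir, which keeps the curve monotone along base_dir and
# therefore simple (non-self-intersecting).
meander_polyline <- function(length_m, start, base_dir, heading_sd,
                             step_m = 500, clamp = 1.05, phi = 0.92) {
  n <- max(2L, round(length_m / step_m))
  ds <- length_m / n
  dev <- numeric(n)
  for (k in 2:n) dev[k] <- max(-clamp, min(clamp, phi * dev[k - 1] + stats::rnorm(1, 0, heading_sd)))
  theta <- base_dir + dev
  x <- start[1] + cumsum(c(0, ds * cos(theta)))
  y <- start[2] + cumsum(c(0, ds * sin(theta)))
  data.frame(x = x, y = y, s = seq(0, length_m, length.out = n + 1))
}

min_dist_between <- function(a, b) {
  # min distance between two vertex sets (coarse clearance check)
  min(sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2))
}

#' Generate a synthetic branching river centreline
#'
#' Draws a meandering main channel of exactly the requested length (the
#' polyline is built from equal arc-length steps, so its centreline length
#' matches `main_channel_length_km` to machine precision) and attaches
#' `n_tributaries` side branches at interior junctions. Each branch is
#' monotone along its own base direction, hence simple; tributaries are
#' re-drawn (up to 25 attempts) if they pass within one channel width of
#' another branch away from their junction, so the returned network is a
#' non-self-intersecting tree. Channel width is attached per vertex, tapering
#' upstream.
#'
#' @param spec A [river_spec()].
#' @return An object of class `river`: a list with `branches` (data frames
#'   `x`, `y`, `s` (arc length, m), `width`), `topology` (branch, parent,
#'   attach_s), `total_length_km` and the originating `spec`.
#' @export
generate_river <- function(spec) {
  stopifnot(inherits(spec, "river_spec"))
  with_seed(spec$seed, {
    L <- spec$main_channel_length_km * 1000
    wmin <- spec$channel_width_m[1]; wmax <- spec$channel_width_m[2]
    heading_sd <- spec$bend_amplitude_m / 2000
    main <- meander_polyline(L, c(0, 0), 0, heading_sd)
    main$width <- wmax + (wmin - wmax) * main$s / L
    branches <- list(main)
    topology <- data.frame(branch = 1L, parent = NA_integer_, attach_s = NA_real_)
    if (spec$n_tributaries > 0) {
      # junctions spread over the middle reaches, alternating banks
      fr <- seq(0.3, 0.8, length.out = spec$n_tributaries) +
        stats::runif(spec$n_tributaries, -0.04, 0.04)
      for (j in seq_len(spec$n_tributaries)) {
        attach_s <- fr[j] * L
        iv <- which.min(abs(main$s - attach_s))
        side <- if (j %% 2 == 1) 1 else -1
        dir_main <- atan2(main$y[min(iv + 1, nrow(main))] - main$y[max(iv - 1, 1)],
                          main$x[min(iv + 1, nrow(main))] - main$x[max(iv - 1, 1)])
        for (try in 1:25) {
          tl <- stats::runif(1, 0.15, 0.30) * L
          base <- dir_main + side * stats::runif(1, 0.9, 1.3)
          tb <- meander_polyline(tl, c(main$x[iv], main$y[iv]), base,
                                 heading_sd, clamp = 0.8)
          # clearance: beyond its first 2 km a tributary must stay clear of
          # every existing branch (junction vicinity excluded on main too)
          far <- tb[tb$s > 2000, , drop = FALSE]
          ok <- TRUE
          if (nrow(far)) {
            for (b in seq_along(branches)) {
              other <- branches[[b]]
              if (b == 1L) other <- other[abs(other$s - main$s[iv]) > 1500, , drop = FALSE]
              if (nrow(other) && min_dist_between(far, other) < 1.5 * wmax) { ok <- FALSE; break }
            }
          }
          if (ok) break
        }
        w0 <- main$width[iv] * 0.8
        tb$width <- pmax(wmin, w0 + (wmin - w0) * tb$s / max(tb$s))
        branches[[length(branches) + 1L]] <- tb
        topology <- rbind(topology,
                          data.frame(branch = length(branches), parent = 1L,
                                     attach_s = main$s[iv]))
      }
    }
    total <- sum(vapply(branches, function(b) max(b$s), 0))
    structure(list(branches = branches, topology = topology,
                   total_length_km = total / 1000, spec = spec),
              class = "river")
  })
}

#' @export
print.river <- function(x, ...) {
  cat(sprintf("<river> main channel %.1f km, %d tributaries, total %.1f km of centreline\n",
              max(x$branches[[1]]$s) / 1000, nrow(x$topology) - 1L, x$total_length_km))
  invisible(x)
}

# Interpolate x, y (and width) at along-branch positions s (metres).
river_position <- function(river, s, branch = 1L) {
  b <- river$branches[[branch]]
  s <- pmin(pmax(s, 0), max(b$s))
  data.frame(x = stats::approx(b$s, b$x, s)$y,
             y = stats::approx(b$s, b$y, s)$y,
             width = stats::approx(b$s, b$width, s)$y)
}

#' Export the river channel outline as WKT
#'
#' Builds an approximate channel outline polygon for each branch by offsetting
#' the centreline by half the local width on either side, and returns a WKT
#' MULTIPOLYGON string. Intended for display/interchange; rasterisation uses
#' exact distance-to-centreline buffering, not this outline.
#'
#' @param river A [generate_river()] object.
#' @return A WKT character scalar.
#' @export
river_wkt <- function(river) {
  polys <- vapply(river$branches, function(b) {
    n <- nrow(b)
    dx <- c(diff(b$x), 0) + c(0, diff(b$x))
    dy <- c(diff(b$y), 0) + c(0, diff(b$y))
    len <- sqrt(dx^2 + dy^2); len[len == 0] <- 1
    nx <- -dy / len; ny <- dx / len
    lx <- b$x + nx * b$width / 2; ly <- b$y + ny * b$width / 2
    rx <- b$x - nx * b$width / 2; ry <- b$y - ny * b$width / 2
    ring <- rbind(cbind(lx, ly), cbind(rev(rx), rev(ry)), cbind(lx[1], ly[1]))
    sprintf("((%s))", paste(sprintf("%.1f %.1f", ring[, 1], ring[, 2]), collapse = ", "))
  }, "")
  sprintf("MULTIPOLYGON(%s)", paste(polys, collapse = ", "))
}
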