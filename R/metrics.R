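#' Snap a track to the water-cell grid
#'
#' Adds the nearest-water-cell columns from [snap_to_river()] to every fix.
#' Off-river fixes (GPS error on the banks) are snapped rather than
#' discarded; inspect `snap_m` to audit gross outliers.
#'
#' @param track Data frame of fixes (`x`, `y`).
#' @param mask A [river_mask].
#' @return `track` with `row`, `col`, `key`, `cell_x`, `cell_y`, `snap_m`.
#' @export
snap_track <- function(track, mask) {
  sn <- snap_to_river(track$x, track$y, mask)
  cbind(track, sn)
}

#' Along-river step distances between consecutive fixes
#'
#' For each pair of consecutive fixes the minimum distance moved is the
#' shortest path along the river (through the water-cell graph), not the
#' straight line. Each interval is labelled by the clock time of its
#' closing fix: a fix at or before 08:00 (or after 18:00) closes the
#' night interval, otherwise the day interval; with the default 08:00 /
#' 18:00 schedule night spans 14 h and day 10 h. Intervals longer than
#' `max_gap_h` (missed fixes) are flagged and excluded from rate-of-movement
#' means but still contribute to total distance.
#'
#' @param track_s A [snap_track()]ed track, time-ordered.
#' @param graph A [build_graph()] movement graph.
#' @param max_gap_h Gap threshold in hours (default 36).
#' @return Data frame: `t0`, `t1`, `duration_h`, `label` (day/night),
#'   `distance_m`, `include_in_rom`.
#' @export
step_distances <- function(track_s, graph, max_gap_h = 36) {
  n <- nrow(track_s)
  if (n < 2) return(data.frame(t0 = as.POSIXct(character()), t1 = as.POSIXct(character()),
                               duration_h = numeric(0), label = character(0),
                               distance_m = numeric(0), include_in_rom = logical(0)))
  track_s <- track_s[order(track_s$timestamp), ]
  uk <- unique(track_s$key)
  D <- river_distance(uk, uk, graph)
  i <- match(track_s$key, uk)
  d <- D[cbind(i[-n], i[-1])]
  t0 <- track_s$timestamp[-n]; t1 <- track_s$timestamp[-1]
  dur <- as.numeric(difftime(t1, t0, units = "hours"))
  h1 <- hour_of(t1)
  label <- ifelse(h1 <= 8 | h1 > 18, "night", "day")
  data.frame(t0 = t0, t1 = t1, duration_h = dur, label = label,
             distance_m = d, include_in_rom = dur <= max_gap_h)
}

#' Rates of movement
#'
#' Day and night ROM are the means, over valid (non-gap) intervals of each
#' label, of along-river distance divided by the actual interval duration
#' (10 h day, 14 h night under the default schedule, not a nominal 12 h).
#' Daily ROM is the total distance closed on each calendar day, in km/day.
#'
#' @param steps A [step_distances()] table.
#' @return A list: `day_rom_m_per_h`, `night_rom_m_per_h`,
#'   `total_distance_km`, `daily_rom` (data frame `date`, `km`).
#' @export
rate_of_movement <- function(steps) {
  rom <- function(lab) {
    s <- steps[steps$label == lab & steps$include_in_rom & steps$duration_h > 0, , drop = FALSE]
    if (!nrow(s)) return(NA_real_)
    mean(s$distance_m / s$duration_h)
  }
  daily <- if (nrow(steps)) {
    agg <- stats::aggregate(steps$distance_m, by = list(date = as.Date(steps$t1, tz = "UTC")), FUN = sum)
    data.frame(date = agg$date, km = agg$x / 1000)
  } else data.frame(date = as.Date(character()), km = numeric(0))
  list(day_rom_m_per_h = rom("day"), night_rom_m_per_h = rom("night"),
       total_distance_km = sum(steps$distance_m) / 1000,
       daily_rom = daily)
}

#' Along-river distance from the core-area centroid
#'
#' Distance of every fix from the KUD 50% centroid, measured along the
#' river; the series reveals exploratory movements away from the core area
#' and its spikes flag long-range (e.g. nesting) excursions.
#'
#' @param track_s A [snap_track()]ed track.
#' @param centroid A [kud_centroid()] row.
#' @param graph A [build_graph()] movement graph.
#' @return Data frame `timestamp`, `dist_km`, with the maximum as attribute
#'   `max_km`.
#' @export
distance_from_centroid_series <- function(track_s, centroid, graph) {
  d <- river_distance(centroid$key, unique(track_s$key), graph)
  dk <- d[1, match(track_s$key, unique(track_s$key))] / 1000
  out <- data.frame(timestamp = track_s$timestamp, dist_km = dk)
  attr(out, "max_km") <- max(dk)
  out
}

#' Pairwise overlap of two volume contours
#'
#' Overlap of contour `a` on `b` is the shared area as a percentage of
#' `a`'s area (and symmetrically for `b`); both directions are returned
#' because the published convention leaves the denominator ambiguous, and
#' the maximum of the two is the conventional headline value.
#'
#' @param a,b [volume_contour()]s on the same lattice.
#' @return A list: `pct_of_a`, `pct_of_b`, `max_pct`, `shared_km2`.
#' @export
pairwise_overlap <- function(a, b) {
  stopifnot(inherits(a, "volume_contour"), inherits(b, "volume_contour"),
            a$cell_size_m == b$cell_size_m)
  shared <- length(intersect(a$keys, b$keys)) * (a$cell_size_m / 1000)^2
  list(pct_of_a = 100 * shared / a$area_km2,
       pct_of_b = 100 * shared / b$area_km2,
       max_pct = max(100 * shared / a$area_km2, 100 * shared / b$area_km2),
       shared_km2 = shared)
}
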