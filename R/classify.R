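#' Stability criterion for ranging-strategy classification
#'
#' A site-fidelic animal's cumulative KUD 95% area stops growing as fixes
#' accumulate; a nomad's keeps climbing. The criterion operationalises
#' stability as relative growth of the cumulative area over the trailing
#' `k_tail` windows being at most `tau`. By default `k_tail` spans the whole
#' series (`n_windows - 1`), i.e. growth since the first window: stability
#' over the entire tracking period, which separates a mean-reverting
#' resident from a diffusively wandering nomad far more reliably than the
#' growth over the last few windows alone (for any diffusive wanderer the
#' short-tail growth ratio is scale-free and highly variable).
#'
#' @param tau Relative-growth threshold (default 0.15).
#' @param k_tail Number of trailing windows the growth is measured over,
#'   between 2 and `n_windows - 1`; `NULL` (default) uses the whole series.
#' @return An object of class `stability_criterion`.
#' @export
stability_criterion <- function(tau = 0.15, k_tail = NULL) {
  stopifnot(tau > 0)
  if (!is.null(k_tail)) stopifnot(k_tail >= 2)
  structure(list(tau = tau, k_tail = k_tail), class = "stability_criterion")
}

#' Classify an individual as site-fidelic or nomadic
#'
#' Computes `growth_stat = (A_last - A_ref) / A_ref`, where `A_ref` is the
#' cumulative KUD 95% area `k_tail` windows before the last, and labels the
#' individual `site_fidelic` iff `growth_stat <= tau`. The statistic is
#' scale-invariant (areas may be in any common unit) and monotone in `tau`.
#'
#' @param areas Numeric vector of cumulative KUD 95% areas, one per window
#'   in order; may contain `NA` for unusable windows.
#' @param criterion A [stability_criterion()].
#' @return A list: `label` (`"site_fidelic"`, `"nomadic"`, or
#'   `"unclassified"` when the needed windows are missing), `growth_stat`,
#'   `windows_used`, `tau`, `k_tail`.
#' @export
classify_strategy <- function(areas, criterion = stability_criterion()) {
  stopifnot(inherits(criterion, "stability_criterion"))
  n <- length(areas)
  k <- criterion$k_tail %||% (n - 1L)
  if (k < 2 || k > n - 1)
    stopf("k_tail must lie between 2 and n_windows - 1 (got %d with %d windows)", k, n)
  need <- c(n - k, n)
  if (n < k + 1 || anyNA(areas[need]) || areas[n - k] <= 0)
    return(list(label = "unclassified", growth_stat = NA_real_,
                windows_used = sum(!is.na(areas)), tau = criterion$tau, k_tail = k))
  growth <- (areas[n] - areas[n - k]) / areas[n - k]
  list(label = if (growth <= criterion$tau) "site_fidelic" else "nomadic",
       growth_stat = growth, windows_used = sum(!is.na(areas)),
       tau = criterion$tau, k_tail = k)
}

#' Detect long-range excursions from the centroid-distance series
#'
#' An excursion is a maximal run of fixes whose along-river distance from
#' the KUD 50% centroid exceeds `multiplier` times the 95th percentile of
#' the baseline-period distances. The baseline defaults to the breeding
#' months (September-November), before the nesting trips of December and
#' January. An excursion `returned` if the series falls back below the
#' threshold before the record ends; a final permanent move does not.
#'
#' @param dist_series A [distance_from_centroid_series()] data frame.
#' @param baseline_start,baseline_end Baseline window dates.
#' @param multiplier Threshold multiplier (default 3).
#' @param min_baseline_fixes Minimum fixes required in the baseline
#'   (default 20); fewer is an error.
#' @return Data frame with one row per excursion: `start_fix`, `end_fix`
#'   (indices into the series), `start_time`, `end_time`, `peak_dist_km`,
#'   `duration_h`, `returned`; plus attributes `threshold_km` and
#'   `baseline_q95_km`.
#' @export
detect_excursions <- function(dist_series, baseline_start = "2010-09-01",
                              baseline_end = "2010-11-30", multiplier = 3,
                              min_baseline_fixes = 20) {
  d <- as.Date(dist_series$timestamp, tz = "UTC")
  base <- dist_series$dist_km[d >= as.Date(baseline_start) & d <= as.Date(baseline_end)]
  if (length(base) < min_baseline_fixes)
    stopf("baseline window holds %d fixes (< %d)", length(base), min_baseline_fixes)
  q95 <- stats::quantile(base, 0.95, names = FALSE)
  thr <- multiplier * q95
  above <- dist_series$dist_km > thr
  out <- data.frame(start_fix = integer(0), end_fix = integer(0),
                    start_time = as.POSIXct(character()), end_time = as.POSIXct(character()),
                    peak_dist_km = numeric(0), duration_h = numeric(0),
                    returned = logical(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    out <- do.call(rbind, lapply(runs, function(k) {
      i0 <- starts[k]; i1 <- ends[k]
      data.frame(start_fix = i0, end_fix = i1,
                 start_time = dist_series$timestamp[i0],
                 end_time = dist_series$timestamp[i1],
                 peak_dist_km = max(dist_series$dist_km[i0:i1]),
                 duration_h = as.numeric(difftime(dist_series$timestamp[i1],
                                                  dist_series$timestamp[i0], units = "hours")),
                 returned = i1 < nrow(dist_series))
    }))
  }
  attr(out, "threshold_km") <- thr
  attr(out, "baseline_q95_km") <- q95
  out
}
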