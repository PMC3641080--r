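#' Published per-individual summary table (packaged fixture)
#'
#' The per-individual summary statistics of a published GPS-tracking study
#' of twelve adult estuarine crocodiles (eight males, four females) in the
#' Wenlock River system, Cape York, tracked twice daily from 01 September
#' to 28 February: body length, day/night rates of movement, total distance
#' moved, river-clipped KUD 95% and 50% areas, and the maximum along-river
#' distance from the KUD 50% centroid. `kud_stabilised` encodes whether the
#' individual's monthly cumulative KUD had stabilised by the end of the
#' study (it had not for the three nomadic males M1-M3). The raw telemetry
#' behind the table was never deposited, so this table is the reference for
#' the group-summary stage.
#'
#' @return Data frame with one row per individual and a `group` column
#'   (`nomadic_male` / `site_fidelic_male` / `female`) derived from sex and
#'   `kud_stabilised`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_wenlock.csv", package = "crocspace")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- ifelse(df$sex == "female", "female",
                     ifelse(df$kud_stabilised, "site_fidelic_male", "nomadic_male"))
  df
}

#' Group summary statistics (mean and standard error)
#'
#' Means and standard errors (sample SD with n-1 denominator, divided by
#' sqrt(n)) of every metric column by group, in long form. The derived
#' metric `kud50_over_kud95_percent` (the core area as a percentage of the
#' home-range area, computed per individual then averaged) is appended
#' when both KUD columns are present. Single-member groups report `NA`
#' standard errors; empty groups are omitted with a warning.
#'
#' @param rows Per-individual summary data frame.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param metrics Metric columns; defaults to all numeric columns.
#' @return Data frame: `group`, `metric`, `n`, `mean`, `se`.
#' @export
group_summary <- function(rows, group_col = "group", metrics = NULL) {
  stopifnot(group_col %in% names(rows))
  rows <- as.data.frame(rows)
  if (all(c("kud50_km2", "kud95_km2") %in% names(rows)))
    rows$kud50_over_kud95_percent <- 100 * rows$kud50_km2 / rows$kud95_km2
  if (is.null(metrics))
    metrics <- names(rows)[vapply(rows, is.numeric, TRUE) & names(rows) != group_col]
  groups <- unique(rows[[group_col]])
  out <- list()
  for (g in groups) {
    sub <- rows[rows[[group_col]] == g, , drop = FALSE]
    if (!nrow(sub)) { warnf("group '%s' is empty; omitted", g); next }
    for (m in metrics) {
      v <- sub[[m]][!is.na(sub[[m]])]
      n <- length(v)
      out[[length(out) + 1]] <- data.frame(
        group = g, metric = m, n = n,
        mean = if (n) mean(v) else NA_real_,
        se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Pull one group/metric mean out of a group summary
#'
#' @param gs A [group_summary()] table.
#' @param group,metric Selectors.
#' @return The mean (numeric scalar).
#' @export
group_mean <- function(gs, group, metric) {
  v <- gs$mean[gs$group == group & gs$metric == metric]
  if (!length(v)) stopf("no summary for group '%s', metric '%s'", group, metric)
  v
}

#' Run the full analysis pipeline for a cohort
#'
#' Orchestrates every stage for each individual in a telemetry table:
#' SDOP/study-window filtering, snapping to the water grid, the full-study
#' kernel surface with river-clipped 95%/50% contours and core centroid,
#' along-river step distances and rates of movement, the
#' distance-from-centroid series, the cumulative monthly KUD series,
#' strategy classification, and (for females, or all individuals with
#' `excursions_for = "all"`) excursion detection. Individuals whose
#' filtered track is unusable are reported with missing fields and a
#' warning. Deterministic: no randomness is consumed.
#'
#' @param fixes Telemetry data frame (all individuals).
#' @param mask A [river_mask].
#' @param graph Optional prebuilt [build_graph()]; built from `mask` if
#'   omitted.
#' @param metadata Optional [read_metadata()]-style data frame (adds sex
#'   and length to the summary).
#' @param fcfg,kcfg,windows,criterion Stage configurations.
#' @param excursions_for `"females"` (default), `"all"` or `"none"`.
#' @param breeding_windows Number of leading windows (default 3, September
#'   to November) used to classify females, whose cumulative range is
#'   expected to be stable only during the breeding period before the
#'   long-distance nesting movements of December-January.
#' @param out_dir If non-`NULL`, writes `summary.csv`, `groups.csv`,
#'   `kud_areas.csv`, `classification.csv`, `excursions.csv`,
#'   `contours.geojson` and `pipeline_log.csv` there.
#' @return A list: `summary` (one row per individual), `groups`,
#'   `kud_series`, `classification`, `excursions`, `per_individual`
#'   (stage objects), `log`.
#' @export
run_pipeline <- function(fixes, mask, graph = NULL, metadata = NULL,
                         fcfg = filter_config(), kcfg = kde_config(),
                         windows = analysis_windows(),
                         criterion = stability_criterion(),
                         excursions_for = c("females", "all", "none"),
                         breeding_windows = 3, out_dir = NULL) {
  excursions_for <- match.arg(excursions_for)
  if (is.null(graph)) graph <- build_graph(mask)
  ids <- unique(fixes$id)
  per <- list(); srows <- list(); kud_series <- list(); cls <- list(); exc <- list()
  logs <- list()
  for (id in ids) {
    track <- fixes[fixes$id == id, , drop = FALSE]
    flt <- filter_fixes(track, fcfg)
    logs[[id]] <- data.frame(id = id, stage = "filter",
                             n_in = nrow(track), n_out = nrow(flt$track),
                             note = sprintf("removed_fraction=%.4f", flt$removed_fraction))
    sex <- if (!is.null(metadata)) metadata$sex[match(id, metadata$id)] else NA_character_
    tl <- if (!is.null(metadata)) metadata$total_length_m[match(id, metadata$id)] else NA_real_
    if (!flt$usable || nrow(flt$track) < 5) {
      warnf("individual '%s' has no usable filtered track; emitting missing summary", id)
      srows[[id]] <- data.frame(id = id, sex = sex, total_length_m = tl,
                                day_rom_m_per_h = NA_real_, night_rom_m_per_h = NA_real_,
                                total_distance_km = NA_real_, kud95_km2 = NA_real_,
                                kud50_km2 = NA_real_, max_dist_centroid_km = NA_real_,
                                strategy = "unclassified", removed_fraction = flt$removed_fraction)
      next
    }
    tr <- snap_track(flt$track, mask)
    surf <- estimate_kde(flt$track, kcfg)
    c95 <- clip_to_river(volume_contour(surf, 0.95), mask)
    c50 <- clip_to_river(volume_contour(surf, 0.50), mask)
    # the reference centroid for exploratory-movement distances is the core
    # of the FIRST window (early-season home range): a full-study centroid
    # is dragged toward any permanent late-season relocation and would mask
    # the very excursions the series is meant to reveal
    d0 <- as.Date(flt$track$timestamp, tz = "UTC")
    first_win <- flt$track[d0 >= windows$start & d0 <= windows$ends[1], , drop = FALSE]
    ctd <- if (nrow(first_win) >= 5) {
      surf1 <- estimate_kde(first_win, kcfg)
      kud_centroid(clip_to_river(volume_contour(surf1, 0.50), mask), mask)
    } else kud_centroid(c50, mask)
    steps <- step_distances(tr, graph)
    rom <- rate_of_movement(steps)
    dser <- distance_from_centroid_series(tr, ctd, graph)
    series <- cumulative_kuds(flt$track, windows, kcfg, mask)
    # females hold a stable range only during the breeding months; their
    # stability is judged on those leading windows
    cl <- if (identical(sex, "female") && breeding_windows >= 3) {
      classify_strategy(series$kud95_km2[seq_len(breeding_windows)],
                        stability_criterion(tau = criterion$tau,
                                            k_tail = min(criterion$k_tail %||% Inf,
                                                         breeding_windows - 1)))
    } else classify_strategy(series$kud95_km2, criterion)
    kud_series[[id]] <- cbind(id = id, series)
    cls[[id]] <- data.frame(id = id, label = cl$label, growth_stat = cl$growth_stat,
                            tau = cl$tau, k_tail = cl$k_tail,
                            windows_used = cl$windows_used)
    want_exc <- excursions_for == "all" ||
      (excursions_for == "females" && identical(sex, "female"))
    if (want_exc) {
      ex <- detect_excursions(dser,
                              baseline_start = windows$start,
                              baseline_end = windows$ends[min(3, length(windows$ends))])
      if (nrow(ex)) exc[[id]] <- cbind(id = id, ex)
    }
    per[[id]] <- list(filtered = flt, surface = surf, kud95 = c95, kud50 = c50,
                      centroid = ctd, steps = steps, rom = rom,
                      dist_series = dser, series = series, classification = cl)
    srows[[id]] <- data.frame(id = id, sex = sex, total_length_m = tl,
                              day_rom_m_per_h = rom$day_rom_m_per_h,
                              night_rom_m_per_h = rom$night_rom_m_per_h,
                              total_distance_km = rom$total_distance_km,
                              kud95_km2 = c95$area_km2, kud50_km2 = c50$area_km2,
                              max_dist_centroid_km = attr(dser, "max_km"),
                              strategy = cl$label,
                              removed_fraction = flt$removed_fraction)
  }
  summary <- do.call(rbind, srows); rownames(summary) <- NULL
  summary$group <- ifelse(summary$sex == "female", "female",
                          ifelse(summary$strategy == "nomadic", "nomadic_male",
                                 "site_fidelic_male"))
  groups <- group_summary(summary[!is.na(summary$sex), , drop = FALSE])
  res <- list(summary = summary, groups = groups,
              kud_series = do.call(rbind, kud_series),
              classification = do.call(rbind, cls),
              excursions = if (length(exc)) do.call(rbind, exc) else NULL,
              per_individual = per,
              log = do.call(rbind, logs))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(res$groups, file.path(out_dir, "groups.csv"), row.names = FALSE)
    utils::write.csv(res$kud_series, file.path(out_dir, "kud_areas.csv"), row.names = FALSE)
    utils::write.csv(res$classification, file.path(out_dir, "classification.csv"), row.names = FALSE)
    if (!is.null(res$excursions))
      utils::write.csv(res$excursions, file.path(out_dir, "excursions.csv"), row.names = FALSE)
    utils::write.csv(res$log, file.path(out_dir, "pipeline_log.csv"), row.names = FALSE)
    cts <- list()
    for (id in names(per)) {
      cts[[paste0(id, "_kud95")]] <- per[[id]]$kud95
      cts[[paste0(id, "_kud50")]] <- per[[id]]$kud50
    }
    if (length(cts)) write_contours_geojson(cts, file.path(out_dir, "contours.geojson"))
  }
  res
}
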