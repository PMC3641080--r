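#' Read GPS telemetry from CSV
#'
#' Expects columns `id`, `timestamp` (ISO-8601, naive local time), `x_m`,
#' `y_m`, `sdop` (the internal names `x`/`y` are also accepted). Rows are
#' grouped by individual and sorted by timestamp; exact duplicates (same id
#' and timestamp) are collapsed to one with a warning. A missing column or
#' an unparseable timestamp/number is a hard error naming the offender.
#'
#' @param source Path to a CSV file, or a data frame already in memory.
#' @return A data frame `id`, `timestamp` (POSIXct), `x`, `y`, `sdop`,
#'   sorted by id then time.
#' @export
read_telemetry <- function(source) {
  df <- if (is.data.frame(source)) source else utils::read.csv(source, stringsAsFactors = FALSE)
  names(df)[names(df) == "x_m"] <- "x"
  names(df)[names(df) == "y_m"] <- "y"
  for (col in c("id", "timestamp", "x", "y", "sdop"))
    if (!col %in% names(df)) stopf("telemetry is missing required column '%s'", col)
  raw <- as.character(df$timestamp)
  ts <- as.POSIXct(rep(NA_real_, length(raw)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(raw[miss], fmt, tz = "UTC"))
  }
  if (anyNA(ts))
    stopf("unparseable timestamp at row %d: '%s'", which(is.na(ts))[1],
          df$timestamp[which(is.na(ts))[1]])
  for (col in c("x", "y", "sdop")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stopf("unparseable number in column '%s' at row %d", col, which(is.na(v))[1])
    df[[col]] <- v
  }
  if (any(df$sdop < 0)) stopf("negative sdop at row %d", which(df$sdop < 0)[1])
  out <- data.frame(id = as.character(df$id), timestamp = ts,
                    x = df$x, y = df$y, sdop = df$sdop)
  out <- out[order(out$id, out$timestamp), ]
  dup <- duplicated(out[c("id", "timestamp")])
  if (any(dup)) {
    warnf("collapsed %d duplicated fix(es) (same id and timestamp)", sum(dup))
    out <- out[!dup, ]
  }
  rownames(out) <- NULL
  out
}

#' Write telemetry to CSV
#'
#' Columns `id`, `timestamp` (ISO-8601), `x_m`, `y_m`, `sdop`, one row per
#' fix.
#'
#' @param fixes Data frame as returned by [read_telemetry()] or
#'   [observe_gps()].
#' @param path Output path.
#' @export
write_telemetry <- function(fixes, path) {
  out <- data.frame(id = fixes$id,
                    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S"),
                    x_m = fixes$x, y_m = fixes$y, sdop = fixes$sdop)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read individual metadata
#'
#' CSV with columns `id`, `sex`, `total_length_m`, `snout_vent_length_m`.
#' Enforces `total_length_m > snout_vent_length_m > 0` where both present.
#' Body mass is not tabulated: supply a conversion through [body_mass()].
#'
#' @param source Path to a CSV file, or a data frame.
#' @return A data frame of individuals.
#' @export
read_metadata <- function(source) {
  df <- if (is.data.frame(source)) source else utils::read.csv(source, stringsAsFactors = FALSE)
  for (col in c("id", "sex", "total_length_m", "snout_vent_length_m"))
    if (!col %in% names(df)) stopf("metadata is missing required column '%s'", col)
  both <- !is.na(df$total_length_m) & !is.na(df$snout_vent_length_m)
  bad <- both & !(df$total_length_m > df$snout_vent_length_m & df$snout_vent_length_m > 0)
  if (any(bad)) stopf("metadata row %d violates total_length_m > snout_vent_length_m > 0",
                      which(bad)[1])
  df
}

#' Body mass from snout-vent length (pluggable allometry)
#'
#' The mass-length conversion used in the original analysis is not published
#' with its coefficients, so no default is provided: pass any function of
#' snout-vent length (m) returning kilograms.
#'
#' @param metadata A [read_metadata()] data frame.
#' @param allometry A function `svl_m -> kg`.
#' @return `metadata` with a `body_mass_kg` column appended.
#' @export
body_mass <- function(metadata, allometry) {
  stopifnot(is.function(allometry))
  metadata$body_mass_kg <- allometry(metadata$snout_vent_length_m)
  metadata
}

#' SDOP / study-window filter configuration
#'
#' Fixes with SDOP at or below `sdop_max` are retained (stationary tag tests
#' put their accuracy near 12 m); fixes above it are removed. Only fixes
#' within the study window contribute.
#'
#' @param sdop_max Maximum SDOP retained (default 3).
#' @param study_start,study_end Study window dates (inclusive).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(sdop_max = 3, study_start = "2010-09-01",
                          study_end = "2011-02-28") {
  stopifnot(sdop_max > 0)
  start <- as.Date(study_start); end <- as.Date(study_end)
  if (!(start < end)) stopf("study_start must precede study_end")
  structure(list(sdop_max = sdop_max, study_start = start, study_end = end),
            class = "filter_config")
}

#' Apply the SDOP quality filter
#'
#' Restricts a track to the study window, drops fixes whose SDOP exceeds
#' `sdop_max`, and reports the removed fraction (removed-by-SDOP over the
#' in-window total). Filtering is idempotent, and retained plus removed
#' counts always equal the in-window total.
#'
#' @param track Data frame of fixes for one individual (or several; the
#'   filter is row-wise).
#' @param cfg A [filter_config()].
#' @return A list: `track` (retained fixes), `removed_fraction`,
#'   `n_in_window`, `n_removed`. An empty retained set is flagged with
#'   `usable = FALSE` and a warning; downstream stages refuse such tracks.
#' @export
filter_fixes <- function(track, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!nrow(track)) stopf("track is empty")
  d <- as.Date(track$timestamp, tz = "UTC")
  inw <- d >= cfg$study_start & d <= cfg$study_end
  win <- track[inw, , drop = FALSE]
  keep <- win$sdop <= cfg$sdop_max
  removed_fraction <- if (nrow(win)) sum(!keep) / nrow(win) else NA_real_
  usable <- any(keep)
  if (!usable) warnf("no fixes retained after SDOP filtering%s",
                     if (length(unique(track$id)) == 1) sprintf(" for '%s'", track$id[1]) else "")
  out <- win[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(track = out, removed_fraction = removed_fraction,
       n_in_window = nrow(win), n_removed = sum(!keep), usable = usable)
}
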