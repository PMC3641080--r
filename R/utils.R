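# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Global-lattice cell key. The 50 m analysis lattice is anchored at (0, 0)
# so every grid (river mask, KDE surfaces) indexes cells identically and
# clipping reduces to key intersection. Rows/cols may be negative.
cell_key <- function(row, col) sprintf("%d_%d", as.integer(row), as.integer(col))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

hour_of <- function(t) as.POSIXlt(t, tz = "UTC")$hour + as.POSIXlt(t, tz = "UTC")$min / 60
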