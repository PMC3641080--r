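sep_times <- function(n) sprintf("2010-09-%02d %02d:00:00",
                                 rep(1:30, each = 2, length.out = n),
                                 rep(c(8, 18), length.out = n))

test_that("a degenerate all-identical-fix surface peaks at the fix cell with unit mass", {
  tr <- fix_df("A", sep_times(5), rep(525, 5), rep(75, 5))
  surf <- estimate_kde(tr, kde_config(h_m = 200, extent_pad_m = 800))
  expect_equal(sum(surf$density), 1, tolerance = 1e-9)
  peak <- which(surf$density == max(surf$density), arr.ind = TRUE)
  expect_equal(unname((surf$col0 + peak[1, 2]) - 0.5) * 50, 525)
  expect_equal(unname((surf$row0 + peak[1, 1]) - 0.5) * 50, 75)
})

test_that("fewer than five fixes are refused", {
  tr <- fix_df("A", sep_times(4), 1:4, 1:4)
  expect_error(estimate_kde(tr), "at least 5")
})

test_that("duplicating every fix leaves the surface unchanged", {
  set.seed(42)
  tr <- fix_df("A", sep_times(12), stats::runif(12, 0, 2000), stats::runif(12, 0, 300))
  s1 <- estimate_kde(tr, kde_config(h_m = 300))
  s2 <- estimate_kde(rbind(tr, tr), kde_config(h_m = 300))
  expect_equal(s1$density, s2$density, tolerance = 1e-12)
})

test_that("the separable-kernel surface equals the brute-force double loop", {
  set.seed(7)
  tr <- fix_df("A", sep_times(20), stats::runif(20, 0, 800), stats::runif(20, 0, 400))
  cfg <- kde_config(h_m = 300, extent_pad_m = 300)
  surf <- estimate_kde(tr, cfg)
  expect_lte(surf$n_rows * surf$n_cols, 800)
  oracle <- brute_kde(tr, surf)
  expect_equal(surf$density, oracle, tolerance = 1e-10)
})

test_that("a uniform surface yields exactly level x n cells", {
  surf <- make_surface(matrix(1, 10, 10))
  ct <- volume_contour(surf, 0.50)
  expect_equal(length(ct$keys), 50)
  expect_equal(ct$area_km2, 50 * 0.0025)
})

test_that("volume contours are minimal prefixes with nested levels", {
  set.seed(9)
  tr <- fix_df("A", sep_times(15), stats::rnorm(15, 1000, 200), stats::rnorm(15, 500, 150))
  surf <- estimate_kde(tr, kde_config(h_m = 250))
  for (lev in c(0.5, 0.95)) {
    ct <- volume_contour(surf, lev)
    expect_gte(ct$mass, lev)
    expect_lt(ct$mass - min(ct$density), lev)  # dropping the last cell breaks the level
  }
  c50 <- volume_contour(surf, 0.50)
  c95 <- volume_contour(surf, 0.95)
  expect_true(all(c50$keys %in% c95$keys))
  expect_lt(length(c50$keys), length(c95$keys))
})

test_that("river clipping is a set intersection with the documented arithmetic", {
  surf <- make_surface(matrix(1, 10, 10))
  ct <- volume_contour(surf, 0.995)         # all 100 cells
  expect_equal(length(ct$keys), 100)
  w <- matrix(FALSE, 10, 10); w[5, 1:10] <- TRUE
  mask <- crocspace:::new_mask(w, 0, 0, 50)
  cl <- clip_to_river(ct, mask)
  expect_equal(length(cl$keys), 10)
  expect_equal(cl$reduction_percent, 90)
  expect_lte(cl$area_km2, ct$area_km2)
  # fully-aquatic contour: zero reduction
  mask_all <- crocspace:::new_mask(matrix(TRUE, 10, 10), 0, 0, 50)
  expect_equal(clip_to_river(ct, mask_all)$reduction_percent, 0)
  # no intersection is an error
  w2 <- matrix(FALSE, 10, 10); w2[1, 1] <- TRUE
  mask_far <- crocspace:::new_mask(w2, 500, 500, 50)
  expect_error(clip_to_river(ct, mask_far), "does not intersect")
})

test_that("the centroid of a symmetric surface sits at the peak and stays on water", {
  mask <- straight_mask(2000, 100)
  tr <- fix_df("A", sep_times(10), rep(c(925, 1025), 5), rep(75, 10))
  surf <- estimate_kde(tr, kde_config(h_m = 200))
  c50 <- clip_to_river(volume_contour(surf, 0.50), mask)
  ctd <- kud_centroid(c50, mask)
  expect_equal(ctd$cell_x, 975)     # midpoint between the two fix clusters
  expect_equal(ctd$row, 2)
  # U-shaped channel with mass in both arms: the raw mean falls on land but
  # the returned centroid is a water cell
  w <- matrix(FALSE, 10, 11)
  w[, 1] <- TRUE; w[, 11] <- TRUE; w[1, ] <- TRUE
  umask <- crocspace:::new_mask(w, 0, 0, 50)
  trU <- fix_df("A", sep_times(10), c(rep(25, 5), rep(525, 5)),
                rep(c(325, 425), 5))
  surfU <- estimate_kde(trU, kde_config(h_m = 150))
  c50U <- clip_to_river(volume_contour(surfU, 0.50), umask)
  ctdU <- kud_centroid(c50U, umask)
  expect_true(umask$water[ctdU$row, ctdU$col])
  expect_gt(ctdU$snap_m, 0)         # the unsnapped mean lay off-water
})

test_that("cumulative windows with no new fixes repeat the same areas", {
  mask <- straight_mask(3000, 100)
  tr <- fix_df("A", sep_times(20), seq(100, 1000, length.out = 20), rep(50, 20))
  ser <- cumulative_kuds(tr, analysis_windows(), kde_config(h_m = 300), mask)
  expect_equal(nrow(ser), 6)
  expect_equal(ser$n_fixes, rep(20, 6))
  expect_equal(ser$kud95_km2, rep(ser$kud95_km2[1], 6))
  expect_equal(ser$kud50_km2, rep(ser$kud50_km2[1], 6))
})

test_that("windows with too few fixes yield missing values with a warning", {
  mask <- straight_mask(3000, 100)
  tr <- fix_df("A", sprintf("2010-12-%02d 08:00:00", 1:20),
               seq(100, 1000, length.out = 20), rep(50, 20))
  w <- capture_warnings(ser <- cumulative_kuds(tr, analysis_windows(),
                                               kde_config(h_m = 300), mask))
  expect_length(w, 3)            # Sep, Sep-Oct and Sep-Nov windows are empty
  expect_match(w, "< 5", all = TRUE)
  expect_true(all(is.na(ser$kud95_km2[1:3])))
  expect_false(anyNA(ser$kud95_km2[4:6]))
})

test_that("shrinking the bandwidth shrinks the home range of a compact cloud", {
  set.seed(3)
  tr <- fix_df("A", sep_times(30), stats::rnorm(30, 0, 60), stats::rnorm(30, 0, 60))
  a750 <- volume_contour(estimate_kde(tr, kde_config(h_m = 750)), 0.95)$area_km2
  a200 <- volume_contour(estimate_kde(tr, kde_config(h_m = 200, extent_pad_m = 3000)), 0.95)$area_km2
  expect_lte(a200, a750)
})

test_that("bandwidth diagnostics bracket sensible scales", {
  set.seed(5)
  tr <- fix_df("A", sep_times(40), stats::rnorm(40, 0, 500), stats::rnorm(40, 0, 500))
  expect_gt(h_ref(tr), 100)
  hl <- h_lscv(tr, lower = 50, upper = 2000)
  expect_gt(hl, 50); expect_lt(hl, 2000)
})

test_that("contours export as valid GeoJSON", {
  surf <- make_surface(matrix(1, 4, 4))
  ct <- volume_contour(surf, 0.5)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_contours_geojson(list(demo = ct), path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(gj$features[[1]]$properties$level, 0.5)
  expect_equal(gj$features[[1]]$geometry$type, "MultiPolygon")
})
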