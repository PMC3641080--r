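chain_track <- function(xs, times, mask) {
  snap_track(fix_df("A", times, xs, rep(25, length(xs))), mask)
}

test_that("step distances follow the river and close on the right interval", {
  mask <- straight_mask(3000, 50)
  g <- build_graph(mask)
  tr <- chain_track(c(25, 25, 1425),
                    c("2010-09-01 08:00:00", "2010-09-01 18:00:00",
                      "2010-09-02 08:00:00"), mask)
  st <- step_distances(tr, g)
  expect_equal(st$distance_m, c(0, 1400))     # same cell; 28 cells apart
  expect_equal(st$label, c("day", "night"))
  expect_equal(st$duration_h, c(10, 14))
  expect_true(all(st$include_in_rom))
})

test_that("gaps beyond 36 h are excluded from ROM but kept in total distance", {
  mask <- straight_mask(3000, 50)
  g <- build_graph(mask)
  tr <- chain_track(c(25, 1025, 2525),
                    c("2010-09-01 18:00:00", "2010-09-02 08:00:00",
                      "2010-09-04 08:00:00"), mask)
  st <- step_distances(tr, g)
  expect_equal(st$include_in_rom, c(TRUE, FALSE))
  rom <- rate_of_movement(st)
  expect_equal(rom$total_distance_km, (1000 + 1500) / 1000)
  expect_equal(rom$night_rom_m_per_h, 1000 / 14)
  expect_true(is.na(rom$day_rom_m_per_h))     # no valid day interval
})

test_that("rates of movement use actual interval durations", {
  mask <- straight_mask(4000, 50)
  g <- build_graph(mask)
  tr <- chain_track(c(25, 1425, 2425),
                    c("2010-09-01 18:00:00", "2010-09-02 08:00:00",
                      "2010-09-02 18:00:00"), mask)
  rom <- rate_of_movement(step_distances(tr, g))
  expect_equal(rom$night_rom_m_per_h, 100)       # 1400 m over 14 h
  expect_equal(rom$day_rom_m_per_h, 100)         # 1000 m over 10 h
  d2 <- rom$daily_rom$km[rom$daily_rom$date == as.Date("2010-09-02")]
  expect_equal(d2, 2.4)                          # 1.4 + 1.0 km on one day
})

test_that("ROM is invariant to the input row order", {
  mask <- straight_mask(4000, 50)
  g <- build_graph(mask)
  times <- sprintf("2010-09-%02d %02d:00:00", rep(1:5, each = 2), rep(c(8, 18), 5))
  xs <- seq(25, 2025, length.out = 10)
  tr <- chain_track(xs, times, mask)
  shuffled <- tr[c(7, 2, 9, 1, 5, 10, 3, 8, 4, 6), ]
  a <- rate_of_movement(step_distances(tr, g))
  b <- rate_of_movement(step_distances(shuffled, g))
  expect_equal(a$day_rom_m_per_h, b$day_rom_m_per_h)
  expect_equal(a$total_distance_km, b$total_distance_km)
})

test_that("the centroid distance series is zero at the centroid and reports its max", {
  mask <- straight_mask(3000, 50)
  g <- build_graph(mask)
  tr <- chain_track(c(525, 1025, 525), sprintf("2010-09-0%d 08:00:00", 1:3), mask)
  ctd <- snap_to_river(525, 25, mask)
  ser <- distance_from_centroid_series(tr, ctd, g)
  expect_equal(ser$dist_km, c(0, 0.5, 0))
  expect_equal(attr(ser, "max_km"), max(ser$dist_km))
  expect_gte(attr(ser, "max_km"), mean(ser$dist_km))
})

test_that("contour overlap percentages follow the set arithmetic", {
  surf <- make_surface(matrix(1, 10, 10))
  all_cells <- volume_contour(surf, 0.995)
  w_a <- matrix(FALSE, 10, 10); w_a[1, 1:10] <- TRUE
  w_b <- matrix(FALSE, 10, 10); w_b[1:4, 1:10] <- TRUE
  a <- clip_to_river(all_cells, crocspace:::new_mask(w_a, 0, 0, 50))
  b <- clip_to_river(all_cells, crocspace:::new_mask(w_b, 0, 0, 50))
  ov <- pairwise_overlap(a, b)
  expect_equal(ov$pct_of_a, 100)     # a (10 cells) inside b (40 cells)
  expect_equal(ov$pct_of_b, 25)
  expect_equal(ov$max_pct, 100)
  expect_equal(pairwise_overlap(a, a)$pct_of_a, 100)
  w_c <- matrix(FALSE, 10, 10); w_c[9, 1:10] <- TRUE
  cc <- clip_to_river(all_cells, crocspace:::new_mask(w_c, 0, 0, 50))
  expect_equal(pairwise_overlap(a, cc)$max_pct, 0)
})

test_that("a stationary track accumulates zero distance", {
  mask <- straight_mask(1000, 50)
  g <- build_graph(mask)
  tr <- chain_track(rep(525, 6),
                    sprintf("2010-09-%02d %02d:00:00", rep(1:3, each = 2),
                            rep(c(8, 18), 3)), mask)
  rom <- rate_of_movement(step_distances(tr, g))
  expect_equal(rom$total_distance_km, 0)
  expect_equal(rom$day_rom_m_per_h, 0)
  expect_equal(rom$night_rom_m_per_h, 0)
})
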