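sf_agent <- function(scale_km = 2, centre_km = 30)
  agent_spec("S1", "male", "site_fidelic_male", 4.0, centre_km,
             territory_scale_km = scale_km,
             step_scale_day_m_per_h = 250, step_scale_night_m_per_h = 350)

test_that("a site-fidelic territory holds ~95% of positions within three scales", {
  rv <- straight_river(60)
  tr <- simulate_agent(sf_agent(scale_km = 2), rv, "2010-09-01", "2011-02-28",
                       seed = 3)
  frac <- mean(abs(tr$s_m - 30000) <= 6000)
  expect_gte(frac, 0.95)
})

test_that("a fully persistent nomad moves monotonically until it reaches an end", {
  rv <- straight_river(60)
  # step scale small enough that neither end is reached within the month,
  # so the along-river positions are monotone throughout
  ag <- agent_spec("N1", "male", "nomadic_male", 3.5, 30, persistence = 1,
                   step_scale_day_m_per_h = 20, step_scale_night_m_per_h = 20)
  tr <- simulate_agent(ag, rv, "2010-09-01", "2010-09-30", seed = 5)
  expect_true(all(tr$s_m > 1000 & tr$s_m < 59000))
  d <- diff(tr$s_m)
  expect_true(all(d >= 0) || all(d <= 0))
})

test_that("a scheduled returning excursion leaves and re-enters the territory", {
  rv <- straight_river(60)
  ag <- agent_spec("F9", "female", "breeding_female", 3.0, 30,
                   territory_scale_km = 2,
                   step_scale_day_m_per_h = 50, step_scale_night_m_per_h = 60,
                   excursion_schedule = list(list(start = "2010-12-10",
                                                  destination_km = 50,
                                                  dwell_h = 48, returns = TRUE)))
  tr <- simulate_agent(ag, rv, "2010-09-01", "2011-02-28", seed = 7)
  far <- abs(tr$s_m - 30000) > 3 * 2000
  runs <- rle(far)
  long_runs <- sum(runs$values & runs$lengths >= 48)   # dt = 1 h
  expect_equal(long_runs, 1)
  expect_false(far[length(far)])                       # back home at the end
})

test_that("excursion destinations beyond the river extent are rejected", {
  rv <- straight_river(60)
  ag <- agent_spec("F9", "female", "breeding_female", 3.0, 30,
                   excursion_schedule = list(list(start = "2010-12-10",
                                                  destination_km = 90,
                                                  dwell_h = 48, returns = TRUE)))
  expect_error(simulate_agent(ag, rv, "2010-09-01", "2011-02-28", seed = 1),
               "beyond the river extent")
  expect_error(simulate_agent(sf_agent(), rv, "2010-09-01", "2011-02-28",
                              dt_h = 0), "dt_h")
})

test_that("every simulated position lies inside the river channel", {
  rv <- generate_river(river_spec(80, n_tributaries = 2, seed = 11))
  mask <- rasterize_river(rv)
  ag <- agent_spec("N1", "male", "nomadic_male", 3.5, 40, persistence = 0.9)
  tr <- simulate_agent(ag, rv, "2010-09-01", "2010-10-31", seed = 13)
  sn <- snap_to_river(tr$x, tr$y, mask)
  # a point on the centreline sits within half a cell diagonal of a water
  # cell centre
  expect_lte(max(sn$snap_m), 50 / sqrt(2) + 1e-9)
})

test_that("noiseless observation reproduces the true positions on schedule", {
  rv <- straight_river(60)
  tr <- simulate_agent(sf_agent(), rv, "2010-09-01", "2011-02-28", seed = 3)
  mod <- observation_model(good_fix_error_sd_m = 0, bad_fix_fraction = 0)
  fx <- observe_gps(tr, mod, seed = 1)
  expect_equal(nrow(fx), 362)                         # 181 days x 2 fixes
  expect_true(all(fx$sdop <= 3))
  m <- match(as.numeric(fx$timestamp), as.numeric(tr$time))
  expect_equal(fx$x, tr$x[m])
  expect_equal(fx$y, tr$y[m])
})

test_that("poor-fix labelling follows the binomial rate", {
  rv <- straight_river(60)
  ag <- agent_spec("S1", "male", "site_fidelic_male", 4.0, 30,
                   step_scale_day_m_per_h = 0, step_scale_night_m_per_h = 0)
  tr <- simulate_agent(ag, rv, "2000-01-01", "2013-09-08", seed = 1)  # 5000 days
  fx <- observe_gps(tr, observation_model(bad_fix_fraction = 0.07), seed = 11)
  expect_equal(nrow(fx), 10000)
  expect_lt(abs(mean(fx$sdop > 3) - 0.07), 0.01)
})

test_that("good-fix positional error matches the configured SD within 10%", {
  rv <- straight_river(60)
  ag <- agent_spec("S1", "male", "site_fidelic_male", 4.0, 30,
                   step_scale_day_m_per_h = 0, step_scale_night_m_per_h = 0)
  tr <- simulate_agent(ag, rv, "2010-01-01", "2011-06-19", seed = 2)  # 535 days
  fx <- observe_gps(tr, observation_model(bad_fix_fraction = 0), seed = 4)
  expect_gte(nrow(fx), 1000)
  m <- match(as.numeric(fx$timestamp), as.numeric(tr$time))
  err <- c(fx$x - tr$x[m], fx$y - tr$y[m])
  expect_lt(abs(stats::sd(err) - 12) / 12, 0.10)
})

test_that("the simulate-observe chain is reproducible under a fixed seed", {
  rv <- generate_river(default_river_spec(seed = 5))
  a <- simulate_cohort(rv, seed = 9)
  b <- simulate_cohort(rv, seed = 9)
  expect_identical(a$fixes, b$fixes)
})

test_that("nomadic displacement grows with tracking duration; site-fidelic does not", {
  rv <- straight_river(120)
  nm <- agent_spec("N1", "male", "nomadic_male", 3.5, 60, persistence = 0.9)
  t3 <- simulate_agent(nm, rv, "2010-09-01", "2010-11-30", seed = 21)
  t6 <- simulate_agent(nm, rv, "2010-09-01", "2011-02-28", seed = 21)
  expect_gt(max(abs(t6$s_m - 60000)), max(abs(t3$s_m - 60000)))
  sf3 <- simulate_agent(sf_agent(2, 60), rv, "2010-09-01", "2010-11-30", seed = 22)
  sf6 <- simulate_agent(sf_agent(2, 60), rv, "2010-09-01", "2011-02-28", seed = 22)
  # bounded territory: variance does not blow up with duration
  expect_lt(stats::var(sf6$s_m) / stats::var(sf3$s_m), 2)
})
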