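test_that("snow simulation is deterministic and stays on the 20% grid", {
  sc <- snow_scenario("gardiner", 2011, "2011-10-20", "2012-05-10",
                      n_fluct = 0)
  s1 <- simulate_snow(sc, seed = 3)
  s2 <- simulate_snow(sc, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1$snow %in% snow_grid()))
  # no fluctuations: a clean ramp up, plateau, ramp down
  expect_equal(count_snow_excursions(s1, "autumn"), 0L)
  expect_equal(count_snow_excursions(s1, "spring"), 0L)
  expect_equal(max(s1$snow), 100)
  expect_equal(s1$snow[1], 0)
  expect_equal(s1$snow[nrow(s1)], 0)
})

test_that("configured fluctuation counts are recovered by the excursion detector", {
  for (k in c(1L, 4L)) {
    sc <- snow_scenario("gardiner", 2011, "2011-11-10", "2012-05-10",
                        n_fluct = k, fluct_amp = 40)
    s <- simulate_snow(sc, seed = 9)
    expect_equal(count_snow_excursions(s, "autumn"), k)
  }
  sc <- snow_scenario("gardiner", 2011, "2011-10-10", "2012-05-10",
                      n_fluct = 0, n_fluct_spring = 1)
  expect_equal(count_snow_excursions(simulate_snow(sc, 9), "spring"), 1L)
})

test_that("the same seed regenerates a byte-identical study", {
  a <- make_fixture("phenology_small", seed = 77)
  b <- make_fixture("phenology_small", seed = 77)
  expect_identical(a$observations, b$observations)
  expect_identical(a$temperatures, b$temperatures)
  expect_identical(a$truth$units, b$truth$units)
  c <- make_fixture("phenology_small", seed = 78)
  expect_false(identical(a$observations, c$observations))
})

test_that("whiteness and snow scores always lie on their legal grids", {
  fx <- make_fixture("behaviour_small", seed = 5)
  obs <- fx$observations
  expect_true(all(obs$whiteness %in% whiteness_grid()))
  expect_true(all(obs$snow1m %in% snow_grid()))
  expect_true(all(obs$snow10m %in% snow_grid()))
  sl <- as.matrix(obs[paste0("slice_", 1:8)])
  expect_true(all(sl[!is.na(sl)] %in% snow_grid()))
})

test_that("the noise-free fully-detected limit reproduces the analytic trajectory exactly", {
  tr <- synthetic_truth(sigma_ind = 0, sigma_obs = 0,
                        beta = c(snow = 0, temp = 0, sex = 0),
                        hare_snow_sd = 0, detection_prob = 1,
                        weekly_hazard = 0, entry_staggered = FALSE)
  fx <- simulate_hares(tr, default_snow_scenarios(2011), n_hares = 4,
                       years = 2011, seed = 12)
  obs <- fx$observations[fx$observations$site == "gardiner", ]
  yr <- ifelse(as.integer(format(obs$date, "%m")) >= 9, 2011, 2011)
  t_aut <- as.integer(obs$date - as.Date("2011-09-01"))
  before_mar <- obs$date < as.Date("2012-03-01")
  t_spr <- as.integer(obs$date - as.Date("2012-03-01"))
  want <- ifelse(before_mar,
                 expected_whiteness(t_aut, 28, 39.9, "autumn"),
                 expected_whiteness(t_spr, 63, 41.9, "spring"))
  expect_equal(obs$whiteness, want, tolerance = 1e-12)
})

test_that("mean simulated lifespan matches the geometric 1/h closed form", {
  tr <- synthetic_truth(weekly_hazard = 0.25, entry_staggered = FALSE,
                        trial_prob = 0, slice_prob = 0)
  sc <- default_snow_scenarios(2011)
  fx <- simulate_hares(tr, sc["gardiner.2011"], n_hares = 2000,
                       years = 2011, seed = 21)
  L <- fx$truth$hares$lifespan_weeks
  expect_equal(length(L), 2000)
  se <- stats::sd(L) / sqrt(length(L))
  expect_lt(abs(mean(L) - 1 / 0.25), 4 * se + 1e-9)
})

test_that("larger individual SD widens the spread of estimated initiation dates", {
  vars <- sapply(c(1, 6, 15), function(s_ind) {
    tr <- synthetic_truth(sigma_ind = s_ind, sigma_obs = 2,
                          weekly_hazard = 0, detection_prob = 1,
                          entry_staggered = FALSE)
    fx <- simulate_hares(tr, default_snow_scenarios(2011)["gardiner.2011"],
                         n_hares = 40, years = 2011, seed = 31)
    md <- prepare_moult_data(fx$observations, fx$temperatures, "gardiner",
                             "autumn")
    cross <- moultshift:::crossing_times(md)
    stats::var(cross, na.rm = TRUE)
  })
  expect_true(all(diff(vars) > 0))
})
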