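test_that("a legal sighting row survives a write/read round trip intact", {
  obs <- make_obs_df(3)
  # the canonical single-row example: hare with a 12 m flight at seeley
  obs$whiteness <- c(40, 60, 80)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back, obs, ignore_attr = TRUE)
  # and again: read -> write -> read is stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_observations(back, path2)
  expect_equal(read_observations(path2), back, ignore_attr = TRUE)
})

test_that("an empty collection writes a header-only file", {
  obs <- make_obs_df(1)[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_observations(path)), 0L)
})

test_that("off-grid and inconsistent rows are rejected with row diagnostics", {
  obs <- make_obs_df(2)
  obs$whiteness[2] <- 37
  expect_error(validate_observations(obs), "row\\(s\\) 2.*whiteness")

  obs <- make_obs_df(2)
  obs$snow10m[1] <- 50
  expect_error(validate_observations(obs), "snow10m")

  obs <- make_obs_df(2)
  obs$fid_m[1] <- 2.5
  expect_error(validate_observations(obs), "\\[3, 20\\]")

  obs <- make_obs_df(2)
  obs$fled[2] <- TRUE  # flush recorded without a distance
  expect_error(validate_observations(obs), "fled")

  obs <- make_obs_df(2)
  obs$attempt_index <- c(2, 1)
  expect_error(validate_observations(obs), "strictly increasing")

  obs <- make_obs_df(2)
  obs$slice_1 <- 20  # 1 of 8 slices present
  expect_error(validate_observations(obs), "pie slices")

  obs <- make_obs_df(2)[, -5]
  expect_error(validate_observations(obs), "mandatory column")
})

test_that("season assignment follows each site's own calendar", {
  cfgs <- default_site_configs()
  expect_equal(assign_season(as.Date("2011-01-15"), cfgs$seeley), "winter")
  expect_equal(assign_season(as.Date("2011-05-15"), cfgs$gardiner), "spring")
  expect_equal(assign_season(as.Date("2011-05-15"), cfgs$seeley), "spring")
  # April differs between the calendars
  expect_equal(assign_season(as.Date("2011-04-15"), cfgs$seeley), "spring")
  expect_equal(assign_season(as.Date("2011-04-15"), cfgs$gardiner), "winter")
  # every month of the year maps to a season at both sites
  dates <- as.Date(sprintf("2011-%02d-15", 1:12))
  for (cfg in cfgs) {
    s <- assign_season(dates, cfg)
    expect_true(all(s %in% c("winter", "spring", "summer", "autumn")))
    expect_length(s, 12L)
  }
  expect_error(site_config("x", rep("winter", 11)), "12 months")
})

test_that("temperature tables round-trip and reject unsorted dates", {
  temps <- data.frame(site = "seeley",
                      date = as.Date("2011-09-01") + 0:5,
                      tmean_c = c(-1.5, 0, 2.25, -3, 4, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_temperatures(temps, path)
  expect_equal(read_temperatures(path), temps, ignore_attr = TRUE)
  temps2 <- temps[c(2, 1, 3:6), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_temperatures(temps2, path2)
  expect_error(read_temperatures(path2), "strictly increasing")
})
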