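#' Generating truth for synthetic hare studies
#'
#' Bundles every parameter of the synthetic-data generator so that any
#' simulated dataset is exactly regenerable and recovery tests can compare
#' estimates against the generating values. Defaults emulate the sampling
#' design of a two-site radiotelemetry study of snowshoe hares: weekly
#' sighting attempts with incomplete detection, heavy mortality-driven
#' censoring, whiteness and snow scored visually on the 20% grid (moult
#' endpoints as 5/95%), an earlier autumn and later spring moult at the
#' high-elevation site, ~40-day moults, and behavioural responses dominated
#' by season, site and concealment rather than colour mismatch.
#'
#' @param mu_init Per-site list of population mean initiation days
#'   (day-of-season: autumn from 1 September, spring from 1 March).
#' @param dbar Base moult durations in days, named by season.
#' @param sigma_ind Between-hare-year SD of initiation (days).
#' @param sigma_obs Observation SD of whiteness (percent) before grid
#'   snapping; 0 disables both noise and snapping.
#' @param beta Duration modifiers (see [effective_duration()]): `snow` per
#'   percent mean snow, `temp` per mean degree day, `sex` in days for the
#'   female (-1) code.
#' @param hare_snow_sd SD of the persistent hare-level local snow offset
#'   (percent) — microhabitat variation around the site snow curve.
#' @param snow_obs_sd SD of per-sighting snow scoring noise before snapping.
#' @param detection_prob Probability a weekly location attempt produces a
#'   sighting.
#' @param weekly_hazard Discrete weekly mortality hazard; the default 0.03
#'   leaves roughly half the hares alive after a 23-week season.
#' @param trial_prob Probability a sighting includes a flight trial.
#' @param slice_prob Probability a sighting includes the 8-slice
#'   used-available protocol.
#' @param slice_sd SD of spot-to-spot snow variation among the nine spots.
#' @param concealment Ordered-logit generator for the 1-4 concealment level:
#'   cutpoints, site/season effects, linear and quadratic contrast
#'   coefficients, hare random-effect SD, and a habituation decline (latent
#'   drop per attempt beyond `decline_onset`).
#' @param fid Flight-initiation generator: constant baseline hazard `h0` per
#'   metre of approach progress and log-hazard coefficients; a habituation
#'   decline adds to the log hazard beyond `decline_onset`.
#' @param resting Resting-spot choice coefficient (logit preference per
#'   percent snow; negative = hares prefer snow-free spots).
#' @param entry_staggered Stagger hare entry uniformly over the study
#'   (otherwise all enter in week one).
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(
    mu_init = list(seeley = c(autumn = 40, spring = 35),
                   gardiner = c(autumn = 28, spring = 63)),
    dbar = c(autumn = 39.9, spring = 41.9),
    sigma_ind = 5,
    sigma_obs = 8,
    beta = c(snow = 0.002, temp = -2e-4, sex = 2),
    hare_snow_sd = 15,
    snow_obs_sd = 6,
    detection_prob = 0.8,
    weekly_hazard = 0.03,
    trial_prob = 0.6,
    slice_prob = 0.5,
    slice_sd = 12,
    concealment = list(cutpoints = c(-1.5, 0.5, 2.5),
                       site = c(seeley = 0.5, gardiner = 0),
                       season = c(winter = 0, spring = 0, summer = 1.2,
                                  autumn = 0.4),
                       contrast = 0.005, contrast2 = -8.5e-5,
                       hare_sd = 0.3,
                       decline_onset = Inf, decline_slope = 0),
    fid = list(h0 = 0.15,
               beta = c(concealment = -0.30, site_gardiner = 0.64,
                        season_summer = 0.19, mismatch_negative = -1.73,
                        mismatch_positive = 0),
               decline_onset = Inf, decline_slope = 0),
    resting = c(snow = -0.016),
    entry_staggered = TRUE) {
  stopifnot(sigma_ind >= 0, sigma_obs >= 0,
            detection_prob >= 0, detection_prob <= 1,
            weekly_hazard >= 0, weekly_hazard <= 1)
  structure(list(mu_init = mu_init, dbar = dbar, sigma_ind = sigma_ind,
                 sigma_obs = sigma_obs, beta = beta,
                 hare_snow_sd = hare_snow_sd, snow_obs_sd = snow_obs_sd,
                 detection_prob = detection_prob,
                 weekly_hazard = weekly_hazard, trial_prob = trial_prob,
                 slice_prob = slice_prob, slice_sd = slice_sd,
                 concealment = concealment, fid = fid, resting = resting,
                 entry_staggered = entry_staggered),
            class = "synthetic_truth")
}

#' Snow-cover scenario for one site-year
#'
#' Describes the seasonal snow curve from 1 September of `year` to 30 June
#' of `year + 1`: bare ground, a ramp to full cover starting at `onset`, a
#' plateau, and a melt ramp finishing at `melt`; plus transient fluctuations
#' against the seasonal direction, each lasting a few days. Autumn
#' fluctuations are early snowfalls of `fluct_amp` percent before the
#' seasonal onset, followed by full melt-out — the conditions that expose
#' still-brown hares on a snowy background; spring fluctuations are late
#' snowfall bumps above the melting base.
#'
#' @param site Site identifier.
#' @param year Calendar year whose autumn begins the snow season.
#' @param onset Date snow accumulation starts.
#' @param melt Date melt completes (the following spring).
#' @param n_fluct Number of autumn fluctuations.
#' @param fluct_amp Fluctuation amplitude in percent (> 30 to register as a
#'   substantial fluctuation).
#' @param n_fluct_spring Number of spring fluctuations.
#' @return List of class `snow_scenario`.
#' @export
snow_scenario <- function(site, year, onset, melt, n_fluct = 1,
                          fluct_amp = 60, n_fluct_spring = 0) {
  onset <- as.Date(onset); melt <- as.Date(melt)
  if (onset >= melt) stop("onset must precede melt", call. = FALSE)
  structure(list(site = site, year = year, onset = onset, melt = melt,
                 n_fluct = n_fluct, fluct_amp = fluct_amp,
                 n_fluct_spring = n_fluct_spring),
            class = "snow_scenario")
}

#' Default snow scenarios per site and year
#'
#' The high-elevation site snows in from late October to mid-May; the
#' low-elevation site from early December to mid-April, matching its shorter
#' snowpack.
#'
#' @param years Calendar years whose autumns start a snow season.
#' @return Named list of [snow_scenario()] objects (`site.year`).
#' @export
default_snow_scenarios <- function(years) {
  out <- list()
  for (y in years) {
    out[[paste0("gardiner.", y)]] <-
      snow_scenario("gardiner", y, sprintf("%d-10-20", y),
                    sprintf("%d-05-10", y + 1), n_fluct = 1)
    out[[paste0("seeley.", y)]] <-
      snow_scenario("seeley", y, sprintf("%d-12-01", y),
                    sprintf("%d-04-10", y + 1), n_fluct = 1)
  }
  out
}

#' Simulate a daily snow-cover series for one site-year
#'
#' Builds the ramp/plateau/melt curve of the scenario, injects the
#' configured fluctuations, and discretises to the 20% visual grid.
#' Deterministic given the seed.
#'
#' @param scenario A [snow_scenario()].
#' @param seed Integer seed.
#' @return Data frame `site, date, snow` (daily, 1 September to 30 June).
#' @export
simulate_snow <- function(scenario, seed) {
  set.seed(stream_seed(seed, paste0("snow.", scenario$site, scenario$year)))
  d0 <- as.Date(sprintf("%d-09-01", scenario$year))
  d1 <- as.Date(sprintf("%d-06-30", scenario$year + 1))
  dates <- seq(d0, d1, by = "day")
  ramp_days <- 10
  melt_days <- 14
  onset <- scenario$onset
  melt <- scenario$melt
  melt_start <- melt - melt_days
  x <- numeric(length(dates))
  x[dates >= onset] <- pmin(100, 100 * as.numeric(dates[dates >= onset] -
                                                    onset) / ramp_days)
  in_melt <- dates >= melt_start
  x[in_melt] <- pmax(0, 100 * as.numeric(melt - dates[in_melt]) / melt_days)
  # autumn fluctuations: transient early snowfalls before the seasonal
  # onset, each fully melting out before the next
  bump_start <- as.Date(sprintf("%d-09-15", scenario$year))
  bump_end <- onset - 6
  if (scenario$n_fluct > 0 && bump_start < bump_end) {
    # a week long, so fluctuations register in weekly sighting averages
    starts <- seq(bump_start, bump_end, length.out = scenario$n_fluct)
    for (s in starts) {
      span <- dates >= s & dates <= s + 6
      x[span] <- pmax(x[span], scenario$fluct_amp)
    }
  }
  # spring fluctuations: transient snowfall bumps during the melt
  if (scenario$n_fluct_spring > 0) {
    # bumps land in the second half of the melt, where fresh snowfall rises
    # well above the declining base
    starts <- seq(melt_start + 8, melt - 5,
                  length.out = scenario$n_fluct_spring)
    for (s in starts) {
      span <- dates >= s & dates <= s + 3
      x[span] <- pmin(100, x[span] + scenario$fluct_amp)
    }
  }
  data.frame(site = scenario$site, date = dates,
             snow = snap_to_grid(x, snow_grid()))
}

#' Count substantial snow fluctuations in a daily series
#'
#' A substantial fluctuation is a contiguous excursion of more than 30%
#' against the seasonal direction of change: in autumn (September-December)
#' a drop of more than 30% below the running maximum; in spring (March-June)
#' a rise of more than 30% above the running minimum.
#'
#' @param snow_series A `site, date, snow` data frame (one site).
#' @param season `"autumn"` or `"spring"`.
#' @return Integer count of excursions.
#' @export
count_snow_excursions <- function(snow_series, season = c("autumn", "spring")) {
  season <- match.arg(season)
  months <- season_window_months(season)
  keep <- as.integer(format(as.Date(snow_series$date), "%m")) %in% months
  x <- snow_series$snow[keep]
  if (!length(x)) return(0L)
  dev <- if (season == "autumn") cummax(x) - x else x - cummin(x)
  r <- rle(dev > 30)
  sum(r$values)
}

#' Simulate daily mean temperatures for the study sites
#'
#' Sinusoidal annual cycle plus day-to-day noise; the high-elevation site is
#' colder year-round. Gap-free by construction.
#'
#' @param years Calendar years to cover (January of the first to December of
#'   the last).
#' @param seed Integer seed.
#' @param sites Character vector of site names (subset of the defaults).
#' @return Data frame `site, date, tmean_c`.
#' @export
simulate_temperatures <- function(years, seed,
                                  sites = c("seeley", "gardiner")) {
  set.seed(stream_seed(seed, "temps"))
  pars <- list(seeley = c(mean = 5.5, amp = 11),
               gardiner = c(mean = 1.5, amp = 12))
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  out <- lapply(sites, function(s) {
    p <- pars[[s]]
    tm <- p[["mean"]] - p[["amp"]] * cos(2 * pi * (doy - 15) / 365.25) +
      stats::rnorm(length(dates), 0, 1.5)
    data.frame(site = s, date = dates, tmean_c = round(tm, 2))
  })
  do.call(rbind, out)
}

# latent whiteness of one hare-year trajectory on arbitrary dates, given the
# per-season change points; winter plateau at 100 between autumn completion
# and spring initiation, summer at 0
latent_whiteness <- function(dates, year, init_a, dur_a, init_s, dur_s) {
  w <- numeric(length(dates))
  ta <- day_of_season(dates, "autumn", year)
  ts <- day_of_season(dates, "spring", year + 1)
  aut <- expected_whiteness(ta, init_a, dur_a, "autumn")
  spr <- expected_whiteness(ts, init_s, dur_s, "spring")
  d_mar <- as.Date(sprintf("%d-03-01", year + 1))
  w <- ifelse(dates < d_mar, aut, spr)
  w
}

#' Simulate a full observation dataset with known truth
#'
#' Generates, per hare: a site, sex, entry week and geometric lifespan
#' (weekly hazard); a persistent local-snow offset (microhabitat); per
#' moult-season initiation dates (population mean plus a Normal individual
#' effect) and durations modified by the hare's mean local snow, mean degree
#' days and sex through [effective_duration()]. Weekly location attempts are
#' thinned by the detection probability; every attempt (detected or not)
#' advances `attempt_index`. Observed whiteness is the latent trajectory
#' plus Normal noise snapped to the legal grid (exact when `sigma_obs = 0`);
#' snow scores are snapped to the 20% grid. Concealment is drawn from an
#' ordered logit, flight trials from a constant-hazard proportional-hazards
#' model over the 20 to 3 m approach (inverse transform on the distance
#' scale, censored as "no flush" at 3 m), and resting spots by a
#' logit-weighted choice among nine candidate spots, the unchosen eight
#' becoming the available pie slices.
#'
#' @param truth A [synthetic_truth()].
#' @param scenarios List of [snow_scenario()]s covering the simulated sites
#'   and years (see [default_snow_scenarios()]).
#' @param n_hares Hares per site.
#' @param years Calendar years whose autumns are simulated (the following
#'   springs are included).
#' @param seed Integer seed; all stage randomness derives from it via named
#'   streams.
#' @param site_configs Named list of [site_config()]s covering the simulated
#'   sites (default [default_site_configs()]).
#' @return List of class `synthetic_study`: `observations` (validated
#'   table), `temperatures`, `snow` (daily series), `truth` (the input plus
#'   per-hare and per-hare-season generating values), `sites`, `years`,
#'   `seed`.
#' @export
simulate_hares <- function(truth, scenarios, n_hares, years, seed,
                           site_configs = default_site_configs()) {
  stopifnot(inherits(truth, "synthetic_truth"), n_hares >= 1)
  sites <- unique(vapply(scenarios, `[[`, "", "site"))
  # temperatures must cover the springs that follow the last simulated autumn
  temps <- simulate_temperatures(seq(min(years), max(years) + 1), seed, sites)
  snow_daily <- do.call(rbind, lapply(scenarios, simulate_snow, seed = seed))
  rownames(snow_daily) <- NULL
  configs <- site_configs

  study_start <- as.Date(sprintf("%d-09-01", min(years)))
  study_end <- as.Date(sprintf("%d-06-30", max(years) + 1))
  n_weeks <- as.integer(floor(as.numeric(study_end - study_start) / 7)) + 1L

  # per-site degree-day lookups, one row per day in each season window
  dd_tab <- list()
  for (s in sites) {
    st <- temps[temps$site == s, , drop = FALSE]
    dd_tab[[s]] <- list(autumn = degree_days(st, "autumn"),
                        spring = degree_days(st, "spring"))
  }
  site_snow <- function(s, dates) {
    z <- snow_daily[snow_daily$site == s, ]
    out <- z$snow[match(dates, z$date)]
    out[is.na(out)] <- 0
    out
  }
  window_dates <- function(season, year)
    seq(season_window_start(season, year), season_window_end(season, year),
        by = "day")

  set.seed(stream_seed(seed, "hares"))
  hares <- data.frame(
    hare_id = sprintf("%s%03d", rep(substr(sites, 1, 1), each = n_hares),
                      rep(seq_len(n_hares), length(sites))),
    site = rep(sites, each = n_hares),
    sex = sample(c("female", "male"), n_hares * length(sites),
                 replace = TRUE),
    snow_offset = stats::rnorm(n_hares * length(sites), 0,
                               truth$hare_snow_sd),
    conceal_re = stats::rnorm(n_hares * length(sites), 0,
                              truth$concealment$hare_sd))
  hares$entry_week <- if (truth$entry_staggered)
    sample.int(max(1L, n_weeks - 8L), nrow(hares), replace = TRUE) else 1L
  hares$lifespan_weeks <- if (truth$weekly_hazard > 0)
    stats::rgeom(nrow(hares), truth$weekly_hazard) + 1L else n_weeks + 1L

  # per hare-season generating change points
  set.seed(stream_seed(seed, "phenology"))
  units <- list()
  for (i in seq_len(nrow(hares))) {
    h <- hares[i, ]
    for (y in years) {
      for (season in c("autumn", "spring")) {
        yy <- if (season == "autumn") y else y + 1
        wdates <- window_dates(season, yy)
        loc_snow <- pmin(100, pmax(0, site_snow(h$site, wdates) +
                                     h$snow_offset))
        ddw <- dd_tab[[h$site]][[season]]
        dd_mean <- mean(ddw$dd[ddw$date %in% wdates])
        sexx <- if (h$sex == "female") -1 else 0
        mu <- truth$mu_init[[h$site]][[season]]
        init <- mu + stats::rnorm(1, 0, truth$sigma_ind)
        dur <- effective_duration(truth$dbar[[season]], mean(loc_snow),
                                  dd_mean, sexx, truth$beta)
        units[[length(units) + 1L]] <-
          data.frame(hare_id = h$hare_id, site = h$site, year = yy,
                     season = season, init = init, duration = dur,
                     snow_cov = mean(loc_snow), dd_cov = dd_mean,
                     sexx = sexx)
      }
    }
  }
  units <- do.call(rbind, units)
  rownames(units) <- NULL

  # weekly sightings
  set.seed(stream_seed(seed, "sightings"))
  rows <- vector("list", nrow(hares))
  noise_free <- truth$sigma_obs == 0
  for (i in seq_len(nrow(hares))) {
    h <- hares[i, ]
    last_week <- min(n_weeks, h$entry_week + h$lifespan_weeks - 1L)
    weeks <- seq.int(h$entry_week, last_week)
    if (!length(weeks)) next
    detected <- stats::runif(length(weeks)) < truth$detection_prob
    if (!any(detected)) next
    attempt <- seq_along(weeks)[detected]
    dates <- study_start + (weeks[detected] - 1L) * 7L
    # latent whiteness per sighting from the hare's own change points
    moult_year <- as.integer(format(dates, "%Y")) -
      (as.integer(format(dates, "%m")) < 9L)
    u <- units[units$hare_id == h$hare_id, ]
    lat <- vapply(seq_along(dates), function(k) {
      ua <- u[u$season == "autumn" & u$year == moult_year[k], ]
      us <- u[u$season == "spring" & u$year == moult_year[k] + 1L, ]
      if (!nrow(ua) || !nrow(us)) return(NA_real_)
      latent_whiteness(dates[k], moult_year[k], ua$init, ua$duration,
                       us$init, us$duration)
    }, numeric(1))
    ok <- !is.na(lat)
    if (!any(ok)) next
    dates <- dates[ok]; lat <- lat[ok]; attempt <- attempt[ok]
    n <- length(dates)
    whiteness <- if (noise_free) lat else
      snap_to_grid(lat + stats::rnorm(n, 0, truth$sigma_obs))
    loc_snow <- pmin(100, pmax(0, site_snow(h$site, dates) + h$snow_offset))
    snow10 <- if (noise_free) snap_to_grid(loc_snow, snow_grid()) else
      snap_to_grid(loc_snow + stats::rnorm(n, 0, truth$snow_obs_sd),
                   snow_grid())

    # resting-spot choice among nine candidate spots; the chosen one becomes
    # the 1-m snow score, the rest the pie slices (when the protocol ran)
    has_slices <- stats::runif(n) < truth$slice_prob
    snow1 <- numeric(n)
    slices <- matrix(NA_real_, n, 8)
    for (k in seq_len(n)) {
      cand <- snap_to_grid(loc_snow[k] + stats::rnorm(9, 0, truth$slice_sd),
                           snow_grid())
      wgt <- exp(truth$resting[["snow"]] * cand)
      pick <- sample.int(9, 1, prob = wgt)
      snow1[k] <- cand[pick]
      if (has_slices[k]) slices[k, ] <- cand[-pick]
    }

    contrast1 <- whiteness - snow1
    contrast10 <- whiteness - snow10
    season_lab <- assign_season(dates, configs[[h$site]])

    # concealment: ordered logit on a latent scale
    cpar <- truth$concealment
    lp_c <- cpar$site[[h$site]] + cpar$season[season_lab] +
      cpar$contrast * contrast1 + cpar$contrast2 * contrast1^2 +
      h$conceal_re -
      cpar$decline_slope * pmax(0, attempt - cpar$decline_onset)
    u_lat <- stats::rlogis(n, lp_c)
    concealment <- 1L + findInterval(u_lat, cpar$cutpoints)

    # flight trials: constant hazard over approach progress (0 at 20 m),
    # censored as "no flush" at 3 m (progress 17)
    fpar <- truth$fid
    has_trial <- stats::runif(n) < truth$trial_prob
    mism10 <- classify_mismatch(contrast10)
    lp_f <- fpar$beta[["concealment"]] * concealment +
      (if (h$site == "gardiner") fpar$beta[["site_gardiner"]] else 0) +
      ifelse(season_lab == "summer", fpar$beta[["season_summer"]], 0) +
      ifelse(mism10 == "negative", fpar$beta[["mismatch_negative"]],
             ifelse(mism10 == "positive", fpar$beta[["mismatch_positive"]],
                    0)) +
      fpar$decline_slope * pmax(0, attempt - fpar$decline_onset)
    s_flee <- stats::rexp(n, fpar$h0 * exp(lp_f))
    fled <- has_trial & s_flee <= 17
    fid_m <- ifelse(has_trial,
                    ifelse(fled, pmin(20, pmax(3, round(20 - s_flee))), 3),
                    NA_real_)

    rows[[i]] <- data.frame(
      hare_id = h$hare_id, site = h$site, date = dates, sex = h$sex,
      whiteness = whiteness, snow1m = snow1, snow10m = snow10,
      concealment = concealment, fid_m = fid_m,
      fled = ifelse(has_trial, fled, NA),
      attempt_index = attempt,
      slice_1 = slices[, 1], slice_2 = slices[, 2], slice_3 = slices[, 3],
      slice_4 = slices[, 4], slice_5 = slices[, 5], slice_6 = slices[, 6],
      slice_7 = slices[, 7], slice_8 = slices[, 8])
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  obs <- validate_observations(obs, grid_scores = !noise_free)

  truth_out <- truth
  truth_out$hares <- hares
  truth_out$units <- units
  truth_out$seed <- seed
  structure(list(observations = obs, temperatures = temps,
                 snow = snow_daily, truth = truth_out, sites = sites,
                 years = years, seed = seed),
            class = "synthetic_study")
}

#' Bundled deterministic test fixtures
#'
#' Named study datasets of fixed size and seed. `phenology_small`: one site
#' (gardiner), 30 hares, two moult years — sized for change-point recovery
#' checks. `behaviour_small`: two sites, 25 hares each collared from the
#' first week, one year, with flight trials and pie slices at every
#' sighting — dense behavioural data. `full_study`: two sites with offset
#' phenologies, 30 hares each, two years — the end-to-end study emulation.
#'
#' @param name Fixture name.
#' @param seed Integer seed (each fixture has a fixed default, so fixtures
#'   regenerate identically across calls).
#' @return A `synthetic_study` list (see [simulate_hares()]).
#' @export
make_fixture <- function(name = c("phenology_small", "behaviour_small",
                                  "full_study"), seed = NULL) {
  name <- match.arg(name)
  switch(name,
    phenology_small = {
      if (is.null(seed)) seed <- 20111
      sc <- default_snow_scenarios(c(2011, 2012))
      sc <- sc[grepl("gardiner", names(sc))]
      simulate_hares(synthetic_truth(), sc, n_hares = 30,
                     years = c(2011, 2012), seed = seed)
    },
    behaviour_small = {
      if (is.null(seed)) seed <- 20112
      tr <- synthetic_truth(trial_prob = 1, slice_prob = 1,
                            weekly_hazard = 0.02, entry_staggered = FALSE)
      simulate_hares(tr, default_snow_scenarios(2011), n_hares = 25,
                     years = 2011, seed = seed)
    },
    full_study = {
      if (is.null(seed)) seed <- 20113
      simulate_hares(synthetic_truth(),
                     default_snow_scenarios(c(2011, 2012)),
                     n_hares = 30, years = c(2011, 2012), seed = seed)
    })
}

#' Simulate used-available resting choices at one snow condition
#'
#' Generates standalone choice sets for calibrating the resting-spot model:
#' each location offers nine candidate spots whose snow cover varies around
#' a common base (a single-snapshot design, so the between-location snow
#' variation that attenuates marginal used-available coefficients is
#' absent), and the hare picks one spot with multinomial probability
#' proportional to `exp(beta_snow * snow)`. Locations are spread over
#' `n_hares` hares.
#'
#' @param n_locations Number of choice sets.
#' @param beta_snow Generating logit preference per percent snow.
#' @param base_snow Common base snow percent.
#' @param spot_sd SD of spot-to-spot snow variation before grid snapping.
#' @param n_hares Number of hares the locations are spread across.
#' @param seed Integer seed.
#' @return A choice-row table in the [build_choice_rows()] layout.
#' @export
simulate_resting_choices <- function(n_locations, beta_snow,
                                     base_snow = 50, spot_sd = 20,
                                     n_hares = max(1, n_locations %/% 4),
                                     seed) {
  set.seed(stream_seed(seed, "resting-choices"))
  hare <- sprintf("h%03d", sample.int(n_hares, n_locations, replace = TRUE))
  out <- vector("list", n_locations)
  for (i in seq_len(n_locations)) {
    cand <- snap_to_grid(base_snow + stats::rnorm(9, 0, spot_sd),
                         snow_grid())
    if (all(cand == 0) || all(cand == 100))
      cand[sample.int(9, 1)] <- if (all(cand == 0)) 20 else 80
    pick <- sample.int(9, 1, prob = exp(beta_snow * cand))
    out[[i]] <- data.frame(
      hare_id = hare[i], date = as.Date("2011-11-01") + i,
      location_id = sprintf("loc%04d", i),
      used = as.integer(seq_len(9) == pick),
      snow = cand, contrast = 100 - cand, whiteness = 100)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic study to disk
#'
#' Emits the observation and temperature CSVs in the package dialects plus
#' the generating truth as YAML.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_obs <- file.path(dir, "observations.csv")
  f_tmp <- file.path(dir, "temperatures.csv")
  f_truth <- file.path(dir, "truth.yaml")
  write_observations(study$observations, f_obs)
  write_temperatures(study$temperatures, f_tmp)
  tr <- study$truth
  tr$hares <- lapply(tr$hares, function(col) unname(col))
  tr$units <- lapply(tr$units, function(col) unname(col))
  yaml::write_yaml(tr, f_truth)
  invisible(c(f_obs, f_tmp, f_truth))
}
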