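# shared builders for small in-code fixtures

# minimal legal observation rows
make_obs_df <- function(n = 3) {
  data.frame(
    hare_id = rep("h1", n), site = rep("seeley", n),
    date = as.Date("2011-10-12") + seq_len(n) * 7, sex = "female",
    whiteness = whiteness_grid()[seq_len(n) + 1],
    snow1m = 0, snow10m = 20, concealment = 2,
    fid_m = c(12, rep(NA, n - 1)), fled = c(TRUE, rep(NA, n - 1)),
    attempt_index = seq_len(n),
    slice_1 = NA_real_, slice_2 = NA_real_, slice_3 = NA_real_,
    slice_4 = NA_real_, slice_5 = NA_real_, slice_6 = NA_real_,
    slice_7 = NA_real_, slice_8 = NA_real_)
}

# hand-built hierarchical moult dataset with exact change-point structure:
# per-unit initiation mu + eps, duration dbar * exp(beta_snow * centred
# snow); observations every 7 days with Gaussian noise (not grid-snapped,
# so likelihood assumptions hold exactly)
make_moult_data <- function(n_hares = 10, years = 2011, mu = 30, dbar = 40,
                            sigma_ind = 4, sigma_obs = 3, beta_snow = 0,
                            snow = NULL, season = "autumn", seed = 1,
                            dur_add = NULL) {
  set.seed(seed)
  units <- expand.grid(hare_id = sprintf("h%02d", seq_len(n_hares)),
                       year = years, stringsAsFactors = FALSE)
  units$unit <- paste(units$hare_id, units$year, sep = ":")
  units$snow <- if (is.null(snow))
    stats::runif(nrow(units), 20, 80) else snow
  units$dd <- 0
  units$sexx <- 0
  units$eps <- stats::rnorm(nrow(units), 0, sigma_ind)
  ms <- mean(units$snow)
  units$duration <- pmax(1, dbar * exp(beta_snow * (units$snow - ms)))
  if (!is.null(dur_add)) units$duration <- units$duration + dur_add
  units$init <- mu + units$eps
  pts <- do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    t <- seq(0, 110, by = 7)
    w <- expected_whiteness(t, u$init, u$duration, season) +
      stats::rnorm(length(t), 0, sigma_obs)
    data.frame(unit = u$unit, t = t, whiteness = pmin(100, pmax(0, w)),
               date = season_start_date(season, u$year) + t)
  }))
  units$n_obs <- as.integer(table(pts$unit)[units$unit])
  structure(list(points = pts,
                 units = units[c("unit", "hare_id", "year", "snow", "dd",
                                 "sexx", "n_obs")],
                 season = season, site = "testsite",
                 truth = units),
            class = "moult_data")
}

season_start_date <- function(season, year) {
  as.Date(sprintf("%d-%02d-01", year, if (season == "autumn") 9L else 3L))
}

# independent brute-force log-likelihood: explicit per-observation normal
# densities and clamped linear ramp, sharing no code with the package
brute_loglik <- function(params, data) {
  total <- 0
  un <- data$units
  eps <- if (is.null(params$eps)) rep(0, nrow(un)) else params$eps
  beta <- params$beta
  b <- function(nm) if (!is.null(beta) && nm %in% names(beta))
    beta[[nm]] else 0
  for (i in seq_len(nrow(data$points))) {
    p <- data$points[i, ]
    j <- which(un$unit == p$unit)
    dur <- params$dbar *
      exp(b("snow") * un$snow[j] + b("temp") * un$dd[j]) +
      b("sex") * un$sexx[j]
    dur <- max(1, dur)
    frac <- (p$t - (params$mu_init + eps[j])) / dur
    frac <- min(1, max(0, frac))
    m <- if (data$season == "autumn") 100 * frac else 100 * (1 - frac)
    s <- params$sigma_obs
    total <- total - 0.5 * log(2 * pi * s^2) -
      (p$whiteness - m)^2 / (2 * s^2)
  }
  for (j in seq_along(eps)) {
    s <- params$sigma_ind
    if (s > 0)
      total <- total - 0.5 * log(2 * pi * s^2) - eps[j]^2 / (2 * s^2)
  }
  total
}

# concealment observations from an ordered-logit generator with optional
# habituation decline and contrast effects
sim_concealment <- function(n_hares, max_att, seed, onset = Inf, slope = 0,
                            b_contrast = 0, b_contrast2 = 0) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_hares), function(i) {
    re <- stats::rnorm(1, 0, 0.3)
    att <- seq_len(max_att)
    contrast1m <- sample(seq(-100, 100, by = 20), max_att, replace = TRUE)
    lp <- 0.5 + re + b_contrast * contrast1m + b_contrast2 * contrast1m^2 -
      slope * pmax(0, att - onset)
    lev <- 1L + findInterval(stats::rlogis(max_att, lp), c(-1.5, 0.5, 2.5))
    data.frame(hare_id = sprintf("h%02d", i), attempt_index = att,
               concealment = lev, contrast1m = contrast1m,
               fid_m = NA_real_, fled = NA)
  }))
}

# grid-search maximiser of the exact intercept+slope binomial likelihood
brute_logit_slope <- function(rows, predictor = "snow") {
  x <- rows[[predictor]]
  y <- rows$used
  ll <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  a_grid <- seq(-5, 1, length.out = 41)
  b_grid <- seq(-0.1, 0.1, length.out = 41)
  for (pass in 1:6) {
    vals <- outer(a_grid, b_grid, Vectorize(ll))
    k <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    a0 <- a_grid[k[1]]; b0 <- b_grid[k[2]]
    da <- diff(a_grid[1:2]); db <- diff(b_grid[1:2])
    a_grid <- seq(a0 - 2 * da, a0 + 2 * da, length.out = 21)
    b_grid <- seq(b0 - 2 * db, b0 + 2 * db, length.out = 21)
  }
  c(intercept = a0, slope = b0)
}
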