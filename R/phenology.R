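#' Expected coat whiteness under the change-point trajectory
#'
#' The moult trajectory is piecewise linear between two change points: flat
#' before initiation, a linear ramp over the moult duration, flat after
#' completion. In autumn the coat ramps brown to white (0 to 100%); in
#' spring white to brown (100 to 0%).
#'
#' @param t Day (numeric, same scale as `init`), vectorised.
#' @param init Individual initiation day.
#' @param duration Individual moult duration in days, > 0.
#' @param season `"autumn"` or `"spring"`.
#' @return Expected per-cent whiteness in [0, 100].
#' @export
expected_whiteness <- function(t, init, duration, season = c("autumn", "spring")) {
  season <- match.arg(season)
  if (any(duration <= 0))
    stop("duration must be positive", call. = FALSE)
  f <- pmin(1, pmax(0, (t - init) / duration))
  if (season == "autumn") 100 * f else 100 * (1 - f)
}

#' Effective moult duration under covariates
#'
#' Covariates modify the moult rate multiplicatively on the duration scale
#' through an exponential link: `duration = dbar * exp(beta_snow * snow +
#' beta_temp * dd) + beta_sex * sexx`, floored at one day. `sexx` codes sex
#' as 0 for males and -1 for females, so a positive `beta_sex` means females
#' complete the moult earlier. A positive `beta_snow` lengthens the spring
#' white-to-brown moult under snow (snow cover slows the change); a negative
#' `beta_temp` shortens it under accumulated warmth.
#'
#' @param dbar Base duration in days, > 0.
#' @param snow Mean per-cent snow cover over the hare's season window.
#' @param dd Mean degree days over the window.
#' @param sexx Sex code (0 = male, -1 = female).
#' @param beta Named numeric vector with any of `snow`, `temp`, `sex`
#'   (missing entries are 0).
#' @return Duration in days, >= 1.
#' @export
effective_duration <- function(dbar, snow = 0, dd = 0, sexx = 0,
                               beta = c(snow = 0, temp = 0, sex = 0)) {
  if (any(dbar <= 0)) stop("dbar must be positive", call. = FALSE)
  b <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  pmax(1, dbar * exp(b("snow") * snow + b("temp") * dd) + b("sex") * sexx)
}

#' Assemble per-hare moult trajectories for change-point fitting
#'
#' Restricts an observation table to one site and one moult season window
#' (autumn: September-December; spring: March-June), converts dates to day
#' of season, and summarises the time-varying covariates per hare-year as
#' window means: mean observed 10-m snow cover, mean degree days at the
#' sighting dates, and the sex code. The unit of the hierarchical model is
#' the hare-year, so a hare observed in two autumns contributes two units
#' (this is what makes between-year reaction norms estimable).
#'
#' @param obs Validated observation table.
#' @param temps Daily temperature table for the same site.
#' @param site Site identifier.
#' @param season `"autumn"` or `"spring"`.
#' @return An object of class `moult_data`: list with `points` (unit, t,
#'   whiteness, date), `units` (unit, hare_id, year, snow, dd, sexx,
#'   n_obs), `season`, `site`.
#' @export
prepare_moult_data <- function(obs, temps, site, season = c("autumn", "spring")) {
  season <- match.arg(season)
  obs <- obs[obs$site == site, , drop = FALSE]
  if (!nrow(obs)) stop("no observations for site ", site, call. = FALSE)
  obs$date <- as.Date(obs$date)
  months <- season_window_months(season)
  obs <- obs[as.integer(format(obs$date, "%m")) %in% months, , drop = FALSE]
  if (!nrow(obs))
    stop("no observations in the ", season, " window for site ", site,
         call. = FALSE)
  obs$year <- as.integer(format(obs$date, "%Y"))
  obs$t <- day_of_season(obs$date, season, obs$year)
  obs$unit <- paste(obs$hare_id, obs$year, sep = ":")

  dd <- degree_days(temps[temps$site == site, , drop = FALSE], season)
  obs$dd_at <- dd$dd[match(obs$date, dd$date)]
  if (any(is.na(obs$dd_at)))
    stop("temperature series does not cover all sighting dates", call. = FALSE)

  units <- do.call(rbind, lapply(split(obs, obs$unit), function(u) {
    data.frame(unit = u$unit[1L], hare_id = u$hare_id[1L], year = u$year[1L],
               snow = mean(u$snow10m), dd = mean(u$dd_at),
               sexx = if (u$sex[1L] == "female") -1 else 0,
               n_obs = nrow(u))
  }))
  rownames(units) <- NULL
  structure(list(points = obs[c("unit", "t", "whiteness", "date")],
                 units = units, season = season, site = site),
            class = "moult_data")
}

#' Log-likelihood of the hierarchical change-point model
#'
#' Gaussian observation model on the latent percentage: the sum over
#' sightings of `Normal(whiteness | expected_whiteness, sigma_obs^2)`
#' log-densities, plus the `Normal(eps | 0, sigma_ind^2)` log-densities of
#' the per-unit initiation random effects. Grid-scored whiteness values are
#' treated as point observations. With `sigma_obs = 0` the density is
#' degenerate: the function returns `-Inf` unless every observation lies
#' exactly on its trajectory.
#'
#' @param params List with `mu_init`, `dbar`, `sigma_ind`, `sigma_obs`,
#'   optional `beta` (named `snow`/`temp`/`sex`), and `eps` (per-unit
#'   initiation offsets, in the order of `data$units`; default all 0).
#' @param data A [prepare_moult_data()] object.
#' @return Scalar log density.
#' @export
log_likelihood <- function(params, data) {
  stopifnot(inherits(data, "moult_data"))
  un <- data$units
  eps <- if (is.null(params$eps)) rep(0, nrow(un)) else params$eps
  beta <- if (is.null(params$beta)) c(snow = 0, temp = 0, sex = 0) else params$beta
  dur <- effective_duration(params$dbar, un$snow, un$dd, un$sexx, beta)
  init <- params$mu_init + eps
  iu <- match(data$points$unit, un$unit)
  mu <- expected_whiteness(data$points$t, init[iu], dur[iu], data$season)
  if (params$sigma_obs == 0) {
    ll_data <- if (all(data$points$whiteness == mu)) Inf else -Inf
  } else {
    ll_data <- sum(stats::dnorm(data$points$whiteness, mu, params$sigma_obs,
                                log = TRUE))
  }
  ll_re <- if (params$sigma_ind == 0) {
    if (all(eps == 0)) 0 else -Inf
  } else {
    sum(stats::dnorm(eps, 0, params$sigma_ind, log = TRUE))
  }
  ll_data + ll_re
}

#' Priors for the change-point model
#'
#' Initiation has a uniform prior over the season-day window; the base
#' duration a uniform prior over plausible moult lengths; the two standard
#' deviations half-normal priors; covariate coefficients diffuse
#' `Normal(0, 10^2)` priors.
#'
#' @param init_window Two days-of-season bounding the population initiation.
#' @param dur_range Two positive bounds on the base duration (days).
#' @param sd_ind_scale,sd_obs_scale Half-normal scales for the individual
#'   and observation SDs.
#' @param beta_sd Prior SD of each covariate coefficient.
#' @return List of class `moult_priors`.
#' @export
moult_priors <- function(init_window = c(0, 120), dur_range = c(1, 120),
                         sd_ind_scale = 15, sd_obs_scale = 15, beta_sd = 10) {
  structure(list(init_window = init_window, dur_range = dur_range,
                 sd_ind_scale = sd_ind_scale, sd_obs_scale = sd_obs_scale,
                 beta_sd = beta_sd), class = "moult_priors")
}

# crude initiation guess: interpolated day at which each unit's trajectory
# crosses 50% whiteness
crossing_times <- function(data) {
  sgn <- if (data$season == "autumn") 1 else -1
  vapply(split(data$points, data$points$unit), function(p) {
    p <- p[order(p$t), ]
    w <- sgn * p$whiteness
    k <- which(w[-1] >= sgn * 50 & w[-nrow(p)] < sgn * 50)
    if (!length(k)) return(NA_real_)
    i <- k[1L]
    t0 <- p$t[i]; t1 <- p$t[i + 1L]
    w0 <- p$whiteness[i]; w1 <- p$whiteness[i + 1L]
    if (w1 == w0) return((t0 + t1) / 2)
    t0 + (50 - w0) * (t1 - t0) / (w1 - w0)
  }, numeric(1))
}

#' Fit the hierarchical change-point model by MCMC
#'
#' Samples the posterior of the population mean initiation day, base moult
#' duration, covariate coefficients, and the per-hare-year initiation random
#' effects, using adaptive random-walk Metropolis-within-Gibbs: scalar
#' parameters are updated one at a time with normal proposals whose scales
#' adapt toward a 44% acceptance rate during warmup, and the conditionally
#' independent random effects are updated in one vectorised sweep per
#' iteration. Covariates are centred internally, so the derived population
#' completion date is `mu_init` plus the effective duration at the observed
#' covariate means. Convergence is checked with the split-chain potential
#' scale reduction statistic (flagged above 1.05); intervals are equal-tailed
#' 95% credible intervals.
#'
#' @param data A [prepare_moult_data()] object with at least two units of
#'   three or more sightings.
#' @param priors A [moult_priors()] object.
#' @param covariates Character subset of `c("snow", "temp", "sex")` to
#'   include as duration modifiers (default none).
#' @param chains Number of chains (>= 2).
#' @param iter Post-warmup iterations per chain.
#' @param warmup Warmup (adaptation) iterations per chain.
#' @param seed Integer seed; mandatory, no hidden global state.
#' @return Object of class `phenology_fit`: posterior draw matrix (including
#'   derived `init` and `completion` days), per-parameter summary with
#'   split-chain R-hat, per-unit random-effect summaries, acceptance rates,
#'   and a `converged` flag.
#' @export
fit_changepoint <- function(data, priors = moult_priors(),
                            covariates = character(),
                            chains = 2L, iter = 1000L, warmup = 500L,
                            seed) {
  stopifnot(inherits(data, "moult_data"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(covariates))
    covariates <- match.arg(covariates, c("snow", "temp", "sex"),
                            several.ok = TRUE)
  if (sum(data$units$n_obs >= 3L) < 2L)
    stop("need at least 2 hare-years with >= 3 sightings", call. = FALSE)

  un <- data$units
  n_u <- nrow(un)
  y <- data$points$whiteness
  tt <- data$points$t
  iu <- match(data$points$unit, un$unit)
  centers <- c(snow = mean(un$snow), temp = mean(un$dd), sexx = mean(un$sexx))
  xs <- un$snow - centers[["snow"]]
  xt <- un$dd - centers[["temp"]]
  xx <- un$sexx - centers[["sexx"]]
  sgn_up <- data$season == "autumn"

  use_s <- "snow" %in% covariates
  use_t <- "temp" %in% covariates
  use_x <- "sex" %in% covariates

  loglik_data <- function(mu, dbar, sobs, bs, bt, bx, eps) {
    dur <- pmax(1, dbar * exp(bs * xs + bt * xt) + bx * xx)
    f <- pmin(1, pmax(0, (tt - (mu + eps)[iu]) / dur[iu]))
    m <- if (sgn_up) 100 * f else 100 * (1 - f)
    stats::dnorm(y, m, sobs, log = TRUE)
  }

  logprior <- function(mu, dbar, sind, sobs, bs, bt, bx) {
    if (mu < priors$init_window[1] || mu > priors$init_window[2]) return(-Inf)
    if (dbar < priors$dur_range[1] || dbar > priors$dur_range[2]) return(-Inf)
    if (sind < 0 || sobs <= 0.05) return(-Inf)
    lp <- stats::dnorm(sind, 0, priors$sd_ind_scale, log = TRUE) +
      stats::dnorm(sobs, 0, priors$sd_obs_scale, log = TRUE)
    if (use_s) lp <- lp + stats::dnorm(bs, 0, priors$beta_sd, log = TRUE)
    if (use_t) lp <- lp + stats::dnorm(bt, 0, priors$beta_sd, log = TRUE)
    if (use_x) lp <- lp + stats::dnorm(bx, 0, priors$beta_sd, log = TRUE)
    lp
  }

  # data-driven starting values from interpolated 50%-crossing days
  cross <- crossing_times(data)
  d0 <- 40
  mu0 <- if (all(is.na(cross))) mean(priors$init_window) else
    mean(cross, na.rm = TRUE) - d0 / 2
  mu0 <- min(max(mu0, priors$init_window[1]), priors$init_window[2])

  par_names <- c("mu_init", "dbar", "sigma_ind", "sigma_obs",
                 if (use_s) "beta_snow", if (use_t) "beta_temp",
                 if (use_x) "beta_sex")
  run_chain <- function(chain_id) {
    set.seed(stream_seed(seed, paste0("chain", chain_id)))
    mu <- mu0 + stats::rnorm(1, 0, 3)
    dbar <- d0 * exp(stats::rnorm(1, 0, 0.1))
    sind <- 4 + chain_id
    sobs <- 8
    bs <- bt <- bx <- 0
    eps <- rep(0, n_u)
    scales <- c(mu_init = 2, dbar = 2, sigma_ind = 1, sigma_obs = 1,
                beta_snow = 0.01, beta_temp = 0.01, beta_sex = 2)
    eps_scale <- 3
    rc_scale <- 2   # recentering move: mu + d, eps - d (likelihood-invariant)
    to_scale <- 2   # trade-off move: mu + d, dbar - d (completion-preserving)
    acc <- stats::setNames(numeric(length(par_names)), par_names)
    eps_acc <- 0
    n_keep <- iter
    draws <- matrix(NA_real_, n_keep, length(par_names) + 2,
                    dimnames = list(NULL, c(par_names, "init", "completion")))
    eps_draws <- matrix(NA_real_, n_keep, n_u)
    ll_pts <- loglik_data(mu, dbar, sobs, bs, bt, bx, eps)
    ll <- sum(ll_pts)
    win_acc <- stats::setNames(numeric(length(par_names)), par_names)
    win_eps <- 0
    rc_acc <- 0
    to_acc <- 0
    total <- warmup + iter
    for (it in seq_len(total)) {
      for (p in par_names) {
        cur <- switch(p, mu_init = mu, dbar = dbar, sigma_ind = sind,
                      sigma_obs = sobs, beta_snow = bs, beta_temp = bt,
                      beta_sex = bx)
        prop <- cur + stats::rnorm(1, 0, scales[[p]])
        mu_p <- mu; dbar_p <- dbar; sind_p <- sind; sobs_p <- sobs
        bs_p <- bs; bt_p <- bt; bx_p <- bx
        switch(p, mu_init = {mu_p <- prop}, dbar = {dbar_p <- prop},
               sigma_ind = {sind_p <- prop}, sigma_obs = {sobs_p <- prop},
               beta_snow = {bs_p <- prop}, beta_temp = {bt_p <- prop},
               beta_sex = {bx_p <- prop})
        lp_new <- logprior(mu_p, dbar_p, sind_p, sobs_p, bs_p, bt_p, bx_p)
        if (is.finite(lp_new)) {
          lre_new <- if (sind_p > 0)
            sum(stats::dnorm(eps, 0, sind_p, log = TRUE))
          else if (all(eps == 0)) 0 else -Inf
          if (p == "sigma_ind") {
            # data term unchanged: only the random-effect prior moves
            ll_new_pts <- ll_pts
          } else {
            ll_new_pts <- loglik_data(mu_p, dbar_p, sobs_p, bs_p, bt_p, bx_p, eps)
          }
          lre_old <- if (sind > 0)
            sum(stats::dnorm(eps, 0, sind, log = TRUE))
          else if (all(eps == 0)) 0 else -Inf
          lp_old <- logprior(mu, dbar, sind, sobs, bs, bt, bx)
          lr <- sum(ll_new_pts) + lre_new + lp_new - (ll + lre_old + lp_old)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            mu <- mu_p; dbar <- dbar_p; sind <- sind_p; sobs <- sobs_p
            bs <- bs_p; bt <- bt_p; bx <- bx_p
            ll_pts <- ll_new_pts; ll <- sum(ll_pts)
            win_acc[p] <- win_acc[p] + 1
            if (it > warmup) acc[p] <- acc[p] + 1
          }
        }
      }
      # vectorised sweep over the conditionally independent random effects
      eps_prop <- eps + stats::rnorm(n_u, 0, eps_scale)
      ll_u_old <- rowsum(ll_pts, iu, reorder = TRUE)[, 1]
      ll_pts_prop <- loglik_data(mu, dbar, sobs, bs, bt, bx, eps_prop)
      ll_u_new <- rowsum(ll_pts_prop, iu, reorder = TRUE)[, 1]
      pri_old <- if (sind > 0) stats::dnorm(eps, 0, sind, log = TRUE) else
        ifelse(eps == 0, 0, -Inf)
      pri_new <- if (sind > 0) stats::dnorm(eps_prop, 0, sind, log = TRUE) else
        ifelse(eps_prop == 0, 0, -Inf)
      lr_u <- (ll_u_new + pri_new) - (ll_u_old + pri_old)
      take <- log(stats::runif(n_u)) < lr_u
      take[!is.finite(lr_u)] <- FALSE
      if (any(take)) {
        eps[take] <- eps_prop[take]
        ll_pts <- ifelse(take[iu], ll_pts_prop, ll_pts)
        ll <- sum(ll_pts)
      }
      win_eps <- win_eps + mean(take)
      if (it > warmup) eps_acc <- eps_acc + mean(take)
      # recentering: shift the population mean against the random effects;
      # the data term is unchanged, only the prior and RE density move
      dlt <- stats::rnorm(1, 0, rc_scale)
      if (priors$init_window[1] <= mu + dlt &&
          mu + dlt <= priors$init_window[2] && sind > 0) {
        lr <- sum(stats::dnorm(eps - dlt, 0, sind, log = TRUE)) -
          sum(stats::dnorm(eps, 0, sind, log = TRUE))
        if (log(stats::runif(1)) < lr) {
          mu <- mu + dlt
          eps <- eps - dlt
          rc_acc <- rc_acc + (it <= warmup)
        }
      }
      # completion-preserving trade-off between initiation and duration
      dlt <- stats::rnorm(1, 0, to_scale)
      mu_p <- mu + dlt; dbar_p <- dbar - dlt
      lp_new <- logprior(mu_p, dbar_p, sind, sobs, bs, bt, bx)
      if (is.finite(lp_new)) {
        ll_new_pts <- loglik_data(mu_p, dbar_p, sobs, bs, bt, bx, eps)
        lp_old <- logprior(mu, dbar, sind, sobs, bs, bt, bx)
        lr <- sum(ll_new_pts) + lp_new - (ll + lp_old)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          mu <- mu_p; dbar <- dbar_p
          ll_pts <- ll_new_pts; ll <- sum(ll_pts)
          to_acc <- to_acc + (it <= warmup)
        }
      }
      # diminishing adaptation toward target acceptance during warmup
      if (it <= warmup && it %% 50L == 0L) {
        rate <- win_acc / 50
        scales[par_names] <- pmin(pmax(scales[par_names] * exp(rate - 0.44),
                                       1e-6), 50)
        eps_scale <- min(max(eps_scale * exp(win_eps / 50 - 0.44), 1e-3), 30)
        rc_scale <- min(max(rc_scale * exp(rc_acc / 50 - 0.44), 1e-3), 30)
        to_scale <- min(max(to_scale * exp(to_acc / 50 - 0.44), 1e-3), 30)
        win_acc[] <- 0; win_eps <- 0; rc_acc <- 0; to_acc <- 0
      }
      if (it > warmup) {
        k <- it - warmup
        comp <- mu + max(1, dbar)
        draws[k, ] <- c(mu, dbar, sind, sobs,
                        if (use_s) bs, if (use_t) bt, if (use_x) bx,
                        mu, comp)
        eps_draws[k, ] <- eps
      }
    }
    list(draws = draws, eps = eps_draws,
         acc = c(acc / iter, eps = eps_acc / iter))
  }

  res <- lapply(seq_len(chains), run_chain)
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  eps_draws <- do.call(rbind, lapply(res, `[[`, "eps"))
  acc <- Reduce(`+`, lapply(res, `[[`, "acc")) / chains

  rhat <- vapply(colnames(draws), function(p) {
    split_rhat(lapply(res, function(r) r$draws[, p]))
  }, numeric(1))
  converged <- all(rhat < 1.05, na.rm = TRUE)
  if (!converged)
    warning("split-chain R-hat exceeds 1.05 for: ",
            paste(names(rhat)[which(rhat >= 1.05)], collapse = ", "),
            call. = FALSE)

  summ <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    ci_low = apply(draws, 2, function(x) eti(x)[1]),
    ci_high = apply(draws, 2, function(x) eti(x)[2]),
    rhat = rhat, row.names = NULL)

  ranef <- data.frame(unit = un$unit, hare_id = un$hare_id, year = un$year,
                      eps_mean = colMeans(eps_draws),
                      eps_sd = apply(eps_draws, 2, stats::sd))

  structure(list(draws = draws, eps_draws = eps_draws, summary = summ,
                 ranef = ranef, acceptance = acc, rhat = rhat,
                 converged = converged, covariates = covariates,
                 centers = centers, season = data$season, site = data$site,
                 data = data, seed = seed,
                 mcmc = list(chains = chains, iter = iter, warmup = warmup)),
            class = "phenology_fit")
}

# split-chain potential scale reduction (each chain halved)
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[(n + 1L):(2L * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.phenology_fit <- function(x, ...) {
  cat("Hierarchical change-point moult model:", x$season, "moult at site",
      x$site, "\n")
  cat(sprintf("%d hare-years, %d sightings; %d chains x %d draws%s\n",
              nrow(x$data$units), nrow(x$data$points), x$mcmc$chains,
              x$mcmc$iter,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Posterior completion-date shift for a covariate change
#'
#' Posterior distribution of the change in the population spring/autumn
#' completion date when one covariate moves from `low` to `high` with the
#' others held at their observed means: per draw,
#' `dbar * (exp(beta * (high - m)) - exp(beta * (low - m)))` for snow and
#' degree days (with `m` the covariate mean), or `beta * (high - low)` on
#' the sex code for sex.
#'
#' @param fit A [fit_changepoint()] result containing the covariate.
#' @param covariate One of `"snow"`, `"temp"`, `"sex"`.
#' @param low,high Covariate values to compare.
#' @return List with `mean`, `ci` (95% equal-tailed), and `draws` (days;
#'   positive = later completion at `high`).
#' @export
covariate_shift <- function(fit, covariate = c("snow", "temp", "sex"),
                            low, high) {
  covariate <- match.arg(covariate)
  if (!covariate %in% fit$covariates)
    stop("covariate '", covariate, "' was not in the fitted model",
         call. = FALSE)
  b <- fit$draws[, paste0("beta_", if (covariate == "temp") "temp" else covariate)]
  if (covariate == "sex") {
    d <- b * (high - low)
  } else {
    m <- fit$centers[[covariate]]
    d <- fit$draws[, "dbar"] * (exp(b * (high - m)) - exp(b * (low - m)))
  }
  list(mean = mean(d), ci = eti(d), draws = d)
}

#' Individual reaction norms across years
#'
#' Extracts, for every hare observed in the same moult season in two or more
#' years, the per-year observed trajectory and fitted initiation/completion
#' dates (posterior means), and the between-year spread of both dates. The
#' plotted trajectories of such repeat individuals are the visual assessment
#' of phenotypic plasticity: a hare whose fitted dates barely move between a
#' snowy and a snow-poor year has an essentially fixed moult.
#'
#' @param data The [prepare_moult_data()] object used for fitting.
#' @param fit The corresponding [fit_changepoint()] result.
#' @return Object of class `reaction_norms`: list with `fits` (one row per
#'   qualifying hare-year: fitted `init`, `completion`, `duration`),
#'   `differences` (per hare: max minus min initiation and completion across
#'   years), and `trajectories` (observed date/whiteness points). Hares seen
#'   in a single year are excluded; the collection may be empty.
#' @export
reaction_norms <- function(data, fit) {
  stopifnot(inherits(fit, "phenology_fit"))
  un <- data$units
  keep_ids <- names(which(table(un$hare_id) >= 2L))
  un <- un[un$hare_id %in% keep_ids, , drop = FALSE]
  if (!nrow(un)) {
    return(structure(list(fits = un, differences = un,
                          trajectories = data$points[0, ]),
                     class = "reaction_norms"))
  }
  post <- fit$summary
  g <- function(p) post$mean[post$parameter == p]
  beta <- c(snow = if ("snow" %in% fit$covariates) g("beta_snow") else 0,
            temp = if ("temp" %in% fit$covariates) g("beta_temp") else 0,
            sex = if ("sex" %in% fit$covariates) g("beta_sex") else 0)
  idx <- match(un$unit, data$units$unit)
  eps_hat <- fit$ranef$eps_mean[idx]
  dur <- effective_duration(g("dbar"),
                            un$snow - fit$centers[["snow"]],
                            un$dd - fit$centers[["temp"]],
                            un$sexx - fit$centers[["sexx"]], beta)
  fits <- data.frame(hare_id = un$hare_id, year = un$year, unit = un$unit,
                     n_obs = un$n_obs,
                     init = g("mu_init") + eps_hat,
                     duration = dur)
  fits$completion <- fits$init + fits$duration
  diffs <- do.call(rbind, lapply(split(fits, fits$hare_id), function(f) {
    data.frame(hare_id = f$hare_id[1L], n_years = nrow(f),
               init_diff = max(f$init) - min(f$init),
               completion_diff = max(f$completion) - min(f$completion))
  }))
  rownames(diffs) <- NULL
  traj <- data$points[data$points$unit %in% un$unit, , drop = FALSE]
  structure(list(fits = fits, differences = diffs, trajectories = traj),
            class = "reaction_norms")
}
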