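test_that("the change-point trajectory is a clamped linear ramp", {
  expect_equal(expected_whiteness(10, init = 20, duration = 40, "autumn"), 0)
  expect_equal(expected_whiteness(40, init = 20, duration = 40, "autumn"), 50)
  expect_equal(expected_whiteness(500, init = 20, duration = 40, "spring"), 0)
  expect_equal(expected_whiteness(20, init = 20, duration = 40, "spring"), 100)
  expect_error(expected_whiteness(10, 20, 0, "autumn"), "positive")
  # monotone within season and bounded in [0, 100]
  t <- seq(-30, 150, by = 0.5)
  aut <- expected_whiteness(t, 25, 37, "autumn")
  spr <- expected_whiteness(t, 25, 37, "spring")
  expect_true(all(diff(aut) >= 0))
  expect_true(all(diff(spr) <= 0))
  expect_true(all(aut >= 0 & aut <= 100 & spr >= 0 & spr <= 100))
})

test_that("covariates modify duration through the exponential link with a 1-day floor", {
  expect_equal(effective_duration(40), 40)
  expect_equal(effective_duration(40, snow = 100, dd = 50,
                                  beta = c(snow = 0, temp = 0, sex = 0)), 40)
  # snow slows the spring brown-out: positive beta_snow lengthens duration
  d0 <- effective_duration(41.9, snow = 0, beta = c(snow = 0.002))
  d100 <- effective_duration(41.9, snow = 100, beta = c(snow = 0.002))
  expect_gt(d100, d0)
  # females (code -1) with positive beta_sex finish earlier
  expect_lt(effective_duration(40, sexx = -1, beta = c(sex = 2)),
            effective_duration(40, sexx = 0, beta = c(sex = 2)))
  expect_equal(effective_duration(2, sexx = -1, beta = c(sex = 100)), 1)
  expect_error(effective_duration(-3), "positive")
})

test_that("log-likelihood matches closed forms and is additive", {
  md <- make_moult_data(n_hares = 1, sigma_ind = 0, sigma_obs = 0, seed = 2)
  md$points <- md$points[1, ]
  md$points$whiteness <- expected_whiteness(md$points$t, 30, 40, "autumn")
  md$units$n_obs <- 1L
  pars <- list(mu_init = 30, dbar = 40, sigma_ind = 0, sigma_obs = 10)
  # a single on-trajectory observation: log N(0 | 0, 10^2)
  expect_equal(log_likelihood(pars, md), -log(10 * sqrt(2 * pi)),
               tolerance = 1e-12)
  # duplicating the data doubles the data term
  md5 <- make_moult_data(n_hares = 2, sigma_ind = 0, sigma_obs = 5, seed = 3)
  base <- log_likelihood(pars, md5)
  md10 <- md5
  md10$points <- rbind(md5$points, md5$points)
  expect_equal(log_likelihood(pars, md10), 2 * base, tolerance = 1e-9)
  # degenerate sigma_obs documents -Inf on imperfect fit
  pars0 <- list(mu_init = 31, dbar = 40, sigma_ind = 0, sigma_obs = 0)
  expect_identical(log_likelihood(pars0, md5), -Inf)
})

test_that("log-likelihood equals an independent brute-force summation", {
  md <- make_moult_data(n_hares = 5, sigma_ind = 3, sigma_obs = 6,
                        beta_snow = 0.003, seed = 8)
  md$points <- md$points[seq(1, nrow(md$points), by = 16), ][1:5, ]
  for (pars in list(
    list(mu_init = 28, dbar = 42, sigma_ind = 4, sigma_obs = 7,
         eps = c(1, -2, 0.5, 0, 3),
         beta = c(snow = 0.002, temp = 0, sex = 0)),
    list(mu_init = 35, dbar = 35, sigma_ind = 2, sigma_obs = 12,
         eps = rep(0, 5), beta = c(snow = -0.001, temp = 1e-4, sex = 1)))) {
    expect_equal(log_likelihood(pars, md), brute_loglik(pars, md),
                 tolerance = 1e-9)
  }
})

test_that("seeded sampling is exactly reproducible", {
  md <- make_moult_data(n_hares = 8, seed = 4)
  f1 <- suppressWarnings(fit_changepoint(md, chains = 2, iter = 150,
                                         warmup = 100, seed = 99))
  f2 <- suppressWarnings(fit_changepoint(md, chains = 2, iter = 150,
                                         warmup = 100, seed = 99))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_changepoint(md, chains = 2, iter = 150,
                                         warmup = 100, seed = 100))
  expect_false(identical(f1$draws, f3$draws))
  expect_error(fit_changepoint(md, chains = 2, iter = 10, warmup = 10),
               "seed")
})

test_that("near-noise-free data pins the posterior initiation to the truth", {
  md <- make_moult_data(n_hares = 10, sigma_ind = 0, sigma_obs = 0.5,
                        mu = 33, dbar = 40, seed = 6)
  fit <- suppressWarnings(fit_changepoint(md, chains = 2, iter = 500,
                                          warmup = 500, seed = 1))
  mu_hat <- fit$summary$mean[fit$summary$parameter == "mu_init"]
  expect_lt(abs(mu_hat - 33), 1)
})

test_that("posterior initiation interval narrows as observation noise shrinks", {
  widths <- sapply(c(8, 3, 0.8), function(s_obs) {
    md <- make_moult_data(n_hares = 10, sigma_ind = 0, sigma_obs = s_obs,
                          mu = 33, dbar = 40, seed = 16)
    fit <- suppressWarnings(fit_changepoint(md, chains = 2, iter = 400,
                                            warmup = 400, seed = 2))
    s <- fit$summary
    s$ci_high[s$parameter == "mu_init"] - s$ci_low[s$parameter == "mu_init"]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("covariate shifts transform draws correctly and carry the sign of beta", {
  md <- make_moult_data(n_hares = 16, years = 2011:2012, sigma_ind = 2,
                        sigma_obs = 4, beta_snow = 0.004, seed = 11)
  fit <- suppressWarnings(fit_changepoint(md, covariates = "snow",
                                          chains = 2, iter = 600,
                                          warmup = 500, seed = 3))
  sh <- covariate_shift(fit, "snow", low = 0, high = 100)
  # analytic shift implied by the generating parameters
  ms <- mean(md$units$snow)
  want <- 40 * (exp(0.004 * (100 - ms)) - exp(0.004 * (0 - ms)))
  expect_lt(sh$ci[1], want)
  expect_gt(sh$ci[2], want)
  expect_equal(sign(sh$mean),
               sign(mean(fit$draws[, "beta_snow"])))
  # zeroing the coefficient draws zeroes the shift identically
  fit0 <- fit
  fit0$draws[, "beta_snow"] <- 0
  expect_equal(covariate_shift(fit0, "snow", 0, 100)$draws,
               rep(0, nrow(fit0$draws)))
  expect_error(covariate_shift(fit, "temp", 0, 10), "not in the fitted")
})

test_that("reaction norms include only repeat hares and recover a rate shift", {
  # 12 hares seen in two springs; snowier second springs lengthen the moult
  snow <- c(rep(20, 12), rep(c(20, 90), c(4, 8)))
  md <- make_moult_data(n_hares = 12, years = 2011:2012, mu = 35, dbar = 40,
                        sigma_ind = 2, sigma_obs = 4, beta_snow = 0.004,
                        snow = snow, season = "spring", seed = 13)
  # drop one hare's second year: it must be excluded from the norms
  drop_unit <- "h01:2012"
  md$points <- md$points[md$points$unit != drop_unit, ]
  md$units <- md$units[md$units$unit != drop_unit, ]
  fit <- suppressWarnings(fit_changepoint(md, covariates = "snow",
                                          chains = 2, iter = 600,
                                          warmup = 500, seed = 5))
  rn <- reaction_norms(md, fit)
  expect_false("h01" %in% rn$fits$hare_id)
  expect_true(all(table(rn$fits$hare_id) >= 2))
  # hares whose snow did not change across years: near-zero completion shift
  flat <- rn$differences[rn$differences$hare_id %in%
                           sprintf("h%02d", 2:4), ]
  expect_true(all(flat$completion_diff < 8))
  # hares moving from snow 20 to snow 90: the generating shift
  want <- 40 * (exp(0.004 * (90 - mean(md$units$snow))) -
                  exp(0.004 * (20 - mean(md$units$snow))))
  shifted <- rn$differences[rn$differences$hare_id %in%
                              sprintf("h%02d", 5:12), ]
  expect_equal(mean(shifted$completion_diff), want, tolerance = 0.45)
})
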