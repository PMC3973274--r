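test_that("AICc follows the closed form and its limits", {
  expect_equal(aicc(-5, 2, 10), 15.7142857, tolerance = 1e-7)
  expect_equal(aicc(-7.3, 0, 25), 14.6)
  expect_equal(aicc(-100, 3, 1e9), -2 * -100 + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(-5, 4, 5), "n > k \\+ 1")
  # ranking is invariant to a constant added to every log-likelihood
  lls <- c(-10, -12, -9.5)
  ks <- c(2, 3, 4)
  r1 <- order(mapply(aicc, lls, ks, MoreArgs = list(n = 40)))
  r2 <- order(mapply(aicc, lls + 7.7, ks, MoreArgs = list(n = 40)))
  expect_identical(r1, r2)
})

test_that("candidate enumeration respects correlation screening and the quadratic hierarchy", {
  cors <- matrix(c(1, 0.85, -0.5,
                   0.85, 1, 0.1,
                   -0.5, 0.1, 1), 3, 3,
                 dimnames = list(c("whiteness", "snow1m", "contrast1m"),
                                 c("whiteness", "snow1m", "contrast1m")))
  cand <- build_candidates(c("whiteness", "snow1m", "contrast1m"), cors,
                           quadratic = "contrast1m")
  joint <- vapply(cand$models, function(m)
    all(c("whiteness", "snow1m") %in% m), logical(1))
  expect_false(any(joint))
  # snow + contrast (r = -0.5) allowed together
  expect_true(any(vapply(cand$models, function(m)
    all(c("snow1m", "contrast1m") %in% m), logical(1))))
  # the squared term never appears without its linear parent
  qmods <- Filter(function(m) "I(contrast1m^2)" %in% m, cand$models)
  expect_gt(length(qmods), 0)
  expect_true(all(vapply(qmods, function(m) "contrast1m" %in% m,
                         logical(1))))
  expect_true(any(vapply(cand$models, function(m) !length(m), logical(1))))
  expect_equal(nrow(cand$excluded_pairs), 1)
})

test_that("habituation truncation finds the onset of a decline", {
  # flat response: no truncation, the full range is kept
  d <- sim_concealment(60, 10, seed = 41)
  h <- suppressWarnings(habituation_truncation(d, "concealment",
                                               k_range = 3:10))
  expect_equal(h$k_trunc, 10)
  expect_equal(nrow(h$data), nrow(d))
  # decline from the first attempt: minimum k, with a warning
  d <- sim_concealment(60, 10, seed = 42, onset = 0, slope = 1.5)
  expect_warning(
    h <- habituation_truncation(d, "concealment", k_range = 3:10),
    "minimum")
  expect_equal(h$k_trunc, 3)
  expect_true(h$all_decline)
  # decline beginning after attempt 9
  d <- sim_concealment(60, 12, seed = 43, onset = 9, slope = 2)
  h <- suppressWarnings(habituation_truncation(d, "concealment",
                                               k_range = 3:12))
  expect_equal(h$k_trunc, 9)
  expect_true(all(h$data$attempt_index <= 9))
})

test_that("concealment selection recovers a generated quadratic contrast effect", {
  d <- sim_concealment(80, 9, seed = 44, b_contrast = 0.004,
                       b_contrast2 = -3e-4)
  cors <- screen_correlations(d, "contrast1m")
  cand <- build_candidates("contrast1m", cors, quadratic = "contrast1m")
  fit <- fit_concealment(d, cand, seed = 10, n_draws = 2e4)
  expect_true(any(grepl("\\^2", fit$best_set$terms)))
  curv <- fit$hpd[fit$hpd$term == "I(contrast1m^2)", ]
  expect_lt(curv$estimate, 0)
  expect_lt(curv$hpd_high, 0)
  expect_error(fit_concealment(d, cand), "seed")
})

make_fid_df <- function(fid, fled, x = NULL) {
  d <- data.frame(hare_id = sprintf("h%02d", seq_along(fid)),
                  fid_m = fid, fled = fled)
  if (!is.null(x)) d$x <- x
  d
}

test_that("null Cox partial likelihood equals minus the summed log risk-set sizes", {
  # two subjects fleeing at progress 1 and 2 (fid 19 and 18 m)
  d <- make_fid_df(c(19, 18), c(TRUE, TRUE), x = c(1, 0))
  cand <- build_candidates("x", screen_correlations(d, "x"))
  fit <- suppressWarnings(fit_fid(d, cand))
  null_row <- fit$table[fit$table$terms == "(intercept)", ]
  expect_equal(null_row$loglik, -log(2), tolerance = 1e-12)
  # a larger tie-free fixture: -sum(log(risk set size)) over event times
  fid <- c(18, 15, 12, 9, 7, 5, 3, 3)
  fled <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  d <- make_fid_df(fid, fled, x = rnorm(8))
  fit <- fit_fid(d, build_candidates("x", screen_correlations(d, "x")))
  prog <- ifelse(fled, 20 - fid, 17)
  ev <- sort(prog[fled])
  want <- -sum(vapply(ev, function(s) log(sum(prog >= s)), numeric(1)))
  null_ll <- fit$table$loglik[fit$table$terms == "(intercept)"]
  expect_equal(null_ll, want, tolerance = 1e-9)
  expect_equal(fit$n_events, sum(fled))
  expect_equal(fit$n_censored, sum(!fled))
})

test_that("constant covariates are dropped from Cox candidates with a warning", {
  d <- make_fid_df(c(19, 18, 15, 10, 3, 3), c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                              FALSE))
  d$x <- 5  # constant
  d$y <- c(1, 0, 1, 0, 1, 0)
  cand <- build_candidates(c("x", "y"), screen_correlations(d, c("x", "y")))
  w <- capture_warnings(fit <- fit_fid(d, cand))
  expect_match(w, "constant covariate", all = TRUE)
  expect_gte(length(w), 1L)
  expect_false(any(grepl("^x$", fit$coefficients$term)))
  expect_error(fit_fid(make_fid_df(c(3, 3), c(FALSE, FALSE)),
                       cand), "no flight events")
})

test_that("a generated FID hazard coefficient is recovered within sampling error", {
  set.seed(55)
  n <- 300
  x <- stats::rnorm(n)
  beta <- 0.6
  s <- stats::rexp(n, 0.15 * exp(beta * x))
  fled <- s <= 17
  d <- data.frame(hare_id = sprintf("h%03d", seq_len(n)),
                  fid_m = ifelse(fled, pmin(20, pmax(3, round(20 - s))), 3),
                  fled = fled, x = x)
  fit <- fit_fid(d, build_candidates("x", screen_correlations(d, "x"),
                                     include_null = FALSE))
  co <- fit$coefficients
  expect_lt(abs(co$coef - beta), 2 * co$se)
  expect_gt(co$hazard_ratio, 1)
  # proportional-hazards diagnostics are reported for the fitted term
  expect_true("x" %in% fit$proportionality$term)
})

test_that("choice-set expansion emits 9 rows per informative location", {
  obs <- make_obs_df(3)
  obs$slice_1 <- c(40, 0, 80); obs$slice_2 <- c(60, 0, 100)
  obs$slice_3 <- c(20, 0, 100); obs$slice_4 <- c(0, 0, 100)
  obs$slice_5 <- c(40, 0, 100); obs$slice_6 <- c(100, 0, 100)
  obs$slice_7 <- c(80, 0, 100); obs$slice_8 <- c(20, 0, 100)
  obs$snow1m <- c(40, 0, 100)
  obs$whiteness <- c(60, 5, 95)
  rows <- build_choice_rows(obs)
  # location 2 is all snow-free: uninformative, excluded; location 3 keeps
  # one 80% slice so it is retained
  locs <- unique(rows$location_id)
  expect_length(locs, 2L)
  expect_equal(nrow(rows), 18L)
  expect_equal(sum(rows$used), 2L)
  expect_equal(rows$contrast, rows$whiteness - rows$snow)
  # used spot leads each block of nine
  expect_equal(rows$used[seq(1, 18, by = 9)], c(1L, 1L))
  obs$slice_8[1] <- NA
  expect_error(build_choice_rows(obs), "exactly 8")
})

test_that("resting-spot coefficient matches a brute-force likelihood maximiser", {
  rows <- simulate_resting_choices(10, beta_snow = -0.02, seed = 61)
  fit <- fit_resting_spot(rows, random_effects = FALSE)
  oracle <- brute_logit_slope(rows, "snow")
  est <- fit$coefficients$estimate[fit$coefficients$predictor == "snow"]
  expect_equal(est, unname(oracle["slope"]), tolerance = 1e-3)
})

test_that("the reported probability ratio is internally consistent with the curve", {
  rows <- simulate_resting_choices(120, beta_snow = -0.016, seed = 62)
  fit <- fit_resting_spot(rows, random_effects = FALSE)
  p0 <- fit$curve$prob[fit$curve$snow == 0]
  p100 <- fit$curve$prob[fit$curve$snow == 100]
  expect_equal(fit$prob_ratio, p0 / p100, tolerance = 1e-9)
  expect_true(all(fit$curve$prob > 0 & fit$curve$prob < 1))
  expect_true(all(fit$curve$lower <= fit$curve$prob &
                    fit$curve$prob <= fit$curve$upper))
})

test_that("the conditional-logit cross-check agrees with the choice preference", {
  rows <- simulate_resting_choices(300, beta_snow = -0.016, seed = 63)
  cl <- fit_resting_clogit(rows, "snow")
  co <- summary(cl)$coefficients
  expect_lt(abs(co[1, "coef"] - (-0.016)), 2 * co[1, "se(coef)"])
})
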