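#' Expand sightings into used-available resting-spot rows
#'
#' Each sighting with the pie-slice protocol becomes nine rows: one for the
#' used resting spot (the 1-m radius, coded 1) and eight for the available
#' pie slices (coded 0), each carrying its snow cover and the colour
#' contrast the hare would have there. Locations where the resting spot and
#' all eight slices are entirely snow-covered or entirely snow-free are
#' excluded — they carry no information about choice.
#'
#' @param obs Validated observation table.
#' @return Data frame `hare_id, date, location_id, used, snow, contrast,
#'   whiteness` with `9 * retained locations` rows.
#' @export
build_choice_rows <- function(obs) {
  has <- !is.na(obs$slice_1)
  d <- obs[has, , drop = FALSE]
  if (!nrow(d)) {
    return(data.frame(hare_id = character(), date = as.Date(character()),
                      location_id = character(), used = integer(),
                      snow = numeric(), contrast = numeric(),
                      whiteness = numeric()))
  }
  slices <- as.matrix(d[paste0("slice_", 1:8)])
  if (anyNA(slices))
    stop("each location must have exactly 8 pie slices", call. = FALSE)
  all9 <- cbind(d$snow1m, slices)
  uninformative <- apply(all9, 1L, function(s) all(s == 0) || all(s == 100))
  d <- d[!uninformative, , drop = FALSE]
  slices <- slices[!uninformative, , drop = FALSE]
  if (!nrow(d)) {
    return(data.frame(hare_id = character(), date = as.Date(character()),
                      location_id = character(), used = integer(),
                      snow = numeric(), contrast = numeric(),
                      whiteness = numeric()))
  }
  n <- nrow(d)
  loc <- paste(d$hare_id, format(d$date, "%Y-%m-%d"), sep = "@")
  out <- data.frame(
    hare_id = rep(d$hare_id, each = 9L),
    date = rep(d$date, each = 9L),
    location_id = rep(loc, each = 9L),
    used = rep(c(1L, rep(0L, 8L)), n),
    snow = as.numeric(t(cbind(d$snow1m, slices))),
    whiteness = rep(d$whiteness, each = 9L))
  out$contrast <- out$whiteness - out$snow
  out
}

# Firth-penalised logistic regression (Jeffreys prior); used as the
# fallback when a plain fit separates completely
firth_logit <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * w
    info <- crossprod(X, XW)
    h <- rowSums((X %*% solve(info)) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(info, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       vcov = solve(info))
}

#' Used-available resting-spot choice model
#'
#' Binomial (logit link) mixed model of spot use: separate univariate fits
#' for snow cover and colour contrast, compared by AICc against the null,
#' with random intercepts for hare and for location nested within hare (the
#' nine spots of one sighting form one choice set). Reports the
#' presence-probability curve over snow 0-100% with a 95% Wald band and the
#' probability ratio between a snow-free and a fully snow-covered spot.
#' With `random_effects = FALSE` plain logistic fits are used (the exact
#' likelihood, convenient for oracle checks); complete separation there is
#' flagged and refitted with a Firth penalty.
#'
#' @param rows A [build_choice_rows()] table with at least two locations.
#' @param random_effects Include the nested random effects (default TRUE).
#' @return Object of class `resting_fit`: `coefficients` (per predictor:
#'   estimate, se, z, p, AICc, dAICc vs null), `curve` (snow, prob, lower,
#'   upper), `prob_ratio` (presence at snow 0 vs snow 100), `separation`
#'   flag, and the fitted `models`.
#' @export
fit_resting_spot <- function(rows, random_effects = TRUE) {
  if (length(unique(rows$location_id)) < 2L)
    stop("need at least 2 retained locations", call. = FALSE)
  preds <- c("snow", "contrast")
  separation <- FALSE
  fit_one <- function(pred) {
    if (random_effects) {
      f <- stats::as.formula(paste(
        "used ~", if (is.null(pred)) "1" else pred,
        "+ (1 | hare_id) + (1 | hare_id:location_id)"))
      suppressWarnings(suppressMessages(
        lme4::glmer(f, data = rows, family = stats::binomial)))
    } else {
      f <- stats::as.formula(paste("used ~",
                                   if (is.null(pred)) "1" else pred))
      suppressWarnings(stats::glm(f, data = rows,
                                  family = stats::binomial))
    }
  }
  info <- function(fit) {
    ll <- stats::logLik(fit)
    co <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
    list(ll = as.numeric(ll), k = attr(ll, "df"), coef = co,
         vcov = as.matrix(stats::vcov(fit)))
  }
  null_fit <- fit_one(NULL)
  fits <- lapply(preds, fit_one)
  names(fits) <- preds
  n <- nrow(rows)
  i0 <- info(null_fit)
  aicc_null <- aicc(i0$ll, i0$k, n)
  coefs <- do.call(rbind, lapply(preds, function(p) {
    fi <- info(fits[[p]])
    est <- fi$coef[[p]]
    se <- sqrt(fi$vcov[p, p])
    if (!random_effects && (abs(est) > 10 || se > 50)) {
      separation <<- TRUE
      X <- cbind(1, rows[[p]])
      colnames(X) <- c("(Intercept)", p)
      ff <- firth_logit(X, rows$used)
      est <- ff$coefficients[[p]]
      se <- sqrt(ff$vcov[2, 2])
    }
    data.frame(predictor = p, estimate = est, se = se, z = est / se,
               p_value = 2 * stats::pnorm(-abs(est / se)),
               AICc = aicc(fi$ll, fi$k, n),
               dAICc_vs_null = aicc(fi$ll, fi$k, n) - aicc_null)
  }))
  if (separation)
    warning("complete separation detected; Firth-penalised estimates used",
            call. = FALSE)
  # presence-probability curve over snow with a Wald band on the link scale
  fs <- info(fits[["snow"]])
  b <- fs$coef[c("(Intercept)", "snow")]
  V <- fs$vcov[c("(Intercept)", "snow"), c("(Intercept)", "snow")]
  sgrid <- seq(0, 100, by = 1)
  eta <- b[1] + b[2] * sgrid
  se_eta <- sqrt(V[1, 1] + sgrid^2 * V[2, 2] + 2 * sgrid * V[1, 2])
  curve <- data.frame(snow = sgrid,
                      prob = stats::plogis(eta),
                      lower = stats::plogis(eta - 1.96 * se_eta),
                      upper = stats::plogis(eta + 1.96 * se_eta))
  prob_ratio <- stats::plogis(b[1]) / stats::plogis(b[1] + 100 * b[2])
  structure(list(coefficients = coefs, curve = curve,
                 prob_ratio = unname(prob_ratio),
                 aicc_null = aicc_null, separation = separation,
                 random_effects = random_effects,
                 models = c(fits, list(null = null_fit))),
            class = "resting_fit")
}

#' Conditional-logit cross-check of resting-spot choice
#'
#' The 1-used-versus-8-available structure makes each location a natural
#' choice stratum; conditional logistic regression (one stratum per
#' location) estimates the same snow preference without random effects and
#' serves as an independent check on [fit_resting_spot()].
#'
#' @param rows A [build_choice_rows()] table.
#' @param predictor `"snow"` or `"contrast"`.
#' @return A `survival::clogit` fit.
#' @export
fit_resting_clogit <- function(rows, predictor = c("snow", "contrast")) {
  predictor <- match.arg(predictor)
  rows$.one <- 1
  f <- stats::as.formula(paste("survival::Surv(.one, used) ~", predictor,
                               "+ survival::strata(location_id)"))
  survival::coxph(f, data = rows, ties = "exact")
}
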