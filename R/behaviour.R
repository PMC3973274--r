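#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`; requires `n > k + 1`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Pairwise correlations among candidate covariates
#'
#' Pearson correlations over complete pairs for numeric covariates;
#' categorical covariates are not screened (correlation 0).
#'
#' @param data Data frame.
#' @param terms Covariate names.
#' @return Symmetric correlation matrix over `terms`.
#' @export
screen_correlations <- function(data, terms) {
  m <- diag(length(terms))
  dimnames(m) <- list(terms, terms)
  num <- terms[vapply(terms, function(t) is.numeric(data[[t]]), logical(1))]
  if (length(num) > 1) {
    # constant covariates have no defined correlation; they are screened as 0
    cc <- suppressWarnings(stats::cor(data[num],
                                      use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    m[num, num] <- cc
  }
  m
}

#' Enumerate admissible candidate models
#'
#' Builds all fixed-effect term combinations of the supplied covariates,
#' excluding any model that contains both members of a highly correlated
#' pair (|r| at or above the threshold — whiteness and snow cover around
#' hares are typically so correlated for most of the year that they are
#' considered separately). Optionally adds quadratic variants for one
#' continuous term (e.g. colour contrast, to allow a curvilinear response);
#' the quadratic appears only alongside its linear term. The intercept-only
#' null model is always included.
#'
#' @param terms Character vector of candidate covariate names.
#' @param correlations Correlation matrix over `terms` (see
#'   [screen_correlations()]).
#' @param r_threshold Exclusion threshold on |r|, default 0.8.
#' @param quadratic Name of a term to also try with a squared component, or
#'   `NULL`.
#' @param include_null Include the intercept-only model (default TRUE; turn
#'   off to force a fixed model set, e.g. for calibration runs).
#' @return Object of class `candidate_set`: `models` (list of character
#'   term vectors; `character(0)` is the null model) and `excluded_pairs`.
#' @export
build_candidates <- function(terms, correlations, r_threshold = 0.8,
                             quadratic = NULL, include_null = TRUE) {
  stopifnot(all(terms %in% rownames(correlations)))
  pairs <- which(abs(correlations) >= r_threshold &
                   upper.tri(correlations), arr.ind = TRUE)
  excluded <- data.frame(
    term1 = rownames(correlations)[pairs[, 1]],
    term2 = colnames(correlations)[pairs[, 2]],
    r = correlations[pairs])
  excluded <- excluded[excluded$term1 %in% terms &
                         excluded$term2 %in% terms, , drop = FALSE]
  n <- length(terms)
  if (n > 14) stop("too many candidate terms to enumerate", call. = FALSE)
  models <- list(character(0))
  for (i in seq_len(2^n - 1)) {
    sel <- terms[bitwAnd(i, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    ok <- TRUE
    if (nrow(excluded)) {
      for (j in seq_len(nrow(excluded))) {
        if (excluded$term1[j] %in% sel && excluded$term2[j] %in% sel) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) models[[length(models) + 1L]] <- sel
  }
  if (!is.null(quadratic)) {
    qv <- paste0("I(", quadratic, "^2)")
    extra <- Filter(function(m) quadratic %in% m, models)
    models <- c(models, lapply(extra, function(m) c(m, qv)))
  }
  if (!include_null)
    models <- Filter(length, models)
  if (!length(models))
    stop("no admissible candidate models", call. = FALSE)
  structure(list(models = models, excluded_pairs = excluded,
                 r_threshold = r_threshold, quadratic = quadratic),
            class = "candidate_set")
}

model_label <- function(terms)
  if (length(terms)) paste(terms, collapse = " + ") else "(intercept)"

#' Detect and truncate habituation to human observers
#'
#' Repeatedly locating the same animal can habituate it: concealment or
#' flight distance may decline with the cumulative number of location
#' attempts. For each truncation point `k`, the response is regressed on
#' `attempt_index` (per-hare random intercept) using only observations with
#' `attempt_index <= k`; the truncation index is the largest `k` whose slope
#' 95% (Wald) interval includes zero — the largest dataset free of a
#' detectable habituation trend. If every `k` shows a significant decline,
#' the minimum `k` is returned with a warning.
#'
#' @param data Observation table (with contrast columns if needed later).
#' @param response `"concealment"` or `"fid"` (flight trials only; censored
#'   trials enter at the 3 m floor).
#' @param k_range Candidate truncation points (default 3 up to the maximum
#'   attempt index).
#' @param conf Confidence level of the slope interval.
#' @return Object of class `habituation`: `k_trunc`, `table` (per-k slope,
#'   SE, interval), `data` (the truncated observation table), `response`,
#'   `all_decline` flag.
#' @export
habituation_truncation <- function(data, response = c("concealment", "fid"),
                                   k_range = NULL, conf = 0.95) {
  response <- match.arg(response)
  d <- data
  if (response == "fid") d <- d[!is.na(d$fid_m), , drop = FALSE]
  d$.resp <- if (response == "fid") d$fid_m else d$concealment
  d <- d[!is.na(d$.resp), , drop = FALSE]
  if (is.null(k_range)) k_range <- 3:max(d$attempt_index)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(k_range, function(k) {
    dk <- d[d$attempt_index <= k, , drop = FALSE]
    if (length(unique(dk$hare_id)) < 3L || nrow(dk) < 10L)
      return(data.frame(k = k, slope = NA, se = NA, lower = NA, upper = NA))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(.resp ~ attempt_index + (1 | hare_id), data = dk,
                   REML = FALSE))),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(k = k, slope = NA, se = NA, lower = NA, upper = NA))
    co <- summary(fit)$coefficients
    est <- co["attempt_index", "Estimate"]
    se <- co["attempt_index", "Std. Error"]
    data.frame(k = k, slope = est, se = se,
               lower = est - z * se, upper = est + z * se)
  })
  tab <- do.call(rbind, rows)
  nonsig <- tab$k[!is.na(tab$lower) & tab$lower <= 0 & tab$upper >= 0]
  all_decline <- !length(nonsig)
  k_trunc <- if (all_decline) min(k_range) else max(nonsig)
  if (all_decline)
    warning("response declines significantly at every truncation point; ",
            "truncating at the minimum k = ", k_trunc, call. = FALSE)
  structure(list(k_trunc = k_trunc, table = tab,
                 data = data[data$attempt_index <= k_trunc, , drop = FALSE],
                 response = response, all_decline = all_decline),
            class = "habituation")
}

fit_one_lmm <- function(terms, data) {
  f <- stats::as.formula(paste(
    "concealment ~", if (length(terms)) paste(terms, collapse = " + ") else "1",
    "+ (1 | hare_id)"))
  suppressWarnings(suppressMessages(
    lme4::lmer(f, data = data, REML = FALSE)))
}

#' Concealment linear mixed models with AICc selection
#'
#' Fits every candidate model of concealment (continuous 1-4 response,
#' per-hare random intercept, maximum likelihood), ranks by AICc, and keeps
#' the best set (within 2 AICc of the top model). For the best model, the
#' precision of fixed effects is summarised by sampling their posterior
#' under a normal approximation at the ML mode (the sampling method is
#' recorded in the result) and reporting 95% highest-posterior-density
#' intervals. Singular random-effect fits are flagged and retained.
#'
#' @param data Truncated observation table (see
#'   [habituation_truncation()]) with contrast/mismatch columns (see
#'   [contrast_metrics()]).
#' @param candidates A [build_candidates()] set.
#' @param seed Integer seed for the posterior sampling.
#' @param n_draws Posterior draws, default 100000.
#' @param hpd_prob HPD coverage, default 0.95.
#' @return Object of class `concealment_fit`: `table` (model_id, terms, k,
#'   loglik, AICc, dAICc, singular), `best_set`, `best_model` (merMod),
#'   `posterior` (draw matrix), `hpd` (per-coefficient intervals),
#'   `method`.
#' @export
fit_concealment <- function(data, candidates, seed, n_draws = 1e5,
                            hpd_prob = 0.95) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  fits <- lapply(candidates$models, fit_one_lmm, data = data)
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    ll <- stats::logLik(fits[[i]])
    data.frame(model_id = i,
               terms = model_label(candidates$models[[i]]),
               k = attr(ll, "df"), loglik = as.numeric(ll),
               AICc = aicc(as.numeric(ll), attr(ll, "df"),
                           stats::nobs(fits[[i]])),
               singular = lme4::isSingular(fits[[i]]))
  }))
  tab$dAICc <- tab$AICc - min(tab$AICc)
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  fits <- fits[ord]
  if (any(tab$singular))
    warning("singular random-effect fit(s) retained: model(s) ",
            paste(tab$model_id[tab$singular], collapse = ", "),
            call. = FALSE)
  best <- fits[[1L]]
  set.seed(stream_seed(seed, "concealment-posterior"))
  fe <- lme4::fixef(best)
  vc <- as.matrix(stats::vcov(best))
  post <- MASS::mvrnorm(n_draws, fe, vc)
  if (is.null(dim(post))) post <- matrix(post, ncol = 1,
                                         dimnames = list(NULL, names(fe)))
  hpd <- do.call(rbind, lapply(colnames(post), function(p) {
    h <- hpd_interval(post[, p], hpd_prob)
    data.frame(term = p, estimate = fe[[p]],
               sd = stats::sd(post[, p]),
               hpd_low = h[["lower"]], hpd_high = h[["upper"]],
               includes_zero = h[["lower"]] <= 0 && h[["upper"]] >= 0)
  }))
  structure(list(table = tab, best_set = tab[tab$dAICc <= 2, ],
                 best_model = best, posterior = post, hpd = hpd,
                 method = "normal approximation at the ML mode",
                 seed = seed),
            class = "concealment_fit")
}

#' Flight initiation distance as distance-censored time-to-event data
#'
#' Flight is the event of interest on the approach-progress scale (metres
#' advanced from the 20 m ranging limit, so progress = 20 - FID); hares
#' that did not flush at the 3 m minimum approach are right-censored at
#' progress 17. Each candidate Cox proportional-hazards model is fitted by
#' partial likelihood with the Efron tie correction (distances are rounded
#' to the metre, so ties are common), ranked by AICc (sample size = number
#' of flights), and the proportional-hazards assumption of the best model is
#' checked per term with scaled Schoenfeld residuals (score test).
#' Covariates constant in the data are dropped from a model with a warning.
#'
#' @param data Truncated observation table with contrast/mismatch columns;
#'   only rows with a flight trial are used.
#' @param candidates A [build_candidates()] set.
#' @return Object of class `fid_fit`: `table`, `best_set`, `best_model`
#'   (coxph), `coefficients` (term, coef, se, hazard_ratio, p),
#'   `proportionality` (cox.zph table), `n_events`, `n_censored`.
#' @export
fit_fid <- function(data, candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  d <- data[!is.na(data$fid_m), , drop = FALSE]
  d$progress <- ifelse(d$fled, 20 - d$fid_m, 17)
  d$event <- as.integer(d$fled)
  if (!sum(d$event)) stop("no flight events to analyse", call. = FALSE)
  # coxph requires strictly positive times; shifting the origin preserves
  # the risk-set order and therefore the partial likelihood
  d$progress <- d$progress + 1
  n_ev <- sum(d$event)
  fit_one <- function(terms) {
    keep <- terms[vapply(terms, function(t) {
      v <- d[[sub("^I\\((.*)\\^2\\)$", "\\1", t)]]
      length(unique(v[!is.na(v)])) > 1L
    }, logical(1))]
    if (length(keep) < length(terms))
      warning("dropping constant covariate(s): ",
              paste(setdiff(terms, keep), collapse = ", "), call. = FALSE)
    f <- stats::as.formula(paste(
      "survival::Surv(progress, event) ~",
      if (length(keep)) paste(keep, collapse = " + ") else "1"))
    survival::coxph(f, data = d, ties = "efron")
  }
  fits <- lapply(candidates$models, fit_one)
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    k <- sum(!is.na(stats::coef(fits[[i]])))
    ll <- fits[[i]]$loglik[length(fits[[i]]$loglik)]
    # a model too rich for the event count cannot be ranked
    data.frame(model_id = i, terms = model_label(candidates$models[[i]]),
               k = k, loglik = ll,
               AICc = if (n_ev > k + 1) aicc(ll, k, n_ev) else Inf)
  }))
  tab$dAICc <- tab$AICc - min(tab$AICc)
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  fits <- fits[ord]
  best <- fits[[1L]]
  coefs <- if (length(stats::coef(best))) {
    s <- summary(best)$coefficients
    data.frame(term = rownames(s), coef = s[, "coef"],
               se = s[, "se(coef)"], hazard_ratio = s[, "exp(coef)"],
               p = s[, "Pr(>|z|)"], row.names = NULL)
  } else data.frame(term = character(), coef = numeric(), se = numeric(),
                    hazard_ratio = numeric(), p = numeric())
  zph <- if (length(stats::coef(best))) {
    z <- survival::cox.zph(best)
    data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
               df = z$table[, "df"], p = z$table[, "p"], row.names = NULL)
  } else NULL
  structure(list(table = tab, best_set = tab[tab$dAICc <= 2, ],
                 best_model = best, coefficients = coefs,
                 proportionality = zph, n_events = n_ev,
                 n_censored = nrow(d) - n_ev),
            class = "fid_fit")
}
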