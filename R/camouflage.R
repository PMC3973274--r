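#' Colour contrast between coat and background
#'
#' Signed difference between the hare's per-cent whiteness and the per-cent
#' snow cover of its background. A positive contrast is a white hare on a
#' non-snowy background; a negative contrast is a brown hare on snow.
#'
#' @param whiteness Per-cent coat whiteness in [0, 100].
#' @param snow Per-cent background snow cover in [0, 100].
#' @return Signed contrast in [-100, 100].
#' @export
colour_contrast <- function(whiteness, snow) {
  if (any(whiteness < 0 | whiteness > 100, na.rm = TRUE) ||
      any(snow < 0 | snow > 100, na.rm = TRUE))
    stop("whiteness and snow must be percentages in [0, 100]", call. = FALSE)
  whiteness - snow
}

#' Classify camouflage mismatch from colour contrast
#'
#' A hare is mismatched when |contrast| reaches the threshold (default 60%,
#' the level at which hares clearly stand out against their background):
#' `positive` for contrast >= threshold (white hare on brown ground),
#' `negative` for contrast <= -threshold (brown hare on snow), `none`
#' otherwise. Both thresholds are inclusive.
#'
#' @param contrast Signed contrast in [-100, 100].
#' @param threshold Mismatch threshold in (0, 100], default 60.
#' @return Character vector in `{"positive", "negative", "none"}` (`NA` in,
#'   `NA` out).
#' @export
classify_mismatch <- function(contrast, threshold = 60) {
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100]", call. = FALSE)
  if (any(abs(contrast) > 100, na.rm = TRUE))
    stop("contrast must be in [-100, 100]", call. = FALSE)
  out <- ifelse(contrast >= threshold, "positive",
                ifelse(contrast <= -threshold, "negative", "none"))
  out
}

#' Add contrast and mismatch columns to an observation table
#'
#' Computes signed contrast at the 1 m and 10 m radii, absolute contrast at
#' 1 m, and mismatch classes at both radii plus the binary absolute-mismatch
#' indicator used when positive and negative mismatch are assumed
#' equivalent.
#'
#' @param obs Validated observation data frame.
#' @param threshold Mismatch threshold, default 60.
#' @return `obs` with columns `contrast1m`, `contrast10m`, `abs_contrast1m`,
#'   `abs_contrast10m`, `mismatch1m`, `mismatch10m` (factors with reference
#'   level `"none"`), `abs_mismatch1m`, `abs_mismatch10m` appended.
#' @export
contrast_metrics <- function(obs, threshold = 60) {
  obs$contrast1m <- colour_contrast(obs$whiteness, obs$snow1m)
  obs$contrast10m <- colour_contrast(obs$whiteness, obs$snow10m)
  obs$abs_contrast1m <- abs(obs$contrast1m)
  obs$abs_contrast10m <- abs(obs$contrast10m)
  # factors with the matched class as reference, so model coefficients read
  # as the effect of becoming mismatched
  lv <- c("none", "negative", "positive")
  obs$mismatch1m <- factor(classify_mismatch(obs$contrast1m, threshold), lv)
  obs$mismatch10m <- factor(classify_mismatch(obs$contrast10m, threshold), lv)
  obs$abs_mismatch1m <- factor(
    ifelse(obs$mismatch1m == "none", "none", "mismatch"),
    c("none", "mismatch"))
  obs$abs_mismatch10m <- factor(
    ifelse(obs$mismatch10m == "none", "none", "mismatch"),
    c("none", "mismatch"))
  obs
}

#' Seasonal degree-day accumulation
#'
#' Degree days measure the seasonal cooling trend in autumn and warming
#' trend in spring: for each day the cumulative sum of daily mean
#' temperature below 0 degrees C in the autumn window (September-December)
#' or above 0 degrees C in the spring window (March-June). Autumn degree
#' days accumulate the magnitude of sub-zero temperatures so both seasons
#' are non-negative and comparable. Accumulation restarts in each site-year
#' window and requires a gap-free daily series within the window; gaps are
#' an error, never imputed.
#'
#' @param temps Temperature data frame (`site, date, tmean_c`).
#' @param season `"autumn"` or `"spring"`.
#' @return Data frame `site, season, date, tmean_c, dd` with `dd`
#'   non-decreasing within each site-year window.
#' @export
degree_days <- function(temps, season) {
  months <- season_window_months(season)
  temps$date <- as.Date(temps$date)
  keep <- as.integer(format(temps$date, "%m")) %in% months
  temps <- temps[keep, , drop = FALSE]
  if (!nrow(temps))
    stop("no temperature records fall in the ", season, " window",
         call. = FALSE)
  temps$year <- as.integer(format(temps$date, "%Y"))
  pieces <- split(temps, list(temps$site, temps$year), drop = TRUE)
  out <- lapply(pieces, function(p) {
    p <- p[order(p$date), ]
    if (any(is.na(p$tmean_c)))
      stop("missing daily temperature inside a ", season,
           " window (site ", p$site[1L], ")", call. = FALSE)
    if (nrow(p) > 1L && any(diff(p$date) != 1L))
      stop("gap in daily temperatures inside a ", season,
           " window (site ", p$site[1L], ")", call. = FALSE)
    daily <- if (season == "autumn") {
      ifelse(p$tmean_c < 0, -p$tmean_c, 0)
    } else {
      ifelse(p$tmean_c > 0, p$tmean_c, 0)
    }
    data.frame(site = p$site, season = season, date = p$date,
               tmean_c = p$tmean_c, dd = cumsum(daily))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$site, res$date), , drop = FALSE]
}

#' Weekly averages of an observed quantity
#'
#' Bins observations into ISO weeks (separately per site and ISO week-based
#' year) and reports the mean of the available values; weeks with no
#' observations are simply absent from the output.
#'
#' @param obs Observation data frame with a `date` and `site` column.
#' @param field Name of the numeric column to average (e.g. `"whiteness"`,
#'   `"snow10m"`).
#' @return Data frame `site, year, week, mean, n` sorted by site, year,
#'   week.
#' @export
weekly_average <- function(obs, field) {
  if (!nrow(obs)) stop("no observations to average", call. = FALSE)
  if (!field %in% names(obs))
    stop("unknown field: ", field, call. = FALSE)
  d <- as.Date(obs$date)
  key <- data.frame(site = obs$site,
                    year = as.integer(format(d, "%G")),
                    week = as.integer(format(d, "%V")),
                    value = obs[[field]])
  key <- key[!is.na(key$value), , drop = FALSE]
  agg <- stats::aggregate(value ~ site + year + week, data = key,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ site + year + week, data = key,
                          FUN = length)
  agg$n <- cnt$value
  names(agg)[names(agg) == "value"] <- "mean"
  agg[order(agg$site, agg$year, agg$week), c("site", "year", "week", "mean", "n")]
}
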