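#' Site configuration: season calendar and location
#'
#' A site configuration carries the month-to-season calendar used to assign
#' seasons to sightings, plus latitude and elevation. Season calendars are
#' site-specific because local climate shifts the effective seasons: at a
#' high-elevation site winter runs longer and spring starts later than at a
#' low-elevation site a few hundred kilometres away.
#'
#' @param site Site identifier (character scalar).
#' @param season_map Character vector of length 12 (January..December), each
#'   element one of `"winter"`, `"spring"`, `"summer"`, `"autumn"`.
#' @param latitude Degrees north.
#' @param elevation Metres above sea level.
#' @return An object of class `site_config`.
#' @export
site_config <- function(site, season_map, latitude = NA_real_,
                        elevation = NA_real_) {
  stopifnot(is.character(site), length(site) == 1L)
  if (length(season_map) != 12L)
    stop("season_map must assign a season to all 12 months", call. = FALSE)
  bad <- setdiff(unique(season_map),
                 c("winter", "spring", "summer", "autumn"))
  if (length(bad))
    stop("unknown season label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(site = site, season_map = unname(season_map),
                 latitude = latitude, elevation = elevation),
            class = "site_config")
}

#' Default study-site configurations
#'
#' Two Montana study sites with offset climates. Seeley Lake (1300-1450 m):
#' winter December-March, spring April-May, summer June-August, autumn
#' September-November. Gardiner (2400-2700 m, snowpack late October to May):
#' winter November-April, spring May-June, summer July-August, autumn
#' September-October.
#'
#' @return Named list of two `site_config` objects, `seeley` and `gardiner`.
#' @export
default_site_configs <- function() {
  seeley <- site_config(
    "seeley",
    c("winter", "winter", "winter", "spring", "spring", "summer",
      "summer", "summer", "autumn", "autumn", "autumn", "winter"),
    latitude = 47.23, elevation = 1375)
  gardiner <- site_config(
    "gardiner",
    c("winter", "winter", "winter", "winter", "spring", "spring",
      "summer", "summer", "autumn", "autumn", "winter", "winter"),
    latitude = 45.08, elevation = 2550)
  list(seeley = seeley, gardiner = gardiner)
}

#' Assign the site-specific season of a date
#'
#' @param date A `Date` vector (or string coercible to `Date`).
#' @param config A [site_config()].
#' @return Character vector of season labels.
#' @export
assign_season <- function(date, config) {
  if (!inherits(config, "site_config"))
    stop("config must be a site_config", call. = FALSE)
  date <- as.Date(date)
  config$season_map[as.integer(format(date, "%m"))]
}

# calendar windows (month spans) used for moult analysis and degree days;
# autumn: September-December, spring: March-June
season_window_months <- function(season) {
  switch(season,
         autumn = 9:12,
         spring = 3:6,
         stop("season must be 'autumn' or 'spring'", call. = FALSE))
}

# first calendar day of the season window in a given year
season_window_start <- function(season, year) {
  m <- season_window_months(season)[1L]
  as.Date(sprintf("%d-%02d-01", year, m))
}

season_window_end <- function(season, year) {
  m <- season_window_months(season)
  last <- m[length(m)]
  # last day of the last month of the window
  as.Date(sprintf("%d-%02d-01", year + (last == 12L), (last %% 12L) + 1L)) - 1L
}

# day-of-season: integer days since the window start (0-based)
day_of_season <- function(date, season, year) {
  as.integer(as.Date(date) - season_window_start(season, year))
}
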