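#' @importFrom utils read.csv write.csv head
NULL

obs_columns <- function() {
  c("hare_id", "site", "date", "sex", "whiteness", "snow1m", "snow10m",
    "concealment", "fid_m", "fled", "attempt_index",
    paste0("slice_", 1:8))
}

#' Validate a table of hare sightings
#'
#' Checks every row against the scoring conventions of the field protocol:
#' whiteness on the {0, 5, 20, ..., 95, 100} grid, snow cover in 20%
#' increments, concealment an ordinal level 1-4, flight initiation distance
#' (when a flight trial occurred) between the 3 m minimum approach and the
#' 20 m ranging limit, `fled = FALSE` meaning the hare did not flush and the
#' trial is censored at 3 m, and `attempt_index` strictly increasing over
#' dates within each hare. Behavioural fields that were not measured are
#' `NA`, never zero: zero is a legal data value.
#'
#' @param obs A data frame with the observation columns (see
#'   [read_observations()]).
#' @param grid_scores Require whiteness and snow on their visual grids
#'   (default TRUE; noise-free diagnostic simulations carry exact latent
#'   percentages instead).
#' @return Invisibly, `obs` with `date` as `Date` and `fled` logical.
#'   Invalid rows raise an error naming the offending rows.
#' @export
validate_observations <- function(obs, grid_scores = TRUE) {
  missing_cols <- setdiff(obs_columns(), names(obs))
  if (length(missing_cols))
    stop("observation table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  obs$date <- as.Date(obs$date)
  obs$fled <- as.logical(obs$fled)
  fail <- function(rows, what) {
    if (any(rows))
      stop("invalid observation row(s) ", paste(which(rows), collapse = ", "),
           ": ", what, call. = FALSE)
  }
  fail(is.na(obs$date), "unparseable date")
  fail(!obs$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  if (grid_scores) {
    fail(!obs$whiteness %in% whiteness_grid(),
         "whiteness must lie on the {0,5,20,40,60,80,95,100} grid")
    for (sc in c("snow1m", "snow10m"))
      fail(!obs[[sc]] %in% snow_grid(),
           paste(sc, "must lie on the 20% grid in [0,100]"))
  } else {
    fail(obs$whiteness < 0 | obs$whiteness > 100,
         "whiteness must be a percentage in [0,100]")
  }
  fail(!is.na(obs$concealment) & !obs$concealment %in% 1:4,
       "concealment must be an ordinal level 1-4")
  has_fid <- !is.na(obs$fid_m)
  fail(has_fid & (obs$fid_m < 3 | obs$fid_m > 20),
       "fid_m must be within [3, 20] metres")
  fail(has_fid & is.na(obs$fled), "fid_m present without a fled flag")
  fail(!has_fid & !is.na(obs$fled) & obs$fled,
       "fled = TRUE requires a recorded distance")
  slices <- as.matrix(obs[paste0("slice_", 1:8)])
  n_slice <- rowSums(!is.na(slices))
  fail(!n_slice %in% c(0L, 8L), "pie slices must be all absent or all 8 present")
  fail(apply(slices, 1L, function(s) any(!is.na(s) & !s %in% snow_grid())),
       "pie-slice snow must lie on the 20% grid")
  fail(is.na(obs$attempt_index) | obs$attempt_index < 1 |
         obs$attempt_index != round(obs$attempt_index),
       "attempt_index must be a positive integer")
  # strictly increasing attempts per hare when rows are date-ordered
  for (id in unique(obs$hare_id)) {
    sub <- obs[obs$hare_id == id, ]
    sub <- sub[order(sub$date), ]
    if (is.unsorted(sub$attempt_index, strictly = TRUE))
      stop("attempt_index not strictly increasing over dates for hare ", id,
           call. = FALSE)
  }
  invisible(obs)
}

#' Read and write hare observation tables
#'
#' Observation tables are comma-delimited UTF-8 text with a header row and
#' one row per sighting; columns are `hare_id, site, date, sex, whiteness,
#' snow1m, snow10m, concealment, fid_m, fled, attempt_index,
#' slice_1..slice_8`. Dates are ISO-8601 (`YYYY-MM-DD`). Absent behavioural
#' measurements are empty fields. `read_observations()` validates every row
#' and rejects files with off-grid or out-of-range values, naming the rows.
#' The pair round-trips losslessly: `read_observations(write_observations(x))`
#' is the identity.
#'
#' @param path File path.
#' @param obs Validated observation data frame (for writing).
#' @return `read_observations()`: a validated data frame;
#'   `write_observations()`: `path`, invisibly.
#' @export
read_observations <- function(path) {
  obs <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(hare_id = "character", site = "character",
                                 date = "character", sex = "character"))
  missing_cols <- setdiff(obs_columns(), names(obs))
  if (length(missing_cols))
    stop("observation table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cn in c("whiteness", "snow1m", "snow10m", "concealment", "fid_m",
               paste0("slice_", 1:8)))
    obs[[cn]] <- as.numeric(obs[[cn]])
  obs$attempt_index <- as.integer(obs$attempt_index)
  obs$fled <- as.logical(obs$fled)
  validate_observations(obs)
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  obs <- validate_observations(obs)
  out <- obs
  out$date <- format(out$date, "%Y-%m-%d")
  out$fled <- ifelse(is.na(out$fled), NA, ifelse(out$fled, "TRUE", "FALSE"))
  write.csv(out[obs_columns()], path, row.names = FALSE, na = "",
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write daily mean-temperature tables
#'
#' CSV with columns `site, date, tmean_c`; dates ISO-8601, temperatures in
#' degrees Celsius. Dates must be strictly increasing within each site.
#'
#' @param path File path.
#' @param temps Temperature data frame (for writing).
#' @return `read_temperatures()`: data frame with `date` as `Date`.
#' @export
read_temperatures <- function(path) {
  temps <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(site = "character", date = "character"))
  missing_cols <- setdiff(c("site", "date", "tmean_c"), names(temps))
  if (length(missing_cols))
    stop("temperature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  temps$date <- as.Date(temps$date)
  for (s in unique(temps$site)) {
    d <- temps$date[temps$site == s]
    if (is.unsorted(d, strictly = TRUE))
      stop("temperature dates must be strictly increasing within site ", s,
           call. = FALSE)
  }
  temps
}

#' @rdname read_temperatures
#' @export
write_temperatures <- function(temps, path) {
  out <- temps[c("site", "date", "tmean_c")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
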