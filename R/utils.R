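#' Legal visual-estimation grids
#'
#' Coat whiteness is scored in 20% increments with just-initiated and
#' nearly-complete moults scored as 5 and 95% rather than 0 and 100%; snow
#' cover is scored on the plain 20% grid.
#'
#' @return Integer vector of legal percentages.
#' @export
whiteness_grid <- function() c(0L, 5L, 20L, 40L, 60L, 80L, 95L, 100L)

#' @rdname whiteness_grid
#' @export
snow_grid <- function() seq(0L, 100L, by = 20L)

#' Snap continuous percentages to a legal scoring grid
#'
#' Maps each value to the nearest member of the grid (ties resolve to the
#' smaller grid value). Values outside [0, 100] are clamped first.
#'
#' @param x Numeric vector of percentages.
#' @param grid Legal grid, default [whiteness_grid()].
#' @return Vector of grid members, same length as `x`.
#' @export
snap_to_grid <- function(x, grid = whiteness_grid()) {
  x <- pmin(100, pmax(0, x))
  grid[max.col(-abs(outer(x, grid, "-")), ties.method = "first")]
}

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the package flows from one user seed; independent
#' stages (snow, lifespans, observation noise, ...) draw from sub-seeds
#' derived by hashing the stage name, so any one stage is reproducible in
#' isolation.
#'
#' @param seed Integer master seed.
#' @param name Character stream name.
#' @return An integer seed in [0, 2^31).
#' @export
stream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

#' Highest posterior density interval from a sample
#'
#' Shortest contiguous interval containing `prob` of the draws.
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Coverage probability, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# equal-tailed interval helper used across fit summaries
eti <- function(x, prob = 0.95) {
  a <- (1 - prob) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE)
}
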