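# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; season-table percentages follow the
#' conventional half-up rule (e.g. 69.5 -> 70), so aggregation uses this
#' helper throughout.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), c(0, 0, 1))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Centered moving average with windows shrunk at the edges (no NA padding).
roll_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  half <- floor(k / 2)
  cs <- cumsum(c(0, x))
  i1 <- pmax(seq_len(n) - half, 1L)
  i2 <- pmin(seq_len(n) + half, n)
  (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
}

# Running median smoother for logger traces; k forced odd, edges kept.
roll_median <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L || n < k) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

mins_between <- function(a, b) as.numeric(difftime(a, b, units = "mins"))
hours_between <- function(a, b) as.numeric(difftime(a, b, units = "hours"))

#' Deterministic substream seed for one simulation unit
#'
#' All randomness in the generators flows from one root seed through this
#' derivation (`(root + 1000003 i + 7919 j) mod (2^31 - 1)`), so any single
#' nest (`i`) and night (`j`) can be re-simulated in isolation. Nest-night
#' gas traces use `j = 100 + night_index`.
#'
#' @param root Root seed (integer).
#' @param i,j Unit indices.
#' @return An integer seed below 2^31 - 1.
#' @export
substream_seed <- function(root, i, j = 0L) {
  as.integer((as.numeric(root) + 1000003 * as.numeric(i) + 7919 * as.numeric(j)) %%
               2147483647)
}

# Evaluate `code` under a temporary RNG state so simulators are
# deterministic in `seed` without clobbering the caller's RNG stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_invalid <- function(msg) abort(msg, class = "torpr_invalid_arg")
stop_format <- function(msg) abort(msg, class = "torpr_format_error")
stop_alignment <- function(msg) abort(msg, class = "torpr_alignment_error")

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(paste0("`", name, "` must be a single finite number."))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_invalid(paste0("`", name, "` must be in [", lower, ", ", upper, "]",
                        if (!allow_zero) " and non-zero" else "", "."))
  }
  invisible(x)
}

# Nights are attributed to the calendar date of their sunset; a timestamp
# before local noon therefore belongs to the previous date.
night_date_of <- function(timestamp, timezone_offset = 0) {
  local <- timestamp + timezone_offset * 3600
  as.Date(ifelse(as.integer(format(local, "%H", tz = "UTC")) < 12,
                 as.Date(local, tz = "UTC") - 1L,
                 as.Date(local, tz = "UTC")),
          origin = "1970-01-01")
}
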