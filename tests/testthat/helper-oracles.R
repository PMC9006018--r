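# Independent brute-force oracles and small fixture builders. All oracles
# are written as explicit loops so they share no code path with the
# package implementation they check.

# Quadratic-scan nearest-neighbour pairing.
oracle_align <- function(nest, ambient, tolerance) {
  idx <- integer(0)
  amb_j <- integer(0)
  for (i in seq_len(nrow(nest))) {
    best <- NA_integer_
    bestd <- Inf
    for (j in seq_len(nrow(ambient))) {
      d <- abs(as.numeric(nest$timestamp[i]) - as.numeric(ambient$timestamp[j]))
      if (d < bestd) {
        bestd <- d
        best <- j
      }
    }
    if (bestd / 60 <= tolerance) {
      idx <- c(idx, i)
      amb_j <- c(amb_j, best)
    }
  }
  tibble::tibble(timestamp = nest$timestamp[idx],
                 t_nest = nest$temp_c[idx],
                 t_a = ambient$temp_c[amb_j])
}

# Quadratic run-length scan for below-criterion events: maximal runs of
# diff <= criterion, merged across gaps < merge_gap minutes, kept when at
# least min_len samples long and entered from above the criterion.
# Returns the index of each qualifying run's first below sample and the
# run's minimum diff.
oracle_runs <- function(diffs, times, criterion, min_len, merge_gap) {
  n <- length(diffs)
  below <- !is.na(diffs) & diffs <= criterion
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      starts <- c(starts, i)
      ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(starts) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          min_diff = numeric()))
  }
  m_starts <- starts[1]
  m_ends <- ends[1]
  if (length(starts) > 1L) {
    for (k in 2L:length(starts)) {
      gap <- (as.numeric(times[starts[k]]) -
                as.numeric(times[m_ends[length(m_ends)]])) / 60
      if (gap < merge_gap) {
        m_ends[length(m_ends)] <- ends[k]
      } else {
        m_starts <- c(m_starts, starts[k])
        m_ends <- c(m_ends, ends[k])
      }
    }
  }
  keep <- logical(length(m_starts))
  for (k in seq_along(m_starts)) {
    long_enough <- (m_ends[k] - m_starts[k] + 1L) >= min_len
    crossed <- m_starts[k] > 1L && !is.na(diffs[m_starts[k] - 1L]) &&
      diffs[m_starts[k] - 1L] > criterion
    keep[k] <- long_enough && crossed
  }
  md <- numeric(sum(keep))
  ki <- 0L
  for (k in seq_along(m_starts)) {
    if (!keep[k]) next
    ki <- ki + 1L
    md[ki] <- min(diffs[m_starts[k]:m_ends[k]], na.rm = TRUE)
  }
  tibble::tibble(start = m_starts[keep], end = m_ends[keep], min_diff = md)
}

# Fine-step Euler integration of the nest heat balance (1-second steps,
# piecewise-constant forcing held at the coarse samples).
oracle_integrate <- function(times, ta, mr, T0, gamma, lambda, fine_dt = 1 / 60) {
  coarse_dt <- (as.numeric(times[2]) - as.numeric(times[1])) / 60
  out <- numeric(length(times))
  out[1] <- T0
  T <- T0
  for (k in seq_len(length(times) - 1L)) {
    steps <- round(coarse_dt / fine_dt)
    for (s in seq_len(steps)) {
      T <- T + fine_dt * (-lambda * (T - ta[k]) + gamma * mr[k])
    }
    out[k + 1L] <- T
  }
  out
}

# Textbook Pearson correlation and t-test p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p)
}

# --- fixture builders ---------------------------------------------------

make_trace <- function(times, temp, id = "n1", role = "nest") {
  tibble::tibble(timestamp = times, temp_c = temp, source_id = id, role = role)
}

five_min_grid <- function(start = "2017-07-01 12:00:00", hours = 24) {
  t0 <- as.POSIXct(start, tz = "UTC")
  seq(t0, t0 + hours * 3600, by = 300)
}

colony_sun <- function(dates = as.Date("2017-07-01")) {
  sun_times(51.0411, 7.8267, dates)
}

# A constructed square drop: flat at ambient + high, step down to
# ambient + low for `low_hours`, step back up.
square_drop <- function(high = 15, low = 5, low_hours = 6, ambient_c = 18) {
  times <- five_min_grid(hours = 24)
  n <- length(times)
  temp <- rep(ambient_c + high, n)
  lo_start <- floor(n / 3)
  lo_len <- low_hours * 12
  temp[lo_start:(lo_start + lo_len - 1L)] <- ambient_c + low
  list(nest = make_trace(times, temp),
       ambient = make_trace(times, rep(ambient_c, n), "amb", "ambient"))
}
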