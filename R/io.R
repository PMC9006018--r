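# On-disk formats: logger CSV ingestion with validation, trace alignment,
# and stable TSV writers for events / night scores / occupancy.
# Reads never interpolate gaps; detection modules own gap policy.

ts_fmt <- "%Y-%m-%dT%H:%M:%SZ"

format_ts <- function(x) format(x, ts_fmt, tz = "UTC")
parse_ts <- function(x) as.POSIXct(x, format = ts_fmt, tz = "UTC")

# Try several timestamp layouts; rows matching none come back NA (collected
# into the parse report, never an abort).
parse_ts_multi <- function(x, formats = c(ts_fmt, "%Y-%m-%d %H:%M:%S",
                                          "%Y-%m-%dT%H:%M:%S")) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in formats) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' Read a temperature-logger CSV export
#'
#' Two dialects are supported. `generic`: columns `timestamp` (ISO-8601),
#' `temp_c`, and optionally `source_id` and `role`. `ibutton_export`: a
#' free-form preamble followed by a `Date/Time,Unit,Value` header with
#' `dd/mm/yy HH:MM:SS` timestamps in local time (converted using
#' `tz_offset`).
#'
#' Malformed rows (unparseable timestamp or temperature) are excluded from
#' the trace but reported in the `parse_report` attribute, never silently
#' dropped. Non-monotone timestamps are a format error naming the first
#' offending row.
#'
#' @param path File path.
#' @param dialect `"generic"` or `"ibutton_export"`.
#' @param role Trace role, `"nest"` or `"ambient"`; overrides any role
#'   column in the file.
#' @param source_id Identifier; overrides any column in the file; defaults
#'   to the file name without extension.
#' @param tz_offset Hours east of UTC of the logger clock
#'   (`ibutton_export` only).
#' @return Tibble `timestamp`, `temp_c`, `source_id`, `role` with
#'   attributes `interval` (median spacing, minutes) and `parse_report`
#'   (tibble of skipped rows).
#' @export
read_temperature_csv <- function(path,
                                 dialect = c("generic", "ibutton_export"),
                                 role = NULL, source_id = NULL,
                                 tz_offset = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    stop_format(paste0("Empty file: ", path))
  }
  default_id <- sub("\\.[^.]*$", "", basename(path))

  if (dialect == "generic") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    if (!all(c("timestamp", "temp_c") %in% names(df))) {
      stop_format("Generic dialect requires `timestamp` and `temp_c` columns.")
    }
    ts <- parse_ts_multi(df$timestamp)
    temp <- suppressWarnings(as.numeric(df$temp_c))
    sid <- if (!is.null(source_id)) source_id else
      if ("source_id" %in% names(df)) df$source_id else default_id
    rl <- if (!is.null(role)) role else
      if ("role" %in% names(df)) df$role else "nest"
  } else {
    hdr <- grep("^\\s*Date/Time\\s*,", lines)
    if (length(hdr) == 0L) {
      stop_format("ibutton_export dialect: no `Date/Time,Unit,Value` header found.")
    }
    body <- lines[(hdr[1] + 1L):length(lines)]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0L) stop_format(paste0("No data rows in: ", path))
    parts <- strsplit(body, ",")
    ts <- as.POSIXct(vapply(parts, function(p) trimws(p[1]), ""),
                     format = "%d/%m/%y %H:%M:%S", tz = "UTC") - tz_offset * 3600
    temp <- suppressWarnings(as.numeric(vapply(parts, function(p)
      trimws(p[length(p)]), "")))
    sid <- if (!is.null(source_id)) source_id else default_id
    rl <- if (!is.null(role)) role else "nest"
  }

  bad <- is.na(ts) | is.na(temp)
  report <- tibble::tibble(
    row = which(bad),
    reason = ifelse(is.na(ts[bad]), "unparseable timestamp", "unparseable value")
  )
  out <- tibble::tibble(timestamp = ts[!bad], temp_c = temp[!bad],
                        source_id = rep_len(sid, sum(!bad)),
                        role = rep_len(rl, sum(!bad)))
  if (nrow(out) == 0L) stop_format(paste0("No valid rows in: ", path))
  nonmono <- which(diff(as.numeric(out$timestamp)) <= 0)
  if (length(nonmono) > 0L) {
    stop_format(sprintf(
      "Timestamps not strictly increasing at data row %d (%s).",
      nonmono[1] + 1L, format_ts(out$timestamp[nonmono[1] + 1L])))
  }
  attr(out, "interval") <- if (nrow(out) > 1L)
    median(diff(as.numeric(out$timestamp))) / 60 else NA_real_
  attr(out, "parse_report") <- report
  out
}

#' Read a gas-exchange trace CSV
#'
#' Expects columns `timestamp`, `vo2` and optionally `vco2`, `nest_id`,
#' `night_date`. VCO2 may be absent (the analysis uses VO2 only).
#'
#' @param path File path.
#' @param nest_id Override for the nest identifier.
#' @return Tibble `timestamp`, `vo2`, `vco2` (NA when absent), `nest_id`,
#'   `night_date` (NA when absent).
#' @export
read_gas_csv <- function(path, nest_id = NULL) {
  if (!file.exists(path)) stop_format(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("timestamp", "vo2") %in% names(df))) {
    stop_format("Gas CSV requires `timestamp` and `vo2` columns.")
  }
  ts <- if (inherits(df$timestamp, "POSIXct")) df$timestamp else
    parse_ts(as.character(df$timestamp))
  if (any(is.na(ts))) stop_format("Unparseable timestamps in gas CSV.")
  if (any(diff(as.numeric(ts)) <= 0)) {
    stop_format("Gas CSV timestamps must be strictly increasing.")
  }
  if (any(!is.na(df$vo2) & df$vo2 < 0)) stop_format("vo2 must be >= 0.")
  tibble::tibble(
    timestamp = ts,
    vo2 = as.numeric(df$vo2),
    vco2 = if ("vco2" %in% names(df)) as.numeric(df$vco2) else NA_real_,
    nest_id = if (!is.null(nest_id)) nest_id else
      if ("nest_id" %in% names(df)) as.character(df$nest_id) else
        sub("\\.[^.]*$", "", basename(path)),
    night_date = if ("night_date" %in% names(df)) as.Date(df$night_date) else
      as.Date(NA)
  )
}

#' Pair nest samples with the nearest ambient samples
#'
#' Each nest sample is matched to the ambient sample nearest in time within
#' `tolerance`; unmatched samples are excluded and counted (attribute
#' `n_unmatched`). No values are interpolated or fabricated: every output
#' row maps one real nest sample to one real ambient sample.
#'
#' @param nest,ambient Temperature-trace tibbles (`timestamp`, `temp_c`).
#' @param tolerance Maximum pairing distance in minutes; default half the
#'   median nest sampling interval.
#' @return Tibble `timestamp` (nest time), `t_nest`, `t_a`,
#'   `diff = t_nest - t_a`, `nest_id`.
#' @export
align_traces <- function(nest, ambient, tolerance = NULL) {
  if (nrow(nest) == 0L || nrow(ambient) == 0L) {
    stop_alignment("Cannot align empty traces.")
  }
  tn <- as.numeric(nest$timestamp)
  ta <- as.numeric(ambient$timestamp)
  if (max(tn) < min(ta) || max(ta) < min(tn)) {
    stop_alignment("Nest and ambient traces do not overlap in time.")
  }
  if (is.null(tolerance)) {
    tolerance <- if (length(tn) > 1L) median(diff(tn)) / 60 / 2 else 2.5
  }
  lo <- findInterval(tn, ta)
  hi <- pmin(lo + 1L, length(ta))
  lo <- pmax(lo, 1L)
  d_lo <- abs(tn - ta[lo])
  d_hi <- abs(tn - ta[hi])
  j <- ifelse(d_hi < d_lo, hi, lo)
  dist_min <- pmin(d_lo, d_hi) / 60
  keep <- dist_min <= tolerance
  out <- tibble::tibble(
    timestamp = nest$timestamp[keep],
    t_nest = nest$temp_c[keep],
    t_a = ambient$temp_c[j[keep]],
    nest_id = if ("source_id" %in% names(nest))
      nest$source_id[keep] else NA_character_
  )
  out$diff <- out$t_nest - out$t_a
  attr(out, "n_unmatched") <- sum(!keep)
  out
}

# Stable TSV writers: documented column order, numerics at fixed 4-decimal
# precision, ISO-8601 timestamps -- diff-able across runs.
event_cols <- c("nest_id", "night_date", "start_time", "criterion_time",
                "end_time", "magnitude", "duration", "min_tnest", "min_diff",
                "shape_score", "accepted", "gapped", "n_samples")
score_cols <- c("nest_id", "night_date", "peak_time", "arrival_detected",
                "mr_ref", "mr_min", "mr_min_time", "reduction_pct",
                "onset_time", "onset_vs_sunset", "arousal_end_time",
                "end_vs_sunrise", "arousal_truncated", "bout_duration",
                "torpor", "tnest_drop", "tnest_lag_min", "rer_mean")

fixed_tsv <- function(df, path, cols) {
  df <- df[, intersect(cols, names(df)), drop = FALSE]
  out <- df
  for (nm in names(out)) {
    col <- out[[nm]]
    if (inherits(col, "POSIXct")) out[[nm]] <- format_ts(col)
    else if (is.numeric(col) && !is.integer(col)) out[[nm]] <- sprintf("%.4f", col)
    if (is.character(out[[nm]])) out[[nm]][out[[nm]] %in% c("NA", "NaN")] <- NA
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write / read detected drop events as TSV
#'
#' Stable column order, ISO-8601 timestamps, numerics at 4 decimals.
#' An empty event set yields a header-only file.
#'
#' @param events Tibble of drop events from [detect_drops()].
#' @param path File path.
#' @return `write_events()` the path, invisibly; `read_events()` the tibble.
#' @export
write_events <- function(events, path) {
  tmpl <- tibble::tibble(
    nest_id = character(), night_date = as.Date(character()),
    start_time = as.POSIXct(character(), tz = "UTC"),
    criterion_time = as.POSIXct(character(), tz = "UTC"),
    end_time = as.POSIXct(character(), tz = "UTC"),
    magnitude = numeric(), duration = numeric(), min_tnest = numeric(),
    min_diff = numeric(), shape_score = numeric(), accepted = logical(),
    gapped = logical(), n_samples = integer()
  )
  events <- dplyr::bind_rows(tmpl, events)
  fixed_tsv(events, path, event_cols)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = "NA",
                        col_types = readr::cols(
                          nest_id = readr::col_character(),
                          night_date = readr::col_date(),
                          start_time = readr::col_character(),
                          criterion_time = readr::col_character(),
                          end_time = readr::col_character(),
                          accepted = readr::col_logical(),
                          gapped = readr::col_logical(),
                          n_samples = readr::col_integer(),
                          .default = readr::col_double()
                        ))
  for (nm in c("start_time", "criterion_time", "end_time")) {
    df[[nm]] <- parse_ts(df[[nm]])
  }
  tibble::as_tibble(df)
}

#' Write / read night scores as TSV
#'
#' @param scores Tibble of night scores from [score_night()] /
#'   [classify_torpor()].
#' @param path File path.
#' @return `write_night_scores()` the path, invisibly;
#'   `read_night_scores()` the tibble.
#' @export
write_night_scores <- function(scores, path) {
  fixed_tsv(scores, path, score_cols)
}

#' @rdname write_night_scores
#' @export
read_night_scores <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = "NA",
                        col_types = readr::cols(
                          nest_id = readr::col_character(),
                          night_date = readr::col_date(),
                          peak_time = readr::col_character(),
                          mr_min_time = readr::col_character(),
                          onset_time = readr::col_character(),
                          arousal_end_time = readr::col_character(),
                          .default = readr::col_guess()
                        ))
  for (nm in intersect(c("peak_time", "mr_min_time", "onset_time",
                         "arousal_end_time"), names(df))) {
    df[[nm]] <- parse_ts(as.character(df[[nm]]))
  }
  tibble::as_tibble(df)
}

#' Write a simulated season to a directory
#'
#' Writes `temperature.csv` (nest + ambient series), `gas.csv`,
#' `ground_truth.tsv` and `config.yaml`. Deterministic: identical seasons
#' produce byte-identical files.
#'
#' @param sim A `torpr_season` from [simulate_season()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_season <- function(sim, dir) {
  stopifnot(inherits(sim, "torpr_season"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  temp <- dplyr::bind_rows(
    sim$ambient[, c("timestamp", "temp_c", "source_id", "role")],
    sim$nest_temp[, c("timestamp", "temp_c", "source_id", "role")]
  )
  temp$timestamp <- format_ts(temp$timestamp)
  readr::write_csv(temp, file.path(dir, "temperature.csv"), progress = FALSE)
  if (!is.null(sim$gas) && nrow(sim$gas) > 0L) {
    gas <- sim$gas
    gas$timestamp <- format_ts(gas$timestamp)
    readr::write_csv(gas, file.path(dir, "gas.csv"), progress = FALSE)
  }
  truth <- sim$truth
  for (nm in c("true_entry_time", "true_arousal_onset", "true_peak_time")) {
    truth[[nm]] <- format_ts(truth[[nm]])
  }
  readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"), na = "NA",
                   progress = FALSE)
  write_sim_config(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a simulated season back from a directory
#'
#' @param dir Directory written by [write_season()].
#' @return A list with `config`, `temperature` (combined tibble), `gas`
#'   (or NULL), `truth`.
#' @export
read_season <- function(dir) {
  temp <- readr::read_csv(file.path(dir, "temperature.csv"),
                          show_col_types = FALSE, progress = FALSE)
  temp$timestamp <- parse_ts(temp$timestamp)
  gas_path <- file.path(dir, "gas.csv")
  gas <- NULL
  if (file.exists(gas_path)) {
    gas <- readr::read_csv(gas_path, show_col_types = FALSE, progress = FALSE)
    gas$timestamp <- parse_ts(gas$timestamp)
    gas$night_date <- as.Date(gas$night_date)
  }
  truth <- readr::read_tsv(file.path(dir, "ground_truth.tsv"),
                           show_col_types = FALSE, progress = FALSE, na = "NA")
  truth$night_date <- as.Date(truth$night_date)
  for (nm in c("true_entry_time", "true_arousal_onset", "true_peak_time")) {
    truth[[nm]] <- parse_ts(as.character(truth[[nm]]))
  }
  list(config = read_sim_config(file.path(dir, "config.yaml")),
       temperature = tibble::as_tibble(temp),
       gas = if (!is.null(gas)) tibble::as_tibble(gas) else NULL,
       truth = tibble::as_tibble(truth))
}
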