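#' Construct a breath-by-breath series
#'
#' Container for raw breath-by-breath oxygen-uptake samples as exported by a
#' metabolic cart: irregular timestamps, one V̇O2 value per breath, and a
#' per-breath exclusion flag with a reason code. Preprocessing never mutates
#' the stored values — exclusion is flag-only, so the raw record stays
#' auditable.
#'
#' @param t Breath timestamps in seconds, strictly increasing.
#' @param vo2 Oxygen uptake per breath, mL·kg⁻¹·min⁻¹, all non-negative.
#' @param excluded Logical exclusion flags (default all `FALSE`).
#' @param reason Character reason codes (`""`, `"manual"` or `"errant"`).
#' @return An object of class `breath_series`.
#' @export
breath_series <- function(t, vo2, excluded = rep(FALSE, length(t)),
                          reason = rep("", length(t))) {
  t <- as.numeric(t)
  vo2 <- as.numeric(vo2)
  if (length(t) != length(vo2) || length(t) != length(excluded)) {
    stop("t, vo2 and excluded must have equal length", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(!is.finite(vo2))) {
    stop("breath_series requires finite t and vo2", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("breath timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(vo2 < 0)) stop("vo2 values must be non-negative", call. = FALSE)
  structure(
    list(t = t, vo2 = vo2, excluded = as.logical(excluded),
         reason = as.character(reason)),
    class = "breath_series"
  )
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d breaths over %.1f s (%d excluded)\n",
              length(x$t), diff(range(x$t)), sum(x$excluded)))
  invisible(x)
}

#' Construct a uniform (interpolated) series
#'
#' The fitting substrate: V̇O2 values on a uniform time grid (1-s step by
#' default), with a provenance record listing the operations that produced
#' it.
#'
#' @param t0 Grid origin, seconds.
#' @param dt Grid step, seconds (> 0).
#' @param vo2 Values on the grid, mL·kg⁻¹·min⁻¹, no missing values.
#' @param provenance Character vector describing applied operations.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(t0, dt = 1, vo2, provenance = character(0)) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  vo2 <- as.numeric(vo2)
  if (any(!is.finite(vo2))) stop("uniform_series cannot hold missing values", call. = FALSE)
  structure(
    list(t0 = as.numeric(t0), dt = as.numeric(dt), vo2 = vo2,
         provenance = provenance),
    class = "uniform_series"
  )
}

#' Grid times of a uniform series
#' @param u A [uniform_series()].
#' @return Numeric vector of grid times, seconds.
#' @export
series_times <- function(u) {
  u$t0 + u$dt * (seq_along(u$vo2) - 1L)
}

#' @export
print.uniform_series <- function(x, ...) {
  tt <- series_times(x)
  cat(sprintf("<uniform_series> %d points, t = %.0f..%.0f s (dt = %g s)\n",
              length(x$vo2), tt[1], tt[length(tt)], x$dt))
  if (length(x$provenance)) {
    cat("  provenance: ", paste(x$provenance, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

# Deviation of one breath (position i) from a robust local centre built
# from the other breaths. Interior breaths use the median of the symmetric
# centred window of `window - 1` neighbours, which is unbiased on a locally
# linear trend and tolerates one gross outlier. Near the series edges the
# window is one-sided, so the trend no longer cancels: there the centre is
# the median of the `window - 1` nearest neighbours detrended by a local
# Theil-Sen slope (median of all pairwise slopes over the nearest
# `2*(window - 1)` breaths) — a low-noise slope estimate, in time units so
# irregular breath spacing is handled, that itself tolerates outlying
# neighbours.
.deviation_at <- function(x, t, i, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  m <- window - 1L
  if (i - half >= 1L && i + half <= n) {
    nb <- setdiff((i - half):(i + half), i)
    return(x[i] - stats::median(x[nb]))
  }
  others <- setdiff(seq_len(n), i)
  if (length(others) < 2L) return(0)
  ord <- others[order(abs(others - i))]
  near <- sort(ord[seq_len(min(m, length(ord)))])
  wide <- sort(ord[seq_len(min(2L * m, length(ord)))])
  pairs <- utils::combn(wide, 2L)
  dt <- t[pairs[2L, ]] - t[pairs[1L, ]]
  ok <- dt != 0
  slope <- if (any(ok)) {
    stats::median((x[pairs[2L, ok]] - x[pairs[1L, ok]]) / dt[ok])
  } else {
    0
  }
  x[i] - stats::median(x[near] + slope * (t[i] - t[near]))
}

.local_deviation <- function(x, t, window) {
  vapply(seq_along(x), function(i) .deviation_at(x, t, i, window), numeric(1))
}

# Robust scale of the deviation statistic: SD of the central 80% (by
# absolute value), rescaled by the corresponding truncated-normal factor.
# Tolerates up to 20% gross outliers with better sampling efficiency than
# the MAD.
.trimmed_scale <- function(dev, trim = 0.2) {
  a <- abs(dev)
  keep <- a <= stats::quantile(a, 1 - trim, names = FALSE)
  sqrt(mean(dev[keep]^2)) / 0.6616
}

#' Flag errant breaths
#'
#' Flags physiologically implausible outlier breaths (coughs, swallows,
#' sighs) prior to interpolation and fitting. Each breath's deviation from
#' a robust local centre (the median of its `window - 1` nearest
#' neighbouring breaths, slope-detrended near the series edges; the breath
#' itself excluded) is computed, and the typical scale of that deviation
#' statistic is estimated robustly across the whole series by a trimmed SD
#' (central 80% by absolute value, rescaled to be unbiased under Gaussian
#' noise). A breath is flagged when its deviation exceeds `k` times this
#' scale. Because the local median centre tracks the transient and the
#' trimmed scale ignores a fraction of gross outliers, the rule keeps a
#' near-zero false-flag rate on clean Gaussian breath noise while reliably
#' catching large (several noise-SD) artefacts. Flagging is applied
#' repeatedly, rescoring the remaining breaths — and restoring flagged
#' breaths that are no longer outlying once their errant neighbours are
#' gone — until the flag set is stable, so a further pass with the same
#' settings is a no-op.
#'
#' Values are never altered; flags only are set (reason `"errant"`).
#'
#' @param b A [breath_series()].
#' @param window Centred window size in breaths (odd, >= 3; default 5).
#' @param k Deviation threshold in robust deviation-SD multiples
#'   (default 5).
#' @return The input series with updated `excluded`/`reason` flags.
#' @export
exclude_errant <- function(b, window = 5, k = 5) {
  stopifnot(inherits(b, "breath_series"))
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3", call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  n <- length(b$t)
  if (n < window) {
    warning("series shorter than window; no breaths flagged")
    return(b)
  }
  for (pass in seq_len(20L)) {
    usable <- which(!b$excluded)
    if (length(usable) < window) {
      warning("fewer usable breaths than window; no further breaths flagged")
      return(b)
    }
    dev <- .local_deviation(b$vo2[usable], b$t[usable], window)
    scale <- .trimmed_scale(dev)  # robust SD of the deviation statistic
    if (scale == 0) scale <- stats::sd(dev)
    if (!is.finite(scale) || scale == 0) break
    flag <- abs(dev) > k * scale
    if (any(flag)) {
      idx <- usable[flag]
      b$excluded[idx] <- TRUE
      b$reason[idx] <- "errant"
      next
    }
    # No new outliers: re-score each auto-flagged breath against the clean
    # series alone. A breath flagged only because its window was
    # contaminated by a true errant (e.g. a breath flanked by two errants)
    # is no longer outlying once the errants are gone, and is restored.
    restored <- FALSE
    for (j in which(b$excluded & b$reason == "errant")) {
      aug <- sort(c(usable, j))
      dj <- .deviation_at(b$vo2[aug], b$t[aug], match(j, aug), window)
      if (abs(dj) <= k * scale) {
        b$excluded[j] <- FALSE
        b$reason[j] <- ""
        restored <- TRUE
      }
    }
    if (!restored) break
  }
  b
}

#' Interpolate breaths to a 1-s grid
#'
#' Linearly interpolates the non-excluded breaths onto integer seconds
#' spanning `[ceiling(first), floor(last)]` of the usable breath times. No
#' extrapolation is performed: the grid is clipped inside the observed span.
#' Excluded breaths contribute nothing.
#'
#' @param b A [breath_series()].
#' @return A [uniform_series()] with `dt = 1`.
#' @export
interpolate_1s <- function(b) {
  stopifnot(inherits(b, "breath_series"))
  keep <- !b$excluded
  if (sum(keep) < 2) stop("insufficient data: need >= 2 non-excluded breaths", call. = FALSE)
  t <- b$t[keep]
  v <- b$vo2[keep]
  t0 <- ceiling(t[1])
  t1 <- floor(t[length(t)])
  if (t1 < t0) stop("usable span too short for a 1-s grid", call. = FALSE)
  grid <- seq(t0, t1, by = 1)
  vo2 <- stats::approx(t, v, xout = grid, method = "linear", ties = "ordered")$y
  uniform_series(
    t0 = t0, dt = 1, vo2 = vo2,
    provenance = c(sprintf("interpolate_1s: %d breaths (%d excluded)",
                           length(b$t), sum(b$excluded)))
  )
}

#' Ensemble-average repeated transitions
#'
#' Pointwise mean of several time-aligned uniform series over the common
#' span of their grids (intersection). All series must share the same grid
#' step and commensurate origins.
#'
#' @param series List of [uniform_series()] objects.
#' @return A [uniform_series()]; provenance records the replicate count.
#' @export
ensemble_average <- function(series) {
  if (!length(series)) stop("ensemble_average needs at least one series", call. = FALSE)
  stopifnot(all(vapply(series, inherits, logical(1), "uniform_series")))
  dt <- series[[1]]$dt
  if (!all(vapply(series, function(s) isTRUE(all.equal(s$dt, dt)), logical(1)))) {
    stop("all series must share the same grid step", call. = FALSE)
  }
  offs <- vapply(series, function(s) (s$t0 - series[[1]]$t0) / dt, numeric(1))
  if (any(abs(offs - round(offs)) > 1e-8)) {
    stop("series grids are not aligned (origins differ by non-multiples of dt)",
         call. = FALSE)
  }
  lo <- max(vapply(series, function(s) s$t0, numeric(1)))
  hi <- min(vapply(series, function(s) s$t0 + s$dt * (length(s$vo2) - 1L), numeric(1)))
  if (hi < lo) stop("series grids have empty intersection", call. = FALSE)
  grid <- seq(lo, hi, by = dt)
  vals <- vapply(series, function(s) {
    idx <- round((grid - s$t0) / dt) + 1L
    s$vo2[idx]
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  uniform_series(
    t0 = lo, dt = dt, vo2 = rowMeans(vals),
    provenance = c(sprintf("ensemble_average: %d transitions", length(series)))
  )
}

# Centred rolling statistic with truncated windows (no padding).
.roll_stat <- function(x, width, fun) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    fun(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Smooth a uniform series
#'
#' Centred rolling filters for the interpolated V̇O2 series. Window edges
#' are handled by truncation (no padded or invented data at the transition
#' boundaries), and the output grid is unchanged.
#'
#' @param u A [uniform_series()].
#' @param method One of `"moving_average"` (rolling mean, width in seconds),
#'   `"median"` (rolling median, width in seconds) or `"breath_average"`
#'   (rolling mean, width in samples).
#' @param width Window width: seconds for the time filters, samples for
#'   `"breath_average"`; must be >= 1.
#' @return A smoothed [uniform_series()].
#' @export
smooth_series <- function(u, method = c("moving_average", "median", "breath_average"),
                          width = 5) {
  stopifnot(inherits(u, "uniform_series"))
  if (!is.character(method)) stop("method must be a character string", call. = FALSE)
  method <- method[1]
  supported <- c("moving_average", "median", "breath_average")
  if (!method %in% supported) {
    stop("unknown smoothing method '", method, "'; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  w <- if (method == "breath_average") round(width) else max(1, round(width / u$dt))
  if (w %% 2 == 0) w <- w + 1L  # centred windows need odd width
  fun <- if (method == "median") stats::median else mean
  uniform_series(
    t0 = u$t0, dt = u$dt, vo2 = .roll_stat(u$vo2, w, fun),
    provenance = c(u$provenance, sprintf("smooth: %s width=%g", method, width))
  )
}

#' Peak oxygen uptake from the last 30 s
#'
#' Peak V̇O2 computed as the mean of the final 30 seconds of an
#' exercise-phase series (grid points with `t >= t_end - 30`, inclusive).
#'
#' @param u A [uniform_series()] spanning at least 30 s.
#' @return Peak V̇O2, mL·kg⁻¹·min⁻¹.
#' @export
vo2peak_last30 <- function(u) {
  stopifnot(inherits(u, "uniform_series"))
  tt <- series_times(u)
  span <- tt[length(tt)] - tt[1]
  if (span < 30) {
    stop(sprintf("series spans only %.1f s; need >= 30 s", span), call. = FALSE)
  }
  mean(u$vo2[tt >= tt[length(tt)] - 30])
}

#' Read a delimited breath-by-breath table
#'
#' Reads breath tables as exported by metabolic carts: comma, semicolon or
#' tab delimited, with a decimal comma tolerated in the semicolon dialect.
#' Lines starting with `#` are treated as comments.
#'
#' @param path Path to the delimited text file.
#' @param time_col,vo2_col Column names holding breath time (s) and V̇O2
#'   (mL·kg⁻¹·min⁻¹).
#' @return A [breath_series()].
#' @export
read_breath_table <- function(path, time_col = "time", vo2_col = "vo2") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("no data rows in ", path, call. = FALSE)
  header <- lines[1]
  sep <- if (grepl(";", header)) ";" else if (grepl(",", header)) "," else "\t"
  dec <- "."
  if (sep == ";" && any(grepl("[0-9],[0-9]", lines[-1]))) dec <- ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep, dec = dec,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(time_col, vo2_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path,
           " (available: ", paste(names(df), collapse = ", "), ")", call. = FALSE)
    }
    if (!is.numeric(df[[col]])) {
      stop("column '", col, "' in ", path, " is not numeric; check delimiter/decimal",
           call. = FALSE)
    }
  }
  excl <- if ("excluded" %in% names(df)) as.logical(df$excluded) else rep(FALSE, nrow(df))
  breath_series(df[[time_col]], df[[vo2_col]], excluded = excl)
}

#' Write a breath series to delimited text
#'
#' @param b A [breath_series()].
#' @param path Output path.
#' @param header Optional named character/numeric vector written as
#'   `# name: value` comment lines.
#' @return Invisibly, `path`.
#' @export
write_breath_table <- function(b, path, header = NULL) {
  stopifnot(inherits(b, "breath_series"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) {
    writeLines(sprintf("# %s: %s", names(header), as.character(header)), con)
  }
  utils::write.table(
    data.frame(time = b$t, vo2 = b$vo2, excluded = b$excluded, reason = b$reason),
    con, sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a processed uniform series with provenance header
#'
#' Writes the series as comma-delimited `time,vo2` rows preceded by
#' `#`-prefixed provenance lines.
#'
#' @param u A [uniform_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_uniform_series <- function(u, path) {
  stopifnot(inherits(u, "uniform_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# t0: %g", u$t0),
    sprintf("# dt: %g", u$dt),
    sprintf("# provenance: %s", paste(u$provenance, collapse = " | "))
  ), con)
  utils::write.table(data.frame(time = series_times(u), vo2 = u$vo2),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
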