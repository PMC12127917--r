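#' Percentile confidence interval from bootstrap replicates
#'
#' Empirical quantiles at `(1 - level)/2` and `(1 + level)/2` with linear
#' interpolation between order statistics (type-7 quantiles).
#'
#' @param replicates Numeric vector of replicate estimates (>= 2).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' percentile_ci(1:100)  # c(3.475, 97.525)
#' @export
percentile_ci <- function(replicates, level = 0.95) {
  if (!length(replicates)) stop("empty replicate vector", call. = FALSE)
  if (length(replicates) < 2) stop("need >= 2 replicates", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must be strictly between 0 and 1", call. = FALSE)
  }
  q <- stats::quantile(replicates, probs = c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Residual bootstrap for a fitted transient model
#'
#' Parameter uncertainty for a single exercise transition: residuals of the
#' base fit are resampled with replacement, added back onto the fitted
#' curve, and the model refitted to each pseudo-series with the base
#' estimates as warm start. The residual (rather than case) bootstrap
#' preserves the time grid, which carries the model structure in kinetics
#' data. Replicates that fail to converge are dropped and counted; the
#' result is flagged unreliable when more than 20% fail.
#'
#' @param u The [uniform_series()] the base model was fitted to.
#' @param base A converged `vo2_fit` on `u`.
#' @param n_samples Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @param level Confidence level for the percentile intervals (default
#'   0.95).
#' @return An object of class `vo2_boot`: `replicates` (matrix, one row per
#'   converged replicate, columns = free parameters), per-parameter `sd`,
#'   `cv` (percent), `ci` (2 x p matrix), `n_samples`, `n_failed`,
#'   `unreliable` flag, `seed`, and `ci_method` (`"percentile"`).
#' @export
residual_bootstrap <- function(u, base, n_samples = 1000, seed, level = 0.95) {
  stopifnot(inherits(u, "uniform_series"), inherits(base, "vo2_fit"))
  if (!base$converged) stop("base fit did not converge", call. = FALSE)
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (missing(seed)) stop("seed is required for a reproducible bootstrap", call. = FALSE)
  spec <- base$spec
  free <- spec$free
  n <- base$n
  init <- base$estimates[free]
  reps <- matrix(NA_real_, nrow = n_samples, ncol = length(free),
                 dimnames = list(NULL, free))
  ok <- logical(n_samples)
  with_seed(seed, {
    for (b in seq_len(n_samples)) {
      idx <- sample.int(n, n, replace = TRUE)
      ystar <- base$fitted + base$residuals[idx]
      ustar <- uniform_series(u$t0, u$dt, ystar)
      f <- tryCatch(
        suppressWarnings(fit_vo2(ustar, spec, init = init, n_restarts = 1)),
        error = function(e) NULL
      )
      if (!is.null(f) && f$converged) {
        reps[b, ] <- f$estimates[free]
        ok[b] <- TRUE
      }
    }
  })
  reps <- reps[ok, , drop = FALSE]
  n_failed <- n_samples - nrow(reps)
  if (!nrow(reps)) stop("all bootstrap replicates failed to converge", call. = FALSE)
  sds <- apply(reps, 2, stats::sd)
  means <- colMeans(reps)
  cvs <- ifelse(means == 0, NA_real_, 100 * sds / means)
  cis <- apply(reps, 2, percentile_ci, level = level)
  structure(
    list(spec = spec, n_samples = n_samples, replicates = reps,
         sd = sds, cv = cvs, ci = cis, level = level,
         n_failed = n_failed, unreliable = n_failed > 0.2 * n_samples,
         seed = seed, ci_method = "percentile",
         bootstrap_method = "residual"),
    class = "vo2_boot"
  )
}

#' @export
print.vo2_boot <- function(x, digits = 4, ...) {
  cat(sprintf("<vo2_boot> %s bootstrap, %d/%d replicates converged%s\n",
              x$bootstrap_method, nrow(x$replicates), x$n_samples,
              if (x$unreliable) "  [UNRELIABLE]" else ""))
  out <- rbind(mean = colMeans(x$replicates), sd = x$sd, `cv%` = x$cv, x$ci)
  print(round(out, digits))
  invisible(x)
}

#' Serialize a bootstrap result to JSON
#'
#' @param x A `vo2_boot`.
#' @param path Output path.
#' @param dump_replicates Also write the per-replicate estimates as a
#'   delimited text file next to `path` (same name, `.replicates.csv`
#'   suffix).
#' @return Invisibly, `path`.
#' @export
write_bootstrap_report <- function(x, path, dump_replicates = FALSE) {
  stopifnot(inherits(x, "vo2_boot"))
  report <- list(
    form = x$spec$form, direction = x$spec$direction,
    bootstrap_method = x$bootstrap_method, ci_method = x$ci_method,
    n_samples = x$n_samples, n_converged = nrow(x$replicates),
    n_failed = x$n_failed, unreliable = x$unreliable, seed = x$seed,
    level = x$level,
    mean = as.list(colMeans(x$replicates)),
    sd = as.list(x$sd), cv_percent = as.list(x$cv),
    ci_lower = as.list(x$ci["lower", ]), ci_upper = as.list(x$ci["upper", ])
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (dump_replicates) {
    utils::write.table(as.data.frame(x$replicates),
                       sub("\\.json$", "", path) |> paste0(".replicates.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
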