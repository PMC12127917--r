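#' Preset kinetic parameters by intensity domain
#'
#' Physiologically realistic parameter presets for the four swimming
#' intensity domains (low, moderate, heavy, severe), grounded in cohort
#' mean estimates from incremental front-crawl testing of trained swimmers.
#' Off-transient presets carry the end-exercise plateau, primary amplitude
#' and time constant with no time delay; on-transient presets carry the
#' pre-exercise baseline (peak minus amplitude), amplitude, time constant
#' and a primary delay. An optional slow component (amplitude 8, delay 90 s,
#' time constant 60 s) can be appended for exercising the bi-exponential
#' forms.
#'
#' @param domain One of `"low"`, `"moderate"`, `"heavy"`, `"severe"`.
#' @param direction `"on"` or `"off"`.
#' @param slow Append slow-component parameters (default `FALSE`).
#' @return Named numeric parameter vector.
#' @examples
#' vo2_presets("severe", "off")
#' @export
vo2_presets <- function(domain = c("severe", "low", "moderate", "heavy"),
                        direction = c("off", "on"), slow = FALSE) {
  domain <- match.arg(domain)
  direction <- match.arg(direction)
  off <- list(
    low      = c(EEVO2 = 38.8, Ap = 30.1, taup = 30.8, TDp = 0),
    moderate = c(EEVO2 = 38.9, Ap = 29.9, taup = 29.7, TDp = 0),
    heavy    = c(EEVO2 = 46.3, Ap = 36.0, taup = 28.7, TDp = 0),
    severe   = c(EEVO2 = 51.0, Ap = 40.3, taup = 37.0, TDp = 0)
  )
  on <- list(
    low      = c(VO2base = 7.4,  Ap = 31.6, taup = 15.8, TDp = 22.4),
    moderate = c(VO2base = 9.0,  Ap = 33.2, taup = 11.3, TDp = 19.8),
    heavy    = c(VO2base = 9.6,  Ap = 38.4, taup = 13.9, TDp = 20.5),
    severe   = c(VO2base = 11.1, Ap = 40.3, taup = 10.3, TDp = 19.6)
  )
  p <- if (direction == "off") off[[domain]] else on[[domain]]
  if (slow) p <- c(p, Asc = 8, TDsc = 90, tausc = 60)
  p
}

#' Configuration for the synthetic-data generator
#'
#' Bundles everything needed to generate a validation dataset: the model and
#' true parameters, duration, sampling (uniform rate or a breath-interval
#' distribution), Gaussian noise level, errant-breath contamination, and
#' the seed.
#'
#' @param spec A [vo2_model()] specification.
#' @param truth Named numeric vector of true parameter values (validated
#'   against `spec`).
#' @param duration Series duration in seconds (> 0, default 180).
#' @param rate Uniform sampling rate in Hz for [generate_uniform()]
#'   (default 1).
#' @param breath_interval_mean,breath_interval_sd Mean and SD (s) of the
#'   truncated-normal breath-interval process for [generate_breaths()]
#'   (defaults 3 and 0.75 s, typical of exercise hyperpnoea).
#' @param noise_sd SD of additive Gaussian noise, mL·kg⁻¹·min⁻¹ (>= 0,
#'   default 0).
#' @param errant_rate Fraction of breaths displaced as errant artefacts
#'   (in \[0, 0.2), default 0).
#' @param errant_magnitude Displacement magnitude in multiples of
#'   `noise_sd` (default 10).
#' @param seed Integer seed (required).
#' @return An object of class `vo2_generator_config`.
#' @export
generator_config <- function(spec, truth, duration = 180, rate = 1,
                             breath_interval_mean = 3, breath_interval_sd = 0.75,
                             noise_sd = 0, errant_rate = 0, errant_magnitude = 10,
                             seed) {
  stopifnot(inherits(spec, "vo2_model_spec"))
  truth <- validate_params(spec, truth)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (breath_interval_mean <= 0) stop("breath interval mean must be > 0", call. = FALSE)
  if (breath_interval_sd < 0) stop("breath interval SD must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (errant_rate < 0 || errant_rate >= 0.2) {
    stop("errant_rate must lie in [0, 0.2)", call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  structure(
    list(spec = spec, truth = truth, duration = duration, rate = rate,
         breath_interval_mean = breath_interval_mean,
         breath_interval_sd = breath_interval_sd,
         noise_sd = noise_sd, errant_rate = errant_rate,
         errant_magnitude = errant_magnitude, seed = as.integer(seed)),
    class = "vo2_generator_config"
  )
}

#' Generate a uniformly sampled validation series
#'
#' Model curve sampled on a uniform grid from 0 to the configured duration,
#' with optional i.i.d. Gaussian noise. With `noise_sd = 0` the series
#' reproduces the model exactly, which is the noise-free validation setting:
#' refitting the generating model must recover the true parameters with a
#' standard error of regression at numerical zero.
#'
#' @param cfg A [generator_config()].
#' @return List with `series` (a [uniform_series()]), `truth` (the full
#'   true parameter vector), `spec`, and `config`.
#' @export
generate_uniform <- function(cfg) {
  stopifnot(inherits(cfg, "vo2_generator_config"))
  dt <- 1 / cfg$rate
  tt <- seq(0, cfg$duration, by = dt)
  clean <- eval_vo2(cfg$spec, cfg$truth, tt)
  vo2 <- if (cfg$noise_sd > 0) {
    with_seed(cfg$seed, clean + stats::rnorm(length(tt), 0, cfg$noise_sd))
  } else {
    clean
  }
  list(
    series = uniform_series(
      0, dt, vo2,
      provenance = sprintf("generate_uniform: %s %s, noise_sd=%g, seed=%d",
                           cfg$spec$direction, cfg$spec$form, cfg$noise_sd, cfg$seed)
    ),
    truth = cfg$truth, spec = cfg$spec, config = cfg
  )
}

#' Generate a realistic breath-by-breath series
#'
#' Emulates raw analyser output: breath timestamps from a truncated-normal
#' interval process (truncated below at a fifth of the mean interval; zero
#' interval SD gives uniform spacing), per-breath values from the model
#' curve plus Gaussian noise, and a configurable fraction of breaths
#' displaced by `errant_magnitude * noise_sd` (random sign, reflected
#' upward when a downward displacement would cross zero) to mimic coughs
#' and swallows for the exclusion filter.
#'
#' @param cfg A [generator_config()].
#' @return List with `breaths` (a [breath_series()]), `truth`, `spec`,
#'   `errant_idx` (indices of injected errant breaths) and `config`.
#' @export
generate_breaths <- function(cfg) {
  stopifnot(inherits(cfg, "vo2_generator_config"))
  with_seed(cfg$seed, {
    lo <- cfg$breath_interval_mean / 5
    t <- numeric(0)
    cur <- 0
    repeat {
      iv <- if (cfg$breath_interval_sd == 0) {
        cfg$breath_interval_mean
      } else {
        repeat {
          iv <- stats::rnorm(1, cfg$breath_interval_mean, cfg$breath_interval_sd)
          if (iv > lo) break
        }
        iv
      }
      cur <- cur + iv
      if (cur > cfg$duration) break
      t <- c(t, cur)
    }
    t <- c(0, t)
    vo2 <- eval_vo2(cfg$spec, cfg$truth, t) +
      if (cfg$noise_sd > 0) stats::rnorm(length(t), 0, cfg$noise_sd) else 0
    errant_idx <- integer(0)
    if (cfg$errant_rate > 0 && cfg$noise_sd > 0) {
      errant_idx <- which(stats::runif(length(t)) < cfg$errant_rate)
      if (length(errant_idx)) {
        disp <- sample(c(-1, 1), length(errant_idx), replace = TRUE) *
          cfg$errant_magnitude * cfg$noise_sd
        # reflect a downward displacement upward when it would cross zero,
        # so every injected artefact keeps its full nominal magnitude
        disp <- ifelse(vo2[errant_idx] + disp < 0, abs(disp), disp)
        vo2[errant_idx] <- vo2[errant_idx] + disp
      }
    }
    vo2 <- pmax(vo2, 0)
    list(
      breaths = breath_series(t, vo2),
      truth = cfg$truth, spec = cfg$spec, errant_idx = errant_idx, config = cfg
    )
  })
}

#' Write a generated dataset with its truth sidecar
#'
#' Writes the generated data in the delimited breath-table format the
#' reader consumes, and the generating model plus true parameters as a JSON
#' sidecar (`<path>.truth.json`).
#'
#' @param gen Result of [generate_uniform()] or [generate_breaths()].
#' @param path Output path for the data file.
#' @return Invisibly, `path`.
#' @export
write_synthetic <- function(gen, path) {
  hdr <- c(model = paste(gen$spec$direction, gen$spec$form),
           seed = gen$config$seed, noise_sd = gen$config$noise_sd)
  if (!is.null(gen$series)) {
    u <- gen$series
    con <- file(path, "w")
    writeLines(sprintf("# %s: %s", names(hdr), as.character(hdr)), con)
    utils::write.table(data.frame(time = series_times(u), vo2 = u$vo2),
                       con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
  } else {
    write_breath_table(gen$breaths, path, header = hdr)
  }
  jsonlite::write_json(
    list(direction = gen$spec$direction, form = gen$spec$form,
         truth = as.list(gen$truth),
         noise_sd = gen$config$noise_sd, duration = gen$config$duration,
         errant_idx = gen$errant_idx, seed = gen$config$seed),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
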