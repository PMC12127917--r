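# Run code with a temporary RNG state so that seeded internals never disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Time constants are optimized on the log scale: the model is undefined for
# tau <= 0, and the log transform keeps the optimizer unconstrained while
# preserving the printed model exactly.
.log_params <- c("taup", "tausc")

.to_internal <- function(par) {
  for (nm in intersect(names(par), .log_params)) par[[nm]] <- log(par[[nm]])
  par
}

.from_internal <- function(par) {
  for (nm in intersect(names(par), .log_params)) par[[nm]] <- exp(par[[nm]])
  par
}

#' Data-driven starting values for a model fit
#'
#' Heuristic initial parameter estimates: the plateau (`EEVO2` or `VO2base`)
#' from the first 30-s mean, the primary amplitude from the observed range,
#' the primary time constant from the time to cross 63% of the range, and
#' fixed physiological defaults for the delayed terms (`TDp` 10 s, `TDsc`
#' 90 s, `Asc` one tenth of the primary amplitude). A degenerate (constant)
#' series falls back to a zero amplitude guard.
#'
#' @param u A [uniform_series()].
#' @param spec A [vo2_model()] specification.
#' @return Named numeric vector of starting values for the spec's free
#'   parameters.
#' @export
default_init <- function(u, spec) {
  stopifnot(inherits(u, "uniform_series"), inherits(spec, "vo2_model_spec"))
  tt <- series_times(u)
  v <- u$vo2
  if (length(v) < 4) stop("need at least 4 points for initialization", call. = FALSE)
  first30 <- mean(v[tt <= tt[1] + 30])
  rng <- max(v) - min(v)
  Ap <- if (rng > sqrt(.Machine$double.eps)) rng else 0
  span <- tt[length(tt)] - tt[1]
  # 63% crossing measured from the first observed value
  tau <- span / 4
  if (Ap > 0) {
    target <- if (spec$direction == "off") v[1] - 0.632 * Ap else v[1] + 0.632 * Ap
    hit <- if (spec$direction == "off") which(v <= target) else which(v >= target)
    if (length(hit)) tau <- max(tt[hit[1]] - tt[1], 1)
  }
  init <- c(first30, Ap, tau)
  names(init) <- c(spec$free[1], "Ap", "taup")
  if ("TDp" %in% spec$free) init[["TDp"]] <- 10
  if ("Asc" %in% spec$free) {
    init[["Asc"]] <- 0.1 * Ap
    init[["TDsc"]] <- min(90, tt[1] + 0.5 * span)
    init[["tausc"]] <- 60
  }
  init[["taup"]] <- max(init[["taup"]], 1)
  init[spec$free]
}

# Deterministic multistart perturbations around a base init (natural scale).
.perturb_init <- function(init, i) {
  out <- init
  for (nm in names(out)) {
    if (nm %in% c("taup", "tausc")) {
      out[[nm]] <- out[[nm]] * exp(stats::runif(1, -0.5, 0.5))
    } else if (nm %in% c("TDp", "TDsc")) {
      out[[nm]] <- abs(out[[nm]] + stats::runif(1, -20, 20))
    } else {
      out[[nm]] <- out[[nm]] * exp(stats::runif(1, -0.25, 0.25)) +
        stats::runif(1, -1, 1)
    }
  }
  out
}

#' Fit a transient model by nonlinear least squares
#'
#' Unconstrained least-squares estimation of a mono- or bi-exponential
#' transient model on a uniform series, minimizing the residual sum of
#' squares with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]). Time constants are optimized on the log scale
#' (the model is undefined at non-positive time constants); all other
#' parameters, including time delays, are free of constraints unless box
#' `bounds` are supplied. Because the gated time-delay terms make the
#' objective non-smooth where a delay crosses a grid point, a small
#' deterministic multistart (perturbed copies of the initial values, seeded)
#' is used and the lowest-RSS converged solution returned.
#'
#' @param u A [uniform_series()].
#' @param spec A [vo2_model()] specification.
#' @param init Optional named starting values for the free parameters;
#'   defaults to [default_init()].
#' @param bounds Optional list with named numeric vectors `lower` and/or
#'   `upper` (natural scale) for box constraints.
#' @param n_restarts Number of multistart attempts (>= 1, default 5); the
#'   first uses `init` unperturbed.
#' @param seed Integer seed for the deterministic multistart perturbations.
#' @return An object of class `vo2_fit`: spec, `estimates` (full parameter
#'   vector including fixed values), `rss`, `ser` (= sqrt(rss/(n-p))), `n`,
#'   `p`, `residuals`, `fitted`, `converged`, `n_restarts_used`, and the
#'   grid descriptors `t0`, `dt`.
#' @examples
#' spec <- vo2_model("off", "MONO_NO_TD")
#' truth <- c(EEVO2 = 51, Ap = 40.3, taup = 37)
#' u <- uniform_series(0, 1, eval_vo2(spec, truth, 0:180))
#' fit_vo2(u, spec)
#' @export
fit_vo2 <- function(u, spec, init = NULL, bounds = NULL, n_restarts = 5, seed = 1L) {
  stopifnot(inherits(u, "uniform_series"), inherits(spec, "vo2_model_spec"))
  tt <- series_times(u)
  y <- u$vo2
  n <- length(y)
  p <- length(spec$free)
  if (n <= p) stop(sprintf("n = %d points cannot identify %d parameters", n, p),
                   call. = FALSE)
  if (is.null(init)) init <- default_init(u, spec)
  init <- merge_params(spec, c(init, spec$fixed))[spec$free]
  span <- tt[n] - tt[1]
  if (is.finite(init[["taup"]]) && span < 4 * init[["taup"]]) {
    warning(sprintf("series span (%.0f s) is below 4x the initial tau guess (%.0f s); %s",
                    span, init[["taup"]], "estimates may be poorly identified"))
  }

  lower <- rep(-Inf, p); upper <- rep(Inf, p)
  names(lower) <- names(upper) <- spec$free
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  lower <- .to_internal(lower); upper <- .to_internal(upper)

  resid_fn <- function(par) {
    natural <- .from_internal(par)
    full <- merge_params(spec, c(natural, spec$fixed))
    r <- y - .eval_vo2_raw(spec, full, tt)
    if (any(!is.finite(r))) r[!is.finite(r)] <- 1e6
    r
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13, ptol = 1e-13)
  starts <- with_seed(seed, {
    c(list(init), lapply(seq_len(max(0, n_restarts - 1)),
                         function(i) .perturb_init(init, i)))
  })

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = .to_internal(s), fn = resid_fn,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ok <- res$info %in% 1:4 && is.finite(res$deviance)
    cand <- list(par = res$par, rss = res$deviance, converged = ok)
    if (is.null(best) ||
        (cand$converged && !best$converged) ||
        (cand$converged == best$converged && cand$rss < best$rss)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    best <- list(par = .to_internal(init), rss = sum(resid_fn(.to_internal(init))^2),
                 converged = FALSE)
  }
  estimates <- merge_params(spec, c(.from_internal(best$par), spec$fixed))
  fitted <- .eval_vo2_raw(spec, estimates, tt)
  rss <- sum((y - fitted)^2)
  structure(
    list(spec = spec, estimates = estimates, rss = rss,
         ser = sqrt(rss / (n - p)), n = n, p = p,
         residuals = y - fitted, fitted = fitted,
         converged = best$converged, n_restarts_used = length(starts),
         t0 = u$t0, dt = u$dt),
    class = "vo2_fit"
  )
}

#' @export
print.vo2_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<vo2_fit> %s-transient %s on %d points%s\n",
              x$spec$direction, x$spec$form, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$estimates, digits))
  cat(sprintf("  RSS = %.6g   SER = %.6g (n = %d, p = %d)\n", x$rss, x$ser, x$n, x$p))
  invisible(x)
}

#' Predicted values from a fitted model
#' @param object A `vo2_fit`.
#' @param t Times in seconds (default: the fitted grid).
#' @param ... Unused.
#' @export
predict.vo2_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$t0 + object$dt * (seq_len(object$n) - 1L)
  .eval_vo2_raw(object$spec, object$estimates, t)
}

# TRUE when the `simple` form is nested in the `complex` form.
.is_nested_form <- function(simple, complex) {
  nesting <- list(
    MONO_NO_TD   = c("MONO_TD", "BIEXP_NO_TDP", "BIEXP_TD"),
    MONO_TD      = "BIEXP_TD",
    BIEXP_NO_TDP = "BIEXP_TD",
    BIEXP_TD     = character(0)
  )
  complex %in% nesting[[simple]]
}

#' Extra-sum-of-squares F-test between nested fits
#'
#' Compares a simpler model nested in a more complex one, both fitted to the
#' same series: `F = ((RSS1 - RSS2)/(p2 - p1)) / (RSS2/(n - p2))`, with the
#' p-value from the upper tail of the F distribution. A perfect complex fit
#' (`RSS2 = 0`) against an imperfect simple one yields `F = Inf`, `p = 0`.
#'
#' @param simple,complex `vo2_fit` objects for nested forms on identical
#'   data.
#' @return An object of class `vo2_model_comparison` with elements `F`,
#'   `df1`, `df2`, `p_value` and the two fits' forms and RSS values.
#' @export
f_test_nested <- function(simple, complex) {
  stopifnot(inherits(simple, "vo2_fit"), inherits(complex, "vo2_fit"))
  if (simple$spec$direction != complex$spec$direction ||
      !.is_nested_form(simple$spec$form, complex$spec$form)) {
    stop("models are not nested (", simple$spec$form, " vs ", complex$spec$form, ")",
         call. = FALSE)
  }
  if (simple$n != complex$n || simple$t0 != complex$t0 || simple$dt != complex$dt) {
    stop("fits are not on the same data grid", call. = FALSE)
  }
  df1 <- complex$p - simple$p
  df2 <- complex$n - complex$p
  if (df1 <= 0 || df2 <= 0) stop("invalid degrees of freedom", call. = FALSE)
  if (complex$rss == 0) {
    Fv <- if (simple$rss > 0) Inf else 0
  } else {
    Fv <- max(0, ((simple$rss - complex$rss) / df1) / (complex$rss / df2))
  }
  pv <- if (is.infinite(Fv)) 0 else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  structure(
    list(simple_form = simple$spec$form, complex_form = complex$spec$form,
         F = Fv, df1 = df1, df2 = df2, p_value = pv,
         rss_simple = simple$rss, rss_complex = complex$rss),
    class = "vo2_model_comparison"
  )
}

#' @export
print.vo2_model_comparison <- function(x, ...) {
  cat(sprintf("<vo2_model_comparison> %s vs %s: F(%d,%d) = %.4g, p = %.4g\n",
              x$simple_form, x$complex_form, x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' Fit all four transient models and select the best
#'
#' Fits the four model forms for one direction and selects, among the
#' converged fits whose estimates lie inside the physiological parameter
#' space (see [validate_params()]; e.g. a negative slow-component amplitude
#' disqualifies a bi-exponential fit), the one with the lowest standard
#' error of regression. If no converged fit passes the validity screen, all
#' converged fits are admitted.
#' A parsimony rule then resolves near-ties: if a converged simpler model
#' nested in the winner is not significantly worse by the extra-sum-of-
#' squares F-test at level `alpha` (or both fits are numerically perfect,
#' SER below 1e-6), the simplest such model is preferred.
#'
#' @param u A [uniform_series()].
#' @param direction `"on"` or `"off"`.
#' @param alpha Significance level for the nested F-test tie-break
#'   (default 0.05).
#' @param n_restarts,seed Passed to [fit_vo2()].
#' @return An object of class `vo2_selection`: `best` (the selected
#'   `vo2_fit`), `fits` (all four), and `table`, a data frame reporting each
#'   form's convergence, RSS and SER with the selected row flagged.
#' @export
select_best <- function(u, direction = c("off", "on"), alpha = 0.05,
                        n_restarts = 5, seed = 1L) {
  direction <- match.arg(direction)
  specs <- list_models(direction)
  fits <- lapply(specs, function(sp) {
    suppressWarnings(fit_vo2(u, sp, n_restarts = n_restarts, seed = seed))
  })
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(conv)) {
    stop("no model converged; SERs at final iterates: ",
         paste(sprintf("%s=%.3g", names(fits),
                       vapply(fits, function(f) f$ser, numeric(1))),
               collapse = ", "),
         call. = FALSE)
  }
  sers <- vapply(fits, function(f) f$ser, numeric(1))
  # a converged fit only represents its physiological model if the
  # estimates lie inside the parameter space (e.g. non-negative slow
  # amplitude); invalid fits are reported but not selectable
  valid <- vapply(fits, function(f) {
    tryCatch({ validate_params(f$spec, f$estimates); TRUE },
             error = function(e) FALSE)
  }, logical(1))
  cand <- names(fits)[conv & valid]
  if (!length(cand)) cand <- names(fits)[conv]
  best_form <- cand[which.min(sers[cand])]
  # parsimony: repeatedly step down to the simplest converged nested model
  # that is not significantly worse than the current choice, until no
  # further simplification is possible
  perfect_tol <- 1e-6
  repeat {
    stepped <- FALSE
    for (form in .vo2_forms) {
      if (form == best_form) break
      if (!(form %in% cand) || !.is_nested_form(form, best_form)) next
      equivalent <- if (fits[[form]]$ser <= perfect_tol &&
                        fits[[best_form]]$ser <= perfect_tol) {
        TRUE
      } else {
        f_test_nested(fits[[form]], fits[[best_form]])$p_value > alpha
      }
      if (equivalent) {
        best_form <- form
        stepped <- TRUE
        break
      }
    }
    if (!stepped) break
  }
  table <- data.frame(
    form = names(fits),
    p_free = vapply(fits, function(f) f$p, integer(1)),
    converged = conv,
    valid = valid,
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    ser = sers,
    selected = names(fits) == best_form,
    row.names = NULL
  )
  structure(
    list(best = fits[[best_form]], fits = fits, table = table,
         direction = direction, alpha = alpha),
    class = "vo2_selection"
  )
}

#' @export
print.vo2_selection <- function(x, ...) {
  cat(sprintf("<vo2_selection> %s-transient, best model: %s\n",
              x$direction, x$best$spec$form))
  print(x$table, digits = 5)
  invisible(x)
}

#' Coefficient of variation of replicate estimates
#'
#' `100 * sd(values) / mean(values)` (sample SD), as a percentage.
#'
#' @param values Numeric vector of replicate parameter estimates (>= 2
#'   values, non-zero mean).
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Write a fit or selection report as JSON
#'
#' Machine-readable report: the model spec, estimates, goodness of fit and
#' (for selections) the per-model comparison table, tagged with the package
#' version.
#'
#' @param x A `vo2_fit` or `vo2_selection`.
#' @param path Output path.
#' @param extra Optional named list merged into the report (e.g. a run
#'   configuration for provenance).
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(x, path, extra = NULL) {
  report <- if (inherits(x, "vo2_selection")) {
    c(fit_report_list(x$best), list(selection = x$table, alpha = x$alpha))
  } else if (inherits(x, "vo2_fit")) {
    fit_report_list(x)
  } else {
    stop("x must be a vo2_fit or vo2_selection", call. = FALSE)
  }
  report$package_version <- as.character(utils::packageVersion("vo2kinetics"))
  if (length(extra)) report <- c(report, extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

fit_report_list <- function(fit) {
  list(
    direction = fit$spec$direction,
    form = fit$spec$form,
    estimates = as.list(fit$estimates),
    rss = fit$rss, ser = fit$ser, n = fit$n, p = fit$p,
    converged = fit$converged
  )
}

#' One-row flat summary of a fit
#'
#' A single delimited-friendly row (form, convergence, estimates, RSS, SER)
#' for spreadsheet use; absent parameters are `NA`.
#'
#' @param fit A `vo2_fit`.
#' @return A one-row data frame.
#' @export
fit_summary_row <- function(fit) {
  stopifnot(inherits(fit, "vo2_fit"))
  all_names <- c("EEVO2", "VO2base", "Ap", "TDp", "taup", "Asc", "TDsc", "tausc")
  est <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
  est[names(fit$estimates)] <- fit$estimates
  cbind(
    data.frame(direction = fit$spec$direction, form = fit$spec$form,
               converged = fit$converged, n = fit$n, p = fit$p),
    as.data.frame(as.list(est)),
    data.frame(rss = fit$rss, ser = fit$ser)
  )
}
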