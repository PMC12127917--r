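#' Heaviside step function
#'
#' Right-continuous Heaviside step: 0 for negative arguments, 1 at and above
#' zero. Used to gate the delayed exponential components of the transient
#' models so that a component contributes nothing before its time delay.
#'
#' @param x Numeric vector (seconds relative to a time delay).
#' @return Integer vector of 0/1 values, same length as `x`.
#' @examples
#' heaviside(c(-5, 0, 3))
#' @export
heaviside <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("heaviside() requires finite numeric input", call. = FALSE)
  }
  as.integer(x >= 0)
}

# Canonical model form identifiers, in nesting order (simple -> complex).
.vo2_forms <- c("MONO_NO_TD", "MONO_TD", "BIEXP_NO_TDP", "BIEXP_TD")

# Gated exponential component: A * (1 - exp(-(t - TD)/tau)) for t >= TD,
# exactly 0 before TD. Computed branch-wise rather than by multiplying with
# heaviside() so that exp() overflow at t << TD cannot produce NaN.
.exp_component <- function(t, A, TD, tau) {
  out <- numeric(length(t))
  i <- t >= TD
  if (any(i)) out[i] <- A * (1 - exp(-(t[i] - TD) / tau))
  out
}

#' Construct a transient model specification
#'
#' A model specification identifies one of the eight supported oxygen-uptake
#' transient models: the crossing of direction (`"on"` for exercise onset,
#' `"off"` for recovery) with four functional forms,
#' \describe{
#'   \item{MONO_NO_TD}{mono-exponential, primary time delay fixed at 0;}
#'   \item{MONO_TD}{mono-exponential with free primary time delay;}
#'   \item{BIEXP_NO_TDP}{bi-exponential (adds a delayed slow component),
#'     primary time delay fixed at 0;}
#'   \item{BIEXP_TD}{bi-exponential with both time delays free.}
#' }
#' Off-transient models describe recovery as a plateau (`EEVO2`, the
#' end-exercise oxygen uptake) minus gated exponential decays; on-transient
#' models mirror them as a baseline (`VO2base`) plus gated exponential rises.
#'
#' @param direction `"on"` or `"off"`.
#' @param form One of `"MONO_NO_TD"`, `"MONO_TD"`, `"BIEXP_NO_TDP"`,
#'   `"BIEXP_TD"`.
#' @return An object of class `vo2_model_spec`: a list with elements
#'   `direction`, `form`, `free` (ordered free parameter names) and `fixed`
#'   (named numeric vector of fixed parameters, e.g. `TDp = 0`).
#' @seealso [list_models()], [eval_vo2()]
#' @examples
#' vo2_model("off", "MONO_NO_TD")
#' @export
vo2_model <- function(direction = c("off", "on"), form = .vo2_forms) {
  direction <- match.arg(direction)
  form <- match.arg(form)
  base <- if (direction == "off") "EEVO2" else "VO2base"
  free <- switch(form,
    MONO_NO_TD   = c(base, "Ap", "taup"),
    MONO_TD      = c(base, "Ap", "TDp", "taup"),
    BIEXP_NO_TDP = c(base, "Ap", "taup", "Asc", "TDsc", "tausc"),
    BIEXP_TD     = c(base, "Ap", "TDp", "taup", "Asc", "TDsc", "tausc")
  )
  fixed <- if (form %in% c("MONO_NO_TD", "BIEXP_NO_TDP")) c(TDp = 0) else numeric(0)
  structure(
    list(direction = direction, form = form, free = free, fixed = fixed),
    class = "vo2_model_spec"
  )
}

#' @export
print.vo2_model_spec <- function(x, ...) {
  cat(sprintf("<vo2_model_spec> %s-transient %s\n", x$direction, x$form))
  cat("  free : ", paste(x$free, collapse = ", "), "\n", sep = "")
  if (length(x$fixed)) {
    cat("  fixed: ", paste(names(x$fixed), x$fixed, sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Enumerate the supported transient models
#'
#' Returns the four model specifications for one direction, ordered from
#' simplest to most complex so that each earlier mono form is nested in the
#' later forms that extend it (`MONO_NO_TD` in `MONO_TD`, and the
#' bi-exponential pair analogously).
#'
#' @param direction `"on"` or `"off"`.
#' @return Named list of four [vo2_model()] specifications.
#' @examples
#' names(list_models("off"))
#' @export
list_models <- function(direction = c("off", "on")) {
  direction <- match.arg(direction)
  specs <- lapply(.vo2_forms, function(f) vo2_model(direction, f))
  names(specs) <- .vo2_forms
  specs
}

# All parameter names a spec references (free then fixed).
model_param_names <- function(spec) {
  c(spec$free, names(spec$fixed))
}

#' Validate a parameter set against a model specification
#'
#' Checks that the parameters cover every parameter the form references and
#' satisfy the physiological invariants: primary amplitude and time constant
#' strictly positive, time delays non-negative, and (for bi-exponential
#' forms) non-negative slow amplitude, positive slow time constant and a
#' slow-component delay at or after the primary delay.
#'
#' @param spec A [vo2_model()] specification.
#' @param params Named numeric vector of parameter values.
#' @return Invisibly, the full parameter vector (free + fixed) in canonical
#'   order. Errors if a parameter is missing, non-finite, or violates an
#'   invariant.
#' @export
validate_params <- function(spec, params) {
  full <- merge_params(spec, params)
  if (any(!is.finite(full))) {
    stop("non-finite parameter value(s): ",
         paste(names(full)[!is.finite(full)], collapse = ", "), call. = FALSE)
  }
  if (full[["Ap"]] <= 0) stop("invalid parameters: Ap must be > 0", call. = FALSE)
  if (full[["taup"]] <= 0) stop("invalid parameters: taup must be > 0", call. = FALSE)
  if (full[["TDp"]] < 0) stop("invalid parameters: TDp must be >= 0", call. = FALSE)
  if ("Asc" %in% names(full)) {
    if (full[["Asc"]] < 0) stop("invalid parameters: Asc must be >= 0", call. = FALSE)
    if (full[["tausc"]] <= 0) stop("invalid parameters: tausc must be > 0", call. = FALSE)
    if (full[["TDsc"]] < full[["TDp"]]) {
      stop("invalid parameters: TDsc must be >= TDp", call. = FALSE)
    }
  }
  invisible(full)
}

# Merge user-supplied free parameters with the spec's fixed parameters into
# the canonical full vector; errors on missing names. Extra names are
# ignored and fixed values take precedence, so a full preset can be passed
# to a reduced form.
merge_params <- function(spec, params) {
  if (is.list(params)) params <- unlist(params)
  need <- model_param_names(spec)
  fixed <- spec$fixed
  vals <- vapply(need, function(nm) {
    if (nm %in% names(fixed)) {
      unname(fixed[[nm]])
    } else if (nm %in% names(params)) {
      unname(params[[nm]])
    } else {
      stop("missing parameter '", nm, "' for form ", spec$form, call. = FALSE)
    }
  }, numeric(1))
  names(vals) <- need
  vals
}

# Raw (non-validating) evaluation used by the fitter, which must be able to
# probe parameter values outside the physiological region.
.eval_vo2_raw <- function(spec, full, t) {
  prim <- .exp_component(t, full[["Ap"]], full[["TDp"]], full[["taup"]])
  slow <- if ("Asc" %in% names(full)) {
    .exp_component(t, full[["Asc"]], full[["TDsc"]], full[["tausc"]])
  } else {
    0
  }
  if (spec$direction == "off") {
    full[[1L]] - prim - slow
  } else {
    full[[1L]] + prim + slow
  }
}

#' Evaluate a transient model
#'
#' Closed-form evaluation of an on- or off-transient oxygen-uptake model at
#' times `t`. Time zero is the transition: exercise onset for on-transient
#' models, exercise cessation for off-transient models. Before the primary
#' time delay the curve equals the plateau exactly (`EEVO2` for off,
#' `VO2base` for on); off-transient curves are non-increasing and
#' on-transient curves non-decreasing in `t`.
#'
#' @param spec A [vo2_model()] specification.
#' @param params Named numeric vector (or list) of parameter values covering
#'   the spec's free parameters; fixed parameters are taken from the spec.
#'   Units: amplitudes and plateaus in mL·kg⁻¹·min⁻¹, delays and time
#'   constants in seconds.
#' @param t Numeric vector of times in seconds.
#' @param validate Check parameter invariants before evaluating (default
#'   `TRUE`).
#' @return Numeric vector of oxygen-uptake values, mL·kg⁻¹·min⁻¹.
#' @examples
#' spec <- vo2_model("off", "MONO_NO_TD")
#' eval_vo2(spec, c(EEVO2 = 51.0, Ap = 40.3, taup = 37.0), t = c(0, 37, 180))
#' @export
eval_vo2 <- function(spec, params, t, validate = TRUE) {
  stopifnot(inherits(spec, "vo2_model_spec"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("t must be finite numeric", call. = FALSE)
  }
  full <- if (validate) validate_params(spec, params) else merge_params(spec, params)
  .eval_vo2_raw(spec, full, t)
}

#' Serialize a model specification to JSON
#'
#' @param spec A [vo2_model()] specification.
#' @return A JSON string with fields `direction`, `form` and `fixed`.
#' @seealso [model_from_json()]
#' @export
model_to_json <- function(spec) {
  stopifnot(inherits(spec, "vo2_model_spec"))
  jsonlite::toJSON(
    list(direction = spec$direction, form = spec$form, fixed = as.list(spec$fixed)),
    auto_unbox = TRUE
  )
}

#' Deserialize a model specification from JSON
#'
#' @param txt JSON string as produced by [model_to_json()].
#' @return A [vo2_model()] specification.
#' @export
model_from_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt)
  spec <- vo2_model(doc$direction, doc$form)
  if (length(doc$fixed)) {
    given <- unlist(doc$fixed)
    if (!isTRUE(all.equal(given[names(spec$fixed)], spec$fixed,
                          check.attributes = FALSE))) {
      stop("fixed parameters in JSON do not match form ", doc$form, call. = FALSE)
    }
  }
  spec
}
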