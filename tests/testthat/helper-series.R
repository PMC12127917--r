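# Shared fixtures: model-generated series used across the suite.

severe_off_truth <- c(EEVO2 = 51.0, Ap = 40.3, taup = 37.0)

# Noise-free uniform series from a spec + truth on a 1-s grid.
make_series <- function(spec, truth, duration = 180) {
  uniform_series(0, 1, eval_vo2(spec, truth, seq(0, duration)))
}

# Quietly fitted model (the span/tau warning is irrelevant for fixtures).
quiet_fit <- function(...) suppressWarnings(fit_vo2(...))

# Truth vector restricted to a spec's free parameters (fixed values merged).
free_truth <- function(spec, truth) {
  vo2kinetics:::merge_params(spec, truth)[spec$free]
}
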