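test_that("heaviside follows the right-continuous convention", {
  expect_identical(heaviside(c(-5, 0, 3)), c(0L, 1L, 1L))
  expect_error(heaviside(NA_real_), "finite")
  expect_error(heaviside(Inf), "finite")
})

test_that("off-transient evaluation matches hand-computed values", {
  spec <- vo2_model("off", "MONO_NO_TD")
  # boundary: full plateau at exercise cessation
  expect_equal(eval_vo2(spec, severe_off_truth, 0), 51.0)
  # one time constant into recovery: EEVO2 - Ap*(1 - exp(-1))
  expect_equal(eval_vo2(spec, severe_off_truth, 37),
               51.0 - 40.3 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(round(eval_vo2(spec, severe_off_truth, 37), 2), 25.53)
  # asymptote EEVO2 - Ap
  expect_equal(eval_vo2(spec, severe_off_truth, 1e6), 10.7, tolerance = 1e-6)
})

test_that("on-transient evaluation matches hand-computed values", {
  spec <- vo2_model("on", "MONO_TD")
  p <- c(VO2base = 10, Ap = 30, TDp = 20, taup = 15)
  expect_identical(eval_vo2(spec, p, 10), 10)      # before the delay
  expect_equal(eval_vo2(spec, p, 35), 10 + 30 * (1 - exp(-1)), tolerance = 1e-12)
  # degenerate slow component reduces BIEXP_TD to MONO_TD pointwise
  bi <- vo2_model("on", "BIEXP_TD")
  pb <- c(p, Asc = 0, TDsc = 60, tausc = 40)
  tt <- seq(0, 600)
  expect_equal(eval_vo2(bi, pb, tt), eval_vo2(spec, p, tt), tolerance = 1e-14)
})

test_that("gating is exact: plateau before the primary delay", {
  for (dir in c("off", "on")) {
    spec <- vo2_model(dir, "BIEXP_TD")
    base <- if (dir == "off") c(EEVO2 = 48) else c(VO2base = 9)
    p <- c(base, Ap = 35, TDp = 17.5, taup = 25, Asc = 6, TDsc = 90, tausc = 50)
    tt <- seq(0, 17.4, by = 0.1)
    expect_identical(eval_vo2(spec, p, tt), rep(unname(base), length(tt)))
  }
})

test_that("model list covers four nested forms per direction", {
  off <- list_models("off")
  expect_named(off, c("MONO_NO_TD", "MONO_TD", "BIEXP_NO_TDP", "BIEXP_TD"))
  expect_equal(unname(vapply(off, function(s) length(s$free), integer(1))),
               c(3L, 4L, 6L, 7L))
  expect_true(all(vapply(off, function(s) "EEVO2" %in% s$free, logical(1))))
  expect_identical(off$MONO_NO_TD$fixed, c(TDp = 0))
  expect_identical(off$BIEXP_NO_TDP$fixed, c(TDp = 0))

  on <- list_models("on")
  expect_true(all(vapply(on, function(s) "VO2base" %in% s$free, logical(1))))
})

test_that("nested forms agree where the extra parameters vanish", {
  tt <- seq(0, 600)
  truth <- c(severe_off_truth, TDp = 0)
  expect_equal(
    eval_vo2(vo2_model("off", "MONO_TD"), truth, tt),
    eval_vo2(vo2_model("off", "MONO_NO_TD"), truth, tt),
    tolerance = 1e-14
  )
  bi <- c(severe_off_truth, Asc = 0, TDsc = 90, tausc = 60)
  expect_equal(
    eval_vo2(vo2_model("off", "BIEXP_NO_TDP"), bi, tt),
    eval_vo2(vo2_model("off", "MONO_NO_TD"), severe_off_truth, tt),
    tolerance = 1e-14
  )
})

test_that("off forms are non-increasing and on forms non-decreasing", {
  set.seed(42)
  tt <- seq(0, 600, by = 2)
  for (rep in 1:25) {
    p <- c(
      EEVO2 = runif(1, 35, 60), VO2base = runif(1, 5, 15),
      Ap = runif(1, 20, 45), TDp = runif(1, 0, 25), taup = runif(1, 8, 60),
      Asc = runif(1, 0, 12), tausc = runif(1, 30, 200)
    )
    p <- c(p, TDsc = unname(p["TDp"]) + runif(1, 0, 150))
    for (form in c("MONO_NO_TD", "MONO_TD", "BIEXP_NO_TDP", "BIEXP_TD")) {
      d_off <- diff(eval_vo2(vo2_model("off", form), p, tt))
      d_on <- diff(eval_vo2(vo2_model("on", form), p, tt))
      expect_true(all(d_off <= 1e-12))
      expect_true(all(d_on >= -1e-12))
    }
  }
})

test_that("evaluation matches an independently transcribed expression", {
  # independent oracle: literal transcription of the gated bi-exponential,
  # scalar arithmetic with explicit Heaviside factors
  oracle <- function(dir, EE, Ap, TDp, taup, Asc, TDsc, tausc, t) {
    H <- function(z) if (z >= 0) 1 else 0
    prim <- H(t - TDp) * Ap * (1 - exp(-(t - TDp) / taup))
    slow <- if (is.na(Asc)) 0 else H(t - TDsc) * Asc * (1 - exp(-(t - TDsc) / tausc))
    if (dir == "off") EE - prim - slow else EE + prim + slow
  }
  set.seed(7)
  for (rep in 1:1000) {
    dir <- sample(c("off", "on"), 1)
    form <- sample(c("MONO_NO_TD", "MONO_TD", "BIEXP_NO_TDP", "BIEXP_TD"), 1)
    spec <- vo2_model(dir, form)
    TDp <- if ("TDp" %in% spec$free) runif(1, 0, 30) else 0
    p <- c(runif(1, 5, 60), Ap = runif(1, 15, 45), TDp = TDp,
           taup = runif(1, 5, 80))
    names(p)[1] <- spec$free[1]
    bi <- grepl("BIEXP", form)
    if (bi) p <- c(p, Asc = runif(1, 0, 15), TDsc = TDp + runif(1, 0, 150),
                   tausc = runif(1, 20, 300))
    t <- runif(1, 0, 400)
    got <- eval_vo2(spec, p, t)
    want <- oracle(dir, p[[1]], p[["Ap"]], TDp, p[["taup"]],
                   if (bi) p[["Asc"]] else NA, if (bi) p[["TDsc"]] else NA,
                   if (bi) p[["tausc"]] else NA, t)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("parameter invariants are enforced", {
  spec <- vo2_model("off", "BIEXP_TD")
  ok <- c(EEVO2 = 50, Ap = 40, TDp = 5, taup = 30, Asc = 5, TDsc = 90, tausc = 60)
  expect_silent(validate_params(spec, ok))
  bad <- ok; bad[["Ap"]] <- -1
  expect_error(validate_params(spec, bad), "Ap")
  bad <- ok; bad[["taup"]] <- 0
  expect_error(validate_params(spec, bad), "taup")
  bad <- ok; bad[["TDsc"]] <- 2   # before the primary delay
  expect_error(validate_params(spec, bad), "TDsc")
  expect_error(validate_params(spec, ok[-1]), "missing parameter")
})

test_that("model specs round-trip through JSON", {
  for (dir in c("off", "on")) for (form in names(list_models(dir))) {
    spec <- vo2_model(dir, form)
    back <- model_from_json(model_to_json(spec))
    expect_identical(back$direction, spec$direction)
    expect_identical(back$form, spec$form)
    expect_identical(back$free, spec$free)
    expect_equal(back$fixed, spec$fixed)
  }
})
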