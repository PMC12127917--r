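#' Paired t-test
#'
#' Student's paired t-test for on/off comparisons of kinetic parameters:
#' `t = mean(d) / (sd(d)/sqrt(n))` on the paired differences `d = x - y`,
#' with a two-sided p-value on `n - 1` degrees of freedom.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2) whose
#'   differences have non-zero SD.
#' @return List with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  .check_paired(x, y)
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(ht$estimate))
}

.check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate test: paired differences have zero SD", call. = FALSE)
  }
  invisible(d)
}

#' Paired Cohen's d with confidence interval
#'
#' Standardized effect size for paired data, `d = mean(x - y) / sd(x - y)`
#' (difference-SD standardizer), with a normal-approximation confidence
#' interval using `se(d) = sqrt(1/n + d^2/(2n))`. The standardizer and CI
#' method are recorded in the output.
#'
#' @param x,y Paired numeric vectors (as in [paired_t()]).
#' @param level Confidence level, default 0.95.
#' @return List with `d`, `ci` (lower/upper), `level`, `standardizer`,
#'   `ci_method`.
#' @export
cohens_d_paired <- function(x, y, level = 0.95) {
  d <- .check_paired(x, y)
  n <- length(d)
  es <- mean(d) / stats::sd(d)
  se <- sqrt(1 / n + es^2 / (2 * n))
  z <- stats::qnorm((1 + level) / 2)
  list(d = es, ci = c(lower = es - z * se, upper = es + z * se), level = level,
       standardizer = "difference SD", ci_method = "normal approximation")
}

#' Hochberg step-up multiplicity correction
#'
#' Step-up procedure on a family of p-values: with the p-values sorted
#' ascending, all hypotheses `1..k` are rejected for the largest `k` such
#' that `p(k) <= alpha / (m - k + 1)`. Adjusted p-values (monotone,
#' capped at 1) are computed with [stats::p.adjust()]; a hypothesis is
#' rejected exactly when its adjusted p-value is at or below `alpha`.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param alpha Family-wise error level, default 0.05.
#' @return List with `adjusted` (same order as input) and `rejected`
#'   (logical).
#' @export
hochberg_adjust <- function(p_values, alpha = 0.05) {
  if (!is.numeric(p_values) || !length(p_values)) {
    stop("p_values must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adjusted <- stats::p.adjust(p_values, method = "hochberg")
  list(adjusted = adjusted, rejected = adjusted <= alpha)
}

#' Pearson correlation with least-squares line
#'
#' Product-moment correlation `r`, determination `r^2`, two-sided p-value,
#' and the ordinary least-squares regression line of `y` on `x`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r`, `r2`, `p_value`, `slope`, `intercept`, `n`.
#' @export
pearson_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  co <- stats::coef(stats::lm(y ~ x))
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p_value = ct$p.value, slope = unname(co[2]), intercept = unname(co[1]),
       n = length(x))
}

#' On/off symmetry table across intensity domains
#'
#' Builds the full symmetry characterization for a cohort: for every kinetic
#' parameter measured in both directions, the per-domain on and off means
#' and SDs with a paired t-test and paired Cohen's d (95% CI); and, for each
#' parameter and direction, the paired contrasts between consecutive
#' intensity domains with a Hochberg step-up correction applied within each
#' (parameter, direction) contrast family.
#'
#' @param data Long-format data frame with columns `subject`, `domain`,
#'   `parameter`, `direction` (`"on"`/`"off"`) and `value`. Subjects must be
#'   matched within each (parameter, domain) pair and across consecutive
#'   domains.
#' @param domain_order Character vector giving the intensity domains in
#'   increasing order (default `c("low", "moderate", "heavy", "severe")`).
#' @param alpha Significance level for the Hochberg correction (default
#'   0.05).
#' @param level Confidence level for effect-size CIs (default 0.95).
#' @return List of two data frames: `symmetry` (per parameter x domain:
#'   on/off mean, SD, paired p, d, d CI) and `contrasts` (per parameter x
#'   direction x consecutive-domain pair: raw and Hochberg-adjusted p, d,
#'   d CI).
#' @export
symmetry_table <- function(data, domain_order = c("low", "moderate", "heavy", "severe"),
                           alpha = 0.05, level = 0.95) {
  need <- c("subject", "domain", "parameter", "direction", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  domains <- domain_order[domain_order %in% unique(data$domain)]

  pull <- function(par, dom, dir) {
    sub <- data[data$parameter == par & data$domain == dom & data$direction == dir, ]
    sub <- sub[order(sub$subject), ]
    stats::setNames(sub$value, sub$subject)
  }

  # on vs off within each domain
  sym_rows <- list()
  both <- intersect(unique(data$parameter[data$direction == "on"]),
                    unique(data$parameter[data$direction == "off"]))
  for (par in both) {
    for (dom in domains) {
      on <- pull(par, dom, "on"); off <- pull(par, dom, "off")
      if (!length(on) || !length(off)) next
      if (length(on) != length(off) || !identical(names(on), names(off))) {
        stop("mismatched subject pairing for ", par, " at ", dom, call. = FALSE)
      }
      tt <- tryCatch(paired_t(on, off), error = function(e) NULL)
      es <- tryCatch(cohens_d_paired(on, off, level), error = function(e) NULL)
      if (is.null(tt)) {
        warning("degenerate on/off test for ", par, " at ", dom,
                " (zero difference SD)")
      }
      sym_rows[[length(sym_rows) + 1L]] <- data.frame(
        parameter = par, domain = dom, n = length(on),
        on_mean = mean(on), on_sd = stats::sd(on),
        off_mean = mean(off), off_sd = stats::sd(off),
        p = if (is.null(tt)) NA_real_ else tt$p_value,
        d = if (is.null(es)) 0 else es$d,
        d_lower = if (is.null(es)) NA_real_ else es$ci[["lower"]],
        d_upper = if (is.null(es)) NA_real_ else es$ci[["upper"]]
      )
    }
  }

  # consecutive-domain contrasts within each parameter x direction
  con_rows <- list()
  for (par in unique(data$parameter)) {
    for (dir in intersect(c("on", "off"), unique(data$direction[data$parameter == par]))) {
      fam <- list()
      for (i in seq_len(length(domains) - 1L)) {
        a <- pull(par, domains[i], dir); b <- pull(par, domains[i + 1L], dir)
        if (!length(a) || !length(b)) next
        if (length(a) != length(b) || !identical(names(a), names(b))) {
          stop("mismatched subject pairing for ", par, " ", dir, " across domains",
               call. = FALSE)
        }
        tt <- tryCatch(paired_t(a, b), error = function(e) NULL)
        es <- tryCatch(cohens_d_paired(a, b, level), error = function(e) NULL)
        fam[[length(fam) + 1L]] <- data.frame(
          parameter = par, direction = dir,
          contrast = paste(domains[i], "vs", domains[i + 1L]),
          p_raw = if (is.null(tt)) NA_real_ else tt$p_value,
          d = if (is.null(es)) 0 else es$d,
          d_lower = if (is.null(es)) NA_real_ else es$ci[["lower"]],
          d_upper = if (is.null(es)) NA_real_ else es$ci[["upper"]]
        )
      }
      if (!length(fam)) next
      fam <- do.call(rbind, fam)
      okp <- !is.na(fam$p_raw)
      fam$p_adjusted <- NA_real_
      fam$rejected <- NA
      if (any(okp)) {
        h <- hochberg_adjust(fam$p_raw[okp], alpha)
        fam$p_adjusted[okp] <- h$adjusted
        fam$rejected[okp] <- h$rejected
      }
      con_rows[[length(con_rows) + 1L]] <- fam
    }
  }

  list(
    symmetry = if (length(sym_rows)) do.call(rbind, sym_rows) else NULL,
    contrasts = if (length(con_rows)) do.call(rbind, con_rows) else NULL,
    alpha = alpha, level = level,
    effect_size = "Cohen's d, difference-SD standardizer, normal-approximation CI"
  )
}

#' Write a symmetry table as delimited text
#'
#' @param x Result of [symmetry_table()].
#' @param path Output path; the contrasts block follows the symmetry block,
#'   separated by a `#` header line.
#' @return Invisibly, `path`.
#' @export
write_symmetry_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# on/off symmetry (alpha = %g; %s)", x$alpha, x$effect_size), con)
  if (!is.null(x$symmetry)) {
    utils::write.table(x$symmetry, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines("# consecutive-domain contrasts (Hochberg step-up within family)", con)
  if (!is.null(x$contrasts)) {
    utils::write.table(x$contrasts, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
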