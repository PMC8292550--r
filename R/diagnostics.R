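## Residual diagnostics and replicate aggregation for global fits.

#' Wald-Wolfowitz runs-test z statistic on residual signs
#'
#' Counts runs of consecutive same-sign residuals (zeros dropped) and
#' standardises against the null of random sign order. Structured residuals
#' (long same-sign stretches) give large negative z; over-alternating
#' residuals give large positive z.
#'
#' @param x numeric residual vector.
#' @return z statistic, or `NA` if fewer than 10 usable points or all
#'   residuals share one sign (the latter with a `degenerate` attribute; a
#'   single-sign trace of usable length is maximally structured and is
#'   flagged by [residual_diagnostics()]).
#' @export
runs_test_z <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n <- length(s)
  if (n < 10) return(NA_real_)
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0L || n2 == 0L)
    return(structure(NA_real_, degenerate = "single-sign"))
  runs <- 1L + sum(s[-1] != s[-n])
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  (runs - mu) / sqrt(v)
}

#' Lag-1 autocorrelation of a residual trace
#'
#' @param x numeric vector.
#' @return lag-1 autocorrelation; 0 (with a `degenerate` attribute) when the
#'   trace has zero variance.
#' @export
lag1_autocorr <- function(x) {
  n <- length(x)
  if (n < 2) return(structure(0, degenerate = "too-short"))
  x <- x - mean(x)
  v <- sum(x * x)
  if (v <= 0) return(structure(0, degenerate = "zero-variance"))
  sum(x[-1] * x[-n]) / v
}

#' Residual diagnostics for a global fit
#'
#' Screens each curve's fit residuals for systematic divergence from the
#' binding model: the Wald-Wolfowitz runs-test z on residual signs and the
#' lag-1 autocorrelation. A curve is flagged `systematic` when |z| > `z_max`
#' or |lag-1 autocorrelation| > `acf_max`, or when all usable residuals
#' share one sign. Traces shorter than 10 points are skipped with a
#' warning.
#'
#' @param result a `global_fit_result` from [fit_global()], or a list of
#'   numeric residual vectors.
#' @param z_max runs-test flag threshold (default 3; calibrated to a <= 1
#'   percent false-positive rate on white noise).
#' @param acf_max lag-1 autocorrelation flag threshold (default 0.5).
#' @return A data.frame with one row per curve: `curve`, `n`,
#'   `runs_test_z`, `lag1_autocorr`, `systematic`.
#' @export
residual_diagnostics <- function(result, z_max = 3, acf_max = 0.5) {
  res <- if (inherits(result, "global_fit_result"))
    lapply(result$residuals, `[[`, "residual")
  else if (is.list(result)) result
  else list(as.numeric(result))
  out <- data.frame(curve = seq_along(res), n = lengths(res),
                    runs_test_z = NA_real_, lag1_autocorr = NA_real_,
                    systematic = NA)
  for (i in seq_along(res)) {
    x <- res[[i]]
    if (length(x) < 10) {
      warning("curve ", i, ": residual trace shorter than 10 points; ",
              "diagnostics skipped")
      next
    }
    z <- runs_test_z(x)
    a <- lag1_autocorr(x)
    single_sign <- identical(attr(z, "degenerate"), "single-sign")
    out$runs_test_z[i] <- as.numeric(z)
    out$lag1_autocorr[i] <- as.numeric(a)
    out$systematic[i] <- single_sign ||
      (is.finite(z) && abs(z) > z_max) ||
      (!is.null(a) && abs(as.numeric(a)) > acf_max &&
         is.null(attr(a, "degenerate")))
  }
  out
}

#' Aggregate kinetic parameters over replicate series
#'
#' Arithmetic mean and sample standard deviation of `k_on`, `k_off` and
#' `K_D` over independent experimental series, the way replicate kinetic
#' tables are reported. With a single replicate the mean is reported and
#' the SD is `NA` (an SD needs n >= 2). Note this between-series SD is
#' distinct from the per-fit standard errors in `param_sd`; both are
#' available and labelled.
#'
#' @param results list of `global_fit_result` objects (n >= 1).
#' @return A data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
aggregate_replicates <- function(results) {
  if (length(results) < 1L) stop("need at least one fit result")
  stopifnot(all(vapply(results, inherits, TRUE, "global_fit_result")))
  grab <- function(f) vapply(results, f, 0)
  vals <- list(k_on = grab(function(r) r$params$k_on),
               k_off = grab(function(r) r$params$k_off),
               K_D = grab(function(r) r$K_D))
  n <- length(results)
  data.frame(parameter = names(vals),
             mean = vapply(vals, mean, 0),
             sd = if (n >= 2) vapply(vals, sd, 0) else NA_real_,
             n = n, row.names = NULL)
}

#' Per-concentration K_D consistency check
#'
#' Fits each curve of a series individually (shared `Rmax` and `k_t` fixed
#' at the global estimates; `k_on`, `k_off` and the bulk offset free) and
#' compares the per-curve K_D with the global K_D. For a well-specified 1:1
#' interaction the fitted K_D is independent of analyte concentration;
#' concentration-dependent K_D (or `Rmax`) indicates a model violation.
#'
#' @param series a [referenced_series()].
#' @param model as in [fit_global()].
#' @param global a precomputed `global_fit_result`, or `NULL` to fit here.
#' @param ... passed to [fit_global()].
#' @return A data.frame with one row per curve: `concentration_M`, `K_D`,
#'   `ratio_to_global`.
#' @export
concentration_independence_check <- function(series,
                                             model = c("two_compartment",
                                                       "langmuir"),
                                             global = NULL, ...) {
  model <- match.arg(model)
  if (is.null(global)) global <- fit_global(series, model, ...)
  p <- global$params
  out <- data.frame(concentration_M = NA_real_, K_D = NA_real_,
                    ratio_to_global = NA_real_)[0, ]
  for (cv in series$curves) {
    fit <- fit_single_curve(cv, model, p)
    out <- rbind(out, data.frame(concentration_M = cv$concentration,
                                 K_D = fit$K_D,
                                 ratio_to_global = fit$K_D / global$K_D))
  }
  out
}

## Individual-curve fit with Rmax and k_t pinned to the global estimates.
fit_single_curve <- function(cv, model, global_params) {
  keep <- cv$time >= 0
  tt <- cv$time[keep]
  rr <- cv$response[keep]
  resid_fn <- function(theta) {
    pred <- model_response(tt, cv$concentration, cv$t_assoc,
                           10^theta[1], 10^theta[2], global_params$Rmax,
                           global_params$k_t, model)
    pred + theta[3] - rr
  }
  b <- .fit_bounds
  fit <- lm_least_squares(
    c(log10(global_params$k_on), log10(global_params$k_off), 0),
    resid_fn,
    lower = c(log10(b$k_on[1]), log10(b$k_off[1]), -Inf),
    upper = c(log10(b$k_on[2]), log10(b$k_off[2]), Inf))
  list(k_on = 10^fit$par[1], k_off = 10^fit$par[2],
       K_D = 10^(fit$par[2] - fit$par[1]), chi2 = fit$ssr)
}
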