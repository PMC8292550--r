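## Global nonlinear fitting of a referenced concentration series to the
## 1:1 (optionally mass-transport-limited) binding model, with residual
## diagnostics and replicate aggregation.

## Physically plausible SPR parameter ranges; fits are boxed inside these
## (log10 scale for the rates and transport coefficient).
.fit_bounds <- list(
  k_on  = c(1e2, 1e8),    # 1/(M s)
  k_off = c(1e-6, 1),     # 1/s
  Rmax  = c(1e-2, 1e6),   # RU
  k_t   = c(1e6, 1e13)    # RU/(M s)
)

#' Global fit of an SPR concentration series
#'
#' Fits all curves of a referenced concentration series simultaneously with
#' shared kinetic parameters (`k_on`, `k_off`, `Rmax`, and `k_t` for the
#' two-compartment model) plus one bulk-offset nuisance parameter per curve.
#' Minimisation is damped least squares (Levenberg-Marquardt) over
#' log10-transformed rate parameters inside physically plausible bounds,
#' with a 3-point multi-start over the `k_on` initialisation to guard
#' against local minima. Standard errors come from the Jacobian at the
#' solution. The fit is deterministic given the inputs and initialisation.
#'
#' @param series a [referenced_series()] (>= 2 curves at distinct
#'   concentrations for a well-posed fit; a single curve triggers an
#'   identifiability warning).
#' @param model `"two_compartment"` (1:1 Langmuir with mass-transport step;
#'   default) or `"langmuir"` (transport-unlimited closed form).
#' @param init `"auto"` (initialise `k_off` from a tail log-linear fit of
#'   the highest-concentration dissociation, `k_on` from the slope of the
#'   observed rate k_obs versus concentration, `Rmax` from the peak response
#'   and expected fractional occupancy) or a [rate_constants()] object.
#' @param fit_offsets include a per-curve bulk offset nuisance parameter
#'   (default `TRUE`; residual bulk refractive jumps survive double
#'   referencing in practice).
#' @param multi_start number of log-spaced `k_on` starts (default 3).
#' @param rtol integrator relative tolerance used during fitting.
#' @return An object of class `global_fit_result`: `params`
#'   ([rate_constants()]), `K_D` (M), `per_curve_offsets` (RU), `param_sd`
#'   (named standard errors on the natural scale), `chi2` (sum of squared
#'   residuals, RU^2), `residuals` (per-curve traces over t >= 0),
#'   `diagnostics` (see [residual_diagnostics()]), `model`, `converged`,
#'   `at_bound`.
#' @seealso [residual_diagnostics()], [aggregate_replicates()],
#'   [concentration_independence_check()]
#' @export
fit_global <- function(series, model = c("two_compartment", "langmuir"),
                       init = "auto", fit_offsets = TRUE, multi_start = 3L,
                       rtol = 1e-8) {
  model <- match.arg(model)
  stopifnot(inherits(series, "referenced_series"))
  curves <- series$curves
  n_curves <- length(curves)
  if (n_curves < 2L)
    warning("single-concentration series: kinetic parameters are weakly ",
            "identifiable; interpret the fit with caution")
  peak <- max(abs(unlist(lapply(curves, `[[`, "response"))))
  if (peak < 1e-9)
    stop("all responses are (numerically) zero; kinetic parameters are ",
         "unidentifiable from this series")

  init_p <- if (identical(init, "auto")) auto_init(curves, model)
            else {
              stopifnot(inherits(init, "rate_constants"))
              init
            }

  fit_kt <- model == "two_compartment"
  starts <- if (multi_start > 1L)
    init_p$k_on * 10^seq(-1, 1, length.out = multi_start)
  else init_p$k_on
  starts <- pmin(pmax(starts, .fit_bounds$k_on[1]), .fit_bounds$k_on[2])

  best <- NULL
  for (k_on0 in starts) {
    fit <- try(fit_global_once(curves, model, k_on0, init_p$k_off,
                               init_p$Rmax,
                               if (fit_kt) init_p$k_t else Inf,
                               fit_offsets, rtol),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$ssr < best$ssr) best <- fit
  }
  if (is.null(best))
    stop("global fit failed from every start (no convergent ",
         "Levenberg-Marquardt run)")

  build_fit_result(best, curves, model, fit_offsets)
}

## One LM run from a fixed start. Parameter vector layout:
## log10(k_on), log10(k_off), log10(Rmax), [log10(k_t)], offsets...
fit_global_once <- function(curves, model, k_on0, k_off0, Rmax0, k_t0,
                            fit_offsets, rtol) {
  fit_kt <- model == "two_compartment"
  n_curves <- length(curves)
  n_shared <- 3L + as.integer(fit_kt)
  idx <- lapply(curves, function(cv) cv$time >= 0)

  unpack <- function(theta) {
    list(k_on = 10^theta[1], k_off = 10^theta[2], Rmax = 10^theta[3],
         k_t = if (fit_kt) 10^theta[4] else Inf,
         offsets = if (fit_offsets)
           theta[(n_shared + 1):(n_shared + n_curves)]
         else rep(0, n_curves))
  }
  resid_fn <- function(theta) {
    p <- unpack(theta)
    unlist(lapply(seq_len(n_curves), function(i) {
      cv <- curves[[i]]
      keep <- idx[[i]]
      pred <- model_response(cv$time[keep], cv$concentration, cv$t_assoc,
                             p$k_on, p$k_off, p$Rmax, p$k_t, model,
                             rtol = rtol)
      pred + p$offsets[i] - cv$response[keep]
    }), use.names = FALSE)
  }

  theta0 <- c(log10(k_on0), log10(k_off0), log10(Rmax0),
              if (fit_kt) log10(k_t0),
              if (fit_offsets) rep(0, n_curves))
  lower <- c(log10(.fit_bounds$k_on[1]), log10(.fit_bounds$k_off[1]),
             log10(.fit_bounds$Rmax[1]),
             if (fit_kt) log10(.fit_bounds$k_t[1]),
             if (fit_offsets) rep(-Inf, n_curves))
  upper <- c(log10(.fit_bounds$k_on[2]), log10(.fit_bounds$k_off[2]),
             log10(.fit_bounds$Rmax[2]),
             if (fit_kt) log10(.fit_bounds$k_t[2]),
             if (fit_offsets) rep(Inf, n_curves))

  fit <- lm_least_squares(theta0, resid_fn, lower, upper)
  fit$unpacked <- unpack(fit$par)
  fit$n_shared <- n_shared
  fit$fit_offsets <- fit_offsets
  fit$keep_idx <- idx
  fit
}

build_fit_result <- function(fit, curves, model, fit_offsets) {
  p <- fit$unpacked
  n_curves <- length(curves)
  params <- rate_constants(p$k_on, p$k_off, p$Rmax, p$k_t)

  sd_theta <- lm_param_sd(fit)
  # delta method: SE on natural scale for the log10-fitted parameters
  ln10 <- log(10)
  nat <- c(p$k_on, p$k_off, p$Rmax, if (model == "two_compartment") p$k_t)
  sd_nat <- sd_theta[seq_along(nat)] * ln10 * nat
  names(sd_nat) <- c("k_on", "k_off", "Rmax",
                     if (model == "two_compartment") "k_t")
  # K_D SE ignoring k_on/k_off covariance would understate; use full covar
  kd_sd <- kd_se_from_fit(fit, p)

  res_list <- vector("list", n_curves)
  pos <- 0L
  for (i in seq_len(n_curves)) {
    n_i <- sum(fit$keep_idx[[i]])
    res_list[[i]] <- list(
      time = curves[[i]]$time[fit$keep_idx[[i]]],
      residual = fit$residuals[pos + seq_len(n_i)],
      concentration = curves[[i]]$concentration)
    pos <- pos + n_i
  }

  out <- structure(list(
    params = params,
    K_D = params$K_D,
    per_curve_offsets = p$offsets,
    param_sd = c(sd_nat, K_D = kd_sd),
    chi2 = fit$ssr,
    residuals = res_list,
    model = model,
    converged = fit$converged,
    at_bound = any(fit$at_bound[seq_len(fit$n_shared)]),
    n_curves = n_curves,
    iterations = fit$iterations
  ), class = "global_fit_result")
  out$diagnostics <- residual_diagnostics(out)
  out
}

## SE of K_D = k_off/k_on by the delta method on the log10 scale, where
## var(log10 KD) = var(th2) + var(th1) - 2 cov(th1, th2).
kd_se_from_fit <- function(fit, p) {
  J <- fit$jacobian
  m <- length(fit$residuals)
  dof <- max(m - ncol(J), 1L)
  sigma2 <- fit$ssr / dof
  sv <- svd(crossprod(J))
  dinv <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
  Ainv <- sv$v %*% (dinv * t(sv$u))
  cov2 <- Ainv[1:2, 1:2] * sigma2
  v <- cov2[1, 1] + cov2[2, 2] - 2 * cov2[1, 2]
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v) * log(10) * p$k_off / p$k_on
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf("Global %s fit: %d curves, chi2 = %.4g RU^2%s\n",
              x$model, x$n_curves, x$chi2,
              if (x$at_bound) " [parameter at bound]" else ""))
  est <- c(k_on = x$params$k_on, k_off = x$params$k_off,
           Rmax = x$params$Rmax,
           if (x$model == "two_compartment") c(k_t = x$params$k_t))
  for (nm in names(est))
    cat(sprintf("  %-5s = %.4g (SE %.2g)\n", nm, est[[nm]],
                x$param_sd[[nm]]))
  cat(sprintf("  K_D   = %.4g M (%.4g nM, SE %.2g nM)\n", x$K_D,
              x$K_D * 1e9, x$param_sd[["K_D"]] * 1e9))
  flagged <- sum(x$diagnostics$systematic, na.rm = TRUE)
  cat(sprintf("  residual diagnostics: %d/%d curves flagged systematic\n",
              flagged, x$n_curves))
  invisible(x)
}

## Automatic initialisation from the data.
auto_init <- function(curves, model) {
  concs <- vapply(curves, `[[`, 0, "concentration")
  hi <- which.max(concs)
  cv <- curves[[hi]]

  # k_off: log-linear tail fit of the highest-concentration dissociation
  dis <- cv$time > cv$t_assoc
  r <- cv$response[dis]
  t <- cv$time[dis]
  k_off0 <- 1e-3
  if (length(r) > 10 && max(r) > 0) {
    use <- r > 0.2 * max(r)
    if (sum(use) > 5) {
      sl <- coef(lm(log(r[use]) ~ t[use]))[2]
      if (is.finite(sl) && sl < 0) k_off0 <- -sl
    }
  }

  # k_on: slope of observed association rate k_obs vs concentration, where
  # k_obs comes from dR/dt = const - k_obs * R during association
  kobs <- rep(NA_real_, length(curves))
  for (i in seq_along(curves)) {
    ci <- curves[[i]]
    asc <- ci$time >= 0 & ci$time <= ci$t_assoc
    tt <- ci$time[asc]
    rr <- ci$response[asc]
    if (length(tt) < 10) next
    drdt <- diff(rr) / diff(tt)
    rmid <- (rr[-1] + rr[-length(rr)]) / 2
    sl <- coef(lm(drdt ~ rmid))[2]
    if (is.finite(sl) && sl < 0) kobs[i] <- -sl
  }
  k_on0 <- 1e4
  ok <- is.finite(kobs) & concs > 0
  if (sum(ok) >= 2) {
    sl <- coef(lm(kobs[ok] ~ concs[ok]))[2]
    if (is.finite(sl) && sl > 0) k_on0 <- sl
  } else if (sum(ok) == 1) {
    k_on0 <- max(kobs[ok] - k_off0, kobs[ok] / 2) / concs[ok]
  }

  b <- .fit_bounds
  k_on0 <- min(max(k_on0, b$k_on[1] * 10), b$k_on[2] / 10)
  k_off0 <- min(max(k_off0, b$k_off[1] * 10), b$k_off[2] / 10)

  kd0 <- k_off0 / k_on0
  cmax <- max(concs)
  occ <- cmax / (cmax + kd0)
  rmax0 <- max(vapply(curves, function(cv) max(cv$response), 0)) /
    max(occ, 0.05)
  rmax0 <- min(max(rmax0, b$Rmax[1] * 10), b$Rmax[2] / 10)

  rate_constants(k_on0, k_off0, rmax0,
                 k_t = if (model == "two_compartment") 1e8 else Inf)
}
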