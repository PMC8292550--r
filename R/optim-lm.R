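## Small dense Levenberg-Marquardt least-squares solver with box bounds.
## Written in-package because no LM implementation is guaranteed in the
## runtime; validated in tests against optim(method = "L-BFGS-B") on the
## same objective and against generator ground truth.

## Forward-difference Jacobian of a residual function, stepping away from an
## active bound when necessary.
fd_jacobian <- function(fn, par, r0, lower, upper, rel_step = 1e-6) {
  n <- length(par)
  J <- matrix(0, length(r0), n)
  for (i in seq_len(n)) {
    h <- rel_step * max(abs(par[i]), 1e-4)
    pi_plus <- par[i] + h
    if (pi_plus > upper[i]) h <- -h
    p <- par
    p[i] <- par[i] + h
    J[, i] <- (fn(p) - r0) / h
  }
  J
}

## Minimise sum(fn(par)^2) over lower <= par <= upper. Returns the solution,
## the residuals and Jacobian at the solution, and convergence information.
lm_least_squares <- function(par, fn, lower = -Inf, upper = Inf,
                             max_iter = 200L, ftol = 1e-12, ptol = 1e-12,
                             step_max = 3) {
  n <- length(par)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  par <- clamp(par)
  r <- fn(par)
  if (any(!is.finite(r))) stop("residuals not finite at starting point")
  ssr <- sum(r * r)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L

  try_point <- function(par_new) {
    r_new <- fn(par_new)
    if (any(!is.finite(r_new))) Inf else sum(r_new * r_new)
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    J <- fd_jacobian(fn, par, r, lower, upper)
    g <- crossprod(J, r)
    A <- crossprod(J)
    # damping scales with a floor relative to the largest diagonal, so a
    # locally flat direction cannot make the damped system singular
    d2 <- pmax(diag(A), 1e-10 * max(diag(A), 1e-300))
    improved <- FALSE
    repeat {
      M <- A + lambda * diag(d2, n)
      step <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (!is.null(step)) {
        # cap per-coordinate moves: one LM step never jumps more than
        # step_max in any parameter (log-decades for log parameters),
        # which keeps the iterate in the region the Jacobian describes
        step <- pmin(pmax(as.vector(step), -step_max), step_max)
        par_new <- clamp(par + step)
        r_new <- fn(par_new)
        ssr_new <- if (any(!is.finite(r_new))) Inf else sum(r_new * r_new)
        if (ssr_new < ssr) {
          rel_f <- (ssr - ssr_new) / max(ssr, .Machine$double.xmin)
          rel_p <- max(abs(par_new - par) / pmax(abs(par), 1e-8))
          par <- par_new
          r <- r_new
          ssr <- ssr_new
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (rel_f < ftol || rel_p < ptol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e14) break
    }
    if (!improved) {
      # last resort before declaring a stationary point: projected
      # steepest-descent backtracking
      gmax <- max(abs(g))
      if (gmax > 0) {
        for (s in 10^seq(0, -10)) {
          par_new <- clamp(par - s * step_max * as.vector(g) / gmax)
          ssr_new <- try_point(par_new)
          if (ssr_new < ssr) {
            r <- fn(par_new)
            par <- par_new
            ssr <- ssr_new
            lambda <- 1e-3
            improved <- TRUE
            break
          }
        }
      }
    }
    if (!improved || converged) {
      if (!improved) converged <- TRUE # stationary within damping range
      break
    }
  }

  J <- fd_jacobian(fn, par, r, lower, upper)
  at_lower <- abs(par - lower) < 1e-10 * pmax(abs(lower), 1)
  at_upper <- abs(par - upper) < 1e-10 * pmax(abs(upper), 1)
  list(par = par, ssr = ssr, residuals = r, jacobian = J,
       iterations = iter, converged = converged,
       at_bound = at_lower | at_upper)
}

## Parameter covariance from the Jacobian at the solution, via SVD
## pseudo-inverse so that unidentifiable directions give large (not bogus)
## standard errors.
lm_param_sd <- function(fit) {
  m <- length(fit$residuals)
  n <- ncol(fit$jacobian)
  dof <- max(m - n, 1L)
  sigma2 <- fit$ssr / dof
  sv <- svd(fit$jacobian)
  d <- sv$d
  tol <- max(d) * 1e-10
  dinv2 <- ifelse(d > tol, 1 / d^2, 1 / tol^2)
  se2 <- rowSums(sweep(sv$v^2, 2, dinv2, `*`)) * sigma2
  sqrt(se2)
}
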