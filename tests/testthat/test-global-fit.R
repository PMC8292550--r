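noiseless_series <- function(k_on, k_off, Rmax = 100, k_t = 1e8,
                             concs = c(50, 250, 1000, 2000) * 1e-9,
                             dt = 2) {
  sc <- sensorgram_scenario(rate_constants(k_on, k_off, Rmax, k_t),
                            concentrations = concs,
                            schedule = injection_schedule(dt = dt),
                            noise_sd = 0, drift = 0, bulk_jump = 0,
                            seed = 1)
  reference_series(generate_sensorgram_series(sc))
}

test_that("noiseless synthetic series recovers generator parameters", {
  truth <- list(k_on = 3.75e3, k_off = 5.15e-4, Rmax = 100, k_t = 1e8)
  ref <- noiseless_series(truth$k_on, truth$k_off, truth$Rmax, truth$k_t)
  fit <- fit_global(ref, model = "two_compartment")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$k_on / truth$k_on - 1), 1e-4)
  expect_lt(abs(fit$params$k_off / truth$k_off - 1), 1e-4)
  expect_lt(abs(fit$params$Rmax / truth$Rmax - 1), 1e-4)
  expect_lt(abs(fit$K_D / (truth$k_off / truth$k_on) - 1), 1e-4)
  expect_lt(fit$chi2, 1e-4)
  # invariant: K_D field equals k_off/k_on of the fitted params
  expect_identical(fit$K_D, fit$params$k_off / fit$params$k_on)
})

test_that("langmuir fit on transport-unlimited data matches two-compartment",
{
  ref <- noiseless_series(1e4, 1e-3, k_t = Inf)
  f1 <- fit_global(ref, model = "langmuir")
  f2 <- fit_global(ref, model = "two_compartment")
  expect_lt(abs(f1$K_D / f2$K_D - 1), 1e-3)
  expect_lt(f1$chi2, 1e-6)
  expect_lt(f2$chi2, f1$chi2 + 1e-6)
})

test_that("global fit is deterministic given inputs and init", {
  sc <- sensorgram_scenario(rate_constants(8.13e3, 3.19e-4, 100, 1e8),
                            seed = 99)
  ref <- reference_series(generate_sensorgram_series(sc))
  f1 <- fit_global(ref)
  f2 <- fit_global(ref)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$chi2, f2$chi2)
})

test_that("all-zero series errors rather than silently succeeding", {
  times <- seq(-10, 960, by = 2)
  curves <- lapply(c(5e-8, 5e-7), function(C)
    sensorgram(times, rep(0, length(times)), C, 360))
  expect_error(fit_global(referenced_series(curves)), "unidentifiable")
})

test_that("single-concentration series warns about identifiability", {
  times <- seq(-10, 960, by = 2)
  resp <- langmuir_closed_form(times, 5e-7, 360, 1e4, 1e-3, 100)
  expect_warning(
    fit_global(referenced_series(list(sensorgram(times, resp, 5e-7, 360))),
               model = "langmuir"),
    "identifiab")
})

test_that("aggregate_replicates computes mean and sample SD", {
  ref <- noiseless_series(1e4, 1e-3, concs = c(1e-7, 1e-6), dt = 5)
  fit <- fit_global(ref, model = "langmuir")
  # three identical results -> SD 0
  s <- aggregate_replicates(list(fit, fit, fit))
  expect_equal(s$sd, rep(0, 3), tolerance = 1e-12)
  expect_equal(s$mean[s$parameter == "K_D"], fit$K_D)
  # frozen hand arithmetic: K_D {20, 23, 25.4} nM -> mean 22.8, SD 2.7055
  fits <- lapply(c(20e-9, 23e-9, 25.4e-9), function(kd) {
    f <- fit
    f$params <- rate_constants(1e4, kd * 1e4)
    f$K_D <- f$params$K_D
    f
  })
  s2 <- aggregate_replicates(fits)
  expect_equal(s2$mean[s2$parameter == "K_D"], 22.8e-9, tolerance = 1e-10)
  expect_equal(s2$sd[s2$parameter == "K_D"], 2.705549851693736e-9,
               tolerance = 1e-9)
  # single result: mean reported, SD absent
  s1 <- aggregate_replicates(list(fit))
  expect_true(all(is.na(s1$sd)))
  expect_equal(s1$n, rep(1L, 3))
  expect_error(aggregate_replicates(list()), "at least one")
})

test_that("per-curve K_D is concentration-independent under the true model",
{
  ref <- noiseless_series(3.75e3, 5.15e-4)
  fit <- fit_global(ref)
  tab <- concentration_independence_check(ref, global = fit)
  expect_equal(nrow(tab), length(ref$curves))
  expect_true(all(abs(tab$ratio_to_global - 1) < 0.15))
})

test_that("concentration-dependent Rmax (model violation) is detected", {
  # curves generated with Rmax growing with concentration violate 1:1
  concs <- c(50, 250, 1000, 2000) * 1e-9
  times <- seq(-10, 960, by = 2)
  curves <- lapply(seq_along(concs), function(i) {
    rmax_i <- 100 * (1 + 1.5 * (i - 1))
    sensorgram(times,
               langmuir_closed_form(times, concs[i], 360, 3.75e3, 5.15e-4,
                                    rmax_i),
               concs[i], 360)
  })
  ref <- referenced_series(curves)
  fit <- fit_global(ref)
  tab <- concentration_independence_check(ref, global = fit)
  expect_gt(max(abs(tab$ratio_to_global - 1)), 0.15)
})

test_that("parameter standard errors shrink with more curves", {
  mk <- function(concs) {
    sc <- sensorgram_scenario(rate_constants(1e4, 1e-3, 100, 1e8),
                              concentrations = concs,
                              schedule = injection_schedule(dt = 4),
                              noise_sd = 0.5, seed = 5)
    fit_global(reference_series(generate_sensorgram_series(sc)),
               model = "langmuir")
  }
  f_small <- mk(c(100, 2000) * 1e-9)
  f_large <- mk(c(50, 100, 250, 500, 1000, 2000) * 1e-9)
  expect_lt(f_large$param_sd[["K_D"]], f_small$param_sd[["K_D"]])
})
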