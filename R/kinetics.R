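## Kinetic models for 1:1 surface binding: closed-form Langmuir and the
## two-compartment (mass-transport-limited) variant.

#' Rate constants for a 1:1 surface binding interaction
#'
#' Bundles the kinetic parameters of a reversible bimolecular surface
#' reaction A + B <-> AB as measured by SPR: the association rate constant
#' `k_on`, the dissociation rate constant `k_off`, the maximal analyte
#' binding capacity `Rmax`, and a mass-transport coefficient `k_t` coupling
#' bulk and surface analyte concentration. `k_t = Inf` means
#' transport-unlimited binding (plain Langmuir kinetics).
#'
#' Units follow biosensor convention: `k_on` in 1/(M*s), `k_off` in 1/s,
#' `Rmax` in RU, and `k_t` in RU/(M*s) so that bulk and surface analyte
#' concentrations share molar units. The RU-based `k_t` conflates the
#' instrument's mass-to-signal conversion into the transport coefficient;
#' this is the usual single-number parameterisation and is documented here
#' rather than resolved.
#'
#' @param k_on association rate constant, 1/(M*s); must be > 0.
#' @param k_off dissociation rate constant, 1/s; must be >= 0.
#' @param Rmax maximal binding capacity, RU; must be > 0.
#' @param k_t mass-transport coefficient, RU/(M*s); finite positive, or
#'   `Inf` for transport-unlimited binding (default).
#' @return An object of class `rate_constants` (a named list) with fields
#'   `k_on`, `k_off`, `Rmax`, `k_t`, and the derived `K_D = k_off/k_on`.
#' @seealso [kd_from_rates()], [simulate_langmuir()],
#'   [simulate_two_compartment()]
#' @examples
#' rate_constants(k_on = 4.5e4, k_off = 1.03e-3, Rmax = 100)
#' @export
rate_constants <- function(k_on, k_off, Rmax = 100, k_t = Inf) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L,
            is.numeric(k_off), length(k_off) == 1L,
            is.numeric(Rmax), length(Rmax) == 1L,
            is.numeric(k_t), length(k_t) == 1L)
  if (!is.finite(k_on) || k_on <= 0)
    stop("k_on must be a finite positive number, got ", k_on)
  if (!is.finite(k_off) || k_off < 0)
    stop("k_off must be finite and >= 0, got ", k_off)
  if (!is.finite(Rmax) || Rmax <= 0)
    stop("Rmax must be a finite positive number, got ", Rmax)
  if (is.na(k_t) || k_t <= 0)
    stop("k_t must be positive (possibly Inf), got ", k_t)
  structure(
    list(k_on = k_on, k_off = k_off, Rmax = Rmax, k_t = k_t,
         K_D = k_off / k_on),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (1:1 binding)\n")
  cat(sprintf("  k_on  = %.4g 1/(M s)\n", x$k_on))
  cat(sprintf("  k_off = %.4g 1/s\n", x$k_off))
  cat(sprintf("  Rmax  = %.4g RU\n", x$Rmax))
  cat(sprintf("  k_t   = %.4g RU/(M s)%s\n", x$k_t,
              if (is.infinite(x$k_t)) " (transport-unlimited)" else ""))
  cat(sprintf("  K_D   = %.4g M (%.4g nM)\n", x$K_D, x$K_D * 1e9))
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' Computes `K_D = k_off / k_on`. Lower values mean tighter binding. Note
#' that some texts loosely call K_D "the k_on/k_off ratio"; dimensional
#' analysis (and any published table of kinetic constants) requires
#' `k_off / k_on`, with units of molar, and that is what this function
#' returns.
#'
#' @param k_on association rate constant(s), 1/(M*s); must be > 0.
#' @param k_off dissociation rate constant(s), 1/s.
#' @return K_D in molar; vectorised over its arguments.
#' @examples
#' kd_from_rates(4.5e4, 1.03e-3) # ~2.29e-8 M (22.9 nM)
#' @export
kd_from_rates <- function(k_on, k_off) {
  if (!is.numeric(k_on) || !is.numeric(k_off))
    stop("k_on and k_off must be numeric")
  if (any(!is.finite(k_on)) || any(k_on <= 0))
    stop("k_on must be finite and positive")
  k_off / k_on
}

#' Injection schedule for a single SPR cycle
#'
#' @param t_assoc association (injection) duration, s; > 0.
#' @param t_dissoc dissociation (buffer wash) duration, s; >= 0.
#' @param concentration analyte bulk concentration, M; >= 0.
#' @param dt sampling interval, s; > 0.
#' @param t_baseline pre-injection baseline recorded before the injection
#'   start, s; >= 0. Used by the referencing step to zero curves.
#' @return An object of class `injection_schedule`.
#' @export
injection_schedule <- function(t_assoc = 360, t_dissoc = 600,
                               concentration = 0, dt = 1, t_baseline = 10) {
  stopifnot(t_assoc > 0, t_dissoc >= 0, dt > 0, concentration >= 0,
            t_baseline >= 0)
  structure(list(t_assoc = t_assoc, t_dissoc = t_dissoc,
                 concentration = concentration, dt = dt,
                 t_baseline = t_baseline),
            class = "injection_schedule")
}

schedule_times <- function(schedule) {
  with(schedule,
       seq(-t_baseline, t_assoc + t_dissoc, by = dt))
}

#' Construct a sensorgram object
#'
#' A sensorgram is one injection cycle's time/response trace at a known
#' analyte concentration. Time is in seconds with the injection start at
#' t = 0; response is in RU.
#'
#' @param time numeric vector of times, s, strictly increasing.
#' @param response numeric vector of responses, RU, same length as `time`.
#' @param concentration analyte concentration, M.
#' @param t_assoc association duration, s (dissociation starts at
#'   `t = t_assoc`).
#' @param label free-text label.
#' @return An object of class `sensorgram`: a list with fields `time`,
#'   `response`, `concentration`, `t_assoc`, `phase_marks` (indices of the
#'   first sample at/after injection start and dissociation start) and
#'   `label`.
#' @export
sensorgram <- function(time, response, concentration, t_assoc,
                       label = "") {
  time <- as.numeric(time)
  response <- as.numeric(response)
  if (length(time) != length(response))
    stop("time and response must have equal length")
  if (length(time) < 2L || any(diff(time) <= 0))
    stop("time must be strictly increasing with >= 2 samples")
  if (!is.finite(concentration) || concentration < 0)
    stop("concentration must be finite and >= 0")
  structure(
    list(time = time, response = response,
         concentration = concentration, t_assoc = t_assoc,
         phase_marks = c(injection_start = which(time >= 0)[1],
                         dissociation_start = which(time >= t_assoc)[1]),
         label = as.character(label)),
    class = "sensorgram"
  )
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf(
    "Sensorgram%s: %d samples, t in [%g, %g] s, C = %g nM, peak %.2f RU\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$time), min(x$time), max(x$time), x$concentration * 1e9,
    max(x$response)))
  invisible(x)
}

#' @export
as.data.frame.sensorgram <- function(x, ...) {
  data.frame(time_s = x$time, response_RU = x$response)
}

## Closed-form 1:1 Langmuir response at times t (injection start at 0),
## association up to t_assoc, exponential decay afterwards.
langmuir_response <- function(times, conc, t_assoc, k_on, k_off, Rmax) {
  kd <- k_off / k_on
  req <- if (conc == 0) 0 else Rmax * conc / (conc + kd)
  kobs <- k_on * conc + k_off
  r <- numeric(length(times))
  assoc <- times > 0 & times <= t_assoc
  dissoc <- times > t_assoc
  r[assoc] <- req * (1 - exp(-kobs * times[assoc]))
  r_end <- req * (1 - exp(-kobs * t_assoc))
  r[dissoc] <- r_end * exp(-k_off * (times[dissoc] - t_assoc))
  r
}

#' Simulate a transport-unlimited 1:1 Langmuir sensorgram
#'
#' Closed-form forward model for reversible 1:1 surface binding without
#' mass-transport limitation. During association (analyte concentration C):
#' \deqn{R(t) = R_{eq} (1 - e^{-(k_{on} C + k_{off}) t}),\quad
#'       R_{eq} = \frac{R_{max} C}{C + K_D}}
#' and during dissociation \eqn{R(t) = R(t_{assoc}) e^{-k_{off}(t -
#' t_{assoc})}}. The response starts at 0 at the injection start.
#'
#' @param params a [rate_constants()] object (its `k_t` is ignored; the
#'   closed form is the `k_t = Inf` limit).
#' @param schedule an [injection_schedule()].
#' @return A [sensorgram()].
#' @examples
#' s <- simulate_langmuir(rate_constants(4.5e4, 1.03e-3, Rmax = 100),
#'                        injection_schedule(concentration = 500e-9))
#' max(s$response)
#' @export
simulate_langmuir <- function(params, schedule) {
  stopifnot(inherits(params, "rate_constants"),
            inherits(schedule, "injection_schedule"))
  times <- schedule_times(schedule)
  resp <- langmuir_response(times, schedule$concentration, schedule$t_assoc,
                            params$k_on, params$k_off, params$Rmax)
  sensorgram(times, resp, schedule$concentration, schedule$t_assoc,
             label = sprintf("langmuir C=%gnM",
                             schedule$concentration * 1e9))
}

#' Simulate a mass-transport-limited (two-compartment) sensorgram
#'
#' Forward model for 1:1 binding with a mass-transport step. Analyte in an
#' inner compartment at the sensor surface, concentration `Cs`, exchanges
#' with the bulk at rate `k_t` and binds the ligand:
#' \deqn{dR/dt = k_{on} C_s (R_{max} - R) - k_{off} R}
#' with `Cs` in quasi-steady state,
#' \eqn{C_s = (k_t C + k_{off} R) / (k_t + k_{on}(R_{max} - R))}. The
#' resulting scalar ODE is integrated with an adaptive Dormand-Prince
#' RK5(4) scheme. As `k_t` grows the trace converges to
#' [simulate_langmuir()].
#'
#' @inheritParams simulate_langmuir
#' @param rtol,atol integrator relative / absolute (RU) tolerances. The
#'   defaults (1e-8, 1e-10) are far below instrument noise; tighten `rtol`
#'   for convergence studies.
#' @return A [sensorgram()].
#' @examples
#' p <- rate_constants(4.5e4, 1.03e-3, Rmax = 100, k_t = 1e8)
#' s <- simulate_two_compartment(p, injection_schedule(concentration = 5e-7))
#' @export
simulate_two_compartment <- function(params, schedule,
                                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "rate_constants"),
            inherits(schedule, "injection_schedule"))
  times <- schedule_times(schedule)
  resp <- .simulate_twocomp_cpp(times, schedule$concentration,
                                schedule$t_assoc, params$k_on, params$k_off,
                                params$Rmax, params$k_t, rtol, atol)
  sensorgram(times, resp, schedule$concentration, schedule$t_assoc,
             label = sprintf("twocomp C=%gnM",
                             schedule$concentration * 1e9))
}

## Model response evaluated on an arbitrary (sorted) time grid; used by the
## fitting routines. model is "langmuir" or "two_compartment".
model_response <- function(times, conc, t_assoc, k_on, k_off, Rmax,
                           k_t = Inf, model = "two_compartment",
                           rtol = 1e-8, atol = 1e-10) {
  if (model == "langmuir" || is.infinite(k_t)) {
    langmuir_response(times, conc, t_assoc, k_on, k_off, Rmax)
  } else {
    .simulate_twocomp_cpp(times, conc, t_assoc, k_on, k_off, Rmax, k_t,
                          rtol, atol)
  }
}
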