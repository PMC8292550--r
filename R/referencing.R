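## Double-referencing preprocessing of raw sensorgrams.

#' Double-reference a raw sensorgram
#'
#' Standard biosensor double referencing: the buffer-blank injection is
#' subtracted from the sample curve, then the trace recorded on the
#' ligand-free (empty) reference surface is subtracted from the result. Both
#' reference curves are linearly interpolated onto the sample's time grid,
#' and the referenced curve is re-zeroed so that the response is 0 at the
#' injection start (mean of the `zero_window` seconds preceding t = 0, or
#' the value at the first sample if no pre-injection baseline exists).
#'
#' The two subtractions commute, but the stated order
#' (blank first, then surface) is recorded in the result's label for
#' auditability. Negative post-reference responses are retained; clipping
#' them would bias downstream fits.
#'
#' @param sample raw sample [sensorgram()].
#' @param blank buffer-blank [sensorgram()] (zero-concentration injection
#'   over the same surface), or `NULL` to skip.
#' @param empty_surface [sensorgram()] recorded on the ligand-free surface,
#'   or `NULL` to skip.
#' @param zero_window length of the pre-injection window averaged for
#'   zeroing, s.
#' @return A referenced [sensorgram()] on the sample's time grid.
#' @examples
#' sch <- injection_schedule(concentration = 5e-7)
#' s <- simulate_langmuir(rate_constants(4.5e4, 1e-3), sch)
#' identical_curve <- double_reference(s, NULL, NULL)
#' @export
double_reference <- function(sample, blank = NULL, empty_surface = NULL,
                             zero_window = 5) {
  stopifnot(inherits(sample, "sensorgram"))
  resp <- sample$response
  for (ref in list(blank, empty_surface)) {
    if (is.null(ref)) next
    stopifnot(inherits(ref, "sensorgram"))
    if (min(ref$time) > min(sample$time) + 1e-9 ||
        max(ref$time) < max(sample$time) - 1e-9)
      stop("reference curve does not cover the sample's time range ",
           "(alignment error)")
    if (!isTRUE(all.equal(ref$t_assoc, sample$t_assoc)))
      stop("reference and sample have different injection schedules")
    resp <- resp - approx(ref$time, ref$response, xout = sample$time,
                          rule = 1)$y
  }
  out <- sensorgram(sample$time, resp, sample$concentration,
                    sample$t_assoc,
                    label = paste0(sample$label, " [blank-, surface-ref]"))
  rezero(out, zero_window)
}

## Subtract the pre-injection baseline: mean response over the zero_window
## seconds before t = 0, falling back to the first sample when the trace
## starts at or after the injection.
rezero <- function(sg, zero_window = 5) {
  pre <- sg$time < 0 & sg$time >= -zero_window
  base <- if (any(pre)) mean(sg$response[pre]) else sg$response[1]
  sg$response <- sg$response - base
  sg
}

#' Bundle referenced sensorgrams into a concentration series
#'
#' @param curves list of referenced [sensorgram()] objects at distinct
#'   analyte concentrations.
#' @param blank_applied,surface_applied provenance flags recording which
#'   referencing steps produced the curves.
#' @return An object of class `referenced_series`.
#' @seealso [double_reference()], [fit_global()]
#' @export
referenced_series <- function(curves, blank_applied = TRUE,
                              surface_applied = TRUE) {
  stopifnot(is.list(curves), length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "sensorgram")))
  concs <- vapply(curves, `[[`, 0, "concentration")
  if (anyDuplicated(concs))
    warning("duplicate analyte concentrations in series")
  curves <- curves[order(concs)]
  structure(list(curves = curves,
                 blank_applied = isTRUE(blank_applied),
                 surface_applied = isTRUE(surface_applied)),
            class = "referenced_series")
}

#' @export
print.referenced_series <- function(x, ...) {
  concs <- vapply(x$curves, `[[`, 0, "concentration") * 1e9
  cat(sprintf("Referenced series: %d curves at %s nM%s\n",
              length(x$curves), paste(signif(concs, 3), collapse = ", "),
              if (x$blank_applied && x$surface_applied)
                " (double-referenced)" else ""))
  invisible(x)
}
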