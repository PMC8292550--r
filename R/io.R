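## Sensorgram CSV I/O: one curve per file (columns time_s, response_RU),
## with a JSON sidecar carrying the injection metadata.

#' Write a sensorgram as CSV with a JSON metadata sidecar
#'
#' @param sg a [sensorgram()].
#' @param path output CSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(sg, path) {
  stopifnot(inherits(sg, "sensorgram"))
  write.csv(as.data.frame(sg), path, row.names = FALSE)
  meta <- list(concentration_M = sg$concentration, t_assoc_s = sg$t_assoc,
               t_dissoc_s = max(sg$time) - sg$t_assoc, label = sg$label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sensorgram CSV (with optional JSON sidecar)
#'
#' @param path CSV path with columns `time_s`, `response_RU`. Metadata is
#'   taken from `paste0(path, ".json")` when present, else from the
#'   arguments.
#' @param concentration,t_assoc,label metadata fallbacks when no sidecar
#'   exists.
#' @return A [sensorgram()].
#' @export
read_sensorgram_csv <- function(path, concentration = NULL, t_assoc = NULL,
                                label = "") {
  df <- read.csv(path)
  if (!all(c("time_s", "response_RU") %in% names(df)))
    stop("sensorgram CSV needs columns time_s, response_RU")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    concentration <- concentration %||% meta$concentration_M
    t_assoc <- t_assoc %||% meta$t_assoc_s
    if (!nzchar(label) && !is.null(meta$label)) label <- meta$label
  }
  if (is.null(concentration) || is.null(t_assoc))
    stop("concentration and t_assoc must come from a sidecar or arguments")
  sensorgram(df$time_s, df$response_RU, concentration, t_assoc, label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
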