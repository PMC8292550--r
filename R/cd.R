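## Circular dichroism: conversion of raw instrument signal to molar
## ellipticity per residue.

#' Molar ellipticity per residue from raw CD signal
#'
#' Converts raw circular dichroism signal to molar ellipticity per residue:
#' \deqn{\theta = \frac{CD}{10 \, n \, p \, c}}
#' where CD is the instrument signal in mdeg, `n` the number of residues,
#' `p` the cell path length in cm and `c` the molar protein concentration
#' in mol/L. The formula is applied to the mdeg signal exactly as stated;
#' note that some conventions insert an extra factor of 1000 (deg vs mdeg)
#' — the output here is in the instrument-mdeg-based units
#' deg cm^2 dmol^-1 commonly printed as "molar ellipticity per residue".
#'
#' @param raw_cd raw CD signal, mdeg (vectorised over a spectrum).
#' @param n number of residues; > 0.
#' @param p path length, cm; > 0 (typical cells: 0.1 or 0.01 cm).
#' @param c molar protein concentration, mol/L; > 0.
#' @return Molar ellipticity per residue, same length as `raw_cd`.
#' @examples
#' molar_ellipticity(10, n = 100, p = 0.1, c = 1e-5) # 1e4
#' @export
molar_ellipticity <- function(raw_cd, n, p, c) {
  stopifnot(is.numeric(raw_cd), is.numeric(n), is.numeric(p), is.numeric(c))
  if (length(n) != 1L || !is.finite(n) || n <= 0)
    stop("n (residue count) must be a single positive number")
  if (length(p) != 1L || !is.finite(p) || p <= 0)
    stop("p (path length, cm) must be a single positive number")
  if (length(c) != 1L || !is.finite(c) || c <= 0)
    stop("c (molar concentration) must be a single positive number")
  raw_cd / (10 * n * p * c)
}

#' Build or convert a CD spectrum
#'
#' @param wavelength wavelength grid, nm.
#' @param raw_cd raw CD signal, mdeg, same length as `wavelength`.
#' @param n_residues,path_length_cm,concentration_M sample metadata used by
#'   the conversion (see [molar_ellipticity()]).
#' @return An object of class `cd_spectrum`: a data.frame with columns
#'   `wavelength_nm`, `cd_mdeg`, `theta` plus metadata attributes.
#' @export
cd_spectrum <- function(wavelength, raw_cd, n_residues, path_length_cm,
                        concentration_M) {
  stopifnot(length(wavelength) == length(raw_cd))
  theta <- molar_ellipticity(raw_cd, n_residues, path_length_cm,
                             concentration_M)
  structure(
    data.frame(wavelength_nm = as.numeric(wavelength),
               cd_mdeg = as.numeric(raw_cd), theta = theta),
    n_residues = n_residues, path_length_cm = path_length_cm,
    concentration_M = concentration_M,
    class = c("cd_spectrum", "data.frame"))
}

#' Convert a CD spectrum CSV
#'
#' Reads a spectrum CSV with columns `wavelength_nm`, `cd_mdeg`, appends a
#' `theta` column (molar ellipticity per residue) and optionally writes the
#' result back out.
#'
#' @param path input CSV path.
#' @param n_residues,path_length_cm,concentration_M conversion metadata.
#' @param out optional output CSV path.
#' @return The converted `cd_spectrum` (invisibly when `out` is given).
#' @export
convert_cd_csv <- function(path, n_residues, path_length_cm,
                           concentration_M, out = NULL) {
  df <- read.csv(path)
  if (!all(c("wavelength_nm", "cd_mdeg") %in% names(df)))
    stop("spectrum CSV needs columns wavelength_nm, cd_mdeg")
  sp <- cd_spectrum(df$wavelength_nm, df$cd_mdeg, n_residues,
                    path_length_cm, concentration_M)
  if (!is.null(out)) {
    write.csv(as.data.frame(sp), out, row.names = FALSE)
    return(invisible(sp))
  }
  sp
}
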