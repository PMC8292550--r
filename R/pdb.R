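## Minimal fixed-column PDB reader/writer for two-chain coordinate frames.
## Handles ATOM/HETATM records and MODEL/ENDMDL blocks (a multi-MODEL file
## is treated as a trajectory). Per-atom partial charges can be carried in
## the occupancy column (PQR-like convention), since the PDB format has no
## charge field of useful precision.

#' Build a coordinate frame
#'
#' A frame is a data.frame of atoms from a two-molecule system: columns
#' `atom_id`, `atom_name`, `residue_name` (3-letter code), `residue_number`,
#' `molecule_tag` (chain identifier, two distinct values), `x`, `y`, `z`
#' (angstrom) and `charge` (elementary charge units, default 0).
#'
#' @param atom_id integer atom serials.
#' @param atom_name atom names.
#' @param residue_name 3-letter residue codes.
#' @param residue_number integer residue numbers.
#' @param molecule_tag chain/molecule identifier per atom.
#' @param x,y,z coordinates, angstrom; must be finite.
#' @param charge optional partial charges, e.
#' @return A data.frame of class `c("contact_frame", "data.frame")`.
#' @export
contact_frame <- function(atom_id, atom_name, residue_name, residue_number,
                          molecule_tag, x, y, z, charge = 0) {
  df <- data.frame(atom_id = as.integer(atom_id),
                   atom_name = as.character(atom_name),
                   residue_name = as.character(residue_name),
                   residue_number = as.integer(residue_number),
                   molecule_tag = as.character(molecule_tag),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   charge = as.numeric(rep_len(charge, length(x))),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite coordinates in frame")
  class(df) <- c("contact_frame", "data.frame")
  df
}

#' Read a PDB file into a frame or trajectory
#'
#' Parses ATOM/HETATM records by fixed columns. A file with multiple
#' MODEL/ENDMDL blocks returns a trajectory (list of frames, class
#' `md_trajectory`); otherwise a single frame. Coordinates are assumed to
#' be whole, imaged molecules: no periodic-boundary treatment is applied.
#'
#' @param path PDB file path.
#' @param charge_from `"none"` (charges 0) or `"occupancy"` (read partial
#'   charges from the occupancy column, the convention used by
#'   [write_pdb()] and PQR-style files).
#' @return A `contact_frame` or an `md_trajectory` (list of frames).
#' @export
read_pdb <- function(path, charge_from = c("none", "occupancy")) {
  charge_from <- match.arg(charge_from)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  parse_block <- function(block) {
    block <- block[substr(block, 1, 6) %in% c("ATOM  ", "HETATM")]
    if (!length(block)) stop("no ATOM records in PDB block")
    contact_frame(
      atom_id = as.integer(substr(block, 7, 11)),
      atom_name = trimws(substr(block, 13, 16)),
      residue_name = trimws(substr(block, 18, 20)),
      residue_number = as.integer(substr(block, 23, 26)),
      molecule_tag = trimws(substr(block, 22, 22)),
      x = as.numeric(substr(block, 31, 38)),
      y = as.numeric(substr(block, 39, 46)),
      z = as.numeric(substr(block, 47, 54)),
      charge = if (charge_from == "occupancy")
        as.numeric(substr(block, 55, 60)) else 0)
  }
  if (length(model_starts) <= 1L) {
    if (!any(is_atom)) stop("no ATOM records found in ", path)
    return(parse_block(lines[is_atom]))
  }
  ends <- c(model_starts[-1] - 1L, length(lines))
  frames <- lapply(seq_along(model_starts), function(i)
    parse_block(lines[model_starts[i]:ends[i]]))
  md_trajectory(frames)
}

#' Write a frame or trajectory as (multi-MODEL) PDB
#'
#' @param x a `contact_frame` or `md_trajectory`.
#' @param path output file path.
#' @param charge_in_occupancy write partial charges into the occupancy
#'   column (readable back with `read_pdb(..., charge_from = "occupancy")`).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, charge_in_occupancy = TRUE) {
  frames <- if (inherits(x, "md_trajectory")) x else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    occ <- if (charge_in_occupancy) f$charge else rep(1, nrow(f))
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      f$atom_id, substr(f$atom_name, 1, 4), substr(f$residue_name, 1, 3),
      substr(f$molecule_tag, 1, 1), f$residue_number,
      f$x, f$y, f$z, occ, 0), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Bundle coordinate frames into a trajectory
#'
#' @param frames list of `contact_frame` objects with an identical atom
#'   roster (same serials, names and residues, in the same order).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            all(vapply(frames, inherits, TRUE, "contact_frame")))
  roster <- function(f) paste(f$atom_id, f$atom_name, f$residue_number,
                              f$molecule_tag)
  r1 <- roster(frames[[1]])
  for (f in frames[-1])
    if (!identical(roster(f), r1))
      stop("frames do not share an identical atom roster")
  structure(frames, class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("MD trajectory: %d frames, %d atoms (%s)\n", length(x),
              nrow(x[[1]]),
              paste(unique(x[[1]]$molecule_tag), collapse = "/")))
  invisible(x)
}
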