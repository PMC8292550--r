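## Residue-level cross-molecule contact mapping of MD coordinate frames:
## per-frame flagging, trajectory aggregation into contact sites with
## occupancy, Coulomb electrostatic scoring, and a relative stability screen.

## Coulomb constant converting e^2/angstrom to kcal/mol.
COULOMB_KCAL <- 332.0636

split_chains <- function(frame) {
  tags <- sort(unique(frame$molecule_tag))
  if (length(tags) != 2L)
    stop("frame must contain exactly two molecule tags, found: ",
         paste(tags, collapse = ", "))
  list(A = frame[frame$molecule_tag == tags[1], , drop = FALSE],
       B = frame[frame$molecule_tag == tags[2], , drop = FALSE],
       tags = tags)
}

#' Flag residue-pair contacts in one coordinate frame
#'
#' A cross-molecule residue pair (a in molecule A, b in molecule B) is
#' flagged as a possible binding contact when at least `min_atoms` distinct
#' atoms of one residue lie within `cutoff` angstrom of atoms of the partner
#' residue. The rule is applied symmetrically from both molecules and the
#' triggering side is recorded: an atom counts once no matter how many
#' partner atoms it is near (the rule counts atoms of the flagging residue,
#' not atom pairs). The default 3 atoms within 3 angstrom is the standard
#' per-step interface screen for trajectory post-processing.
#'
#' Neighbour search is a sorted sweep over the x axis (exact, no grid
#' approximation); tests verify equality with a naive all-pairs oracle.
#'
#' @param frame a [contact_frame()] containing exactly two molecule tags.
#' @param cutoff distance cutoff, angstrom; > 0.
#' @param min_atoms minimum number of distinct atoms of the flagging
#'   residue within `cutoff`; >= 1.
#' @return A data.frame, one row per flagged residue pair, ordered by
#'   (residue_A_number, residue_B_number): residue names/numbers for both
#'   molecules, atom counts within cutoff from each side (`n_atoms_A`,
#'   `n_atoms_B`), and `trigger` (`"A"`, `"B"` or `"both"`).
#' @export
flag_contacts <- function(frame, cutoff = 3.0, min_atoms = 3L) {
  stopifnot(inherits(frame, "contact_frame"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive number")
  if (min_atoms < 1L) stop("min_atoms must be >= 1")
  ch <- split_chains(frame)
  A <- ch$A
  B <- ch$B
  empty <- data.frame(residue_A_name = character(),
                      residue_A_number = integer(),
                      residue_B_name = character(),
                      residue_B_number = integer(),
                      n_atoms_A = integer(), n_atoms_B = integer(),
                      trigger = character(), stringsAsFactors = FALSE)
  pairs <- .cross_pairs_within_cpp(as.matrix(A[, c("x", "y", "z")]),
                                   as.matrix(B[, c("x", "y", "z")]),
                                   cutoff)
  if (nrow(pairs) == 0L) return(empty)
  ia <- pairs[, 1]
  ib <- pairs[, 2]
  key <- paste(A$residue_number[ia], B$residue_number[ib], sep = "|")
  rows <- lapply(split(seq_along(key), key), function(k) {
    nA <- length(unique(ia[k]))
    nB <- length(unique(ib[k]))
    if (nA < min_atoms && nB < min_atoms) return(NULL)
    i1 <- ia[k[1]]
    j1 <- ib[k[1]]
    data.frame(residue_A_name = A$residue_name[i1],
               residue_A_number = A$residue_number[i1],
               residue_B_name = B$residue_name[j1],
               residue_B_number = B$residue_number[j1],
               n_atoms_A = nA, n_atoms_B = nB,
               trigger = if (nA >= min_atoms && nB >= min_atoms) "both"
                         else if (nA >= min_atoms) "A" else "B",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$residue_A_number, out$residue_B_number), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-frame contacts into contact sites with occupancy
#'
#' Runs [flag_contacts()] on every frame, takes the union of flagged
#' residue pairs, and reports for each pair the list of frames in which it
#' was flagged and its occupancy (flagged frames / total frames). Residue
#' pairs are then merged into site groups when they are sequence-adjacent
#' on both molecules (within `adjacency` residues) and co-occur in time
#' (Jaccard similarity of their frame sets >= `jaccard_min`), mirroring how
#' interface runs of consecutive residues are reported as one binding site.
#'
#' @param trajectory an [md_trajectory()] (>= 1 frame).
#' @param cutoff,min_atoms contact rule parameters, see [flag_contacts()].
#' @param adjacency maximum residue-number gap (on both molecules) for two
#'   pairs to join one site group.
#' @param jaccard_min minimum frame-set Jaccard similarity for grouping.
#' @return A data.frame of class `contact_sites`, one row per residue pair:
#'   residue identities, `n_frames`, `n_total_frames`, `occupancy`,
#'   `frames` (list column of flagged frame indices, sorted unique) and
#'   `site_group` (integer site id).
#' @export
aggregate_sites <- function(trajectory, cutoff = 3.0, min_atoms = 3L,
                            adjacency = 2L, jaccard_min = 0.5) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  n_frames <- length(trajectory)
  if (n_frames < 1L) stop("empty trajectory")
  per_frame <- lapply(seq_len(n_frames), function(i) {
    fl <- flag_contacts(trajectory[[i]], cutoff, min_atoms)
    if (nrow(fl)) fl$frame <- i
    fl
  })
  all_fl <- do.call(rbind, per_frame[vapply(per_frame, nrow, 0L) > 0])
  if (is.null(all_fl) || nrow(all_fl) == 0L) {
    out <- data.frame(residue_A_name = character(),
                      residue_A_number = integer(),
                      residue_B_name = character(),
                      residue_B_number = integer(),
                      n_frames = integer(), n_total_frames = integer(),
                      occupancy = numeric(), site_group = integer())
    out$frames <- list()
    class(out) <- c("contact_sites", "data.frame")
    return(out)
  }
  key <- paste(all_fl$residue_A_number, all_fl$residue_B_number, sep = "|")
  groups <- split(seq_len(nrow(all_fl)), key)
  first <- vapply(groups, `[`, 0L, 1L)
  frames_list <- lapply(groups, function(k) sort(unique(all_fl$frame[k])))
  out <- data.frame(
    residue_A_name = all_fl$residue_A_name[first],
    residue_A_number = all_fl$residue_A_number[first],
    residue_B_name = all_fl$residue_B_name[first],
    residue_B_number = all_fl$residue_B_number[first],
    n_frames = lengths(frames_list),
    n_total_frames = n_frames,
    occupancy = lengths(frames_list) / n_frames,
    stringsAsFactors = FALSE)
  out$frames <- unname(frames_list)
  ord <- order(out$residue_A_number, out$residue_B_number)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$site_group <- group_sites(out, adjacency, jaccard_min)
  class(out) <- c("contact_sites", "data.frame")
  out
}

## Union-find grouping of residue pairs into sites.
group_sites <- function(sites, adjacency, jaccard_min) {
  n <- nrow(sites)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) return(1)
    length(intersect(a, b)) / u
  }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(sites$residue_A_number[i] - sites$residue_A_number[j]) >
        adjacency) next
    if (abs(sites$residue_B_number[i] - sites$residue_B_number[j]) >
        adjacency) next
    if (jaccard(sites$frames[[i]], sites$frames[[j]]) < jaccard_min) next
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Coulomb electrostatic score of a contact site in one frame
#'
#' Pairwise Coulomb interaction energy between the site's two residues:
#' \deqn{E = \sum_{i \in a, j \in b, r_{ij} \le r_{max}}
#'       332.0636 \, q_i q_j / (\varepsilon \, r_{ij})}
#' in kcal/mol with charges in e and distances in angstrom. The sign is
#' retained (negative = attractive); downstream ranking uses the magnitude.
#' This is a ranking proxy for interaction strength, not a force-field
#' energy: no solvent screening beyond the uniform dielectric, no
#' long-range correction.
#'
#' @param site one row of a `contact_sites` data.frame, or a list with
#'   `residue_A_number` and `residue_B_number`.
#' @param frame a [contact_frame()] with partial charges.
#' @param dielectric uniform relative dielectric constant (> 0, default 1).
#' @param pair_cutoff atom-pair distance cutoff for the sum, angstrom.
#' @return Energy score, kcal/mol (0 with a warning when every atom charge
#'   in the site is zero).
#' @export
electrostatic_score <- function(site, frame, dielectric = 1.0,
                                pair_cutoff = 12.0) {
  stopifnot(inherits(frame, "contact_frame"), dielectric > 0)
  ch <- split_chains(frame)
  a <- ch$A[ch$A$residue_number == site$residue_A_number, , drop = FALSE]
  b <- ch$B[ch$B$residue_number == site$residue_B_number, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("site residues not found in frame")
  if (all(a$charge == 0) && all(b$charge == 0)) {
    warning("all partial charges in the site are zero; score is 0")
    return(0)
  }
  dx <- outer(a$x, b$x, `-`)
  dy <- outer(a$y, b$y, `-`)
  dz <- outer(a$z, b$z, `-`)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  qq <- outer(a$charge, b$charge)
  keep <- r <= pair_cutoff & r > 0
  sum(COULOMB_KCAL * qq[keep] / (dielectric * r[keep]))
}

#' Score every contact site against a frame
#'
#' Convenience wrapper applying [electrostatic_score()] to each row of a
#' `contact_sites` table. With a trajectory, scores are averaged over the
#' frames in which the site was flagged (its contact geometry is only
#' meaningful there).
#'
#' @param sites a `contact_sites` data.frame from [aggregate_sites()].
#' @param frames a [contact_frame()] or an [md_trajectory()].
#' @inheritParams electrostatic_score
#' @return `sites` with an `electrostatic_score` column added.
#' @export
score_sites <- function(sites, frames, dielectric = 1.0,
                        pair_cutoff = 12.0) {
  stopifnot(inherits(sites, "contact_sites"))
  single <- inherits(frames, "contact_frame")
  sites$electrostatic_score <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    if (single)
      return(electrostatic_score(s, frames, dielectric, pair_cutoff))
    mean(vapply(s$frames[[1]], function(fi)
      electrostatic_score(s, frames[[fi]], dielectric, pair_cutoff), 0))
  }, 0)
  sites
}

#' Classify contact sites as stable or unstable
#'
#' Relative stability screen: a site is considered *unstable* when the
#' magnitude of its electrostatic score is lower than `threshold_fraction`
#' (default ten percent) of the highest magnitude among the sites, and
#' *stable* otherwise. A singleton list is stable (it is its own maximum),
#' as are ties at the maximum.
#'
#' @param sites a `contact_sites` data.frame carrying an
#'   `electrostatic_score` column (see [score_sites()]), or a bare numeric
#'   vector of scores.
#' @param threshold_fraction fraction of the largest |score| below which a
#'   site is unstable (default 0.10).
#' @return `sites` with a logical `stable` column (or, for a numeric
#'   input, the logical vector itself).
#' @examples
#' classify_stability(c(-100, -50, -9)) # TRUE TRUE FALSE
#' @export
classify_stability <- function(sites, threshold_fraction = 0.10) {
  scores <- if (is.numeric(sites)) sites
            else {
              stopifnot(inherits(sites, "contact_sites"))
              if (is.null(sites$electrostatic_score))
                stop("sites carry no electrostatic_score; run score_sites()")
              sites$electrostatic_score
            }
  if (length(scores) == 0L) stop("no sites to classify")
  stopifnot(threshold_fraction >= 0, threshold_fraction <= 1)
  stable <- abs(scores) >= threshold_fraction * max(abs(scores))
  if (is.numeric(sites)) return(stable)
  sites$stable <- stable
  sites
}
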