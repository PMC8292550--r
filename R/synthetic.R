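## Synthetic-data generators: sensorgram series with known kinetic truth
## (emulating the study design: 50-2000 nM analyte series, 360 s
## association, 600 s dissociation) and toy two-chain complexes with
## planted interfaces for the contact-mapping rule.

## Run code with a local, restored RNG state so generators are
## deterministic given their seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old))
      rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(code)
}

#' Define a synthetic sensorgram scenario
#'
#' Describes one simulated SPR experiment: the true rate constants, the
#' analyte concentration series, the injection schedule, and the nuisance
#' structure (Gaussian noise, linear baseline drift, a bulk
#' refractive-index jump during the injection).
#'
#' Defaults mirror a typical kinetic titration on a research-grade
#' instrument: six two-fold-ish concentrations spanning 50-2000 nM, 360 s
#' association / 600 s dissociation at 1 Hz, 0.5 RU noise, 0.002 RU/s
#' drift, a 5 RU bulk jump, and a transport coefficient k_t = 1e8
#' RU/(M s) (barely transport-limited at these rates).
#'
#' @param truth a [rate_constants()] object (the generating parameters).
#' @param concentrations analyte concentrations, M (distinct, >= 0).
#' @param schedule an [injection_schedule()] (its concentration field is
#'   overridden per curve).
#' @param noise_sd Gaussian noise SD on every recorded curve, RU; >= 0.
#' @param drift linear baseline drift, RU/s (carried by sample and blank).
#' @param bulk_jump bulk refractive-index jump during the injection, RU
#'   (carried by sample and empty-surface curves).
#' @param seed integer RNG seed (Mersenne-Twister).
#' @return An object of class `sensorgram_scenario`.
#' @export
sensorgram_scenario <- function(truth,
                                concentrations = c(50, 100, 250, 500, 1000,
                                                   2000) * 1e-9,
                                schedule = injection_schedule(),
                                noise_sd = 0.5, drift = 0.002,
                                bulk_jump = 5, seed = 1234) {
  stopifnot(inherits(truth, "rate_constants"),
            inherits(schedule, "injection_schedule"),
            noise_sd >= 0, all(concentrations >= 0),
            !anyDuplicated(concentrations))
  structure(list(truth = truth, concentrations = sort(concentrations),
                 schedule = schedule, noise_sd = noise_sd, drift = drift,
                 bulk_jump = bulk_jump, seed = as.integer(seed)),
            class = "sensorgram_scenario")
}

#' Generate a raw sensorgram series with ground truth
#'
#' For each concentration, produces the three curves an instrument records
#' for double referencing: the `sample` (binding model + drift + bulk jump
#' + noise), the buffer `blank` (drift + noise) and the `empty_surface`
#' trace (bulk jump + noise). Deterministic given the scenario seed. The
#' noiseless, drift-free, jump-free scenario closes exactly: sample minus
#' blank minus empty surface equals the pure model trace.
#'
#' @param scenario a [sensorgram_scenario()].
#' @return A list of class `sensorgram_series`: `curves` (per
#'   concentration, each a list with `sample`, `blank`, `empty_surface`),
#'   and `truth` (a machine-readable record of every generating
#'   parameter).
#' @seealso [reference_series()] to double-reference the output,
#'   [write_series_fixtures()] to serialise it.
#' @export
generate_sensorgram_series <- function(scenario) {
  stopifnot(inherits(scenario, "sensorgram_scenario"))
  tr <- scenario$truth
  sch <- scenario$schedule
  times <- schedule_times(sch)
  t0 <- min(times)
  with_seed(scenario$seed, {
    curves <- lapply(scenario$concentrations, function(conc) {
      sch_c <- sch
      sch_c$concentration <- conc
      model <- if (is.infinite(tr$k_t))
        simulate_langmuir(tr, sch_c)$response
      else
        simulate_two_compartment(tr, sch_c)$response
      drift_term <- scenario$drift * (times - t0)
      jump <- scenario$bulk_jump * (times > 0 & times <= sch$t_assoc)
      noise <- function() rnorm(length(times), 0, scenario$noise_sd)
      mk <- function(resp, what)
        sensorgram(times, resp, conc, sch$t_assoc,
                   label = sprintf("%s C=%gnM", what, conc * 1e9))
      list(sample = mk(model + drift_term + jump + noise(), "sample"),
           blank = mk(drift_term + noise(), "blank"),
           empty_surface = mk(jump + noise(), "empty"))
    })
    structure(list(
      curves = curves,
      truth = list(k_on = tr$k_on, k_off = tr$k_off, Rmax = tr$Rmax,
                   k_t = tr$k_t, K_D = tr$K_D,
                   concentrations_M = scenario$concentrations,
                   t_assoc_s = sch$t_assoc, t_dissoc_s = sch$t_dissoc,
                   dt_s = sch$dt, noise_sd_RU = scenario$noise_sd,
                   drift_RU_per_s = scenario$drift,
                   bulk_jump_RU = scenario$bulk_jump,
                   seed = scenario$seed)),
      class = "sensorgram_series")
  })
}

#' Double-reference a generated series
#'
#' Applies [double_reference()] (blank first, then empty surface) to every
#' concentration of a generated series.
#'
#' @param series a `sensorgram_series` from [generate_sensorgram_series()].
#' @return A [referenced_series()] ready for [fit_global()].
#' @export
reference_series <- function(series) {
  stopifnot(inherits(series, "sensorgram_series"))
  referenced_series(lapply(series$curves, function(tripl)
    double_reference(tripl$sample, tripl$blank, tripl$empty_surface)))
}

#' Kinetic parameter catalog of the studied interactions
#'
#' The published rate constants for full-length MPP1 and its truncated
#' mutants binding flotillin 1 (FL1) or flotillin 2 (FL2), as determined by
#' global 1:1 fitting of SPR series (averages of 3 independent series;
#' interactions with no detectable binding are omitted). `K_D_printed` is
#' the K_D value as printed in the source table (rounded to 3 significant
#' digits); `k_off/k_on` reproduces it to within one unit in the last
#' digit.
#'
#' These parameter sets are the default truths for the synthetic scenario
#' catalog, spanning the observed affinity range 22.8 nM - 982 nM.
#'
#' @return A data.frame with columns `interaction`, `k_on`, `k_off`,
#'   `K_D_printed`.
#' @export
kinetics_catalog <- function() {
  data.frame(
    interaction = c("FL1-MPP1", "FL1-MPP1-Mut2", "FL1-MPP1-Mut3",
                    "FL1-MPP1-Mut4", "FL2-MPP1", "FL2-MPP1-Mut2",
                    "FL2-MPP1-Mut3", "FL2-MPP1-Mut4"),
    k_on  = c(4.50e4, 1.68e3, 3.75e3, 8.13e3, 4.13e4, 1.63e3, 4.17e3,
              5.60e3),
    k_off = c(1.03e-3, 1.18e-3, 5.15e-4, 3.19e-4, 1.28e-3, 1.60e-3,
              8.28e-4, 2.81e-4),
    K_D_printed = c(2.28e-8, 7.02e-7, 1.37e-7, 3.92e-8, 3.10e-8, 9.82e-7,
                    1.99e-7, 5.02e-8),
    stringsAsFactors = FALSE)
}

#' Write a generated series to CSV fixtures with a truth sidecar
#'
#' One CSV per curve (`sample_<i>.csv`, `blank_<i>.csv`,
#' `empty_<i>.csv`, each with a JSON metadata sidecar) plus `truth.json`
#' recording every generating parameter.
#'
#' @param series a `sensorgram_series`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series_fixtures <- function(series, dir) {
  stopifnot(inherits(series, "sensorgram_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(series$curves)) {
    tripl <- series$curves[[i]]
    write_sensorgram_csv(tripl$sample,
                         file.path(dir, sprintf("sample_%02d.csv", i)))
    write_sensorgram_csv(tripl$blank,
                         file.path(dir, sprintf("blank_%02d.csv", i)))
    write_sensorgram_csv(tripl$empty_surface,
                         file.path(dir, sprintf("empty_%02d.csv", i)))
  }
  jsonlite::write_json(series$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Define a planted interface for a toy two-chain complex
#'
#' @param pairs data.frame with one row per planted residue pair: `res_A`,
#'   `res_B` (residue numbers on chains A and B), `n_within` (number of
#'   chain-B atoms placed within `distance` of the chain-A residue),
#'   `distance` (angstrom, > 0), `occupancy` (fraction of frames in
#'   contact, 0..1), and optionally `q_A`, `q_B` (partial charges planted
#'   on the contacting atoms; default 0).
#' @param n_res_A,n_res_B chain lengths (default: enough to hold the
#'   planted residues plus two).
#' @param jitter_sd per-atom Gaussian positional jitter per frame,
#'   angstrom.
#' @return An object of class `planted_interface`.
#' @export
planted_interface <- function(pairs, n_res_A = NULL, n_res_B = NULL,
                              jitter_sd = 0.05) {
  stopifnot(is.data.frame(pairs),
            all(c("res_A", "res_B", "n_within", "distance", "occupancy")
                %in% names(pairs)))
  if (any(pairs$distance <= 0)) stop("target distances must be > 0")
  if (any(pairs$occupancy < 0 | pairs$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  if (any(pairs$n_within < 1 | pairs$n_within > 4))
    stop("n_within must be between 1 and 4 (toy residues have 5 atoms)")
  if (anyDuplicated(pairs$res_B) || anyDuplicated(pairs$res_A))
    stop("each residue may carry at most one planted contact")
  if (is.null(pairs$q_A)) pairs$q_A <- 0
  if (is.null(pairs$q_B)) pairs$q_B <- 0
  structure(list(pairs = pairs,
                 n_res_A = n_res_A %||% (max(pairs$res_A) + 2L),
                 n_res_B = n_res_B %||% (max(pairs$res_B) + 2L),
                 jitter_sd = jitter_sd),
            class = "planted_interface")
}

## Alanine-like 5-atom toy residue: CA plus four atoms on the -y side so
## that a partner placed at +y only approaches the CA.
toy_residue_local <- function() {
  rbind(CA = c(0, 0, 0),
        N  = c(-1.2, -1.0, 0),
        C  = c(1.2, -1.0, 0),
        O  = c(1.2, -2.0, 0),
        CB = c(-1.2, -2.0, 0))
}

#' Generate a toy two-chain complex trajectory with planted contacts
#'
#' Builds two rigid chains of 5-atom alanine-like residues (4 angstrom CA
#' spacing along x; chain B offset 20 angstrom in y) and, for each planted
#' pair, moves `n_within` atoms of the chain-B residue to exactly the
#' target distance from the chain-A residue's CA while keeping every other
#' inter-chain atom pair well outside the contact cutoff. Contacts follow a
#' deterministic occupancy schedule (a pair with occupancy q is in contact
#' in the first `round(q * n_frames)` frames; in the remaining frames the
#' chain-B residue is displaced 15 angstrom away). Gaussian jitter is added
#' to every atom of every frame. No force-field realism is attempted — the
#' geometry exists to exercise the >= `min_atoms`-within-cutoff rule with
#' known ground truth.
#'
#' @param spec a [planted_interface()].
#' @param n_frames number of trajectory frames; >= 1.
#' @param seed integer RNG seed.
#' @return A list: `trajectory` (an [md_trajectory()]), `truth` (data.frame
#'   with the planted pairs, their scheduled contact frames and exact
#'   occupancy), and `spec`.
#' @export
generate_toy_complex <- function(spec, n_frames = 20L, seed = 1234) {
  stopifnot(inherits(spec, "planted_interface"), n_frames >= 1L)
  local5 <- toy_residue_local()
  build_chain <- function(n_res, tag, y0, id0) {
    do.call(rbind, lapply(seq_len(n_res), function(i) {
      xyz <- sweep(local5, 2, c(4 * i, y0, 0), `+`)
      data.frame(atom_id = id0 + (i - 1L) * 5L + seq_len(5L),
                 atom_name = rownames(local5), residue_name = "ALA",
                 residue_number = i, molecule_tag = tag,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = 0,
                 stringsAsFactors = FALSE)
    }))
  }
  A <- build_chain(spec$n_res_A, "A", 0, 0L)
  B <- build_chain(spec$n_res_B, "B", 20, nrow(A))
  # chain A residues face +y (partner side); flip the local -y geometry of B
  # so its non-contact atoms point away (+y)
  B$y <- 40 - B$y

  pairs <- spec$pairs
  contact_until <- round(pairs$occupancy * n_frames)
  # base (non-jittered) B positions for "in contact" and "apart" states
  place_pair <- function(Bdf, k, in_contact) {
    pr <- pairs[k, ]
    sel <- which(Bdf$residue_number == pr$res_B)
    ca_A <- c(4 * pr$res_A, 0, 0)
    if (in_contact) {
      # place the contact atoms on a sphere of radius `distance` around the
      # chain-A CA, spread over two angular axes so they stay > 1 A apart
      # (robust to jitter) yet > 3 A from every other chain-A atom
      angles <- list(c(-0.3, 0), c(0, 0.3), c(0.3, 0), c(0, -0.3))
      for (m in seq_len(pr$n_within)) {
        a <- angles[[m]]
        u <- c(sin(a[1]), cos(a[1]) * cos(a[2]), cos(a[1]) * sin(a[2]))
        Bdf[sel[m], c("x", "y", "z")] <- ca_A + pr$distance * u
      }
      if (pr$n_within < 5L)
        for (m in (pr$n_within + 1L):5L)
          Bdf[sel[m], c("x", "y", "z")] <-
            ca_A + c(1.5 * (m - 3), pr$distance + 6, 0)
    } else {
      for (m in seq_len(5L))
        Bdf[sel[m], c("x", "y", "z")] <-
          ca_A + c(1.5 * (m - 3), 15 + pr$distance, 0)
    }
    Bdf[sel, "charge"] <- 0
    Bdf[sel[seq_len(pr$n_within)], "charge"] <- pr$q_B / pr$n_within
    Bdf
  }
  A$charge[match(pairs$res_A, A$residue_number)] <- pairs$q_A # the CA row

  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    Bf <- B
    for (k in seq_len(nrow(pairs)))
      Bf <- place_pair(Bf, k, f <= contact_until[k])
    df <- rbind(A, Bf)
    n <- nrow(df)
    df$x <- df$x + rnorm(n, 0, spec$jitter_sd)
    df$y <- df$y + rnorm(n, 0, spec$jitter_sd)
    df$z <- df$z + rnorm(n, 0, spec$jitter_sd)
    class(df) <- c("contact_frame", "data.frame")
    df
  }))
  check_overlaps(frames[[1]])

  truth <- data.frame(res_A = pairs$res_A, res_B = pairs$res_B,
                      n_within = pairs$n_within,
                      distance = pairs$distance,
                      occupancy_requested = pairs$occupancy,
                      contact_frames = I(lapply(contact_until, function(u)
                        if (u >= 1L) seq_len(u) else integer())),
                      occupancy_exact = contact_until / n_frames)
  list(trajectory = md_trajectory(frames), truth = truth, spec = spec)
}

check_overlaps <- function(frame, min_dist = 0.5) {
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  d <- stats::dist(xyz)
  if (min(d) < min_dist)
    stop("infeasible geometry: atoms closer than ", min_dist,
         " angstrom (min distance ", signif(min(d), 3), ")")
  invisible(TRUE)
}
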