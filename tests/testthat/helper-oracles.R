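# Independent oracles used across the suite. These deliberately re-derive
# results through different code paths (naive enumeration, fixed-step
# integration, direct formula evaluation) and must stay independent of the
# package internals they check.

# Naive all-pairs contact oracle: full cross-chain distance matrix, then
# per-residue-pair counting of distinct atoms within the cutoff.
brute_force_contacts <- function(frame, cutoff = 3.0, min_atoms = 3L) {
  tags <- sort(unique(frame$molecule_tag))
  A <- frame[frame$molecule_tag == tags[1], ]
  B <- frame[frame$molecule_tag == tags[2], ]
  d <- sqrt(outer(A$x, B$x, `-`)^2 + outer(A$y, B$y, `-`)^2 +
              outer(A$z, B$z, `-`)^2)
  hits <- which(d <= cutoff, arr.ind = TRUE)
  out <- NULL
  if (nrow(hits)) {
    key <- paste(A$residue_number[hits[, 1]], B$residue_number[hits[, 2]],
                 sep = "|")
    for (k in unique(key)) {
      rows <- hits[key == k, , drop = FALSE]
      nA <- length(unique(rows[, 1]))
      nB <- length(unique(rows[, 2]))
      if (nA >= min_atoms || nB >= min_atoms)
        out <- rbind(out, data.frame(
          residue_A_number = A$residue_number[rows[1, 1]],
          residue_B_number = B$residue_number[rows[1, 2]],
          n_atoms_A = nA, n_atoms_B = nB))
    }
  }
  if (is.null(out))
    return(data.frame(residue_A_number = integer(),
                      residue_B_number = integer(),
                      n_atoms_A = integer(), n_atoms_B = integer()))
  out <- out[order(out$residue_A_number, out$residue_B_number), ]
  rownames(out) <- NULL
  out
}

# Fixed-step classic RK4 integration of the quasi-steady two-compartment
# model, written straight from the rate law.
rk4_twocomp <- function(times, conc, t_assoc, k_on, k_off, Rmax, k_t,
                        step = 0.1) {
  f <- function(R, C) {
    fs <- Rmax - R
    k_t * (k_on * C * fs - k_off * R) / (k_t + k_on * fs)
  }
  integrate_to <- function(R, t0, t1, C) {
    if (t1 <= t0) return(R)
    n <- ceiling((t1 - t0) / step)
    h <- (t1 - t0) / n
    for (i in seq_len(n)) {
      k1 <- f(R, C)
      k2 <- f(R + h / 2 * k1, C)
      k3 <- f(R + h / 2 * k2, C)
      k4 <- f(R + h * k3, C)
      R <- R + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    R
  }
  out <- numeric(length(times))
  R <- 0
  t_prev <- 0
  for (i in seq_along(times)) {
    t <- times[i]
    if (t <= 0) { out[i] <- 0; next }
    if (t_prev < t_assoc) {
      R <- integrate_to(R, t_prev, min(t, t_assoc), conc)
      if (t > t_assoc) R <- integrate_to(R, t_assoc, t, 0)
    } else {
      R <- integrate_to(R, t_prev, t, 0)
    }
    out[i] <- R
    t_prev <- t
  }
  out
}

# Direct evaluation of the stated closed form (independent of the package
# implementation).
langmuir_closed_form <- function(times, C, t_assoc, k_on, k_off, Rmax) {
  KD <- k_off / k_on
  req <- if (C > 0) Rmax * C / (C + KD) else 0
  kobs <- k_on * C + k_off
  r <- ifelse(times <= 0, 0,
              ifelse(times <= t_assoc, req * (1 - exp(-kobs * times)),
                     req * (1 - exp(-kobs * t_assoc)) *
                       exp(-k_off * (times - t_assoc))))
  as.numeric(r)
}

# Random two-chain frame for oracle-equivalence testing: two overlapping
# clouds so that genuine contacts occur.
random_contact_frame <- function(n_atoms = 200L, n_res_per_chain = 20L,
                                 box = 18) {
  half <- n_atoms %/% 2L
  mk <- function(n, tag, shift, id0)
    contact_frame(
      atom_id = id0 + seq_len(n),
      atom_name = "X",
      residue_name = "GLY",
      residue_number = sample.int(n_res_per_chain, n, replace = TRUE),
      molecule_tag = tag,
      x = runif(n, 0, box) + shift, y = runif(n, 0, box),
      z = runif(n, 0, box),
      charge = rnorm(n, 0, 0.3))
  rbind_frames(mk(half, "A", 0, 0L), mk(n_atoms - half, "B", box / 3, half))
}

rbind_frames <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("contact_frame", "data.frame")
  out
}

# Published rate-constant sets (re-keyed independently from the catalog helper so
# a typo in one shows up as a test failure, not silent agreement).
published_rates <- data.frame(
  interaction = c("FL1-MPP1", "FL1-MPP1-Mut2", "FL1-MPP1-Mut3",
                  "FL1-MPP1-Mut4", "FL2-MPP1", "FL2-MPP1-Mut2",
                  "FL2-MPP1-Mut3", "FL2-MPP1-Mut4"),
  k_on = c(4.50e4, 1.68e3, 3.75e3, 8.13e3, 4.13e4, 1.63e3, 4.17e3, 5.60e3),
  k_off = c(1.03e-3, 1.18e-3, 5.15e-4, 3.19e-4, 1.28e-3, 1.60e-3, 8.28e-4,
            2.81e-4),
  K_D_printed = c(2.28e-8, 7.02e-7, 1.37e-7, 3.92e-8, 3.10e-8, 9.82e-7,
                  1.99e-7, 5.02e-8))
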