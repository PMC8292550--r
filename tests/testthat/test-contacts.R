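# Fixture: chain A residue 1 with `n_close` chain-B atoms at `d` angstrom
# of its CA, remaining B atoms far away.
boundary_frame <- function(n_close, d = 2.9, n_far = 2) {
  ca <- c(0, 0, 0)
  b_close <- t(vapply(seq_len(max(n_close, 1)), function(m)
    ca + d * c(sin(0.3 * (m - 2)), cos(0.3 * (m - 2)), 0), numeric(3)))
  b_close <- b_close[seq_len(n_close), , drop = FALSE]
  b_far <- cbind(seq_len(n_far) * 2, rep(9, n_far), 0)
  b <- rbind(b_close, b_far)
  contact_frame(
    atom_id = seq_len(5 + nrow(b)),
    atom_name = "X", residue_name = "ALA",
    residue_number = c(rep(1L, 5), rep(1L, nrow(b))),
    molecule_tag = c(rep("A", 5), rep("B", nrow(b))),
    x = c(0, -1.2, 1.2, 1.2, -1.2, b[, 1]),
    y = c(0, -1, -1, -2, -2, b[, 2]),
    z = c(0, 0, 0, 0, 0, b[, 3]))
}

test_that("contact rule boundary: 3 atoms within cutoff flag, 2 do not", {
  expect_equal(nrow(flag_contacts(boundary_frame(3))), 1L)
  expect_equal(nrow(flag_contacts(boundary_frame(2))), 0L)
  # the flagging side is recorded
  fl <- flag_contacts(boundary_frame(3))
  expect_equal(fl$trigger, "B")
  expect_equal(fl$n_atoms_B, 3L)
  # min_atoms monotonicity
  expect_equal(nrow(flag_contacts(boundary_frame(3), min_atoms = 4)), 0L)
  expect_equal(nrow(flag_contacts(boundary_frame(2), min_atoms = 2)), 1L)
})

test_that("fully separated chains give an empty contact list", {
  f <- boundary_frame(0)
  expect_equal(nrow(flag_contacts(f)), 0L)
})

test_that("flag_contacts equals the brute-force all-pairs oracle", {
  set.seed(424)
  for (rep in 1:50) {
    f <- random_contact_frame(200)
    got <- flag_contacts(f)
    want <- brute_force_contacts(f)
    expect_equal(got$residue_A_number, want$residue_A_number)
    expect_equal(got$residue_B_number, want$residue_B_number)
    expect_equal(got$n_atoms_A, want$n_atoms_A)
    expect_equal(got$n_atoms_B, want$n_atoms_B)
  }
})

test_that("flagged pairs are monotone in cutoff and min_atoms", {
  set.seed(77)
  f <- random_contact_frame(200)
  key <- function(fl) paste(fl$residue_A_number, fl$residue_B_number)
  small <- key(flag_contacts(f, cutoff = 2.5))
  large <- key(flag_contacts(f, cutoff = 4))
  expect_true(all(small %in% large))
  strict <- key(flag_contacts(f, min_atoms = 4))
  loose <- key(flag_contacts(f, min_atoms = 2))
  expect_true(all(strict %in% loose))
})

test_that("contacts are invariant under rigid rotation + translation", {
  set.seed(12)
  f <- random_contact_frame(150)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(as.data.frame(f)[, c("x", "y", "z")]) %*% Rz
  f2 <- f
  f2$x <- xyz[, 1] + 5
  f2$y <- xyz[, 2] - 3
  f2$z <- xyz[, 3] + 11
  fl1 <- flag_contacts(f)
  fl2 <- flag_contacts(f2)
  expect_equal(fl1[c("residue_A_number", "residue_B_number", "n_atoms_A",
                     "n_atoms_B")],
               fl2[c("residue_A_number", "residue_B_number", "n_atoms_A",
                     "n_atoms_B")])
})

test_that("flag_contacts validates its input", {
  f <- boundary_frame(3)
  expect_error(flag_contacts(f, cutoff = -1), "positive")
  single <- f[f$molecule_tag == "A", ]
  class(single) <- c("contact_frame", "data.frame")
  expect_error(flag_contacts(single), "two molecule tags")
})

test_that("aggregate_sites computes occupancy and is frame-order invariant",
{
  toy <- generate_toy_complex(planted_interface(data.frame(
    res_A = c(2, 6), res_B = c(2, 6), n_within = c(3, 4),
    distance = c(2.5, 2.6), occupancy = c(0.9, 0.1)), jitter_sd = 0),
    n_frames = 20, seed = 3)
  sites <- aggregate_sites(toy$trajectory)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$occupancy[sites$residue_A_number == 2], 0.9)
  expect_equal(sites$occupancy[sites$residue_A_number == 6], 0.1)
  expect_equal(sites$frames[[1]], 1:18)
  # permuted frames: same occupancies
  perm <- sample(20)
  traj2 <- md_trajectory(unclass(toy$trajectory)[perm])
  sites2 <- aggregate_sites(traj2)
  expect_equal(sites2$occupancy[order(sites2$residue_A_number)],
               sites$occupancy[order(sites$residue_A_number)])
  expect_error(aggregate_sites(md_trajectory(list())), "")
})

test_that("adjacent residue pairs sharing frames merge into one site group",
{
  toy <- generate_toy_complex(planted_interface(data.frame(
    res_A = c(4, 5, 12), res_B = c(4, 5, 12), n_within = 3,
    distance = 2.5, occupancy = c(1, 1, 1)), jitter_sd = 0),
    n_frames = 10, seed = 8)
  sites <- aggregate_sites(toy$trajectory)
  expect_equal(nrow(sites), 3L)
  g <- sites$site_group[order(sites$residue_A_number)]
  expect_equal(g[1], g[2])   # residues 4 and 5: one site
  expect_false(g[3] == g[1]) # residue 12: separate site
})

test_that("electrostatic score matches hand Coulomb arithmetic", {
  # two unit charges +1/-1 at 3.320636 A -> -100 kcal/mol exactly
  f <- contact_frame(atom_id = 1:2, atom_name = "X", residue_name = "GLY",
                     residue_number = c(1L, 1L),
                     molecule_tag = c("A", "B"),
                     x = c(0, 3.320636), y = 0, z = 0,
                     charge = c(1, -1))
  site <- list(residue_A_number = 1L, residue_B_number = 1L)
  expect_equal(electrostatic_score(site, f), -100, tolerance = 1e-12)
  # doubling the dielectric halves the score
  expect_equal(electrostatic_score(site, f, dielectric = 2), -50,
               tolerance = 1e-12)
  # atoms beyond the 12 A pair cutoff do not contribute
  f2 <- f
  f2$x[2] <- 13
  expect_equal(electrostatic_score(site, f2), 0)
  # all-zero charges: score 0 with warning
  f3 <- f
  f3$charge <- 0
  expect_warning(s <- electrostatic_score(site, f3), "zero")
  expect_equal(s, 0)
})

test_that("classify_stability applies the 10%-of-max rule", {
  expect_equal(classify_stability(c(-100, -50, -9)),
               c(TRUE, TRUE, FALSE))
  expect_equal(classify_stability(c(-100, -50, -10)), rep(TRUE, 3))
  expect_true(classify_stability(-42))            # singleton -> stable
  expect_equal(classify_stability(rep(7, 4)), rep(TRUE, 4)) # ties at max
  expect_error(classify_stability(numeric()), "no sites")
})

test_that("score_sites + classify_stability work end to end on a complex", {
  toy <- generate_toy_complex(planted_interface(data.frame(
    res_A = c(2, 6), res_B = c(2, 6), n_within = 3, distance = 2.5,
    occupancy = 1, q_A = c(1, 0.02), q_B = c(-1, -0.02)),
    jitter_sd = 0), n_frames = 5, seed = 2)
  sites <- aggregate_sites(toy$trajectory)
  sites <- score_sites(sites, toy$trajectory)
  sites <- classify_stability(sites)
  strong <- sites$residue_A_number == 2
  expect_lt(sites$electrostatic_score[strong], 0)
  expect_true(sites$stable[strong])
  expect_false(sites$stable[!strong]) # 4e-4 of the strong site's charge
})
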