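test_that("noiseless generation closes exactly under double referencing", {
  sc <- sensorgram_scenario(rate_constants(4.5e4, 1.03e-3, 100, 1e8),
                            concentrations = c(1e-7, 1e-6),
                            schedule = injection_schedule(dt = 2),
                            noise_sd = 0, drift = 0.01, bulk_jump = 6,
                            seed = 10)
  gen <- generate_sensorgram_series(sc)
  ref <- reference_series(gen)
  for (cv in ref$curves) {
    sch <- injection_schedule(concentration = cv$concentration, dt = 2)
    pure <- simulate_two_compartment(
      rate_constants(4.5e4, 1.03e-3, 100, 1e8), sch)
    expect_equal(cv$response, pure$response, tolerance = 1e-9)
  }
})

test_that("generation is deterministic given the seed", {
  sc <- sensorgram_scenario(rate_constants(1e4, 1e-3, 100, 1e8),
                            concentrations = c(1e-7, 1e-6),
                            schedule = injection_schedule(dt = 5),
                            seed = 77)
  g1 <- generate_sensorgram_series(sc)
  g2 <- generate_sensorgram_series(sc)
  expect_identical(g1$curves[[1]]$sample$response,
                   g2$curves[[1]]$sample$response)
  # serialisation is byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  write_series_fixtures(g1, d1)
  write_series_fixtures(g2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_true(all(mapply(function(a, b)
    identical(readLines(a), readLines(b)), f1, f2)))
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_sensorgram_series(sc)); after <- rnorm(1)
  expect_identical(before, after)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("fixtures round trip through CSV + sidecar", {
  sc <- sensorgram_scenario(rate_constants(1e4, 1e-3, 100, 1e8),
                            concentrations = c(1e-7),
                            schedule = injection_schedule(dt = 5),
                            seed = 3)
  gen <- generate_sensorgram_series(sc)
  d <- tempfile()
  write_series_fixtures(gen, d)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$k_on, 1e4)
  expect_equal(truth$seed, 3)
  sg <- read_sensorgram_csv(file.path(d, "sample_01.csv"))
  expect_equal(sg$concentration, 1e-7)
  expect_equal(sg$response, gen$curves[[1]]$sample$response,
               tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})

test_that("scenario invariants are enforced", {
  p <- rate_constants(1e4, 1e-3)
  expect_error(sensorgram_scenario(p, concentrations = c(1e-7, 1e-7)),
               "anyDuplicated|distinct")
  expect_error(sensorgram_scenario(p, noise_sd = -1), "noise_sd")
})

test_that("planted interfaces satisfy/violate the contact rule as built", {
  # 3 atoms at 2.5 A, occupancy 1 -> flagged in every frame
  toy3 <- generate_toy_complex(planted_interface(data.frame(
    res_A = 2, res_B = 2, n_within = 3, distance = 2.5, occupancy = 1)),
    n_frames = 10, seed = 4)
  sites <- aggregate_sites(toy3$trajectory)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$occupancy, 1)
  # 2 atoms at 2.5 A (rest far) -> never flagged
  toy2 <- generate_toy_complex(planted_interface(data.frame(
    res_A = 2, res_B = 2, n_within = 2, distance = 2.5, occupancy = 1)),
    n_frames = 10, seed = 4)
  expect_equal(nrow(aggregate_sites(toy2$trajectory)), 0L)
  # zero jitter, identical frames: occupancy exactly 0 or 1
  toy <- generate_toy_complex(planted_interface(data.frame(
    res_A = c(2, 5), res_B = c(2, 5), n_within = 3, distance = 2.5,
    occupancy = c(1, 0)), jitter_sd = 0), n_frames = 7, seed = 5)
  s <- aggregate_sites(toy$trajectory)
  expect_true(all(s$occupancy %in% c(0, 1)))
  # occupancy truth sidecar matches the module output within one frame
  toy9 <- generate_toy_complex(planted_interface(data.frame(
    res_A = c(2, 5), res_B = c(2, 5), n_within = c(3, 4),
    distance = c(2.5, 2.7), occupancy = c(0.9, 0.1))),
    n_frames = 20, seed = 6)
  s9 <- aggregate_sites(toy9$trajectory)
  s9 <- s9[order(s9$residue_A_number), ]
  expect_true(all(abs(s9$n_frames -
                        toy9$truth$occupancy_exact * 20) <= 1))
})

test_that("infeasible geometry (atom overlap) errors", {
  spec <- planted_interface(data.frame(
    res_A = 2, res_B = 2, n_within = 3, distance = 0.1, occupancy = 1),
    jitter_sd = 0)
  expect_error(generate_toy_complex(spec, n_frames = 1, seed = 1),
               "infeasible")
})

test_that("the catalog ships all detectable interactions", {
  cat_tab <- kinetics_catalog()
  expect_equal(nrow(cat_tab), 8L)
  expect_true(all(kd_from_rates(cat_tab$k_on, cat_tab$k_off) > 0))
  # ratio agrees with the printed K_D to within one unit in the 3rd digit
  ulp3 <- 10^(floor(log10(cat_tab$K_D_printed)) - 2)
  expect_true(all(abs(cat_tab$k_off / cat_tab$k_on - cat_tab$K_D_printed)
                  <= ulp3 + 1e-15))
})
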