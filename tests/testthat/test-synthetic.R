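test_that("occupancy model matches the closed form and its limits", {
  # symmetric sites at rho = 0 give even splicing
  expect_equal(occupancy_psi(make_event(kwp = 1.7, kwd = 1.7), 0), 0.5)
  # pure mutant with vanishing proximal affinity abolishes inclusion
  ev <- make_event(kwp = 1, kwd = 1, kmp = 1e-12, kmd = 1)
  expect_lt(occupancy_psi(ev, Inf), 1e-9)
  # hand evaluation: rho=1, Kwp=2, Kwd=1, Kmp=1, Kmd=1 -> 1.5/2.5
  ev <- make_event(kwp = 2, kwd = 1, kmp = 1, kmd = 1)
  expect_equal(occupancy_psi(ev, 1), 0.6)
})

test_that("occupancy model rejects invalid parameters", {
  expect_error(occupancy_psi(make_event(), -0.1), "rho")
  expect_error(make_event(kwp = 0), "ka_wt_prox")
  expect_error(make_event(kmd = -1), "ka_mut_dist")
})

test_that("psi is monotone in rho with sign Kmp*Kwd - Kmd*Kwp", {
  set.seed(7)
  for (i in 1:200) {
    k <- exp(rnorm(4, 0, 1))
    ev <- make_event(kwp = k[1], kwd = k[2], kmp = k[3], kmd = k[4])
    rho <- sort(runif(2, 0, 5))
    d <- occupancy_psi(ev, rho[2]) - occupancy_psi(ev, rho[1])
    expected_sign <- sign(k[3] * k[2] - k[4] * k[1])
    if (abs(d) > 1e-12) expect_equal(sign(d), expected_sign)
  }
})

test_that("sim_event validates its sequence window", {
  expect_silent(make_event(m3 = "T", window = "CCCCCCCCCCCCCCCCCTAGGGA"))
  expect_error(make_event(m3 = "T", window = "CCCCCCCCCCCCCCCCCTACGGA"), "AG")
  expect_error(make_event(m3 = "C", window = "CCCCCCCCCCCCCCCCCTAGGGA"),
               "disagrees")
})

test_that("cohort simulation honours degenerate and null configurations", {
  ev <- list(make_event("e1"), make_event("e2"))
  cfg0 <- sim_cohort_config(n_wt_samples = 3, n_mut_samples = 1,
                            ratio_per_mut_sample = 0.5,
                            read_depth_per_event = 0, allele_depth = 0,
                            noise_seed = 1)
  co <- simulate_cohort(ev, cfg0)
  expect_true(all(co$junctions$inclusion_reads == 0))
  expect_true(all(co$junctions$exclusion_reads == 0))

  expect_error(simulate_cohort(list(), cfg0), "non-empty")

  # null cohort (all ratios zero): per-event mean delta psi vs cohort
  # median is centred on zero
  cfg <- sim_cohort_config(n_wt_samples = 40, n_mut_samples = 5,
                           ratio_per_mut_sample = rep(0, 5),
                           read_depth_per_event = 1000,
                           allele_depth = 100, noise_seed = 3)
  events <- simulate_events(50, seed = 4)
  co <- simulate_cohort(events, cfg)
  pm <- psi_matrix(co$junctions, events, min_informative = 20)
  med <- apply(pm$psi, 1, median)
  dpsi <- sweep(pm$psi, 1, med)
  expect_lt(abs(mean(dpsi)), 0.005)
})

test_that("higher mutant ratio raises inclusion of mutant-favoured events", {
  # -3C proximal sites with Kmp/Kwp > 1 at rho 0.3 vs 0.8, depth 1e4,
  # >= 50 replicate events: Monte Carlo against the occupancy oracle
  events <- lapply(1:60, function(i) {
    make_event(sprintf("e%02d", i), m3 = "C", kwp = 1, kwd = 1,
               kmp = 2.5, kmd = 1)
  })
  cfg <- sim_cohort_config(n_wt_samples = 1, n_mut_samples = 2,
                           ratio_per_mut_sample = c(0.3, 0.8),
                           read_depth_per_event = 1e4,
                           allele_depth = 100, noise_seed = 11)
  co <- simulate_cohort(events, cfg)
  pm <- psi_matrix(co$junctions, events)
  expect_gt(mean(pm$psi[, "MUT_002"]), mean(pm$psi[, "MUT_001"]))
  # and both agree with the occupancy-model expectation
  expect_equal(mean(pm$psi[, "MUT_002"]),
               occupancy_psi(events[[1]], 0.8), tolerance = 0.01)
})

test_that("estimated psi converges to true psi with depth", {
  ev <- make_event(kwp = 1.3, kwd = 1, kmp = 2, kmd = 1)
  truth <- occupancy_psi(ev, 0.6)
  set.seed(5)
  est <- rbinom(100, 1e5, truth) / 1e5
  expect_lt(abs(mean(est) - truth), 0.01)
})

test_that("identical seeds reproduce cohorts byte-identically", {
  events <- simulate_events(20, seed = 9)
  cfg <- sim_cohort_config(n_wt_samples = 5, n_mut_samples = 2,
                           ratio_per_mut_sample = c(0.3, 0.7),
                           read_depth_per_event = 50, allele_depth = 50,
                           noise_seed = 13)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(events, cfg), d1)
  write_cohort(simulate_cohort(events, cfg), d2)
  for (f in c("junctions.tsv", "alleles.tsv", "events.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("simulated titrations follow the depletion isotherm", {
  # zero protein reports the free-RNA anisotropy
  t0 <- simulate_titration(100, 10, c(0, 1, 2, 5, 10, 20), noise_sd = 0)
  expect_equal(t0$anisotropy[1], 0.05)
  # saturation approaches the bound endpoint
  ts <- simulate_titration(100, 10,
                           c(0, 10, 100, 1e3, 1e4, 1e5, 1e6), noise_sd = 0)
  expect_equal(ts$anisotropy[7], 0.20, tolerance = 1e-3)
  # hyperbolic limit: rna << kd and protein = kd gives half saturation
  th <- simulate_titration(100, 1e-3,
                           c(0, 25, 50, 100, 200, 400), noise_sd = 0)
  fb <- (th$anisotropy[4] - 0.05) / (0.20 - 0.05)
  expect_equal(fb, 0.5, tolerance = 0.01)
  # binding must increase the signal
  expect_error(simulate_titration(100, 10, c(0, 1, 2, 5, 10, 20),
                                  a_free = 0.2, a_bound = 0.1),
               "increases on binding")
  # unsorted concentrations rejected
  expect_error(simulate_titration(100, 10, c(5, 1, 2, 8, 10, 20)),
               "ascending")
})
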