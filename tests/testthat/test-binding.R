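std_concs <- function(kd) kd * c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50)

test_that("noiseless titrations recover the dissociation constant", {
  tt <- simulate_titration(100, 10, std_concs(100), noise_sd = 0)
  fit <- fit_titration(tt)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd / 100 - 1), 0.001)
  expect_equal(fit$ka * fit$kd, 1)
  expect_equal(fit$a_free, 0.05, tolerance = 1e-4)
  expect_equal(fit$a_bound, 0.20, tolerance = 1e-4)
})

test_that("flat series are reported unconverged with diagnostics", {
  flat <- titration("flat", 10, 1:10, rep(0.07, 10))
  fit <- fit_titration(flat)
  expect_false(fit$converged)
  expect_match(fit$diagnostics, "flat|unidentifiable|noise")
})

test_that("the depletion fit reduces to the hyperbola when RNA is scarce", {
  # at rna << kd the half-saturation point of the hyperbola is kd
  tt <- simulate_titration(50, 50e-4, std_concs(50), noise_sd = 0)
  fit <- fit_titration(tt)
  expect_lt(abs(fit$kd / 50 - 1), 0.01)
})

test_that("fit residual shrinks as noise shrinks", {
  fits <- lapply(c(0.01, 0.002), function(ns) {
    tt <- simulate_titration(80, 8, std_concs(80),
                             noise_sd = ns * 0.15, seed = 91)
    fit_titration(tt)
  })
  expect_lt(fits[[2]]$residual_norm, fits[[1]]$residual_norm)
})

test_that("triplicate noisy titrations recover KD within 10% median error", {
  errs <- vapply(1:30, function(i) {
    kd <- 10^runif(1, 0, 2)
    hats <- vapply(1:3, function(r) {
      tt <- simulate_titration(kd, kd / 10, std_concs(kd),
                               noise_sd = 0.02 * 0.15,
                               seed = 9000 + 10 * i + r)
      fit_titration(tt)$kd
    }, numeric(1))
    abs(mean(hats) / kd - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("fold changes use Welch's t test on log affinities", {
  wt <- lapply(c(1, 1.1, 0.9), fake_fit)
  same <- fold_change(wt, wt)
  expect_equal(same$fc, 1)
  expect_equal(same$p_value, 1)

  mut <- lapply(c(2, 2.2, 1.8), fake_fit)
  up <- fold_change(wt, mut)
  expect_equal(up$fc, 2)
  expect_true(up$significant)

  mut_ns <- lapply(c(1, 1.2, 0.95), fake_fit)
  ns <- fold_change(wt, mut_ns)
  expect_false(ns$significant)

  expect_error(fold_change(wt[1:2], mut), ">= 3 replicate")
  bad <- wt
  bad[[1]]$converged <- FALSE
  expect_error(fold_change(bad, mut), "converged")
})

test_that("Welch test does not exceed its nominal level on null affinities", {
  # with triplicates the Welch-Satterthwaite approximation is
  # conservative (true size ~0.034 at nominal 0.05), so the honest
  # property is control of, not equality to, the nominal level
  set.seed(101)
  reject <- vapply(1:2000, function(i) {
    a <- exp(rnorm(3, 0, 0.2))
    b <- exp(rnorm(3, 0, 0.2))
    fold_change(lapply(a, fake_fit), lapply(b, fake_fit))$significant
  }, logical(1))
  rate <- mean(reject)
  ci <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(rate, 0.05 + ci)
  expect_gt(rate, 0.01)
})

test_that("competition rule reproduces the published site patterns", {
  sig_down <- fold_change_result("p", 0.4, 0.01)
  sig_up <- fold_change_result("p", 1.8, 0.01)
  ns <- fold_change_result("d", 1.0, 0.6)
  # proximal loss alone: exon skipping
  expect_equal(predict_direction(sig_down, ns), "decreased")
  # proximal gain alone: exon inclusion
  expect_equal(predict_direction(sig_up, ns), "increased")
  # both sites lose but the distal loses more: net proximal gain
  both_p <- fold_change_result("p", 0.7, 0.04)
  both_d <- fold_change_result("d", 0.3, 0.01)
  expect_equal(predict_direction(both_p, both_d), "increased")
  # no significant change anywhere: no call
  expect_equal(predict_direction(ns, ns), "no_call")
})

test_that("swapping proximal and distal sites flips the prediction", {
  set.seed(102)
  flip <- c(increased = "decreased", decreased = "increased",
            no_call = "no_call")
  for (i in 1:100) {
    p <- fold_change_result("p", exp(rnorm(1)), runif(1))
    d <- fold_change_result("d", exp(rnorm(1)), runif(1))
    expect_equal(predict_direction(d, p),
                 unname(flip[predict_direction(p, d)]))
  }
})

test_that("concordance scoring counts matches and excludes unobserved events", {
  p <- fold_change_result("p", 2, 0.01)
  d <- fold_change_result("d", 1, 0.5)
  good <- competition_prediction("e1", p, d, observed = "increased")
  bad <- competition_prediction("e2", p, d, observed = "decreased")
  none <- competition_prediction("e3", p, d)
  expect_true(good$concordant)
  expect_false(bad$concordant)

  all_good <- concordance(list(good, good))
  expect_equal(all_good$fraction, 1)

  empty <- concordance(list())
  expect_equal(empty$total, 0)
  expect_true(is.nan(empty$fraction))

  expect_warning(mix <- concordance(list(good, none)), "without an observed")
  expect_equal(mix$total, 1)

  # a no_call prediction scores discordant even when something was observed
  nc <- competition_prediction("e4", d, d, observed = "increased")
  expect_equal(nc$predicted, "no_call")
  expect_false(nc$concordant)
})
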