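test_that("F-18 decay factor matches the closed form", {
  # (1 - 2^(-20/109.77)) * 109.77 / (20 ln 2)
  expect_rel_equal(decay_factor(20), 0.9394310, 1e-6)
  expect_lt(decay_factor(200), decay_factor(5))
  expect_error(decay_factor(0), "positive")
})

test_that("energy-window survival matches the normal-CDF closed form", {
  g <- build_scanner("uexplorer")
  s <- energy_fwhm(g, 307) / (2 * sqrt(2 * log(2)))
  expect_rel_equal(energy_fwhm(g, 307), 46.341, 1e-4)
  expect_rel_equal(energy_window_survival(g, 307, c(250, 350)), 0.9836, 2e-4)
  # raising the low edge 250 -> 290 removes 19.2% of the photopeak under
  # the Gaussian resolution model
  removed <- energy_window_survival(g, 307, c(250, 350)) -
    energy_window_survival(g, 307, c(290, 350))
  expect_rel_equal(removed, 0.192, 5e-3)
  expect_rel_equal(energy_window_survival(g, 307, c(-1e5, 1e5)), 1, 1e-12)
  # sampled events agree with the closed form
  set.seed(31)
  pass <- apply_energy_window(g, rep(307, 2e4), c(250, 350))
  expect_lt(abs(mean(pass) - 0.9836), 0.005)
  expect_error(energy_window_survival(g, 307, c(350, 250)), "low edge")
})

test_that("blank simulation is linear in duration and rate, and seeded", {
  su <- tiny_setup()
  lu <- lu_source_model()
  b1 <- simulate_blank(su$geometry, su$lors, lu, duration_min = 10,
                       exposure_scale = 1e-5, seed = 4L)
  b2 <- simulate_blank(su$geometry, su$lors, lu, duration_min = 20,
                       exposure_scale = 1e-5, seed = 4L)
  expect_rel_equal(sum(b2$expectation), 2 * sum(b1$expectation), 1e-12)
  # doubling observed totals consistent within 3 sigma of Poisson
  expect_lt(abs(sum(b2$counts) - 2 * sum(b1$counts)),
            3 * sqrt(sum(b2$counts) + 4 * sum(b1$counts)) + 1)
  lu0 <- lu_source_model(rate_per_cc = 0)
  b0 <- simulate_blank(su$geometry, su$lors, lu0, seed = 4L)
  expect_true(all(b0$counts == 0))
  b1b <- simulate_blank(su$geometry, su$lors, lu, duration_min = 10,
                        exposure_scale = 1e-5, seed = 4L)
  expect_identical(b1$counts, b1b$counts)
  # exposure calibration hits the requested total
  ex <- exposure_for_counts(su$geometry, su$lors, lu, 20, 1e6)
  b <- simulate_blank(su$geometry, su$lors, lu, 20, ex)
  expect_rel_equal(sum(b$expectation), 1e6, 1e-9)
})

test_that("transmission expectation is the blank attenuated at 307 keV", {
  sv <- single_voxel_problem(200)
  ph <- list(mu = array(0.0096, c(1, 1, 1)),
             activity = array(0, c(1, 1, 1)),
             voxel_size = 200, dim = c(1L, 1L, 1L),
             origin = sv$grid$origin)
  class(ph) <- "phantom"
  lu <- lu_source_model()
  bl <- simulate_blank(sv$geometry, sv$lors, lu, 20, exposure_scale = 1e6,
                       seed = 1L)
  tr <- simulate_transmission(sv$geometry, ph, sv$lors, lu, 20,
                              exposure_scale = 1e6, seed = 1L)
  # 200 mm of water: ratio exp(-eta * 0.0096 * 200) = 0.0947
  expect_rel_equal(mean(tr$counts) / bl$expectation, 0.0947,
                   5 / sqrt(tr$counts))
  expect_true(all(tr$categories$scattered_307 == 0))
  expect_true(all(tr$categories$contamination_511 == 0))
  # category bookkeeping is an exact integer identity
  expect_identical(tr$counts, tr$categories$true_307 +
                     tr$categories$scattered_307 +
                     tr$categories$contamination_511)
})

test_that("vacuum transmission equals the blank in distribution", {
  su <- tiny_setup()
  ph <- small_phantom()
  vac <- ph
  vac$mu <- array(0, ph$dim)
  vac$activity <- array(0, ph$dim)
  lu <- lu_source_model()
  ex <- exposure_for_counts(su$geometry, su$lors, lu, 20, 2e5)
  bl <- simulate_blank(su$geometry, su$lors, lu, 20, ex, seed = 7L)
  tr <- simulate_transmission(su$geometry, vac, su$lors, lu, 20, ex,
                              seed = 8L)
  ks <- suppressWarnings(stats::ks.test(bl$counts, tr$counts))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-scatter mode adds a separate contaminating category", {
  su <- tiny_setup()
  ph <- small_phantom()
  lu <- lu_source_model()
  ex <- exposure_for_counts(su$geometry, su$lors, lu, 20, 5e5)
  tr0 <- simulate_transmission(su$geometry, ph, su$lors, lu, 20, ex,
                               seed = 9L)
  trS <- simulate_transmission(su$geometry, ph, su$lors, lu, 20, ex,
                               scatter_mode = "single_scatter", seed = 9L)
  expect_identical(trS$categories$true_307, tr0$categories$true_307)
  expect_gt(sum(trS$categories$scattered_307), 0)
  # a tighter 290 keV threshold removes a larger fraction of the scatter
  # than of the photopeak
  tr290 <- simulate_transmission(su$geometry, ph, su$lors, lu, 20, ex,
                                 gamma_window = c(290, 350),
                                 scatter_mode = "single_scatter", seed = 9L)
  frac_sc <- sum(tr290$categories$scattered_307) /
    sum(trS$categories$scattered_307)
  frac_true <- sum(tr290$categories$true_307) /
    sum(trS$categories$true_307)
  expect_lt(frac_sc, frac_true)
})

test_that("emission sinograms marginalize to the attenuated projection", {
  su <- tiny_setup()
  ph <- small_phantom()
  grid <- phantom_grid(ph)
  ex <- emission_exposure_for_counts(su$geometry, ph, su$lors, 20, 3e5)
  em <- simulate_emission(su$geometry, ph, su$lors, 20, ex, seed = 10L,
                          keep_expectation = TRUE)
  a <- attenuation_factors(ph$mu, su$lors, grid, 511)
  nf <- forward_project(ph$activity, su$lors, grid) * a *
    20 * 60 * decay_factor(20) * ex
  expect_true(all(abs(rowSums(em$expectation) - nf) <=
                    1e-3 * pmax(nf, 1e-9)))
  # zero activity gives zeros
  vac <- ph; vac$activity <- array(0, ph$dim)
  em0 <- simulate_emission(su$geometry, vac, su$lors, 20, ex, seed = 10L)
  expect_equal(sum(em0$counts), 0)
})

test_that("TOF rejection separates crystal-origin from body-origin events", {
  g <- build_scanner("uexplorer")
  sigma <- g$ctr_ps / (2 * sqrt(2 * log(2)))
  set.seed(32)
  # emission at the midpoint of a 786-mm LOR: essentially always rejected
  acc_mid <- reject_by_tof(g, rep(0, 2e4), 786)
  expect_lt(mean(acc_mid), 1 - stats::pnorm(2121.8 / sigma) + 0.01)
  # event at the crystal sits 500 ps above threshold per side
  acc_cry <- reject_by_tof(g, rep(786 / 2, 2e4), 786)
  expect_lt(abs(mean(acc_cry) - stats::pnorm(500 / sigma)), 0.01)
  # short LOR: negative threshold accepts everything
  expect_true(all(reject_by_tof(g, runif(1000, -50, 50), 100)))
  # contamination surviving the TOF gate decreases as timing improves
  acc <- vapply(c(700, 430, 200), function(ctr) {
    gg <- g; gg$ctr_ps <- ctr
    mean(reject_by_tof(gg, runif(2e4, -100, 100), 786))
  }, 0)
  expect_true(all(diff(acc) <= 0))
})

test_that("normalization factors are unity in ideal mode and recover an
           injected efficiency", {
  su <- tiny_setup()
  nf <- normalization_factors(su$geometry, su$lors, "ideal")
  expect_true(all(nf$n == 1))
  nfa <- normalization_factors(su$geometry, su$lors, "annulus",
                               duration_min = 3000, seed = 12L)
  expect_lt(max(abs(nfa$efficiency - 1)), 0.01)
  # double one crystal's efficiency and recover it within 5%
  eff <- rep(1, su$geometry$crystals_per_ring)
  eff[5] <- 2
  nfb <- normalization_factors(su$geometry, su$lors, "annulus",
                               efficiency = eff, duration_min = 3000,
                               seed = 13L)
  rec <- nfb$efficiency[5] / mean(nfb$efficiency[-5])
  expect_lt(abs(rec - 2) / 2, 0.05)
})

test_that("sinogram sets round-trip through the binary container", {
  su <- tiny_setup()
  set.seed(14)
  arrs <- list(blank = rpois(su$lors$n, 5),
               emission = matrix(rpois(su$lors$n * 3, 1), su$lors$n))
  d <- file.path(tempdir(), "sino_rt")
  write_sinograms(arrs, list(duration_min = 20, seed = 14), d)
  back <- read_sinograms(d)
  expect_equal(back$arrays$blank, as.numeric(arrs$blank))
  expect_equal(back$arrays$emission, matrix(as.numeric(arrs$emission),
                                            su$lors$n))
  expect_equal(back$header$duration_min, 20)
  unlink(d, recursive = TRUE)
})
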