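test_that("DOI depth matches the truncated-exponential closed form", {
  expect_rel_equal(doi_depth(0.6, eta = 1), 7.623288, 1e-5)
  expect_rel_equal(doi_depth(0.6, eta = 1.2276), 6.966008, 1e-5)
  expect_equal(doi_depth(0, eta = 1), 0)
  expect_rel_equal(doi_depth(1, eta = 1), 18.1, 1e-9)
  # strictly increasing in Y, decreasing in eta
  y <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(doi_depth(y, eta = 1)) > 0))
  expect_true(all(doi_depth(y, eta = 1.2276) < doi_depth(y, eta = 1)))
  expect_error(doi_depth(1.2), "0, 1")
})

test_that("Siddon traversal conserves the clipped chord length", {
  grid <- list(origin = c(-48, -48, -48), voxel_size = 4,
               dim = c(24L, 24L, 24L))
  # axis-aligned ray: one entry per voxel, each the voxel size
  p <- siddon_path(c(-100, -2, -2), c(100, -2, -2), grid)
  expect_equal(nrow(p), 24L)
  expect_true(all(abs(p$length - 4) < 1e-9))
  # ray missing the grid
  expect_equal(nrow(siddon_path(c(-100, 200, 0), c(100, 200, 0), grid)), 0L)
  expect_error(siddon_path(c(1, 2, 3), c(1, 2, 3), grid), "degenerate")
  # random oblique rays vs an independent fine-sampling clip oracle
  set.seed(21)
  for (i in 1:50) {
    p1 <- runif(3, -120, 120); p2 <- runif(3, -120, 120)
    pp <- siddon_path(p1, p2, grid)
    tt <- seq(0, 1, length.out = 40001)
    pts <- outer(tt, p2 - p1) + rep(p1, each = length(tt))
    lo <- grid$origin; hi <- grid$origin + grid$dim * grid$voxel_size
    inside <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
    oracle <- sqrt(sum((p2 - p1)^2)) * mean(inside)
    expect_lt(abs(sum(pp$length) - oracle), 0.05)
  }
})

test_that("back projection is the exact adjoint of forward projection", {
  ph <- small_phantom()
  grid <- phantom_grid(ph)
  g <- build_scanner("uexplorer")
  set.seed(22)
  n <- 200
  p1 <- cbind(runif(n, -400, -300), runif(n, -60, 60), runif(n, -60, 60))
  p2 <- cbind(runif(n, 300, 400), runif(n, -60, 60), runif(n, -60, 60))
  lt <- manual_lor_table(g, p1, p2)
  x <- array(runif(prod(grid$dim)), grid$dim)
  y <- runif(n)
  lhs <- sum(forward_project(x, lt, grid) * y)
  rhs <- sum(x * back_project(y, lt, grid))
  expect_rel_equal(lhs, rhs, 1e-9)
  # TOF version
  nt <- 15L
  sm <- matrix(runif(n * nt), n)
  lhs <- sum(tof_forward_project(x, lt, grid, nt) * sm)
  rhs <- sum(x * tof_back_project(sm, lt, grid))
  expect_rel_equal(lhs, rhs, 1e-9)
})

test_that("attenuation factors follow the exponential line integral", {
  sv <- single_voxel_problem(200)
  mu <- array(0.0096, c(1, 1, 1))
  a511 <- attenuation_factors(mu, sv$lors, sv$grid, 511)
  a307 <- attenuation_factors(mu, sv$lors, sv$grid, 307)
  expect_rel_equal(a511, exp(-1.92), 1e-9)
  expect_rel_equal(a307, exp(-1.2276 * 1.92), 1e-9)
  # empty path
  lt0 <- manual_lor_table(sv$geometry, c(-400, 500, 0), c(400, 500, 0))
  expect_equal(attenuation_factors(mu, lt0, sv$grid), 1)
  expect_error(attenuation_factors(array(-1, c(1, 1, 1)), sv$lors, sv$grid),
               "negative")
  # multiplicative under path splitting
  grid2 <- list(origin = c(-100, -50, -50), voxel_size = 100,
                dim = c(2L, 1L, 1L))
  mu2 <- array(c(0.0096, 0.005), c(2, 1, 1))
  whole <- attenuation_factors(mu2, sv$lors, grid2)
  gA <- list(origin = c(-100, -50, -50), voxel_size = 100, dim = c(1L, 1L, 1L))
  gB <- list(origin = c(0, -50, -50), voxel_size = 100, dim = c(1L, 1L, 1L))
  expect_rel_equal(whole,
                   attenuation_factors(array(0.0096, c(1, 1, 1)), sv$lors, gA) *
                     attenuation_factors(array(0.005, c(1, 1, 1)), sv$lors, gB),
                   1e-9)
})

test_that("TOF projection marginalizes to the non-TOF projection", {
  ph <- small_phantom()
  grid <- phantom_grid(ph)
  g <- build_scanner("uexplorer")
  set.seed(23)
  n <- 100
  p1 <- cbind(runif(n, -400, -350), runif(n, -40, 40), runif(n, -40, 40))
  p2 <- cbind(runif(n, 350, 400), runif(n, -40, 40), runif(n, -40, 40))
  lt <- manual_lor_table(g, p1, p2)
  nt <- n_tof_bins(g, lt)
  tf <- tof_forward_project(ph$activity, lt, grid, nt)
  nf <- forward_project(ph$activity, lt, grid)
  expect_true(all(abs(rowSums(tf) - nf) <= 1e-3 * pmax(nf, 1e-12)))
})

test_that("a displaced point source shifts the TOF peak by one bin", {
  g <- build_scanner("uexplorer")
  grid <- list(origin = c(-96, -96, -96), voxel_size = 4,
               dim = c(48L, 48L, 48L))
  lt <- manual_lor_table(g, c(393, -2, -2), c(-393, -2, -2))
  src <- function(ix) {
    a <- array(0, grid$dim); a[ix, 24, 24] <- 1; a
  }
  center <- tof_forward_project(src(24L), lt, grid, 21L)   # x = -2
  # 40.92 mm along the LOR corresponds to one 273 ps bin
  moved <- tof_forward_project(src(14L), lt, grid, 21L)    # x = -42
  expect_equal(which.max(center[1, ]), 11L)
  expect_equal(which.max(moved[1, ]), 12L)
})

test_that("eta transform scales and round-trips", {
  m <- array(c(0, 0.0096, 0.017), c(3, 1, 1))
  m307 <- eta_transform(m)
  expect_equal(m307[2], 0.01178496)
  expect_equal(eta_transform(array(0, c(2, 2, 2))), array(0, c(2, 2, 2)))
  expect_equal(eta_transform(m307, eta = 1 / 1.2276), m, tolerance = 1e-12)
})
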