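test_that("presets reproduce the printed acceptance angles", {
  u <- build_scanner("uexplorer")
  m <- build_scanner("one_meter")
  s <- build_scanner("conventional_24cm")
  expect_equal(u$n_axial_units, 8L)
  expect_equal(u$mud, 4)
  expect_equal(m$mud, Inf)
  expect_equal(s$n_axial_units, 1L)
  expect_equal(max_acceptance_angle(u, rounded = TRUE), 57)
  expect_equal(max_acceptance_angle(m, rounded = TRUE), 51)
  expect_equal(max_acceptance_angle(s, rounded = TRUE), 17)
  # span equal to the ring diameter gives exactly 45 degrees
  g45 <- build_scanner(n_axial_units = 1L, unit_length = 786, mud = Inf)
  expect_equal(max_acceptance_angle(g45), 45)
})

test_that("geometry validation rejects inconsistent policies", {
  expect_error(build_scanner(n_axial_units = 8L, mud = 9),
               "mud \\+ 1")
  expect_error(build_scanner(ring_diameter = -1), "positive")
  expect_error(build_scanner("not_a_scanner"))
})

test_that("acceptance angle is monotone in mud and unit count", {
  angs <- vapply(0:7, function(m)
    max_acceptance_angle(build_scanner(n_axial_units = 8L, mud = m)), 0)
  expect_true(all(diff(angs) > 0))
  angs2 <- vapply(1:8, function(k)
    max_acceptance_angle(build_scanner(n_axial_units = k, mud = Inf)), 0)
  expect_true(all(diff(angs2) > 0))
})

test_that("MUD policy gates LORs and the boundary is inclusive", {
  g <- desk_scale(build_scanner("uexplorer"))
  rpu <- g$rings_per_unit
  mk <- function(u1, u2) {
    list(a = list(trans = 0L, ring = u1 * rpu),
         b = list(trans = g$crystals_per_ring %/% 2L, ring = u2 * rpu))
  }
  p <- mk(0, 5)  # unit difference 5 under mud 4
  expect_false(lor_allowed(g, p$a, p$b))
  p <- mk(2, 2)  # same unit
  expect_true(lor_allowed(g, p$a, p$b))
  p <- mk(0, 4)  # boundary difference 4
  expect_true(lor_allowed(g, p$a, p$b))
  expect_error(lor_allowed(g, list(trans = -1, ring = 0),
                           list(trans = 0, ring = 0)), "out of range")
})

test_that("sinogram indexing round-trips and mashing groups rings", {
  g <- desk_scale(build_scanner("uexplorer"))
  sp <- sinogram_spec(g, axial_mash = 3)
  # mashed group of rings 4 and 5 is group 1 for both
  ca <- list(trans = 0L, ring = 4L)
  cb <- list(trans = 40L, ring = 5L)
  idx <- sinogram_index(g, sp, ca, cb)
  expect_equal(idx$plane %% sp$n_mashed, 1)   # floor(4/3)
  expect_equal(idx$plane %/% sp$n_mashed, 1)  # floor(5/3)
  # round trip over random allowed LORs
  set.seed(11)
  nc <- g$crystals_per_ring; nr <- g$n_rings
  n_ok <- 0L; tried <- 0L
  while (tried < 500L) {
    a <- list(trans = sample(0:(nc - 1), 1), ring = sample(0:(nr - 1), 1))
    b <- list(trans = sample(0:(nc - 1), 1), ring = sample(0:(nr - 1), 1))
    if (!lor_allowed(g, a, b)) next
    tried <- tried + 1L
    i1 <- sinogram_index(g, sp, a, b)
    cr <- sinogram_crystals(g, sp, i1$radial, i1$angle, i1$plane)
    i2 <- sinogram_index(g, sp, cr$a, cr$b)
    if (all(i1 == i2)) n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 500L)
  # transaxial bin keys are unique
  expect_equal(anyDuplicated(paste(sp$trans_lut$a, sp$trans_lut$r)), 0L)
  expect_equal(anyDuplicated(paste(sp$trans_lut$d1, sp$trans_lut$d2)), 0L)
})

test_that("TOF threshold follows the center-to-center transit time", {
  g <- build_scanner("uexplorer")
  expect_rel_equal(tof_threshold(g, 786), 2121.8, 1e-4)
  # a LOR of length c x 500 ps sits exactly at threshold zero
  expect_lt(abs(tof_threshold(g, 299.792 * 0.5)), 1e-9)
  expect_equal(tof_threshold(g, 0), -500)
})

test_that("allowed LORs respect the acceptance angle and preset equivalence", {
  g <- desk_scale(build_scanner("uexplorer"))
  sp <- sinogram_spec(g, axial_mash = 1)
  lt <- lor_table(g, sp)
  dz <- abs(lt$p2[, 3] - lt$p1[, 3])
  # every plane pair obeys the policy's axial span
  span <- tan(max_acceptance_angle(g) * pi / 180) * g$ring_diameter
  expect_true(all(dz <= span + 1e-6))
  # restricting the 194-cm geometry to 17 degrees and to one unit's rings
  # reproduces the 24-cm scanner's plane-pair set at that axial position
  sp17 <- sinogram_spec(g, axial_mash = 1, max_acceptance_angle = 17.14626)
  g24 <- desk_scale(build_scanner("conventional_24cm"))
  sp24 <- sinogram_spec(g24, axial_mash = 1)
  rpu <- g$rings_per_unit
  unit3 <- sp17$plane_pairs$m1 %/% rpu == 3 & sp17$plane_pairs$m2 %/% rpu == 3
  pp17 <- sp17$plane_pairs[unit3, ]
  key17 <- sort(paste(pp17$m1 %% rpu, pp17$m2 %% rpu))
  key24 <- sort(paste(sp24$plane_pairs$m1, sp24$plane_pairs$m2))
  expect_equal(key17, key24)
})

test_that("scanner configs round-trip through the YAML schema", {
  g <- desk_scale(build_scanner("one_meter"))
  p <- file.path(tempdir(), "geom.yaml")
  write_scanner_config(g, p)
  g2 <- read_scanner_config(p)
  for (f in c("ring_diameter", "n_axial_units", "unit_length", "mud",
              "crystal_pitch_trans", "crystal_pitch_axial", "n_rings",
              "crystals_per_ring", "ctr_ps", "tof_bin_width_ps")) {
    expect_equal(g2[[f]], g[[f]], info = f)
  }
  # the shipped preset file reproduces the full-size scanner
  shipped <- read_scanner_config(system.file("extdata", "uexplorer.yaml",
                                             package = "lutran"))
  expect_equal(max_acceptance_angle(shipped, rounded = TRUE), 57)
  expect_equal(shipped$n_rings, build_scanner("uexplorer")$n_rings)
  unlink(p)
})

test_that("bed protocols conserve scan time and cover the body", {
  p1 <- bed_protocol("uexplorer")
  p2 <- bed_protocol("one_meter")
  p8 <- bed_protocol("conventional_24cm")
  expect_equal(p1$n_beds * p1$per_bed_duration_min, 20)
  expect_equal(p2$n_beds * p2$per_bed_duration_min, 20)
  expect_equal(p8$n_beds * p8$per_bed_duration_min, 20)
  # two 1000-mm beds at 50% overlap cover 1500 mm
  p <- list(bed_axial_positions = c(-250, 250))
  expect_equal(bed_coverage(p, 1000), 1500)
  # eight abutting 242.5-mm beds cover 1940 mm
  expect_equal(bed_coverage(p8, 242.5), 1940)
})
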