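# Shared fixtures, built in code. Heavyweight objects are memoized per test
# run so several test files can reuse them.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

small_phantom <- function() {
  memo("small_phantom", {
    # compact torso: body + one lung + liver + spine, on a 24^3-ish grid
    spec <- list(
      list(name = "body", shape = "cylinder", tissue = "soft", activity = 2,
           center = c(0, 0), semi = c(40, 36), zlim = c(-44, 44)),
      list(name = "lung_left", shape = "ellipsoid", tissue = "lung",
           activity = 1, center = c(-18, 0, 10), semi = c(14, 16, 24)),
      list(name = "liver", shape = "ellipsoid", tissue = "liver",
           activity = 5, center = c(16, 2, -14), semi = c(18, 16, 20)),
      list(name = "spine", shape = "cylinder", tissue = "bone",
           activity = 1.5, center = c(0, 26), semi = c(8, 8),
           zlim = c(-44, 44))
    )
    build_phantom(spec, voxel_size = 4, dim = c(24L, 24L, 24L),
                  total_activity = 2)
  })
}

tiny_geometry <- function() memo("tiny_geometry", build_scanner("uexplorer"))

# a compact desk acquisition for integration-style tests: few rings, small
# phantom, so a full simulate+reconstruct loop takes seconds
tiny_setup <- function() {
  memo("tiny_setup", {
    ph <- small_phantom()
    cond <- desk_conditions()
    cond$crystals_per_ring <- 40L
    cond$rings_per_unit <- 2L
    cond$support_radius <- 60
    cond$blank_counts_20min <- 4e6
    cond$emission_counts_20min <- 2e6
    desk_setup(ph, "uexplorer", conditions = cond)
  })
}

# single-voxel problem: one LOR through one voxel of a given chord
single_voxel_problem <- function(chord_mm = 200) {
  g <- build_scanner("uexplorer")
  grid <- list(origin = rep(-chord_mm / 2, 3), voxel_size = chord_mm,
               dim = c(1L, 1L, 1L))
  lors <- manual_lor_table(g, c(-400, 0, 0), c(400, 0, 0))
  list(geometry = g, grid = grid, lors = lors)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-300), tol)
}
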