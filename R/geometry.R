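#' @useDynLib lutran, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois rnorm runif rbinom quantile median sd
#' @importFrom utils head tail
NULL

SPEED_OF_LIGHT_MM_NS <- 299.792 # mm per ns

#' Build a cylindrical scanner geometry
#'
#' Constructs a parametrized cylindrical PET scanner model. Three presets are
#' provided: \code{"uexplorer"} (eight 242.5-mm axial units, 194 cm axial
#' coverage, maximum-unit-difference policy MUD = 4), \code{"one_meter"}
#' (four units, no unit-difference restriction) and \code{"conventional_24cm"}
#' (a single unit, no restriction). All lengths are in mm.
#'
#' The crystal lattice can be coarsened for desk-scale work with
#' \code{\link{desk_scale}}, which preserves the ring diameter, the axial unit
#' structure and the MUD semantics so that acceptance-angle and policy math
#' stay exact while sinograms remain small.
#'
#' @param preset one of \code{"uexplorer"}, \code{"one_meter"},
#'   \code{"conventional_24cm"}, or \code{NULL} to build from explicit fields.
#' @param ring_diameter detector ring diameter in mm.
#' @param n_axial_units number of axial detector units.
#' @param unit_length axial length of one unit in mm (194 cm / 8 by default).
#' @param mud maximum unit difference allowed between the two crystals of a
#'   coincidence; \code{Inf} means unrestricted.
#' @param crystal_pitch_trans,crystal_pitch_axial crystal pitch in mm.
#' @param crystal_length crystal length (depth) in mm.
#' @param coincidence_window_ns coincidence time window in ns.
#' @param ctr_ps coincidence timing resolution, FWHM in ps.
#' @param energy_resolution_511 fractional energy resolution (FWHM) at 511 keV.
#' @param tof_bin_width_ps TOF bin width in ps.
#' @param transaxial_fov transaxial field of view diameter in mm.
#' @return an object of class \code{scanner_geometry}.
#' @export
build_scanner <- function(preset = NULL,
                          ring_diameter = 786,
                          n_axial_units = 8,
                          unit_length = 1940 / 8,
                          mud = 4,
                          crystal_pitch_trans = 2.76,
                          crystal_pitch_axial = 2.76,
                          crystal_length = 18.1,
                          coincidence_window_ns = 6.9,
                          ctr_ps = 430,
                          energy_resolution_511 = 0.117,
                          tof_bin_width_ps = 273,
                          transaxial_fov = 600) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("uexplorer", "one_meter", "conventional_24cm"))
    if (preset == "uexplorer") {
      n_axial_units <- 8L; mud <- 4
    } else if (preset == "one_meter") {
      n_axial_units <- 4L; mud <- Inf
    } else {
      n_axial_units <- 1L; mud <- Inf
    }
  }
  g <- list(
    preset = if (is.null(preset)) "custom" else preset,
    ring_diameter = ring_diameter,
    n_axial_units = as.integer(n_axial_units),
    unit_length = unit_length,
    mud = mud,
    crystal_pitch_trans = crystal_pitch_trans,
    crystal_pitch_axial = crystal_pitch_axial,
    crystal_length = crystal_length,
    coincidence_window_ns = coincidence_window_ns,
    ctr_ps = ctr_ps,
    energy_resolution_511 = energy_resolution_511,
    tof_bin_width_ps = tof_bin_width_ps,
    transaxial_fov = transaxial_fov,
    axial_offset = 0
  )
  g$crystals_per_ring <- as.integer(round(pi * ring_diameter / crystal_pitch_trans))
  if (g$crystals_per_ring %% 2L == 1L) g$crystals_per_ring <- g$crystals_per_ring + 1L
  g$rings_per_unit <- as.integer(round(unit_length / crystal_pitch_axial))
  g$n_rings <- g$n_axial_units * g$rings_per_unit
  class(g) <- "scanner_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  lens <- c(g$ring_diameter, g$unit_length, g$crystal_pitch_trans,
            g$crystal_pitch_axial, g$crystal_length, g$transaxial_fov)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all scanner lengths must be positive and finite")
  if (is.finite(g$mud)) {
    if (g$mud < 0 || g$mud != round(g$mud))
      stop("mud must be a non-negative integer or Inf")
    if (g$mud + 1 > g$n_axial_units)
      stop("mud + 1 must not exceed the number of axial units")
  }
  if (g$n_rings != g$n_axial_units * g$rings_per_unit)
    stop("inconsistent ring/unit counts")
  invisible(g)
}

#' Coarsen a scanner geometry to desk scale
#'
#' Replaces the crystal lattice with a reduced one (larger pitch), keeping the
#' ring diameter, the unit structure and the coincidence policy untouched.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param crystals_per_ring number of crystals per ring (even).
#' @param rings_per_unit number of crystal rings per axial unit.
#' @return the modified \code{scanner_geometry}.
#' @export
desk_scale <- function(geometry, crystals_per_ring = 80L, rings_per_unit = 8L) {
  stopifnot(inherits(geometry, "scanner_geometry"))
  crystals_per_ring <- as.integer(crystals_per_ring)
  if (crystals_per_ring %% 2L == 1L) stop("crystals_per_ring must be even")
  g <- geometry
  g$crystals_per_ring <- crystals_per_ring
  g$crystal_pitch_trans <- pi * g$ring_diameter / crystals_per_ring
  g$rings_per_unit <- as.integer(rings_per_unit)
  g$crystal_pitch_axial <- g$unit_length / g$rings_per_unit
  g$n_rings <- g$n_axial_units * g$rings_per_unit
  validate_geometry(g)
  g
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf("scanner_geometry [%s]: %d axial units x %.1f mm, ring diameter %.0f mm\n",
              x$preset, x$n_axial_units, x$unit_length, x$ring_diameter))
  cat(sprintf("  %d crystals/ring, %d rings, MUD %s, max acceptance angle %.1f deg\n",
              x$crystals_per_ring, x$n_rings,
              if (is.finite(x$mud)) as.character(x$mud) else "unrestricted",
              max_acceptance_angle(x)))
  invisible(x)
}

#' Maximum acceptance angle of a geometry
#'
#' Polar angle (from the transaxial plane) of the most oblique line of response
#' the coincidence policy permits: \code{atan(span / ring_diameter)} where the
#' allowed axial span is \code{(mud + 1) * unit_length} under a finite
#' maximum-unit-difference policy and the full axial length otherwise.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param rounded round to the nearest integer degree (reporting convention).
#' @return angle in degrees.
#' @export
max_acceptance_angle <- function(geometry, rounded = FALSE) {
  span <- if (is.finite(geometry$mud)) {
    (geometry$mud + 1) * geometry$unit_length
  } else {
    geometry$n_axial_units * geometry$unit_length
  }
  ang <- atan(span / geometry$ring_diameter) * 180 / pi
  if (rounded) round(ang) else ang
}

crystal_axial_length <- function(g) g$n_rings * g$crystal_pitch_axial

#' Crystal front-face center positions
#'
#' @param geometry a \code{scanner_geometry}.
#' @param trans transaxial crystal index, 0-based.
#' @param ring crystal ring index, 0-based.
#' @return matrix with columns x, y, z (mm); origin at the scanner center.
#' @export
crystal_position <- function(geometry, trans, ring) {
  g <- geometry
  if (any(trans < 0 | trans >= g$crystals_per_ring) ||
      any(ring < 0 | ring >= g$n_rings))
    stop("crystal index out of range")
  phi <- 2 * pi * (trans + 0.5) / g$crystals_per_ring
  r <- g$ring_diameter / 2
  z <- (ring + 0.5) * g$crystal_pitch_axial - crystal_axial_length(g) / 2 +
    g$axial_offset
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

crystal_unit <- function(g, ring) ring %/% g$rings_per_unit

#' Coincidence-policy check for a line of response
#'
#' A LOR is allowed when the axial unit difference of its two crystals is
#' within the MUD policy (always true when unrestricted) and the LOR crosses
#' the transaxial field of view.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param crystal_a,crystal_b lists or data frames with elements/columns
#'   \code{trans} and \code{ring} (0-based, vectorized).
#' @return logical vector.
#' @export
lor_allowed <- function(geometry, crystal_a, crystal_b) {
  g <- geometry
  ta <- crystal_a$trans; ra <- crystal_a$ring
  tb <- crystal_b$trans; rb <- crystal_b$ring
  if (any(c(ta, tb) < 0 | c(ta, tb) >= g$crystals_per_ring) ||
      any(c(ra, rb) < 0 | c(ra, rb) >= g$n_rings))
    stop("crystal index out of range")
  ok_mud <- if (is.finite(g$mud)) {
    abs(crystal_unit(g, ra) - crystal_unit(g, rb)) <= g$mud
  } else rep(TRUE, length(ta))
  delta <- abs(ta - tb)
  delta <- pmin(delta, g$crystals_per_ring - delta)
  s <- (g$ring_diameter / 2) * abs(cos(pi * delta / g$crystals_per_ring))
  ok_mud & (s <= g$transaxial_fov / 2) & (delta > 0)
}

#' Sinogram binning specification
#'
#' Enumerates the sinogram layout for a geometry: the transaxial
#' (radial, angle) lattice restricted to LORs crossing the FOV, axially mashed
#' plane pairs restricted to the acceptance angle, and the TOF axis for
#' emission data. The transaxial lookup table and the mashed plane table are
#' precomputed so that crystal-pair-to-bin mapping is a table lookup.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param axial_mash number of crystal rings binned into one sinogram plane.
#' @param max_acceptance_angle acceptance angle limit in degrees; defaults to
#'   the geometry's policy angle. Smaller values restrict the plane pairs
#'   (axial-span criterion \code{|dz| <= tan(angle) * ring_diameter}).
#' @param tof logical; include a TOF axis (emission sinograms).
#' @return object of class \code{sinogram_spec}.
#' @export
sinogram_spec <- function(geometry, axial_mash = 3L,
                          max_acceptance_angle = NULL, tof = FALSE) {
  g <- geometry
  nc <- g$crystals_per_ring
  if (is.null(max_acceptance_angle)) {
    max_acceptance_angle <- max_acceptance_angle(g)
  }
  # transaxial LUT: all unordered FOV-crossing crystal pairs, canonical d1 < d2
  dmin_cos <- g$transaxial_fov / g$ring_diameter  # |cos(pi delta / nc)| <= this
  delta_all <- 1:(nc - 1)
  keep <- abs(cos(pi * delta_all / nc)) <= dmin_cos
  delta_all <- delta_all[keep]
  rows <- list()
  for (a in 0:(nc - 1)) {
    del <- delta_all[delta_all %% 2L == a %% 2L]
    d0 <- del[del <= a]                      # branch 0: d1 + d2 = a
    d1v <- (a - d0) / 2
    b0 <- data.frame(a = rep(a, length(d0)), delta = d0,
                     br = rep(0L, length(d0)), d1 = d1v, d2 = d1v + d0)
    dB <- del[a + del <= nc - 2]             # branch 1: d1 + d2 = a + nc
    d1w <- (a - dB) / 2 + nc / 2
    b1 <- data.frame(a = rep(a, length(dB)), delta = dB,
                     br = rep(1L, length(dB)), d1 = d1w, d2 = d1w + dB)
    bb <- rbind(b0, b1)
    if (nrow(bb) == 0) next
    # signed radial coordinate: mirrored LORs (branch 1) sit on the other
    # side of the center within the same parallel family
    bb$s <- (g$ring_diameter / 2) * cos(pi * bb$delta / nc) *
      ifelse(bb$br == 0L, 1, -1)
    bb <- bb[order(bb$s), ]
    bb$r <- seq_len(nrow(bb)) - 1L
    rows[[a + 1L]] <- bb
  }
  lut <- do.call(rbind, rows)
  # mashed axial planes: representative z = mean z of rings in the group
  nm <- as.integer(ceiling(g$n_rings / axial_mash))
  zc <- (0:(g$n_rings - 1) + 0.5) * g$crystal_pitch_axial -
    crystal_axial_length(g) / 2
  grp <- (0:(g$n_rings - 1)) %/% axial_mash
  zm <- as.numeric(tapply(zc, grp, mean))
  rep_ring <- as.integer(tapply(0:(g$n_rings - 1), grp,
                                function(v) v[ceiling(length(v) / 2)]))
  span <- tan(max_acceptance_angle * pi / 180) * g$ring_diameter
  pp <- expand.grid(m1 = 0:(nm - 1), m2 = 0:(nm - 1))
  dz <- abs(zm[pp$m1 + 1] - zm[pp$m2 + 1])
  ok <- dz <= span + 1e-9
  if (is.finite(g$mud)) {
    u1 <- crystal_unit(g, rep_ring[pp$m1 + 1])
    u2 <- crystal_unit(g, rep_ring[pp$m2 + 1])
    ok <- ok & (abs(u1 - u2) <= g$mud)
  }
  pp <- pp[ok, ]
  spec <- list(
    axial_mash = as.integer(axial_mash),
    max_acceptance_angle = max_acceptance_angle,
    n_angles = nc,
    n_radial = max(table(lut$a)),
    n_mashed = nm,
    trans_lut = lut,
    plane_pairs = pp,
    mashed_z = zm,
    rep_ring = rep_ring,
    tof = tof
  )
  class(spec) <- "sinogram_spec"
  spec
}

#' Sinogram bin index for a crystal pair, and its inverse
#'
#' Maps an allowed LOR (two crystals) to its \code{(radial, angle, plane)}
#' sinogram bin. The axial plane is the ordered pair of mashed ring groups of
#' the two crystals, ordering fixed by the canonical transaxial representation
#' (smaller transaxial index first). \code{sinogram_crystals} returns the
#' representative crystals for a bin; the round trip bin -> crystals -> bin is
#' the identity.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param spec a \code{sinogram_spec}.
#' @param crystal_a,crystal_b lists with \code{trans}, \code{ring} (0-based).
#' @return data frame with columns \code{radial}, \code{angle}, \code{plane}.
#' @export
sinogram_index <- function(geometry, spec, crystal_a, crystal_b) {
  g <- geometry
  # the MUD policy is applied when coincidences are accepted (lor_allowed)
  # and when plane pairs are enumerated; binning itself only requires the
  # LOR to cross the FOV (mash groups may straddle unit boundaries, so a
  # bin's representative crystals need not satisfy the event-level policy)
  ta <- crystal_a$trans; ra <- crystal_a$ring
  tb <- crystal_b$trans; rb <- crystal_b$ring
  swap <- ta > tb
  d1 <- ifelse(swap, tb, ta); r1 <- ifelse(swap, rb, ra)
  d2 <- ifelse(swap, ta, tb); r2 <- ifelse(swap, ra, rb)
  if (any(c(ta, tb) < 0 | c(ta, tb) >= g$crystals_per_ring) ||
      any(c(ra, rb) < 0 | c(ra, rb) >= g$n_rings))
    stop("crystal index out of range")
  key <- paste(d1, d2)
  lut <- spec$trans_lut
  m <- match(key, paste(lut$d1, lut$d2))
  if (anyNA(m)) stop("disallowed LOR: does not cross the transaxial FOV")
  m1 <- r1 %/% spec$axial_mash
  m2 <- r2 %/% spec$axial_mash
  data.frame(radial = lut$r[m], angle = lut$a[m],
             plane = m1 + spec$n_mashed * m2)
}

#' @rdname sinogram_index
#' @param radial,angle,plane bin coordinates as returned by
#'   \code{sinogram_index}.
#' @export
sinogram_crystals <- function(geometry, spec, radial, angle, plane) {
  lut <- spec$trans_lut
  m <- match(paste(angle, radial), paste(lut$a, lut$r))
  if (anyNA(m)) stop("invalid transaxial bin")
  m1 <- plane %% spec$n_mashed
  m2 <- plane %/% spec$n_mashed
  list(a = list(trans = lut$d1[m], ring = spec$rep_ring[m1 + 1]),
       b = list(trans = lut$d2[m], ring = spec$rep_ring[m2 + 1]))
}

#' TOF acceptance threshold of a LOR
#'
#' Transmission coincidences originate in a crystal, so their time difference
#' is (up to timing resolution) the full LOR transit time; emission
#' contamination originates inside the body and has a smaller |TOF|. The
#' per-LOR threshold is the crystal center-to-center transit time minus
#' 500 ps; it may be negative for short LORs, in which case nothing is
#' rejected.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param lor_length_mm center-to-center LOR length(s) in mm.
#' @return threshold(s) in ps.
#' @export
tof_threshold <- function(geometry, lor_length_mm) {
  lor_length_mm / (SPEED_OF_LIGHT_MM_NS / 1000) - 500
}

#' Enumerate the LOR table of a sinogram
#'
#' Builds the flat table of sinogram bins with representative-crystal
#' endpoint coordinates (front-face centers). This is the container all
#' simulation and reconstruction routines operate on.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param spec a \code{sinogram_spec}.
#' @return a list of class \code{lor_table} with endpoint matrices \code{p1},
#'   \code{p2} (front-face centers, mm), LOR lengths, bin coordinates and the
#'   generating geometry/spec.
#' @export
lor_table <- function(geometry, spec) {
  g <- geometry
  lut <- spec$trans_lut
  pp <- spec$plane_pairs
  nt <- nrow(lut); np <- nrow(pp)
  it <- rep(seq_len(nt), times = np)
  ip <- rep(seq_len(np), each = nt)
  r <- g$ring_diameter / 2
  phi1 <- 2 * pi * (lut$d1[it] + 0.5) / g$crystals_per_ring
  phi2 <- 2 * pi * (lut$d2[it] + 0.5) / g$crystals_per_ring
  z1 <- spec$mashed_z[pp$m1[ip] + 1] + g$axial_offset
  z2 <- spec$mashed_z[pp$m2[ip] + 1] + g$axial_offset
  p1 <- cbind(r * cos(phi1), r * sin(phi1), z1)
  p2 <- cbind(r * cos(phi2), r * sin(phi2), z2)
  len <- sqrt(rowSums((p2 - p1)^2))
  structure(list(
    p1 = p1, p2 = p2, length = len,
    angle = lut$a[it], radial = lut$r[it],
    plane = pp$m1[ip] + spec$n_mashed * pp$m2[ip],
    n = nt * np, geometry = g, spec = spec
  ), class = "lor_table")
}

#' @export
print.lor_table <- function(x, ...) {
  cat(sprintf("lor_table: %d bins (%d angles x <=%d radial x %d planes)\n",
              x$n, x$spec$n_angles, x$spec$n_radial, nrow(x$spec$plane_pairs)))
  invisible(x)
}

#' Read / write scanner geometry configuration
#'
#' Human-readable YAML serialization of a scanner geometry (the preset files
#' shipped under \code{inst/extdata} use the same schema: one key per
#' geometry field, \code{mud: unrestricted} for no unit-difference policy).
#'
#' @param path YAML file path.
#' @param geometry a \code{scanner_geometry}.
#' @return \code{read_scanner_config}: a \code{scanner_geometry};
#'   \code{write_scanner_config}: the path, invisibly.
#' @export
read_scanner_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$mud, "unrestricted")) y$mud <- Inf
  g <- build_scanner(preset = NULL,
                     ring_diameter = y$ring_diameter,
                     n_axial_units = y$n_axial_units,
                     unit_length = y$unit_length,
                     mud = y$mud,
                     crystal_pitch_trans = y$crystal_pitch_trans,
                     crystal_pitch_axial = y$crystal_pitch_axial,
                     crystal_length = y$crystal_length,
                     coincidence_window_ns = y$coincidence_window_ns,
                     ctr_ps = y$ctr_ps,
                     energy_resolution_511 = y$energy_resolution_511,
                     tof_bin_width_ps = y$tof_bin_width_ps,
                     transaxial_fov = y$transaxial_fov)
  if (!is.null(y$name)) g$preset <- y$name
  g
}

#' @rdname read_scanner_config
#' @export
write_scanner_config <- function(geometry, path) {
  g <- geometry
  y <- list(name = g$preset, ring_diameter = g$ring_diameter,
            n_axial_units = g$n_axial_units, unit_length = g$unit_length,
            mud = if (is.finite(g$mud)) g$mud else "unrestricted",
            crystal_pitch_trans = g$crystal_pitch_trans,
            crystal_pitch_axial = g$crystal_pitch_axial,
            crystal_length = g$crystal_length,
            coincidence_window_ns = g$coincidence_window_ns,
            ctr_ps = g$ctr_ps,
            energy_resolution_511 = g$energy_resolution_511,
            tof_bin_width_ps = g$tof_bin_width_ps,
            transaxial_fov = g$transaxial_fov)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Construct a LOR table from explicit endpoints
#'
#' Convenience constructor for small hand-built LOR sets (closed-form checks,
#' single-LOR problems). Endpoints are used as given (no DOI adjustment).
#'
#' @param geometry a \code{scanner_geometry}.
#' @param p1,p2 endpoint matrices (n x 3, mm).
#' @param angle optional per-LOR angle indices (subset bookkeeping).
#' @return a \code{lor_table}.
#' @export
manual_lor_table <- function(geometry, p1, p2, angle = NULL) {
  p1 <- matrix(as.numeric(p1), ncol = 3)
  p2 <- matrix(as.numeric(p2), ncol = 3)
  n <- nrow(p1)
  if (is.null(angle)) angle <- rep(0L, n)
  lt <- structure(list(
    p1 = p1, p2 = p2, length = sqrt(rowSums((p2 - p1)^2)),
    angle = angle, radial = seq_len(n) - 1L, plane = rep(0L, n),
    n = n, geometry = geometry,
    spec = list(n_angles = 1L, n_radial = n, n_mashed = 1L)
  ), class = "lor_table")
  # identity endpoints for both energies: hand-built sets skip the DOI model
  lt$doi511 <- lt$doi307 <- list(p1 = p1, p2 = p2)
  lt
}

#' Restrict a LOR table to a support cylinder
#'
#' Keeps only the sinogram bins whose LOR segment intersects the cylinder
#' \code{x^2 + y^2 <= radius^2, zlim[1] <= z <= zlim[2]} (the computational
#' FOV around the object). Bins outside never see the object and carry no
#' attenuation information.
#'
#' @param lors a \code{lor_table}.
#' @param radius support cylinder radius, mm.
#' @param zlim support axial range, mm (length 2).
#' @return the filtered \code{lor_table} (with a \code{kept} index into the
#'   original table).
#' @export
filter_lors <- function(lors, radius, zlim) {
  p1 <- lors$p1; p2 <- lors$p2
  d <- p2 - p1
  # parameter interval where the segment is inside the transaxial circle
  a <- d[, 1]^2 + d[, 2]^2
  b <- 2 * (p1[, 1] * d[, 1] + p1[, 2] * d[, 2])
  cc <- p1[, 1]^2 + p1[, 2]^2 - radius^2
  disc <- b^2 - 4 * a * cc
  ok <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  t0 <- pmax((-b - sq) / (2 * a), 0)
  t1 <- pmin((-b + sq) / (2 * a), 1)
  ok <- ok & (t1 > t0)
  # z range covered while inside the circle must overlap zlim
  za <- p1[, 3] + t0 * d[, 3]
  zb <- p1[, 3] + t1 * d[, 3]
  zlo <- pmin(za, zb); zhi <- pmax(za, zb)
  keep <- which(ok & zhi >= zlim[1] & zlo <= zlim[2])
  out <- lors
  out$p1 <- lors$p1[keep, , drop = FALSE]
  out$p2 <- lors$p2[keep, , drop = FALSE]
  out$length <- lors$length[keep]
  out$angle <- lors$angle[keep]
  out$radial <- lors$radial[keep]
  out$plane <- lors$plane[keep]
  out$n <- length(keep)
  out$kept <- keep
  out
}

#' Number of TOF bins needed to cover a LOR set
#'
#' Odd bin count covering the largest possible |TOF| plus the 3-sigma kernel
#' tail, so that TOF marginalization loses no counts.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param lors a \code{lor_table}.
#' @return odd integer bin count.
#' @export
n_tof_bins <- function(geometry, lors) {
  tmax <- max(lors$length) / (SPEED_OF_LIGHT_MM_NS / 1000)
  sigma <- geometry$ctr_ps / (2 * sqrt(2 * log(2)))
  2L * as.integer(ceiling((tmax + 3 * sigma) / geometry$tof_bin_width_ps)) + 1L
}
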