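F18_HALF_LIFE_MIN <- 109.77
ELECTRON_REST_KEV <- 510.999

#' Lutetium-176 background source model
#'
#' Intrinsic background of LYSO crystals: each decay deposits a beta in the
#' host crystal and emits prompt gammas, of which only the 307 keV line can
#' produce transmission coincidences in the windows used here (202 and 88 keV
#' fall below every window; their probabilities are kept for rate accounting).
#' The blank-scan coincidence rate is calibrated against the measured
#' 92.2 cps per cc of LYSO in the 430-645 keV window, with the beta detection
#' probability folded into a single calibration constant.
#'
#' @param rate_per_cc singles rate per cc of LYSO (cps) in the reference
#'   window.
#' @param gamma_lines emission probabilities of the prompt gamma lines.
#' @param beta_detection_prob probability that the beta deposit falls in the
#'   chosen beta window (calibration constant).
#' @return object of class \code{lu_source_model}.
#' @export
lu_source_model <- function(rate_per_cc = 92.2,
                            gamma_lines = c("307" = 1.00, "202" = 0.833,
                                            "88" = 0.155),
                            beta_detection_prob = 1.0) {
  stopifnot(rate_per_cc >= 0, all(gamma_lines >= 0 & gamma_lines <= 1),
            beta_detection_prob >= 0, beta_detection_prob <= 1)
  structure(list(rate_per_cc = rate_per_cc, gamma_lines = gamma_lines,
                 beta_detection_prob = beta_detection_prob),
            class = "lu_source_model")
}

#' Gaussian energy resolution (FWHM) at an energy
#'
#' Fractional resolution scales as 1/sqrt(E) from the 511 keV reference.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param energy_kev photon energy in keV.
#' @return FWHM in keV.
#' @export
energy_fwhm <- function(geometry, energy_kev) {
  geometry$energy_resolution_511 * sqrt(511 / energy_kev) * energy_kev
}

#' Energy-window survival fraction (closed form)
#'
#' Probability that a line at \code{energy_kev}, blurred by the Gaussian
#' resolution model, is measured inside the window.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param energy_kev line energy in keV.
#' @param window numeric length-2, keV.
#' @return fraction in [0, 1].
#' @export
energy_window_survival <- function(geometry, energy_kev, window) {
  if (window[1] >= window[2]) stop("window low edge must be below high edge")
  s <- energy_fwhm(geometry, energy_kev) / (2 * sqrt(2 * log(2)))
  stats::pnorm((window[2] - energy_kev) / s) -
    stats::pnorm((window[1] - energy_kev) / s)
}

#' Apply an energy window to sampled event energies
#'
#' Adds Gaussian measurement noise to each true deposit energy and tests the
#' measured value against the window.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param energies_kev true deposit energies.
#' @param window numeric length-2, keV.
#' @return logical pass mask.
#' @export
apply_energy_window <- function(geometry, energies_kev, window) {
  if (window[1] >= window[2]) stop("window low edge must be below high edge")
  s <- energy_fwhm(geometry, energies_kev) / (2 * sqrt(2 * log(2)))
  meas <- energies_kev + rnorm(length(energies_kev), 0, s)
  meas >= window[1] & meas <= window[2]
}

#' Time-integrated F-18 decay factor
#'
#' Mean of the decay exponential over a scan of the given duration (activity
#' referenced to scan start).
#'
#' @param duration_min scan duration in minutes.
#' @param half_life_min isotope half life (F-18 by default).
#' @return factor in (0, 1].
#' @export
decay_factor <- function(duration_min, half_life_min = F18_HALF_LIFE_MIN) {
  if (duration_min <= 0) stop("duration must be positive")
  (1 - 2^(-duration_min / half_life_min)) * half_life_min /
    (duration_min * log(2))
}

# Per-LOR blank coincidence rate (cps): beta trigger in one crystal, its
# 307 keV gamma detected in the opposing crystal (both orderings). The
# geometric factor is the receiving crystal's front-face solid angle with
# obliquity; intrinsic gamma efficiency is the photoelectric-free absorption
# 1 - exp(-eta mu_LYSO D) and the energy-window survival of the 307 line.
blank_rate <- function(geometry, lors, lu_model, gamma_window = c(250, 350)) {
  g <- geometry
  vol_cc <- g$crystal_pitch_trans * g$crystal_pitch_axial * g$crystal_length /
    1000
  beta_rate <- lu_model$rate_per_cc * vol_cc * lu_model$beta_detection_prob
  area <- g$crystal_pitch_trans * g$crystal_pitch_axial
  dvec <- lors$p2 - lors$p1
  len <- lors$length
  # obliquity: angle between the LOR and the radial crystal normal
  rad1 <- lors$p1[, 1:2, drop = FALSE] /
    sqrt(rowSums(lors$p1[, 1:2, drop = FALSE]^2))
  rad2 <- lors$p2[, 1:2, drop = FALSE] /
    sqrt(rowSums(lors$p2[, 1:2, drop = FALSE]^2))
  cos1 <- abs((dvec[, 1] * rad1[, 1] + dvec[, 2] * rad1[, 2]) / len)
  cos2 <- abs((dvec[, 1] * rad2[, 1] + dvec[, 2] * rad2[, 2]) / len)
  eps <- (1 - exp(-ETA_DEFAULT * MU_LYSO_511 * g$crystal_length)) *
    energy_window_survival(g, 307, gamma_window) *
    lu_model$gamma_lines[["307"]]
  beta_rate * eps * area * (cos1 + cos2) / (4 * pi * len^2)
}

#' Exposure scale reaching a target blank count total
#'
#' The desk-scale simulator keeps the physical rate model but applies one
#' global exposure factor so that a scan completes with a practical number of
#' counts; the factor is recorded in every simulated data set.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param lors a \code{lor_table}.
#' @param lu_model a \code{lu_source_model}.
#' @param duration_min scan duration.
#' @param target_counts desired total expected blank counts.
#' @param gamma_window 307 keV window, keV.
#' @return scalar exposure factor.
#' @export
exposure_for_counts <- function(geometry, lors, lu_model, duration_min,
                                target_counts, gamma_window = c(250, 350)) {
  raw <- sum(blank_rate(geometry, lors, lu_model, gamma_window)) *
    duration_min * 60
  target_counts / raw
}

#' Simulate a blank lutetium transmission scan
#'
#' Poisson counts per LOR with no object in the FOV.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param lors a \code{lor_table}.
#' @param lu_model a \code{lu_source_model}.
#' @param duration_min scan duration in minutes.
#' @param exposure_scale global exposure factor
#'   (\code{\link{exposure_for_counts}}).
#' @param gamma_window 307 keV energy window, keV.
#' @param seed integer seed.
#' @return list with \code{counts}, \code{expectation}, and the scan
#'   parameters.
#' @export
simulate_blank <- function(geometry, lors, lu_model = lu_source_model(),
                           duration_min = 200, exposure_scale = 1,
                           gamma_window = c(250, 350), seed = 1L) {
  stopifnot(duration_min > 0)
  expec <- blank_rate(geometry, lors, lu_model, gamma_window) *
    duration_min * 60 * exposure_scale
  set.seed(seed)
  list(counts = rpois(length(expec), expec), expectation = expec,
       duration_min = duration_min, exposure_scale = exposure_scale,
       gamma_window = gamma_window, seed = seed)
}

# Klein-Nishina differential cross-section (unnormalized) over scattering
# angle theta for an incident photon of energy E (keV); includes sin(theta)
# from the solid-angle element.
klein_nishina_pdf <- function(theta, energy_kev) {
  k <- energy_kev / ELECTRON_REST_KEV
  r <- 1 / (1 + k * (1 - cos(theta)))   # E'/E
  r^2 * (r + 1 / r - sin(theta)^2) * sin(theta)
}

sample_klein_nishina <- function(n, energy_kev, n_grid = 720) {
  th <- seq(0, pi, length.out = n_grid + 1)[-1]
  p <- klein_nishina_pdf(th, energy_kev)
  th[sample.int(n_grid, n, replace = TRUE, prob = p)] +
    runif(n, -pi / n_grid / 2, pi / n_grid / 2)
}

#' Simulate an object lutetium transmission scan
#'
#' Expected unscattered ("true") counts are the blank expectation attenuated
#' by the 307 keV factors of the phantom. With
#' \code{scatter_mode = "single_scatter"} the photons removed from the primary
#' beam are given one Klein-Nishina scatter vertex: a scattering angle is
#' sampled, the scattered energy computed, passed through the energy
#' resolution model and the gamma window, and surviving events are recorded in
#' the same LOR as a separate \code{scattered_307} category. Emission
#' contamination (511 keV pairs down-scattered into the transmission window)
#' is generated from the emission forward model, assigned a body-origin TOF
#' and filtered by the per-LOR TOF threshold. Categories are stored
#' separately: the "no scatter" data set is the \code{true_307} category.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param phantom a \code{phantom}.
#' @param lors a \code{lor_table}.
#' @param lu_model a \code{lu_source_model}.
#' @param duration_min scan duration in minutes.
#' @param exposure_scale global exposure factor for the transmission chain.
#' @param gamma_window 307 keV window (250-350 default, or 290-350).
#' @param scatter_mode \code{"none"} or \code{"single_scatter"}.
#' @param emission_exposure exposure factor of the emission chain (for the
#'   contamination channel); 0 disables contamination.
#' @param contamination_fraction fraction of emission coincidences whose
#'   second photon down-scatters into the gamma window (candidate rate).
#' @param tof_reject apply the per-LOR TOF threshold to contamination events.
#' @param seed integer seed.
#' @return list with \code{counts} (total), \code{categories} (true_307,
#'   scattered_307, contamination_511), \code{blank_expectation}, \code{r}
#'   (additive expectation, 0 here) and scan parameters.
#' @export
simulate_transmission <- function(geometry, phantom, lors,
                                  lu_model = lu_source_model(),
                                  duration_min = 20, exposure_scale = 1,
                                  gamma_window = c(250, 350),
                                  scatter_mode = c("none", "single_scatter"),
                                  emission_exposure = 0,
                                  contamination_fraction = 0.05,
                                  tof_reject = TRUE,
                                  seed = 1L) {
  scatter_mode <- match.arg(scatter_mode)
  grid <- phantom_grid(phantom)
  bexp <- blank_rate(geometry, lors, lu_model, gamma_window) *
    duration_min * 60 * exposure_scale
  a307 <- attenuation_factors(phantom$mu, lors, grid, energy_mode = 307)
  set.seed(seed)
  n <- lors$n
  true_307 <- rpois(n, bexp * a307)
  scattered_307 <- integer(n)
  contamination_511 <- integer(n)
  contamination_rejected <- 0L

  if (scatter_mode == "single_scatter") {
    # photons removed from the primary beam, one scatter vertex each
    cand <- rpois(n, bexp * (1 - a307))
    idx <- rep.int(seq_len(n), cand)
    if (length(idx)) {
      th <- sample_klein_nishina(length(idx), 307)
      e_sc <- 307 / (1 + (307 / ELECTRON_REST_KEV) * (1 - cos(th)))
      keep <- apply_energy_window(geometry, e_sc, gamma_window)
      scattered_307 <- tabulate(idx[keep], nbins = n)
    }
    if (emission_exposure > 0) {
      # body-origin candidates from the emission forward model
      a511 <- attenuation_factors(phantom$mu, lors, grid, energy_mode = 511)
      eexp <- forward_project(phantom$activity, lors, grid, energy = 511) *
        a511 * duration_min * 60 * decay_factor(duration_min) *
        emission_exposure * contamination_fraction
      ccand <- rpois(n, eexp)
      cidx <- rep.int(seq_len(n), ccand)
      if (length(cidx)) {
        # emission position along the LOR: uniform over the chord through
        # the body support (adequate for a rejection-rate model)
        u <- runif(length(cidx), -0.25, 0.25) * lors$length[cidx]
        acc <- reject_by_tof(geometry, u, lors$length[cidx],
                             apply = tof_reject)
        contamination_511 <- tabulate(cidx[acc], nbins = n)
        contamination_rejected <- sum(!acc)
      }
    }
  }
  counts <- true_307 + scattered_307 + contamination_511
  list(counts = counts,
       categories = list(true_307 = true_307, scattered_307 = scattered_307,
                         contamination_511 = contamination_511),
       contamination_rejected = contamination_rejected,
       blank_expectation = bexp, r = numeric(n),
       duration_min = duration_min, exposure_scale = exposure_scale,
       gamma_window = gamma_window, scatter_mode = scatter_mode, seed = seed)
}

#' TOF acceptance of transmission-window events
#'
#' A coincidence is accepted as a transmission event when its measured |TOF|
#' exceeds the per-LOR threshold (crystal-to-crystal transit time minus
#' 500 ps). Crystal-origin events sit 500 ps above the threshold by
#' construction; body-origin (emission) events have smaller |TOF| and are
#' mostly rejected. The measured TOF is 2u/c plus Gaussian timing noise.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param u_mm signed emission position along the LOR, from the midpoint (mm).
#' @param lor_length_mm LOR length(s), mm.
#' @param apply if FALSE, accept everything (bookkeeping convenience).
#' @return logical acceptance mask.
#' @export
reject_by_tof <- function(geometry, u_mm, lor_length_mm, apply = TRUE) {
  if (!apply) return(rep(TRUE, length(u_mm)))
  sigma <- geometry$ctr_ps / (2 * sqrt(2 * log(2)))
  tof <- 2 * u_mm / (SPEED_OF_LIGHT_MM_NS / 1000) +
    rnorm(length(u_mm), 0, sigma)
  abs(tof) > tof_threshold(geometry, lor_length_mm)
}

#' Exposure scale reaching a target emission count total
#'
#' @param geometry a \code{scanner_geometry}.
#' @param phantom a \code{phantom}.
#' @param lors a \code{lor_table}.
#' @param duration_min scan duration.
#' @param target_counts desired total expected emission counts.
#' @return scalar exposure factor.
#' @export
emission_exposure_for_counts <- function(geometry, phantom, lors,
                                         duration_min, target_counts) {
  grid <- phantom_grid(phantom)
  a511 <- attenuation_factors(phantom$mu, lors, grid, energy_mode = 511)
  raw <- sum(forward_project(phantom$activity, lors, grid, energy = 511) *
               a511) * duration_min * 60 * decay_factor(duration_min)
  target_counts / raw
}

#' Simulate a TOF emission scan
#'
#' Per-LOR, per-TOF-bin expected counts are the TOF-resolved forward
#' projection of the activity map, attenuated at 511 keV, scaled by duration,
#' the time-integrated F-18 decay factor and the exposure factor; counts are
#' Poisson. Randoms are not generated, and the scattered category is empty
#' (scatter-corrected data are emulated by construction).
#'
#' @param geometry a \code{scanner_geometry}.
#' @param phantom a \code{phantom}.
#' @param lors a \code{lor_table}.
#' @param duration_min scan duration in minutes.
#' @param exposure_scale global exposure factor
#'   (\code{\link{emission_exposure_for_counts}}).
#' @param n_tof number of TOF bins; default from \code{\link{n_tof_bins}}.
#' @param seed integer seed.
#' @param keep_expectation retain the expectation matrix (memory).
#' @return list with \code{counts} (matrix LOR x TOF bin), \code{s} (additive
#'   expectation, 0), \code{n_tof} and scan parameters.
#' @export
simulate_emission <- function(geometry, phantom, lors, duration_min = 20,
                              exposure_scale = 1, n_tof = NULL, seed = 1L,
                              keep_expectation = FALSE) {
  grid <- phantom_grid(phantom)
  if (is.null(n_tof)) n_tof <- n_tof_bins(geometry, lors)
  a511 <- attenuation_factors(phantom$mu, lors, grid, energy_mode = 511)
  fp <- tof_forward_project(phantom$activity, lors, grid, n_tof)
  expec <- fp * (a511 * duration_min * 60 * decay_factor(duration_min) *
                   exposure_scale)
  set.seed(seed)
  counts <- matrix(rpois(length(expec), expec), nrow = nrow(expec))
  out <- list(counts = counts, s = 0, n_tof = n_tof,
              duration_min = duration_min, exposure_scale = exposure_scale,
              seed = seed)
  if (keep_expectation) out$expectation <- expec
  out
}

#' Normalization factors
#'
#' Per-LOR normalization, mean 1. \code{"ideal"} returns unit factors (the
#' simulator has uniform detector efficiency). \code{"annulus"} emulates the
#' component-based iterative estimation from a scan of a thin annulus shell
#' source: counts are generated from the analytic chord length of each LOR
#' through the shell times the (possibly perturbed) crystal efficiencies, and
#' transaxial crystal efficiencies and radial geometric factors are estimated
#' by alternating fan-sum updates.
#'
#' @param geometry a \code{scanner_geometry}.
#' @param lors a \code{lor_table}.
#' @param mode \code{"ideal"} or \code{"annulus"}.
#' @param efficiency optional per-transaxial-crystal efficiency vector used to
#'   generate the annulus data (parameter-recovery studies).
#' @param duration_min,rate_scale annulus scan exposure controls.
#' @param n_iter alternating update iterations.
#' @param annulus_diameter inner/outer shell diameters, mm.
#' @param seed integer seed.
#' @return list with \code{n} (per-LOR factors, mean 1) and, for annulus mode,
#'   the estimated crystal efficiencies.
#' @export
normalization_factors <- function(geometry, lors,
                                  mode = c("ideal", "annulus"),
                                  efficiency = NULL, duration_min = 30,
                                  rate_scale = 2, n_iter = 10,
                                  annulus_diameter = c(772, 778),
                                  seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "ideal")
    return(list(n = rep(1, lors$n), efficiency = NULL))
  g <- geometry
  nc <- g$crystals_per_ring
  if (is.null(efficiency)) efficiency <- rep(1, nc)
  stopifnot(length(efficiency) == nc)
  # analytic chord of each LOR through the annulus shell cylinder
  chord_cyl <- function(R) {
    d <- lors$p2 - lors$p1
    a <- d[, 1]^2 + d[, 2]^2
    b <- 2 * (lors$p1[, 1] * d[, 1] + lors$p1[, 2] * d[, 2])
    cc <- lors$p1[, 1]^2 + lors$p1[, 2]^2 - R^2
    disc <- b^2 - 4 * a * cc
    t2d <- ifelse(disc > 0, sqrt(pmax(disc, 0)) / a, 0)
    t2d * lors$length  # parametric width times 3D length
  }
  gfac <- pmax(chord_cyl(annulus_diameter[2] / 2) -
                 chord_cyl(annulus_diameter[1] / 2), 0)
  # transaxial crystal ids of the representative crystals
  lut <- lors$spec$trans_lut
  key <- paste(lors$angle, lors$radial)
  m <- match(key, paste(lut$a, lut$r))
  c1 <- lut$d1[m] + 1L
  c2 <- lut$d2[m] + 1L
  expec <- gfac * efficiency[c1] * efficiency[c2] * duration_min * 60 *
    rate_scale / mean(lors$length)
  set.seed(seed)
  y <- rpois(lors$n, expec)
  if (all(y[gfac > 0] == 0)) stop("annulus scan produced no counts")
  # alternating component estimation: crystal efficiencies vs geometric term
  e_hat <- rep(1, nc)
  g_hat <- gfac
  for (it in seq_len(n_iter)) {
    pred_wo <- g_hat
    # fan-sum update of the crystal efficiencies
    num <- as.numeric(tapply(y, c1, sum)[as.character(1:nc)])
    den <- as.numeric(tapply(pred_wo * e_hat[c2], c1,
                             sum)[as.character(1:nc)])
    num2 <- as.numeric(tapply(y, c2, sum)[as.character(1:nc)])
    den2 <- as.numeric(tapply(pred_wo * e_hat[c1], c2,
                              sum)[as.character(1:nc)])
    num[is.na(num)] <- 0; den[is.na(den)] <- 0
    num2[is.na(num2)] <- 0; den2[is.na(den2)] <- 0
    tot_num <- num + num2
    tot_den <- den + den2
    upd <- ifelse(tot_den > 0, tot_num / tot_den, 1)
    e_hat <- e_hat * upd
    e_hat <- e_hat / mean(e_hat)
    # geometric component per radial bin
    rad_id <- lors$radial + 1L
    pr <- e_hat[c1] * e_hat[c2]
    gnum <- as.numeric(tapply(y, rad_id, sum))
    gden <- as.numeric(tapply(pr * (gfac > 0), rad_id, sum))
    scale_r <- ifelse(gden > 0, gnum / gden, 0)
    g_hat <- ifelse(gfac > 0, scale_r[rad_id], 0)
  }
  nfac <- e_hat[c1] * e_hat[c2]
  nfac <- nfac / mean(nfac)
  if (any(!is.finite(nfac)) || any(nfac <= 0))
    stop("non-positive normalization factors")
  list(n = nfac, efficiency = e_hat)
}

#' Write / read a simulated sinogram set
#'
#' Chunked binary container: one little-endian double array per component
#' plus a JSON header describing geometry, spec, durations, windows and
#' seeds.
#'
#' @param set named list of numeric arrays (e.g. blank counts, transmission
#'   categories, emission matrix).
#' @param header list of scan metadata stored alongside.
#' @param dir output directory.
#' @return \code{write_sinograms}: the directory, invisibly;
#'   \code{read_sinograms}: list with \code{arrays} and \code{header}.
#' @export
write_sinograms <- function(set, header, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shapes <- list()
  for (nm in names(set)) {
    x <- set[[nm]]
    shapes[[nm]] <- if (is.matrix(x)) dim(x) else length(x)
    con <- file(file.path(dir, paste0(nm, ".f64")), "wb")
    writeBin(as.numeric(x), con, size = 8, endian = "little")
    close(con)
  }
  header$arrays <- shapes
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sinograms
#' @export
read_sinograms <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  arrays <- list()
  for (nm in names(header$arrays)) {
    shp <- as.integer(unlist(header$arrays[[nm]]))
    con <- file(file.path(dir, paste0(nm, ".f64")), "rb")
    x <- readBin(con, "numeric", n = prod(shp), size = 8, endian = "little")
    close(con)
    arrays[[nm]] <- if (length(shp) > 1) array(x, shp) else x
  }
  list(arrays = arrays, header = header)
}
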