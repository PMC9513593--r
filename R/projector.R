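MU_LYSO_511 <- 0.0815 # mm^-1, LYSO linear attenuation at 511 keV

#' Depth of interaction inside a crystal
#'
#' Mean interaction distance from the crystal front face for a photon entering
#' along the crystal axis, modeled as the inverse-CDF of an exponential
#' attenuation profile truncated at the crystal length:
#' \code{-log(1 - Y (1 - exp(-eta mu D))) / (eta mu)}. With uniform random
#' \code{Y} this samples the truncated exponential; the fixed quantile
#' \code{Y = 0.6} gives the deterministic ~7 mm endpoint used by default.
#'
#' @param Y depth quantile(s) in [0, 1].
#' @param eta energy scale of the attenuation coefficient (1 at 511 keV,
#'   1.2276 at 307 keV).
#' @param mu_lyso crystal attenuation coefficient at 511 keV (mm^-1).
#' @param D crystal length in mm.
#' @return depth(s) in mm, in [0, D].
#' @export
doi_depth <- function(Y, eta = 1, mu_lyso = MU_LYSO_511, D = 18.1) {
  if (any(Y < 0 | Y > 1)) stop("Y must be in [0, 1]")
  d <- -log(1 - Y * (1 - exp(-eta * mu_lyso * D))) / (eta * mu_lyso)
  pmin(pmax(d, 0), D)
}

#' LOR endpoints with the depth-of-interaction model
#'
#' Pushes each crystal front-face endpoint radially outward (into the crystal)
#' by the energy-dependent interaction depth. With \code{random = FALSE} the
#' fixed quantile \code{Y = 0.6} is used for every endpoint; otherwise each
#' endpoint samples its own uniform \code{Y}.
#'
#' @param lors a \code{lor_table}.
#' @param energy 511 or 307 (keV); selects the eta scale of the crystal
#'   attenuation.
#' @param Y fixed depth quantile.
#' @param random sample \code{Y} per endpoint.
#' @return list with matrices \code{p1}, \code{p2} (mm).
#' @export
doi_endpoints <- function(lors, energy = 511, Y = 0.6, random = FALSE) {
  g <- lors$geometry
  eta <- if (energy == 307) ETA_DEFAULT else 1
  n <- lors$n
  y1 <- if (random) runif(n) else rep(Y, n)
  y2 <- if (random) runif(n) else rep(Y, n)
  d1 <- doi_depth(y1, eta, D = g$crystal_length)
  d2 <- doi_depth(y2, eta, D = g$crystal_length)
  push <- function(p, d) {
    rr <- sqrt(p[, 1]^2 + p[, 2]^2)
    cbind(p[, 1] * (1 + d / rr), p[, 2] * (1 + d / rr), p[, 3])
  }
  list(p1 = push(lors$p1, d1), p2 = push(lors$p2, d2))
}

#' Voxel grid of a phantom
#' @param phantom a \code{phantom}.
#' @return list with \code{origin} (lower corner, mm), \code{voxel_size},
#'   \code{dim}.
#' @export
phantom_grid <- function(phantom) {
  list(origin = phantom$origin, voxel_size = phantom$voxel_size,
       dim = as.integer(phantom$dim))
}

#' Siddon ray trace through a voxel grid
#'
#' Exact voxel intersection lengths of the segment p1 -> p2 clipped to the
#' grid, in traversal order. The lengths sum to the clipped chord length.
#'
#' @param p1,p2 numeric length-3 endpoints in mm.
#' @param grid a grid description, see \code{\link{phantom_grid}}.
#' @return data frame with \code{index} (linear 1-based voxel index),
#'   \code{length} (mm) and \code{u} (signed arc length of the segment
#'   midpoint of each intersection, measured from the LOR midpoint).
#' @export
siddon_path <- function(p1, p2, grid) {
  if (sqrt(sum((p2 - p1)^2)) <= 0) stop("degenerate zero-length ray")
  r <- cpp_siddon(as.numeric(p1), as.numeric(p2), as.numeric(grid$origin),
                  grid$voxel_size, as.integer(grid$dim))
  data.frame(index = r$index, length = r$length, u = r$u)
}

#' Forward and back projection over a LOR set
#'
#' Line integrals of a volume along every LOR (\code{forward_project}) and the
#' exact adjoint accumulation (\code{back_project}). Endpoints are the
#' DOI-adjusted crystal positions for the requested energy, or raw front-face
#' centers with \code{energy = NA}.
#'
#' @param img 3D volume (or vector of grid length).
#' @param lors a \code{lor_table}.
#' @param grid a grid description.
#' @param energy 511, 307 or NA (front faces).
#' @param values per-LOR values to smear back (for \code{back_project}).
#' @return \code{forward_project}: numeric vector of line integrals (mm x
#'   image units); \code{back_project}: a 3D array on the grid.
#' @export
forward_project <- function(img, lors, grid, energy = 511) {
  ep <- project_endpoints(lors, energy)
  cpp_forward(ep$p1, ep$p2, as.numeric(img), as.numeric(grid$origin),
              grid$voxel_size, as.integer(grid$dim))
}

#' @rdname forward_project
#' @export
back_project <- function(values, lors, grid, energy = 511) {
  ep <- project_endpoints(lors, energy)
  array(cpp_back(ep$p1, ep$p2, as.numeric(values), as.numeric(grid$origin),
                 grid$voxel_size, as.integer(grid$dim)), grid$dim)
}

project_endpoints <- function(lors, energy) {
  if (is.na(energy)) return(list(p1 = lors$p1, p2 = lors$p2))
  key <- paste0("doi", energy)
  if (!is.null(lors[[key]])) return(lors[[key]])
  doi_endpoints(lors, energy)
}

#' Cache DOI endpoints on a LOR table
#'
#' Precomputes and stores the 511 and 307 keV DOI-adjusted endpoints so
#' repeated projections do not recompute them.
#'
#' @param lors a \code{lor_table}.
#' @return the \code{lor_table} with cached endpoints.
#' @export
cache_doi <- function(lors) {
  lors$doi511 <- doi_endpoints(lors, 511)
  lors$doi307 <- doi_endpoints(lors, 307)
  lors
}

#' Attenuation factors along a LOR set
#'
#' \code{a_i = exp(-eta sum_j l_ij mu_j)} for every LOR, with the mu map
#' stored at 511 keV and 307 keV physics expressed through the single energy
#' scale factor eta.
#'
#' @param mu_map 3D attenuation volume at 511 keV (mm^-1).
#' @param lors a \code{lor_table}.
#' @param grid a grid description.
#' @param energy_mode 511 (eta = 1) or 307 (eta = 1.2276).
#' @param eta override for the energy scale factor.
#' @return numeric vector of factors in (0, 1].
#' @export
attenuation_factors <- function(mu_map, lors, grid, energy_mode = 511,
                                eta = NULL) {
  if (any(mu_map < 0)) stop("negative attenuation coefficients")
  if (is.null(eta)) eta <- if (energy_mode == 307) ETA_DEFAULT else 1
  z <- forward_project(mu_map, lors, grid, energy = energy_mode)
  exp(-eta * z)
}

#' TOF-resolved forward and back projection
#'
#' Distributes each voxel's contribution over TOF bins with a Gaussian kernel
#' of FWHM equal to the coincidence timing resolution, truncated at +/- 3
#' sigma and renormalized so that summing over TOF bins reproduces the
#' non-TOF projection. The kernel center for a voxel at arc length u from the
#' LOR midpoint is at t = 2u/c.
#'
#' @param img activity volume.
#' @param lors a \code{lor_table}.
#' @param grid a grid description.
#' @param n_tof number of TOF bins (odd); see \code{\link{n_tof_bins}}.
#' @param sino matrix of per-LOR, per-TOF-bin values to smear back.
#' @return \code{tof_forward_project}: matrix [n LOR x n_tof];
#'   \code{tof_back_project}: a 3D array.
#' @export
tof_forward_project <- function(img, lors, grid, n_tof) {
  g <- lors$geometry
  ep <- project_endpoints(lors, 511)
  sigma <- g$ctr_ps / (2 * sqrt(2 * log(2)))
  cpp_tof_forward(ep$p1, ep$p2, as.numeric(img), as.numeric(grid$origin),
                  grid$voxel_size, as.integer(grid$dim),
                  g$tof_bin_width_ps, as.integer(n_tof), sigma)
}

#' @rdname tof_forward_project
#' @export
tof_back_project <- function(sino, lors, grid) {
  g <- lors$geometry
  ep <- project_endpoints(lors, 511)
  sigma <- g$ctr_ps / (2 * sqrt(2 * log(2)))
  array(cpp_tof_back(ep$p1, ep$p2, sino, as.numeric(grid$origin),
                     grid$voxel_size, as.integer(grid$dim),
                     g$tof_bin_width_ps, ncol(sino), sigma), grid$dim)
}

#' Energy-scale transform of an attenuation map
#'
#' Voxelwise multiplication by the 307/511 keV scale factor eta.
#'
#' @param mu511_map attenuation volume at 511 keV.
#' @param eta scale factor.
#' @return attenuation volume at 307 keV.
#' @export
eta_transform <- function(mu511_map, eta = ETA_DEFAULT) {
  if (any(mu511_map < 0)) stop("negative attenuation coefficients")
  mu511_map * eta
}
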