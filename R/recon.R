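#' Reconstruction configuration
#'
#' Iteration schedule, subset count, penalty and transmission weights for the
#' three algorithms. Geometry defaults follow the study settings: 10 subsets
#' for the long geometries and 4 for the 24-cm scanner; penalty weight beta
#' 10000 / 20000 / 80000 for the uEXPLORER, one-meter and 24-cm geometries;
#' MLTR runs 50 iterations; OSEM and MLAA-TX use iteration 3 (uEXPLORER) or
#' 2 (shorter scanners); MLAA-TX interleaves one activity update with five
#' attenuation updates per outer iteration.
#'
#' @param algorithm \code{"osem"}, \code{"mltr"} or \code{"mlaa_tx"}.
#' @param preset geometry preset name used for defaults.
#' @param n_iterations iteration count (outer iterations for mlaa_tx).
#' @param n_subsets ordered subsets; must divide the number of sinogram
#'   angles.
#' @param beta quadratic penalty weight.
#' @param alpha transmission-data weight in MLAA-TX.
#' @param mu_updates_per_iteration attenuation updates per outer MLAA-TX
#'   iteration.
#' @param seed seed fixing the subset processing order.
#' @param epsilon curvature floor.
#' @return object of class \code{recon_config}.
#' @export
recon_config <- function(algorithm = c("osem", "mltr", "mlaa_tx"),
                         preset = "uexplorer",
                         n_iterations = NULL, n_subsets = NULL, beta = NULL,
                         alpha = 1, mu_updates_per_iteration = 5L,
                         seed = 1L, epsilon = 1e-8) {
  algorithm <- match.arg(algorithm)
  short <- identical(preset, "conventional_24cm")
  if (is.null(n_subsets)) n_subsets <- if (short) 4L else 10L
  if (is.null(beta)) {
    beta <- switch(preset, uexplorer = 10000, one_meter = 20000,
                   conventional_24cm = 80000, 10000)
  }
  if (is.null(n_iterations)) {
    n_iterations <- if (algorithm == "mltr") 50L else if (short) 2L else 3L
  }
  stopifnot(beta >= 0, alpha >= 0, n_iterations >= 1, n_subsets >= 1)
  structure(list(algorithm = algorithm, preset = preset,
                 n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets), beta = beta,
                 alpha = alpha,
                 mu_updates_per_iteration = as.integer(mu_updates_per_iteration),
                 seed = as.integer(seed), epsilon = epsilon),
            class = "recon_config")
}

# Subset index lists: projections equidistant in angle; the processing order
# of the subsets is a fixed permutation drawn from the config seed.
make_subsets <- function(lors, config) {
  ns <- config$n_subsets
  nang <- lors$spec$n_angles
  if (nang %% ns != 0) stop("n_subsets must divide the angular dimension")
  sub <- lapply(0:(ns - 1), function(k) which(lors$angle %% ns == k))
  set.seed(config$seed)
  sub[sample.int(ns)]
}

#' Optimal separable-surrogate curvature for a Poisson bin
#'
#' Curvature bound of \code{h(Z) = (B exp(-Z) + r) - y log(B exp(-Z) + r)}
#' guaranteeing monotone surrogate descent: the precomputed optimal curvature
#' \code{2 (h(0) - h(Z) + Z h'(Z)) / Z^2} for \code{Z > 0} and the Newton
#' curvature at \code{Z = 0}, floored at a small positive epsilon. The same
#' form serves the transmission term (B = blank) and the emission term of the
#' joint update (B = activity forward projection, r = scatter expectation).
#'
#' @param B per-LOR reference expectation (blank counts or forward-projected
#'   activity).
#' @param y measured counts.
#' @param r additive expectation.
#' @param Z current line integral (eta-scaled for transmission).
#' @param epsilon curvature floor.
#' @return per-LOR curvature vector (> 0).
#' @export
sqs_curvature <- function(B, y, r = 0, Z, epsilon = 1e-8) {
  h <- function(zz) {
    yb <- B * exp(-zz) + r
    yb - ifelse(y > 0, y * log(pmax(yb, 1e-300)), 0)
  }
  be <- B * exp(-Z)
  hp <- y * ifelse(be + r > 0, be / (be + r), 1) - be
  c0 <- ifelse(B + r > 0, B * (1 - y * r / (B + r)^2), 0) # h''(0)
  copt <- ifelse(Z > 1e-12, 2 * (h(0) - h(Z) + Z * hp) / Z^2, c0)
  pmax(copt, epsilon)
}

quad_penalty <- function(img, dim) cpp_quad_penalty(as.numeric(img),
                                                    as.integer(dim))

penalty_value <- function(img, dim) {
  # U = sum_j sum_k w_jk (mu_k - mu_j)^2 / 4; grad = sum_k w_jk (mu_j - mu_k)
  # so U = sum_j mu_j * grad_j / 2 ... only for quadratic forms with symmetric
  # w; computed directly from the gradient identity.
  p <- quad_penalty(img, dim)
  sum(as.numeric(img) * p$grad) / 2
}

#' Penalized MLTR reconstruction of an attenuation map
#'
#' Transmission-only separable-quadratic-surrogate (SQS) update of the 511 keV
#' attenuation map from blank/transmission count pairs. Per subset, with
#' \code{Z_i = eta z_i} the 307 keV line integral, the additive update is
#'
#' \code{mu_j <- mu_j - (sum_i l_ij eta H'_i + beta dU_j) /
#'   (sum_i l_ij eta^2 c_i L_i + beta sum_k w_jk)}
#'
#' followed by a non-negativity clamp; \code{H'} is the derivative of the
#' Poisson transmission negative log-likelihood, \code{c_i} the optimal
#' curvature and \code{L_i} the LOR chord length through the grid. Subset
#' data terms are scaled by the subset count so the penalty balance matches
#' the full objective.
#'
#' @param transmission per-LOR transmission counts.
#' @param blank per-LOR blank counts (or expectations).
#' @param lors a \code{lor_table}.
#' @param grid a grid description (\code{\link{phantom_grid}}).
#' @param config a \code{recon_config}.
#' @param r per-LOR additive expectation (scatter), default 0.
#' @param norm per-LOR normalization factors, default 1 (transmission and
#'   blank share detector effects, which therefore cancel).
#' @param init initial attenuation map (default zero).
#' @param eta 307/511 keV energy scale factor.
#' @param track_objective evaluate the penalized negative log-likelihood each
#'   iteration (costs one extra forward projection).
#' @return list with \code{mu} (mm^-1 at 511 keV) and \code{objective}.
#' @export
mltr_reconstruct <- function(transmission, blank, lors, grid,
                             config = recon_config("mltr"),
                             r = 0, norm = NULL, init = NULL,
                             eta = ETA_DEFAULT, track_objective = FALSE) {
  n <- lors$n
  stopifnot(length(transmission) == n, length(blank) == n)
  if (length(r) == 1) r <- rep(r, n)
  B <- blank * if (is.null(norm)) 1 else norm
  bad <- B <= 0 & transmission > 0
  if (any(bad)) {
    warning(sum(bad), " bins with zero blank but nonzero transmission excluded")
  }
  use <- B > 0
  mu <- if (is.null(init)) array(0, grid$dim) else init
  subsets <- make_subsets(lors, config)
  ns <- length(subsets)
  ep <- project_endpoints(lors, 307)
  objective <- numeric(0)
  for (it in seq_len(config$n_iterations)) {
    for (s in subsets) {
      s <- s[use[s]]
      if (!length(s)) next
      bp <- cpp_mltr_subset(ep$p1[s, , drop = FALSE],
                            ep$p2[s, , drop = FALSE], as.numeric(mu),
                            as.numeric(grid$origin), grid$voxel_size,
                            as.integer(grid$dim), B[s], transmission[s],
                            r[s], eta, config$epsilon)
      pen <- quad_penalty(mu, grid$dim)
      num <- ns * bp$num + config$beta * pen$grad
      den <- ns * bp$den + config$beta * pen$wsum
      mu <- array(pmax(as.numeric(mu) - num / pmax(den, 1e-300), 0),
                  grid$dim)
    }
    if (track_objective) {
      z <- cpp_forward(ep$p1[use, , drop = FALSE], ep$p2[use, , drop = FALSE],
                       as.numeric(mu), as.numeric(grid$origin),
                       grid$voxel_size, as.integer(grid$dim))
      yb <- B[use] * exp(-eta * z) + r[use]
      nll <- sum(yb - ifelse(transmission[use] > 0,
                             transmission[use] * log(pmax(yb, 1e-300)), 0))
      objective <- c(objective, nll + config$beta *
                       penalty_value(mu, grid$dim))
    }
  }
  list(mu = mu, objective = objective)
}

#' TOF-OSEM reconstruction of an activity map
#'
#' Ordered-subset TOF-MLEM with a fixed attenuation map. The expected counts
#' model is \code{w_i p_itj lambda_j + s_it} with \code{w_i = a_i n_i cal},
#' where \code{a_i} are the 511 keV attenuation factors of \code{mu_map},
#' \code{n_i} the normalization factors and \code{cal} the counts-per-activity
#' calibration (duration x decay factor x exposure), so the reconstruction is
#' returned in the activity map's units (kBq/ml). With one subset and a
#' single TOF bin this is classical MLEM.
#'
#' @param emission emission scan (list from \code{\link{simulate_emission}},
#'   or a counts matrix).
#' @param mu_map attenuation map at 511 keV used for the correction.
#' @param lors a \code{lor_table}.
#' @param grid a grid description.
#' @param config a \code{recon_config}.
#' @param norm per-LOR normalization factors (default 1).
#' @param calibration counts-per-(kBq/ml) calibration factor; taken from the
#'   emission scan metadata when available.
#' @param s_it additive expectation (scalar or matrix), default 0.
#' @param init initial activity (default uniform 1 on the support).
#' @param track_objective evaluate the Poisson log-likelihood each iteration.
#' @return list with \code{activity} (kBq/ml) and \code{objective}.
#' @export
osem_reconstruct <- function(emission, mu_map, lors, grid,
                             config = recon_config("osem"),
                             norm = NULL, calibration = NULL, s_it = 0,
                             init = NULL, track_objective = FALSE) {
  y <- if (is.list(emission)) emission$counts else emission
  if (is.null(calibration) && is.list(emission)) {
    calibration <- emission$duration_min * 60 *
      decay_factor(emission$duration_min) * emission$exposure_scale
  }
  if (is.null(calibration)) calibration <- 1
  n <- lors$n
  ntof <- ncol(y)
  stopifnot(nrow(y) == n)
  a <- attenuation_factors(mu_map, lors, grid, energy_mode = 511)
  w <- a * (if (is.null(norm)) 1 else norm) * calibration
  subsets <- make_subsets(lors, config)
  ns <- length(subsets)
  ep <- project_endpoints(lors, 511)
  gO <- as.numeric(grid$origin); gv <- grid$voxel_size
  gd <- as.integer(grid$dim)
  sens <- lapply(subsets, function(s) {
    cpp_back(ep$p1[s, , drop = FALSE], ep$p2[s, , drop = FALSE], w[s],
             gO, gv, gd)
  })
  lam <- if (is.null(init)) {
    supp <- Reduce(`+`, sens) > 0
    array(as.numeric(supp), grid$dim)
  } else init
  g <- lors$geometry
  sigma <- g$ctr_ps / (2 * sqrt(2 * log(2)))
  objective <- numeric(0)
  for (it in seq_len(config$n_iterations)) {
    for (k in seq_along(subsets)) {
      s <- subsets[[k]]
      bp <- cpp_osem_subset(ep$p1[s, , drop = FALSE],
                            ep$p2[s, , drop = FALSE], as.numeric(lam),
                            gO, gv, gd, y[s, , drop = FALSE], w[s],
                            s_it, g$tof_bin_width_ps, sigma)
      sk <- as.numeric(sens[[k]])
      upd <- as.numeric(bp) / pmax(sk, 1e-300)
      # a voxel unseen by this subset carries no information: leave it as is
      upd[sk <= 0] <- 1
      lam <- array(as.numeric(lam) * upd, grid$dim)
    }
    if (track_objective) {
      fp <- cpp_tof_forward(ep$p1, ep$p2, as.numeric(lam), gO, gv, gd,
                            g$tof_bin_width_ps, ntof, sigma)
      ybar <- fp * w + s_it
      objective <- c(objective,
                     sum(ifelse(y > 0, y * log(pmax(ybar, 1e-300)), 0) - ybar))
    }
  }
  list(activity = lam, objective = objective)
}

#' Joint activity/attenuation reconstruction with a transmission term
#'
#' MLAA-TX: interleaved updates maximizing the combined objective
#' \code{L_emis(lambda, mu) + alpha L_tran(eta mu) - beta U(mu)}. Each outer
#' iteration performs one TOF-OSEM pass over the activity (attenuation held
#' fixed), then several SQS attenuation passes combining the emission
#' surrogate derivative \code{h'_i = (y_i / (phi_i e^{-z_i} + s_i) - 1)
#' phi_i e^{-z_i}} with the alpha- and eta-weighted transmission term of the
#' MLTR update. Initialization with the regularized MLTR map is the intended
#' use. \code{alpha = 0} degenerates to emission-only attenuation updates;
#' large \code{alpha} approaches the MLTR solution.
#'
#' @param emission emission scan (see \code{\link{osem_reconstruct}}).
#' @param transmission,blank per-LOR transmission/blank counts.
#' @param lors a \code{lor_table}.
#' @param grid a grid description.
#' @param init_mu initial attenuation map (MLTR output).
#' @param config a \code{recon_config} (\code{alpha}, \code{beta},
#'   \code{mu_updates_per_iteration}).
#' @param norm per-LOR normalization factors (default 1).
#' @param r,s_it additive expectations for transmission and emission.
#' @param eta 307/511 keV energy scale factor.
#' @param calibration emission counts calibration (see
#'   \code{\link{osem_reconstruct}}).
#' @param track_objective evaluate the combined objective each outer
#'   iteration.
#' @return list with \code{activity}, \code{mu} and \code{objective}.
#' @export
mlaa_tx_reconstruct <- function(emission, transmission, blank, lors, grid,
                                init_mu,
                                config = recon_config("mlaa_tx"),
                                norm = NULL, r = 0, s_it = 0,
                                eta = ETA_DEFAULT, calibration = NULL,
                                track_objective = FALSE) {
  y_tof <- if (is.list(emission)) emission$counts else emission
  if (is.null(calibration) && is.list(emission)) {
    calibration <- emission$duration_min * 60 *
      decay_factor(emission$duration_min) * emission$exposure_scale
  }
  if (is.null(calibration)) calibration <- 1
  n <- lors$n
  y_emis <- rowSums(y_tof)
  if (length(r) == 1) r <- rep(r, n)
  nfac <- if (is.null(norm)) rep(1, n) else norm
  B <- blank * nfac
  use <- B > 0
  mu <- init_mu
  lam <- NULL
  subsets <- make_subsets(lors, config)
  ns <- length(subsets)
  ep511 <- project_endpoints(lors, 511)
  ep307 <- project_endpoints(lors, 307)
  gO <- as.numeric(grid$origin); gv <- grid$voxel_size
  gd <- as.integer(grid$dim)
  L_t <- cpp_forward(ep307$p1, ep307$p2, rep(1, prod(gd)), gO, gv, gd)
  L_e <- cpp_forward(ep511$p1, ep511$p2, rep(1, prod(gd)), gO, gv, gd)
  cfg_act <- config
  cfg_act$n_iterations <- 1L
  objective <- numeric(0)
  for (it in seq_len(config$n_iterations)) {
    # (1) one TOF-OSEM activity pass with the current attenuation
    res <- osem_reconstruct(y_tof, mu, lors, grid, cfg_act, norm = nfac,
                            calibration = calibration, s_it = s_it,
                            init = lam)
    lam <- res$activity
    # phi: expected emission counts at unit attenuation (includes calibration)
    phi <- cpp_forward(ep511$p1, ep511$p2, as.numeric(lam), gO, gv, gd) *
      nfac * calibration
    # (2) attenuation passes combining emission and transmission terms
    for (m in seq_len(config$mu_updates_per_iteration)) {
      for (s in subsets) {
        su <- s[use[s]]
        if (!length(su)) next
        q1 <- ep511$p1[su, , drop = FALSE]; q2 <- ep511$p2[su, , drop = FALSE]
        t1 <- ep307$p1[su, , drop = FALSE]; t2 <- ep307$p2[su, , drop = FALSE]
        z <- cpp_forward(q1, q2, as.numeric(mu), gO, gv, gd)
        Z <- eta * cpp_forward(t1, t2, as.numeric(mu), gO, gv, gd)
        pe <- phi[su] * exp(-z)
        ye <- pe + s_it
        hp <- y_emis[su] * ifelse(ye > 0, pe / ye, 1) - pe
        ce <- sqs_curvature(phi[su], y_emis[su], s_it, z, config$epsilon)
        be <- B[su] * exp(-Z)
        yt <- be + r[su]
        Hp <- transmission[su] * ifelse(yt > 0, be / yt, 1) - be
        ct <- sqs_curvature(B[su], transmission[su], r[su], Z, config$epsilon)
        bpe <- cpp_back2(q1, q2, hp, ce * L_e[su], gO, gv, gd)
        bpt <- cpp_back2(t1, t2, config$alpha * eta * Hp,
                         config$alpha * eta^2 * ct * L_t[su], gO, gv, gd)
        pen <- quad_penalty(mu, grid$dim)
        num <- ns * (bpe$b1 + bpt$b1) + config$beta * pen$grad
        den <- ns * (bpe$b2 + bpt$b2) + config$beta * pen$wsum
        mu <- array(pmax(as.numeric(mu) - num / pmax(den, 1e-300), 0),
                    grid$dim)
      }
    }
    if (track_objective) {
      z <- cpp_forward(ep511$p1, ep511$p2, as.numeric(mu), gO, gv, gd)
      Z <- eta * cpp_forward(ep307$p1, ep307$p2, as.numeric(mu), gO, gv, gd)
      ye <- phi * exp(-z) + s_it
      yt <- B * exp(-Z) + r
      le <- sum(ifelse(y_emis > 0, y_emis * log(pmax(ye, 1e-300)), 0) - ye)
      lt <- sum(ifelse(transmission[use] > 0,
                       transmission[use] * log(pmax(yt[use], 1e-300)), 0) -
                  yt[use])
      objective <- c(objective, le + config$alpha * lt -
                       config$beta * penalty_value(mu, grid$dim))
    }
  }
  list(activity = lam, mu = mu, objective = objective)
}

shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

dilate6 <- function(a) {
  a | shift3(a, 1, 0, 0) | shift3(a, -1, 0, 0) |
    shift3(a, 0, 1, 0) | shift3(a, 0, -1, 0) |
    shift3(a, 0, 0, 1) | shift3(a, 0, 0, -1)
}

dilate4_xy <- function(a) {
  a | shift3(a, 1, 0, 0) | shift3(a, -1, 0, 0) |
    shift3(a, 0, 1, 0) | shift3(a, 0, -1, 0)
}

grow_region <- function(seed, allowed, dil = dilate6, max_iter = 1000L) {
  cur <- seed & allowed
  for (i in seq_len(max_iter)) {
    nxt <- dil(cur) & allowed
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

#' Body-contour mask of a reconstructed attenuation map
#'
#' Transmission reconstructions carry positive-only noise in the air around
#' the body (the non-negativity clamp makes the air noise one-sided), which
#' systematically inflates attenuation correction along lines that traverse
#' a lot of air, for example through the neck. The standard remedy is a body
#' contour: the map is smoothed, thresholded, reduced to the connected body
#' component, internal low-attenuation cavities (lungs) are refilled by a
#' background flood from the grid boundary, and everything outside the
#' contour is set to zero.
#'
#' @param mu_map reconstructed attenuation volume (mm^-1).
#' @param threshold body threshold on the smoothed map, mm^-1.
#' @param sigma Gaussian smoothing sigma in voxels.
#' @return list with \code{mu} (masked map) and \code{mask} (logical array).
#' @export
mu_body_mask <- function(mu_map, threshold = 0.003, sigma = 2) {
  d <- dim(mu_map)
  sm <- array(cpp_gauss3d(as.numeric(mu_map), as.integer(d), sigma, 3.5), d)
  b <- sm > threshold
  if (!any(b)) return(list(mu = mu_map, mask = array(TRUE, d)))
  # connected body component from the strongest voxel
  seed <- array(FALSE, d)
  seed[which.max(sm)] <- TRUE
  body <- grow_region(seed, b)
  # morphological closing seals thin low-attenuation channels through the
  # body surface before cavities are identified
  closed <- body
  for (i in 1:2) closed <- dilate6(closed)
  for (i in 1:2) closed <- !dilate6(!closed)
  # background flood from the transaxial boundary, slice by slice: internal
  # cavities (lungs) are ringed by tissue in every transaxial plane, while
  # true outside air touches the grid edge of its slice
  edge <- array(FALSE, d)
  edge[c(1, d[1]), , ] <- TRUE
  edge[, c(1, d[2]), ] <- TRUE
  outside <- grow_region(edge & !closed, !closed, dil = dilate4_xy)
  mask <- closed | (!closed & !outside)
  list(mu = mu_map * mask, mask = mask)
}

#' Write reconstruction volumes
#'
#' Stores the result volumes as NIfTI files with the config echoed into a
#' JSON sidecar, and the objective trace as delimited text.
#'
#' @param result list from one of the reconstruction functions.
#' @param config the \code{recon_config} used.
#' @param grid the grid description.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_recon <- function(result, config, grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- grid$voxel_size
  for (nm in intersect(names(result), c("activity", "mu"))) {
    if (is.null(result[[nm]])) next
    img <- RNifti::asNifti(result[[nm]], pixdim = c(vs, vs, vs))
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  if (length(result$objective)) {
    utils::write.table(
      data.frame(iteration = seq_along(result$objective),
                 objective = result$objective),
      file.path(dir, "objective.tsv"), sep = "\t", row.names = FALSE)
  }
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
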