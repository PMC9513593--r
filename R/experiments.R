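#' Desk-scale study conditions
#'
#' The fixed conditions all desk-scale studies share: the reduced crystal
#' lattice (80 crystals per ring, 8 rings per axial unit), no axial mashing
#' (the coarse lattice already provides the sampling the full-size scanner
#' reaches after mash-3), the computational support cylinder around the
#' phantom, and the count levels of a 20-min-equivalent scan (blank counts at
#' the 20-min exposure and total emission counts, both of order 10^7; object
#' transmission counts land in the 10^6-10^7 range).
#'
#' @return list of named defaults.
#' @export
desk_conditions <- function() {
  list(crystals_per_ring = 120L, rings_per_unit = 8L, axial_mash = 1L,
       support_radius = 100, support_margin = 10,
       blank_counts_20min = 2e7, emission_counts_20min = 1.4e7,
       blank_duration_min = 200)
}

#' Build the desk-scale acquisition model for a phantom
#'
#' Geometry (preset coarsened to desk scale), sinogram spec, and the LOR
#' table restricted to the phantom support, with DOI endpoints cached. For
#' multi-bed protocols the per-bed LOR tables are built at each bed's axial
#' offset and stitched.
#'
#' @param phantom a \code{phantom}.
#' @param preset scanner preset name.
#' @param angle acceptance-angle override in degrees (NULL = policy angle).
#' @param protocol a bed protocol (\code{\link{bed_protocol}}); default for
#'   the preset.
#' @param conditions desk conditions (\code{\link{desk_conditions}}).
#' @return list with \code{geometry}, \code{spec}, \code{lors},
#'   \code{protocol}.
#' @export
desk_setup <- function(phantom, preset = "uexplorer", angle = NULL,
                       protocol = NULL, conditions = desk_conditions()) {
  g <- desk_scale(build_scanner(preset),
                  crystals_per_ring = conditions$crystals_per_ring,
                  rings_per_unit = conditions$rings_per_unit)
  if (is.null(protocol)) protocol <- bed_protocol(preset)
  spec <- sinogram_spec(g, axial_mash = conditions$axial_mash,
                        max_acceptance_angle = angle)
  zpad <- conditions$support_margin
  zlim <- range(phantom$origin[3],
                phantom$origin[3] + phantom$dim[3] * phantom$voxel_size) +
    c(-zpad, zpad)
  beds <- lapply(seq_len(protocol$n_beds), function(k) {
    gk <- g
    gk$axial_offset <- protocol$bed_axial_positions[k]
    lt <- lor_table(gk, spec)
    lt <- filter_lors(lt, conditions$support_radius, zlim)
    lt$bed <- rep(k, lt$n)
    lt$duration_min <- protocol$per_bed_duration_min
    lt
  })
  lors <- stitch_beds(beds)
  lors <- cache_doi(lors)
  list(geometry = g, spec = spec, lors = lors, protocol = protocol,
       conditions = conditions)
}

#' Bed protocols of the three scanner geometries
#'
#' Whole-body coverage with conserved total scan time (20 min): a single bed
#' on the 194-cm scanner, two 50-percent-overlapping beds (10 min each) on
#' the one-meter scanner, and eight abutting beds (2.5 min each) on the 24-cm
#' scanner.
#'
#' @param preset scanner preset name.
#' @param total_duration_min total scan time divided across beds.
#' @return list with \code{n_beds}, \code{bed_axial_positions} (mm),
#'   \code{overlap_fraction}, \code{per_bed_duration_min}.
#' @export
bed_protocol <- function(preset = "uexplorer", total_duration_min = 20) {
  u <- 1940 / 8
  p <- switch(preset,
    uexplorer = list(n_beds = 1L, bed_axial_positions = 0,
                     overlap_fraction = 0),
    one_meter = list(n_beds = 2L, bed_axial_positions = c(-1, 1) * u,
                     overlap_fraction = 0.5),
    conventional_24cm = list(n_beds = 8L,
                             bed_axial_positions = u * ((0:7) - 3.5),
                             overlap_fraction = 0),
    stop("unknown preset: ", preset)
  )
  p$per_bed_duration_min <- total_duration_min / p$n_beds
  p
}

#' Axial coverage of a bed protocol
#'
#' @param protocol a bed protocol.
#' @param fov_length axial FOV length of one bed position, mm.
#' @return total covered axial extent, mm.
#' @export
bed_coverage <- function(protocol, fov_length) {
  diff(range(protocol$bed_axial_positions)) + fov_length
}

#' Stitch per-bed LOR tables into one joint set
#'
#' Concatenates the per-bed LOR tables (each already carrying its bed's axial
#' offset in the endpoint coordinates) so that a single reconstruction uses
#' the bed-summed sensitivity. A single bed passes through unchanged.
#'
#' @param beds list of \code{lor_table}s.
#' @return one \code{lor_table} with a \code{bed} column.
#' @export
stitch_beds <- function(beds) {
  if (length(beds) == 1) return(beds[[1]])
  out <- beds[[1]]
  out$p1 <- do.call(rbind, lapply(beds, `[[`, "p1"))
  out$p2 <- do.call(rbind, lapply(beds, `[[`, "p2"))
  for (f in c("length", "angle", "radial", "plane", "bed", "kept")) {
    out[[f]] <- unlist(lapply(beds, `[[`, f))
  }
  out$n <- length(out$length)
  out$duration_min <- beds[[1]]$duration_min
  out
}

#' Run the lutetium-based attenuation-correction pipeline on one data set
#'
#' The full desk-scale chain for one seed: simulate the blank and object
#' transmission scans, reconstruct the attenuation map with penalized MLTR,
#' simulate the TOF emission scan, reconstruct activity with TOF-OSEM using
#' (a) the MLTR map and optionally (b) the ground-truth map, optionally run
#' MLAA-TX initialized from MLTR, and compute the metric reports.
#'
#' @param phantom a \code{phantom} with VOIs (and lesions for lesion
#'   analysis).
#' @param setup acquisition model from \code{\link{desk_setup}}.
#' @param duration_min transmission/emission scan duration (total).
#' @param beta penalty weight (NULL = preset default).
#' @param seed integer seed for all Poisson sampling of this replicate.
#' @param mltr_iterations MLTR iteration count.
#' @param recon_activity reconstruct the emission data.
#' @param gt_reference also reconstruct with the ground-truth attenuation
#'   map.
#' @param run_mlaa run MLAA-TX (initialized from the MLTR map).
#' @param alpha MLAA-TX transmission weight.
#' @param gamma_window transmission energy window, keV.
#' @param scatter_mode \code{"none"} or \code{"single_scatter"}.
#' @param water_scale apply water-peak scaling to the MLTR map before AC
#'   (used when scatter is included).
#' @param mask_support apply the body-contour mask
#'   (\code{\link{mu_body_mask}}) to the MLTR map before it is used for AC.
#' @param osem_iterations activity iterations (NULL = preset default).
#' @return list with the simulated data, reconstructions and
#'   \code{metrics_report}s.
#' @export
run_lu_ac_study <- function(phantom, setup, duration_min = 20, beta = NULL,
                            seed = 1L, mltr_iterations = 50L,
                            recon_activity = TRUE, gt_reference = TRUE,
                            run_mlaa = FALSE, alpha = 1,
                            gamma_window = c(250, 350),
                            scatter_mode = "none", water_scale = NULL,
                            mask_support = TRUE,
                            osem_iterations = NULL) {
  g <- setup$geometry
  lors <- setup$lors
  grid <- phantom_grid(phantom)
  cond <- setup$conditions
  lu <- lu_source_model()
  # one global exposure factor per geometry: 20-min blank at the target level
  expo <- exposure_for_counts(g, lors, lu, 20, cond$blank_counts_20min,
                              gamma_window)
  per_bed <- duration_min / setup$protocol$n_beds
  blank <- simulate_blank(g, lors, lu, cond$blank_duration_min, expo,
                          gamma_window, seed = seed * 13L + 1L)
  # blank rescaled to the object-scan duration (counts stay Poisson-clean)
  bfac <- per_bed / cond$blank_duration_min
  tran <- simulate_transmission(g, phantom, lors, lu, per_bed, expo,
                                gamma_window, scatter_mode,
                                seed = seed * 13L + 2L)
  cfg_mltr <- recon_config("mltr", preset = g$preset,
                           n_iterations = mltr_iterations, seed = seed)
  if (!is.null(beta)) cfg_mltr$beta <- beta
  mltr <- mltr_reconstruct(tran$counts, blank$expectation * bfac, lors, grid,
                           cfg_mltr)
  mu_ac <- mltr$mu
  if (mask_support) mu_ac <- mu_body_mask(mu_ac)$mu
  wps <- NULL
  if (isTRUE(water_scale) ||
      (is.null(water_scale) && scatter_mode != "none")) {
    wps <- water_peak_scale(mu_ac)
    mu_ac <- wps$mu
  }
  out <- list(setup = setup, blank = blank, transmission = tran,
              mltr = mltr, mu_ac = mu_ac, water_peak = wps,
              mu_report = metrics_report(mu_ac, phantom$mu, phantom,
                                         label = "mu_mltr"),
              seed = seed, duration_min = duration_min)
  if (!recon_activity) return(out)

  eexpo <- emission_exposure_for_counts(g, phantom, lors, 20,
                                        cond$emission_counts_20min)
  emis <- simulate_emission(g, phantom, lors, per_bed, eexpo,
                            seed = seed * 13L + 3L)
  cfg_osem <- recon_config("osem", preset = g$preset, seed = seed)
  if (!is.null(osem_iterations)) cfg_osem$n_iterations <-
    as.integer(osem_iterations)
  act_lu <- osem_reconstruct(emis, mu_ac, lors, grid, cfg_osem)
  out$emission <- emis
  out$osem_lu <- act_lu
  out$activity_report <- metrics_report(act_lu$activity, phantom$activity,
                                        phantom, label = "osem_lu_ac")
  if (gt_reference) {
    act_gt <- osem_reconstruct(emis, phantom$mu, lors, grid, cfg_osem)
    out$osem_gt <- act_gt
    out$gt_report <- metrics_report(act_gt$activity, phantom$activity,
                                    phantom, label = "osem_gt_ac")
    if (length(phantom$lesions)) {
      out$lesions <- lesion_suvmax_bias(act_lu$activity, phantom$activity,
                                        act_gt$activity, phantom)
    }
  }
  if (run_mlaa) {
    cfg_mlaa <- recon_config("mlaa_tx", preset = g$preset, alpha = alpha,
                             seed = seed)
    if (!is.null(beta)) cfg_mlaa$beta <- beta
    mlaa <- mlaa_tx_reconstruct(emis, tran$counts, blank$expectation * bfac,
                                lors, grid, init_mu = mltr$mu,
                                config = cfg_mlaa)
    out$mlaa <- mlaa
    out$mlaa_mu_report <- metrics_report(mlaa$mu, phantom$mu, phantom,
                                         label = "mu_mlaa_tx")
    out$mlaa_activity_report <- metrics_report(mlaa$activity,
                                               phantom$activity, phantom,
                                               label = "mlaa_tx")
  }
  out
}

#' Experiment configuration
#'
#' Config object for the study drivers: acceptance-angle sweep, scan-duration
#' sweep, scanner-geometry comparison, MLAA-TX weighting-factor sweep, and
#' the scatter / energy-threshold study.
#'
#' @param experiment one of \code{"angle_sweep"}, \code{"duration_sweep"},
#'   \code{"geometry_compare"}, \code{"alpha_sweep"}, \code{"scatter_study"}.
#' @param angles acceptance angles in degrees (angle sweep).
#' @param durations scan durations in minutes (duration sweep).
#' @param duration_betas penalty weights per duration arm.
#' @param presets scanner presets (geometry comparison).
#' @param alphas MLAA-TX weights (alpha sweep).
#' @param thresholds low energy-window edges in keV (scatter study).
#' @param scatter_modes scatter settings (scatter study).
#' @param seeds replicate seeds.
#' @param phantom_dim,voxel_size phantom grid controls.
#' @param mltr_iterations,osem_iterations iteration overrides (smaller values
#'   for quick runs).
#' @param recon_activity include the emission chain where applicable.
#' @return object of class \code{experiment_config}.
#' @export
experiment_config <- function(experiment = c("angle_sweep", "duration_sweep",
                                             "geometry_compare",
                                             "alpha_sweep", "scatter_study"),
                              angles = c(57, 51, 43, 32, 17),
                              durations = c(5, 10, 20),
                              duration_betas = c(40000, 20000, 10000),
                              presets = c("uexplorer", "one_meter",
                                          "conventional_24cm"),
                              alphas = c(0.1, 1, 10),
                              thresholds = c(250, 290),
                              scatter_modes = c("none", "single_scatter"),
                              seeds = 1L,
                              phantom_dim = c(48L, 48L, 180L),
                              voxel_size = 4,
                              mltr_iterations = 50L,
                              osem_iterations = NULL,
                              recon_activity = FALSE) {
  experiment <- match.arg(experiment)
  structure(list(experiment = experiment, angles = angles,
                 durations = durations, duration_betas = duration_betas,
                 presets = presets, alphas = alphas, thresholds = thresholds,
                 scatter_modes = scatter_modes, seeds = as.integer(seeds),
                 phantom_dim = as.integer(phantom_dim),
                 voxel_size = voxel_size,
                 mltr_iterations = as.integer(mltr_iterations),
                 osem_iterations = osem_iterations,
                 recon_activity = recon_activity),
            class = "experiment_config")
}

#' Run a configured experiment
#'
#' Executes every arm of the configured study (simulate, reconstruct,
#' quantify), writes per-arm artifacts (volumes, reports, the echoed config)
#' under \code{outdir} when given, and returns the bundle of metric reports.
#' A failing arm is recorded and the remaining arms continue.
#'
#' @param config an \code{experiment_config}.
#' @param outdir output directory (NULL = in-memory only).
#' @return list of per-arm results with class \code{experiment_bundle}.
#' @export
run_experiment <- function(config, outdir = NULL) {
  ph <- default_phantom(seed = config$seeds[1], dim = config$phantom_dim,
                        voxel_size = config$voxel_size)
  arms <- switch(config$experiment,
    angle_sweep = lapply(config$angles, function(a)
      list(label = sprintf("angle_%g", a), preset = "uexplorer", angle = a)),
    duration_sweep = lapply(seq_along(config$durations), function(i)
      list(label = sprintf("duration_%gmin", config$durations[i]),
           preset = "uexplorer", duration = config$durations[i],
           beta = config$duration_betas[i])),
    geometry_compare = lapply(config$presets, function(p)
      list(label = p, preset = p)),
    alpha_sweep = lapply(config$alphas, function(a)
      list(label = sprintf("alpha_%g", a), preset = "uexplorer", alpha = a,
           mlaa = TRUE)),
    scatter_study = {
      grid <- expand.grid(thr = config$thresholds,
                          sc = config$scatter_modes,
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i)
        list(label = sprintf("thr%g_%s", grid$thr[i], grid$sc[i]),
             preset = "uexplorer", threshold = grid$thr[i],
             scatter = grid$sc[i]))
    })
  setups <- new.env()
  bundle <- list()
  for (arm in arms) {
    res <- tryCatch({
      key <- paste(arm$preset, arm$angle %||% "policy")
      if (is.null(setups[[key]])) {
        setups[[key]] <- desk_setup(ph, arm$preset, angle = arm$angle)
      }
      arm_res <- list(arm = arm, seeds = list())
      for (sd in config$seeds) {
        st <- run_lu_ac_study(
          ph, setups[[key]],
          duration_min = arm$duration %||% 20,
          beta = arm$beta, seed = sd,
          mltr_iterations = config$mltr_iterations,
          recon_activity = config$recon_activity || isTRUE(arm$mlaa),
          gt_reference = config$recon_activity,
          run_mlaa = isTRUE(arm$mlaa), alpha = arm$alpha %||% 1,
          gamma_window = c(arm$threshold %||% 250, 350),
          scatter_mode = arm$scatter %||% "none",
          osem_iterations = config$osem_iterations)
        keep <- st[grep("report|lesions|water_peak|seed", names(st))]
        keep$mu <- st$mu_ac
        if (!is.null(st$osem_lu)) keep$activity <- st$osem_lu$activity
        arm_res$seeds[[as.character(sd)]] <- keep
        if (!is.null(outdir)) {
          d <- file.path(outdir, arm$label, paste0("seed", sd))
          write_recon(list(mu = keep$mu, activity = keep$activity),
                      recon_config("mltr", preset = arm$preset),
                      phantom_grid(ph), d)
        }
      }
      arm_res
    }, error = function(e) list(arm = arm, error = conditionMessage(e)))
    bundle[[arm$label]] <- res
  }
  out <- structure(list(config = config, arms = bundle, phantom_dim = ph$dim),
                   class = "experiment_bundle")
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an experiment report
#'
#' Machine-readable JSON metrics plus delimited summary tables (NRMSE/SSIM
#' per arm, per-organ bias statistics, per-lesion SUVmax bias).
#'
#' @param bundle an \code{experiment_bundle}.
#' @param dir output directory.
#' @return \code{write_report}: the directory, invisibly;
#'   \code{read_report}: the parsed JSON report.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summarize <- function(arm) {
    if (!is.null(arm$error)) return(list(error = arm$error))
    lapply(arm$seeds, function(st) {
      o <- list()
      for (nm in names(st)) {
        if (inherits(st[[nm]], "metrics_report")) {
          o[[nm]] <- list(nrmse = st[[nm]]$nrmse, ssim = st[[nm]]$ssim,
                          max_abs_mean_bias = st[[nm]]$max_abs_mean_bias,
                          voi = st[[nm]]$voi)
        }
      }
      if (!is.null(st$lesions)) o$lesions <- st$lesions
      o
    })
  }
  rep <- list(experiment = bundle$config$experiment,
              seeds = bundle$config$seeds,
              phantom_dim = bundle$phantom_dim,
              arms = lapply(bundle$arms, summarize))
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  # flat summary table
  rows <- list()
  for (lbl in names(bundle$arms)) {
    arm <- bundle$arms[[lbl]]
    if (!is.null(arm$error)) next
    for (sd in names(arm$seeds)) {
      st <- arm$seeds[[sd]]
      for (nm in names(st)) {
        if (inherits(st[[nm]], "metrics_report")) {
          rows[[length(rows) + 1L]] <-
            data.frame(arm = lbl, seed = sd, image = st[[nm]]$label,
                       nrmse = st[[nm]]$nrmse, ssim = st[[nm]]$ssim,
                       max_abs_mean_bias = st[[nm]]$max_abs_mean_bias)
        }
      }
    }
  }
  if (length(rows)) {
    utils::write.table(do.call(rbind, rows),
                       file.path(dir, "summary.tsv"), sep = "\t",
                       row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
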