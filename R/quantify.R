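#' Water-peak scaling of an attenuation map
#'
#' Finds the soft-tissue (water) mode in the histogram of the map and rescales
#' the whole volume so the mode lands on the known attenuation coefficient of
#' water. Used to correct the global underestimation caused by unmodeled
#' scatter in the transmission data.
#'
#' @param mu_map attenuation volume (mm^-1 at 511 keV).
#' @param target_mu_water target water value, mm^-1.
#' @param bin_width histogram bin width, mm^-1.
#' @param search_window mode search window, mm^-1.
#' @param smooth_bins moving-average smoothing width (odd).
#' @return list with \code{mu} (scaled map) and \code{factor}; factor 1 with a
#'   warning when no mode lies in the window.
#' @export
water_peak_scale <- function(mu_map, target_mu_water = 0.0096,
                             bin_width = 2e-4,
                             search_window = c(0.007, 0.012),
                             smooth_bins = 3L) {
  v <- as.numeric(mu_map)
  v <- v[v > 0]
  if (!length(v)) {
    warning("no positive voxels; water peak not found, factor 1")
    return(list(mu = mu_map, factor = 1))
  }
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = edges, plot = FALSE)
  counts <- as.numeric(stats::filter(h$counts, rep(1 / smooth_bins,
                                                   smooth_bins),
                                     sides = 2))
  counts[is.na(counts)] <- 0
  mids <- h$mids
  inwin <- mids >= search_window[1] & mids <= search_window[2]
  if (!any(inwin) || all(counts[inwin] == 0)) {
    warning("no histogram mode in the water search window, factor 1")
    return(list(mu = mu_map, factor = 1))
  }
  mode_mu <- mids[inwin][which.max(counts[inwin])]
  f <- target_mu_water / mode_mu
  list(mu = mu_map * f, factor = f)
}

#' Normalized root-mean-square error
#'
#' RMSE between an evaluated volume and the ground truth, normalized by the
#' evaluated image's own value range and reported in percent. A switch offers
#' the conventional ground-truth-range normalization instead.
#'
#' @param x evaluated volume.
#' @param x_ref ground-truth volume on the same grid.
#' @param denominator \code{"evaluated_range"} (default) or
#'   \code{"reference_range"}.
#' @param mask optional logical mask restricting the comparison.
#' @return NRMSE in percent.
#' @export
nrmse <- function(x, x_ref, denominator = c("evaluated_range",
                                            "reference_range"),
                  mask = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(length(x) == length(x_ref))
  xa <- as.numeric(x); xr <- as.numeric(x_ref)
  if (!is.null(mask)) { xa <- xa[mask]; xr <- xr[mask] }
  rng <- if (denominator == "evaluated_range") diff(range(xa)) else
    diff(range(xr))
  if (rng <= 0) stop("zero value range in the normalizing image")
  100 * sqrt(mean((xa - xr)^2)) / rng
}

#' Structural similarity index (3D, Gaussian-windowed)
#'
#' Mean local SSIM with equal (unit) weighting of the luminance, contrast and
#' structural terms, a Gaussian window of sigma 1.5 voxels (truncated at 3.5
#' sigma, replicate padding) and stabilizing constants C1 = (0.01 L)^2,
#' C2 = (0.03 L)^2, C3 = C2/2 with L the ground-truth dynamic range. Border
#' voxels within the window radius are excluded from the mean.
#'
#' @param x evaluated volume.
#' @param x_ref ground-truth volume on the same grid.
#' @param sigma Gaussian window sigma in voxels.
#' @param data_range L; defaults to the ground-truth range.
#' @return SSIM in [-1, 1]; 1 iff identical.
#' @export
ssim <- function(x, x_ref, sigma = 1.5, data_range = NULL) {
  stopifnot(all(dim(x) == dim(x_ref)))
  d <- dim(x)
  if (length(d) != 3) stop("ssim expects 3D volumes")
  truncate <- 3.5
  r <- floor(truncate * sigma + 0.5)
  if (any(d < 2 * r + 1)) stop("volume smaller than the SSIM window")
  if (is.null(data_range)) data_range <- diff(range(x_ref))
  if (data_range <= 0) data_range <- 1
  G <- function(v) cpp_gauss3d(as.numeric(v), as.integer(d), sigma, truncate)
  ux <- G(x); uy <- G(x_ref)
  vx <- G(x * x) - ux * ux
  vy <- G(x_ref * x_ref) - uy * uy
  vxy <- G(x * x_ref) - ux * uy
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  S <- array(S, d)
  core <- S[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r)]
  mean(core)
}

#' Voxel-wise relative bias
#'
#' \code{(x - x_ref) / x_ref} per voxel; voxels with zero ground truth are
#' masked (NA).
#'
#' @param x evaluated volume.
#' @param x_ref ground-truth volume.
#' @return bias volume (fractional; NA where the ground truth is 0).
#' @export
voxel_bias <- function(x, x_ref) {
  stopifnot(length(x) == length(x_ref))
  b <- (x - x_ref) / x_ref
  b[x_ref == 0] <- NA
  array(b, dim(x))
}

#' Per-organ VOI statistics of a bias volume
#'
#' Pools the bias voxels of each organ group's VOIs and reports boxplot
#' statistics: mean, median, quartiles, whiskers at 1.5 IQR and outlier
#' count. The headline statistic is the maximum over organs of the absolute
#' mean bias.
#'
#' @param bias_volume volume from \code{\link{voxel_bias}}.
#' @param phantom a \code{phantom} with VOIs attached
#'   (\code{\link{define_vois}}).
#' @return data frame (one row per organ group) with attribute
#'   \code{max_abs_mean}.
#' @export
voi_stats <- function(bias_volume, phantom) {
  if (!length(phantom$vois)) stop("phantom has no VOIs")
  groups <- unique(vapply(phantom$vois, `[[`, "", "group"))
  rows <- lapply(groups, function(gr) {
    vox <- unlist(lapply(phantom$vois[vapply(phantom$vois, `[[`, "",
                                             "group") == gr],
                         `[[`, "voxels"))
    b <- as.numeric(bias_volume)[vox]
    b <- b[!is.na(b)]
    if (!length(b)) stop("empty VOI group: ", gr)
    q <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo_f <- q[1] - 1.5 * iqr
    hi_f <- q[3] + 1.5 * iqr
    inw <- b[b >= lo_f & b <= hi_f]
    data.frame(group = gr, n_voxels = length(b), mean = mean(b),
               median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = if (length(inw)) min(inw) else q[1],
               whisker_high = if (length(inw)) max(inw) else q[3],
               n_outliers = sum(b < lo_f | b > hi_f))
  })
  out <- do.call(rbind, rows)
  attr(out, "max_abs_mean") <- max(abs(out$mean))
  out
}

#' Lesion SUVmax bias against two references
#'
#' For each lesion, SUVmax is the maximum voxel value inside the lesion
#' sphere dilated by one voxel (the maximum location may differ between
#' images). The percentage bias is reported against the ground-truth activity
#' map and against a reference reconstruction (OSEM with the ground-truth
#' attenuation map). The SUV normalization constant cancels in the
#' percentages and is fixed to 1.
#'
#' @param activity evaluated activity volume.
#' @param ref_truth ground-truth activity volume.
#' @param ref_recon reference reconstruction volume (may be NULL).
#' @param phantom a \code{phantom} with lesions embedded.
#' @return data frame with one row per lesion: host organ, contrast,
#'   diameter, SUVmax of each image and the percentage biases.
#' @export
lesion_suvmax_bias <- function(activity, ref_truth, ref_recon, phantom) {
  if (!length(phantom$lesions)) stop("phantom has no lesions")
  rows <- lapply(seq_along(phantom$lesions), function(i) {
    le <- phantom$lesions[[i]]
    vox <- sphere_voxels(phantom, le$center,
                         le$diameter / 2 + phantom$voxel_size)
    if (!length(vox)) stop("empty lesion search region")
    sm <- max(as.numeric(activity)[vox])
    st <- max(as.numeric(ref_truth)[vox])
    sr <- if (is.null(ref_recon)) NA_real_ else
      max(as.numeric(ref_recon)[vox])
    data.frame(lesion = i, host = le$host, diameter = le$diameter,
               contrast = le$contrast, suvmax = sm, suvmax_truth = st,
               suvmax_ref = sr,
               bias_vs_truth = 100 * (sm - st) / st,
               bias_vs_ref = if (is.null(ref_recon)) NA_real_ else
                 100 * (sm - sr) / sr)
  })
  do.call(rbind, rows)
}

#' Assemble a metrics report
#'
#' Pure summary of one reconstruction arm: NRMSE, SSIM, VOI bias statistics
#' and (optionally) lesion SUVmax biases; identical inputs give identical
#' reports.
#'
#' @param x evaluated volume.
#' @param x_ref ground-truth volume.
#' @param phantom a \code{phantom} with VOIs.
#' @param lesion_refs optional list(truth =, recon =) activity references for
#'   lesion analysis.
#' @param label arm label stored in the report.
#' @return object of class \code{metrics_report}.
#' @export
metrics_report <- function(x, x_ref, phantom, lesion_refs = NULL,
                           label = "") {
  vs <- voi_stats(voxel_bias(x, x_ref), phantom)
  rep <- list(label = label,
              nrmse = nrmse(x, x_ref),
              ssim = ssim(x, x_ref),
              voi = vs,
              max_abs_mean_bias = attr(vs, "max_abs_mean"))
  if (!is.null(lesion_refs)) {
    rep$lesions <- lesion_suvmax_bias(x, lesion_refs$truth,
                                      lesion_refs$recon, phantom)
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report [%s]: NRMSE %.2f%%, SSIM %.4f, max |organ mean bias| %.2f%%\n",
              x$label, x$nrmse, x$ssim, 100 * x$max_abs_mean_bias))
  invisible(x)
}
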