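ETA_DEFAULT <- 1.2276 # 307/511 keV attenuation scale factor (tissue fit)

#' Tissue attenuation / activity reference table
#'
#' Linear attenuation coefficients at 511 keV (mm^-1) for the tissue classes
#' used by the synthetic phantom, with the 307 keV column either derived by the
#' single energy-scale factor eta (\code{mode = "eta_consistent"},
#' mu_307 = eta * mu_511 for every tissue) or supplied per tissue
#' (\code{mode = "independent"}, for model-mismatch studies).
#'
#' @param mode \code{"eta_consistent"} or \code{"independent"}.
#' @param mu_307 named numeric vector (per tissue) when independent.
#' @param eta energy scale factor, default 1.2276.
#' @return data frame with rows per tissue class and columns \code{mu_511},
#'   \code{mu_307}, \code{activity} (default concentration, kBq/ml).
#' @export
tissue_mu_table <- function(mode = c("eta_consistent", "independent"),
                            mu_307 = NULL, eta = ETA_DEFAULT) {
  mode <- match.arg(mode)
  tab <- data.frame(
    row.names = c("air", "lung", "adipose", "soft", "liver", "blood",
                  "brain", "bone", "marrow", "water"),
    mu_511 = c(0, 0.0027, 0.0088, 0.0096, 0.0099, 0.0098,
               0.0099, 0.0172, 0.0098, 0.0096),
    activity = c(0, 1.0, 1.2, 2.0, 5.0, 4.0, 12.0, 1.5, 3.0, 0)
  )
  if (mode == "eta_consistent") {
    tab$mu_307 <- eta * tab$mu_511
  } else {
    if (is.null(mu_307) || !all(rownames(tab) %in% names(mu_307)))
      stop("independent mode requires a mu_307 value for every tissue")
    tab$mu_307 <- as.numeric(mu_307[rownames(tab)])
  }
  if (any(tab$mu_511 < 0) || any(tab$mu_307 < 0)) stop("negative mu")
  tab
}

#' Default synthetic torso body specification
#'
#' Geometric-primitive stand-in for a voxelized whole-body phantom: torso,
#' neck and head with skull and brain, two lungs, liver, left-ventricle blood
#' pool with myocardium, spine and hip bones with marrow cores, and a hot
#' bladder. Organs listed later take priority where shapes overlap (they carve
#' into earlier ones). Sizes are chosen so the body fits a
#' 192 x 192 x 720 mm grid; positions are in mm about the grid center.
#'
#' @return list of organ definitions (name, shape, parameters, tissue class,
#'   activity concentration in kBq/ml before global scaling).
#' @export
default_body_spec <- function() {
  org <- function(name, shape, tissue, activity, ...)
    c(list(name = name, shape = shape, tissue = tissue, activity = activity),
      list(...))
  list(
    org("body", "cylinder", "soft", 2.0,
        center = c(0, 0), semi = c(88, 64), zlim = c(-360, 200)),
    org("neck", "cylinder", "soft", 2.0,
        center = c(0, 10), semi = c(38, 38), zlim = c(200, 248)),
    org("skull", "shell", "bone", 1.5,
        center = c(0, 0, 296), r_outer = 64, r_inner = 40),
    org("brain", "sphere", "brain", 12.0, center = c(0, 0, 296), r = 40),
    org("lung_left", "ellipsoid", "lung", 1.0,
        center = c(-44, -6, 110), semi = c(34, 42, 82)),
    org("lung_right", "ellipsoid", "lung", 1.0,
        center = c(44, -6, 110), semi = c(34, 42, 82)),
    org("liver", "ellipsoid", "liver", 5.0,
        center = c(36, 6, -24), semi = c(44, 42, 48)),
    org("myocardium", "shell", "soft", 7.0,
        center = c(0, -6, 56), r_outer = 38, r_inner = 24),
    org("lv_blood", "sphere", "blood", 4.0, center = c(0, -6, 56), r = 24),
    org("spine", "cylinder", "bone", 1.5,
        center = c(0, 40), semi = c(20, 20), zlim = c(-340, 190)),
    org("spine_marrow", "cylinder", "marrow", 3.0,
        center = c(0, 40), semi = c(12, 12), zlim = c(-340, 190)),
    org("hip_left", "ellipsoid", "bone", 1.5,
        center = c(-48, 6, -292), semi = c(38, 36, 64)),
    org("hip_right", "ellipsoid", "bone", 1.5,
        center = c(48, 6, -292), semi = c(38, 36, 64)),
    org("hip_marrow_left", "ellipsoid", "marrow", 3.0,
        center = c(-48, 6, -310), semi = c(26, 24, 36)),
    org("hip_marrow_right", "ellipsoid", "marrow", 3.0,
        center = c(48, 6, -310), semi = c(26, 24, 36)),
    org("bladder", "sphere", "water", 25.0, center = c(0, -16, -300), r = 28)
  )
}

organ_mask <- function(organ, cx, cy, cz) {
  switch(organ$shape,
    ellipsoid = {
      ((cx - organ$center[1]) / organ$semi[1])^2 +
        ((cy - organ$center[2]) / organ$semi[2])^2 +
        ((cz - organ$center[3]) / organ$semi[3])^2 <= 1
    },
    sphere = {
      (cx - organ$center[1])^2 + (cy - organ$center[2])^2 +
        (cz - organ$center[3])^2 <= organ$r^2
    },
    shell = {
      d2 <- (cx - organ$center[1])^2 + (cy - organ$center[2])^2 +
        (cz - organ$center[3])^2
      d2 <= organ$r_outer^2 & d2 >= organ$r_inner^2
    },
    cylinder = {
      ((cx - organ$center[1]) / organ$semi[1])^2 +
        ((cy - organ$center[2]) / organ$semi[2])^2 <= 1 &
        cz >= organ$zlim[1] & cz <= organ$zlim[2]
    },
    stop("unknown organ shape: ", organ$shape)
  )
}

#' Build the synthetic voxelized phantom
#'
#' Rasterizes a body specification onto an isotropic voxel grid centered at
#' the scanner origin (voxel-center inclusion), assigns ground-truth 511 keV
#' attenuation coefficients and activity concentrations from the tissue table
#' (with per-organ activity overrides), optionally embeds lesions, and scales
#' the activity globally so the total matches \code{total_activity}.
#'
#' @param body_spec list of organs, see \code{\link{default_body_spec}}.
#' @param voxel_size isotropic voxel size in mm.
#' @param dim integer grid dimensions (nx, ny, nz).
#' @param total_activity target total activity in MBq (voxel sum x voxel
#'   volume); \code{NULL} disables scaling.
#' @param lesions optional lesion catalog applied before activity scaling.
#' @param tissue_table tissue reference, see \code{\link{tissue_mu_table}}.
#' @param seed integer seed recorded with the phantom (construction itself is
#'   deterministic).
#' @return object of class \code{phantom} with label, mu (511 keV, mm^-1) and
#'   activity (kBq/ml) volumes, the grid description, organ map and catalogs.
#' @export
build_phantom <- function(body_spec = default_body_spec(),
                          voxel_size = 4,
                          dim = c(48L, 48L, 180L),
                          total_activity = 21,
                          lesions = NULL,
                          tissue_table = tissue_mu_table(),
                          seed = 1L) {
  dim <- as.integer(dim)
  origin <- -dim * voxel_size / 2
  xc <- origin[1] + (seq_len(dim[1]) - 0.5) * voxel_size
  yc <- origin[2] + (seq_len(dim[2]) - 0.5) * voxel_size
  zc <- origin[3] + (seq_len(dim[3]) - 0.5) * voxel_size
  cx <- array(rep(xc, times = dim[2] * dim[3]), dim)
  cy <- array(rep(rep(yc, each = dim[1]), times = dim[3]), dim)
  cz <- array(rep(zc, each = dim[1] * dim[2]), dim)

  labels <- array(0L, dim)  # 0 = air
  for (k in seq_along(body_spec)) {
    o <- body_spec[[k]]
    m <- organ_mask(o, cx, cy, cz)
    if (!any(m)) stop("organ outside the grid: ", o$name)
    labels[m] <- k
  }
  tiss <- vapply(body_spec, `[[`, "", "tissue")
  act0 <- vapply(body_spec, `[[`, 0, "activity")
  if (!all(tiss %in% rownames(tissue_table)))
    stop("unknown tissue class in body spec")
  mu <- array(0, dim)
  activity <- array(0, dim)
  inb <- labels > 0L
  mu[inb] <- tissue_table[tiss[labels[inb]], "mu_511"]
  activity[inb] <- act0[labels[inb]]

  ph <- structure(list(
    labels = labels, mu = mu, activity = activity,
    voxel_size = voxel_size, dim = dim, origin = origin,
    organs = vapply(body_spec, `[[`, "", "name"),
    organ_tissue = tiss, organ_activity = act0,
    body_spec = body_spec, tissue_table = tissue_table,
    lesions = list(), vois = list(), seed = as.integer(seed),
    total_activity = NA_real_
  ), class = "phantom")
  ph$total_activity <- phantom_total_activity(ph)

  if (!is.null(lesions)) ph <- embed_lesions(ph, lesions)
  if (!is.null(total_activity)) {
    cur <- phantom_total_activity(ph)
    if (cur <= 0) {
      if (total_activity > 0) stop("cannot scale an all-zero activity map")
    } else {
      f <- total_activity / cur
      ph$activity <- ph$activity * f
      ph$organ_activity <- ph$organ_activity * f
      ph$total_activity <- phantom_total_activity(ph)
    }
  }
  ph
}

#' Total phantom activity in MBq
#' @param phantom a \code{phantom}.
#' @return total activity (MBq): voxel sum (kBq/ml) x voxel volume.
#' @export
phantom_total_activity <- function(phantom) {
  sum(phantom$activity) * phantom$voxel_size^3 / 1e6
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d x %d voxels @ %.1f mm, %d organs, %d lesions, %d VOIs\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size,
              length(x$organs), length(x$lesions), length(x$vois)))
  cat(sprintf("  total activity %.3f MBq\n", x$total_activity))
  invisible(x)
}

voxel_centers <- function(phantom) {
  d <- phantom$dim; vs <- phantom$voxel_size; o <- phantom$origin
  list(x = o[1] + (seq_len(d[1]) - 0.5) * vs,
       y = o[2] + (seq_len(d[2]) - 0.5) * vs,
       z = o[3] + (seq_len(d[3]) - 0.5) * vs)
}

sphere_voxels <- function(phantom, center, radius) {
  cc <- voxel_centers(phantom)
  d <- phantom$dim
  ix <- which((cc$x - center[1])^2 <= radius^2)
  iy <- which((cc$y - center[2])^2 <= radius^2)
  iz <- which((cc$z - center[3])^2 <= radius^2)
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  g <- expand.grid(ix = ix, iy = iy, iz = iz)
  r2 <- (cc$x[g$ix] - center[1])^2 + (cc$y[g$iy] - center[2])^2 +
    (cc$z[g$iz] - center[3])^2
  g <- g[r2 <= radius^2, ]
  g$ix + d[1] * (g$iy - 1L) + d[1] * d[2] * (g$iz - 1L)
}

#' Default lesion catalog
#'
#' Twenty-two spherical activity lesions: 5 in the liver, 3 in each lung,
#' 4 pelvic lymph nodes, 4 neck lymph nodes and 3 in the brain, with diameters
#' 8-12 mm and lesion-to-background contrasts 2.4-24.
#'
#' @return data frame with columns x, y, z, diameter, contrast, host.
#' @export
default_lesion_catalog <- function() {
  L <- rbind(
    c(20, -6, -40, 12, 2.4), c(52, 0, -12, 10, 4), c(28, 20, -12, 8, 8),
    c(48, -12, -44, 10, 16), c(36, 10, -56, 8, 24),          # liver
    c(-44, -6, 70, 10, 10), c(-52, -14, 130, 8, 24), c(-36, 6, 150, 12, 4),
    c(44, -6, 70, 10, 6), c(52, -14, 130, 8, 12), c(36, 6, 150, 12, 2.4),
    c(24, -36, -260, 8, 24), c(-24, -36, -260, 10, 16),
    c(30, 30, -236, 8, 8), c(-30, 30, -236, 12, 4),          # pelvic nodes
    c(16, 0, 224, 8, 2.4), c(-16, 0, 224, 8, 6),
    c(14, 24, 224, 10, 12), c(-14, 24, 224, 8, 24),          # neck nodes
    c(16, 12, 280, 10, 2.4), c(-16, -12, 312, 8, 4), c(0, 16, 320, 12, 3)
  )
  data.frame(
    x = L[, 1], y = L[, 2], z = L[, 3], diameter = L[, 4], contrast = L[, 5],
    host = c(rep("liver", 5), rep("lung_left", 3), rep("lung_right", 3),
             rep("body", 4), rep("neck", 4), rep("brain", 3))
  )
}

#' Embed spherical activity lesions in a phantom
#'
#' Sets the activity of every voxel whose center lies inside a lesion sphere
#' to \code{contrast} times the host organ's background concentration.
#' Attenuation is unchanged: the lesions are emission-only. The phantom's
#' total-activity field is updated (no rescaling).
#'
#' @param phantom a \code{phantom}.
#' @param catalog data frame as in \code{\link{default_lesion_catalog}}.
#' @return the phantom with lesions embedded and recorded.
#' @export
embed_lesions <- function(phantom, catalog = default_lesion_catalog()) {
  for (i in seq_len(nrow(catalog))) {
    le <- catalog[i, ]
    host <- match(le$host, phantom$organs)
    if (is.na(host)) stop("unknown host organ: ", le$host)
    vox <- sphere_voxels(phantom, c(le$x, le$y, le$z), le$diameter / 2)
    if (!length(vox)) stop("lesion ", i, " covers no voxel centers")
    if (!all(phantom$labels[vox] == host))
      stop("lesion ", i, " extends outside its host organ (", le$host, ")")
    if (le$contrast <= 1) stop("lesion contrast must exceed 1")
    phantom$activity[vox] <- le$contrast * phantom$organ_activity[host]
    phantom$lesions[[length(phantom$lesions) + 1L]] <- list(
      center = c(le$x, le$y, le$z), diameter = le$diameter,
      contrast = le$contrast, host = le$host, voxels = vox
    )
  }
  phantom$total_activity <- phantom_total_activity(phantom)
  phantom
}

#' Default VOI catalog
#'
#' Twenty-three spherical volumes of interest on the organs evaluated in the
#' quantification analysis (lungs, liver, left-ventricle blood pool, cerebrum,
#' skull bone, spine marrow, hip bone and marrow, bladder, myocardium, soft
#' tissue). Each VOI lies entirely within its organ's label region.
#'
#' @return data frame with columns x, y, z, radius, organ, group.
#' @export
default_voi_catalog <- function() {
  V <- rbind(
    c(-44, -6, 110, 16), c(44, -6, 110, 16),              # lungs
    c(36, 6, -24, 14), c(24, -16, 0, 10),                 # liver
    c(0, -6, 56, 12),                                     # LV blood pool
    c(16, 0, 296, 12), c(-16, 0, 296, 12),                # cerebrum
    c(0, 52, 296, 6), c(0, -52, 296, 6),
    c(-52, 0, 296, 6), c(52, 0, 296, 6),                  # skull bone
    c(-48, 6, -255, 9), c(48, 6, -255, 9),                # hip bone
    c(-48, 6, -310, 10), c(48, 6, -310, 10),              # hip marrow
    c(0, -16, -300, 14),                                  # bladder
    c(-50, 20, -120, 12), c(50, 20, -120, 12),
    c(-40, -30, -160, 12), c(40, -30, -160, 12),
    c(0, -35, -60, 10), c(0, -20, -180, 14),
    c(0, 0, 224, 8)                                       # soft tissue
  )
  data.frame(
    x = V[, 1], y = V[, 2], z = V[, 3], radius = V[, 4],
    organ = c("lung_left", "lung_right", "liver", "liver", "lv_blood",
              "brain", "brain", "skull", "skull", "skull", "skull",
              "hip_left", "hip_right", "hip_marrow_left",
              "hip_marrow_right", "bladder",
              "body", "body", "body", "body", "body", "body", "neck"),
    group = c("lung", "lung", "liver", "liver", "lv_blood_pool",
              "cerebrum", "cerebrum", "skull_bone", "skull_bone",
              "skull_bone", "skull_bone", "hip_bone", "hip_bone",
              "hip_marrow", "hip_marrow", "bladder",
              rep("soft_tissue", 7))
  )
}

#' Attach volumes of interest to a phantom
#'
#' Validates that every VOI sphere lies entirely within its organ's label
#' region (voxel-center inclusion) and records the VOI voxel sets.
#'
#' @param phantom a \code{phantom}.
#' @param catalog data frame as in \code{\link{default_voi_catalog}}.
#' @return the phantom with \code{vois} populated.
#' @export
define_vois <- function(phantom, catalog = default_voi_catalog()) {
  phantom$vois <- list()
  for (i in seq_len(nrow(catalog))) {
    v <- catalog[i, ]
    k <- match(v$organ, phantom$organs)
    if (is.na(k)) stop("VOI ", i, ": unknown organ ", v$organ)
    vox <- sphere_voxels(phantom, c(v$x, v$y, v$z), v$radius)
    if (!length(vox)) stop("VOI ", i, " covers no voxel centers")
    if (!all(phantom$labels[vox] == k))
      stop("VOI ", i, " (", v$organ, ") crosses its organ boundary")
    phantom$vois[[i]] <- list(center = c(v$x, v$y, v$z), radius = v$radius,
                              organ = v$organ, group = v$group, voxels = vox)
  }
  phantom
}

#' The default study phantom
#'
#' Convenience constructor: default torso body, 22 lesions, 23 VOIs, activity
#' scaled to 21 MBq total.
#'
#' @param seed integer seed recorded with the phantom.
#' @param dim,voxel_size grid parameters.
#' @return a \code{phantom}.
#' @export
default_phantom <- function(seed = 1L, dim = c(48L, 48L, 180L), voxel_size = 4) {
  ph <- build_phantom(dim = dim, voxel_size = voxel_size,
                      lesions = default_lesion_catalog(), seed = seed)
  define_vois(ph)
}

#' Export / import phantom volumes
#'
#' Writes the label, attenuation and activity volumes as NIfTI files plus a
#' JSON catalog of organs, lesions and VOIs; \code{read_phantom} restores the
#' phantom from such a directory.
#'
#' @param phantom a \code{phantom}.
#' @param dir output directory (created if needed).
#' @return \code{write_phantom}: the directory, invisibly;
#'   \code{read_phantom}: a \code{phantom}.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$voxel_size
  for (nm in c("labels", "mu", "activity")) {
    img <- RNifti::asNifti(phantom[[nm]], pixdim = c(vs, vs, vs))
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  meta <- phantom[c("voxel_size", "dim", "origin", "organs", "organ_tissue",
                    "organ_activity", "seed", "total_activity")]
  meta$lesions <- lapply(phantom$lesions, function(l) l[names(l) != "voxels"])
  meta$vois <- lapply(phantom$vois, function(v) v[names(v) != "voxels"])
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  dm <- as.integer(meta$dim)
  vol <- function(nm) array(as.numeric(RNifti::readNifti(
    file.path(dir, paste0(nm, ".nii.gz")))), dm)
  ph <- structure(list(
    labels = array(as.integer(vol("labels")), dm),
    mu = vol("mu"), activity = vol("activity"),
    voxel_size = meta$voxel_size, dim = dm, origin = as.numeric(meta$origin),
    organs = meta$organs, organ_tissue = meta$organ_tissue,
    organ_activity = meta$organ_activity,
    body_spec = NULL, tissue_table = tissue_mu_table(),
    lesions = list(), vois = list(), seed = as.integer(meta$seed),
    total_activity = meta$total_activity
  ), class = "phantom")
  if (length(meta$lesions)) {
    for (i in seq_along(meta$lesions)) {
      l <- meta$lesions[[i]]
      l$voxels <- sphere_voxels(ph, as.numeric(l$center), l$diameter / 2)
      ph$lesions[[i]] <- l
    }
  }
  if (length(meta$vois)) {
    for (i in seq_along(meta$vois)) {
      v <- meta$vois[[i]]
      v$voxels <- sphere_voxels(ph, as.numeric(v$center), v$radius)
      ph$vois[[i]] <- v
    }
  }
  ph
}
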