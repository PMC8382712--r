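# Per-nucleus volumetric and intensity measurement, and the
# post-segmentation volume gate.

#' Principal axes of a voxel region
#'
#' Eigen-decomposition of the second central moments of the voxel
#' coordinates (micrometres). Axis lengths follow the convention of the
#' ellipsoid with the same normalized second central moments as the region:
#' a solid ellipsoid of semi-axis a has moment a^2/5, so the full axis
#' length along eigenvalue lambda is 2*sqrt(5*lambda). A voxel-smearing
#' term spacing^2/12 per axis is included, as in common region-property
#' implementations.
#'
#' @param coords numeric matrix, one row per voxel, columns (z, y, x) in
#'   micrometres (voxel centres).
#' @param spacing voxel spacing (dz, dy, dx) used for the smearing term;
#'   use c(0, 0, 0) for exact point clouds.
#' @return list with `lengths` (p_major >= p_intermediate >= p_minor, um)
#'   and `vectors` (3x3 matrix; columns e1, e2, e3 are unit vectors in
#'   (z, y, x) components, sign-fixed so the first nonzero component is
#'   positive).
#' @export
principal_axes <- function(coords, spacing = c(0, 0, 0)) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("need at least 4 voxels for principal axes")
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  C0 <- crossprod(cc) / nrow(coords)
  if (min(eigen(C0, symmetric = TRUE, only.values = TRUE)$values) < 1e-12 &&
      all(spacing == 0))
    stop("degenerate (coplanar) region: principal axes undefined")
  C <- C0 + diag(as.numeric(spacing)^2 / 12)
  ev <- eigen(C, symmetric = TRUE)
  vec <- ev$vectors
  for (j in 1:3) {
    nz <- which(abs(vec[, j]) > 1e-12)[1]
    if (!is.na(nz) && vec[nz, j] < 0) vec[, j] <- -vec[, j]
  }
  list(lengths = 2 * sqrt(5 * pmax(ev$values, 0)), vectors = vec)
}

#' Sphericity from volume and surface area
#'
#' `pi^(1/3) * (6 V)^(2/3) / A`; 1 for a perfect sphere, (pi/6)^(1/3) for
#' a cube.
#'
#' @param volume cubic micrometres, > 0.
#' @param surface_area square micrometres, > 0.
#' @return Dimensionless sphericity.
#' @export
sphericity <- function(volume, surface_area) {
  if (any(volume <= 0) || any(surface_area <= 0))
    stop("volume and surface_area must be positive")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

#' Iso-surface area of a binary voxel mask
#'
#' The mask is lightly smoothed (Gaussian, `smooth_sigma` voxels) and the
#' area of the 0.5 iso-surface is integrated by marching tetrahedra. The
#' smoothing removes the voxelization staircase so that digital spheres
#' measure close to their analytic area (a raw binary iso-surface
#' overestimates it, which would break the sphericity <= 1 contract).
#'
#' @param mask 3D logical/0-1 array, dim (z, y, x).
#' @param spacing voxel spacing (dz, dy, dx), micrometres.
#' @param smooth_sigma Gaussian bandwidth in voxels.
#' @return Surface area in square micrometres.
#' @export
surface_area_mesh <- function(mask, spacing, smooth_sigma = 1) {
  d <- dim(mask)
  pad <- as.integer(ceiling(3 * smooth_sigma) + 1)
  dp <- d + 2L * pad
  vol <- array(0, dim = dp)
  vol[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- as.numeric(mask)
  if (smooth_sigma > 0) {
    k <- gaussian_kernel(smooth_sigma)
    for (axis in 0:2) vol <- cpp_convolve_axis(vol, dp, k, axis)
  }
  cpp_surface_area(vol, dp, as.numeric(spacing), 0.5)
}

#' Measure per-nucleus volumetric and intensity features
#'
#' For every label: voxel-count volume, marching-tetrahedra surface area,
#' centroid (micrometres), extent (volume / axis-aligned bounding box
#' volume), principal axis lengths and orientations, sphericity, and the
#' per-channel integrated intensity (sum of raw voxel values under the
#' label; intensities should be measured on the raw interpolated stack,
#' not the smoothed one, since smoothing redistributes intensity across
#' nucleus boundaries).
#'
#' @param labels a [label_volume].
#' @param channels named list of [voxel_grid]s sharing the labels'
#'   geometry (or a single grid).
#' @param spheroid_id identifier recorded in every row.
#' @return data.frame with one row per label: `label`, `spheroid_id`,
#'   `centroid_z/y/x` and `depth` (um), `volume` (um^3), `surface_area`
#'   (um^2), `extent`, `p_major`, `p_intermediate`, `p_minor` (um),
#'   `e1_z ... e3_x` (unit orientation vectors), `sphericity`, and one
#'   `itg_<channel>` column per channel.
#' @export
measure_nuclei <- function(labels, channels, spheroid_id = "spheroid") {
  stopifnot(inherits(labels, "label_volume"))
  if (inherits(channels, "voxel_grid")) {
    channels <- setNames(list(channels), channels$channel)
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  d <- dim(labels$labels)
  for (nm in names(channels)) {
    g <- channels[[nm]]
    stopifnot_same_geometry(d, labels$spacing, dim(g$data), g$spacing,
                            sprintf("channel '%s'", nm))
  }
  nlab <- max(labels$labels)
  if (nlab == 0L) stop("label volume contains no objects")
  st <- cpp_label_stats(labels$labels, d, labels$spacing,
                        lapply(channels, function(g) g$data))
  mom <- st$moments; bbox <- st$bbox; inten <- st$intensity
  sp <- labels$spacing
  voxvol <- prod(sp)
  n <- mom[, 1]
  present <- n > 0
  cz <- mom[, 2] / n; cy <- mom[, 3] / n; cx <- mom[, 4] / n
  volume <- n * voxvol
  bb_vox <- (bbox[, 2] - bbox[, 1] + 1) * (bbox[, 4] - bbox[, 3] + 1) *
    (bbox[, 6] - bbox[, 5] + 1)
  extent <- n / bb_vox
  p_len <- matrix(NA_real_, nlab, 3)
  evec <- matrix(NA_real_, nlab, 9)
  area <- rep(NA_real_, nlab)
  for (l in seq_len(nlab)) {
    if (!present[l]) next
    # covariance from accumulated moments + voxel smearing term
    C <- matrix(c(mom[l, 5] / n[l] - cz[l]^2, mom[l, 8] / n[l] - cz[l] * cy[l], mom[l, 9] / n[l] - cz[l] * cx[l],
                  mom[l, 8] / n[l] - cz[l] * cy[l], mom[l, 6] / n[l] - cy[l]^2, mom[l, 10] / n[l] - cy[l] * cx[l],
                  mom[l, 9] / n[l] - cz[l] * cx[l], mom[l, 10] / n[l] - cy[l] * cx[l], mom[l, 7] / n[l] - cx[l]^2),
                3, 3) + diag(sp^2 / 12)
    ev <- eigen(C, symmetric = TRUE)
    v <- ev$vectors
    for (j in 1:3) {
      nz <- which(abs(v[, j]) > 1e-12)[1]
      if (!is.na(nz) && v[nz, j] < 0) v[, j] <- -v[, j]
    }
    p_len[l, ] <- 2 * sqrt(5 * pmax(ev$values, 0))
    evec[l, ] <- as.numeric(v)
    sub <- labels$labels[(bbox[l, 1] + 1):(bbox[l, 2] + 1),
                         (bbox[l, 3] + 1):(bbox[l, 4] + 1),
                         (bbox[l, 5] + 1):(bbox[l, 6] + 1), drop = FALSE]
    area[l] <- surface_area_mesh(array(sub == l, dim = dim(sub)), sp)
  }
  rec <- data.frame(label = seq_len(nlab),
                    spheroid_id = spheroid_id,
                    centroid_z = cz, centroid_y = cy, centroid_x = cx,
                    depth = cz,
                    volume = volume,
                    surface_area = area,
                    extent = extent,
                    p_major = p_len[, 1], p_intermediate = p_len[, 2],
                    p_minor = p_len[, 3],
                    e1_z = evec[, 1], e1_y = evec[, 2], e1_x = evec[, 3],
                    e2_z = evec[, 4], e2_y = evec[, 5], e2_x = evec[, 6],
                    e3_z = evec[, 7], e3_y = evec[, 8], e3_x = evec[, 9],
                    sphericity = sphericity(pmax(volume, 1e-12), pmax(area, 1e-12)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(channels)) {
    rec[[paste0("itg_", names(channels)[k])]] <- inten[, k]
  }
  rec[present, , drop = FALSE]
}

#' Volume gate
#'
#' Keeps nuclei whose volume lies within `[low_fraction, high_fraction]`
#' times the median volume (inclusive bounds), discarding unresolved
#' clusters, polyploid giants and debris. Both partitions are returned;
#' the discarded records remain available for, e.g., polyploidy studies.
#'
#' @param records non-empty data.frame with a `volume` column.
#' @param low_fraction lower bound as fraction of the median (0.6 = 60%).
#' @param high_fraction upper bound as fraction of the median (1.8 = 180%).
#' @return list with `kept` and `discarded` data.frames.
#' @export
volume_gate <- function(records, low_fraction = 0.6, high_fraction = 1.8) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  med <- median(records$volume)
  keep <- records$volume >= low_fraction * med &
    records$volume <= high_fraction * med
  list(kept = records[keep, , drop = FALSE],
       discarded = records[!keep, , drop = FALSE])
}
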