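# Spheroid surface approximation, nucleus-perimeter distances, concentric
# layers, nuclear alignment angles, axis ratios and radial trends.

#' Approximate the spheroid surface by morphological closing
#'
#' The union of all nucleus voxels is closed with a ball of
#' `closing_radius` (dilation then erosion, both via exact Euclidean
#' distance transforms), interior holes are filled and the largest
#' connected component is kept. The spheroid center is the centroid of the
#' closed mask, which is robust to uneven nuclear density.
#'
#' @param labels a non-empty [label_volume].
#' @param closing_radius ball radius in micrometres (default 10, about the
#'   inter-nuclear gap scale).
#' @return A `spheroid_geometry`: list with `mask` (logical array),
#'   `spacing`, and `center` (z, y, x in micrometres).
#' @export
approximate_surface <- function(labels, closing_radius = 10) {
  stopifnot(inherits(labels, "label_volume"))
  if (max(labels$labels) == 0L) stop("empty label volume")
  d <- dim(labels$labels)
  fg <- labels$labels > 0L
  # dilation: voxels within closing_radius of the foreground
  dist_to_fg <- cpp_edt(!fg, d, labels$spacing)
  dil <- dist_to_fg <= closing_radius
  rm(dist_to_fg)
  # erosion of the dilated set by the same ball
  dist_in_dil <- cpp_edt(dil, d, labels$spacing)
  closed <- dist_in_dil >= closing_radius
  closed <- closed | fg                    # closing never removes the input
  rm(dist_in_dil)
  closed <- closed | !cpp_flood_background(closed, d)   # fill holes
  comp <- cpp_label_components(closed, d, 26L)
  nlab <- max(comp)
  if (nlab > 1L) {
    sizes <- tabulate(comp[comp > 0L], nbins = nlab)
    closed <- array(comp == which.max(sizes), dim = d)
  }
  idx <- which(closed)
  co <- arrayInd(idx, d)
  ctr <- (colMeans(co) - 1) * labels$spacing
  structure(list(mask = closed, spacing = labels$spacing, center = ctr),
            class = "spheroid_geometry")
}

#' @export
print.spheroid_geometry <- function(x, ...) {
  cat(sprintf("<spheroid_geometry> %d mask voxels, center (%.1f, %.1f, %.1f) um\n",
              sum(x$mask), x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

centroid_voxel <- function(records, geometry) {
  d <- dim(geometry$mask)
  vz <- pmin(pmax(round(records$centroid_z / geometry$spacing[1]) + 1, 1), d[1])
  vy <- pmin(pmax(round(records$centroid_y / geometry$spacing[2]) + 1, 1), d[2])
  vx <- pmin(pmax(round(records$centroid_x / geometry$spacing[3]) + 1, 1), d[3])
  cbind(vz, vy, vx)
}

#' Filter detached nuclei
#'
#' Nuclei whose centroid falls outside the closed spheroid body are flagged
#' as detached and excluded from spatial statistics.
#'
#' @param records nucleus records with centroid columns.
#' @param geometry a `spheroid_geometry` from [approximate_surface()].
#' @return list with `kept` and `detached` data.frames
#'   (`kept` + `detached` = input).
#' @export
filter_detached <- function(records, geometry) {
  inside <- geometry$mask[centroid_voxel(records, geometry)]
  list(kept = records[inside, , drop = FALSE],
       detached = records[!inside, , drop = FALSE])
}

#' Nucleus-perimeter distances
#'
#' Euclidean distance from each nucleus centroid to the spheroid perimeter
#' (the boundary of the closed mask), sampled from the interior distance
#' transform.
#'
#' @param records filtered nucleus records (all centroids inside the mask).
#' @param geometry a `spheroid_geometry`.
#' @return Numeric vector of distances in micrometres.
#' @export
perimeter_distance <- function(records, geometry) {
  vox <- centroid_voxel(records, geometry)
  inside <- geometry$mask[vox]
  if (!all(inside))
    stop("centroid outside the spheroid mask; run filter_detached() first")
  dist <- cpp_edt(geometry$mask, dim(geometry$mask), geometry$spacing)
  dist[vox]
}

#' Assign concentric layers from perimeter distances
#'
#' Layer i covers distances in the half-open interval
#' `[i * width, (i + 1) * width)`, layer 0 outermost; distances at or
#' beyond `max_depth` are pooled into the innermost layer.
#'
#' @param distances nucleus-perimeter distances (um), >= 0.
#' @param width layer width in micrometres (default 10).
#' @param max_depth pooling depth in micrometres (default 60).
#' @return Integer layer indices (0-based).
#' @export
assign_layers <- function(distances, width = 10, max_depth = 60) {
  if (any(distances < 0)) stop("distances must be >= 0")
  pmin(floor(distances / width), max_depth / width - 1)
}

#' Per-layer S/G2 counts and fractions
#'
#' Treating spheroids individually, counts the S/G2-called nuclei and the
#' S/G2 fraction in each concentric layer, then aggregates across spheroids
#' as mean and standard deviation. Layers containing no cells in a spheroid
#' get an `NaN` fraction and are excluded from the across-spheroid mean
#' (deep layers hold few cells, making fractions volatile).
#'
#' @param calls per-nucleus class calls (`"SG2"` = positive).
#' @param layers aligned integer layer indices from [assign_layers()].
#' @param spheroid_id aligned spheroid identifiers.
#' @param n_layers number of layers to report (default 6: 0-60 um by 10).
#' @return list with `per_spheroid` (long data.frame: spheroid_id, layer,
#'   n, sg2_count, sg2_fraction) and `summary` (per layer: mean/sd of count
#'   and fraction across spheroids, with `n_spheroids` contributing).
#' @export
layer_stats <- function(calls, layers, spheroid_id, n_layers = 6) {
  stopifnot(length(calls) == length(layers),
            length(calls) == length(spheroid_id))
  per <- NULL
  for (sph in unique(spheroid_id)) {
    sel <- spheroid_id == sph
    for (l in 0:(n_layers - 1)) {
      in_layer <- sel & layers == l
      n <- sum(in_layer)
      sg2 <- sum(calls[in_layer] == "SG2")
      per <- rbind(per, data.frame(spheroid_id = sph, layer = l, n = n,
                                   sg2_count = sg2,
                                   sg2_fraction = if (n > 0) sg2 / n else NaN))
    }
  }
  agg <- do.call(rbind, lapply(0:(n_layers - 1), function(l) {
    rows <- per[per$layer == l, ]
    ok <- is.finite(rows$sg2_fraction)
    data.frame(layer = l,
               count_mean = mean(rows$sg2_count), count_sd = sd(rows$sg2_count),
               fraction_mean = if (any(ok)) mean(rows$sg2_fraction[ok]) else NaN,
               fraction_sd = if (sum(ok) > 1) sd(rows$sg2_fraction[ok]) else NaN,
               n_spheroids = sum(ok))
  }))
  list(per_spheroid = per, summary = agg)
}

#' Nuclear alignment angle
#'
#' The angle between the spheroid-center-to-nucleus vector and the plane
#' spanned by the nucleus's major (e1) and intermediate (e2) principal
#' axes, computed as `asin(|r_hat . e3_hat|)` with e3 the minor axis
#' (numerically stable near 0 and 90 degrees). 0 deg = nucleus aligned
#' with the radius (radial), 90 deg = major axis perpendicular to the
#' radius (tangential, the minor axis pointing along the radius).
#'
#' @param e3 minor-axis unit vector(s): length-3 vector or n x 3 matrix in
#'   (z, y, x) components.
#' @param r_center center-to-nucleus vector(s), same shape; must be
#'   nonzero.
#' @return Angle(s) in degrees, in `[0, 90]`.
#' @export
alignment_angle <- function(e3, r_center) {
  e3 <- matrix(e3, ncol = 3)
  r <- matrix(r_center, ncol = 3)
  rn <- sqrt(rowSums(r^2))
  if (any(rn < 1e-12)) stop("nucleus centroid coincides with the spheroid center")
  en <- sqrt(rowSums(e3^2))
  dt <- abs(rowSums(e3 * r)) / (rn * en)
  asin(pmin(dt, 1)) * 180 / pi
}

#' Alignment angles for a record table
#'
#' @param records nucleus records with centroid and `e3_*` columns.
#' @param center spheroid center (z, y, x) in micrometres.
#' @return Angles in degrees, one per record.
#' @export
record_alignment_angle <- function(records, center) {
  e3 <- as.matrix(records[, c("e3_z", "e3_y", "e3_x")])
  r <- cbind(records$centroid_z - center[1],
             records$centroid_y - center[2],
             records$centroid_x - center[3])
  alignment_angle(e3, r)
}

#' z alignment angle
#'
#' The angle between the microscope z-axis and the plane spanned by the
#' major and intermediate principal axes — the construction of
#' [alignment_angle()] with the z unit vector in place of the
#' center-to-nucleus vector. Used to quantify axial (point-spread)
#' elongation artefacts: nuclei seen at different z alignment angles
#' present different axes to the poorer axial resolution.
#'
#' @param e3 minor-axis unit vector(s), (z, y, x) components.
#' @return Angle(s) in degrees, in `[0, 90]`.
#' @export
z_alignment_angle <- function(e3) {
  e3 <- matrix(e3, ncol = 3)
  en <- sqrt(rowSums(e3^2))
  asin(pmin(abs(e3[, 1]) / en, 1)) * 180 / pi
}

#' Nuclear axis ratios
#'
#' @param records records with `p_major`, `p_intermediate`, `p_minor`.
#' @return data.frame with `major_minor` (p_major / p_minor) and
#'   `major_intermediate` (p_major / p_intermediate), both >= 1.
#' @export
axis_ratios <- function(records) {
  data.frame(major_minor = records$p_major / records$p_minor,
             major_intermediate = records$p_major / records$p_intermediate)
}

#' Radial trend of a per-nucleus quantity
#'
#' Bins values into half-open concentric distance bins and reports a
#' central value with dispersion per bin: mean with standard deviation, or
#' median with median absolute deviation.
#'
#' @param values per-nucleus values.
#' @param distances aligned nucleus-perimeter distances (um).
#' @param bin bin width in micrometres (default 5).
#' @param stat `"mean"` or `"median"`.
#' @return data.frame with `bin_lo`, `bin_mid`, `n`, `center`,
#'   `dispersion` and `sparse` (TRUE for bins with fewer than 3 nuclei).
#' @export
radial_trend <- function(values, distances, bin = 5, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(length(values) == length(distances))
  b <- floor(distances / bin)
  out <- do.call(rbind, lapply(sort(unique(b)), function(k) {
    v <- values[b == k]
    data.frame(bin_lo = k * bin, bin_mid = (k + 0.5) * bin, n = length(v),
               center = if (stat == "mean") mean(v) else median(v),
               dispersion = if (stat == "mean") sd(v) else mad(v),
               sparse = length(v) < 3)
  }))
  rownames(out) <- NULL
  out
}

#' Fit the axial elongation artefact
#'
#' Least-squares fit of each principal-axis length against the z alignment
#' angle; the slope, expressed as the length difference between a nucleus
#' at 0 deg and one at 90 deg, quantifies how much the poorer axial
#' resolution stretches apparent nuclear axes.
#'
#' @param records >= 30 nucleus records with axis lengths and `e3_*`
#'   orientation columns; a warning is issued if the orientations span
#'   less than 30 degrees.
#' @return data.frame with one row per axis (`p_major`, `p_intermediate`,
#'   `p_minor`): `intercept` (um at 0 deg), `slope` (um per degree) and
#'   `difference_0_90` (um; intercept-to-90-degree change, negative when
#'   lengths shrink with angle).
#' @export
fit_z_artifact <- function(records) {
  if (nrow(records) < 30) stop("need at least 30 records to fit the z artefact")
  ang <- z_alignment_angle(as.matrix(records[, c("e3_z", "e3_y", "e3_x")]))
  if (diff(range(ang)) < 30)
    warning("orientation spread below 30 degrees; artefact fit is poorly constrained")
  do.call(rbind, lapply(c("p_major", "p_intermediate", "p_minor"), function(axis) {
    fit <- lm(records[[axis]] ~ ang)
    data.frame(axis = axis, intercept = as.numeric(coef(fit)[1]),
               slope = as.numeric(coef(fit)[2]),
               difference_0_90 = as.numeric(coef(fit)[2]) * 90)
  }))
}
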