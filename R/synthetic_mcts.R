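# Ground-truthed synthetic spheroid phantoms.
#
# The image generator emulates what the analysis assumes about a
# DNA-stained, cleared spheroid confocal stack: a spherical aggregate of
# near-touching ellipsoidal nuclei, stoichiometric DNA intensity (2N at
# one unit, 4N at two, S in between), linear depth attenuation,
# anisotropic voxels, optical blur and sensor noise — with exported truth
# labels and a per-nucleus truth table. A statistical twin
# (simulate_records) produces the same per-nucleus quantities without
# rasterizing images, for cohort-scale classifier experiments.

#' Phantom specification
#'
#' Defaults mirror the imaging conditions the analysis targets: a
#' 140 um diameter spheroid of ~300 nuclei with principal axis lengths
#' 16.3 / 11.8 / 8.2 um, voxels 0.4393 um lateral and 0.9 um axial, a 2N
#' G1 majority with an S/G2 minority, and linear depth attenuation.
#'
#' @param spheroid_radius um (default 70: 140 um diameter).
#' @param n_nuclei number of nuclei (default 300).
#' @param nucleus_axes_mean,nucleus_axes_sd full principal-axis lengths
#'   (major, intermediate, minor), um. The default sds are the intrinsic
#'   spreads that reproduce measured spreads of about (2.3, 1.4, 1.2) um
#'   once the cell-cycle volume coupling and measurement noise are added
#'   on top (a population's printed dispersion already contains both).
#' @param orientation_mode `"isotropic"` or `"tangential"`.
#' @param tangential_strength 0..1 blend toward perfect tangential
#'   alignment (minor axis radial) when `orientation_mode = "tangential"`.
#' @param radial_volume_gradient fractional volume decrease per um of
#'   distance from the surface (0 = no gradient).
#' @param g1_fraction,g1s_fraction,sg2_fraction cell-cycle class
#'   probabilities (sum to 1); defaults follow an ~81/7/12 split.
#' @param sg2_g2_fraction fraction of S/G2 cells that are 4N (content
#'   exactly 2); the rest are S cells.
#' @param s_content_range DNA content range for S cells (uniform).
#' @param volume_content_coupling exponent kappa in volume ~ content^kappa
#'   (1 = nuclear volume doubles through S phase).
#' @param intensity_per_content integrated DNA-stain intensity per content
#'   unit (arbitrary fluorescence units).
#' @param reporter_intensity mean integrated reporter (RFP/GFP) intensity
#'   of a positive channel.
#' @param attenuation_slope fractional intensity loss per um of imaging
#'   depth.
#' @param transfection_rate probability a nucleus carries the FUCCI
#'   reporters.
#' @param noise_sd additive Gaussian read noise (intensity units). The
#'   default 0 models photon-counting PMT acquisition, where read noise
#'   is negligible and empty background stays exactly dark; note that any
#'   appreciable additive noise on a zero background defeats a plain
#'   local-mean threshold (about half of pure-noise voxels exceed their
#'   own mean), which is what the threshold offset parameter of the
#'   segmentation is for.
#' @param poisson_noise apply Poisson shot noise (voxel intensities are
#'   treated as expected photon counts); the default, matching
#'   photon-limited confocal acquisition.
#' @param blur_sigma optical blur Gaussian sigma (z, y, x), um; the default
#'   approximates the diffraction-limited point spread of a 63x/1.40 oil
#'   objective with a 0.9 um pinhole section.
#' @param z_stretch axial elongation factor applied to every nucleus
#'   (models the apparent stretching from poorer axial resolution;
#'   1 = none).
#' @param spacing voxel spacing (dz, dy, dx), um.
#' @param margin extra empty border around the spheroid, um.
#' @param packing_factor two nuclei are accepted when their centers are at
#'   least this fraction of the summed directional support radii apart;
#'   0.9 (a 10 percent shrink) gives realistic near-touching packings that
#'   stress the watershed, values above 1 force visible gaps.
#' @param seed integer seed; every random draw derives from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(spheroid_radius = 70,
                         n_nuclei = 300,
                         nucleus_axes_mean = c(16.3, 11.8, 8.2),
                         nucleus_axes_sd = c(2.0, 1.1, 1.0),
                         orientation_mode = c("isotropic", "tangential"),
                         tangential_strength = 0.8,
                         radial_volume_gradient = 0,
                         g1_fraction = 0.813,
                         g1s_fraction = 0.070,
                         sg2_fraction = 0.117,
                         sg2_g2_fraction = 0.5,
                         s_content_range = c(1.1, 1.9),
                         volume_content_coupling = 1,
                         intensity_per_content = 2e6,
                         reporter_intensity = 1e6,
                         attenuation_slope = 0.004,
                         transfection_rate = 0.25,
                         noise_sd = 0,
                         poisson_noise = TRUE,
                         blur_sigma = c(0.4, 0.15, 0.15),
                         z_stretch = 1,
                         spacing = c(0.9, 0.4393, 0.4393),
                         margin = 6,
                         packing_factor = 0.9,
                         seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  spec <- as.list(environment())
  fr <- c(g1_fraction, g1s_fraction, sg2_fraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-6)
    stop("class fractions must be nonnegative and sum to 1")
  if (spheroid_radius <= 0 || n_nuclei <= 0)
    stop("radius and nucleus count must be positive")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> R %.0f um, %d nuclei, %s orientation, seed %d\n",
              x$spheroid_radius, x$n_nuclei, x$orientation_mode, x$seed))
  invisible(x)
}

#' Write / read a phantom spec as YAML
#'
#' @param spec a [phantom_spec].
#' @param path YAML file path.
#' @return `write_phantom_spec` returns `path`; `read_phantom_spec`
#'   returns the reconstructed [phantom_spec].
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(phantom_spec, vals)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

# Haar-uniform random rotation matrix (QR with sign fix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

unitize <- function(v) v / sqrt(sum(v^2))

# Rotation whose third column (minor axis) blends toward `radial`.
oriented_rotation <- function(mode, strength, radial) {
  R <- random_rotation()
  if (mode == "tangential") {
    e3 <- unitize((1 - strength) * R[, 3] + strength * unitize(radial) *
                    sign(sum(R[, 3] * radial) + 1e-12))
    # complete an orthonormal frame with a random in-plane rotation
    u <- R[, 1] - sum(R[, 1] * e3) * e3
    if (sqrt(sum(u^2)) < 1e-6) u <- c(e3[2], -e3[1], 0)
    e1 <- unitize(u)
    e2 <- unitize(c(e3[2] * e1[3] - e3[3] * e1[2],
                    e3[3] * e1[1] - e3[1] * e1[3],
                    e3[1] * e1[2] - e3[2] * e1[1]))
    R <- cbind(e1, e2, e3)
  }
  R
}

sample_truth <- function(spec) {
  n <- spec$n_nuclei
  R0 <- spec$spheroid_radius
  cls <- sample(c("G1", "G1S", "SG2"), n, replace = TRUE,
                prob = c(spec$g1_fraction, spec$g1s_fraction, spec$sg2_fraction))
  content <- numeric(n)
  content[cls == "G1"] <- 1
  content[cls == "G1S"] <- runif(sum(cls == "G1S"), 1.0, 1.1)
  is_sg2 <- cls == "SG2"
  g2 <- is_sg2 & (runif(n) < spec$sg2_g2_fraction)
  content[g2] <- 2
  s_cells <- is_sg2 & !g2
  content[s_cells] <- runif(sum(s_cells), spec$s_content_range[1], spec$s_content_range[2])
  transfected <- runif(n) < spec$transfection_rate

  # nuclear shape: base axes, scaled by DNA content and the radial gradient
  semi <- matrix(0, n, 3)
  centers <- matrix(0, n, 3)           # (z, y, x) um relative to spheroid center
  rot <- vector("list", n)
  shape <- matrix(0, n, 9)             # Sigma = R diag(semi^2) R', row-major-ish
  placed <- 0
  attempts <- 0
  max_attempts <- 300 * n
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1
    i <- placed + 1
    ax <- pmax(rnorm(3, spec$nucleus_axes_mean, spec$nucleus_axes_sd),
               0.3 * spec$nucleus_axes_mean)
    ax <- sort(ax, decreasing = TRUE) / 2          # semi-axes
    ax <- ax * content[i]^(spec$volume_content_coupling / 3)
    # uniform position in the admissible ball
    ctr <- c(0, 0, 0)
    repeat {
      ctr <- runif(3, -R0, R0)
      if (sum(ctr^2) <= R0^2) break
    }
    depth_from_surface <- R0 - sqrt(sum(ctr^2))
    g <- max(1 - spec$radial_volume_gradient * depth_from_surface, 0.2)
    ax <- ax * g^(1 / 3)
    Rm <- oriented_rotation(spec$orientation_mode, spec$tangential_strength, ctr)
    Sig <- Rm %*% diag(ax^2) %*% t(Rm)
    # keep the whole nucleus inside the spheroid
    rhat <- if (sqrt(sum(ctr^2)) > 1e-9) unitize(ctr) else c(0, 0, 1)
    s_out <- sqrt(drop(rhat %*% Sig %*% rhat))
    if (sqrt(sum(ctr^2)) + s_out > R0) next
    # overlap check on directional support radii, shrunk by 10%
    ok <- TRUE
    if (placed > 0) {
      dd <- sweep(centers[seq_len(placed), , drop = FALSE], 2, ctr, "-")
      dn <- sqrt(rowSums(dd^2))
      dh <- dd / pmax(dn, 1e-12)
      Sh <- shape[seq_len(placed), , drop = FALSE]
      qj <- Sh[, 1] * dh[, 1]^2 + Sh[, 5] * dh[, 2]^2 + Sh[, 9] * dh[, 3]^2 +
        2 * (Sh[, 2] * dh[, 1] * dh[, 2] + Sh[, 3] * dh[, 1] * dh[, 3] +
               Sh[, 6] * dh[, 2] * dh[, 3])
      qi <- colSums((Sig %*% t(dh)) * t(dh))
      if (any(dn < spec$packing_factor * (sqrt(qi) + sqrt(qj)))) ok <- FALSE
    }
    if (!ok) next
    placed <- i
    semi[i, ] <- ax
    centers[i, ] <- ctr
    rot[[i]] <- Rm
    shape[i, ] <- as.numeric(Sig)
  }
  if (placed < n)
    stop(sprintf("phantom packing failed: placed %d of %d nuclei", placed, n))
  list(class = cls, content = content, transfected = transfected,
       semi = semi, centers = centers, rot = rot, shape = shape)
}

truth_table <- function(spec, tr) {
  n <- spec$n_nuclei
  S <- diag(c(spec$z_stretch, 1, 1))
  eff_len <- matrix(0, n, 3)
  eff_vec <- matrix(0, n, 9)
  for (i in seq_len(n)) {
    Sig_eff <- S %*% matrix(tr$shape[i, ], 3, 3) %*% S
    ev <- eigen(Sig_eff, symmetric = TRUE)
    v <- ev$vectors
    for (j in 1:3) {
      nz <- which(abs(v[, j]) > 1e-12)[1]
      if (!is.na(nz) && v[nz, j] < 0) v[, j] <- -v[, j]
    }
    eff_len[i, ] <- 2 * sqrt(pmax(ev$values, 0))
    eff_vec[i, ] <- as.numeric(v)
  }
  R0 <- spec$spheroid_radius
  data.frame(label = seq_len(n),
             spheroid_id = sprintf("phantom_seed%d", spec$seed),
             class = tr$class,
             content = tr$content,
             transfected = tr$transfected,
             centroid_z = tr$centers[, 1] + R0 + spec$margin,
             centroid_y = tr$centers[, 2] + R0 + spec$margin,
             centroid_x = tr$centers[, 3] + R0 + spec$margin,
             depth = tr$centers[, 1] + R0 + spec$margin,
             volume = 4 / 3 * pi * apply(tr$semi, 1, prod) * spec$z_stretch,
             p_major = eff_len[, 1], p_intermediate = eff_len[, 2],
             p_minor = eff_len[, 3],
             e1_z = eff_vec[, 1], e1_y = eff_vec[, 2], e1_x = eff_vec[, 3],
             e2_z = eff_vec[, 4], e2_y = eff_vec[, 5], e2_x = eff_vec[, 6],
             e3_z = eff_vec[, 7], e3_y = eff_vec[, 8], e3_x = eff_vec[, 9],
             stringsAsFactors = FALSE)
}

rasterize_truth <- function(spec, tr, spacing) {
  ext <- 2 * (spec$spheroid_radius + spec$margin)
  dims <- as.integer(ceiling(ext / spacing) + 1)
  n <- spec$n_nuclei
  S <- diag(c(spec$z_stretch, 1, 1))
  quad <- matrix(0, n, 9)
  radius <- numeric(n)
  for (i in seq_len(n)) {
    Rm <- tr$rot[[i]]
    M <- Rm %*% diag(1 / tr$semi[i, ]^2) %*% t(Rm)
    Si <- solve(S)
    quad[i, ] <- as.numeric(Si %*% M %*% Si)
    radius[i] <- max(tr$semi[i, ]) * spec$z_stretch
  }
  ctr_um <- sweep(tr$centers, 2, c(spec$spheroid_radius + spec$margin), "+")
  lab <- cpp_rasterize_ellipsoids(dims, spacing, ctr_um, quad, radius)
  label_volume(lab, spacing)
}

#' Generate a synthetic spheroid phantom
#'
#' Places non-overlapping ellipsoidal nuclei inside a sphere by dart
#' throwing (overlap rejected on directional support radii shrunk by 10
#' percent, so near-touching packings stress the watershed), renders a
#' stoichiometric DNA channel (integrated intensity proportional to true
#' DNA content) with linear depth attenuation, optional FUCCI reporter
#' channels, anisotropic Gaussian blur and noise, and returns truth labels
#' plus a per-nucleus truth table. All randomness derives from
#' `spec$seed`; the same spec reproduces bit-identical output.
#'
#' @param spec a [phantom_spec].
#' @param channels which fluorescence channels to render (subset of
#'   `"dapi"`, `"rfp"`, `"gfp"`).
#' @param isotropic_truth also return the truth labels rasterized at
#'   isotropic (lateral) spacing, for voxel-overlap scoring against
#'   segmentations of the interpolated stack.
#' @return list with `channels` (named list of [voxel_grid]s at
#'   acquisition spacing), `truth_labels` ([label_volume], acquisition
#'   spacing), `truth_labels_iso` (isotropic spacing, if requested),
#'   `truth` (data.frame truth table) and `spec`.
#' @export
generate_phantom <- function(spec, channels = c("dapi", "rfp", "gfp"),
                             isotropic_truth = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    tr <- sample_truth(spec)
    truth <- truth_table(spec, tr)
    labels <- rasterize_truth(spec, tr, spec$spacing)
    d <- dim(labels$labels)
    nvox <- tabulate(labels$labels[labels$labels > 0L], nbins = spec$n_nuclei)
    zcoord <- ((seq_len(d[1]) - 1) * spec$spacing[1])
    atten <- pmax(1 - spec$attenuation_slope * zcoord, 0.05)
    render <- function(amount) {
      lut <- c(0, amount / pmax(nvox, 1))
      img <- array(lut[labels$labels + 1L], dim = d)
      img <- img * atten                       # recycles along z (first axis)
      for (axis in 0:2) {
        svox <- spec$blur_sigma[axis + 1] / spec$spacing[axis + 1]
        if (svox > 0.05) img <- cpp_convolve_axis(img, d, gaussian_kernel(svox), axis)
      }
      if (spec$poisson_noise) img <- array(rpois(length(img), pmax(img, 0)), dim = d)
      if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
      img[img < 0] <- 0
      img
    }
    out_ch <- list()
    if ("dapi" %in% channels) {
      out_ch$dapi <- voxel_grid(render(tr$content * spec$intensity_per_content),
                                spec$spacing, "dapi")
    }
    if ("rfp" %in% channels) {
      amt <- ifelse(tr$transfected & tr$class %in% c("G1", "G1S"),
                    spec$reporter_intensity * runif(spec$n_nuclei, 0.5, 1.5), 0)
      out_ch$rfp <- voxel_grid(render(amt), spec$spacing, "rfp")
    }
    if ("gfp" %in% channels) {
      amt <- ifelse(tr$transfected & tr$class %in% c("SG2", "G1S"),
                    spec$reporter_intensity * runif(spec$n_nuclei, 0.5, 1.5), 0)
      out_ch$gfp <- voxel_grid(render(amt), spec$spacing, "gfp")
    }
    res <- list(channels = out_ch, truth_labels = labels, truth = truth,
                spec = spec)
    if (isotropic_truth) {
      iso_sp <- rep(min(spec$spacing), 3)
      res$truth_labels_iso <- rasterize_truth(spec, tr, iso_sp)
    }
    res
  })
}

#' Statistical cohort twin of the image phantom
#'
#' Draws per-nucleus records with the same statistical structure the image
#' phantom renders — cell-cycle classes, DNA content, content-coupled
#' volumetrics, depth-attenuated integrated DNA intensity, FUCCI reporter
#' intensities and multiplicative measurement noise — without rasterizing
#' any image. Intended for cohort-scale classifier experiments where
#' per-voxel rendering adds nothing.
#'
#' @param n_per_class named integer vector of exact per-class nucleus
#'   counts for the transfected population, e.g.
#'   `c(G1 = 1291, G1S = 111, SG2 = 185, NONTRANSFECTED = 4698)`
#'   (non-transfected cells are assigned true classes by `spec`'s class
#'   fractions but carry no reporters); alternatively `NULL` to draw
#'   `spec$n_nuclei` cells at the spec's rates.
#' @param spec a [phantom_spec] providing the population parameters.
#' @param n_spheroids cells are split evenly across this many spheroids.
#' @param measurement_cv multiplicative measurement noise (coefficient of
#'   variation) on integrated intensities and volumetrics.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return data.frame shaped like [measure_nuclei()] output plus
#'   `true_class`, `true_content` and `transfected` columns, with
#'   `itg_dapi`, `itg_rfp`, `itg_gfp` intensity columns.
#' @export
simulate_records <- function(n_per_class = NULL, spec = phantom_spec(),
                             n_spheroids = 10, measurement_cv = 0.05,
                             seed = spec$seed) {
  with_seed(seed, {
    if (is.null(n_per_class)) {
      n <- spec$n_nuclei
      cls <- sample(c("G1", "G1S", "SG2"), n, replace = TRUE,
                    prob = c(spec$g1_fraction, spec$g1s_fraction, spec$sg2_fraction))
      transfected <- runif(n) < spec$transfection_rate
    } else {
      stopifnot(!is.null(names(n_per_class)))
      n <- sum(n_per_class)
      cls0 <- rep(names(n_per_class), n_per_class)
      transfected <- cls0 != "NONTRANSFECTED"
      cls <- cls0
      nt <- sum(!transfected)
      cls[!transfected] <- sample(c("G1", "G1S", "SG2"), nt, replace = TRUE,
                                  prob = c(spec$g1_fraction, spec$g1s_fraction,
                                           spec$sg2_fraction))
      ord <- sample(n)
      cls <- cls[ord]; transfected <- transfected[ord]
    }
    content <- numeric(n)
    content[cls == "G1"] <- 1
    content[cls == "G1S"] <- runif(sum(cls == "G1S"), 1.0, 1.1)
    is_sg2 <- cls == "SG2"
    g2 <- is_sg2 & (runif(n) < spec$sg2_g2_fraction)
    content[g2] <- 2
    s_cells <- is_sg2 & !g2
    content[s_cells] <- runif(sum(s_cells), spec$s_content_range[1],
                              spec$s_content_range[2])
    R0 <- spec$spheroid_radius
    ctr <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      repeat {
        p <- runif(3, -R0, R0)
        if (sum(p^2) <= R0^2) { ctr[i, ] <- p; break }
      }
    }
    noise <- function(n) pmax(1 + rnorm(n, 0, measurement_cv), 0.05)
    ax <- cbind(rnorm(n, spec$nucleus_axes_mean[1], spec$nucleus_axes_sd[1]),
                rnorm(n, spec$nucleus_axes_mean[2], spec$nucleus_axes_sd[2]),
                rnorm(n, spec$nucleus_axes_mean[3], spec$nucleus_axes_sd[3]))
    ax <- pmax(ax, 2) * content^(spec$volume_content_coupling / 3)
    ax <- t(apply(ax, 1, sort, decreasing = TRUE))
    volume <- 4 / 3 * pi * apply(ax / 2, 1, prod) * noise(n)
    # Thomsen's approximation for ellipsoid surface area
    p <- 1.6075
    ab <- (ax[, 1] / 2 * ax[, 2] / 2)^p
    ac <- (ax[, 1] / 2 * ax[, 3] / 2)^p
    bc <- (ax[, 2] / 2 * ax[, 3] / 2)^p
    area <- 4 * pi * ((ab + ac + bc) / 3)^(1 / p) * noise(n)
    depth <- ctr[, 1] + R0
    atten <- pmax(1 - spec$attenuation_slope * depth, 0.05)
    itg_dapi <- content * spec$intensity_per_content * atten * noise(n)
    rfp_on <- transfected & cls %in% c("G1", "G1S")
    gfp_on <- transfected & cls %in% c("SG2", "G1S")
    bg <- 0.01 * spec$reporter_intensity
    itg_rfp <- bg * noise(n) +
      ifelse(rfp_on, spec$reporter_intensity * runif(n, 0.5, 1.5), 0) * atten
    itg_gfp <- bg * noise(n) +
      ifelse(gfp_on, spec$reporter_intensity * runif(n, 0.5, 1.5), 0) * atten
    sph <- sprintf("spheroid%02d", rep_len(seq_len(n_spheroids), n))
    ev <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), n)
    data.frame(label = seq_len(n), spheroid_id = sph,
               centroid_z = ctr[, 1] + R0, centroid_y = ctr[, 2] + R0,
               centroid_x = ctr[, 3] + R0, depth = depth,
               volume = volume, surface_area = area,
               extent = pmin(pi / 6 * noise(n), 1),
               p_major = ax[, 1] * noise(n),
               p_intermediate = ax[, 2] * noise(n),
               p_minor = ax[, 3] * noise(n),
               e1_z = ev[, 1], e1_y = ev[, 2], e1_x = ev[, 3],
               e2_z = ev[, 4], e2_y = ev[, 5], e2_x = ev[, 6],
               e3_z = ev[, 7], e3_y = ev[, 8], e3_x = ev[, 9],
               sphericity = pmin(sphericity(volume, area), 1),
               itg_dapi = itg_dapi, itg_rfp = itg_rfp, itg_gfp = itg_gfp,
               true_class = cls, true_content = content,
               transfected = transfected,
               stringsAsFactors = FALSE)
  })
}

#' Match segmented nuclei to phantom truth
#'
#' Detection scoring by one-to-one centroid matching: each truth nucleus is
#' greedily paired (closest first) with an unclaimed segmented nucleus
#' within `match_radius` (default: the truth nucleus's equivalent-sphere
#' radius). Voxel-overlap Jaccard indices are computed for matched pairs
#' when label volumes are supplied.
#'
#' @param records segmented nucleus records (centroids in um).
#' @param truth phantom truth table.
#' @param pred_labels,truth_labels optional [label_volume]s on a common
#'   grid for Jaccard computation.
#' @param match_radius matching radius (um); `NULL` uses per-nucleus
#'   equivalent-sphere radii.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `matches` (data.frame truth label, pred label, distance) and
#'   `jaccard` (per matched pair, if labels given).
#' @export
match_nuclei <- function(records, truth, pred_labels = NULL,
                         truth_labels = NULL, match_radius = NULL) {
  tc <- as.matrix(truth[, c("centroid_z", "centroid_y", "centroid_x")])
  pc <- as.matrix(records[, c("centroid_z", "centroid_y", "centroid_x")])
  rad <- if (is.null(match_radius))
    (3 * truth$volume / (4 * pi))^(1 / 3) else rep(match_radius, nrow(truth))
  dm <- outer(rowSums(tc^2), rep(1, nrow(pc))) +
    outer(rep(1, nrow(tc)), rowSums(pc^2)) - 2 * tc %*% t(pc)
  dm <- sqrt(pmax(dm, 0))
  ord <- order(dm)
  used_t <- logical(nrow(tc)); used_p <- logical(nrow(pc))
  mt <- NULL
  for (k in ord) {
    ti <- (k - 1) %% nrow(tc) + 1
    pi_ <- (k - 1) %/% nrow(tc) + 1
    if (used_t[ti] || used_p[pi_]) next
    if (dm[ti, pi_] > rad[ti]) next
    used_t[ti] <- TRUE; used_p[pi_] <- TRUE
    mt <- rbind(mt, data.frame(truth_label = truth$label[ti],
                               pred_label = records$label[pi_],
                               distance = dm[ti, pi_]))
  }
  tp <- sum(used_t); fn <- sum(!used_t); fp <- sum(!used_p)
  res <- list(tp = tp, fp = fp, fn = fn,
              precision = tp / (tp + fp), recall = tp / (tp + fn),
              f1 = 2 * tp / (2 * tp + fp + fn), matches = mt)
  if (!is.null(pred_labels) && !is.null(truth_labels) && !is.null(mt) && nrow(mt) > 0) {
    if (max(abs(pred_labels$spacing - truth_labels$spacing)) > 1e-9)
      stop("pred and truth label volumes must share voxel spacing")
    # physical origins coincide; crop both to the common box
    dc <- pmin(dim(pred_labels$labels), dim(truth_labels$labels))
    pl <- pred_labels$labels[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), drop = FALSE]
    tl <- truth_labels$labels[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), drop = FALSE]
    ov <- cpp_overlap_counts(tl, pl)
    tsize <- tapply(ov[, 3], ov[, 1], sum)
    psize <- tapply(ov[, 3], ov[, 2], sum)
    jac <- numeric(nrow(mt))
    for (i in seq_len(nrow(mt))) {
      ti <- mt$truth_label[i]; pi_ <- mt$pred_label[i]
      hit <- ov[, 1] == ti & ov[, 2] == pi_
      ni <- if (any(hit)) sum(ov[hit, 3]) else 0
      un <- tsize[[as.character(ti)]] + psize[[as.character(pi_)]] - ni
      jac[i] <- ni / un
    }
    res$jaccard <- jac
  }
  res
}
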