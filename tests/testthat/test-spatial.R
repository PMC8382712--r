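test_that("surface closing of a nuclear shell yields a solid ball with the right center", {
  # nuclei on a Fibonacci-lattice shell of radius 30 (even ~8.7 um point
  # spacing, so a 10 um closing seals the surface), closing radius 10
  n <- c(72L, 72L, 72L)
  lab <- array(0L, n)
  npts <- 150
  i <- seq_len(npts)
  phi <- (1 + sqrt(5)) / 2
  zc <- 1 - (2 * i - 1) / npts
  th <- 2 * pi * i / phi
  pts <- round(cbind(36 + 30 * zc,
                     36 + 30 * sqrt(1 - zc^2) * cos(th),
                     36 + 30 * sqrt(1 - zc^2) * sin(th)))
  for (j in seq_len(npts)) {
    b <- ball_mask(n, pts[j, ], 4)
    lab[b & lab == 0L] <- j
  }
  geom <- approximate_surface(label_volume(lab, c(1, 1, 1)), closing_radius = 10)
  expect_equal(geom$center, c(35, 35, 35), tolerance = 0.06)   # (36-1)*1 um
  # mask approximates a solid ball of radius ~ 34 (shell + nuclear radius)
  vol <- sum(geom$mask)
  expect_equal(vol, 4 / 3 * pi * 34^3, tolerance = 0.15)
  # label renumbering does not change the mask
  set.seed(41)
  perm <- sample(max(lab))
  lab2 <- array(0L, n); lab2[lab > 0] <- perm[lab[lab > 0]]
  geom2 <- approximate_surface(label_volume(lab2, c(1, 1, 1)), 10)
  expect_identical(geom2$mask, geom$mask)
  # single nucleus: closing adds at most a ~1-voxel rind
  one <- array(0L, c(24L, 24L, 24L))
  one[ball_mask(c(24L, 24L, 24L), c(12, 12, 12), 6)] <- 1L
  g1 <- approximate_surface(label_volume(one, c(1, 1, 1)), 10)
  expect_true(all(g1$mask[one > 0L]))
  expect_lt(sum(g1$mask), sum(ball_mask(c(24L, 24L, 24L), c(12, 12, 12), 7.5)))
  expect_error(approximate_surface(label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})

test_that("detached nuclei are exactly those outside the closed body", {
  n <- c(60L, 60L, 90L)
  lab <- array(0L, n)
  ctr <- rbind(c(30, 30, 30), c(30, 36, 24), c(24, 30, 34), c(36, 28, 28))
  for (i in seq_len(nrow(ctr))) lab[ball_mask(n, ctr[i, ], 5)] <- i
  lab[ball_mask(n, c(30, 30, 75), 5)] <- 5L     # satellite 30+ um away
  lv <- label_volume(lab, c(1, 1, 1))
  geom <- approximate_surface(lv, 8)
  rec <- measure_nuclei(lv, list(d = voxel_grid(array(1, n), c(1, 1, 1))))
  parts <- filter_detached(rec, geom)
  expect_equal(parts$detached$label, 5)
  expect_equal(nrow(parts$kept) + nrow(parts$detached), nrow(rec))
  # compact phantom: nothing detached
  parts2 <- filter_detached(rec[1:4, ], geom)
  expect_equal(nrow(parts2$detached), 0)
})

test_that("perimeter distances follow ball geometry and rigid translation", {
  n <- c(64L, 64L, 64L)
  lab <- array(0L, n)
  lab[ball_mask(n, c(32, 32, 32), 30)] <- 1L
  geom <- list(mask = lab > 0L, spacing = c(1, 1, 1), center = c(31, 31, 31))
  class(geom) <- "spheroid_geometry"
  rec <- make_records(2)
  rec$centroid_z <- c(31, 31); rec$centroid_y <- c(31, 31)
  rec$centroid_x <- c(31, 31 + 29)
  d <- perimeter_distance(rec, geom)
  expect_equal(d[1], 30, tolerance = 0.05)       # center of a radius-30 ball
  expect_lte(d[2], 2)                            # at the surface
  # translation invariance (grid large enough that the ball stays whole)
  n2 <- c(72L, 72L, 72L)
  lab2 <- array(0L, n2); lab2[ball_mask(n2, c(38, 36, 35), 30)] <- 1L
  geom2 <- list(mask = lab2 > 0L, spacing = c(1, 1, 1), center = c(37, 35, 34))
  class(geom2) <- "spheroid_geometry"
  rec2 <- rec
  rec2$centroid_z <- rec$centroid_z + 6; rec2$centroid_y <- rec$centroid_y + 4
  rec2$centroid_x <- rec$centroid_x + 3
  expect_equal(perimeter_distance(rec2, geom2), d, tolerance = 1e-9)
  # unfiltered centroid outside the mask is an error
  rec3 <- rec; rec3$centroid_x[2] <- 63
  expect_error(perimeter_distance(rec3, geom), "outside")
})

test_that("layer assignment is half-open with innermost pooling", {
  expect_equal(assign_layers(4.2), 0)
  expect_equal(assign_layers(10), 1)            # half-open convention
  expect_equal(assign_layers(63, max_depth = 60), 5)
  expect_equal(assign_layers(c(0, 9.999, 25, 59.9, 80)), c(0, 0, 2, 5, 5))
  expect_error(assign_layers(-1), ">= 0")
})

test_that("layer statistics count S/G2 per layer and flag empty layers", {
  calls <- c("SG2", rep("G1", 9))
  layers <- rep(0, 10)
  ls <- layer_stats(calls, layers, rep("s1", 10))
  l0 <- ls$per_spheroid[ls$per_spheroid$layer == 0, ]
  expect_equal(l0$sg2_count, 1)
  expect_equal(l0$sg2_fraction, 0.1)
  # empty layers flagged NaN and excluded from the mean
  expect_true(is.nan(ls$per_spheroid$sg2_fraction[ls$per_spheroid$layer == 3]))
  expect_equal(ls$summary$n_spheroids[ls$summary$layer == 3], 0)
  # layer counts over all layers sum to the retained nuclei
  expect_equal(sum(ls$per_spheroid$n), 10)
})

test_that("uniform S/G2 fraction phantoms have a flat layer profile", {
  set.seed(44)
  n <- 4000
  dist <- runif(n, 0, 60)
  calls <- ifelse(runif(n) < 0.12, "SG2", "G1")
  sph <- sprintf("s%d", rep(1:8, length.out = n))
  ls <- layer_stats(calls, assign_layers(dist), sph)
  fit <- lm(fraction_mean ~ layer, data = ls$summary)
  ci <- confint(fit)["layer", ]
  expect_true(ci[1] < 0 && ci[2] > 0)    # slope CI contains 0
})

test_that("alignment angle reproduces the radial and tangential limits", {
  # e1 parallel to the center-nucleus vector: 0 degrees
  e3 <- c(1, 0, 0)                        # minor axis on z
  expect_equal(alignment_angle(e3, c(0, 0, 1)), 0)
  # minor axis along the radius (major perpendicular): 90 degrees
  expect_equal(alignment_angle(e3, c(1, 0, 0)), 90)
  # 45 degrees geometry
  expect_equal(alignment_angle(e3, c(1, 0, 1)), 45)
  expect_error(alignment_angle(e3, c(0, 0, 0)), "center")
})

test_that("z alignment angle limits and isotropic law hold", {
  expect_equal(z_alignment_angle(c(1, 0, 0)), 90)   # e3 along z
  expect_equal(z_alignment_angle(c(0, 0, 1)), 0)    # e3 perpendicular to z
  # for isotropic orientations P(angle <= a) = sin(a)
  set.seed(45)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ang <- z_alignment_angle(u)
  aa <- seq(5, 85, by = 10)
  emp <- vapply(aa, function(a) mean(ang <= a), numeric(1))
  expect_equal(emp, sin(aa * pi / 180), tolerance = 0.02)
})

test_that("axis ratios follow their definitions and scale invariance", {
  rec <- make_records(1)
  r <- axis_ratios(rec)                       # lengths (16, 12, 8)
  expect_equal(r$major_minor, 2)
  expect_equal(r$major_intermediate, 4 / 3, tolerance = 1e-12)
  sphere <- rec; sphere$p_major <- sphere$p_intermediate <- sphere$p_minor <- 10
  expect_equal(unlist(axis_ratios(sphere)), c(1, 1), ignore_attr = TRUE)
  scaled <- rec
  scaled[c("p_major", "p_intermediate", "p_minor")] <-
    scaled[c("p_major", "p_intermediate", "p_minor")] * 3
  expect_equal(axis_ratios(scaled), r)
})

test_that("radial trends bin correctly and recover a linear gradient", {
  d <- seq(0, 29.9, by = 0.1)
  tr <- radial_trend(d, d, bin = 5)
  expect_equal(tr$center, tr$bin_mid, tolerance = 0.5)
  tr2 <- radial_trend(rep(7, 300), d, bin = 5)
  expect_true(all(tr2$dispersion == 0))
  # volume decreasing linearly toward the center: slope recovered within 10%
  set.seed(46)
  dist <- runif(3000, 0, 50)
  vol <- 1000 - 8 * dist + rnorm(3000, 0, 30)
  tr3 <- radial_trend(vol, dist, bin = 5)
  fit <- lm(center ~ bin_mid, data = tr3)
  expect_equal(as.numeric(coef(fit)[2]), -8, tolerance = 0.1)
  expect_true(all(tr3$n >= 3) || any(tr3$sparse))
})

test_that("z-artefact fit recovers generator elongation and ignores record order", {
  set.seed(47)
  n <- 400
  u <- matrix(rnorm(3 * n), ncol = 3); u <- u / sqrt(rowSums(u^2))
  ang <- z_alignment_angle(u)
  rec <- make_records(n)
  rec[, c("e3_z", "e3_y", "e3_x")] <- u
  # no z anisotropy: slopes ~ 0
  rec$p_major <- 16; rec$p_intermediate <- 12; rec$p_minor <- 8
  f0 <- fit_z_artifact(rec)
  expect_equal(f0$difference_0_90, c(0, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  # imposed 2 um difference between 0 and 90 degrees on the major axis
  rec$p_major <- 18 - 2 * ang / 90 + rnorm(n, 0, 0.2)
  f1 <- fit_z_artifact(rec)
  expect_equal(f1$difference_0_90[f1$axis == "p_major"], -2, tolerance = 0.2)
  # order invariance
  perm <- sample(n)
  f2 <- fit_z_artifact(rec[perm, ])
  expect_equal(f2, f1, tolerance = 1e-9)
  expect_error(fit_z_artifact(rec[1:10, ]), "at least 30")
})
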