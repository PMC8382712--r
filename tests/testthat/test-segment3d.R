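test_that("z interpolation preserves constants, identity, and linear ramps", {
  # constant field is invariant
  g <- voxel_grid(array(7, c(5, 8, 8)), c(0.9, 0.45, 0.45))
  gi <- interpolate_isotropic(g)
  expect_equal(gi$spacing, c(0.45, 0.45, 0.45))
  expect_equal(dim(gi$data)[1], 9)           # same physical extent
  expect_true(all(gi$data == 7))
  # already isotropic: returned unchanged
  g2 <- voxel_grid(array(rnorm(4^3), c(4, 4, 4)), c(0.5, 0.5, 0.5))
  expect_identical(interpolate_isotropic(g2), g2)
  # linear ramp I(z) = z_um matches the analytic ramp at new positions
  ramp <- array(0, c(6, 4, 4))
  for (z in 1:6) ramp[z, , ] <- (z - 1) * 0.9
  gr <- interpolate_isotropic(voxel_grid(ramp, c(0.9, 0.45, 0.45)))
  expected <- (seq_len(dim(gr$data)[1]) - 1) * 0.45
  expect_equal(gr$data[, 2, 2], expected, tolerance = 1e-12)
  # anisotropic lateral spacing refused
  expect_error(interpolate_isotropic(voxel_grid(ramp, c(0.9, 0.5, 0.45))),
               "lateral")
})

test_that("gaussian smoothing matches a sampled kernel and conserves mass", {
  g <- voxel_grid(array(rnorm(5^3), c(5, 5, 5)), c(1, 1, 1))
  expect_identical(smooth_grid(g, 0), g)
  expect_error(smooth_grid(g, -1), "sigma")
  # single bright voxel -> sampled separable gaussian kernel
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  sm <- smooth_grid(voxel_grid(imp, c(1, 1, 1)), 1)
  k1 <- exp(-0.5 * (-3:3)^2); k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  expect_equal(sm$data[2:8, 2:8, 2:8], expected, tolerance = 1e-12)
  expect_equal(sum(sm$data), 1, tolerance = 1e-3)   # mass conserved
  # constant grid unchanged
  cg <- smooth_grid(voxel_grid(array(3, c(8, 8, 8)), c(1, 1, 1)), 1)
  expect_equal(cg$data, array(3, c(8, 8, 8)), tolerance = 1e-9)
})

test_that("adaptive threshold recovers a bright cube and zeroes constants", {
  # bright 20^3 cube centered in dark 60^3 volume
  vol <- array(0, c(60, 60, 60))
  vol[21:40, 21:40, 21:40] <- 100
  m <- adaptive_threshold(voxel_grid(vol, c(1, 1, 1)))
  truth <- array(FALSE, c(60, 60, 60)); truth[21:40, 21:40, 21:40] <- TRUE
  expect_gte(mean(m$mask == truth), 0.99)
  # constant image -> empty foreground (strict inequality)
  mc <- adaptive_threshold(voxel_grid(array(5, c(12, 12, 12)), c(1, 1, 1)))
  expect_false(any(mc$mask))
  # window below 3 voxels refused
  expect_error(adaptive_threshold(voxel_grid(array(1, c(4, 30, 30)), c(1, 1, 1))),
               "window")
})

test_that("adaptive threshold boundary sits within one voxel of a step", {
  # two-level step along x, compared against a brute-force local mean
  n <- c(10L, 10L, 24L)
  vol <- array(0, dim = n); vol[, , 13:24] <- 10
  g <- voxel_grid(vol, c(1, 1, 1))
  m <- adaptive_threshold(g)
  # brute-force local mean at the central line
  w <- round(n / 2); rlo <- (w - 1) %/% 2; rhi <- w - 1 - rlo
  brute <- logical(n[3])
  for (x in 1:n[3]) {
    zr <- max(1, 5 - rlo[1]):min(n[1], 5 + rhi[1])
    yr <- max(1, 5 - rlo[2]):min(n[2], 5 + rhi[2])
    xr <- max(1, x - rlo[3]):min(n[3], x + rhi[3])
    brute[x] <- vol[5, 5, x] > mean(vol[zr, yr, xr])
  }
  expect_identical(m$mask[5, 5, ], brute)
  # the detected boundary at the step (first foreground voxel) sits within
  # one voxel of the true step; deep inside the bright plateau the local
  # mean equals the plateau value, so that region is legitimately dropped
  rising <- which(m$mask[5, 5, ])[1] - 1
  expect_lte(abs(rising - 12), 1)
})

test_that("mask cleanup fills shells and drops small components", {
  n <- c(30L, 30L, 30L)
  shell <- ball_mask(n, c(15, 15, 15), 10) & !ball_mask(n, c(15, 15, 15), 7)
  cleaned <- clean_mask(as_mask(shell), min_object_volume = 0)
  expect_equal(sum(cleaned$mask), sum(ball_mask(n, c(15, 15, 15), 10)))
  # small component removed, large kept
  two <- array(FALSE, n)
  two[2:3, 2:3, 2:3] <- TRUE                 # 8 voxels
  two[10:27, 10:27, 10:27] <- TRUE           # 5832 voxels
  cl2 <- clean_mask(as_mask(two), min_object_volume = 100)
  expect_false(any(cl2$mask[2:3, 2:3, 2:3]))
  expect_true(all(cl2$mask[10:27, 10:27, 10:27]))
  # empty in, empty out
  expect_false(any(clean_mask(as_mask(array(FALSE, n)))$mask))
})

test_that("seed generation finds one seed per convex body and merges with deep H-minima", {
  n <- c(24L, 24L, 24L)
  sph <- as_mask(ball_mask(n, c(12, 12, 12), 8))
  s <- generate_seeds(sph, 1)
  expect_equal(nrow(s$points), 1)
  expect_true(all(abs(s$points - 12) <= 1))
  # dumbbell: two spheres r = 8, centers 1.5 r apart
  nd <- c(24L, 24L, 40L)
  db <- ball_mask(nd, c(12, 12, 14), 8) | ball_mask(nd, c(12, 12, 26), 8)
  s2 <- generate_seeds(as_mask(db), 1)
  expect_equal(nrow(s2$points), 2)
  expect_equal(sort(abs(s2$points[, 3] - 20)), c(6, 6), tolerance = 1)
  # hmin deeper than the neck contrast merges the lobes
  s3 <- generate_seeds(as_mask(db), 5)
  expect_equal(nrow(s3$points), 1)
})

test_that("more H-minima depth never increases the seed count", {
  set.seed(31)
  spec <- phantom_spec(spheroid_radius = 22, n_nuclei = 8, seed = 5,
                       spacing = c(1, 1, 1), margin = 4)
  ph <- generate_phantom(spec, channels = "dapi")
  mask <- as_mask(ph$truth_labels$labels > 0L, c(1, 1, 1))
  counts <- vapply(c(0.5, 1, 2, 3, 5), function(h)
    nrow(generate_seeds(mask, h)$points), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed partitions the foreground and respects symmetry", {
  nd <- c(24L, 24L, 40L)
  db <- ball_mask(nd, c(12, 12, 14), 8) | ball_mask(nd, c(12, 12, 26), 8)
  m <- as_mask(db)
  s <- generate_seeds(m, 1)
  lab <- watershed_split(m, s)
  expect_equal(max(lab$labels), 2)
  expect_equal(sum(lab$labels > 0), sum(db))            # partition
  # dividing surface within one voxel of the symmetry plane x = 20
  x1 <- range(which(apply(lab$labels == lab$labels[12, 12, 14], 3, any)))
  expect_lte(x1[2], 21)
  # single sphere, central seed -> one label covering the sphere
  sph <- as_mask(ball_mask(c(20L, 20L, 20L), c(10, 10, 10), 7))
  lab2 <- watershed_split(sph, seed_set(matrix(c(10L, 10L, 10L), 1)))
  expect_equal(sum(lab2$labels == 1L), sum(sph$mask))
  # background seed is refused by name
  expect_error(watershed_split(sph, seed_set(matrix(c(1L, 1L, 1L), 1))),
               "background")
})

test_that("seed pruning drops sub-median objects exactly at the stated fraction", {
  # volumes {100, 100, 30, 100}: the 30 um^3 object is below 70% of median
  n <- c(8L, 8L, 40L)
  vols <- array(0L, n)
  pts <- NULL
  sizes <- c(100, 100, 30, 100)
  x0 <- 1
  for (i in seq_along(sizes)) {
    len <- sizes[i] / (5 * 5)
    vols[2:6, 2:6, x0:(x0 + ceiling(len) - 1)] <- i
    # trim to exact voxel count
    extra <- sum(vols == i) - sizes[i]
    if (extra > 0) {
      idx <- which(vols == i)
      vols[idx[seq_len(extra)]] <- 0L
    }
    pts <- rbind(pts, c(4L, 4L, as.integer(x0)))
    x0 <- x0 + ceiling(len) + 2
  }
  lab <- label_volume(vols, c(1, 1, 1))
  seeds <- seed_set(pts)
  pruned <- prune_small_seeds(lab, seeds, 0.7)
  expect_equal(nrow(pruned$points), 3)
  expect_false(any(pruned$points[, 3] == pts[3, 3]))
  expect_true(all(pruned$source == "PRUNED"))
  # all-equal volumes: nothing pruned; single object never pruned
  one <- array(1L, c(4, 4, 4))
  s1 <- seed_set(matrix(c(2L, 2L, 2L), 1))
  expect_equal(nrow(prune_small_seeds(label_volume(one, c(1, 1, 1)), s1)$points), 1)
})

test_that("oversized detection uses a strict 40%-above-median rule", {
  mk <- function(sizes) {
    n <- c(6L, 6L, as.integer(sum(ceiling(sizes / 25)) + 3 * length(sizes)))
    vols <- array(0L, n); x0 <- 1
    for (i in seq_along(sizes)) {
      len <- ceiling(sizes[i] / 25)
      vols[2:6, 2:6, x0:(x0 + len - 1)] <- i
      extra <- sum(vols == i) - sizes[i]
      if (extra > 0) { idx <- which(vols == i); vols[idx[seq_len(extra)]] <- 0L }
      x0 <- x0 + len + 2
    }
    label_volume(vols, c(1, 1, 1))
  }
  expect_equal(find_oversized(mk(c(100, 100, 150)), 1.4), 3)
  expect_length(find_oversized(mk(c(100, 100, 100)), 1.4), 0)
  expect_length(find_oversized(mk(c(100, 100, 139)), 1.4), 0)  # strict >
  expect_error(find_oversized(label_volume(array(0L, c(3, 3, 3)), c(1, 1, 1))),
               "empty")
})

test_that("seed injection replaces cluster seeds and validates membership", {
  nd <- c(24L, 24L, 40L)
  db <- ball_mask(nd, c(12, 12, 14), 8) | ball_mask(nd, c(12, 12, 26), 8)
  m <- as_mask(db)
  merged <- generate_seeds(m, 5)                  # one seed for both lobes
  lab1 <- watershed_split(m, merged)
  expect_equal(max(lab1$labels), 1)
  inj <- inject_seeds(merged,
                      list("1" = rbind(c(12L, 12L, 14L), c(12L, 12L, 26L))),
                      lab1)
  expect_equal(nrow(inj$points), 2)
  expect_true(all(inj$source == "INJECTED"))
  lab2 <- watershed_split(m, inj)
  expect_equal(max(lab2$labels), 2)
  # empty replacement map: unchanged
  expect_identical(inject_seeds(merged, list(), lab1), merged)
  # point outside the named cluster: error
  expect_error(inject_seeds(merged, list("1" = matrix(c(1L, 1L, 1L), 1)), lab1),
               "outside")
})

test_that("full segmentation recovers sparse ellipsoids and tolerates empty stacks", {
  # truly non-touching (packing_factor > 1) and a tight size distribution,
  # so every ellipsoid is isolated and none falls under the pruning cut
  spec <- phantom_spec(spheroid_radius = 40, n_nuclei = 50,
                       nucleus_axes_mean = c(13, 10, 7),
                       nucleus_axes_sd = c(0.8, 0.6, 0.5),
                       packing_factor = 1.2,
                       spacing = c(1.0, 0.5, 0.5), margin = 5, seed = 3)
  ph <- generate_phantom(spec, channels = "dapi", isotropic_truth = TRUE)
  seg <- segment_nuclei(ph$channels$dapi, segmentation_config())
  expect_equal(max(seg$labels$labels), 50)
  rec <- measure_nuclei(seg$labels,
                        list(dapi = interpolate_isotropic(ph$channels$dapi)))
  m <- match_nuclei(rec, ph$truth, pred_labels = seg$labels,
                    truth_labels = ph$truth_labels_iso)
  expect_gte(m$f1, 0.95)
  expect_gte(min(m$jaccard), 0.7)
  # empty stack: zero labels, no error
  empty <- voxel_grid(array(0, c(20, 20, 20)), c(1, 1, 1))
  seg0 <- segment_nuclei(empty, segmentation_config())
  expect_equal(max(seg0$labels$labels), 0)
})

test_that("segmentation is equivariant under axis-aligned rotation", {
  spec <- phantom_spec(spheroid_radius = 20, n_nuclei = 6, seed = 9,
                       spacing = c(1, 1, 1), margin = 4)
  ph <- generate_phantom(spec, channels = "dapi")
  g <- ph$channels$dapi
  seg <- segment_nuclei(g, segmentation_config())
  rot <- voxel_grid(aperm(g$data, c(1, 3, 2))[, , dim(g$data)[2]:1],
                    g$spacing, g$channel)
  seg_rot <- segment_nuclei(rot, segmentation_config())
  expect_equal(max(seg_rot$labels$labels), max(seg$labels$labels))
  # foreground equal up to border effects (the clipped local-mean window
  # is asymmetric by one voxel for even window sizes)
  expect_equal(sum(seg_rot$labels$labels > 0), sum(seg$labels$labels > 0),
               tolerance = 0.01)
})
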