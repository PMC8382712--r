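test_that("FUCCI classing follows the two-reporter truth table", {
  rec <- make_records(4)
  rec$itg_rfp <- c(1000, 10, 1000, 10)
  rec$itg_gfp <- c(10, 1000, 1000, 10)
  bg <- list(rfp = c(10, 5), gfp = c(10, 5))
  out <- classify_fucci(rec, k = 3, background = bg)
  expect_identical(out$fucci_class, c("G1", "SG2", "G1S", "NONTRANSFECTED"))
  # exactly at threshold counts negative (deterministic tie rule)
  rec$itg_rfp <- c(25, 25, 25, 25); rec$itg_gfp <- c(10, 10, 10, 10)
  out2 <- classify_fucci(rec, k = 3, background = bg)
  expect_true(all(out2$fucci_class == "NONTRANSFECTED"))
  expect_error(classify_fucci(rec[, setdiff(names(rec), "itg_rfp")]),
               "itg_rfp")
})

test_that("a cohort drawn at the reference class counts is recovered exactly", {
  counts <- c(G1 = 1291, G1S = 111, SG2 = 185, NONTRANSFECTED = 4698)
  rec <- simulate_records(n_per_class = counts, seed = 2)
  # k = 5: reporter expression sits orders of magnitude above background,
  # so a stringent gate recovers the generating classes without flips
  out <- classify_fucci(rec, k = 5)
  got <- table(out$fucci_class)
  expect_equal(as.integer(got[names(counts)]), as.integer(counts))
  # the printed positive/negative transfection efficacy arithmetic
  expect_equal(round(100 * transfection_efficacy(out$fucci_class), 1), 33.8)
  expect_equal(transfection_efficacy(out$fucci_class, "total"),
               1587 / 6285, tolerance = 1e-12)
})

test_that("depth correction recovers the generator attenuation and flattens it", {
  spec <- phantom_spec(n_nuclei = 300, attenuation_slope = 0.004)
  rec <- simulate_records(spec = spec, n_spheroids = 1, seed = 8,
                          measurement_cv = 0.03)
  cor <- depth_correct(rec, "itg_dapi")
  fit <- attr(cor, "depth_fit")
  expect_equal(fit$relative_slope, -0.004, tolerance = 0.05)
  # corrected intensities have ~zero fitted slope
  refit <- lm(cor$itg_dapi_corrected ~ cor$depth)
  rel <- coef(refit)[2] / coef(refit)[1]
  expect_lt(abs(rel), 5e-4)      # > 8x flatter than the imposed 4e-3
  # no attenuation: correction ~ identity
  spec0 <- phantom_spec(n_nuclei = 200, attenuation_slope = 0)
  rec0 <- simulate_records(spec = spec0, n_spheroids = 1, seed = 9)
  cor0 <- depth_correct(rec0, "itg_dapi")
  expect_equal(cor0$itg_dapi_corrected / cor0$itg_dapi, rep(1, nrow(cor0)),
               tolerance = 0.02)
  # scale equivariance: doubling intensities doubles corrections
  rec2 <- rec; rec2$itg_dapi <- 2 * rec$itg_dapi
  cor2 <- depth_correct(rec2, "itg_dapi")
  expect_equal(cor2$itg_dapi_corrected, 2 * cor$itg_dapi_corrected,
               tolerance = 1e-9)
  # insufficient depth span: warning + identity
  shallow <- rec[1:5, ]
  expect_warning(cs <- depth_correct(shallow, "itg_dapi"), "identity")
  expect_equal(cs$itg_dapi_corrected, shallow$itg_dapi)
})

test_that("DNA content normalizes to the per-spheroid median", {
  rec <- make_records(4)
  rec$itg_dapi_corrected <- c(2, 4, 2, 2)
  out <- normalize_dna(rec)
  expect_equal(out$dna_content, c(1, 2, 1, 1))
  # two spheroids with 3x gain difference superpose after normalization
  rec2 <- make_records(8, spheroid_id = rep(c("a", "b"), each = 4))
  rec2$itg_dapi_corrected <- c(2, 4, 2, 2, 6, 12, 6, 6)
  out2 <- normalize_dna(rec2)
  expect_equal(out2$dna_content[1:4], out2$dna_content[5:8])
  # all-identical intensities give content 1
  rec3 <- make_records(5); rec3$itg_dapi_corrected <- 7
  expect_true(all(normalize_dna(rec3)$dna_content == 1))
  # undersized spheroid excluded with warning
  rec4 <- make_records(5, spheroid_id = c("a", "a", "a", "b", "b"))
  rec4$itg_dapi_corrected <- 1
  expect_warning(out4 <- normalize_dna(rec4), "fewer than 3")
  expect_equal(nrow(out4), 3)
})

test_that("threshold optimization matches an exhaustive oracle", {
  # independent brute-force scan over the same grid
  oracle <- function(pos, neg, grid) {
    best <- -Inf; opt <- NA
    for (t in grid) {
      j <- mean(pos > t) - mean(neg > t)
      if (j >= best) { best <- j; opt <- t }   # ties toward larger threshold
    }
    opt
  }
  g1 <- c(0.9, 1.0, 1.1); sg2 <- c(1.6, 2.0)
  grid <- seq(0.5, 3, by = 0.05)
  cur <- optimal_threshold(c(g1, sg2), c(rep("G1", 3), rep("SG2", 2)), grid)
  expect_equal(cur$optimum, oracle(sg2, g1, grid))
  expect_equal(cur$optimum, max(grid[grid < 1.6]))
  i <- which(cur$thresholds == cur$optimum)
  expect_equal(cur$tpr[i], 1); expect_equal(cur$fpr[i], 0)
  # endpoints: below all values TPR = FPR = 1, above all both 0
  expect_equal(cur$tpr[1], 1); expect_equal(cur$fpr[1], 1)
  expect_equal(cur$tpr[length(grid)], 0); expect_equal(cur$fpr[length(grid)], 0)
  # rates are non-increasing in the threshold
  expect_true(all(diff(cur$tpr) <= 0)); expect_true(all(diff(cur$fpr) <= 0))
  # interleaved classes have no separability
  vals <- rep(seq(0.8, 2, length.out = 10), 2)
  cls <- rep(c("G1", "SG2"), each = 10)
  cur2 <- optimal_threshold(vals, cls, grid)
  i2 <- which(cur2$thresholds == cur2$optimum)
  expect_lte(cur2$tpr[i2] - cur2$fpr[i2], 0.1 + 1e-12)
  expect_error(optimal_threshold(g1, rep("G1", 3)), "both")
})

test_that("threshold optimum brackets the modes of a two-gaussian mixture", {
  set.seed(21)
  g1 <- rnorm(2000, 1, 0.08)
  sg2 <- c(rnorm(1500, 2, 0.12), runif(500, 1.2, 1.8))
  cur <- optimal_threshold(c(g1, sg2),
                           c(rep("G1", 2000), rep("SG2", 2000)))
  expect_gt(cur$optimum, 1)
  expect_lt(cur$optimum, 2)
})

test_that("threshold classification is strict and reproduces the 1.25 rule", {
  expect_identical(threshold_classify(2.0, 1.25), "SG2")
  expect_identical(threshold_classify(1.25, 1.25), "G1")   # strict inequality
  expect_identical(threshold_classify(rep(1, 5), 1.25), rep("G1", 5))
  expect_error(threshold_classify(1, 0), "positive")
})

test_that("neighbor normalization divides by the k-nearest mean", {
  # 6 nuclei on a line: five with volume 100, one with 150
  ctr <- cbind(seq(0, 50, by = 10), 0, 0)
  rec <- make_records(6, volume = c(100, 100, 150, 100, 100, 100),
                      centroid = ctr)
  rec$dna_content <- 1.2
  f <- neighbor_normalize(rec, k = 5)
  expect_equal(f[3, "volume_nn"], 1.5, ignore_attr = TRUE)
  expect_equal(f[3, "dna_content"], 1.2, ignore_attr = TRUE)
  # identical nuclei on a lattice: every normalized feature is 1
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:2)) * 10
  rec2 <- make_records(27, volume = 100, centroid = grid)
  rec2$dna_content <- 1
  f2 <- neighbor_normalize(rec2, k = 5)
  expect_true(all(abs(f2[, 1:7] - 1) < 1e-12))
  # invariance under rigid motion of the centroids
  th <- 0.7
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, byrow = TRUE)
  ctr3 <- sweep(as.matrix(rec[, c("centroid_z", "centroid_y", "centroid_x")]) %*% t(R),
                2, c(5, -3, 11), "+")
  rec3 <- rec
  rec3[, c("centroid_z", "centroid_y", "centroid_x")] <- ctr3
  expect_equal(neighbor_normalize(rec3, k = 5), f, tolerance = 1e-9)
  expect_error(neighbor_normalize(rec[1:4, ], k = 5), "fewer than")
})

test_that("confusion arithmetic matches hand computation, degenerate cases flagged", {
  pred <- c(rep("SG2", 9), rep("G1", 91))
  truth <- c(rep("SG2", 7), "G1", "G1", rep("SG2", 3), rep("G1", 88))
  r <- evaluate_calls(pred, truth)
  expect_equal(c(r$TP, r$FP, r$FN, r$TN), c(7, 2, 3, 88))
  expect_equal(r$tpr, 0.7)
  expect_equal(r$fpr, 2 / 90)
  expect_equal(r$precision, 7 / 9)
  expect_equal(r$accuracy, 0.95)
  expect_equal(r$balanced_accuracy, (0.7 + 88 / 90) / 2)
  # perfect prediction
  p <- evaluate_calls(truth, truth)
  expect_equal(p$tpr, 1); expect_equal(p$fpr, 0); expect_equal(p$precision, 1)
  # all predicted negative: precision NaN with degenerate flag
  q <- evaluate_calls(rep("G1", 10), c(rep("SG2", 3), rep("G1", 7)))
  expect_true(is.nan(q$precision))
  expect_true(q$degenerate)
  expect_equal(q$tpr, 0); expect_equal(q$fpr, 0)
  expect_error(evaluate_calls("G1", c("G1", "SG2")), "length")
})

test_that("SVM separates separable data, fails permuted labels, and is deterministic", {
  set.seed(33)
  n <- 300
  x <- cbind(f1 = c(rnorm(n, 0), rnorm(n, 4)), f2 = c(rnorm(n, 0), rnorm(n, 4)))
  y <- rep(c("G1", "SG2"), each = n)
  fit <- train_svm(x, y, seed = 5)
  expect_equal(fit$report$balanced_accuracy, 1, tolerance = 0.02)
  # permuted labels: chance-level held-out accuracy
  set.seed(34)
  yp <- sample(y)
  fitp <- train_svm(x, yp, seed = 5)
  expect_lt(abs(fitp$report$balanced_accuracy - 0.5), 0.1)
  # identical seeds give identical models and reports
  fit2 <- train_svm(x, y, seed = 5)
  expect_identical(fit$report, fit2$report)
  expect_equal(fit$model$cost, fit2$model$cost)
  expect_equal(fit$model$gamma, fit2$model$gamma)
  expect_error(train_svm(x, rep("G1", 2 * n), seed = 1), "both classes")
})
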