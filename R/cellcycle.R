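# DNA-content cell-cycle analysis: FUCCI reference labelling, depth
# correction of integrated DNA-stain intensity, per-spheroid median
# normalization, TPR-FPR threshold optimization, neighbor-normalized
# RBF-SVM classification, and confusion-matrix evaluation.
#
# Class conventions (fucci_class / predicted_class):
#   "G1"             RFP+ / GFP-   (cdt1 reporter only)
#   "G1S"            RFP+ / GFP+   (G1-to-S transition)
#   "SG2"            RFP- / GFP+   (geminin reporter: S and G2)
#   "NONTRANSFECTED" RFP- / GFP-
#   "UNCLASSIFIED"   no call

#' Classify nuclei from FUCCI reporter intensities
#'
#' A channel is positive when its integrated intensity exceeds
#' `mean + k * sd` of its background population. By default the
#' background center and spread are estimated as the median and scaled
#' MAD of the whole channel — robust because in each single reporter
#' channel fewer than half the nuclei are positive (the non-transfected
#' mode dominates). An explicit background can be supplied instead. Ties
#' at the threshold count as negative.
#'
#' @param records data.frame with integrated-intensity columns for both
#'   reporter channels.
#' @param rfp_channel,gfp_channel column names, e.g. `"itg_rfp"`.
#' @param k positivity stringency: threshold = background mean +
#'   `k` * background sd.
#' @param background optional list with `rfp` and `gfp` elements, each
#'   `c(mean, sd)` of the background (non-transfected) population.
#' @return `records` with a `fucci_class` column added.
#' @export
classify_fucci <- function(records, rfp_channel = "itg_rfp",
                           gfp_channel = "itg_gfp", k = 3,
                           background = NULL) {
  for (ch in c(rfp_channel, gfp_channel)) {
    if (!ch %in% names(records)) stop(sprintf("missing channel column '%s'", ch))
  }
  thr <- function(x, bg) {
    if (is.null(bg)) bg <- c(median(x), mad(x))
    bg[1] + k * bg[2]
  }
  rfp_pos <- records[[rfp_channel]] > thr(records[[rfp_channel]], background$rfp)
  gfp_pos <- records[[gfp_channel]] > thr(records[[gfp_channel]], background$gfp)
  cls <- ifelse(rfp_pos & gfp_pos, "G1S",
         ifelse(rfp_pos, "G1",
         ifelse(gfp_pos, "SG2", "NONTRANSFECTED")))
  records$fucci_class <- cls
  records
}

#' FUCCI transfection efficacy
#'
#' Ratio of FUCCI-positive nuclei (G1, G1S or SG2) to either the
#' non-transfected count (`"negative"`) or all nuclei (`"total"`). With the
#' positive/negative convention, counts of 1291 G1 + 111 G1S + 185 SG2
#' against 4698 non-transfected give 33.8 percent.
#'
#' @param fucci_class character vector of FUCCI classes, or a named count
#'   vector/table with entries G1, G1S, SG2, NONTRANSFECTED.
#' @param denominator `"negative"` (positives / non-transfected) or
#'   `"total"` (positives / all).
#' @return Efficacy as a fraction.
#' @export
transfection_efficacy <- function(fucci_class, denominator = c("negative", "total")) {
  denominator <- match.arg(denominator)
  if (is.character(fucci_class)) fucci_class <- table(fucci_class)
  cnt <- function(nm) if (nm %in% names(fucci_class)) as.numeric(fucci_class[[nm]]) else 0
  pos <- cnt("G1") + cnt("G1S") + cnt("SG2")
  neg <- cnt("NONTRANSFECTED")
  if (denominator == "negative") pos / neg else pos / (pos + neg)
}

#' Depth-correct integrated intensities
#'
#' Even in a cleared spheroid, integrated DNA-stain intensity decays with
#' imaging depth. Per spheroid, median intensity in 5 um depth bins is fit
#' linearly against depth, and every intensity is rescaled by
#' `fit(reference depth) / fit(nucleus depth)`, the reference being the
#' shallowest nucleus. After correction the fitted slope is ~0. Spheroids
#' with fewer than 10 nuclei or less than 20 um of depth span are left
#' uncorrected with a warning.
#'
#' @param records data.frame with `depth`, `spheroid_id` and the intensity
#'   column.
#' @param channel intensity column name, e.g. `"itg_dapi"`.
#' @param bin_width depth bin width (um) for the median-binned fit.
#' @return `records` with a `<channel>_corrected` column and, as attribute
#'   `"depth_fit"`, a per-spheroid data.frame of `intercept`, `slope`
#'   (intensity / um) and `relative_slope` (fraction / um, slope divided by
#'   the fit value at depth 0).
#' @export
depth_correct <- function(records, channel = "itg_dapi", bin_width = 5) {
  if (!channel %in% names(records)) stop(sprintf("missing channel column '%s'", channel))
  out_col <- paste0(channel, "_corrected")
  records[[out_col]] <- records[[channel]]
  fits <- list()
  for (sph in unique(records$spheroid_id)) {
    sel <- records$spheroid_id == sph
    z <- records$depth[sel]
    y <- records[[channel]][sel]
    if (sum(sel) < 10 || diff(range(z)) < 20) {
      warning(sprintf("spheroid '%s': insufficient depth span; identity correction", sph))
      fits[[sph]] <- data.frame(spheroid_id = sph, intercept = NA_real_,
                                slope = NA_real_, relative_slope = NA_real_)
      next
    }
    bins <- floor(z / bin_width)
    med <- tapply(y, bins, median)
    ctrs <- (as.numeric(names(med)) + 0.5) * bin_width
    fit <- lm(med ~ ctrs)
    a <- coef(fit)[1]; b <- coef(fit)[2]
    zref <- min(z)
    pred <- a + b * z
    ok <- pred > 0
    records[[out_col]][sel][ok] <- y[ok] * as.numeric(a + b * zref) / pred[ok]
    fits[[sph]] <- data.frame(spheroid_id = sph, intercept = as.numeric(a),
                              slope = as.numeric(b),
                              relative_slope = as.numeric(b / a))
  }
  attr(records, "depth_fit") <- do.call(rbind, fits)
  records
}

#' Normalize DNA content to the per-spheroid median
#'
#' Each nucleus's (depth-corrected) integrated DNA-stain intensity is
#' divided by the median over all nuclei of the same spheroid, so that the
#' diploid (2N) population sits at 1 and the 4N population at 2 regardless
#' of staining gain; only then may spheroids be pooled. Spheroids with
#' fewer than 3 nuclei are excluded with a warning.
#'
#' @param records data.frame with `spheroid_id` and the intensity column.
#' @param channel intensity column to normalize (use the depth-corrected
#'   column, e.g. `"itg_dapi_corrected"`).
#' @return `records` with a `dna_content` column, minus excluded spheroids.
#' @export
normalize_dna <- function(records, channel = "itg_dapi_corrected") {
  if (!channel %in% names(records)) stop(sprintf("missing channel column '%s'", channel))
  keep <- rep(TRUE, nrow(records))
  records$dna_content <- NA_real_
  for (sph in unique(records$spheroid_id)) {
    sel <- records$spheroid_id == sph
    if (sum(sel) < 3) {
      warning(sprintf("spheroid '%s' has fewer than 3 nuclei; excluded", sph))
      keep[sel] <- FALSE
      next
    }
    records$dna_content[sel] <- records[[channel]][sel] / median(records[[channel]][sel])
  }
  records[keep, , drop = FALSE]
}

#' Optimal DNA-content threshold by the TPR-FPR maximum
#'
#' Scans candidate thresholds; at each, nuclei with `dna_content` strictly
#' above the threshold are called S/G2. TPR is computed over FUCCI-S/G2
#' nuclei, FPR over FUCCI-G1 and G1S nuclei. The optimum maximizes
#' TPR - FPR, ties broken toward the largest threshold.
#'
#' @param dna_content numeric vector of normalized DNA content.
#' @param fucci_class FUCCI classes aligned with `dna_content`; only G1,
#'   G1S and SG2 entries participate.
#' @param grid ascending candidate thresholds.
#' @return A `threshold_curve`: list with `thresholds`, `tpr`, `fpr` and
#'   `optimum`.
#' @export
optimal_threshold <- function(dna_content, fucci_class,
                              grid = seq(0.5, 3.0, by = 0.01)) {
  pos <- dna_content[fucci_class == "SG2"]
  neg <- dna_content[fucci_class %in% c("G1", "G1S")]
  if (length(pos) == 0 || length(neg) == 0)
    stop("need both S/G2 and G1 (or G1S) nuclei to optimize a threshold")
  grid <- sort(grid)
  tpr <- vapply(grid, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(grid, function(t) mean(neg > t), numeric(1))
  j <- tpr - fpr
  opt <- grid[max(which(j == max(j)))]
  structure(list(thresholds = grid, tpr = tpr, fpr = fpr, optimum = opt),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  i <- which(x$thresholds == x$optimum)
  cat(sprintf("<threshold_curve> optimum %.3f (TPR %.3f, FPR %.3f, TPR-FPR %.3f)\n",
              x$optimum, x$tpr[i], x$fpr[i], x$tpr[i] - x$fpr[i]))
  invisible(x)
}

#' Threshold classifier on DNA content
#'
#' @param dna_content normalized DNA content values.
#' @param threshold classification threshold (> 0); content strictly above
#'   it is called `"SG2"`, otherwise `"G1"` (values exactly at the
#'   threshold are G1).
#' @return Character vector of predicted classes.
#' @export
threshold_classify <- function(dna_content, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  ifelse(dna_content > threshold, "SG2", "G1")
}

VOLUMETRIC_FEATURES <- c("volume", "surface_area", "extent",
                         "p_major", "p_intermediate", "p_minor", "sphericity")

#' Neighbor-normalized feature matrix
#'
#' Each volumetric feature of a nucleus is divided by the mean of that
#' feature over its `k` nearest neighbors (centroid Euclidean distance,
#' same spheroid, self excluded), removing the radial gradients in nuclear
#' size and shape so the classifier does not learn spatial position.
#' `dna_content` is appended un-normalized.
#'
#' @param records data.frame with centroid columns, the volumetric feature
#'   columns and `dna_content`; every spheroid must have at least `k + 1`
#'   nuclei.
#' @param k number of nearest neighbors (default 5).
#' @return Numeric matrix, rows aligned with `records`, columns the
#'   neighbor-normalized volumetrics plus `dna_content`.
#' @export
neighbor_normalize <- function(records, k = 5) {
  feats <- VOLUMETRIC_FEATURES
  miss <- setdiff(c(feats, "dna_content", "centroid_z", "centroid_y", "centroid_x"),
                  names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- matrix(NA_real_, nrow(records), length(feats) + 1,
                dimnames = list(NULL, c(paste0(feats, "_nn"), "dna_content")))
  for (sph in unique(records$spheroid_id)) {
    sel <- which(records$spheroid_id == sph)
    if (length(sel) < k + 1)
      stop(sprintf("spheroid '%s' has fewer than k + 1 = %d nuclei", sph, k + 1))
    xyz <- as.matrix(records[sel, c("centroid_z", "centroid_y", "centroid_x")])
    dm <- as.matrix(dist(xyz))
    diag(dm) <- Inf
    nn <- apply(dm, 1, function(dr) order(dr)[seq_len(k)])
    for (f in seq_along(feats)) {
      v <- records[[feats[f]]][sel]
      nnmean <- colMeans(matrix(v[nn], nrow = k))
      out[sel, f] <- v / nnmean
    }
  }
  out[, "dna_content"] <- records$dna_content
  out
}

#' Confusion-matrix evaluation (S/G2 positive)
#'
#' @param predicted,truth aligned class vectors; entries equal to
#'   `positive` are the positive class, everything else negative.
#' @param positive positive-class code (default `"SG2"`).
#' @return An `eval_report`: confusion counts (TP, FP, TN, FN) and derived
#'   rates: `tpr` (recall), `fpr`, `tnr`, `precision`, `accuracy` and
#'   `balanced_accuracy` = (TPR + TNR) / 2, all as fractions. A precision
#'   with no positive predictions is reported as `NaN` with
#'   `degenerate = TRUE`.
#' @export
evaluate_calls <- function(predicted, truth, positive = "SG2") {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  pp <- predicted == positive
  tp <- truth == positive
  TP <- sum(pp & tp); FP <- sum(pp & !tp)
  FN <- sum(!pp & tp); TN <- sum(!pp & !tp)
  tpr <- if (TP + FN > 0) TP / (TP + FN) else NaN
  fpr <- if (FP + TN > 0) FP / (FP + TN) else NaN
  tnr <- if (FP + TN > 0) TN / (FP + TN) else NaN
  precision <- if (TP + FP > 0) TP / (TP + FP) else NaN
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 tpr = tpr, fpr = fpr, tnr = tnr,
                 precision = precision,
                 accuracy = (TP + TN) / length(truth),
                 balanced_accuracy = (tpr + tnr) / 2,
                 degenerate = (TP + FP) == 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  TPR %.1f%%  FPR %.1f%%  precision %.1f%%  accuracy %.1f%%  balanced %.1f%%\n",
              100 * x$tpr, 100 * x$fpr, 100 * x$precision, 100 * x$accuracy,
              100 * x$balanced_accuracy))
  invisible(x)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Train the RBF-SVM cell-cycle classifier
#'
#' A soft-margin support vector machine with a radial-basis-function kernel
#' on standardized features, with balanced class weights (the G1 class far
#' outnumbers S/G2). Hyperparameters (cost, kernel width gamma) are chosen
#' by stratified cross-validated grid search over log-spaced ranges,
#' maximizing balanced accuracy; the final model is refit on the whole
#' training split and evaluated once on the untouched test split.
#'
#' @param features numeric feature matrix (e.g. from
#'   [neighbor_normalize()]).
#' @param classes aligned vector with entries `"G1"` / `"SG2"`.
#' @param split training fraction (stratified; default 0.8).
#' @param folds cross-validation folds (default 5).
#' @param seed integer seed controlling the split, fold assignment and
#'   search order; identical seeds give identical models and reports.
#' @param cost_grid,gamma_grid hyperparameter candidates.
#' @return list with `model` (class `cellcycle_svm`: the fitted e1071 svm
#'   plus scaling and search metadata) and `report` (an `eval_report` on
#'   the held-out test split).
#' @export
train_svm <- function(features, classes, split = 0.8, folds = 5, seed = 1,
                      cost_grid = 2^seq(-2, 8, by = 2),
                      gamma_grid = 2^seq(-9, 1, by = 2) / ncol(features)) {
  features <- as.matrix(features)
  classes <- as.character(classes)
  if (length(unique(classes)) < 2) stop("training data must contain both classes")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # stratified train/test split
  test <- logical(length(classes))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    n_test <- max(1L, round((1 - split) * length(idx)))
    test[sample(idx, n_test)] <- TRUE
  }
  xtr <- features[!test, , drop = FALSE]; ytr <- classes[!test]
  xte <- features[test, , drop = FALSE];  yte <- classes[test]
  if (length(unique(ytr)) < 2) stop("training split lost a class; lower `split`")
  mu <- colMeans(xtr); sg <- apply(xtr, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  scale_x <- function(x) sweep(sweep(x, 2, mu), 2, sg, "/")
  xtr_s <- scale_x(xtr)
  wts <- length(ytr) / (2 * table(ytr))           # balanced class weights
  fold <- stratified_folds(ytr, folds)
  search <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  cv_bal <- numeric(nrow(search))
  for (i in seq_len(nrow(search))) {
    accs <- numeric(folds)
    for (f in seq_len(folds)) {
      fit <- e1071::svm(xtr_s[fold != f, , drop = FALSE],
                        factor(ytr[fold != f]),
                        kernel = "radial", cost = search$cost[i],
                        gamma = search$gamma[i], class.weights = wts,
                        scale = FALSE)
      pred <- predict(fit, xtr_s[fold == f, , drop = FALSE])
      accs[f] <- evaluate_calls(as.character(pred), ytr[fold == f])$balanced_accuracy
    }
    cv_bal[i] <- mean(accs)
  }
  best <- which.max(cv_bal)
  model <- e1071::svm(xtr_s, factor(ytr), kernel = "radial",
                      cost = search$cost[best], gamma = search$gamma[best],
                      class.weights = wts, scale = FALSE)
  pred_te <- as.character(predict(model, scale_x(xte)))
  report <- evaluate_calls(pred_te, yte)
  fitted <- structure(list(svm = model, center = mu, scale = sg,
                           cost = search$cost[best], gamma = search$gamma[best],
                           seed = seed, folds = folds,
                           search = cbind(search, balanced_accuracy = cv_bal),
                           feature_names = colnames(features)),
                      class = "cellcycle_svm")
  list(model = fitted, report = report)
}

#' Predict cell-cycle classes with a trained SVM
#'
#' @param object a `cellcycle_svm` from [train_svm()].
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return Character vector of `"G1"` / `"SG2"` calls.
#' @export
predict.cellcycle_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.character(predict(object$svm, xs))
}

#' @export
print.cellcycle_svm <- function(x, ...) {
  cat(sprintf("<cellcycle_svm> RBF kernel, cost %g, gamma %g, %d SVs (seed %d)\n",
              x$cost, x$gamma, nrow(x$svm$SV), x$seed))
  invisible(x)
}
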