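# Small geometric fixtures built in code.

# Solid ball mask in a cubic grid (voxel units unless spacing given).
ball_mask <- function(n, center, radius, spacing = c(1, 1, 1)) {
  idx <- arrayInd(seq_len(prod(n)), n)
  d2 <- ((idx[, 1] - center[1]) * spacing[1])^2 +
    ((idx[, 2] - center[2]) * spacing[2])^2 +
    ((idx[, 3] - center[3]) * spacing[3])^2
  array(d2 <= radius^2, dim = n)
}

# Axis-aligned solid ellipsoid mask.
ellipsoid_mask <- function(n, center, semi, spacing = c(1, 1, 1)) {
  idx <- arrayInd(seq_len(prod(n)), n)
  q <- (((idx[, 1] - center[1]) * spacing[1]) / semi[1])^2 +
    (((idx[, 2] - center[2]) * spacing[2]) / semi[2])^2 +
    (((idx[, 3] - center[3]) * spacing[3]) / semi[3])^2
  array(q <= 1, dim = n)
}

as_mask <- function(mask, spacing = c(1, 1, 1)) {
  mctsnuclei:::voxel_mask(mask, spacing)
}

# Minimal nucleus record table for classifier/spatial tests.
make_records <- function(n, spheroid_id = "s1", volume = 100,
                         centroid = NULL, seed = 42) {
  set.seed(seed)
  if (is.null(centroid)) centroid <- matrix(runif(3 * n, 0, 100), n)
  data.frame(label = seq_len(n), spheroid_id = spheroid_id,
             centroid_z = centroid[, 1], centroid_y = centroid[, 2],
             centroid_x = centroid[, 3], depth = centroid[, 1],
             volume = rep_len(volume, n),
             surface_area = rep_len(104, n), extent = 0.52,
             p_major = 16, p_intermediate = 12, p_minor = 8,
             e1_z = 0, e1_y = 0, e1_x = 1,
             e2_z = 0, e2_y = 1, e2_x = 0,
             e3_z = 1, e3_y = 0, e3_x = 0,
             sphericity = 0.9,
             stringsAsFactors = FALSE)
}
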