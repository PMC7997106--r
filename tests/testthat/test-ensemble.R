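# ensemble statistics: distance series, distance distributions, signed
# overlap coefficients, PCA projections

make_constant_ensemble <- function(n, order = 2, label = "const") {
  set.seed(99)
  k <- descriptor_count(order)
  v <- runif(k)
  frames <- lapply(seq_len(n), function(i)
    fake_bundle(v, v / 2, v / 3, order, sprintf("%s#%d", label, i)))
  descriptor_ensemble(frames, label = label)
}

test_that("distance-to-reference series starts at zero for its own frame", {
  set.seed(10)
  e <- gaussian_shape_ensemble(runif(descriptor_count(2)) + 1, 6, 0.05, 2, "E")
  s <- distance_to_reference(e, e$frames[[1]], "shape")
  expect_length(s, 6)
  expect_equal(s[1], 0)
  expect_true(all(s >= 0))
})

test_that("identical frames give a constant (zero) series", {
  e <- make_constant_ensemble(5)
  expect_equal(distance_to_reference(e, e$frames[[1]], "shape"), rep(0, 5))
  expect_equal(distance_to_reference(e, e$frames[[1]], "elec"), rep(0, 5))
})

test_that("pairwise distance counts follow intra/inter combinatorics", {
  set.seed(11)
  k <- descriptor_count(2)
  e5 <- gaussian_shape_ensemble(runif(k) + 1, 5, 0.1, 2, "A")
  e3 <- gaussian_shape_ensemble(runif(k) + 2, 3, 0.1, 2, "B")
  e4 <- gaussian_shape_ensemble(runif(k) + 3, 4, 0.1, 2, "C")
  intra <- pairwise_distances(e5, channel = "shape")
  expect_length(intra$samples, 10)           # C(5, 2)
  expect_equal(intra$label, "D-Intra_A")
  inter <- pairwise_distances(e3, e4, channel = "shape")
  expect_length(inter$samples, 12)           # 3 * 4
  expect_equal(inter$label, "D-Inter_B-C")
  # the elec channel is the mean of the per-sign diagnostic channels
  expect_equal(pairwise_distances(e5, channel = "elec")$samples,
               (pairwise_distances(e5, channel = "elec_pos")$samples +
                  pairwise_distances(e5, channel = "elec_neg")$samples) / 2)
  # intra on identical frames is all zeros (self-pairs excluded, so the
  # zeros come from genuine duplicate conformations)
  expect_equal(pairwise_distances(make_constant_ensemble(4),
                                  channel = "shape")$samples, rep(0, 6))
  one <- descriptor_ensemble(e5$frames[1], label = "single")
  expect_error(pairwise_distances(one, channel = "shape"), ">= 2 frames")
})

test_that("overlap of a distribution with itself is exactly one", {
  set.seed(12)
  d <- rgamma(200, shape = 3)
  o <- signed_overlap(d, d)
  expect_equal(o$value, 1, tolerance = 1e-9)
  expect_equal(o$magnitude, 1, tolerance = 1e-9)
})

test_that("disjoint distributions overlap by at most 0.01", {
  set.seed(13)
  o <- signed_overlap(runif(200), runif(200) + 100)
  expect_lte(o$magnitude, 0.01)
  expect_equal(sign(o$value), -1)  # first mean is lower
})

test_that("the overlap sign follows the distribution means and flips on swap", {
  set.seed(14)
  for (i in 1:10) {
    d1 <- rnorm(60, mean = runif(1, 0, 4))
    d2 <- rnorm(60, mean = runif(1, 0, 4))
    o12 <- signed_overlap(d1, d2)
    o21 <- signed_overlap(d2, d1)
    expect_equal(abs(o12$value), abs(o21$value), tolerance = 1e-9)
    if (mean(d1) != mean(d2)) expect_equal(o12$value, -o21$value)
    expect_equal(o12$value >= 0, mean(d1) >= mean(d2))
  }
})

test_that("overlap magnitude stays in [0, 1] across random draws", {
  set.seed(15)
  for (i in 1:100) {
    d1 <- rnorm(30, mean = runif(1, -2, 2), sd = runif(1, 0.1, 2))
    d2 <- rnorm(30, mean = runif(1, -2, 2), sd = runif(1, 0.1, 2))
    m <- signed_overlap(d1, d2)$magnitude
    expect_gte(m, 0)
    expect_lte(m, 1)
  }
})

test_that("zero-variance samples are refused with advice", {
  expect_error(signed_overlap(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("the overlap matrix has a unit diagonal and antisymmetric signs", {
  set.seed(16)
  mk <- function(mu, lab) structure(
    list(label = lab, samples = rnorm(80, mu, 0.5), channel = "shape"),
    class = "distance_distribution")
  dists <- list(mk(1, "D-Intra_A"), mk(2, "D-Intra_B"), mk(4, "D-Inter_A-B"))
  m <- overlap_matrix(dists)
  expect_equal(diag(m), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rownames(m), c("D-Intra_A", "D-Intra_B", "D-Inter_A-B"))
  for (i in 1:3) for (j in 1:3) if (i != j) {
    expect_equal(m[i, j], -m[j, i], tolerance = 1e-9)
    expect_lte(abs(m[i, j]), 1)
  }
  # the higher-mean distribution gets the positive sign
  expect_gt(m[3, 1], 0)
  expect_lt(m[1, 3], 0)
})

test_that("PCA recovers an exact low-rank structure", {
  # descriptors confined to a 2D affine subspace: two components explain
  # all variance, and the loadings are orthonormal
  set.seed(17)
  k <- descriptor_count(3)
  u1 <- runif(k); u2 <- runif(k)
  frames <- lapply(1:12, function(i) {
    v <- abs(2 + sin(i) * u1 + cos(2 * i) * u2)
    fake_bundle(v, v, v, 3, sprintf("f%d", i))
  })
  e <- descriptor_ensemble(frames, label = "plane")
  p <- pca_project(e, "shape", n_components = 2)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  expect_equal(crossprod(p$rotation), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(nrow(p$scores), 12)
})

test_that("PCA separates planted clusters and recovers their distance", {
  set.seed(18)
  k <- descriptor_count(4)
  base <- runif(k) + 2
  delta <- 3  # planted centroid separation along a random direction
  dir <- rnorm(k); dir <- dir / sqrt(sum(dir^2))
  e1 <- gaussian_shape_ensemble(base, 40, 0.05, 4, "low")
  e2 <- gaussian_shape_ensemble(base + delta * dir, 40, 0.05, 4, "high")
  p <- pca_project(list(e1, e2), "shape")
  sc <- p$scores
  c1 <- colMeans(sc[sc$ensemble == "low", c("PC1", "PC2")])
  c2 <- colMeans(sc[sc$ensemble == "high", c("PC1", "PC2")])
  recovered <- sqrt(sum((c1 - c2)^2))
  expect_lt(abs(recovered - delta) / delta, 0.1)
  # labels separate along PC1
  expect_true(max(sc$PC1[sc$ensemble == "low"]) <
                min(sc$PC1[sc$ensemble == "high"]) ||
              min(sc$PC1[sc$ensemble == "low"]) >
                max(sc$PC1[sc$ensemble == "high"]))
})

test_that("PCA refuses a constant matrix", {
  e <- make_constant_ensemble(5)
  expect_error(pca_project(e, "shape"), "constant")
})

test_that("subsampling keeps every k-th frame", {
  e <- make_constant_ensemble(10)
  s <- subsample_frames(e, 3)
  expect_equal(s$frame_ids, c(1L, 4L, 7L, 10L))
})

test_that("the two-cluster criterion separates bimodal from unimodal data", {
  set.seed(19)
  bim <- c(rnorm(50, 0, 0.3), rnorm(50, 5, 0.3))
  uni <- rnorm(100)
  expect_true(two_cluster_separation(bim)$bimodal)
  expect_false(two_cluster_separation(uni)$bimodal)
  expect_false(two_cluster_separation(rep(1, 10))$bimodal)
})
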