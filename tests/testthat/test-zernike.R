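# Zernike moments, invariants, reconstruction, and the descriptor pipeline

# a smooth radial Gaussian blob grid, offset from center so it has content
# at every (n, l)
blob_grid <- function(dim) {
  ax <- -1 + (2 * seq_len(dim) - 1) / dim
  co <- expand.grid(x = ax, y = ax, z = ax)
  r2 <- (co$x - 0.2)^2 + (co$y + 0.1)^2 + co$z^2
  ball <- (co$x^2 + co$y^2 + co$z^2) <= 0.9^2
  vals <- array(0, c(dim, dim, dim))
  vals[ball] <- exp(-r2[ball] / 0.08)
  structure(list(dim = dim, values = vals, channel = "shape",
                 center = c(0, 0, 0), scale = 1, ball_fill = 0.9),
            class = "voxel_grid")
}

test_that("descriptor_count enumerates (n, l) pairs with n - l even", {
  expect_identical(descriptor_count(20), 121)
  expect_identical(descriptor_count(0), 1)
  expect_identical(descriptor_count(2), 4)  # (0,0) (1,1) (2,0) (2,2)
  expect_error(descriptor_count(-1), "order")
  idx <- descriptor_index(4)
  expect_equal(nrow(idx), descriptor_count(4))
  expect_true(all((idx$n - idx$l) %% 2 == 0))
  expect_true(all(idx$l <= idx$n))
  expect_false(is.unsorted(idx$n))
})

test_that("an all-zero grid has all-zero moments and invariants", {
  g <- blob_grid(16)
  g$values[] <- 0
  mom <- zernike_moments(g, 6)
  expect_true(all(Mod(mom$coef) == 0))
  expect_equal(as.numeric(zernike_invariants(mom)),
               rep(0, descriptor_count(6)))
})

test_that("the uniform ball projects onto the constant basis function only", {
  dim <- 48
  ax <- -1 + (2 * seq_len(dim) - 1) / dim
  co <- expand.grid(x = ax, y = ax, z = ax)
  vals <- array(as.numeric(co$x^2 + co$y^2 + co$z^2 <= 0.999), c(dim, dim, dim))
  g <- structure(list(dim = dim, values = vals, channel = "shape",
                      center = c(0, 0, 0), scale = 1, ball_fill = 1),
                 class = "voxel_grid")
  mom <- zernike_moments(g, 6)
  i000 <- which(mom$nlm$n == 0 & mom$nlm$l == 0 & mom$nlm$m == 0)
  expect_equal(Re(mom$coef[i000]), 1, tolerance = 0.005)
  expect_lt(max(Mod(mom$coef[-i000])), 0.01)
})

test_that("moments carry the conjugate symmetry of real fields", {
  mom <- zernike_moments(blob_grid(24), 6)
  for (i in which(mom$nlm$m > 0)) {
    j <- which(mom$nlm$n == mom$nlm$n[i] & mom$nlm$l == mom$nlm$l[i] &
                 mom$nlm$m == -mom$nlm$m[i])
    expect_equal(mom$coef[j],
                 (-1)^mom$nlm$m[i] * Conj(mom$coef[i]), tolerance = 1e-12)
  }
})

test_that("moments out of a grid with mass outside the ball are refused", {
  g <- blob_grid(16)
  g$values[1, 1, 1] <- 1  # corner voxel, radius sqrt(3) * (1 - 1/16)
  expect_error(zernike_moments(g, 4), "outside the unit ball")
})

test_that("moments match the direct polynomial-evaluation oracle", {
  g <- random_ball_grid(24, seed = 11)
  expect_lt(oracle_max_rel_err(g, 6), 1e-6)
})

test_that("invariants are the per-(n,l) norms over m", {
  # single nonzero C_000 = c gives F_00 = |c| and zeros elsewhere
  mom <- zernike_moments(blob_grid(16), 4)
  mom$coef[] <- 0
  i000 <- which(mom$nlm$n == 0 & mom$nlm$l == 0 & mom$nlm$m == 0)
  mom$coef[i000] <- -2.5 + 1.2i
  f <- zernike_invariants(mom)
  expect_equal(f[1], Mod(-2.5 + 1.2i), ignore_attr = TRUE)
  expect_equal(as.numeric(f[-1]), rep(0, length(f) - 1))
})

test_that("descriptor energy is non-decreasing with nested orders", {
  g <- blob_grid(24)
  energies <- vapply(c(2, 4, 6, 8), function(N) {
    sum(as.numeric(zernike_invariants(zernike_moments(g, N)))^2)
  }, numeric(1))
  expect_true(all(diff(energies) >= 0))
})

test_that("reconstruction error decreases with order and round-trips", {
  g <- blob_grid(24)
  mom0 <- zernike_moments(g, 2)
  mom0$coef[] <- 0
  expect_equal(zernike_reconstruct(mom0, dim = 8), array(0, c(8, 8, 8)))
  errs <- vapply(c(2, 4, 8), function(N) {
    rec <- zernike_reconstruct(zernike_moments(g, N), dim = 24)
    sqrt(sum((rec - g$values)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  # moments of the reconstructed field recover the originals
  mom <- zernike_moments(g, 4)
  rec <- g
  rec$values <- zernike_reconstruct(mom, dim = 24)
  mom2 <- zernike_moments(rec, 4)
  expect_lt(max(Mod(mom2$coef - mom$coef)) / max(Mod(mom$coef)), 0.05)
})

test_that("neutral patches have zero electrostatic channels", {
  cfg <- small_config()
  zd <- describe_patch(make_atomset("helix", charge = 0), NULL, cfg)
  expect_equal(as.numeric(zd$elec_pos), rep(0, descriptor_count(cfg$order)))
  expect_equal(as.numeric(zd$elec_neg), rep(0, descriptor_count(cfg$order)))
  expect_gt(sum(zd$shape), 0)
  expect_length(zd$shape, descriptor_count(cfg$order))
})

test_that("negating every charge swaps the electrostatic channels exactly", {
  cfg <- small_config()
  at <- make_atomset("helix", charge = c(0.2, -0.2))
  neg <- at; neg$charge <- -neg$charge
  z1 <- describe_patch(at, NULL, cfg)
  z2 <- describe_patch(atomset(neg), NULL, cfg)
  expect_equal(as.numeric(z1$shape), as.numeric(z2$shape))
  expect_identical(as.numeric(z1$elec_pos), as.numeric(z2$elec_neg))
  expect_identical(as.numeric(z1$elec_neg), as.numeric(z2$elec_pos))
})

test_that("translation leaves descriptors unchanged to float tolerance", {
  cfg <- small_config()
  at <- make_atomset("helix", charge = c(0.2, -0.2))
  z1 <- describe_patch(at, NULL, cfg)
  z2 <- describe_patch(apply_rigid_motion(at, seed = 0,
                                          translation = c(17.3, -42.1, 8.8)),
                       NULL, cfg)
  for (ch in c("shape", "elec_pos", "elec_neg"))
    expect_equal(as.numeric(z1[[ch]]), as.numeric(z2[[ch]]), tolerance = 1e-9)
})

test_that("rotated patches keep their descriptors within sampling noise", {
  cfg <- zp_config(order = 8, dim = 32, samples_per_atom = 400)
  at <- make_atomset("helix", charge = c(0.2, -0.2))
  z1 <- describe_patch(at, NULL, cfg)
  for (s in c(4, 13)) {
    z2 <- describe_patch(apply_rigid_motion(at, seed = s,
                                            translation = c(1, 2, -3)),
                         NULL, cfg)
    expect_lt(rel_l1(z1$shape, z2$shape), 0.05)
    expect_lt(rel_l1(z1$elec_pos, z2$elec_pos), 0.05)
  }
})

test_that("patch selection feeds the pipeline and keeps occlusion", {
  cfg <- small_config()
  at <- make_atomset("helix", n_atoms = 30, charge = c(0.2, -0.2))
  zd <- describe_patch(at, "1-10", cfg)
  expect_gt(sum(zd$shape), 0)
  # selecting a non-existent range propagates the selection error
  expect_error(describe_patch(at, "400-410", cfg), "matches no atoms")
})

test_that("descriptor bundles round-trip through the TSV format", {
  cfg <- small_config()
  zd <- describe_patch(make_atomset("dipole", charge = 0.5), NULL, cfg)
  path <- tempfile(fileext = ".tsv")
  write_descriptor(zd, path)
  back <- read_descriptor(path)
  expect_equal(as.numeric(back$shape), as.numeric(zd$shape))
  expect_equal(as.numeric(back$elec_neg), as.numeric(zd$elec_neg))
  expect_equal(back$order, zd$order)
  expect_equal(back$config$dim, cfg$dim)
})
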