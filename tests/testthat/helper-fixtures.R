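# shared helpers: small fast configuration and synthetic descriptor bundles

small_config <- function(...) {
  zp_config(order = 8, dim = 32, samples_per_atom = 100, ...)
}

# build a zernike_descriptor directly from three numeric vectors
fake_bundle <- function(shape, pos, neg, order, label = "fake") {
  structure(list(shape = descriptor_vector(shape, order, "shape"),
                 elec_pos = descriptor_vector(pos, order, "elec_pos"),
                 elec_neg = descriptor_vector(neg, order, "elec_neg"),
                 order = order, config = NULL, label = label),
            class = "zernike_descriptor")
}

# random nonnegative descriptor bundle of a tiny order (length 4 at order 2)
random_bundle <- function(order = 2, scale = 1, label = "rnd") {
  k <- descriptor_count(order)
  fake_bundle(runif(k) * scale, runif(k) * scale, runif(k) * scale,
              order, label)
}

# ensemble of bundles drawn around a given shape-centroid with Gaussian sd
gaussian_shape_ensemble <- function(centroid, n, sd, order, label) {
  k <- descriptor_count(order)
  frames <- lapply(seq_len(n), function(i) {
    v <- pmax(centroid + rnorm(k, sd = sd), 0)
    fake_bundle(v, rep(0.1, k), rep(0.1, k), order, sprintf("%s#%d", label, i))
  })
  descriptor_ensemble(frames, label = label)
}

# relative L1 deviation between two descriptor vectors
rel_l1 <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (sum(a) == 0 && sum(b) == 0) return(0)
  sum(abs(a - b)) / sum(a)
}
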