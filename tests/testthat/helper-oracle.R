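# Independent brute-force oracle for Zernike moments: evaluates every
# basis function directly at each voxel center from its radial x spherical
# harmonic form (pracma Legendre functions, Jacobi three-term recurrence)
# and sums the discretized moment integral. No monomial expansion is
# involved, so this is a fully separate computational route from the
# package's geometric-moment implementation.

# Jacobi polynomials P_k^(0, beta)(u) for k = 0..kmax, three-term recurrence
oracle_jacobi <- function(kmax, beta, u) {
  P <- vector("list", kmax + 1)
  P[[1]] <- rep(1, length(u))
  if (kmax >= 1) P[[2]] <- 1 + (beta + 2) * (u - 1) / 2
  if (kmax >= 2) {
    for (k in 2:kmax) {
      c1 <- 2 * k * (k + beta) * (2 * k + beta - 2)
      c2 <- (2 * k + beta - 1) * ((2 * k + beta) * (2 * k + beta - 2) * u - beta^2)
      c3 <- 2 * (k - 1) * (k + beta - 1) * (2 * k + beta)
      P[[k + 1]] <- (c2 * P[[k]] - c3 * P[[k - 1]]) / c1
    }
  }
  P
}

oracle_moments <- function(grid, order) {
  dim <- grid$dim
  ax <- -1 + (2 * seq_len(dim) - 1) / dim
  co <- expand.grid(x = ax, y = ax, z = ax)
  f <- as.vector(grid$values)
  keep <- f != 0
  x <- co$x[keep]; y <- co$y[keep]; z <- co$z[keep]; f <- f[keep]
  r <- sqrt(x^2 + y^2 + z^2)
  rs <- pmax(r, 1e-300)
  cost <- z / rs
  phi <- atan2(y, x)
  voxvol <- (2 / dim)^3
  nl <- descriptor_index(order)
  out <- list()
  for (i in seq_len(nrow(nl))) {
    n <- nl$n[i]; l <- nl$l[i]; k <- (n - l) / 2
    J <- oracle_jacobi(k, l + 0.5, 2 * r^2 - 1)[[k + 1]]
    R <- sqrt((4 * pi / 3) * (2 * n + 3)) * r^l * J
    Pl <- pracma::legendre(l, cost)  # rows m = 0..l, Condon-Shortley phase
    if (is.null(dim(Pl))) Pl <- matrix(Pl, nrow = 1)
    for (m in 0:l) {
      norm <- sqrt((2 * l + 1) / (4 * pi) *
                     exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      Ybar <- norm * Pl[m + 1, ] * exp(-1i * m * phi)
      cf <- (3 / (4 * pi)) * voxvol * sum(f * R * Ybar)
      out[[sprintf("%d_%d_%d", n, l, m)]] <- cf
    }
  }
  out
}

# a reproducible random voxel grid supported inside the unit ball
random_ball_grid <- function(dim, seed = 1) {
  set.seed(seed)
  ax <- -1 + (2 * seq_len(dim) - 1) / dim
  co <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  vals <- array(0, c(dim, dim, dim))
  inside <- r <= 0.95
  vals[inside] <- runif(sum(inside))
  structure(list(dim = dim, values = vals, channel = "shape",
                 center = c(0, 0, 0), scale = 1, ball_fill = 0.95),
            class = "voxel_grid")
}

# moments of a grid compared coefficient-by-coefficient against the oracle;
# returns the maximum relative error over all (n, l, m >= 0)
oracle_max_rel_err <- function(grid, order) {
  mom <- zernike_moments(grid, order)
  orc <- oracle_moments(grid, order)
  key <- sprintf("%d_%d_%d", mom$nlm$n, mom$nlm$l, mom$nlm$m)
  sel <- mom$nlm$m >= 0
  impl <- mom$coef[sel]
  ref <- unlist(orc[key[sel]])
  max(Mod(impl - ref) / pmax(Mod(ref), 1e-14 * max(Mod(ref))))
}
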