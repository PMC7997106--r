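# Internal 3D Zernike basis machinery.
#
# Basis convention: Z_nlm(r, theta, phi) = R_nl(r) * Y_lm(theta, phi) with
# Y_lm the orthonormal complex spherical harmonics (Condon-Shortley phase)
# and the radial part
#
#   R_nl(r) = sqrt((4*pi/3) * (2n+3)) * r^l * P_k^(0, l+1/2)(2 r^2 - 1),
#   k = (n - l)/2  (n - l even),
#
# a Jacobi-polynomial form normalized so that (3/(4*pi)) * integral over the
# unit ball of Z_nlm * conj(Z_n'l'm') equals the Kronecker delta. Moments of
# a real field f are C_nlm = (3/(4*pi)) * integral f * conj(Z_nlm); the
# rotation invariants are F_nl = sqrt(sum_m |C_nlm|^2).
#
# Production route: each Z_nlm is expanded once into monomials x^a y^b z^c
# (degree <= order), so moments become a dense complex matrix product with
# the grid's geometric moments. A direct per-voxel polynomial evaluator
# (recurrences) backs reconstruction; tests carry an independent
# explicit-sum oracle.

.zp_cache <- new.env(parent = emptyenv())

# (n, l) pairs with n - l even, ascending n then l: the descriptor ordering.
zd_nl_table <- function(order) {
  n <- unlist(lapply(0:order, function(nn) rep(nn, floor(nn / 2) + 1)))
  l <- unlist(lapply(0:order, function(nn) seq(nn %% 2, nn, by = 2)))
  data.frame(n = n, l = l)
}

# generalized binomial coefficient choose(a, s) for real a, integer s >= 0
gbinom <- function(a, s) {
  if (s == 0) return(1)
  prod((a - s + seq_len(s)) / seq_len(s))
}

# Coefficients a_v of r^(l + 2v), v = 0..k, of the normalized radial
# polynomial R_nl (see header). Exact up to double rounding; coefficient
# growth is moderate through order 20.
radial_poly_coeffs <- function(n, l) {
  k <- (n - l) / 2
  if (k != round(k) || k < 0) stop_zp("invalid (n, l) = (%d, %d): n - l must be even >= 0", n, l)
  beta <- l + 0.5
  a <- numeric(k + 1)
  for (v in 0:k) {
    s_range <- max(0, k - v):k
    tot <- 0
    for (s in s_range) {
      tot <- tot + choose(k, k - s) * gbinom(k + beta, s) * choose(s, v - k + s)
    }
    a[v + 1] <- (-1)^(k - v) * tot
  }
  a * sqrt((4 * pi / 3) * (2 * n + 3))
}

# Monomial expansion of the solid harmonic r^l * Y_lm (m >= 0):
#   r^l Y_lm = sqrt((2l+1)/(4pi) (l+m)! (l-m)!) *
#     sum_k [ (-(x+iy)/2)^(m+k) ((x-iy)/2)^k z^(l-m-2k) ] /
#           [ (m+k)! k! (l-m-2k)! ]
# Returns list(pows = t x 3 integer matrix, coef = complex t-vector).
solid_harmonic_monomials <- function(l, m) {
  pref_log <- 0.5 * (log(2 * l + 1) - log(4 * pi) +
                     lgamma(l + m + 1) + lgamma(l - m + 1))
  acc <- list()
  add <- function(px, py, pz, cf) {
    key <- paste(px, py, pz)
    acc[[key]] <<- (acc[[key]] %||% 0 + 0i) + cf
  }
  for (k in 0:((l - m) %/% 2)) {
    a <- m + k          # power of -(x + iy)/2
    b <- k              # power of  (x - iy)/2
    cz <- l - m - 2 * k # power of z
    base_log <- pref_log - (m + 2 * k) * log(2) -
      lgamma(a + 1) - lgamma(b + 1) - lgamma(cz + 1)
    sgn <- (-1)^a
    for (j in 0:a) {
      for (j2 in 0:b) {
        cf <- sgn * exp(base_log + lchoose(a, j) + lchoose(b, j2)) *
          (1i)^j * (-1i)^j2
        add(a - j + b - j2, j + j2, cz, cf)
      }
    }
  }
  keys <- names(acc)
  pows <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  list(pows = pows, coef = unlist(acc, use.names = FALSE))
}

# Monomial expansion of (x^2 + y^2 + z^2)^v.
r2pow_monomials <- function(v) {
  if (v == 0) return(list(pows = matrix(0L, 1, 3), coef = 1))
  idx <- expand.grid(i1 = 0:v, i2 = 0:v)
  idx <- idx[idx$i1 + idx$i2 <= v, ]
  i3 <- v - idx$i1 - idx$i2
  coef <- exp(lgamma(v + 1) - lgamma(idx$i1 + 1) - lgamma(idx$i2 + 1) -
              lgamma(i3 + 1))
  list(pows = cbind(2L * idx$i1, 2L * idx$i2, 2L * i3), coef = round(coef))
}

# Monomial coefficient table for all Z_nlm with m >= 0 at a given order.
# Returns list(order, nlm = data.frame(n, l, m >= 0), pows = monomial power
# matrix, chi = complex [n_monomials x n_nlm] matrix). Memoized per order.
zernike_chi <- function(order) {
  key <- sprintf("chi_%d", order)
  if (!is.null(.zp_cache[[key]])) return(.zp_cache[[key]])

  # monomial universe: all (a, b, c) with a + b + c <= order
  grid <- expand.grid(a = 0:order, b = 0:order, c = 0:order)
  grid <- grid[grid$a + grid$b + grid$c <= order, ]
  pows <- as.matrix(grid)
  n_mono <- nrow(pows)
  mono_id <- array(NA_integer_, c(order + 1, order + 1, order + 1))
  mono_id[pows + 1L] <- seq_len(n_mono)

  nl <- zd_nl_table(order)
  nlm <- do.call(rbind, lapply(seq_len(nrow(nl)), function(i) {
    data.frame(n = nl$n[i], l = nl$l[i], m = 0:nl$l[i])
  }))
  chi <- matrix(0 + 0i, n_mono, nrow(nlm))

  harm_cache <- list()
  r2_cache <- lapply(0:(order %/% 2), r2pow_monomials)
  for (i in seq_len(nrow(nl))) {
    n <- nl$n[i]; l <- nl$l[i]
    a <- radial_poly_coeffs(n, l)
    for (m in 0:l) {
      hkey <- sprintf("%d_%d", l, m)
      if (is.null(harm_cache[[hkey]]))
        harm_cache[[hkey]] <- solid_harmonic_monomials(l, m)
      harm <- harm_cache[[hkey]]
      col <- which(nlm$n == n & nlm$l == l & nlm$m == m)
      h <- nrow(harm$pows)
      for (v in seq_along(a)) {
        t2 <- r2_cache[[v]]  # (x^2+y^2+z^2)^(v-1)
        t <- nrow(t2$pows)
        pp <- harm$pows[rep(seq_len(h), each = t), , drop = FALSE] +
          t2$pows[rep(seq_len(t), h), , drop = FALSE]
        cf <- a[v] * harm$coef[rep(seq_len(h), each = t)] *
          t2$coef[rep(seq_len(t), h)]
        ids <- mono_id[pp + 1L]
        agg <- rowsum(cbind(Re(cf), Im(cf)), ids)
        slots <- as.integer(rownames(agg))
        chi[slots, col] <- chi[slots, col] + complex(real = agg[, 1],
                                                     imaginary = agg[, 2])
      }
    }
  }
  res <- list(order = order, nlm = nlm, pows = pows, chi = chi)
  .zp_cache[[key]] <- res
  res
}

# Associated Legendre functions P_l^m(x) (Condon-Shortley phase) for all
# 0 <= m <= l <= lmax, via the standard stable recurrences, vectorized over
# x. Returns a list indexed [[l + 1]][[m + 1]].
assoc_legendre_all <- function(lmax, x) {
  s <- sqrt(pmax(0, 1 - x^2))
  P <- vector("list", lmax + 1)
  for (l in 0:lmax) P[[l + 1]] <- vector("list", l + 1)
  P[[1]][[1]] <- rep(1, length(x))
  if (lmax == 0) return(P)
  for (m in 0:lmax) {
    if (m > 0) {
      # P_mm = -(2m - 1) * s * P_(m-1)(m-1)
      P[[m + 1]][[m + 1]] <- -(2 * m - 1) * s * P[[m]][[m]]
    }
    if (m + 1 <= lmax) {
      P[[m + 2]][[m + 1]] <- (2 * m + 1) * x * P[[m + 1]][[m + 1]]
    }
    if (m + 2 <= lmax) {
      for (l in (m + 2):lmax) {
        P[[l + 1]][[m + 1]] <- ((2 * l - 1) * x * P[[l]][[m + 1]] -
                                  (l + m - 1) * P[[l - 1]][[m + 1]]) / (l - m)
      }
    }
  }
  P
}

# Evaluate R_nl at radii r from the cached radial coefficients.
radial_eval <- function(n, l, r) {
  a <- radial_poly_coeffs(n, l)
  r2 <- r * r
  acc <- rep(a[length(a)], length(r))
  if (length(a) > 1) for (v in (length(a) - 1):1) acc <- acc * r2 + a[v]
  acc * r^l
}
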