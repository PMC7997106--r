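# surface_field: solvent-accessible surface sampling, Coulomb potential,
# sign splitting, and voxelization onto the unit ball.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci (golden-angle) lattice: reproducible without a random seed and
#' close to area-uniform for any sample count.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  if (!is_count(n) || n < 1) stop_zp("n must be a positive integer")
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Sample the solvent-accessible surface of an atom set
#'
#' Each atom's sphere of radius (atomic radius + probe radius) is sampled on
#' a deterministic Fibonacci lattice; samples buried strictly inside any
#' other atom's expanded sphere are removed. The retained points, with their
#' owning atom index, form the SAS point cloud; per-point potential starts
#' at 0.
#'
#' When the patch of interest is embedded in a larger structure, pass the
#' full structure here (so that surrounding atoms occlude) and give the
#' patch atom indices in `keep_owners` to retain only the points the patch
#' generates.
#'
#' @param atoms an [atomset()]; all radii must be positive.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param samples_per_atom lattice points per atom sphere (>= 12,
#'   default 200).
#' @param keep_owners optional integer vector of atom indices; only surface
#'   points owned by these atoms are returned (occlusion still uses every
#'   atom).
#' @return A `surface_points` object: list with `points` (n x 3 matrix),
#'   `potential` (numeric n, initially 0), `owner` (integer n, index into
#'   `atoms`), plus the sampling parameters.
#' @export
compute_sas <- function(atoms, probe_radius = 1.4, samples_per_atom = 200,
                        keep_owners = NULL) {
  if (nrow(atoms) == 0) stop_zp("empty atom set")
  if (probe_radius < 0) stop_zp("probe_radius must be >= 0")
  if (!is_count(samples_per_atom) || samples_per_atom < 12)
    stop_zp("samples_per_atom must be an integer >= 12")
  if (any(atoms$radius <= 0)) stop_zp("all atomic radii must be > 0")
  n_atoms <- nrow(atoms)
  centers <- atom_coords(atoms)
  expanded <- atoms$radius + probe_radius
  dirs <- fibonacci_sphere(samples_per_atom)
  tol <- 1e-9

  pts_list <- vector("list", n_atoms)
  owner_list <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) {
    p <- sweep(dirs * expanded[i], 2, centers[i, ], `+`)
    # candidate occluders: atoms whose expanded sphere can reach these points
    d_cc <- sqrt(colSums((t(centers) - centers[i, ])^2))
    occ <- which(d_cc < expanded[i] + expanded & seq_len(n_atoms) != i)
    keep <- rep(TRUE, nrow(p))
    for (j in occ) {
      dj2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
        (p[, 3] - centers[j, 3])^2
      keep <- keep & dj2 >= (expanded[j] * (1 - tol))^2
      if (!any(keep)) break
    }
    pts_list[[i]] <- p[keep, , drop = FALSE]
    owner_list[[i]] <- rep.int(i, sum(keep))
  }
  points <- do.call(rbind, pts_list)
  owner <- unlist(owner_list, use.names = FALSE)
  if (!is.null(keep_owners)) {
    sel <- owner %in% keep_owners
    points <- points[sel, , drop = FALSE]
    owner <- owner[sel]
  }
  if (length(owner) == 0) stop_zp("no exposed surface (all sample points buried)")
  structure(list(points = points, potential = rep(0, length(owner)),
                 owner = owner, probe_radius = probe_radius,
                 samples_per_atom = samples_per_atom),
            class = "surface_points")
}

#' @export
print.surface_points <- function(x, ...) {
  cat(sprintf("surface_points: %d points from %d atoms (probe %.2f A)\n",
              nrow(x$points), length(unique(x$owner)), x$probe_radius))
  invisible(x)
}

#' Coulomb electrostatic potential on surface points
#'
#' Bare Coulomb sum with a uniform dielectric: the potential at point p is
#' (1/dielectric) * sum_i q_i / |p - x_i| with charges in elementary-charge
#' units and distances in Angstrom. All atoms of `atoms` contribute,
#' whether or not they own surface points.
#'
#' @param surface a `surface_points` object.
#' @param atoms the charged [atomset()] (typically the full structure).
#' @param dielectric uniform relative dielectric constant (> 0, default 4,
#'   a conventional protein-interior screening value).
#' @return The `surface_points` object with `potential` filled in
#'   (e / Angstrom, dielectric-scaled).
#' @export
coulomb_potential <- function(surface, atoms, dielectric = 4) {
  if (dielectric <= 0) stop_zp("dielectric must be > 0")
  p <- surface$points
  q <- atoms$charge
  centers <- atom_coords(atoms)
  pot <- numeric(nrow(p))
  for (j in seq_len(nrow(atoms))) {
    d2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
      (p[, 3] - centers[j, 3])^2
    zero <- d2 == 0
    if (any(zero))
      stop_zp("surface point(s) %s coincide with atom center %d (division by zero)",
              paste(utils::head(which(zero), 5), collapse = ","), j)
    if (q[j] != 0) pot <- pot + q[j] / sqrt(d2)
  }
  surface$potential <- pot / dielectric
  surface
}

#' Split a surface potential by sign
#'
#' The Zernike formalism describes patterns of nonzero values but not their
#' sign, so positive and negative potential are described as two separate
#' nonnegative fields: pos = max(potential, 0), neg = max(-potential, 0);
#' pos - neg reconstructs the potential exactly and pos * neg = 0 pointwise.
#'
#' @param surface a `surface_points` object with potential populated.
#' @return list with nonnegative numeric vectors `pos` and `neg`.
#' @export
split_potential <- function(surface) {
  pot <- surface$potential
  list(pos = pmax(pot, 0), neg = pmax(-pot, 0))
}

#' Voxelize weighted surface points into a unit-ball grid
#'
#' Points are translated to their centroid and isotropically scaled so the
#' farthest point sits at radius `ball_fill` inside the unit ball, then
#' each point deposits its weight onto the grid; total grid mass equals
#' total weight exactly under either deposition rule. The grid spans the
#' cube [-1, 1]^3 with `dim` voxels per edge; the affine placement map is
#' stored in the result for provenance.
#'
#' Deposition: `"trilinear"` (default) splits each point's weight over its
#' eight neighboring voxel centers with trilinear (cloud-in-cell) fractions,
#' which suppresses the grid-alignment noise that otherwise dominates the
#' rotation-invariance error of the downstream descriptors; `"nearest"`
#' assigns the whole weight to the containing voxel.
#'
#' @param surface a `surface_points` object.
#' @param weights per-point nonnegative weights; NULL means unit weights
#'   (shape channel).
#' @param dim voxels per edge (>= 16, default 64).
#' @param ball_fill fraction of the unit-ball radius occupied by the
#'   farthest point, in (0, 1) (default 0.7; keeps mass away from the ball
#'   boundary where the polynomial basis is truncated).
#' @param channel label stored with the grid: "shape", "elec_pos" or
#'   "elec_neg".
#' @param method deposition rule, "trilinear" or "nearest".
#' @param binarize if TRUE, occupied voxels are set to 1 instead of
#'   accumulating weight.
#' @return A `voxel_grid`: list with `dim`, `values` (dim^3 array),
#'   `channel`, `center`, `scale`, `ball_fill`.
#' @export
voxelize <- function(surface, weights = NULL, dim = 64, ball_fill = 0.7,
                     channel = "shape", method = c("trilinear", "nearest"),
                     binarize = FALSE) {
  method <- match.arg(method)
  if (!is_count(dim) || dim < 16) stop_zp("dim must be an integer >= 16")
  if (!(ball_fill > 0 && ball_fill < 1)) stop_zp("ball_fill must be in (0,1)")
  pts <- surface$points
  n <- nrow(pts)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop_zp("weights length %d != number of points %d", length(weights), n)
  if (any(weights < 0)) stop_zp("weights must be >= 0")
  center <- colMeans(pts)
  centered <- sweep(pts, 2, center)
  rmax <- sqrt(max(rowSums(centered^2)))
  if (n == 1) {
    # a single point is a legitimate delta: place it at the grid center
    rmax <- 1
  } else if (rmax == 0) {
    stop_zp("degenerate point set: all points coincide")
  }
  scale <- ball_fill / rmax
  u <- centered * scale
  vals <- array(0, c(dim, dim, dim))
  deposit <- function(ii, jj, kk, w) {
    flat <- (kk - 1) * dim * dim + (jj - 1) * dim + ii
    acc <- rowsum(w, flat)
    slots <- as.integer(rownames(acc))
    vals[slots] <<- vals[slots] + acc[, 1]
  }
  if (method == "nearest") {
    ijk <- floor((u + 1) / 2 * dim) + 1
    ijk[ijk < 1] <- 1
    ijk[ijk > dim] <- dim
    deposit(ijk[, 1], ijk[, 2], ijk[, 3], weights)
  } else {
    # continuous voxel coordinate: g = t at the center of voxel t
    g <- (u + 1) / 2 * dim + 0.5
    i0 <- floor(g)
    frac <- g - i0
    for (dx in 0:1) {
      for (dy in 0:1) {
        for (dz in 0:1) {
          w <- weights *
            (if (dx) frac[, 1] else 1 - frac[, 1]) *
            (if (dy) frac[, 2] else 1 - frac[, 2]) *
            (if (dz) frac[, 3] else 1 - frac[, 3])
          ii <- pmin(pmax(i0[, 1] + dx, 1), dim)
          jj <- pmin(pmax(i0[, 2] + dy, 1), dim)
          kk <- pmin(pmax(i0[, 3] + dz, 1), dim)
          deposit(ii, jj, kk, w)
        }
      }
    }
  }
  if (binarize) vals[vals > 0] <- 1
  structure(list(dim = dim, values = vals, channel = channel,
                 center = center, scale = scale, ball_fill = ball_fill),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d^3, channel '%s', mass %.4g, %d occupied voxels\n",
              x$dim, x$channel, sum(x$values), sum(x$values != 0)))
  invisible(x)
}

# voxel-center coordinates along one axis of the [-1,1] cube
voxel_axis <- function(dim) -1 + (2 * seq_len(dim) - 1) / dim

#' Export surface points as xyz-with-scalar text
#'
#' One line per point: x y z potential owner. For external inspection.
#' @param surface a `surface_points` object.
#' @param path output file path.
#' @export
write_surface_xyz <- function(surface, path) {
  df <- data.frame(surface$points, potential = surface$potential,
                   owner = surface$owner)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a voxel grid as versioned plain text
#'
#' Header lines (prefixed `#`) record the format version, dimensions,
#' channel and placement map; values follow in column-major order, one per
#' line. [read_voxel_grid()] inverts this exactly.
#'
#' @param grid a `voxel_grid`.
#' @param path output file path.
#' @export
write_voxel_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# zernpatch voxel_grid v1",
               sprintf("# dim %d", grid$dim),
               sprintf("# channel %s", grid$channel),
               sprintf("# center %.17g %.17g %.17g",
                       grid$center[1], grid$center[2], grid$center[3]),
               sprintf("# scale %.17g", grid$scale),
               sprintf("# ball_fill %.17g", grid$ball_fill)), con)
  writeLines(sprintf("%.17g", as.vector(grid$values)), con)
  invisible(path)
}

#' Read a voxel grid written by [write_voxel_grid()]
#' @param path input file path.
#' @return A `voxel_grid`.
#' @export
read_voxel_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) == 0 || !grepl("voxel_grid v1", hdr[1]))
    stop_zp("not a zernpatch voxel_grid file: %s", path)
  get_field <- function(key) {
    h <- hdr[grepl(paste0("^# ", key, " "), hdr)][1]
    strsplit(sub(paste0("^# ", key, " "), "", h), " ")[[1]]
  }
  dim <- as.integer(get_field("dim"))
  vals <- as.numeric(lines[!startsWith(lines, "#")])
  structure(list(dim = dim, values = array(vals, c(dim, dim, dim)),
                 channel = get_field("channel"),
                 center = as.numeric(get_field("center")),
                 scale = as.numeric(get_field("scale")),
                 ball_fill = as.numeric(get_field("ball_fill"))),
            class = "voxel_grid")
}
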