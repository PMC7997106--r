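# synthetic_fixtures: deterministic analytic atom sets, rigid motions,
# complementary bump/cavity pairs and two-state ensembles, so every stage
# of the pipeline can be exercised without external data. All randomness
# flows through explicit integer seeds; identical (spec, seed) gives an
# identical fixture.

fixture_df <- function(pos, radius, charge, name = "CA", resname = "ALA",
                       chain = "A", resno = NULL) {
  n <- nrow(pos)
  data.frame(serial = seq_len(n), name = name, resname = resname,
             chain = chain, resno = resno %||% seq_len(n),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             radius = rep_len(radius, n), charge = rep_len(charge, n),
             stringsAsFactors = FALSE)
}

# quasi-uniform points on a spherical zone cos_lo <= cos(alpha) <= cos_hi
# of a sphere of radius R centered at `center` (alpha measured from +z)
spherical_cap_points <- function(R, center, cos_range, n_sphere = 150,
                                 flip = FALSE) {
  dirs <- fibonacci_sphere(n_sphere)
  if (flip) dirs[, 3] <- -dirs[, 3]
  keep <- dirs[, 3] >= cos_range[1] & dirs[, 3] <= cos_range[2]
  sweep(dirs[keep, , drop = FALSE] * R, 2, center, `+`)
}

# square plate of atoms in the z = 0 plane; atoms closer than `hole` to the
# z axis are omitted
plate_points <- function(half_width = 8, spacing = 2.8, hole = 0) {
  g <- seq(-half_width, half_width, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g))
  pts <- cbind(pts, z = 0)
  if (hole > 0) pts <- pts[sqrt(pts[, 1]^2 + pts[, 2]^2) >= hole, , drop = FALSE]
  pts
}

#' Generate an analytic fixture atom set
#'
#' Deterministic atom sets for testing: a single `sphere`, a +/- `dipole`
#' along z, a CA-trace-like `helix` (100 degree turn, 1.5 Angstrom rise,
#' 2.3 Angstrom helical radius per atom), a convex `bump` (spherical cap on
#' a plate), or a concave `cavity` (bowl recessed into a plate with a
#' matching opening). Residue numbers run 1..n so residue selections work
#' on fixtures.
#'
#' @param kind one of "sphere", "dipole", "helix", "bump", "cavity".
#' @param n_atoms atoms in the helix trace (helix only, default 20).
#' @param radius atomic radius in Angstrom (default 1.7).
#' @param charge per-atom charge pattern, recycled (sphere/dipole/helix);
#'   for `dipole` the two atoms get +charge and -charge; for
#'   `bump`/`cavity` the cap/bowl lining atoms get this charge (plate atoms
#'   stay neutral).
#' @param separation dipole separation in Angstrom (default 4).
#' @param cap_radius curvature radius of the bump/cavity sphere (default 5).
#' @param cap_cos cosine of the cap's angular half-extent (default 0.5,
#'   i.e. 60 degrees).
#' @param seed integer; nonzero values add a small deterministic positional
#'   jitter (sd 0.02 Angstrom) so replicate fixtures differ; 0 = none.
#' @return An [atomset()].
#' @export
make_atomset <- function(kind = c("sphere", "dipole", "helix", "bump", "cavity"),
                         n_atoms = 20, radius = 1.7, charge = 0,
                         separation = 4, cap_radius = 5, cap_cos = 0.5,
                         seed = 0) {
  kind <- match.arg(kind)
  if (radius <= 0) stop_zp("radius must be > 0")
  if (kind == "sphere") {
    df <- fixture_df(matrix(0, 1, 3), radius, charge[1])
  } else if (kind == "dipole") {
    q <- abs(charge[1])
    pos <- rbind(c(0, 0, separation / 2), c(0, 0, -separation / 2))
    df <- fixture_df(pos, radius, c(q, -q), resno = 1:2)
  } else if (kind == "helix") {
    i <- seq_len(n_atoms) - 1
    theta <- i * 100 * pi / 180
    pos <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    df <- fixture_df(pos, radius, charge)
  } else {
    # bump / cavity: an annular plate whose central hole (radius
    # R * sin(acos(cap_cos))) is spanned by a spherical cap of curvature
    # radius R -- a dome rising above the plane (bump) or a bowl recessed
    # below it (cavity). A bump and a cavity with equal (R, cap_cos) are
    # exact mirror images of each other through the plate plane, so their
    # surfaces are geometrically complementary by construction.
    R <- cap_radius
    rim <- R * sqrt(1 - cap_cos^2)
    plate <- plate_points(hole = rim)
    cap <- if (kind == "bump") {
      spherical_cap_points(R, c(0, 0, -R * cap_cos), c(cap_cos, 1))
    } else {
      spherical_cap_points(R, c(0, 0, R * cap_cos), c(-1, -cap_cos))
    }
    pos <- rbind(plate, cap)
    qvec <- c(rep(0, nrow(plate)), rep(charge[1], nrow(cap)))
    df <- fixture_df(pos, radius, qvec)
  }
  if (seed != 0) {
    jit <- with_seed(seed, matrix(stats::rnorm(nrow(df) * 3, sd = 0.02),
                                  ncol = 3))
    df$x <- df$x + jit[, 1]; df$y <- df$y + jit[, 2]; df$z <- df$z + jit[, 3]
  }
  atomset(df, source_label = sprintf("fixture:%s(seed=%d)", kind, seed))
}

#' Uniform random rotation matrix from a seed
#'
#' Seed 0 is reserved for the identity; any other seed draws a uniform
#' rotation (normalized Gaussian quaternion).
#'
#' @param seed integer.
#' @return 3 x 3 orthogonal matrix with determinant +1.
#' @export
rotation_from_seed <- function(seed) {
  if (seed == 0) return(diag(3))
  q <- with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Apply a seeded rigid-body motion to an atom set
#'
#' Rotates about the centroid by the uniform random rotation drawn from
#' `seed` ([rotation_from_seed()]; seed 0 = identity), then translates.
#' Pairwise interatomic distances are preserved to float tolerance, which
#' is what makes this the test harness for rotation/translation invariance.
#'
#' @param atoms an [atomset()].
#' @param seed rotation seed (0 = identity).
#' @param translation length-3 numeric translation vector (Angstrom).
#' @return The transformed [atomset()].
#' @export
apply_rigid_motion <- function(atoms, seed = 0, translation = c(0, 0, 0)) {
  Rm <- rotation_from_seed(seed)
  pos <- atom_coords(atoms)
  ctr <- colMeans(pos)
  moved <- sweep(sweep(pos, 2, ctr) %*% t(Rm), 2, ctr + translation, `+`)
  out <- atoms
  out$x <- moved[, 1]; out$y <- moved[, 2]; out$z <- moved[, 3]
  atomset(out, source_label = sprintf("%s+motion(seed=%d)",
                                      attr(atoms, "source_label") %||% "", seed))
}

#' Complementary bump/cavity fixture pair with a mismatched control
#'
#' Planted ground truth for complementarity scoring: a `receptor` plate
#' with a hemispherical cavity lined with charge +q, a `ligand` bump of
#' matching curvature lined with charge -q, and a `control` bump of
#' mismatched (flatter) curvature also lined with -q. The receptor/ligand
#' pair is the positive case; pairing bumps (ligand vs control) is the
#' negative control.
#'
#' @param seed fixture jitter seed (see [make_atomset()]).
#' @param charge magnitude q of the lining charges (default 0.3 e; 0 gives
#'   a shape-only pair).
#' @return list of three [atomset()]s: `receptor`, `ligand`, `control`.
#' @export
make_complementary_pair <- function(seed = 0, charge = 0.3) {
  R <- 5; cc <- 0.5
  # control bump: much flatter curvature but the same rim radius, so it
  # differs from the matched bump only where complementarity lives
  R2 <- 9
  cc2 <- sqrt(1 - (R * sqrt(1 - cc^2) / R2)^2)
  list(receptor = make_atomset("cavity", charge = +charge, cap_radius = R,
                               cap_cos = cc, seed = seed),
       ligand = make_atomset("bump", charge = -charge, cap_radius = R,
                             cap_cos = cc, seed = seed),
       control = make_atomset("bump", charge = -charge, cap_radius = R2,
                              cap_cos = cc2, seed = seed))
}

#' Two-state conformational ensemble fixture
#'
#' Frames alternate between two distinct helix conformers (the second has
#' its C-terminal half hinge-bent by 35 degrees) with small seeded
#' isotropic Gaussian jitter, mimicking a trajectory that hops between two
#' conformational states. With `jitter = 0` there are exactly two unique
#' conformations.
#'
#' @param n_frames number of frames (>= 4).
#' @param seed jitter seed.
#' @param jitter per-coordinate Gaussian displacement sd (Angstrom,
#'   default 0.1).
#' @param charge per-atom charge pattern for the helix (default alternating
#'   +0.2/-0.2 e so electrostatic channels are exercised).
#' @return list with `frames` (list of [atomset()]s) and `states` (integer
#'   1/2 state labels per frame).
#' @export
make_two_state_ensemble <- function(n_frames, seed = 1, jitter = 0.1,
                                    charge = c(0.2, -0.2)) {
  if (!is_count(n_frames) || n_frames < 4) stop_zp("n_frames must be >= 4")
  base <- make_atomset("helix", n_atoms = 20, charge = charge)
  # state 2: hinge-bend the second half about the y axis through atom 10
  bent <- base
  pivot <- as.numeric(base[10, c("x", "y", "z")])
  ang <- 35 * pi / 180
  Rm <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)),
               3, 3, byrow = TRUE)
  tail_idx <- 11:nrow(base)
  moved <- sweep(sweep(atom_coords(base)[tail_idx, , drop = FALSE], 2, pivot) %*%
                   t(Rm), 2, pivot, `+`)
  bent$x[tail_idx] <- moved[, 1]
  bent$y[tail_idx] <- moved[, 2]
  bent$z[tail_idx] <- moved[, 3]
  states <- rep_len(c(1L, 2L), n_frames)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    conf <- if (states[i] == 1L) base else bent
    if (jitter > 0) {
      jit <- matrix(stats::rnorm(nrow(conf) * 3, sd = jitter), ncol = 3)
      conf$x <- conf$x + jit[, 1]
      conf$y <- conf$y + jit[, 2]
      conf$z <- conf$z + jit[, 3]
    }
    atomset(conf, source_label = sprintf("fixture:two_state#%d(state=%d)",
                                         i, states[i]))
  }))
  list(frames = frames, states = states)
}

#' Write an atom set as a PQR file
#'
#' Whitespace-delimited ATOM records ending in charge and radius, readable
#' by [read_pqr()].
#'
#' @param atoms an [atomset()].
#' @param path output file path.
#' @export
write_pqr <- function(atoms, path) {
  chain <- ifelse(nzchar(atoms$chain), atoms$chain, "A")
  lines <- sprintf("ATOM %6d %-4s %-4s %s %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
                   atoms$serial, atoms$name, atoms$resname, chain,
                   atoms$resno, atoms$x, atoms$y, atoms$z,
                   atoms$charge, atoms$radius)
  writeLines(lines, path)
  invisible(path)
}

# crude element from a fixture atom name: leading digits mean hydrogen,
# otherwise the first alphabetic character
fixture_element <- function(name) {
  ifelse(grepl("^[0-9]", name), "H",
         substr(gsub("[^A-Za-z]", "", name), 1, 1))
}

#' Write atom sets as a (multi-model) PDB file
#'
#' Fixed-column ATOM records; several atom sets become MODEL/ENDMDL blocks
#' readable by [read_pdb_models()]. Charges and radii are not representable
#' in PDB and are dropped.
#'
#' @param atomsets an [atomset()] or list of them (one per model).
#' @param path output file path.
#' @export
write_pdb_models <- function(atomsets, path) {
  if (inherits(atomsets, "atomset")) atomsets <- list(atomsets)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(atomsets) > 1
  for (k in seq_along(atomsets)) {
    a <- atomsets[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    nm <- ifelse(nchar(a$name) <= 3, paste0(" ", a$name), a$name)
    chain <- ifelse(nzchar(a$chain), substr(a$chain, 1, 1), "A")
    writeLines(sprintf("ATOM  %5d %-4s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       a$serial, nm, a$resname, chain, a$resno,
                       a$x, a$y, a$z, 1, 0,
                       fixture_element(a$name)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
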