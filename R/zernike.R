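# zernike_core: 3D Zernike moments, rotation/translation invariants, and
# truncated reconstruction of voxelized fields on the unit ball.

#' Number of invariant descriptor components at a given order
#'
#' One component per (n, l) pair with 0 <= l <= n <= order and n - l even:
#' sum over n of (floor(n/2) + 1). Order 20 gives 121 components.
#'
#' @param order maximum expansion order N (integer >= 0).
#' @return integer count.
#' @export
descriptor_count <- function(order) {
  if (!is_count(order)) stop_zp("order must be a nonnegative integer")
  sum(floor(0:order / 2) + 1)
}

#' Descriptor component index
#'
#' The fixed (n, l) ordering of descriptor vectors: ascending n, then
#' ascending l within n. Serialized vectors are comparable across runs
#' because this ordering never changes.
#'
#' @param order maximum expansion order N.
#' @return data frame with columns `n`, `l`.
#' @export
descriptor_index <- function(order) {
  if (!is_count(order)) stop_zp("order must be a nonnegative integer")
  zd_nl_table(order)
}

#' 3D Zernike moments of a voxel grid
#'
#' Discretizes the moment integral over the unit ball:
#' C_nlm = (3/(4 pi)) * sum_voxels grid(v) * conj(Z_nlm(v)) * voxel_volume,
#' computed through the monomial (geometric-moment) expansion of the basis.
#' For real grids the negative-m moments follow from conjugate symmetry
#' C_(n,l,-m) = (-1)^m * conj(C_nlm) and are stored explicitly.
#'
#' @param grid a `voxel_grid` (all nonzero voxels inside the unit ball).
#' @param order maximum expansion order N; orders above 20 trigger a
#'   numerical-stability warning.
#' @return A `zernike_moments` object: list with `order`, `nlm` (data frame
#'   n, l, m over the complete index set) and `coef` (complex vector).
#' @export
zernike_moments <- function(grid, order = 20) {
  if (!inherits(grid, "voxel_grid")) stop_zp("grid must be a voxel_grid")
  if (!is_count(order)) stop_zp("order must be a nonnegative integer")
  if (order > 20)
    warning("orders above 20 are numerically fragile in double precision")
  dim <- grid$dim
  ax <- voxel_axis(dim)
  nz <- which(grid$values != 0)
  if (length(nz) > 0) {
    ijk <- arrayInd(nz, c(dim, dim, dim))
    x <- ax[ijk[, 1]]; y <- ax[ijk[, 2]]; z <- ax[ijk[, 3]]
    r2 <- x^2 + y^2 + z^2
    if (any(r2 > 1 + 1e-12))
      stop_zp("grid has mass outside the unit ball (max voxel-center radius %.4f)",
              sqrt(max(r2)))
    f <- grid$values[nz]
  } else {
    x <- y <- z <- f <- numeric(0)
  }
  basis <- zernike_chi(order)
  n_mono <- nrow(basis$pows)
  M <- numeric(n_mono)
  if (length(f) > 0) {
    pow_mat <- function(v) outer(v, 0:order, `^`)
    Px <- pow_mat(x); Py <- pow_mat(y); Pz <- pow_mat(z)
    for (a in 0:order) {
      for (b in 0:(order - a)) {
        w <- f * Px[, a + 1] * Py[, b + 1]
        cmax <- order - a - b
        vals <- crossprod(Pz[, seq_len(cmax + 1), drop = FALSE], w)
        ids <- basis$pows[, 1] == a & basis$pows[, 2] == b
        M[ids] <- vals[basis$pows[ids, 3] + 1]
      }
    }
  }
  voxvol <- (2 / dim)^3
  c_pos <- as.vector(t(Conj(basis$chi)) %*% M) * (3 / (4 * pi)) * voxvol

  # full index set including negative m via conjugate symmetry (real grid)
  nlm_pos <- basis$nlm
  full <- do.call(rbind, lapply(unique(paste(nlm_pos$n, nlm_pos$l)), function(key) {
    nl <- as.integer(strsplit(key, " ")[[1]])
    data.frame(n = nl[1], l = nl[2], m = -nl[2]:nl[2])
  }))
  pos_key <- paste(nlm_pos$n, nlm_pos$l, nlm_pos$m)
  match_pos <- match(paste(full$n, full$l, abs(full$m)), pos_key)
  coef <- c_pos[match_pos]
  negm <- full$m < 0
  coef[negm] <- (-1)^abs(full$m[negm]) * Conj(coef[negm])
  structure(list(order = order, nlm = full, coef = coef),
            class = "zernike_moments")
}

#' @export
print.zernike_moments <- function(x, ...) {
  cat(sprintf("zernike_moments: order %d, %d coefficients, max |C| = %.4g\n",
              x$order, length(x$coef), if (length(x$coef)) max(Mod(x$coef)) else 0))
  invisible(x)
}

#' Rotation/translation-invariant Zernike descriptors
#'
#' F_nl = sqrt(sum over m of |C_nlm|^2): the per-(n, l) norms of the
#' moments, invariant under rotation (the m-components mix unitarily) and,
#' given centroid centering at voxelization, under translation. Components
#' follow the fixed [descriptor_index()] ordering.
#'
#' @param moments a `zernike_moments` object.
#' @param channel label carried on the result.
#' @return A `descriptor_vector`: nonnegative numeric vector of length
#'   [descriptor_count()] with attributes `order` and `channel`.
#' @export
zernike_invariants <- function(moments, channel = "shape") {
  if (!inherits(moments, "zernike_moments")) stop_zp("moments must be zernike_moments")
  nl <- zd_nl_table(moments$order)
  key <- paste(moments$nlm$n, moments$nlm$l)
  vals <- vapply(seq_len(nrow(nl)), function(i) {
    sel <- key == paste(nl$n[i], nl$l[i])
    sqrt(sum(Mod(moments$coef[sel])^2))
  }, numeric(1))
  descriptor_vector(vals, moments$order, channel)
}

#' Construct a descriptor vector
#' @param values nonnegative numeric vector of length
#'   [descriptor_count]\code{(order)}.
#' @param order expansion order.
#' @param channel channel label ("shape", "elec_pos", "elec_neg").
#' @return A `descriptor_vector`.
#' @export
descriptor_vector <- function(values, order, channel = "shape") {
  if (length(values) != descriptor_count(order))
    stop_zp("descriptor length %d does not match order %d (expected %d)",
            length(values), order, descriptor_count(order))
  if (any(values < -1e-12)) stop_zp("descriptor components must be >= 0")
  structure(as.numeric(pmax(values, 0)), order = order, channel = channel,
            class = "descriptor_vector")
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat(sprintf("descriptor_vector: order %d, channel '%s', %d components, L1 norm %.4g\n",
              attr(x, "order"), attr(x, "channel"), length(x), sum(abs(x))))
  invisible(x)
}

#' Truncated Zernike reconstruction of a field
#'
#' Evaluates the truncated series sum C_nlm * Z_nlm on a dim^3 grid of
#' voxel centers (real result for real input fields). Used to validate the
#' expansion; not part of the descriptor pipeline.
#'
#' @param moments a `zernike_moments` object.
#' @param dim voxels per edge of the evaluation grid.
#' @return dim^3 numeric array (zero outside the unit ball).
#' @export
zernike_reconstruct <- function(moments, dim = 32) {
  ax <- voxel_axis(dim)
  coords <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt(coords$x^2 + coords$y^2 + coords$z^2)
  inside <- r <= 1
  x <- coords$x[inside]; y <- coords$y[inside]; z <- coords$z[inside]
  r <- r[inside]
  rsafe <- pmax(r, 1e-300)
  cost <- z / rsafe
  phi <- atan2(y, x)
  order <- moments$order
  P <- assoc_legendre_all(order, cost)
  nl <- zd_nl_table(order)
  key <- paste(moments$nlm$n, moments$nlm$l, moments$nlm$m)
  field <- numeric(length(r))
  for (i in seq_len(nrow(nl))) {
    n <- nl$n[i]; l <- nl$l[i]
    R <- radial_eval(n, l, r)
    for (m in 0:l) {
      cf <- moments$coef[match(paste(n, l, m), key)]
      if (Mod(cf) == 0) next
      norm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      Ylm <- norm * P[[l + 1]][[m + 1]] * exp(1i * m * phi)
      contrib <- cf * R * Ylm
      field <- field + if (m == 0) Re(contrib) else 2 * Re(contrib)
    }
  }
  out <- array(0, c(dim, dim, dim))
  out[inside] <- field
  out
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the descriptor pipeline with its
#' default: expansion order 20 (121 components per channel), 64^3 grid,
#' ball fill 0.7, water-probe radius 1.4 Angstrom, uniform dielectric 4,
#' 200 surface samples per atom.
#'
#' @param order Zernike expansion order.
#' @param dim voxel grid edge length.
#' @param ball_fill fraction of the unit-ball radius for the farthest point.
#' @param probe_radius solvent probe radius (Angstrom).
#' @param dielectric uniform relative dielectric for the Coulomb potential.
#' @param samples_per_atom SAS lattice samples per atom.
#' @param voxel_method deposition rule for [voxelize()]: "trilinear"
#'   (default) or "nearest".
#' @param binarize_elec if TRUE, electrostatic voxels record occupancy (0/1)
#'   instead of accumulated potential magnitude.
#' @param normalize if TRUE, each descriptor vector is scaled to unit L2
#'   norm before use.
#' @return A `zp_config` list.
#' @export
zp_config <- function(order = 20, dim = 64, ball_fill = 0.7,
                      probe_radius = 1.4, dielectric = 4,
                      samples_per_atom = 200,
                      voxel_method = c("trilinear", "nearest"),
                      binarize_elec = FALSE, normalize = FALSE) {
  voxel_method <- match.arg(voxel_method)
  if (!is_count(order)) stop_zp("order must be a nonnegative integer")
  if (!is_count(dim) || dim < 16) stop_zp("dim must be an integer >= 16")
  if (!(ball_fill > 0 && ball_fill < 1)) stop_zp("ball_fill must be in (0,1)")
  if (probe_radius < 0) stop_zp("probe_radius must be >= 0")
  if (dielectric <= 0) stop_zp("dielectric must be > 0")
  if (!is_count(samples_per_atom) || samples_per_atom < 12)
    stop_zp("samples_per_atom must be an integer >= 12")
  structure(list(order = order, dim = dim, ball_fill = ball_fill,
                 probe_radius = probe_radius, dielectric = dielectric,
                 samples_per_atom = samples_per_atom,
                 voxel_method = voxel_method,
                 binarize_elec = binarize_elec, normalize = normalize),
            class = "zp_config")
}

# indices of atoms matched by a selection (NULL selection = all atoms)
patch_indices <- function(atoms, selection) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.character(selection)) selection <- residue_selection(selection)
  keep <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(selection))) {
    hit <- atoms$resno >= selection$start[i] & atoms$resno <= selection$end[i]
    if (!is.na(selection$chain[i]))
      hit <- hit & atoms$chain == selection$chain[i]
    keep <- keep | hit
  }
  if (!any(keep)) stop_zp("selection matches no atoms")
  which(keep)
}

#' Describe a surface patch by shape and electrostatic Zernike descriptors
#'
#' Full pipeline: select patch atoms, sample the SAS of the whole structure
#' (retaining the patch-owned points, so surrounding atoms occlude),
#' evaluate the Coulomb potential on the points, split it by sign, voxelize
#' the three channels (shape with unit weights, positive and negative
#' potential with their magnitudes), and reduce each grid to its invariant
#' descriptor vector. All three channels share one centering and scaling.
#'
#' @param atoms the full [atomset()] (with charges for the electrostatic
#'   channels; zero charges give all-zero electrostatic descriptors).
#' @param selection residue ranges defining the patch (string,
#'   `residue_selection`, or NULL for every atom).
#' @param config a [zp_config()].
#' @param label optional label stored on the result.
#' @return A `zernike_descriptor`: list with `descriptor_vector`s `shape`,
#'   `elec_pos`, `elec_neg`, plus `order`, `config`, `label`.
#' @export
describe_patch <- function(atoms, selection = NULL, config = zp_config(),
                           label = NULL) {
  idx <- patch_indices(atoms, selection)
  surface <- compute_sas(atoms, probe_radius = config$probe_radius,
                         samples_per_atom = config$samples_per_atom,
                         keep_owners = idx)
  surface <- coulomb_potential(surface, atoms, dielectric = config$dielectric)
  sp <- split_potential(surface)
  chans <- list(shape = NULL, elec_pos = sp$pos, elec_neg = sp$neg)
  vecs <- lapply(names(chans), function(ch) {
    grid <- voxelize(surface, weights = chans[[ch]], dim = config$dim,
                     ball_fill = config$ball_fill, channel = ch,
                     method = config$voxel_method,
                     binarize = !identical(ch, "shape") && config$binarize_elec)
    v <- zernike_invariants(zernike_moments(grid, config$order), channel = ch)
    if (config$normalize && sum(v^2) > 0)
      v <- descriptor_vector(v / sqrt(sum(v^2)), config$order, ch)
    v
  })
  names(vecs) <- names(chans)
  structure(list(shape = vecs$shape, elec_pos = vecs$elec_pos,
                 elec_neg = vecs$elec_neg, order = config$order,
                 config = config,
                 label = label %||% (attr(atoms, "source_label") %||% "")),
            class = "zernike_descriptor")
}

#' @export
print.zernike_descriptor <- function(x, ...) {
  cat(sprintf("zernike_descriptor: order %d (%d components/channel)%s\n",
              x$order, length(x$shape),
              if (nzchar(x$label)) sprintf(" [%s]", x$label) else ""))
  cat(sprintf("  L1 norms  shape %.4g | elec_pos %.4g | elec_neg %.4g\n",
              sum(x$shape), sum(x$elec_pos), sum(x$elec_neg)))
  invisible(x)
}

#' Write a descriptor bundle as TSV
#'
#' Plain-text serialization: `#`-prefixed provenance header (format version,
#' order, label, JSON-serialized config), then one row per (n, l) component
#' with the three channel values.
#'
#' @param zd a `zernike_descriptor`.
#' @param path output file path.
#' @export
write_descriptor <- function(zd, path) {
  nl <- zd_nl_table(zd$order)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# zernpatch descriptor v1",
               sprintf("# order %d", zd$order),
               sprintf("# label %s", zd$label),
               sprintf("# config %s",
                       jsonlite::toJSON(unclass(zd$config), auto_unbox = TRUE))),
             con)
  df <- data.frame(n = nl$n, l = nl$l,
                   shape = as.numeric(zd$shape),
                   elec_pos = as.numeric(zd$elec_pos),
                   elec_neg = as.numeric(zd$elec_neg))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor bundle written by [write_descriptor()]
#' @param path input file path.
#' @return A `zernike_descriptor` (config restored from the header).
#' @export
read_descriptor <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) == 0 || !grepl("descriptor v1", hdr[1]))
    stop_zp("not a zernpatch descriptor file: %s", path)
  order <- as.integer(sub("^# order ", "", hdr[grepl("^# order ", hdr)][1]))
  label <- sub("^# label ", "", hdr[grepl("^# label ", hdr)][1])
  cfg_json <- sub("^# config ", "", hdr[grepl("^# config ", hdr)][1])
  cfg <- do.call(zp_config, jsonlite::fromJSON(cfg_json))
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  structure(list(shape = descriptor_vector(df$shape, order, "shape"),
                 elec_pos = descriptor_vector(df$elec_pos, order, "elec_pos"),
                 elec_neg = descriptor_vector(df$elec_neg, order, "elec_neg"),
                 order = order, config = cfg, label = label),
            class = "zernike_descriptor")
}
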