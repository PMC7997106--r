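# ensemble_analysis: descriptor ensembles from conformational sampling and
# the statistics used to compare them -- distance-to-reference series,
# intra/inter pairwise distance distributions, the signed kernel-density
# overlap coefficient, and PCA projection of descriptor vectors.

#' Construct a descriptor ensemble
#'
#' One `zernike_descriptor` per conformation (e.g. per MD frame), all of
#' one order, in frame order.
#'
#' @param frames list of `zernike_descriptor` objects.
#' @param label ensemble label (used in distribution names).
#' @param frame_ids integer frame identifiers (default 1..n).
#' @return A `descriptor_ensemble`.
#' @export
descriptor_ensemble <- function(frames, label = "ensemble",
                                frame_ids = seq_along(frames)) {
  if (length(frames) == 0) stop_zp("ensemble needs at least one frame")
  orders <- vapply(frames, function(f) f$order, numeric(1))
  if (length(unique(orders)) != 1)
    stop_zp("all frames must share one descriptor order")
  if (length(frame_ids) != length(frames))
    stop_zp("frame_ids length mismatch")
  structure(list(label = label, frames = frames,
                 frame_ids = as.integer(frame_ids),
                 order = orders[1]),
            class = "descriptor_ensemble")
}

#' Describe every frame of a conformational ensemble
#'
#' Runs [describe_patch()] on each atom set with one shared selection and
#' configuration.
#'
#' @param atomsets list of [atomset()] objects (e.g. from
#'   [read_pdb_models()] or a fixture generator).
#' @param selection shared residue selection (or NULL for all atoms).
#' @param config a [zp_config()].
#' @param label ensemble label.
#' @return A `descriptor_ensemble`.
#' @export
describe_frames <- function(atomsets, selection = NULL, config = zp_config(),
                            label = "ensemble") {
  frames <- lapply(seq_along(atomsets), function(i) {
    describe_patch(atomsets[[i]], selection, config,
                   label = sprintf("%s#%d", label, i))
  })
  descriptor_ensemble(frames, label = label)
}

#' @export
print.descriptor_ensemble <- function(x, ...) {
  cat(sprintf("descriptor_ensemble '%s': %d frames, order %d\n",
              x$label, length(x$frames), x$order))
  invisible(x)
}

# channel distance between two descriptor bundles: shape = shape Manhattan
# distance, elec = similarity average of pos-pos and neg-neg (like the
# "elec" rows of ensemble overlap tables); the per-sign channels are
# exposed for diagnostics
channel_distance <- function(a, b,
                             channel = c("shape", "elec",
                                         "elec_pos", "elec_neg")) {
  channel <- match.arg(channel)
  switch(channel,
         shape = manhattan_distance(a$shape, b$shape),
         elec = (manhattan_distance(a$elec_pos, b$elec_pos) +
                   manhattan_distance(a$elec_neg, b$elec_neg)) / 2,
         elec_pos = manhattan_distance(a$elec_pos, b$elec_pos),
         elec_neg = manhattan_distance(a$elec_neg, b$elec_neg))
}

#' Distance of each frame to a reference descriptor
#'
#' The descriptor-space analogue of an RMSD-versus-time trace: one channel
#' distance per frame, in frame order, against a fixed reference (typically
#' the starting structure).
#'
#' @param ensemble a `descriptor_ensemble`.
#' @param reference a `zernike_descriptor` of the same order.
#' @param channel "shape", "elec" (average of the like-sign channel
#'   distances), or the per-sign diagnostics "elec_pos" / "elec_neg".
#' @return numeric vector, one nonnegative value per frame.
#' @export
distance_to_reference <- function(ensemble, reference,
                                  channel = c("shape", "elec",
                                              "elec_pos", "elec_neg")) {
  channel <- match.arg(channel)
  if (reference$order != ensemble$order)
    stop_zp("reference order %d != ensemble order %d",
            reference$order, ensemble$order)
  vapply(ensemble$frames, channel_distance, numeric(1),
         b = reference, channel = channel)
}

#' Pairwise descriptor distance distribution
#'
#' Within one ensemble (`e2` missing): all unordered frame pairs i < j,
#' n(n-1)/2 samples, labeled `D-Intra_<label>`. Between two ensembles: all
#' ordered pairs, n1*n2 samples, labeled `D-Inter_<label1>-<label2>`.
#' Intra distributions exclude self-pairs by construction.
#'
#' @param e1 a `descriptor_ensemble`.
#' @param e2 optional second `descriptor_ensemble` of the same order.
#' @param channel "shape", "elec", "elec_pos" or "elec_neg".
#' @return A `distance_distribution`: list with `label`, `samples`,
#'   `channel`.
#' @export
pairwise_distances <- function(e1, e2 = NULL,
                               channel = c("shape", "elec",
                                           "elec_pos", "elec_neg")) {
  channel <- match.arg(channel)
  intra <- is.null(e2)
  if (intra) {
    n <- length(e1$frames)
    if (n < 2) stop_zp("intra-ensemble distribution needs >= 2 frames")
    pairs <- utils::combn(n, 2)
    samples <- vapply(seq_len(ncol(pairs)), function(k) {
      channel_distance(e1$frames[[pairs[1, k]]], e1$frames[[pairs[2, k]]],
                       channel)
    }, numeric(1))
    label <- sprintf("D-Intra_%s", e1$label)
  } else {
    if (e1$order != e2$order) stop_zp("ensemble order mismatch")
    idx <- expand.grid(i = seq_along(e1$frames), j = seq_along(e2$frames))
    samples <- vapply(seq_len(nrow(idx)), function(k) {
      channel_distance(e1$frames[[idx$i[k]]], e2$frames[[idx$j[k]]], channel)
    }, numeric(1))
    label <- sprintf("D-Inter_%s-%s", e1$label, e2$label)
  }
  structure(list(label = label, samples = samples, channel = channel),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance_distribution %s (%s): %d samples, mean %.4g\n",
              x$label, x$channel, length(x$samples), mean(x$samples)))
  invisible(x)
}

#' Signed overlap coefficient between two distance distributions
#'
#' The magnitude is the shared area under the two kernel density estimates,
#' integral of min(f1, f2): 1 for identical distributions, 0 for disjoint
#' ones. The sign marks which distribution sits higher: positive if the
#' first distribution's mean is >= the second's, negative otherwise, so
#' swapping the arguments flips the sign whenever the means differ.
#'
#' Densities use a Gaussian kernel with Silverman's rule-of-thumb bandwidth
#' ([stats::bw.nrd0()]), evaluated on a common grid of `grid_n` points
#' spanning the pooled sample range extended by 3 bandwidths; each density
#' is renormalized to unit mass on that grid so the overlap is a true
#' density-area fraction (a distribution against itself scores exactly 1).
#'
#' @param d1,d2 `distance_distribution` objects (or numeric sample
#'   vectors), each with >= 2 samples and nonzero spread.
#' @param grid_n number of evaluation points (default 512).
#' @param bw optional fixed bandwidth overriding Silverman's rule.
#' @return An `overlap_result`: list with `value` (signed, in [-1, 1]),
#'   `magnitude`, `mean1`, `mean2`, `bandwidths`.
#' @export
signed_overlap <- function(d1, d2, grid_n = 512, bw = NULL) {
  s1 <- if (inherits(d1, "distance_distribution")) d1$samples else as.numeric(d1)
  s2 <- if (inherits(d2, "distance_distribution")) d2$samples else as.numeric(d2)
  if (length(s1) < 2 || length(s2) < 2)
    stop_zp("each distribution needs >= 2 samples")
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0)
    stop_zp(paste("zero-variance sample set: kernel bandwidth is undefined;",
                  "compare exactly instead of by density overlap"))
  bw1 <- bw %||% stats::bw.nrd0(s1)
  bw2 <- bw %||% stats::bw.nrd0(s2)
  pad <- 3 * max(bw1, bw2)
  lo <- min(s1, s2) - pad
  hi <- max(s1, s2) + pad
  f1 <- stats::density(s1, bw = bw1, from = lo, to = hi, n = grid_n)
  f2 <- stats::density(s2, bw = bw2, from = lo, to = hi, n = grid_n)
  y1 <- f1$y / pracma::trapz(f1$x, f1$y)
  y2 <- f2$y / pracma::trapz(f2$x, f2$y)
  magnitude <- min(1, max(0, pracma::trapz(f1$x, pmin(y1, y2))))
  sgn <- if (mean(s1) >= mean(s2)) 1 else -1
  structure(list(value = sgn * magnitude, magnitude = magnitude,
                 mean1 = mean(s1), mean2 = mean(s2),
                 bandwidths = c(bw1, bw2)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %.4f (magnitude %.4f; means %.4g vs %.4g)\n",
              x$value, x$magnitude, x$mean1, x$mean2))
  invisible(x)
}

#' Signed overlap matrix of several distance distributions
#'
#' Entry (i, j) is `signed_overlap(d[i], d[j])$value`; the diagonal is 1 by
#' construction and off-diagonal signs are antisymmetric whenever means
#' differ.
#'
#' @param distributions named list of `distance_distribution` objects.
#' @param ... passed to [signed_overlap()].
#' @return square numeric matrix with distribution labels as dimnames.
#' @export
overlap_matrix <- function(distributions, ...) {
  k <- length(distributions)
  labels <- vapply(distributions, function(d) d$label, character(1))
  m <- diag(1, k)
  if (k > 1) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j)
          m[i, j] <- signed_overlap(distributions[[i]], distributions[[j]], ...)$value
      }
    }
  }
  dimnames(m) <- list(labels, labels)
  m
}

# flatten one frame to the numeric vector used for PCA: the shape channel,
# or the concatenated positive+negative electrostatic channels
frame_matrix_row <- function(frame, channel) {
  if (channel == "shape") as.numeric(frame$shape)
  else c(as.numeric(frame$elec_pos), as.numeric(frame$elec_neg))
}

#' PCA projection of descriptor ensembles
#'
#' Fits PCA ([stats::prcomp()], mean-centered, unscaled) on the pooled
#' frames of all ensembles and projects every frame into the leading
#' principal components -- the "essential space" in which distinct pockets
#' or states separate.
#'
#' @param ensembles a `descriptor_ensemble` or list of them (pooled fit).
#' @param channel "shape" (descriptor vector) or "elec" (concatenated
#'   positive and negative channels).
#' @param n_components number of components to return (default 2).
#' @return list with `scores` (data frame: ensemble, frame_id, PC1..),
#'   `explained` (variance fractions per returned component),
#'   `rotation` (loadings matrix).
#' @export
pca_project <- function(ensembles, channel = c("shape", "elec"),
                        n_components = 2) {
  channel <- match.arg(channel)
  if (inherits(ensembles, "descriptor_ensemble")) ensembles <- list(ensembles)
  rows <- list(); labels <- character(); ids <- integer()
  for (e in ensembles) {
    for (i in seq_along(e$frames)) {
      rows[[length(rows) + 1]] <- frame_matrix_row(e$frames[[i]], channel)
      labels <- c(labels, e$label)
      ids <- c(ids, e$frame_ids[i])
    }
  }
  X <- do.call(rbind, rows)
  if (nrow(X) < n_components + 1)
    stop_zp("need >= %d pooled frames for %d components",
            n_components + 1, n_components)
  if (all(apply(X, 2, stats::sd) == 0))
    stop_zp("constant descriptor matrix: PCA is undefined")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  scores <- data.frame(ensemble = labels, frame_id = ids,
                       fit$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE)
  explained <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
  list(scores = scores, explained = explained,
       rotation = fit$rotation[, seq_len(k), drop = FALSE])
}

#' Keep every k-th frame of an ensemble
#'
#' Deterministic (seedless) subsampler for long trajectories.
#'
#' @param ensemble a `descriptor_ensemble`.
#' @param k stride (keep frames 1, 1+k, 1+2k, ...).
#' @return A `descriptor_ensemble`.
#' @export
subsample_frames <- function(ensemble, k) {
  if (!is_count(k) || k < 1) stop_zp("k must be a positive integer")
  keep <- seq(1, length(ensemble$frames), by = k)
  descriptor_ensemble(ensemble$frames[keep], label = ensemble$label,
                      frame_ids = ensemble$frame_ids[keep])
}

#' Two-cluster separation criterion for a 1D series
#'
#' Splits the values into two groups with [stats::kmeans()] (deterministic
#' initialization at the 25% and 75% quantiles) and reports the
#' between-cluster fraction of the total sum of squares. Values near 1 mean
#' two well-separated modes; a unimodal Gaussian scores about 0.64. The
#' default threshold 0.85 flags clear bimodality, as in a two-state
#' distance-to-reference trace.
#'
#' @param x numeric vector (length >= 4).
#' @param threshold separation fraction above which `bimodal` is TRUE.
#' @return list with `separation` (between-SS / total-SS), `bimodal`
#'   (logical), `centers` (the two cluster means).
#' @export
two_cluster_separation <- function(x, threshold = 0.85) {
  if (length(x) < 4) stop_zp("need >= 4 values")
  if (stats::sd(x) == 0)
    return(list(separation = 0, bimodal = FALSE, centers = rep(mean(x), 2)))
  centers <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (centers[1] == centers[2]) centers <- range(x)
  km <- stats::kmeans(x, centers = matrix(centers, 2, 1))
  sep <- km$betweenss / km$totss
  list(separation = sep, bimodal = sep > threshold,
       centers = sort(as.numeric(km$centers)))
}

#' Write a distance distribution (or series) as TSV
#' @param d a `distance_distribution` or numeric vector.
#' @param path output file path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_distribution <- function(d, path, header_lines = character()) {
  samples <- if (inherits(d, "distance_distribution")) d$samples else as.numeric(d)
  label <- if (inherits(d, "distance_distribution")) d$label else "series"
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(data.frame(label = label, index = seq_along(samples),
                                value = samples),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
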