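# comparison: Manhattan-distance similarity and complementarity between
# descriptor bundles.
#
# Shape similarity and shape complementarity are both the Manhattan
# distance between the shape descriptors. Electrostatic similarity
# averages the like-sign channel distances (pos-pos, neg-neg);
# electrostatic complementarity cross-averages them (pos-neg, neg-pos).
# Small distances mean high similarity / high complementarity.

#' Manhattan distance between two descriptor vectors
#'
#' sum_i |T_i - V_i| over the component-wise differences; 0 means
#' identical. Symmetric and satisfies the triangle inequality.
#'
#' @param t_vec,v_vec numeric vectors (equal length; `descriptor_vector`s
#'   or plain numerics).
#' @return nonnegative scalar.
#' @export
manhattan_distance <- function(t_vec, v_vec) {
  if (length(t_vec) != length(v_vec))
    stop_zp("descriptor length mismatch: %d vs %d", length(t_vec), length(v_vec))
  sum(abs(as.numeric(t_vec) - as.numeric(v_vec)))
}

check_matching_order <- function(a, b) {
  if (!inherits(a, "zernike_descriptor") || !inherits(b, "zernike_descriptor"))
    stop_zp("arguments must be zernike_descriptor objects")
  if (a$order != b$order)
    stop_zp("descriptor order mismatch: %d vs %d", a$order, b$order)
}

# the four raw electrostatic channel pairings, always reportable
elec_pairings <- function(a, b) {
  c(pos_pos = manhattan_distance(a$elec_pos, b$elec_pos),
    neg_neg = manhattan_distance(a$elec_neg, b$elec_neg),
    pos_neg = manhattan_distance(a$elec_pos, b$elec_neg),
    neg_pos = manhattan_distance(a$elec_neg, b$elec_pos))
}

patch_score <- function(mode, shape_distance, electrostatic_distance, pairings,
                        labels) {
  structure(list(mode = mode, shape_distance = shape_distance,
                 electrostatic_distance = electrostatic_distance,
                 pairings = pairings, labels = labels),
            class = "patch_score")
}

#' Similarity between two patches
#'
#' Shape: Manhattan distance between shape descriptors. Electrostatics:
#' mean of the positive-positive and negative-negative channel distances.
#'
#' @param a,b `zernike_descriptor` bundles of matching order.
#' @return A `patch_score` with `mode = "similarity"`, fields
#'   `shape_distance`, `electrostatic_distance` and the four raw channel
#'   `pairings`.
#' @export
patch_similarity <- function(a, b) {
  check_matching_order(a, b)
  pr <- elec_pairings(a, b)
  patch_score("similarity",
              manhattan_distance(a$shape, b$shape),
              (pr[["pos_pos"]] + pr[["neg_neg"]]) / 2,
              pr, c(a$label, b$label))
}

#' Complementarity between two patches
#'
#' Shape: Manhattan distance between shape descriptors (identical to the
#' similarity shape term). Electrostatics: mean of the cross-sign channel
#' distances (pos-neg, neg-pos) -- small when one patch's positive pattern
#' matches the other's negative pattern, as across a binding interface.
#'
#' @inheritParams patch_similarity
#' @return A `patch_score` with `mode = "complementarity"`.
#' @export
patch_complementarity <- function(a, b) {
  check_matching_order(a, b)
  pr <- elec_pairings(a, b)
  patch_score("complementarity",
              manhattan_distance(a$shape, b$shape),
              (pr[["pos_neg"]] + pr[["neg_pos"]]) / 2,
              pr, c(a$label, b$label))
}

#' @export
print.patch_score <- function(x, ...) {
  cat(sprintf("patch_score (%s): shape %.6g, electrostatic %.6g\n",
              x$mode, x$shape_distance, x$electrostatic_distance))
  cat(sprintf("  pairings: pos-pos %.6g, neg-neg %.6g, pos-neg %.6g, neg-pos %.6g\n",
              x$pairings[["pos_pos"]], x$pairings[["neg_neg"]],
              x$pairings[["pos_neg"]], x$pairings[["neg_pos"]]))
  invisible(x)
}

#' @export
as.data.frame.patch_score <- function(x, ...) {
  data.frame(pair = paste(x$labels, collapse = " vs "), mode = x$mode,
             shape_distance = x$shape_distance,
             electrostatic_distance = x$electrostatic_distance,
             pos_pos = x$pairings[["pos_pos"]],
             neg_neg = x$pairings[["neg_neg"]],
             pos_neg = x$pairings[["pos_neg"]],
             neg_pos = x$pairings[["neg_pos"]],
             stringsAsFactors = FALSE)
}

#' Write one or more patch scores as TSV
#' @param scores a `patch_score` or list of them.
#' @param path output file path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_scores <- function(scores, path, header_lines = character()) {
  if (inherits(scores, "patch_score")) scores <- list(scores)
  df <- do.call(rbind, lapply(scores, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
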