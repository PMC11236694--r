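#' Score detections against ground truth
#'
#' Matches detected centroids to ground-truth coordinates one-to-one by
#' greedy nearest-pair assignment: candidate pairs closer than `tolerance`
#' are matched in order of increasing distance, each point used at most once.
#' Precision is matched/detected, recall matched/truth, and F1 their harmonic
#' mean. When both sets are empty there is nothing to miss or invent, so F1
#' is defined as 1 (a note is emitted).
#'
#' @param detections a [point_pattern()] or an n x 2 matrix of x, y um.
#' @param truth a [point_pattern()] or an n x 2 matrix of x, y um.
#' @param tolerance matching radius in um (> 0).
#' @return list with `precision`, `recall`, `f1`, `n_matched`, `n_detected`,
#'   `n_truth` and the matched index pairs (`matches`, two columns:
#'   detection row, truth row).
#' @examples
#' truth <- cbind(c(0, 20), c(0, 0))
#' det <- cbind(c(1, 40), c(0, 0))
#' evaluate_detections(det, truth, tolerance = 5)$f1  # 0.5
#' @export
evaluate_detections <- function(detections, truth, tolerance) {
  stopifnot(is.finite(tolerance), tolerance > 0)
  det <- if (inherits(detections, "point_pattern")) detections$points else rbind_points(detections)
  tru <- if (inherits(truth, "point_pattern")) truth$points else rbind_points(truth)
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0 && nt == 0) {
    message("evaluate_detections: both sets empty; F1 defined as 1")
    return(list(precision = 1, recall = 1, f1 = 1, n_matched = 0L,
                n_detected = 0L, n_truth = 0L,
                matches = matrix(integer(0), ncol = 2)))
  }
  matches <- matrix(integer(0), ncol = 2)
  if (nd > 0 && nt > 0) {
    dmat <- sqrt(outer(det[, 1], tru[, 1], "-")^2 +
                 outer(det[, 2], tru[, 2], "-")^2)
    cand <- which(dmat <= tolerance, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        di <- cand[i, 1]; ti <- cand[i, 2]
        if (!used_d[di] && !used_t[ti]) {
          used_d[di] <- TRUE; used_t[ti] <- TRUE
          matches <- rbind(matches, c(di, ti))
        }
      }
    }
  }
  m <- nrow(matches)
  precision <- if (nd > 0) m / nd else 0
  recall <- if (nt > 0) m / nt else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, n_matched = m,
       n_detected = nd, n_truth = nt, matches = matches)
}
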