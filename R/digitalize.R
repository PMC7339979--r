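#' Rank-based AUROC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic:
#' the probability that a randomly chosen positive scores above a randomly
#' chosen negative, with ties counting 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or a factor with levels
#'   `"0"`/`"1"`).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1
#' auroc(c(1, 1, 1, 1), c(1, 0, 1, 0))          # 0.5
#' @export
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(as.character(labels))
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC undefined: need both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Digitalize drug sensitivities into bipartite-graph edge labels
#'
#' Thresholds the continuous dose-response AUC matrix into binary
#' sensitive/resistant labels on the cell-drug bipartite graph. Lower AUC
#' means more sensitive, so a pair is labeled 1 (sensitive) iff its AUC is
#' less than or equal to the drug's threshold. The default rule is a
#' per-drug quantile split (median), since dose-response AUC scales differ
#' by compound; a global absolute threshold is available instead.
#'
#' @param sensitivity Cells x drugs numeric matrix (dose-response AUC),
#'   `NA` for unmeasured pairs.
#' @param q Per-drug quantile in `[0, 1]` (default 0.5, the median). Used
#'   when `threshold` is `NULL`.
#' @param threshold Optional global absolute threshold overriding `q`.
#' @return A data.frame of class `labeled_pairs` with columns `cell_id`,
#'   `drug_id`, `label` (integer 0/1); only non-missing entries appear.
#'   Per-drug thresholds are stored in the `thresholds` attribute.
#' @examples
#' S <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 4, 2,
#'             dimnames = list(paste0("c", 1:4), c("d1", "d2")))
#' digitalize(S, q = 0.5)  # d1: c1,c2 sensitive; d2: c3,c4 sensitive
#' @export
digitalize <- function(sensitivity, q = 0.5, threshold = NULL) {
  stopifnot(is.matrix(sensitivity))
  if (is.null(threshold) && (q < 0 || q > 1)) {
    stop("quantile `q` must lie in [0, 1]", call. = FALSE)
  }
  n_obs <- colSums(!is.na(sensitivity))
  if (any(n_obs == 0L)) {
    stop(sprintf("drug(s) with all sensitivities missing: %s",
                 paste(colnames(sensitivity)[n_obs == 0L], collapse = ", ")),
         call. = FALSE)
  }
  if (any(n_obs < 4L)) {
    stop(sprintf("drug(s) with fewer than 4 measurements: %s",
                 paste(colnames(sensitivity)[n_obs < 4L], collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(threshold)) {
    thresholds <- apply(sensitivity, 2L, stats::quantile, probs = q,
                        na.rm = TRUE, names = FALSE)
  } else {
    thresholds <- rep(threshold, ncol(sensitivity))
  }
  names(thresholds) <- colnames(sensitivity)

  idx <- which(!is.na(sensitivity), arr.ind = TRUE)
  out <- data.frame(
    cell_id = rownames(sensitivity)[idx[, 1L]],
    drug_id = colnames(sensitivity)[idx[, 2L]],
    label = as.integer(sensitivity[idx] <= thresholds[idx[, 2L]]),
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$drug_id, colnames(sensitivity)),
                   match(out$cell_id, rownames(sensitivity))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  attr(out, "rule") <- if (is.null(threshold)) {
    list(kind = "quantile", q = q)
  } else {
    list(kind = "global", threshold = threshold)
  }
  class(out) <- c("labeled_pairs", "data.frame")
  out
}
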