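#' Predict drug sensitivities for new patients
#'
#' Projects each patient's mutation profile onto the training cells via the
#' genomic kernel, concatenates it with each drug's chemical-kernel row,
#' and scores every (patient, drug) pair with the trained classifier. No
#' refit is required. Scores are the classifier's sensitive-class
#' probability in `[0, 1]`; drugs are ranked within each patient
#' (rank 1 = most promising), ties broken lexicographically by drug id.
#'
#' @param object A [fit_drug_response()] model.
#' @param mutations Binary patients x genes matrix on the training gene
#'   panel (rownames = patient ids).
#' @param fingerprints Optional drugs x bits matrix; defaults to the
#'   training drug library.
#' @param classes Optional drug class labels; defaults to the model's.
#' @param ... Unused.
#' @return A data.frame of class `prediction_table` with columns
#'   `patient_id`, `drug_id`, `drug_class`, `score`, `rank` — complete over
#'   patients x drugs.
#' @export
predict.drug_response_model <- function(object, mutations,
                                        fingerprints = NULL, classes = NULL,
                                        ...) {
  if (is.null(fingerprints)) fingerprints <- object$fingerprints
  if (is.null(classes)) classes <- object$classes
  if (!identical(colnames(mutations), colnames(object$mutations))) {
    stop("patient profiles are not on the training gene panel", call. = FALSE)
  }
  if (ncol(fingerprints) != ncol(object$fingerprints)) {
    stop("fingerprint length differs from training", call. = FALSE)
  }
  patients <- rownames(mutations)
  drugs <- rownames(fingerprints)
  if (is.null(patients) || is.null(drugs)) {
    stop("mutation and fingerprint matrices need rownames", call. = FALSE)
  }

  Kg_new <- genomic_kernel(mutations, anchors = object$mutations,
                           method = object$kernel)
  Kc_new <- chemical_kernel(fingerprints, anchors = object$fingerprints,
                            method = object$kernel)
  pid <- rep(patients, each = length(drugs))
  did <- rep(drugs, times = length(patients))
  X <- pair_features(pid, did, Kg_new, Kc_new,
                     anchor_cells = object$anchors$cells,
                     anchor_drugs = object$anchors$drugs)
  raw <- score_backend(object$model_kind, object$fit, X)
  score <- if (object$model_kind == "svm") apply_platt(object$platt, raw) else raw

  drug_class <- if (is.null(classes)) NA_character_ else unname(classes[did])
  out <- data.frame(patient_id = pid, drug_id = did, drug_class = drug_class,
                    score = score, stringsAsFactors = FALSE)
  out$rank <- stats::ave(seq_len(nrow(out)), out$patient_id,
                         FUN = function(i) {
                           o <- order(-out$score[i], out$drug_id[i])
                           r <- integer(length(i)); r[o] <- seq_along(i); r
                         })
  rownames(out) <- NULL
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Summarize predictions by drug mechanism class
#'
#' Averages each patient's predicted sensitivity scores within each drug
#' mechanism class and assigns the patient to the highest-scoring class
#' (the grouping used to read per-patient therapy predictions by
#' kinase-inhibitor type). A hierarchical-clustering mode (average linkage
#' on Euclidean distances between class-score rows) is available for
#' heatmap-style grouping.
#'
#' @param preds A [predict.drug_response_model()] prediction table; every
#'   drug must carry a class label.
#' @param method `"argmax"` (default) or `"hclust"`.
#' @param k Number of clusters when `method = "hclust"`; defaults to the
#'   number of classes.
#' @return A list with `class_scores` (patients x classes mean-score
#'   matrix), `assignment` (named character vector patient -> class for
#'   `"argmax"`, or integer cluster ids for `"hclust"`), and `hclust` (the
#'   dendrogram, `"hclust"` only).
#' @export
group_by_class <- function(preds, method = c("argmax", "hclust"), k = NULL) {
  method <- match.arg(method)
  if (any(is.na(preds$drug_class))) {
    stop("unlabeled drug(s) in prediction table", call. = FALSE)
  }
  patients <- unique(preds$patient_id)
  classes <- sort(unique(preds$drug_class))
  class_scores <- matrix(NA_real_, length(patients), length(classes),
                         dimnames = list(patients, classes))
  agg <- stats::aggregate(score ~ patient_id + drug_class, data = preds, FUN = mean)
  class_scores[cbind(agg$patient_id, agg$drug_class)] <- agg$score

  if (method == "argmax") {
    assignment <- classes[max.col(class_scores, ties.method = "first")]
    names(assignment) <- patients
    list(class_scores = class_scores, assignment = assignment)
  } else {
    if (is.null(k)) k <- length(classes)
    hc <- stats::hclust(stats::dist(class_scores), method = "average")
    assignment <- stats::cutree(hc, k = min(k, length(patients)))
    list(class_scores = class_scores, assignment = assignment, hclust = hc)
  }
}
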