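#' Fit the kernel-based drug response model
#'
#' The central fitting function. Builds the genomic (Jaccard) kernel over
#' training cells and the chemical (Tanimoto) kernel over drugs,
#' digitalizes the dose-response AUC matrix into binary sensitive/resistant
#' edge labels on the cell-drug bipartite graph, represents every labeled
#' pair by its anchor-similarity feature vector, and trains a classifier —
#' random forest (`"rf"`), RBF support vector machine (`"svm"`) or a
#' single-hidden-layer feed-forward network (`"dn"`) — with seeded,
#' stratified k-fold cross-validation. For the SVM, the cost and RBF width
#' are tuned by grid search over `grid`, selecting the point with the best
#' mean held-out AUROC (ties broken toward the smallest cost, then the
#' smallest width). The final model is refit on all data at the selected
#' point.
#'
#' @param mutations Binary cells x genes mutation matrix (rownames = cell
#'   ids matching `rownames(sensitivity)`).
#' @param fingerprints Binary drugs x bits fingerprint matrix (rownames =
#'   drug ids matching `colnames(sensitivity)`).
#' @param sensitivity Cells x drugs dose-response AUC matrix, `NA` for
#'   unmeasured pairs. Lower AUC = more sensitive.
#' @param classes Optional named character vector drug id -> mechanism
#'   class, carried through to predictions.
#' @param model `"rf"`, `"svm"` or `"dn"`.
#' @param q Per-drug digitalization quantile (default median); see
#'   [digitalize()].
#' @param threshold Optional global digitalization threshold overriding `q`.
#' @param grid Hyperparameter grid (data.frame). Defaults: for `"svm"`,
#'   `cost` in \{0.01, 0.1, 1, 10, 100\} x `gamma` in \{1e-3, 1e-2, 0.1, 1,
#'   10\}; for `"rf"`, a single point with 500 trees and default mtry; for
#'   `"dn"`, a single 64-unit hidden layer. Pass a smaller grid to trade
#'   search breadth for speed.
#' @param folds Number of cross-validation folds (default 5).
#' @param cv Cross-validation unit: `"pair"` (default; matches the
#'   bipartite evaluation, but leaks cell identity across folds) or
#'   `"cell"` (leave-cells-out; honest for new-patient generalization).
#' @param kernel `"jaccard"` (default) or `"gaussian"`; applied to both
#'   kernels.
#' @param seed Integer seed controlling fold assignment and model fitting.
#' @return An object of class `drug_response_model` with components
#'   `model_kind`, `fit` (opaque backend fit), `hyperparameters`, `cv_auc`
#'   (mean held-out AUROC at the selected point), `cv_table` (full grid
#'   results), `anchors`, `thresholds`, and the training kernels. Methods:
#'   [predict.drug_response_model()], `print`, `summary`, `fitted`.
#' @examples
#' \donttest{
#' cohort <- simulate_pdc_cohort(sim_config(n_cells = 60, n_drugs = 12,
#'                                          n_genes = 40, n_classes = 3,
#'                                          seed = 11))
#' fit <- fit_drug_response(cohort$mutations, cohort$fingerprints,
#'                          cohort$sensitivity, classes = cohort$classes,
#'                          model = "rf", seed = 11)
#' fit$cv_auc
#' }
#' @export
fit_drug_response <- function(mutations, fingerprints, sensitivity,
                              classes = NULL,
                              model = c("rf", "svm", "dn"),
                              q = 0.5, threshold = NULL,
                              grid = NULL, folds = 5L,
                              cv = c("pair", "cell"),
                              kernel = c("jaccard", "gaussian"),
                              seed = 1L) {
  model <- match.arg(model)
  cv <- match.arg(cv)
  kernel <- match.arg(kernel)
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  if (!identical(rownames(mutations), rownames(sensitivity))) {
    stop("rownames(mutations) must equal rownames(sensitivity)", call. = FALSE)
  }
  if (!identical(rownames(fingerprints), colnames(sensitivity))) {
    stop("rownames(fingerprints) must equal colnames(sensitivity)", call. = FALSE)
  }

  labels <- digitalize(sensitivity, q = q, threshold = threshold)
  y <- labels$label
  if (length(unique(y)) < 2L) {
    stop("single-class training labels; adjust the digitalization rule",
         call. = FALSE)
  }

  Kg <- genomic_kernel(mutations, method = kernel)
  Kc <- chemical_kernel(fingerprints, method = kernel)
  X <- pair_features(labels$cell_id, labels$drug_id, Kg, Kc)
  if (anyNA(X) || any(!is.finite(X))) {
    stop("non-finite pair features", call. = FALSE)
  }

  if (is.null(grid)) grid <- default_grid(model)
  grid <- order_grid(grid)

  # class weights only for non-median digitalization (imbalance expected)
  weights <- NULL
  rule <- attr(labels, "rule")
  if (rule$kind != "quantile" || !isTRUE(all.equal(rule$q, 0.5))) {
    prev <- mean(y)
    weights <- ifelse(y == 1L, 0.5 / prev, 0.5 / (1 - prev))
  }

  fold_id <- assign_folds(labels, folds, cv, seed)

  cv_table <- grid
  cv_table$cv_auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    fold_auc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit_f <- fit_backend(model, X[tr, , drop = FALSE], y[tr],
                           grid[g, , drop = FALSE], weights[tr],
                           seed = substream_seed(seed, sprintf("fold%d", f)))
      sc <- score_backend(model, fit_f, X[!tr, , drop = FALSE])
      fold_auc[f] <- auroc(sc, y[!tr])
    }
    cv_table$cv_auc[g] <- mean(fold_auc)
  }
  best <- which.max(cv_table$cv_auc)  # grid pre-ordered: first max wins ties

  final <- fit_backend(model, X, y, grid[best, , drop = FALSE], weights,
                       seed = substream_seed(seed, "final"))
  raw <- score_backend(model, final, X)
  platt <- NULL
  if (model == "svm") {
    platt <- fit_platt(raw, y)
    fitted_scores <- apply_platt(platt, raw)
  } else {
    fitted_scores <- raw
  }
  names(fitted_scores) <- rownames(X)

  structure(
    list(
      model_kind = model,
      fit = final,
      platt = platt,
      hyperparameters = as.list(grid[best, , drop = FALSE]),
      cv_auc = cv_table$cv_auc[best],
      cv_table = cv_table,
      cv_unit = cv,
      folds = folds,
      anchors = list(cells = rownames(mutations),
                     drugs = rownames(fingerprints)),
      mutations = mutations,
      fingerprints = fingerprints,
      classes = classes,
      kernel = kernel,
      Kg = Kg,
      Kc = Kc,
      labels = labels,
      thresholds = attr(labels, "thresholds"),
      rule = rule,
      fitted = fitted_scores,
      seed = as.integer(seed),
      call = match.call()
    ),
    class = "drug_response_model"
  )
}

default_grid <- function(model) {
  switch(model,
    svm = expand.grid(cost = c(0.01, 0.1, 1, 10, 100),
                      gamma = c(1e-3, 1e-2, 0.1, 1, 10)),
    rf = data.frame(num_trees = 500),
    dn = data.frame(size = 64, decay = 0.01)
  )
}

order_grid <- function(grid) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  if (all(c("cost", "gamma") %in% names(grid))) {
    grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  }
  rownames(grid) <- NULL
  grid
}

# Stratified (by label) or cell-grouped fold assignment, seeded.
assign_folds <- function(labels, folds, cv, seed) {
  set.seed(substream_seed(seed, "folds"))
  n <- nrow(labels)
  fold_id <- integer(n)
  if (cv == "pair") {
    for (lv in unique(labels$label)) {
      i <- which(labels$label == lv)
      fold_id[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  } else {
    cells <- unique(labels$cell_id)
    cell_fold <- sample(rep_len(seq_len(folds), length(cells)))
    names(cell_fold) <- cells
    fold_id <- cell_fold[labels$cell_id]
  }
  fold_id
}

fit_backend <- function(kind, X, y, params, weights, seed) {
  yf <- factor(y, levels = c("0", "1"))
  if (kind == "rf") {
    ranger::ranger(
      y = yf, x = as.data.frame(X),
      num.trees = params$num_trees %||% 500,
      probability = TRUE, num.threads = 1L, seed = seed,
      case.weights = weights
    )
  } else if (kind == "svm") {
    cw <- NULL
    if (!is.null(weights)) {
      cw <- c("0" = 0.5 / mean(y == 0L), "1" = 0.5 / mean(y == 1L))
    }
    e1071::svm(X, yf, kernel = "radial",
               cost = params$cost %||% 1,
               gamma = params$gamma %||% (1 / ncol(X)),
               class.weights = cw)
  } else {
    set.seed(seed)
    w <- if (is.null(weights)) rep(1, length(y)) else weights
    nnet::nnet(x = X, y = y, weights = w,
               size = params$size %||% 64, decay = params$decay %||% 0.01,
               maxit = 200, entropy = TRUE, trace = FALSE, MaxNWts = 1e6)
  }
}

# Raw sensitivity scores: RF/DN probabilities, SVM decision values oriented
# so that larger = more likely sensitive.
score_backend <- function(kind, fit, X) {
  if (kind == "rf") {
    unname(predict(fit, as.data.frame(X), num.threads = 1L)$predictions[, "1"])
  } else if (kind == "svm") {
    dvm <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
    dv <- dvm[, 1L]
    # libsvm orients decision values toward the first class seen in the
    # training data; the column name ("a/b") records that orientation
    if (!startsWith(colnames(dvm)[1L], "1/")) dv <- -dv
    unname(dv)
  } else {
    unname(predict(fit, X)[, 1L])
  }
}

# Deterministic Platt scaling: logistic regression of the labels on the
# decision values, mapping SVM scores into [0, 1].
fit_platt <- function(dv, y) {
  co <- suppressWarnings(
    stats::glm.fit(cbind(1, dv), y, family = stats::binomial())$coefficients
  )
  if (anyNA(co) || !all(is.finite(co))) co <- c(0, 1)
  co
}

apply_platt <- function(co, dv) {
  stats::plogis(co[1L] + co[2L] * dv)
}

#' Held-out AUROC of a trained response model
#'
#' Scores a set of labeled (cell, drug) pairs with the trained classifier
#' and returns the rank-based AUROC. Pair features are rebuilt from the
#' model's training kernels, so the ids must be training cells and drugs;
#' for new patients use [predict.drug_response_model()].
#'
#' @param model A [fit_drug_response()] result.
#' @param pairs A `labeled_pairs` data.frame (`cell_id`, `drug_id`,
#'   `label`).
#' @param features Optional precomputed pair-feature matrix (rows matching
#'   `pairs`).
#' @return AUROC in `[0, 1]`.
#' @export
evaluate_auc <- function(model, pairs, features = NULL) {
  stopifnot(inherits(model, "drug_response_model"))
  if (length(unique(pairs$label)) < 2L) {
    stop("evaluation set has a single class", call. = FALSE)
  }
  if (is.null(features)) {
    features <- pair_features(pairs$cell_id, pairs$drug_id, model$Kg, model$Kc,
                              anchor_cells = model$anchors$cells,
                              anchor_drugs = model$anchors$drugs)
  }
  auroc(score_backend(model$model_kind, model$fit, features), pairs$label)
}

#' @export
fitted.drug_response_model <- function(object, ...) object$fitted

#' @export
print.drug_response_model <- function(x, ...) {
  cat(sprintf("Kernel-based drug response model (%s)\n", toupper(x$model_kind)))
  cat(sprintf("  training : %d cells x %d drugs, %d labeled pairs\n",
              length(x$anchors$cells), length(x$anchors$drugs),
              nrow(x$labels)))
  hp <- paste(names(x$hyperparameters),
              unlist(x$hyperparameters), sep = " = ", collapse = ", ")
  cat(sprintf("  selected : %s\n", hp))
  cat(sprintf("  CV AUROC : %.3f (%d-fold, %s-level folds)\n",
              x$cv_auc, x$folds, x$cv_unit))
  invisible(x)
}

#' @export
summary.drug_response_model <- function(object, ...) {
  structure(
    list(model = object, prevalence = mean(object$labels$label),
         cv_table = object$cv_table),
    class = "summary.drug_response_model"
  )
}

#' @export
print.summary.drug_response_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  sensitive-label prevalence: %.3f\n", x$prevalence))
  if (nrow(x$cv_table) > 1L) {
    cat("  grid search (held-out AUROC):\n")
    print(x$cv_table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
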