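test_that("rank-based AUROC matches the brute-force pairwise oracle", {
  expect_identical(auroc(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0.5)
  expect_identical(auroc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # 4-pair toy with one inversion: pairs (0.9+,0.2-,0.4+,0.6-)
  expect_identical(auroc(c(0.9, 0.2, 0.4, 0.6), c(1, 0, 1, 0)),
                   brute_force_auroc(c(0.9, 0.2, 0.4, 0.6), c(1, 0, 1, 0)))
  set.seed(4)
  for (rep in 1:100) {
    n <- sample(4:200, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(auroc(scores, labels), brute_force_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  # independent library cross-check
  set.seed(9)
  s <- runif(60); y <- rbinom(60, 1, 0.4)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("digitalization thresholds per drug with <= boundary", {
  S <- cbind(d1 = c(1, 2, 3, 4), d2 = c(5, 5, 5, 5))
  rownames(S) <- paste0("c", 1:4)
  lp <- digitalize(S, q = 0.5)
  d1 <- lp[lp$drug_id == "d1", ]
  expect_identical(d1$label[match(paste0("c", 1:4), d1$cell_id)],
                   c(1L, 1L, 0L, 0L))  # median 2.5
  # constant column: every value equals the threshold, all sensitive
  expect_true(all(lp$label[lp$drug_id == "d2"] == 1L))
  expect_equal(unname(attr(lp, "thresholds")), c(2.5, 5))

  S_na <- S; S_na[1, 1] <- NA
  expect_error(digitalize(S_na), "fewer than 4")
  S_allna <- S; S_allna[, 1] <- NA
  expect_error(digitalize(S_allna), "d1")
  expect_error(digitalize(S, q = 2), "\\[0, 1\\]")
})

test_that("noiseless planted labels equal the planted sensitivity indicator", {
  co <- tiny_cohort(noise_sd = 0, seed = 14)
  cfg <- co$config
  target <- co$rule$class_target[co$classes]
  names(target) <- names(co$classes)
  planted_of <- function(lp) {
    mapply(function(c, d) co$mutations[c, target[d]], lp$cell_id, lp$drug_id)
  }
  # a global threshold between the two noiseless levels recovers the rule
  lp <- digitalize(co$sensitivity,
                   threshold = cfg$baseline_auc - cfg$effect_size / 2)
  expect_identical(lp$label, as.integer(planted_of(lp)))
  # the per-drug median split agrees wherever the sensitive fraction is at
  # least half (the <= boundary otherwise absorbs the resistant mode)
  lpq <- digitalize(co$sensitivity, q = 0.5)
  prev <- colMeans(co$mutations[, target, drop = FALSE])
  ok_drugs <- names(co$classes)[prev >= 0.5]
  sub <- lpq[lpq$drug_id %in% ok_drugs, ]
  expect_identical(sub$label, as.integer(planted_of(sub)))
})

test_that("grid search selects by held-out AUROC with deterministic tie-breaks", {
  co <- tiny_cohort(seed = 11)
  grid <- expand.grid(cost = c(0.1, 1), gamma = c(0.01, 0.1))
  fit <- fit_drug_response(co$mutations, co$fingerprints, co$sensitivity,
                           model = "svm", grid = grid, seed = 11)
  expect_identical(nrow(fit$cv_table), 4L)
  expect_identical(fit$cv_auc, max(fit$cv_table$cv_auc))
  chosen <- which(fit$cv_table$cv_auc == fit$cv_auc)
  # ties (if any) resolve to the smallest cost, then smallest gamma
  expect_identical(unlist(fit$hyperparameters),
                   unlist(fit$cv_table[min(chosen), c("cost", "gamma")]))
})

test_that("training is deterministic for a fixed seed", {
  co <- tiny_cohort(seed = 11)
  args <- list(co$mutations, co$fingerprints, co$sensitivity, model = "rf",
               seed = 99)
  f1 <- do.call(fit_drug_response, args)
  f2 <- do.call(fit_drug_response, args)
  expect_identical(f1$cv_auc, f2$cv_auc)
  expect_identical(f1$fitted, f2$fitted)
  sv1 <- fit_drug_response(co$mutations, co$fingerprints, co$sensitivity,
                           model = "svm",
                           grid = data.frame(cost = 1, gamma = 0.01), seed = 99)
  sv2 <- fit_drug_response(co$mutations, co$fingerprints, co$sensitivity,
                           model = "svm",
                           grid = data.frame(cost = 1, gamma = 0.01), seed = 99)
  expect_identical(sv1$hyperparameters, sv2$hyperparameters)
  expect_identical(sv1$cv_auc, sv2$cv_auc)
  expect_identical(sv1$fitted, sv2$fitted)
})

test_that("cv_auc responds monotonically to effect size", {
  aucs <- vapply(c(0, 0.25, 0.5), function(es) {
    co <- tiny_cohort(seed = 33, effect_size = es)
    fit_drug_response(co$mutations, co$fingerprints, co$sensitivity,
                      model = "rf", seed = 33)$cv_auc
  }, numeric(1))
  expect_gte(aucs[2], aucs[1] - 0.02)
  expect_gte(aucs[3], aucs[2] - 0.02)
  expect_gt(aucs[3], 0.8)
  # no signal to learn when effect_size is zero
  expect_gte(aucs[1], 0.40)
  expect_lte(aucs[1], 0.60)
})

test_that("degenerate training inputs are rejected", {
  co <- tiny_cohort(seed = 11)
  constant <- matrix(0.5, nrow(co$sensitivity), ncol(co$sensitivity),
                     dimnames = dimnames(co$sensitivity))
  expect_error(fit_drug_response(co$mutations, co$fingerprints, constant,
                                 model = "rf"),
               "single-class")
  expect_error(fit_drug_response(co$mutations[-1, ], co$fingerprints,
                                 co$sensitivity),
               "rownames")
  expect_error(fit_drug_response(co$mutations, co$fingerprints,
                                 co$sensitivity, folds = 1),
               "folds")
})

test_that("evaluate_auc scores labeled pairs through the fitted model", {
  co <- tiny_cohort(seed = 11)
  fit <- fit_drug_response(co$mutations, co$fingerprints, co$sensitivity,
                           model = "rf", seed = 11)
  lp <- fit$labels
  full <- evaluate_auc(fit, lp)
  expect_gte(full, 0.9)  # in-sample by construction
  single <- lp[lp$label == 1, ]
  expect_error(evaluate_auc(fit, single), "single class")
})

test_that("leave-cells-out folds never split a cell across folds", {
  co <- tiny_cohort(seed = 11)
  fit <- fit_drug_response(co$mutations, co$fingerprints, co$sensitivity,
                           model = "rf", cv = "cell", seed = 11)
  expect_true(fit$cv_auc > 0 && fit$cv_auc < 1)
  expect_identical(fit$cv_unit, "cell")
})

test_that("the optional feed-forward network runs behind the same interface", {
  co <- tiny_cohort(seed = 11)
  fit <- fit_drug_response(co$mutations, co$fingerprints, co$sensitivity,
                           model = "dn", grid = data.frame(size = 8, decay = 0.1),
                           seed = 11)
  expect_s3_class(fit, "drug_response_model")
  expect_true(all(fit$fitted >= 0 & fit$fitted <= 1))
  expect_gt(fit$cv_auc, 0.6)
})
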