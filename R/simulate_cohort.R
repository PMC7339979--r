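#' Simulate a patient-derived-cell pharmacogenomics cohort
#'
#' Generates the full training resource for the response model: a binary
#' somatic-mutation matrix over the gene panel, a drug library with
#' mechanism-class labels and class-structured chemical fingerprints, a
#' cells-by-drugs dose-response AUC matrix with missing entries, and the
#' planted genotype-to-class sensitivity rule that serves as recoverable
#' ground truth.
#'
#' Each mechanism class is assigned one distinct panel gene (its target).
#' Cells mutated in the target gene of a drug's class have their
#' dose-response AUC lowered by `effect_size` (lower AUC = more sensitive,
#' the CTRP convention, recorded in the returned rule). Fingerprints carry a
#' block of class-specific "core" bits that are always set, so within-class
#' Tanimoto similarity exceeds between-class similarity in expectation.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `pdc_cohort`: a list with elements
#'   \describe{
#'     \item{mutations}{binary `n_cells x n_genes` matrix, dimnames set.}
#'     \item{fingerprints}{binary `n_drugs x fingerprint_len` matrix.}
#'     \item{classes}{named character vector, drug id -> class label.}
#'     \item{sensitivity}{`n_cells x n_drugs` numeric matrix with `NA` for
#'       masked entries.}
#'     \item{rule}{list with `class_target` (class -> gene) and
#'       `direction = "lower_is_sensitive"`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' cohort <- simulate_pdc_cohort(sim_config(n_cells = 12, n_drugs = 6,
#'                                          n_genes = 20, n_classes = 3))
#' dim(cohort$sensitivity)
#' cohort$rule$class_target
#' @export
simulate_pdc_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg <- validate_sim_config(cfg)

  panel <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  cell_ids <- sprintf("PDC%03d", seq_len(cfg$n_cells))
  drug_ids <- sprintf("DRUG%02d", seq_len(cfg$n_drugs))
  class_labels <- sprintf("class%02d", seq_len(cfg$n_classes))

  set.seed(substream_seed(cfg$seed, "cohort"))

  mutations <- matrix(
    rbinom(cfg$n_cells * cfg$n_genes, 1L, cfg$mutation_rate),
    nrow = cfg$n_cells, dimnames = list(cell_ids, panel)
  )

  # one distinct target gene per class
  target_genes <- sample(panel, cfg$n_classes)
  names(target_genes) <- class_labels

  classes <- rep_len(class_labels, cfg$n_drugs)
  names(classes) <- drug_ids

  # class-specific core bits (always set) + random background bits
  core_len <- max(1L, cfg$fingerprint_len %/% max(4L, cfg$n_classes))
  fingerprints <- matrix(
    rbinom(cfg$n_drugs * cfg$fingerprint_len, 1L, 0.3),
    nrow = cfg$n_drugs,
    dimnames = list(drug_ids, sprintf("bit%03d", seq_len(cfg$fingerprint_len)))
  )
  for (j in seq_len(cfg$n_drugs)) {
    k <- match(classes[j], class_labels)
    core <- ((k - 1L) * core_len + 1L):(k * core_len)
    fingerprints[j, core] <- 1L
  }

  sensitive <- mutations[, target_genes[classes], drop = FALSE]
  sensitivity <- cfg$baseline_auc - cfg$effect_size * sensitive +
    matrix(rnorm(cfg$n_cells * cfg$n_drugs, 0, cfg$noise_sd), nrow = cfg$n_cells)
  dimnames(sensitivity) <- list(cell_ids, drug_ids)
  if (cfg$missing_frac > 0) {
    mask <- matrix(runif(length(sensitivity)) < cfg$missing_frac,
                   nrow = nrow(sensitivity))
    sensitivity[mask] <- NA_real_
  }

  structure(
    list(
      mutations = mutations,
      fingerprints = fingerprints,
      classes = classes,
      sensitivity = sensitivity,
      rule = list(class_target = target_genes,
                  direction = "lower_is_sensitive"),
      config = cfg
    ),
    class = "pdc_cohort"
  )
}

#' @export
print.pdc_cohort <- function(x, ...) {
  cat(sprintf("PDC cohort: %d cells x %d drugs, %d-gene panel, %d classes\n",
              nrow(x$mutations), length(x$classes), ncol(x$mutations),
              length(x$rule$class_target)))
  cat(sprintf("  sensitivity: %.1f%% missing; %s\n",
              100 * mean(is.na(x$sensitivity)), x$rule$direction))
  invisible(x)
}

#' Simulate patient mutation profiles with a planted sensitive class
#'
#' Draws patient profiles on the cohort's gene panel: background mutations
#' at the cohort mutation rate, with the target gene of the patient's
#' assigned drug class forced to mutated and the other class targets forced
#' to wild type, so each patient's planted class is unambiguous while the
#' profile stays within the cohort's similarity distribution.
#'
#' @param cohort A [simulate_pdc_cohort()] result.
#' @param n_patients Number of patients.
#' @param classes Optional class assignment (recycled); default cycles
#'   through the cohort's classes.
#' @param seed Integer seed.
#' @return Binary `n_patients x n_genes` matrix with attribute
#'   `planted_class` (character vector of assigned class labels).
#' @export
simulate_patient_profiles <- function(cohort, n_patients, classes = NULL,
                                      seed = 1L) {
  stopifnot(inherits(cohort, "pdc_cohort"))
  cfg <- cohort$config
  class_labels <- names(cohort$rule$class_target)
  if (is.null(classes)) classes <- rep_len(class_labels, n_patients)
  classes <- rep_len(as.character(classes), n_patients)
  if (!all(classes %in% class_labels)) {
    stop("unknown class label in `classes`", call. = FALSE)
  }
  set.seed(substream_seed(seed, "patients"))
  panel <- colnames(cohort$mutations)
  profiles <- matrix(
    rbinom(n_patients * length(panel), 1L, cfg$mutation_rate),
    nrow = n_patients,
    dimnames = list(sprintf("PAT%03d", seq_len(n_patients)), panel)
  )
  targets <- cohort$rule$class_target
  profiles[, targets] <- 0L
  for (i in seq_len(n_patients)) {
    profiles[i, targets[classes[i]]] <- 1L
  }
  attr(profiles, "planted_class") <- classes
  profiles
}
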