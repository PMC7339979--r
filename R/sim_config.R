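#' Ordered single-base substitution types
#'
#' The 12 ordered substitution types used throughout the package, in the
#' fixed order `A>C, A>G, A>T, C>A, C>G, C>T, G>A, G>C, G>T, T>A, T>C, T>G`.
#' Spectra are tallied without pyrimidine-strand collapsing, so `C>T` and
#' `G>A` are counted separately.
#'
#' @return Character vector of length 12.
#' @export
substitution_types <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (r in bases) for (a in bases) if (r != a) out <- c(out, paste0(r, ">", a))
  out
}

#' Canonical human chromosome labels
#'
#' `chr1` through `chr22`, `chrX`, `chrY` in karyotype order.
#'
#' @return Character vector of length 24.
#' @export
canonical_chromosomes <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

# Approximate hg38 chromosome lengths in Mb, used only as sampling weights.
.chrom_lengths_mb <- c(
  249, 242, 198, 190, 182, 171, 159, 145, 138, 134,
  135, 133, 114, 107, 102, 90, 83, 80, 59, 64,
  47, 51, 156, 57
)

#' Default substitution-type probabilities
#'
#' A transition-dominated spectrum: `C>T` and `G>A` each carry probability
#' 0.25 and the remaining ten types 0.05 each, emulating the
#' C-to-T/G-to-A-dominated spectra typical of gastric tumour exomes.
#'
#' @return Named numeric vector of length 12 summing to 1.
#' @export
default_spectrum_probs <- function() {
  p <- rep(0.05, 12)
  names(p) <- substitution_types()
  p[c("C>T", "G>A")] <- 0.25
  p
}

#' Default per-chromosome sampling weights
#'
#' Proportional to approximate hg38 chromosome lengths, with chromosome 7
#' up-weighted threefold to emulate the chr7 SNP enrichment observed in
#' plateau gastric-cancer patients.
#'
#' @return Named non-negative numeric vector of length 24.
#' @export
default_chrom_weights <- function() {
  w <- .chrom_lengths_mb
  names(w) <- canonical_chromosomes()
  w["chr7"] <- 3 * w["chr7"]
  w
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic pharmacogenomics and variant
#' generators. Defaults mirror the scale of the PDC training resource
#' (462 cells, 60 small molecules, a 91-gene somatic panel) and a planted
#' genotype-to-drug-class sensitivity rule that downstream stages can
#' recover.
#'
#' @param n_cells Number of patient-derived cells.
#' @param n_drugs Number of drugs.
#' @param n_genes Gene-panel size.
#' @param n_classes Number of drug mechanism classes; each class is assigned
#'   one distinct target gene in the panel.
#' @param fingerprint_len Fingerprint length in bits.
#' @param mutation_rate Per-gene, per-cell mutation probability. The default
#'   0.5 makes per-gene prevalence commensurate with the median
#'   digitalization split, so the planted rule is recoverable from labels.
#' @param effect_size Downward shift of dose-response AUC for
#'   (mutated-target, matching-class) pairs, in AUC units.
#' @param noise_sd Gaussian noise SD added to every dose-response AUC.
#' @param missing_frac Fraction of sensitivity entries masked at random.
#' @param baseline_auc Dose-response AUC of an insensitive pair before noise.
#' @param spectrum_probs Probabilities over the 12 ordered substitution
#'   types (see [substitution_types()]); must sum to 1.
#' @param per_chrom_weights Non-negative sampling weights over the 24
#'   canonical chromosomes.
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_cells = 20, n_drugs = 8, n_genes = 30, n_classes = 4)
#' cfg
#' @export
sim_config <- function(n_cells = 462L,
                       n_drugs = 60L,
                       n_genes = 91L,
                       n_classes = 6L,
                       fingerprint_len = 128L,
                       mutation_rate = 0.5,
                       effect_size = 0.5,
                       noise_sd = 0.1,
                       missing_frac = 0.1,
                       baseline_auc = 0.6,
                       spectrum_probs = default_spectrum_probs(),
                       per_chrom_weights = default_chrom_weights(),
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_drugs = as.integer(n_drugs),
    n_genes = as.integer(n_genes), n_classes = as.integer(n_classes),
    fingerprint_len = as.integer(fingerprint_len),
    mutation_rate = mutation_rate, effect_size = effect_size,
    noise_sd = noise_sd, missing_frac = missing_frac,
    baseline_auc = baseline_auc,
    spectrum_probs = spectrum_probs,
    per_chrom_weights = per_chrom_weights,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
  }
  counts <- c("n_cells", "n_drugs", "n_genes", "n_classes", "fingerprint_len")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L) stop_field(f, "must be a positive count")
  }
  probs <- c("mutation_rate", "missing_frac")
  for (f in probs) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) stop_field(f, "must be a probability in [0, 1]")
  }
  if (cfg$effect_size < 0 || cfg$effect_size > 1) stop_field("effect_size", "must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop_field("noise_sd", "must be non-negative")
  sp <- cfg$spectrum_probs
  if (length(sp) != 12L || any(sp < 0) || any(sp > 1)) {
    stop_field("spectrum_probs", "must be 12 probabilities in [0, 1]")
  }
  if (abs(sum(sp) - 1) > 1e-9) stop_field("spectrum_probs", "must sum to 1")
  if (is.null(names(sp))) names(cfg$spectrum_probs) <- substitution_types()
  w <- cfg$per_chrom_weights
  if (length(w) != 24L || any(w < 0) || all(w == 0)) {
    stop_field("per_chrom_weights", "must be 24 non-negative weights, not all zero")
  }
  if (is.null(names(w))) names(cfg$per_chrom_weights) <- canonical_chromosomes()
  if (cfg$n_classes > cfg$n_drugs) stop_field("n_classes", "must not exceed n_drugs")
  if (cfg$n_classes > cfg$n_genes) stop_field("n_classes", "must not exceed n_genes")
  if (is.na(cfg$seed)) stop_field("seed", "must be an integer")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  cohort : %d cells x %d drugs (%d classes), %d-gene panel\n",
              x$n_cells, x$n_drugs, x$n_classes, x$n_genes))
  cat(sprintf("  signal : effect %.2f, noise sd %.2f, mutation rate %.2f, missing %.2f\n",
              x$effect_size, x$noise_sd, x$mutation_rate, x$missing_frac))
  cat(sprintf("  drugs  : %d-bit fingerprints\n", x$fingerprint_len))
  cat(sprintf("  seed   : %d\n", x$seed))
  invisible(x)
}

# Derived seed for an independent substream, stable across R versions and
# kept below 2^31.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
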