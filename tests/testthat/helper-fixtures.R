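# Small cohorts used across test files; all generation is seeded in code.

tiny_cfg <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(n_cells = 60L, n_drugs = 12L, n_genes = 40L, n_classes = 3L,
         seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

tiny_cohort <- function(seed = 11L, ...) {
  simulate_pdc_cohort(tiny_cfg(seed = seed, ...))
}

# Independent brute-force AUROC: average over all positive-negative pairs,
# ties counting 1/2.
brute_force_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Variant-table key helper
vkey <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
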