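#' Somatic subtraction of germline variants
#'
#' Returns the tumour records whose `(chrom, pos, ref, alt)` key is absent
#' from the matched germline (blood) calls — the standard tumour-minus-
#' germline definition of a somatic mutation.
#'
#' @param tumor,germline Variant tables for the same patient (data.frames
#'   with `chrom`, `pos`, `ref`, `alt`). When both carry a `genome`
#'   attribute the builds must agree.
#' @return The somatic subset of `tumor`.
#' @examples
#' vs <- simulate_paired_variants(sim_config(seed = 2), 5, 50)
#' som <- somatic_filter(vs$tumor, vs$germline)
#' nrow(som)  # 5
#' @export
somatic_filter <- function(tumor, germline) {
  gb_t <- attr(tumor, "genome"); gb_g <- attr(germline, "genome")
  if (!is.null(gb_t) && !is.null(gb_g) && !identical(gb_t, gb_g)) {
    stop(sprintf("genome build mismatch: tumor %s vs germline %s", gb_t, gb_g),
         call. = FALSE)
  }
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  out <- tumor[!(key(tumor) %in% key(germline)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome") <- gb_t
  out
}

check_chromosomes <- function(chrom) {
  known <- canonical_chromosomes()
  noncanonical <- grepl("^(chrM|MT|M)$|_alt$|_random$|^chrUn", chrom)
  unknown <- !(chrom %in% known) & !noncanonical
  if (any(unknown)) {
    stop(sprintf("unknown chromosome label(s): %s",
                 paste(unique(chrom[unknown]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(noncanonical)) {
    message(sprintf("dropping %d record(s) on non-canonical contigs",
                    sum(noncanonical)))
  }
  !noncanonical
}

#' Per-sample SNP counts along the chromosomes
#'
#' Tallies records per canonical chromosome (chr1-22, X, Y) for each sample.
#' Records on recognized non-canonical contigs (chrM, `*_alt`, `*_random`,
#' `chrUn*`) are dropped with a message; any other label is an error.
#'
#' @param variants A variant table.
#' @return Integer matrix, samples x 24 chromosomes; rows sum to each
#'   sample's (canonical) record count.
#' @export
chrom_distribution <- function(variants) {
  chroms <- canonical_chromosomes()
  samples <- unique(variants$sample_id)
  if (length(samples) == 0L) samples <- "sample1"
  keep <- if (nrow(variants)) check_chromosomes(variants$chrom) else logical(0)
  v <- variants[keep, , drop = FALSE]
  counts <- table(factor(v$sample_id, levels = samples),
                  factor(v$chrom, levels = chroms))
  matrix(as.integer(counts), nrow = length(samples),
         dimnames = list(samples, chroms))
}

#' Per-sample substitution spectrum
#'
#' Counts the 12 ordered single-base substitution types per sample, without
#' pyrimidine-strand collapsing (`C>T` and `G>A` are tallied separately).
#'
#' @param variants A variant table of SNVs.
#' @return Integer matrix, samples x 12 types in [substitution_types()]
#'   order; rows sum to each sample's record count.
#' @export
substitution_spectrum <- function(variants) {
  types <- substitution_types()
  samples <- unique(variants$sample_id)
  if (length(samples) == 0L) samples <- "sample1"
  type <- paste0(variants$ref, ">", variants$alt)
  bad <- !(type %in% types)
  if (any(bad)) {
    stop(sprintf("non-SNV substitution(s): %s",
                 paste(unique(type[bad]), collapse = ", ")), call. = FALSE)
  }
  counts <- table(factor(variants$sample_id, levels = samples),
                  factor(type, levels = types))
  matrix(as.integer(counts), nrow = length(samples),
         dimnames = list(samples, types))
}

as_granges_track <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    x <- as.data.frame(rtracklayer::import(x))
    # rtracklayer returns 1-based closed coordinates
    return(x)
  }
  stopifnot(is.data.frame(x))
  x
}

#' Gene-level mean sequencing depth
#'
#' Length-weighted mean depth per gene from a per-base depth track (the
#' `bedtools genomecov` style of summary): for each gene,
#' `sum(depth x overlap_bp) / sum(gene_bp)`, counting uncovered gene bases
#' as depth 0. Gene intervals are merged per gene before averaging.
#'
#' @param depth A BedGraph-style data.frame (`chrom`, `start`, `end`,
#'   `depth`; 0-based half-open) or a path to a BedGraph file.
#' @param genes A data.frame (`chrom`, `start`, `end`, `gene`; 0-based
#'   half-open) or a path to a BED6/GFF3 file (gene name taken from the
#'   `name`, `Name` or `gene_id` attribute).
#' @return data.frame with `gene`, `mean_depth`, `interval_bp` (merged gene
#'   length).
#' @examples
#' genes <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 400),
#'                     gene = "A")
#' depth <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 400),
#'                     depth = c(10, 20))
#' per_gene_coverage(depth, genes)$mean_depth  # (100*10 + 300*20) / 400
#' @export
per_gene_coverage <- function(depth, genes) {
  if (is.character(depth) && length(depth) == 1L) {
    d <- as.data.frame(rtracklayer::import(depth, format = "bedGraph"))
    depth <- data.frame(chrom = as.character(d$seqnames), start = d$start - 1L,
                        end = d$end, depth = d$score)
  }
  if (is.character(genes) && length(genes) == 1L) {
    g <- as.data.frame(rtracklayer::import(genes))
    name <- g$name %||% g$Name %||% g$gene_id
    if (is.null(name)) stop("gene annotation lacks a name attribute", call. = FALSE)
    genes <- data.frame(chrom = as.character(g$seqnames), start = g$start - 1L,
                        end = g$end, gene = as.character(name))
  }
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(depth)),
            all(c("chrom", "start", "end", "gene") %in% names(genes)))
  if (any(depth$end <= depth$start)) {
    stop("depth track has interval with end <= start (coordinate-system mismatch?)",
         call. = FALSE)
  }

  dgr <- GenomicRanges::GRanges(depth$chrom,
                                IRanges::IRanges(depth$start + 1L, depth$end),
                                depth = depth$depth)
  gene_ids <- unique(genes$gene)
  out <- data.frame(gene = gene_ids, mean_depth = 0, interval_bp = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(gene_ids)) {
    gi <- genes[genes$gene == gene_ids[i], , drop = FALSE]
    ggr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(gi$chrom, IRanges::IRanges(gi$start + 1L, gi$end))
    )
    total_bp <- sum(GenomicRanges::width(ggr))
    hits <- GenomicRanges::findOverlaps(dgr, ggr)
    covered <- 0
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(dgr[S4Vectors::queryHits(hits)],
                                      ggr[S4Vectors::subjectHits(hits)])
      covered <- sum(GenomicRanges::width(ov) *
                       dgr$depth[S4Vectors::queryHits(hits)])
    }
    out$mean_depth[i] <- covered / total_bp
    out$interval_bp[i] <- total_bp
  }
  out
}

#' Binary mutation matrix over a gene panel
#'
#' Builds the sample-by-panel indicator matrix the response model consumes:
#' entry 1 iff the sample carries at least one variant annotated to that
#' panel gene. Variants in off-panel genes are ignored with a message.
#'
#' @param variants A variant table with a `gene` column.
#' @param panel Ordered character vector of unique panel gene names.
#' @param samples Optional sample ordering; defaults to order of appearance.
#' @return Binary integer matrix, samples x panel, with attribute
#'   `n_off_panel`.
#' @export
mutation_matrix <- function(variants, panel, samples = NULL) {
  if (length(panel) == 0L || anyDuplicated(panel)) {
    stop("`panel` must be a non-empty set of unique gene names", call. = FALSE)
  }
  if (is.null(samples)) samples <- unique(variants$sample_id)
  on_panel <- variants$gene %in% panel
  n_off <- sum(!on_panel & !is.na(variants$gene) & variants$gene != "")
  if (n_off > 0L) {
    message(sprintf("mutation_matrix: %d variant(s) in off-panel genes ignored",
                    n_off))
  }
  v <- variants[on_panel, , drop = FALSE]
  counts <- table(factor(v$sample_id, levels = samples),
                  factor(v$gene, levels = panel))
  m <- matrix(as.integer(counts > 0), nrow = length(samples),
              dimnames = list(samples, panel))
  attr(m, "n_off_panel") <- n_off
  m
}

#' Overlap of top-k ranked gene lists
#'
#' Selects the k highest-scoring genes from each table (ties at rank k
#' broken lexicographically by gene name) and returns the intersection —
#' the operation behind comparing top-30 driver-gene lists between cohorts.
#'
#' @param scores_a,scores_b data.frames with columns `gene` and `score`.
#' @param k Depth of each ranked list.
#' @return Sorted character vector of shared genes.
#' @examples
#' a <- data.frame(gene = c("TP53", "RYR2", "EGFR"), score = c(3, 2, 1))
#' b <- data.frame(gene = c("TP53", "KRAS", "RYR2"), score = c(5, 4, 3))
#' topk_overlap(a, b, k = 2)
#' @export
topk_overlap <- function(scores_a, scores_b, k) {
  top_k <- function(tab, which) {
    stopifnot(all(c("gene", "score") %in% names(tab)))
    if (anyDuplicated(tab$gene)) {
      stop(sprintf("duplicate gene names in `%s`", which), call. = FALSE)
    }
    if (k > nrow(tab)) {
      stop(sprintf("k = %d exceeds the %d genes in `%s`", k, nrow(tab), which),
           call. = FALSE)
    }
    tab$gene[order(-tab$score, tab$gene)][seq_len(k)]
  }
  sort(intersect(top_k(scores_a, "scores_a"), top_k(scores_b, "scores_b")))
}
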