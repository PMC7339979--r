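#' Simulate paired tumour/germline variant tables
#'
#' Draws a germline variant set present in both tumour and blood, plus a
#' planted set of tumour-only somatic SNVs, so the somatic subtraction
#' downstream has an exact known answer. Chromosomes are drawn from
#' `cfg$per_chrom_weights`, substitution types from `cfg$spectrum_probs`,
#' and positions are unique per chromosome.
#'
#' @param cfg A [sim_config()].
#' @param n_somatic Number of tumour-only (somatic) SNVs.
#' @param n_germline Number of shared germline SNVs.
#' @param sample_id Sample identifier carried in both tables.
#' @return A list with `tumor`, `germline` and `somatic` variant tables
#'   (data.frames with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, carrying a `genome` attribute). `somatic` is the planted
#'   tumour-only subset.
#' @examples
#' vs <- simulate_paired_variants(sim_config(seed = 4), n_somatic = 5,
#'                                n_germline = 20)
#' nrow(vs$tumor) - nrow(vs$germline)
#' @export
simulate_paired_variants <- function(cfg, n_somatic, n_germline,
                                     sample_id = "S01") {
  stopifnot(inherits(cfg, "sim_config"))
  cfg <- validate_sim_config(cfg)
  if (n_somatic < 0 || n_germline < 0) {
    stop("variant counts must be non-negative", call. = FALSE)
  }
  set.seed(substream_seed(cfg$seed, "variants"))

  n <- n_somatic + n_germline
  chroms <- canonical_chromosomes()
  panel <- sprintf("GENE%03d", seq_len(cfg$n_genes))

  draw <- function(n) {
    if (n == 0L) {
      return(data.frame(sample_id = character(0), chrom = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), gene = character(0),
                        stringsAsFactors = FALSE))
    }
    chrom <- sample(chroms, n, replace = TRUE, prob = cfg$per_chrom_weights)
    type <- sample(names(cfg$spectrum_probs), n, replace = TRUE,
                   prob = cfg$spectrum_probs)
    data.frame(
      sample_id = sample_id,
      chrom = chrom,
      pos = sample.int(5e7L, n, replace = TRUE),
      ref = substr(type, 1L, 1L),
      alt = substr(type, 3L, 3L),
      gene = sample(panel, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }

  v <- draw(n)
  # enforce unique positions per chromosome (redraw clashing positions)
  repeat {
    dup <- duplicated(v[c("chrom", "pos")])
    if (!any(dup)) break
    v$pos[dup] <- sample.int(5e7L, sum(dup), replace = TRUE)
  }
  v <- v[order(match(v$chrom, chroms), v$pos), , drop = FALSE]
  rownames(v) <- NULL

  is_somatic <- rep(FALSE, n)
  if (n_somatic > 0L) is_somatic[sample.int(n, n_somatic)] <- TRUE
  somatic <- v[is_somatic, , drop = FALSE]
  germline <- v[!is_somatic, , drop = FALSE]
  rownames(somatic) <- rownames(germline) <- NULL

  set_genome <- function(x) { attr(x, "genome") <- "hg38"; x }
  list(tumor = set_genome(v), germline = set_genome(germline),
       somatic = set_genome(somatic))
}

#' Write a variant table as minimal VCFv4.2
#'
#' One ALT per record, 1-based positions, gene annotation carried in the
#' `GENE` INFO tag and the genome build in a `##reference` header line.
#'
#' @param variants A variant table (see [simulate_paired_variants()]).
#' @param path Output path.
#' @param genome Genome build written to the header; defaults to the
#'   table's `genome` attribute.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  if (is.null(genome)) genome <- attr(variants, "genome") %||% "hg38"
  sample_id <- if (nrow(variants)) variants$sample_id[1L] else "sample1"
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", genome),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Annotated gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  info <- ifelse(is.na(variants$gene) | variants$gene == "", ".",
                 paste0("GENE=", variants$gene))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t0/1",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  info)
  writeLines(c(header, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read variants from VCF or an annotation table
#'
#' VCF input is parsed with \pkg{vcfR}; multi-allelic records are split into
#' one row per ALT and non-SNV records (indels, MNVs) are dropped with a
#' message. Tab-delimited input must carry columns `chrom`, `pos`, `ref`,
#' `alt` and optionally `sample_id` and `gene`.
#'
#' @param path Path to a `.vcf` or tab-delimited annotation file.
#' @param sample_id Sample identifier to assign when the file does not
#'   provide one; for VCF the genotype column name is used when present.
#' @return A variant table data.frame with attributes `genome` (declared
#'   build, if any) and `n_dropped` (non-SNV records removed).
#' @export
read_variants <- function(path, sample_id = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    read_variants_vcf(path, sample_id)
  } else {
    read_variants_tsv(path, sample_id)
  }
}

read_variants_vcf <- function(path, sample_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    gt_cols <- tryCatch(colnames(vcf@gt), error = function(e) NULL)
    gt_cols <- setdiff(gt_cols, "FORMAT")
    sample_id <- if (length(gt_cols)) gt_cols[1L] else "sample1"
  }
  bad_pos <- which(is.na(suppressWarnings(as.integer(fix$POS))))
  if (length(bad_pos)) {
    stop(sprintf("malformed VCF record at data line %d: non-numeric POS",
                 bad_pos[1L]), call. = FALSE)
  }
  gene <- rep(NA_character_, nrow(fix))
  if (!is.null(fix$INFO)) {
    m <- regmatches(fix$INFO, regexpr("GENE=[^;]+", fix$INFO))
    has <- grepl("GENE=", fix$INFO)
    gene[has] <- sub("GENE=", "", m)
  }
  # split multi-allelic records: one row per ALT
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  out <- data.frame(
    sample_id = sample_id,
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alts),
    gene = ifelse(is.na(gene[idx]), "", gene[idx]),
    stringsAsFactors = FALSE
  )
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  n_dropped <- sum(!snv)
  if (n_dropped > 0L) {
    message(sprintf("read_variants: dropped %d non-SNV record(s)", n_dropped))
  }
  out <- out[snv, , drop = FALSE]
  rownames(out) <- NULL
  meta <- vcf@meta
  ref_line <- grep("^##reference=", meta, value = TRUE)
  if (length(ref_line)) attr(out, "genome") <- sub("^##reference=", "", ref_line[1L])
  attr(out, "n_dropped") <- n_dropped
  out
}

read_variants_tsv <- function(path, sample_id = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("annotation table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(tab$sample_id)) tab$sample_id <- sample_id %||% "sample1"
  if (is.null(tab$gene)) tab$gene <- ""
  out <- tab[c("sample_id", "chrom", "pos", "ref", "alt", "gene")]
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  n_dropped <- sum(!snv)
  if (n_dropped > 0L) {
    message(sprintf("read_variants: dropped %d non-SNV record(s)", n_dropped))
  }
  out <- out[snv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Simulate a per-base depth track over gene intervals
#'
#' Every base of a gene interval receives that gene's target depth;
#' intergenic bases are uncovered (depth 0 and absent from the track).
#' Coordinates are 0-based half-open (BedGraph convention).
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `gene`
#'   (a gene may span several intervals).
#' @param depth Named numeric vector of target depths, names matching
#'   `genes$gene`.
#' @return A BedGraph-style data.frame (`chrom`, `start`, `end`, `depth`).
#' @examples
#' genes <- data.frame(chrom = "chr1", start = c(0, 500), end = c(100, 800),
#'                     gene = c("A", "B"))
#' simulate_coverage(genes, c(A = 10, B = 20))
#' @export
simulate_coverage <- function(genes, depth) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(genes)))
  if (any(genes$end <= genes$start)) {
    stop("degenerate gene interval (end <= start)", call. = FALSE)
  }
  if (is.null(names(depth)) || !all(genes$gene %in% names(depth))) {
    stop("`depth` must be named and cover every gene", call. = FALSE)
  }
  track <- data.frame(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    depth = unname(depth[genes$gene]), stringsAsFactors = FALSE
  )
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(hits)) {
    i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
    if (any(track$depth[i] != track$depth[j])) {
      stop("overlapping gene intervals with conflicting depths", call. = FALSE)
    }
  }
  track[order(match(track$chrom, canonical_chromosomes()), track$start), ,
        drop = FALSE]
}

#' Write a BedGraph depth track
#' @param track data.frame with `chrom`, `start`, `end`, `depth`
#'   (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write gene intervals as BED6
#' @param genes data.frame with `chrom`, `start`, `end`, `gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene, 0L, "+",
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
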