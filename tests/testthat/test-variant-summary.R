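test_that("VCF round trip preserves SNVs and splits multi-allelic records", {
  v <- data.frame(sample_id = "s1", chrom = c("chr1", "chr2"),
                  pos = c(100L, 200L), ref = c("C", "G"), alt = c("T", "A"),
                  gene = c("TP53", ""), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f)
  back <- read_variants(f)
  expect_identical(back[c("chrom", "pos", "ref", "alt")],
                   v[c("chrom", "pos", "ref", "alt")])
  expect_identical(back$gene[1], "TP53")
  expect_identical(attr(back, "genome"), "hg38")

  # multi-allelic record becomes one row per ALT
  lines <- readLines(f)
  lines[length(lines)] <- "chr2\t200\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/1"
  writeLines(lines, f)
  back2 <- read_variants(f)
  expect_identical(nrow(back2), 3L)
  expect_identical(back2$alt[back2$chrom == "chr2"], c("A", "T"))
  expect_identical(unique(back2$pos[back2$chrom == "chr2"]), 200L)
})

test_that("non-SNV records are dropped and counted", {
  cfg <- tiny_cfg(seed = 31)
  vs <- simulate_paired_variants(cfg, 0, 200)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs$tumor, f)
  lines <- readLines(f)
  indels <- sprintf("chr%d\t%d\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1", 1:5,
                    99000001:99000005)
  writeLines(c(lines, indels), f)
  expect_message(back <- read_variants(f), "dropped 5")
  expect_identical(nrow(back), 200L)
  expect_identical(attr(back, "n_dropped"), 5L)
})

test_that("annotation-table input is accepted", {
  v <- data.frame(chrom = c("chr1", "chr1"), pos = c(5L, 9L),
                  ref = c("C", "A"), alt = c("T", "AT"), gene = "EGFR")
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(v, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(back <- read_variants(f, sample_id = "p1"), "dropped 1")
  expect_identical(nrow(back), 1L)
  expect_identical(back$sample_id, "p1")
})

test_that("somatic subtraction returns tumour-only records exactly", {
  vs <- simulate_paired_variants(tiny_cfg(seed = 17), 50, 500)
  som <- somatic_filter(vs$tumor, vs$germline)
  expect_identical(sort(vkey(som)), sort(vkey(vs$somatic)))
  # filtering is idempotent and self-subtraction is empty
  expect_identical(vkey(somatic_filter(som, vs$germline)), vkey(som))
  expect_identical(nrow(somatic_filter(vs$tumor, vs$tumor)), 0L)
  # empty germline leaves the tumour table untouched
  empty <- vs$germline[0, ]
  expect_identical(vkey(somatic_filter(vs$tumor, empty)), vkey(vs$tumor))
})

test_that("genome build mismatch is rejected", {
  vs <- simulate_paired_variants(tiny_cfg(seed = 18), 5, 20)
  t2 <- vs$tumor
  attr(t2, "genome") <- "hg19"
  expect_error(somatic_filter(t2, vs$germline), "build mismatch")
})

test_that("chromosome distribution counts per sample and flags bad labels", {
  v <- data.frame(sample_id = c("a", "a", "a", "a", "b"),
                  chrom = c("chr1", "chr1", "chr1", "chrX", "chrX"),
                  pos = 1:5, ref = "C", alt = "T", gene = "")
  d <- chrom_distribution(v)
  expect_identical(d["a", "chr1"], 3L)
  expect_identical(d["a", "chrX"], 1L)
  expect_identical(sum(d["a", ]), 4L)
  expect_true(all(d["b", setdiff(colnames(d), "chrX")] == 0L))

  empty <- v[0, ]
  expect_true(all(chrom_distribution(empty) == 0L))

  v2 <- rbind(v, data.frame(sample_id = "a", chrom = "chrZ", pos = 6,
                            ref = "C", alt = "T", gene = ""))
  expect_error(chrom_distribution(v2), "chrZ")
  v3 <- rbind(v, data.frame(sample_id = "a", chrom = "chrM", pos = 6,
                            ref = "C", alt = "T", gene = ""))
  expect_message(d3 <- chrom_distribution(v3), "non-canonical")
  expect_identical(sum(d3), 5L)
})

test_that("substitution spectrum tallies the 12 ordered types and conserves counts", {
  v <- data.frame(sample_id = "s", chrom = "chr1", pos = 1L, ref = "C",
                  alt = "T", gene = "")
  sp <- substitution_spectrum(v)
  expect_identical(sp[1, "C>T"], 1L)
  expect_identical(sum(sp), 1L)

  vs <- simulate_paired_variants(tiny_cfg(seed = 23), 100, 900)
  spec <- substitution_spectrum(vs$tumor)
  dist <- chrom_distribution(vs$tumor)
  expect_identical(sum(spec), nrow(vs$tumor))
  expect_identical(rowSums(spec)[["S01"]], rowSums(dist)[["S01"]])
  # C>T and G>A dominate under the default transition-heavy spectrum
  expect_true(all(c("C>T", "G>A") %in%
                    colnames(spec)[order(-spec[1, ])][1:2]))
})

test_that("gene-level coverage is the length-weighted mean over merged intervals", {
  genes <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 400),
                      gene = "A")
  depth <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 400),
                      depth = c(10, 20))
  expect_equal(per_gene_coverage(depth, genes)$mean_depth, 17.5)

  half <- data.frame(chrom = "chr1", start = 0, end = 200, gene = "B")
  d_half <- data.frame(chrom = "chr1", start = 0, end = 100, depth = 10)
  expect_equal(per_gene_coverage(d_half, half)$mean_depth, 5)

  # linearity under depth scaling
  d3 <- depth; d3$depth <- 3 * d3$depth
  expect_equal(per_gene_coverage(d3, genes)$mean_depth,
               3 * per_gene_coverage(depth, genes)$mean_depth)

  expect_error(
    per_gene_coverage(data.frame(chrom = "chr1", start = 10, end = 10,
                                 depth = 5), genes),
    "end <= start"
  )
})

test_that("coverage accepts BedGraph and BED files on disk", {
  genes <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 400),
                      gene = "A")
  depth <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 400),
                      depth = c(10, 20))
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bedgraph(depth, bg)
  write_bed(genes, bed)
  expect_equal(per_gene_coverage(bg, bed)$mean_depth, 17.5)
})

test_that("mutation matrix binarizes per panel gene and keeps all-zero rows", {
  v <- data.frame(sample_id = c("p1", "p1", "p1", "p2"),
                  chrom = "chr17", pos = 1:4, ref = "C", alt = "T",
                  gene = c("TP53", "TP53", "TP53", "OFFPANEL"))
  expect_message(
    m <- mutation_matrix(v, panel = c("TP53", "EGFR"), samples = c("p1", "p2")),
    "1 variant"
  )
  expect_identical(m["p1", "TP53"], 1L)
  expect_identical(sum(m["p2", ]), 0L)
  expect_identical(attr(m, "n_off_panel"), 1L)
  expect_error(mutation_matrix(v, panel = c("A", "A")), "unique")
})

test_that("planted cohort mutations are recovered through the variant path", {
  co <- tiny_cohort(seed = 27)
  panel <- colnames(co$mutations)
  cell <- rownames(co$mutations)[1]
  genes <- panel[co$mutations[1, ] == 1]
  v <- data.frame(sample_id = cell, chrom = "chr1",
                  pos = seq_along(genes), ref = "C", alt = "T", gene = genes)
  m <- mutation_matrix(v, panel, samples = cell)
  expect_identical(as.integer(m[1, ]), as.integer(co$mutations[1, ]))
})

test_that("top-k overlap matches a brute-force oracle and breaks ties by name", {
  a <- data.frame(gene = c("TP53", "RYR2", "EGFR"), score = c(3, 2, 1))
  expect_identical(topk_overlap(a, a, 3), sort(a$gene))
  b <- data.frame(gene = c("KRAS", "BRAF", "MET"), score = c(9, 8, 7))
  expect_identical(topk_overlap(a, b, 2), character(0))

  set.seed(99)
  for (rep in 1:10) {
    genes <- paste0("G", sample(100, 20))
    ta <- data.frame(gene = genes, score = sample(5, 20, replace = TRUE))
    tb <- data.frame(gene = genes, score = sample(5, 20, replace = TRUE))
    k <- 5
    oracle_top <- function(tab) {
      picked <- character(0)
      pool <- tab
      while (length(picked) < k) {
        mx <- max(pool$score)
        cand <- sort(pool$gene[pool$score == mx])
        take <- head(cand, k - length(picked))
        picked <- c(picked, take)
        pool <- pool[!pool$gene %in% take, ]
      }
      picked
    }
    expect_identical(topk_overlap(ta, tb, k),
                     sort(intersect(oracle_top(ta), oracle_top(tb))))
  }

  dup <- data.frame(gene = c("X", "X"), score = c(1, 2))
  expect_error(topk_overlap(dup, b, 1), "duplicate")
  expect_error(topk_overlap(a, b, 5), "exceeds")
})
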