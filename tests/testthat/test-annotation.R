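test_that("BED and GFF3 coordinates normalize to 1-based inclusive", {
  bed <- withr::local_tempfile()
  writeLines(c("chr1\t999\t2000\tgeneX\t0\t+",
               "chr1\t5000\t6000\tgeneY\t0\t-",
               "chr2\t0\t100\tgeneZ"), bed)
  g <- load_genes(bed)
  expect_identical(g$start, c(1000L, 5001L, 1L))
  expect_identical(g$end, c(2000L, 6000L, 100L))
  expect_identical(g$strand, c("+", "-", "."))
  expect_identical(g$gene_id, c("geneX", "geneY", "geneZ"))

  gff <- withr::local_tempfile()
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1;Name=geneX",
               "chr1\tsrc\tmRNA\t1000\t1800\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tsrc\texon\t1000\t1200\t.\t+\t.\tParent=t1"), gff)
  h <- load_genes(gff, format = "gff3")
  expect_identical(nrow(h), 2L)  # exon rows ignored
  expect_identical(h[h$feature_kind == "gene", ]$start, 1000L)
  expect_identical(h[h$feature_kind == "gene", ]$gene_id, "geneX")
  expect_identical(h[h$feature_kind == "transcript", ]$end, 1800L)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t999\t2000\tok", "chr1\t300\t200\tinverted"), bad)
  expect_error(load_genes(bad), "line 2")
  short <- withr::local_tempfile()
  writeLines("chr1\t100", short)
  expect_error(load_genes(short), "line 1")
})

test_that("windows classify as genic, flank or intergenic, strand-aware", {
  genes <- data.table(chrom = "1",
                      start = c(25000L, 30501L, 80000L),
                      end = c(27000L, 31500L, 81000L),
                      strand = c("+", "+", "-"),
                      gene_id = c("gA", "gB", "gC"),
                      feature_kind = "gene")
  win <- data.table(chrom = "1",
                    start = c(20001L, 20001L, 50001L, 81001L, 78001L),
                    end = c(30000L, 30000L, 60000L, 90000L, 79000L))
  ## use the first window twice to confirm the gene list aggregates
  ann <- classify_window_regions(win[c(1, 3, 4, 5)], genes)
  expect_identical(ann$region_class[1], "genic")
  expect_identical(ann$genes[1], "gA")
  expect_identical(ann$region_class[2], "intergenic")
  ## [81001, 90000] is 5' of gC (minus strand): upstream within 1 kb
  expect_identical(ann$region_class[3], "upstream")
  ## [78001, 79000] is 3' of gC on minus strand: downstream
  expect_identical(ann$region_class[4], "downstream")

  ## window ending 500 bp before a + strand gene start is upstream
  w2 <- data.table(chrom = "1", start = 20001L, end = 30000L)
  g2 <- data.table(chrom = "1", start = 30500L, end = 32000L, strand = "+",
                   gene_id = "g", feature_kind = "gene")
  expect_identical(classify_window_regions(w2, g2)$region_class, "upstream")
  ## beyond the flank: intergenic
  g3 <- copy(g2)[, `:=`(start = 31001L, end = 32000L)]
  expect_identical(classify_window_regions(w2, g3)$region_class, "intergenic")
  ## genic windows list all overlapping genes
  g4 <- rbind(g2, data.table(chrom = "1", start = 25000L, end = 26000L,
                             strand = "+", gene_id = "h", feature_kind = "gene"))
  g4[1, `:=`(start = 29000L, end = 31000L)]
  ann4 <- classify_window_regions(w2, g4)
  expect_identical(ann4$region_class, "genic")
  expect_setequal(strsplit(ann4$genes, ",")[[1]], c("g", "h"))
})

test_that("classification agrees with a brute-force all-pairs check", {
  set.seed(31L)
  genes <- data.table(chrom = sample(c("1", "2"), 300L, replace = TRUE),
                      start = sample(1e5, 300L))
  genes[, end := start + sample(200:3000, 300L, replace = TRUE)]
  genes[, `:=`(strand = sample(c("+", "-", "."), 300L, replace = TRUE),
               gene_id = sprintf("g%03d", 1:300), feature_kind = "gene")]
  win <- CJ(chrom = c("1", "2"), t = 1:11)[, .(
    chrom, start = (t - 1L) * 10000L + 1L, end = t * 10000L)]
  ann <- classify_window_regions(win, genes, flank_bp = 1000L)
  for (i in seq_len(nrow(win))) {
    gsub <- genes[chrom == win$chrom[i]]
    ov <- gsub[start <= win$end[i] & end >= win$start[i]]
    if (nrow(ov) > 0L) {
      expect_identical(ann$region_class[i], "genic")
      expect_setequal(strsplit(ann$genes[i], ",")[[1]], unique(ov$gene_id))
      next
    }
    up_iv <- rbind(
      gsub[strand %in% c("+", "."), .(s = start - 1000L, e = start - 1L)],
      gsub[strand %in% c("-", "."), .(s = end + 1L, e = end + 1000L)])
    dn_iv <- rbind(
      gsub[strand %in% c("+", "."), .(s = end + 1L, e = end + 1000L)],
      gsub[strand %in% c("-", "."), .(s = start - 1000L, e = start - 1L)])
    up <- nrow(up_iv[s <= win$end[i] & e >= win$start[i]]) > 0L
    dn <- nrow(dn_iv[s <= win$end[i] & e >= win$start[i]]) > 0L
    expected <- if (up) "upstream" else if (dn) "downstream" else "intergenic"
    expect_identical(ann$region_class[i], expected)
  }
})

test_that("gene cross-filter is a pure set difference", {
  expect_setequal(filter_high_genes(c("A", "B", "C"), "B"), c("A", "C"))
  expect_setequal(filter_high_genes(c("A", "B"), c("X", "Y")), c("A", "B"))
  expect_identical(filter_high_genes(c("A", "B"), c("A", "B")), character(0))
  ## idempotent and disjoint from the null set
  out <- filter_high_genes(c("A", "A", "B", "C"), c("C", "C"))
  expect_identical(filter_high_genes(out, c("C")), out)
  expect_identical(intersect(out, "C"), character(0))
})

test_that("GC content of ancestral alleles", {
  calls <- data.table(chrom = "1", pos = 1:4, n_alleles = 2L,
                      aa = c("G", "C", "A", "T"), aa_freq_pooled = 1,
                      agreeing_lineages = "yak,bison")
  expect_identical(aa_gc_content(calls), 0.5)
  expect_identical(aa_gc_content(copy(calls)[, aa := "A"]), 0)
  expect_error(aa_gc_content(calls[0]), "empty")
  ## generator truth: planted GC fraction recovered within sampling error
  co <- small_cohort()
  g <- call_genome(co$freqs)
  p <- co$cfg$aa_gc_fraction
  expect_lt(abs(aa_gc_content(g) - p), 4 * sqrt(p * (1 - p) / nrow(g)))
})

test_that("transcript overlap fraction counts AA positions inside transcripts", {
  calls <- data.table(chrom = "1", pos = c(150L, 250L, 5000L, 9000L),
                      n_alleles = 2L, aa = "A", aa_freq_pooled = 1,
                      agreeing_lineages = "yak,bison")
  tx <- data.table(chrom = "1", start = c(100L, 240L), end = c(200L, 260L),
                   strand = "+", gene_id = c("t1", "t2"),
                   feature_kind = "transcript")
  expect_identical(transcript_overlap_fraction(calls, tx), 0.5)
  expect_identical(transcript_overlap_fraction(calls, tx[0]), 0)
  one <- data.table(chrom = "1", start = 1L, end = 10000L, strand = "+",
                    gene_id = "t", feature_kind = "transcript")
  expect_identical(transcript_overlap_fraction(calls, one), 1)
  ## brute force against generator gene models
  co <- small_cohort()
  bed <- simulate_genes(co$cfg, co$sim$truth, path = withr::local_tempfile())
  genes <- load_genes(bed)
  g <- call_genome(co$freqs)
  brute <- mean(vapply(seq_len(nrow(g)), function(i)
    nrow(genes[chrom == g$chrom[i] & start <= g$pos[i] & end >= g$pos[i]]) > 0,
    logical(1)))
  expect_equal(transcript_overlap_fraction(g, genes), brute)
})
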