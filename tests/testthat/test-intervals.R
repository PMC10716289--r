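test_that("BED parsing preserves coordinates and rejects malformed lines", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100", "chr1\t50\t200\tpk1\t5\t+"), path)
  b <- read_bed(path)
  expect_equal(b$start, c(0L, 50L))
  expect_equal(b$end, c(100L, 200L))

  writeLines(c("chr1\t0\t100", "chr1\t100\t100"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\t10", path)
  expect_error(read_bed(path), "fewer than 3")
  writeLines("chr1\tzero\tten", path)
  expect_error(read_bed(path), "non-numeric")
})

test_that("write_bed then read_bed is the identity on sorted BED6", {
  x <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                      start = c(10L, 400L, 5L), end = c(200L, 450L, 50L),
                      name = c("a", "b", "c"), score = c(1, 2.5, 0),
                      strand = c("+", "-", "."))
  path <- withr::local_tempfile()
  write_bed(x, path)
  expect_equal(read_bed(path), x)
})

test_that("gene models round-trip through GFF3 and flat TSV", {
  genes <- tiny_genes()
  gff <- withr::local_tempfile()
  tsv <- withr::local_tempfile()
  write_gff3_genes(genes, gff)
  write_gene_tsv(genes, tsv)
  expect_equal(read_gff3_genes(gff), genes)
  expect_equal(as.data.frame(read_gene_tsv(tsv)), as.data.frame(genes))
  bad <- genes
  bad$tss[1] <- bad$tes[1]
  expect_error(write_gene_tsv(bad, tsv), "tss == tes")
})

test_that("merge/intersect/jaccard match per-base oracles on random instances", {
  withr::with_seed(42, {
    for (rep in 1:40) {
      a <- random_intervals(sample(1:12, 1))
      b <- random_intervals(sample(1:12, 1))
      m <- merge_intervals(a)
      expect_equal(as.data.frame(m), as.data.frame(oracle_merge(a)),
                   ignore_attr = TRUE)
      # merge is idempotent
      expect_equal(merge_intervals(m), m)
      expect_equal(interval_jaccard(a, b), oracle_jaccard(a, b))
      expect_equal(interval_bp(intersect_intervals(a, b)),
                   oracle_intersect_bp(a, b))
    }
  })
})

test_that("jaccard identities hold", {
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  b <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L)
  d <- tibble::tibble(chrom = "chr1", start = 500L, end = 600L)
  expect_equal(interval_jaccard(a, a), 1)
  expect_equal(interval_jaccard(a, d), 0)
  expect_equal(interval_jaccard(a, b), 50 / 150)
  expect_equal(interval_jaccard(b, a), interval_jaccard(a, b))
  empty <- a[0, ]
  expect_message(expect_equal(interval_jaccard(empty, empty), 0), "empty")
})

test_that("merge collapses overlapping and adjacent intervals", {
  x <- tibble::tibble(chrom = "chr1", start = c(0L, 5L, 20L), end = c(10L, 20L, 30L))
  m <- merge_intervals(x)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 30L)
})

test_that("compartment annotation follows promoter > genic > distal precedence", {
  genes <- tiny_genes()
  peaks <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
    start = c(2500L, 6000L, 100L, 7500L, 10L),
    end = c(3500L, 6500L, 300L, 7600L, 200L),
    peak_id = paste0("p", 1:5)
  )
  expect_message(anno <- annotate_compartment(peaks, genes), "absent")
  expect_equal(as.character(anno$compartment),
               c("promoter", "genic", "distal", "promoter", "distal"))

  # a peak overlapping one gene's promoter window and another's body is promoter
  genes2 <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                           tss = c(10000L, 8000L), tes = c(12000L, 5000L),
                           strand = c("+", "-"))
  pk <- tibble::tibble(chrom = "chr1", start = 7400L, end = 7600L)
  expect_equal(as.character(annotate_compartment(pk, genes2)$compartment),
               "promoter")
})

test_that("compartment labels equal the per-base oracle and partition the set", {
  withr::with_seed(7, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%d", 1:6),
      chrom = sample(c("chr1", "chr2"), 6, replace = TRUE),
      strand = sample(c("+", "-"), 6, replace = TRUE)
    )
    pos <- sample(3000:40000, 6)
    genes$tss <- ifelse(genes$strand == "+", pos, pos + 4000L)
    genes$tes <- ifelse(genes$strand == "+", pos + 4000L, pos)
    peaks <- random_intervals(100, max_pos = 50000)
    anno <- annotate_compartment(peaks, genes)
    oracle <- vapply(seq_len(nrow(peaks)),
                     function(i) oracle_compartment(peaks[i, ], genes),
                     character(1))
    expect_equal(as.character(anno$compartment), oracle)
    expect_equal(sum(table(anno$compartment)), nrow(peaks))
  })
})

test_that("symmetric promoter windows widen the promoter call", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 10000L,
                          tes = 12000L, strand = "+")
  down <- tibble::tibble(chrom = "chr1", start = 12500L, end = 12800L)
  expect_equal(as.character(annotate_compartment(down, genes)$compartment), "distal")
  expect_equal(as.character(
    annotate_compartment(down, genes, promoter_flank = "symmetric")$compartment),
    "promoter")
})

test_that("distance_to_tss uses the peak midpoint and rejects cross-chromosome", {
  pk <- tibble::tibble(chrom = "chr1", start = 990L, end = 1010L)
  g <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 1000L,
                      tes = 2000L, strand = "+")
  expect_equal(distance_to_tss(pk, g), 0)
  g2 <- g
  g2$chrom <- "chr2"
  expect_error(distance_to_tss(pk, g2), "different chromosomes")
})
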