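test_that("fisher exact p equals fixed-margin enumeration", {
  ft <- fisher_enrichment(5, 0, 0, 5)
  expect_equal(ft$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_enrichment(2, 2, 2, 2)$odds_ratio, 1)
  expect_equal(fisher_enrichment(3, 0, 0, 2)$odds_ratio, Inf)
  expect_error(fisher_enrichment(0, 0, 0, 0), "all-zero")

  withr::with_seed(60, {
    for (rep in 1:100) {
      n <- sample(4:30, 1)
      cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
      got <- fisher_enrichment(cells[1], cells[2], cells[3], cells[4])
      expect_equal(got$p,
                   oracle_fisher_greater(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-10)
    }
  })
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  withr::with_seed(61, {
    for (rep in 1:50) {
      p <- runif(sample(1:40, 1))^2
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
      perm <- sample.int(length(p))
      expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
    }
  })
})

test_that("JASPAR matrices round-trip and are validated", {
  pwms <- list(GCCbox = pwm_from_consensus("CGCCGCC", "GCCbox"),
               GArepeat = pwm_from_consensus("GAGAGAG", "GArepeat"))
  path <- withr::local_tempfile()
  write_jaspar(pwms, path)
  rt <- read_jaspar(path)
  expect_equal(names(rt), names(pwms))
  expect_equal(rt$GCCbox$probs, pwms$GCCbox$probs, tolerance = 1e-8)
  expect_error(pwm_from_consensus("CGX"), "A/C/G/T")
})

test_that("the PWM scanner finds planted consensus sites and ignores N runs", {
  pwm <- pwm_from_consensus("CGCCGCC", "GCCbox")
  seq <- paste0(strrep("A", 20), "CGCCGCC", strrep("T", 20))
  hits <- pwm_scan(tibble::tibble(region_id = "r1", seq = seq), pwm)
  expect_true(any(hits$start == 21 & hits$strand == "+"))
  # reverse strand: plant the reverse complement
  seq_rc <- paste0(strrep("A", 10), "GGCGGCG", strrep("T", 10))
  hits_rc <- pwm_scan(tibble::tibble(region_id = "r2", seq = seq_rc), pwm)
  expect_true(any(hits_rc$start == 11 & hits_rc$strand == "-"))

  all_n <- tibble::tibble(region_id = "rn", seq = strrep("N", 50))
  expect_equal(nrow(pwm_scan(all_n, pwm)), 0)
  short <- tibble::tibble(region_id = "rs", seq = "ACGT")
  expect_message(out <- pwm_scan(short, pwm), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("scanner hit sets equal naive enumeration at permissive and strict thresholds", {
  pwm <- pwm_from_consensus("CCGAC", "toy", dominance = 0.85)
  withr::with_seed(62, {
    seqs <- setNames(vapply(1:12, function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE,
                   prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    }, character(1)), paste0("r", 1:12))
  })
  regions <- tibble::tibble(region_id = names(seqs), seq = unname(seqs))
  for (thr in c(1e-2, 1e-3)) {
    got <- suppressMessages(pwm_scan(regions, pwm, p_threshold = thr))
    want <- oracle_pwm_hits(as.list(seqs), pwm$probs, thr)
    expect_setequal(paste(got$region_id, got$start, got$strand),
                    paste(want$region_id, want$start, want$strand))
  }
})

test_that("motif enrichment flags the planted foreground motif", {
  fx <- simulate_motif_fixture(synthetic_config(seed = 63))
  fg <- dplyr::filter(fx$regions, group == "foreground")
  bg <- dplyr::filter(fx$regions, group == "background")
  hits_fg <- dplyr::bind_rows(lapply(fx$pwms, function(w) pwm_scan(fg, w)))
  hits_bg <- dplyr::bind_rows(lapply(fx$pwms, function(w) pwm_scan(bg, w)))
  me <- motif_enrichment(hits_fg, hits_bg, nrow(fg), nrow(bg))
  expect_lt(me$p_adj[me$motif_id == "GCCbox"], 0.01)
  expect_gt(me$odds_ratio[me$motif_id == "GCCbox"], 1)
  # composition: the enrichment p is exactly the Fisher p on the assembled table
  row <- me[me$motif_id == "GCCbox", ]
  expect_equal(row$p, fisher_enrichment(row$n_fg, nrow(fg) - row$n_fg,
                                        row$n_bg, nrow(bg) - row$n_bg)$p)
  # equal hit rates: OR ~ 1, one-sided p near 1
  eq <- motif_enrichment(tibble::tibble(region_id = paste0("f", 1:10),
                                        motif_id = "m"),
                         tibble::tibble(region_id = paste0("b", 1:10),
                                        motif_id = "m"), 100, 100)
  expect_equal(eq$odds_ratio, 1)
  expect_gt(eq$p, 0.5)
  expect_error(motif_enrichment(hits_fg, hits_bg, 0, 10), "empty foreground")
})

test_that("gene-set overlap test reduces to the hypergeometric tail", {
  uni <- paste0("g", 1:20)
  full <- overlap_test(uni, uni, uni)
  expect_equal(full$fold, 1)
  expect_equal(full$p, 1)
  expect_equal(overlap_test(uni[1:5], uni[6:10], uni)$fold, 0)

  a <- uni[1:8]
  b <- uni[5:12]
  got <- overlap_test(a, b, uni)
  expect_equal(got$n_overlap, 4)
  expect_equal(got$p, oracle_fisher_greater(4, 4, 4, 8), tolerance = 1e-12)
  expect_error(overlap_test(a, b, character(0)), "empty universe")
})

test_that("bias classification recovers planted evidence fractions exactly", {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                          tss = seq(10000L, 100000L, by = 10000L))
  genes$tes <- genes$tss + 2000L
  genes$strand <- "+"
  de_table <- tibble::tibble(gene_id = genes$gene_id,
                             de = c(rep(TRUE, 5), rep(FALSE, 5)))
  # 60% of DE genes (3 of 5) get a differential peak in their promoter
  ac <- tibble::tibble(chrom = "chr1",
                       start = genes$tss[1:3] - 500L, end = genes$tss[1:3] - 100L)
  bc <- classify_bias(genes, de_table, diff_ac_peaks = ac)
  expect_equal(glance(bc)$frac_h3k27ac, 0.6)
  expect_equal(glance(bc)$frac_dna_variation, 0)
  expect_equal(glance(bc)$n_de_genes, 5)

  # no evidence layers: all booleans false
  none <- classify_bias(genes, de_table)
  expect_false(any(tidy(none)$h3k27ac_variation))

  # invariant to gene input order
  perm <- withr::with_seed(1, sample.int(10))
  bc2 <- classify_bias(genes[perm, ], de_table, diff_ac_peaks = ac)
  expect_equal(glance(bc2), glance(bc))

  extra <- dplyr::bind_rows(de_table,
                            tibble::tibble(gene_id = "missing", de = TRUE))
  expect_warning(classify_bias(genes, extra, diff_ac_peaks = ac), "excluded")
})

test_that("the internal DE test recovers planted cultivar effects", {
  fx <- small_fixture(64, frac_de_genes = 0.2, noise_sd = 0.4, cell_sd = 0.3)
  gr <- split(fx$sample_sheet$sample_id, fx$sample_sheet$cultivar)
  de <- de_test(fx$expression, gr$A, gr$B)
  tr <- fx$truth$de_genes
  expect_gte(mean(de$de[match(tr$gene_id, de$gene_id)]), 0.9)
  # planted sign: positive log2fc means higher in cultivar B
  got_sign <- sign(de$log2fc[match(tr$gene_id, de$gene_id)])
  expect_gte(mean(got_sign == sign(tr$log2fc)), 0.9)
})
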