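test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(frac_divergent_bins = 1.2), "fractions")
  expect_error(synthetic_config(chrom_length_bp = 1e5 + 50), "divisible")
  expect_error(synthetic_config(link_rho = 2), "link_rho")
})

test_that("genome generation: empty case, determinism, non-overlap", {
  cfg0 <- synthetic_config(n_chromosomes = 2, n_genes = 0)
  g0 <- simulate_genome(cfg0)
  expect_equal(nrow(g0$genes), 0)
  expect_equal(nrow(g0$chrom_sizes), 2)

  cfg <- synthetic_config(n_chromosomes = 1, chrom_length_bp = 1e6, n_genes = 50)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)

  # brute-force pairwise disjointness sweep
  gb <- dplyr::mutate(g1$genes, start = pmin(tss, tes), end = pmax(tss, tes))
  gb <- dplyr::arrange(gb, start)
  expect_true(all(gb$start[-1] >= gb$end[-nrow(gb)]))

  expect_error(
    simulate_genome(synthetic_config(n_chromosomes = 1,
                                     chrom_length_bp = 2e4, n_genes = 50)),
    "cannot place")
})

test_that("cultivar-specific planting follows the configured fraction", {
  cfg0 <- synthetic_config(frac_cultivar_specific_peaks = 0, seed = 3)
  fx0 <- simulate_epigenome(cfg0)
  expect_equal(nrow(fx0$truth$specific_peaks), 0)

  cfg <- synthetic_config(n_peaks = 1000, frac_cultivar_specific_peaks = 0.2,
                          seed = 4)
  fx <- simulate_epigenome(cfg)
  expect_equal(nrow(fx$truth$specific_peaks), 200)
  # a peak is specific to at most one cultivar
  expect_equal(anyDuplicated(fx$truth$specific_peaks$peak_id), 0)
})

test_that("noise_sd = 0 makes replicate columns identical", {
  cfg <- synthetic_config(noise_sd = 0, n_peaks = 100, n_genes = 40,
                          n_true_links = 5, seed = 5)
  fx <- simulate_epigenome(cfg)
  sheet <- fx$sample_sheet
  cells <- split(sheet$sample_id,
                 paste(sheet$cultivar, sheet$condition, sheet$tissue))
  for (ids in cells) {
    expect_equal(fx$signal[[ids[1]]], fx$signal[[ids[2]]])
  }
})

test_that("planted links reach the target correlation", {
  # rho = 1, noise off: perfect correlation for every planted pair
  cfg1 <- synthetic_config(noise_sd = 0, link_rho = 1, n_true_links = 10,
                           n_peaks = 200, n_genes = 100, seed = 6)
  fx1 <- simulate_epigenome(cfg1)
  pc <- pair_correlation(fx1$truth$links, fx1$signal, fx1$expression)
  expect_true(all(abs(pc$r - 1) < 1e-8))

  # rho = 0.8 over several seeds: mean sample r within the stated band
  mean_r <- vapply(1:3, function(s) {
    fx <- simulate_epigenome(synthetic_config(seed = s, n_peaks = 200,
                                              n_genes = 100, n_true_links = 50))
    mean(pair_correlation(fx$truth$links, fx$signal, fx$expression)$r)
  }, numeric(1))
  expect_true(all(mean_r > 0.6 & mean_r < 0.95))

  # null world: no recorded links, near-zero mean |r| over random pairs
  fx0 <- simulate_epigenome(null_world_config(8))
  expect_equal(nrow(fx0$truth$links), 0)
  withr::with_seed(1, {
    rp <- tibble::tibble(peak_id = sample(fx0$catalogue$peak_id, 200, TRUE),
                         gene_id = sample(fx0$genes$gene_id, 200, TRUE))
  })
  expect_lt(abs(mean(pair_correlation(rp, fx0$signal, fx0$expression)$r)), 0.05)

  expect_error(
    simulate_epigenome(synthetic_config(n_peaks = 30, n_genes = 10,
                                        n_true_links = 500)),
    "cannot plant")
})

test_that("state-track divergence is planted exactly and recoverable", {
  cfg0 <- synthetic_config(frac_divergent_bins = 0, n_peaks = 50,
                           n_genes = 20, n_true_links = 0, seed = 9)
  fx0 <- simulate_epigenome(cfg0)
  tr <- split(fx0$state_tracks[, c("chrom", "bin", "state")],
              fx0$state_tracks$sample_id)
  expect_true(all(vapply(tr, function(t) identical(t$state, tr[[1]]$state),
                         logical(1))))

  cfg <- synthetic_config(n_chromosomes = 1, chrom_length_bp = 1e6,
                          frac_divergent_bins = 0.1, n_peaks = 50,
                          n_genes = 20, n_true_links = 0, seed = 10)
  fx <- simulate_epigenome(cfg)  # 5000 bins per chromosome
  expect_equal(nrow(fx$truth$divergent_bins), 500)

  # recomputing divergence from the emitted tracks recovers the truth exactly
  a <- dplyr::filter(fx$state_tracks, sample_id == "A_NN_root_rep1")
  b <- dplyr::filter(fx$state_tracks, sample_id == "B_LN_seed_rep2")
  dyn <- call_dynamic_bins(a, b)
  found <- dyn[dyn$dynamic, c("chrom", "bin")]
  expect_equal(as.data.frame(found),
               as.data.frame(dplyr::arrange(fx$truth$divergent_bins, chrom, bin)),
               ignore_attr = TRUE)
})

test_that("motif fixture plants recoverable placements at the configured rates", {
  cfg0 <- synthetic_config(motif_fg_rate = 0, motif_bg_rate = 0, seed = 11)
  fx0 <- simulate_motif_fixture(cfg0)
  expect_equal(nrow(fx0$truth_motifs), 0)

  fx <- small_fixture(12, n_motif_regions = 100)
  hits <- dplyr::bind_rows(lapply(fx$pwms, function(w)
    pwm_scan(fx$motif_regions, w, p_threshold = 1e-3)))
  planted <- paste(fx$truth$motif_hits$region_id, fx$truth$motif_hits$motif_id,
                   fx$truth$motif_hits$offset)
  found <- paste(hits$region_id, hits$motif_id, hits$start - 1)
  expect_true(all(planted %in% found))
  # fisher odds ratio from truth counts favours the foreground
  tr <- dplyr::filter(fx$truth$motif_hits, motif_id == "GCCbox")
  n_fg <- dplyr::n_distinct(tr$region_id[grepl("^fg", tr$region_id)])
  n_bg <- dplyr::n_distinct(tr$region_id[grepl("^bg", tr$region_id)])
  expect_gt((n_fg / (100 - n_fg)) / ((n_bg + 0.5) / (100 - n_bg)), 1)
})

test_that("fixtures round-trip through disk and checksums track the seed", {
  fx <- small_fixture(13)
  dir1 <- withr::local_tempdir()
  man1 <- write_fixture(fx, dir1)
  rt <- read_fixture(dir1)
  expect_equal(as.data.frame(rt$catalogue[, c("chrom", "start", "end", "peak_id")]),
               as.data.frame(fx$catalogue[, c("chrom", "start", "end", "peak_id")]))
  expect_equal(as.data.frame(rt$genes), as.data.frame(fx$genes))
  expect_equal(as.matrix(rt$signal[, -1]), as.matrix(fx$signal[, -1]),
               tolerance = 1e-12)
  expect_equal(rt$motif_regions$seq, fx$motif_regions$seq)
  tr_rt <- dplyr::arrange(rt$state_tracks, sample_id, chrom, bin)
  tr_fx <- dplyr::arrange(fx$state_tracks, sample_id, chrom, bin)
  expect_equal(tr_rt$state, tr_fx$state)
  expect_equal(sort(link_key(rt$truth$links)), sort(link_key(fx$truth$links)))

  # identical seed reproduces identical bytes; a new seed does not
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture(small_fixture(13), dir2)
  expect_equal(man1$md5, man2$md5)
  dir3 <- withr::local_tempdir()
  man3 <- write_fixture(small_fixture(14), dir3)
  expect_false(all(man1$md5 == man3$md5))
})
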