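test_that("candidate pairing respects the closed distance bound", {
  peaks <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L, peak_id = "p")
  mk_gene <- function(tss) tibble::tibble(gene_id = paste0("g", tss),
                                          chrom = "chr1", tss = tss,
                                          tes = tss + 1000L, strand = "+")
  # midpoint 100: gene at exactly window included, window+1 excluded
  at <- mk_gene(100L + 500000L)
  beyond <- mk_gene(100L + 500001L)
  expect_equal(nrow(candidate_pairs(peaks, at)), 1)
  expect_equal(nrow(candidate_pairs(peaks, beyond)), 0)
  expect_message(out <- candidate_pairs(peaks[0, ], at), "empty")
  expect_equal(nrow(out), 0)
})

test_that("candidate pairs equal the exhaustive double loop on a toy layout", {
  withr::with_seed(50, {
    peaks <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 5, TRUE),
                            start = sample.int(9e5, 5), peak_id = paste0("p", 1:5))
    peaks$end <- peaks$start + 1000L
    genes <- tibble::tibble(gene_id = paste0("g", 1:5),
                            chrom = sample(c("chr1", "chr2"), 5, TRUE),
                            tss = sample.int(9e5, 5))
    genes$tes <- genes$tss + 2000L
    genes$strand <- "+"
  })
  got <- candidate_pairs(peaks, genes, window = 3e5)
  want <- list()
  for (i in 1:5) for (j in 1:5) {
    if (peaks$chrom[i] != genes$chrom[j]) next
    d <- abs(floor((peaks$start[i] + peaks$end[i]) / 2) - genes$tss[j])
    if (d <= 3e5) want[[length(want) + 1]] <- paste(peaks$peak_id[i], genes$gene_id[j])
  }
  expect_setequal(link_key(got), unlist(want))
})

test_that("pair correlation equals the textbook formula", {
  sig <- tibble::tibble(peak_id = "p1", s1 = 1, s2 = 4, s3 = 2, s4 = 8, s5 = 5, s6 = 7)
  expr2 <- dplyr::bind_rows(
    tibble::tibble(gene_id = "gA", s1 = 2 * 1 + 5, s2 = 2 * 4 + 5, s3 = 2 * 2 + 5,
                   s4 = 2 * 8 + 5, s5 = 2 * 5 + 5, s6 = 2 * 7 + 5),
    tibble::tibble(gene_id = "gB", s1 = 3.1, s2 = 0.2, s3 = 5.5, s4 = 2.2,
                   s5 = 9.1, s6 = 1.4))
  pairs <- tibble::tibble(peak_id = "p1", gene_id = c("gA", "gB"))
  pc <- pair_correlation(pairs, sig, expr2)
  expect_equal(pc$r[1], 1)
  x <- as.numeric(sig[1, -1])
  y <- as.numeric(expr2[2, -1])
  expect_equal(pc$r[2], oracle_pearson(x, y), tolerance = 1e-12)
  expect_error(pair_correlation(pairs, sig[, 1:3], expr2), "fewer than 3")
})

test_that("the trans-chromosome null is seeded, centred and never cis", {
  fx <- simulate_epigenome(null_world_config(51))
  null1 <- build_link_null(fx$signal, fx$expression, fx$catalogue, fx$genes,
                           n_draws = 10000, seed = 7)
  null2 <- build_link_null(fx$signal, fx$expression, fx$catalogue, fx$genes,
                           n_draws = 10000, seed = 7)
  expect_equal(glance(null1), glance(null2))
  expect_lt(abs(null1$mu), 0.05)

  # sigma close to the independent-Gaussian limit 1/sqrt(n_samples - 1)
  n_s <- nrow(fx$sample_sheet)
  expect_lt(abs(null1$sigma - 1 / sqrt(n_s - 1)) / (1 / sqrt(n_s - 1)), 0.15)

  # no self-chromosome draw appears in the record
  pk_chrom <- setNames(fx$catalogue$chrom, fx$catalogue$peak_id)
  g_chrom <- setNames(fx$genes$chrom, fx$genes$gene_id)
  expect_true(all(pk_chrom[null1$draws$peak_id] != g_chrom[null1$draws$gene_id]))

  one_chrom <- dplyr::filter(fx$catalogue, chrom == "chr1")
  expect_error(build_link_null(fx$signal, fx$expression, one_chrom,
                               dplyr::filter(fx$genes, chrom == "chr1")),
               "two chromosomes")
})

test_that("link scoring matches the normal tail and is monotone in r", {
  null <- structure(list(mu = 0, sigma = 0.2, n_draws = 10000, seed = 1,
                         draws = tibble::tibble()), class = "link_null")
  pairs <- tibble::tibble(peak_id = "p", gene_id = "g", r = c(0, 0.6))
  sc <- score_links(pairs, null)
  expect_equal(sc$z, c(0, 3))
  expect_equal(sc$p[1], 0.5)
  expect_equal(sc$p[2], pnorm(3, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(round(sc$p[2], 5), 0.00135)

  rs <- seq(-0.9, 0.9, by = 0.05)
  ps <- score_links(tibble::tibble(peak_id = "p", gene_id = "g", r = rs), null)$p
  expect_true(all(diff(ps) < 0))

  bad <- null
  bad$sigma <- 0
  expect_error(score_links(pairs, bad), "sigma")
})

test_that("planted links are recovered with controlled FDR", {
  res <- vapply(61:63, function(s) {
    fx <- simulate_epigenome(link_recovery_config(s))
    la <- link_pipeline(fx$signal, fx$expression, fx$catalogue, fx$genes,
                        n_draws = 4000, seed = s, bh = TRUE)
    sig <- dplyr::filter(tidy(la), significant)
    tk <- link_key(fx$truth$links)
    sk <- link_key(sig)
    c(recall = mean(tk %in% sk),
      fdr = if (length(sk)) mean(!(sk %in% tk)) else 0)
  }, numeric(2))
  expect_gte(mean(res["recall", ]), 0.9)
  expect_lte(mean(res["fdr", ]), 0.15)
})

test_that("the link pipeline is internally consistent and deterministic", {
  fx <- simulate_epigenome(null_world_config(52))
  la <- link_pipeline(fx$signal, fx$expression, fx$catalogue, fx$genes,
                      n_draws = 2000, seed = 3)
  links <- tidy(la)
  sig <- dplyr::filter(links, significant)
  expect_equal(la$summary$n_significant, nrow(sig))
  expect_equal(la$summary$n_unique_peaks, dplyr::n_distinct(sig$peak_id))
  expect_equal(la$summary$n_unique_genes, dplyr::n_distinct(sig$gene_id))
  # null world: significant fraction ~ alpha
  se <- sqrt(0.05 * 0.95 / nrow(links))
  expect_lt(abs(mean(links$significant) - 0.05), 2 * se + 0.01)

  la2 <- link_pipeline(fx$signal, fx$expression, fx$catalogue, fx$genes,
                       n_draws = 2000, seed = 3)
  expect_equal(tidy(la2), links)
})
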