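# Shared small fixtures, built in code at test time.

tiny_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    tss = c(5000L, 19999L, 8000L),
    tes = c(8000L, 15000L, 11000L),
    strand = c("+", "-", "+")
  )
}

# small but complete fixture used across module tests
small_fixture <- function(seed = 101, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length_bp = 4e5, n_genes = 60,
         n_peaks = 120, n_true_links = 10, n_motif_regions = 50, seed = seed),
    list(...))
  simulate_epigenome(do.call(synthetic_config, args))
}

# configuration used for differential-recall checks: one design cell per
# cultivar, three replicates, low noise, 4-fold planted contrast
diff_recall_config <- function(seed) {
  synthetic_config(seed = seed, tissues = "root", conditions = "NN",
                   n_replicates = 3, n_peaks = 500,
                   frac_cultivar_specific_peaks = 0.2, specific_fold = 4,
                   noise_sd = 0.1, cell_sd = 0,
                   n_true_links = 0, frac_de_genes = 0)
}

# pure link worlds (no cultivar-specific peaks, no DE genes)
null_world_config <- function(seed) {
  synthetic_config(n_true_links = 0, frac_cultivar_specific_peaks = 0,
                   frac_de_genes = 0, n_peaks = 200, n_genes = 100,
                   seed = seed)
}

link_recovery_config <- function(seed) {
  synthetic_config(seed = seed, n_peaks = 150, n_genes = 90,
                   chrom_length_bp = 2e6, n_true_links = 50,
                   frac_cultivar_specific_peaks = 0, frac_de_genes = 0)
}

link_key <- function(d) paste(d$peak_id, d$gene_id)
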