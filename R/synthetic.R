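# Synthetic fixture generator. Emulates a 2-cultivar x 2-nitrogen-condition
# x 3-tissue CUT&Tag/RNA-seq design with planted ground truth: cultivar-
# specific peaks, distal-peak->gene links with a chosen correlation,
# divergent chromatin-state bins, motif-bearing dynamic regions, DE genes,
# QTL intervals and a root-trait table. Every planted quantity is recorded
# in a truth object so downstream stages can be validated.

#' Build a synthetic-design configuration
#'
#' All sizes, rates and the seed for [simulate_epigenome()] live here.
#' Defaults describe the study design the package targets: two cultivars
#' (`A`, `B`), normal vs low nitrogen (`NN`, `LN`), three tissues and two
#' replicates per cell (24 samples).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Chromosome length (must be divisible by
#'   `bin_size_bp`).
#' @param n_genes Total genes, spread across chromosomes.
#' @param n_peaks Master peak-catalogue size.
#' @param cultivars,conditions,tissues Factor levels of the design.
#' @param n_replicates Replicates per design cell.
#' @param n_true_links Planted distal-peak -> gene links.
#' @param link_rho Target correlation of planted links, in `[0, 1]`.
#' @param frac_cultivar_specific_peaks Fraction of catalogue peaks made
#'   cultivar-specific.
#' @param specific_fold Signal fold between the owning and the other
#'   cultivar for specific peaks.
#' @param frac_divergent_bins Fraction of 200-bp state bins planted as
#'   divergent between the two cultivars' tracks.
#' @param bin_size_bp State-bin width (default 200 bp).
#' @param noise_sd Gaussian noise added per sample, in signal units.
#' @param cell_sd Spread (signal units) of the additive per-design-cell
#'   effect shared by replicates (what makes signal vary across
#'   tissues/conditions).
#' @param frac_de_genes Fraction of (unlinked) genes planted as
#'   differentially expressed between cultivars.
#' @param de_log2fc Planted DE effect size (log2).
#' @param n_motif_regions Regions per motif group (foreground and
#'   background).
#' @param motif_region_bp Motif-region length.
#' @param motif_fg_rate,motif_bg_rate Planting rate of the enriched motif
#'   in foreground vs background regions.
#' @param n_qtl_per_chrom QTL intervals per chromosome.
#' @param n_trait_replicates Replicates per genotype x condition trait cell.
#' @param seed Integer master seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 3,
                             chrom_length_bp = 1e6,
                             n_genes = 240,
                             n_peaks = 600,
                             cultivars = c("A", "B"),
                             conditions = c("NN", "LN"),
                             tissues = c("root", "leaf", "seed"),
                             n_replicates = 2,
                             n_true_links = 50,
                             link_rho = 0.8,
                             frac_cultivar_specific_peaks = 0.1,
                             specific_fold = 8,
                             frac_divergent_bins = 0.05,
                             bin_size_bp = 200,
                             noise_sd = 1.3,
                             cell_sd = 0.7,
                             frac_de_genes = 0.1,
                             de_log2fc = 2,
                             n_motif_regions = 200,
                             motif_region_bp = 100,
                             motif_fg_rate = 0.5,
                             motif_bg_rate = 0.05,
                             n_qtl_per_chrom = 5,
                             n_trait_replicates = 8,
                             seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(frac_cultivar_specific_peaks, frac_divergent_bins, frac_de_genes,
             motif_fg_rate, motif_bg_rate)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions/rates must lie in [0, 1]")
  if (link_rho < 0 || link_rho > 1) abort("link_rho must lie in [0, 1]")
  if (chrom_length_bp %% bin_size_bp != 0) {
    abort("chrom_length_bp must be divisible by bin_size_bp")
  }
  if (n_chromosomes < 1) abort("need at least one chromosome")
  if (length(cultivars) != 2) abort("the design assumes exactly two cultivars")
  if (seed < 0 || seed >= 2^31 - 1) abort("seed must be a non-negative 32-bit integer")
  structure(cfg, class = "synthetic_config")
}

# deterministic per-generator child seeds, all < 2^31 - 1
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% (2^31 - 2)) + 1L
}

#' Sample sheet implied by a configuration
#'
#' @param config A `synthetic_config`.
#' @return Tibble with `sample_id`, `cultivar`, `condition`, `tissue`,
#'   `replicate`.
#' @export
design_sample_sheet <- function(config) {
  sheet <- tidyr::expand_grid(
    cultivar = config$cultivars,
    condition = config$conditions,
    tissue = config$tissues,
    replicate = seq_len(config$n_replicates)
  )
  mutate(sheet,
         sample_id = paste(.data$cultivar, .data$condition, .data$tissue,
                           paste0("rep", .data$replicate), sep = "_"),
         .before = 1)
}

# place n non-overlapping intervals of the given widths on [0, L)
place_nonoverlapping <- function(n, widths, chrom_length, what) {
  if (n == 0) return(tibble(start = integer(), end = integer()))
  slack <- chrom_length - sum(widths)
  if (slack < 0) {
    abort(sprintf(
      "cannot place %d non-overlapping %s totalling %d bp on a %d bp chromosome",
      n, what, sum(widths), chrom_length))
  }
  cuts <- sort(runif(n, 0, slack))
  starts <- as.integer(floor(cuts)) + c(0L, cumsum(widths[-n]))
  tibble(start = starts, end = starts + widths)
}

#' Generate the genome layout: chromosome sizes and gene models
#'
#' Genes are placed without overlap within each chromosome; strand,
#' TSS and TES follow the package's 0-based convention (minus-strand genes
#' have `tss > tes`).
#'
#' @param config A `synthetic_config`.
#' @param seed Seed (defaults to a child of `config$seed`).
#' @return List with `chrom_sizes` and `genes` tibbles.
#' @export
simulate_genome <- function(config, seed = child_seed(config$seed, 1)) {
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    chrom_sizes <- tibble(chrom = chroms, length = as.integer(config$chrom_length_bp))
    per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
    genes <- purrr::map2_dfr(chroms, per_chrom, function(ch, ng) {
      if (ng == 0) return(tibble())
      widths <- as.integer(round(runif(ng, 1000, 4000)))
      pos <- place_nonoverlapping(ng, widths, config$chrom_length_bp, "genes")
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      tibble(chrom = ch, start = pos$start, end = pos$end, strand = strand)
    })
    if (nrow(genes) == 0) {
      genes <- tibble(gene_id = character(), chrom = character(),
                      tss = integer(), tes = integer(), strand = character())
    } else {
      genes <- mutate(genes,
        gene_id = sprintf("gene_%04d", dplyr::row_number()),
        tss = as.integer(ifelse(.data$strand == "+", .data$start, .data$end - 1L)),
        tes = as.integer(ifelse(.data$strand == "+", .data$end, .data$start))
      )
      genes <- select(genes, "gene_id", "chrom", "tss", "tes", "strand")
    }
    list(chrom_sizes = chrom_sizes, genes = validate_genes(genes))
  })
}

#' Generate the peak catalogue, per-sample presence and the signal matrix
#'
#' A master catalogue of non-overlapping peaks is placed per chromosome.
#' A fraction of peaks are made cultivar-specific: high signal in the
#' owning cultivar, `specific_fold`-fold lower in the other. Signal is a
#' per-peak lognormal baseline, modulated per design cell, plus Gaussian
#' per-sample noise (floored at zero).
#'
#' @param config A `synthetic_config`.
#' @param genome Output of [simulate_genome()].
#' @param seed Seed.
#' @return List with `catalogue` (interval tibble with `peak_id`),
#'   `signal` (wide tibble, `peak_id` + one column per sample),
#'   `presence` (long tibble `sample_id`, `peak_id`) and
#'   `truth_specific` (tibble `peak_id`, `cultivar`).
#' @export
simulate_peaks <- function(config, genome, seed = child_seed(config$seed, 2)) {
  withr::with_seed(seed, {
    sheet <- design_sample_sheet(config)
    chroms <- genome$chrom_sizes$chrom
    per_chrom <- diff(round(seq(0, config$n_peaks, length.out = length(chroms) + 1)))
    catalogue <- purrr::map2_dfr(chroms, per_chrom, function(ch, np) {
      if (np == 0) return(tibble())
      widths <- as.integer(round(runif(np, 400, 1500)))
      pos <- place_nonoverlapping(np, widths, config$chrom_length_bp, "peaks")
      tibble(chrom = ch, start = pos$start, end = pos$end)
    })
    catalogue <- as_intervals(catalogue)
    catalogue$peak_id <- sprintf("peak_%05d", seq_len(nrow(catalogue)))
    np <- nrow(catalogue)

    base <- rlnorm(np, meanlog = 2, sdlog = 1)
    # specificity is planted on peaks of at least median intensity: a
    # near-background peak has no meaningful cultivar contrast
    n_spec <- round(config$frac_cultivar_specific_peaks * np)
    eligible <- catalogue$peak_id[base >= median(base)]
    spec_ids <- sample(eligible, min(n_spec, length(eligible)))
    spec_cultivar <- sample(config$cultivars, length(spec_ids), replace = TRUE)
    truth_specific <- tibble(peak_id = spec_ids, cultivar = spec_cultivar)
    cells <- distinct(sheet, .data$cultivar, .data$condition, .data$tissue)
    cell_key <- paste(cells$cultivar, cells$condition, cells$tissue, sep = "_")
    # additive per-cell effect (shared by replicates) on top of the
    # lognormal baseline; Gaussian in signal units, and smaller than the
    # per-sample noise so cross-sample variation stays close to the
    # independent-Gaussian regime the z-based link p-values assume
    mu <- matrix(base, nrow = np, ncol = nrow(cells),
                 dimnames = list(catalogue$peak_id, cell_key))
    owner <- setNames(rep(NA_character_, np), catalogue$peak_id)
    owner[truth_specific$peak_id] <- truth_specific$cultivar
    for (j in seq_len(ncol(mu))) {
      off <- !is.na(owner) & owner != cells$cultivar[j]
      mu[off, j] <- mu[off, j] / config$specific_fold
    }
    mu <- mu + matrix(rnorm(np * nrow(cells), 0, config$cell_sd), nrow = np)
    sample_cell <- paste(sheet$cultivar, sheet$condition, sheet$tissue, sep = "_")
    sig <- mu[, sample_cell, drop = FALSE]
    colnames(sig) <- sheet$sample_id
    if (config$noise_sd > 0) {
      sig <- sig + matrix(rnorm(length(sig), 0, config$noise_sd), nrow = np)
    }
    sig <- pmax(sig, 0)
    signal <- bind_cols(tibble(peak_id = catalogue$peak_id), as_tibble(sig))

    presence <- tidyr::expand_grid(sample_id = sheet$sample_id,
                                   peak_id = catalogue$peak_id)
    presence <- left_join(presence, sheet[, c("sample_id", "cultivar")], by = "sample_id")
    presence$owner <- owner[presence$peak_id]
    presence <- filter(presence, is.na(.data$owner) | .data$owner == .data$cultivar)
    presence <- select(presence, "sample_id", "peak_id")

    list(catalogue = catalogue, signal = signal, presence = presence,
         truth_specific = truth_specific)
  })
}

#' Plant distal-peak -> gene links and generate the expression matrix
#'
#' For each planted link the gene's expression is an affine function of
#' the peak's signal plus noise scaled so the correlation across samples
#' is close to `link_rho`. Unlinked genes get expression independent of
#' every peak. A fraction of unlinked genes additionally receive a planted
#' cultivar DE effect.
#'
#' @param config A `synthetic_config`.
#' @param genome Output of [simulate_genome()].
#' @param peaks Output of [simulate_peaks()].
#' @param seed Seed.
#' @return List with `expression` (wide tibble `gene_id` + samples),
#'   `truth_links` (tibble `peak_id`, `gene_id`) and `truth_de`
#'   (tibble `gene_id`, `log2fc`).
#' @export
simulate_expression <- function(config, genome, peaks,
                                seed = child_seed(config$seed, 3)) {
  withr::with_seed(seed, {
    sheet <- design_sample_sheet(config)
    genes <- genome$genes
    ng <- nrow(genes)
    sig <- as.matrix(peaks$signal[, sheet$sample_id, drop = FALSE])
    rownames(sig) <- peaks$signal$peak_id

    truth_links <- tibble(peak_id = character(), gene_id = character())
    if (config$n_true_links > 0) {
      anno <- annotate_compartment(peaks$catalogue, genes)
      distal <- filter(anno, .data$compartment == "distal")
      cand <- candidate_pairs(distal, genes)
      # avoid peaks whose cross-sample variance is dominated by the
      # cultivar-specific on/off pattern
      cand <- filter(cand, !(.data$peak_id %in% peaks$truth_specific$peak_id))
      cand <- cand[sample.int(nrow(cand)), ]
      cand <- distinct(cand, .data$gene_id, .keep_all = TRUE)
      cand <- distinct(cand, .data$peak_id, .keep_all = TRUE)
      if (nrow(cand) < config$n_true_links) {
        abort(sprintf(
          "cannot plant %d links: only %d distinct distal-peak/gene pairs within the window",
          config$n_true_links, nrow(cand)))
      }
      cand <- head(cand, config$n_true_links)
      truth_links <- select(cand, "peak_id", "gene_id")
    }

    # per-gene, per-cell baseline expression, independent of all peaks
    cells <- distinct(sheet, .data$cultivar, .data$condition, .data$tissue)
    cell_key <- paste(cells$cultivar, cells$condition, cells$tissue, sep = "_")
    base_g <- rlnorm(ng, meanlog = 3, sdlog = 1)
    cell_eff <- matrix(base_g, nrow = ng, ncol = nrow(cells),
                       dimnames = list(genes$gene_id, cell_key)) +
      matrix(rnorm(ng * nrow(cells), 0, config$cell_sd), nrow = ng)
    sample_cell <- paste(sheet$cultivar, sheet$condition, sheet$tissue, sep = "_")
    expr <- cell_eff[, sample_cell, drop = FALSE]
    colnames(expr) <- sheet$sample_id
    rownames(expr) <- genes$gene_id
    if (config$noise_sd > 0) {
      expr <- expr + matrix(rnorm(length(expr), 0, config$noise_sd), nrow = ng)
    }

    # planted DE between cultivars, on unlinked genes only
    free <- setdiff(genes$gene_id, truth_links$gene_id)
    n_de <- round(config$frac_de_genes * ng)
    n_de <- min(n_de, length(free))
    de_ids <- sample(free, n_de)
    de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
    truth_de <- tibble(gene_id = de_ids, log2fc = de_sign * config$de_log2fc)
    if (n_de > 0) {
      in_b <- sheet$cultivar == config$cultivars[2]
      expr[de_ids, in_b] <- expr[de_ids, in_b] * 2^truth_de$log2fc
    }

    # overwrite linked genes: expression = peak signal + scaled noise
    if (nrow(truth_links) > 0) {
      rho <- config$link_rho
      for (i in seq_len(nrow(truth_links))) {
        x <- sig[truth_links$peak_id[i], ]
        sd_x <- sd(x)
        eps_sd <- if (rho == 0) {
          NA_real_  # fall through: keep independent baseline
        } else if (rho == 1) 0 else sd_x * sqrt(1 / rho^2 - 1)
        if (!is.na(eps_sd)) {
          expr[truth_links$gene_id[i], ] <- pmax(x + 2 + rnorm(length(x), 0, eps_sd), 0)
        }
      }
    }
    expr <- pmax(expr, 0)
    expression <- bind_cols(tibble(gene_id = genes$gene_id), as_tibble(expr))
    list(expression = expression, truth_links = truth_links, truth_de = truth_de)
  })
}

chromatin_states <- function() sprintf("CS%d", 1:15)

#' Default 15-state to 5-category map
#'
#' States CS1-CS4 are Promoter, CS5-CS8 Transcription, CS9-CS11
#' Enhancer-like, CS12-CS14 Repressive and CS15 NoSignal.
#'
#' @return Tibble with `state` and `category`.
#' @export
default_state_categories <- function() {
  tibble(
    state = chromatin_states(),
    category = c(rep("Promoter", 4), rep("Transcription", 4),
                 rep("Enhancer-like", 3), rep("Repressive", 3), "NoSignal")
  )
}

#' Generate per-sample chromatin-state tracks with planted divergence
#'
#' All samples of the first cultivar share one 200-bp-bin state track; the
#' second cultivar's track differs at exactly
#' `round(frac_divergent_bins * n_bins)` bins, whose positions are
#' recorded in the truth.
#'
#' @param config A `synthetic_config`.
#' @param genome Output of [simulate_genome()].
#' @param seed Seed.
#' @return List with `tracks` (long tibble `sample_id`, `chrom`, `bin`,
#'   `state`; `bin` is the 0-based bin index) and `truth_divergent`
#'   (tibble `chrom`, `bin`).
#' @export
simulate_state_tracks <- function(config, genome,
                                  seed = child_seed(config$seed, 4)) {
  withr::with_seed(seed, {
    sheet <- design_sample_sheet(config)
    states <- chromatin_states()
    # NoSignal dominates real segmentations; remaining mass spread evenly
    probs <- c(rep(0.6 / 14, 14), 0.4)
    n_bins <- config$chrom_length_bp / config$bin_size_bp
    base <- purrr::map_dfr(genome$chrom_sizes$chrom, function(ch) {
      tibble(chrom = ch, bin = seq_len(n_bins) - 1L,
             state = sample(states, n_bins, replace = TRUE, prob = probs))
    })
    total <- nrow(base)
    n_div <- round(config$frac_divergent_bins * total)
    div_idx <- sort(sample.int(total, n_div))
    alt <- base
    if (n_div > 0) {
      cur <- alt$state[div_idx]
      alt$state[div_idx] <- vapply(cur, function(s) sample(setdiff(states, s), 1),
                                   character(1))
    }
    truth_divergent <- base[div_idx, c("chrom", "bin")]
    tracks <- purrr::map_dfr(seq_len(nrow(sheet)), function(i) {
      tr <- if (sheet$cultivar[i] == config$cultivars[1]) base else alt
      mutate(tr, sample_id = sheet$sample_id[i], .before = 1)
    })
    list(tracks = tracks, truth_divergent = truth_divergent)
  })
}

#' Generate motif-bearing dynamic regions and position weight matrices
#'
#' Two region groups (`foreground` = dynamic, `background`), each of
#' `n_motif_regions` random sequences. The enriched motif (consensus
#' `CGCCGCC`, an ERF-type GCC-box) is planted at `motif_fg_rate` in the
#' foreground and `motif_bg_rate` in the background; a control
#' GA-repeat motif (`GAGAGAG`, BPC-type) is planted at the background
#' rate in both groups. Every placement is recorded.
#'
#' @param config A `synthetic_config`.
#' @param seed Seed.
#' @return List with `regions` (tibble `region_id`, `group`, `seq`),
#'   `pwms` (list of PWM objects, see [pwm_from_consensus()]) and
#'   `truth_motifs` (tibble `region_id`, `motif_id`, `offset` 0-based,
#'   `strand`).
#' @export
simulate_motif_fixture <- function(config, seed = child_seed(config$seed, 5)) {
  withr::with_seed(seed, {
    n <- config$n_motif_regions
    len <- config$motif_region_bp
    ids <- c(sprintf("fg_%04d", seq_len(n)), sprintf("bg_%04d", seq_len(n)))
    group <- rep(c("foreground", "background"), each = n)
    seqs <- vapply(seq_along(ids), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    motifs <- list(
      list(motif_id = "GCCbox", consensus = "CGCCGCC",
           fg = config$motif_fg_rate, bg = config$motif_bg_rate),
      list(motif_id = "GArepeat", consensus = "GAGAGAG",
           fg = config$motif_bg_rate, bg = config$motif_bg_rate)
    )
    placements <- list()
    occupied <- vector("list", length(ids))  # plantings never overlap
    for (m in motifs) {
      w <- nchar(m$consensus)
      rate <- ifelse(group == "foreground", m$fg, m$bg)
      plant <- runif(length(ids)) < rate
      for (i in which(plant)) {
        taken <- occupied[[i]]
        free <- setdiff(seq_len(len - w + 1) - 1L, taken)
        if (length(free) == 0) next
        off <- free[sample.int(length(free), 1)]
        substr(seqs[i], off + 1, off + w) <- m$consensus
        occupied[[i]] <- c(taken, seq(off - w + 1L, off + w - 1L))
        placements[[length(placements) + 1]] <- tibble(
          region_id = ids[i], motif_id = m$motif_id, offset = off, strand = "+")
      }
    }
    truth_motifs <- if (length(placements)) bind_rows(placements) else {
      tibble(region_id = character(), motif_id = character(),
             offset = integer(), strand = character())
    }
    pwms <- lapply(motifs, function(m) pwm_from_consensus(m$consensus, m$motif_id))
    names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
    list(regions = tibble(region_id = ids, group = group, seq = seqs),
         pwms = pwms, truth_motifs = truth_motifs)
  })
}

simulate_qtl <- function(config, genome, seed = child_seed(config$seed, 6)) {
  withr::with_seed(seed, {
    purrr::map_dfr(genome$chrom_sizes$chrom, function(ch) {
      widths <- as.integer(round(runif(config$n_qtl_per_chrom, 20000, 50000)))
      pos <- place_nonoverlapping(config$n_qtl_per_chrom, widths,
                                  config$chrom_length_bp, "QTL intervals")
      tibble(chrom = ch, start = pos$start, end = pos$end)
    }) |>
      as_intervals() |>
      mutate(name = sprintf("qtl_%03d", dplyr::row_number()))
  })
}

simulate_te <- function(config, genome, seed = child_seed(config$seed, 7)) {
  withr::with_seed(seed, {
    purrr::map_dfr(genome$chrom_sizes$chrom, function(ch) {
      n <- 30
      widths <- as.integer(round(runif(n, 500, 3000)))
      pos <- place_nonoverlapping(n, widths, config$chrom_length_bp, "TE intervals")
      tibble(chrom = ch, start = pos$start, end = pos$end)
    }) |> as_intervals()
  })
}

simulate_traits <- function(config, seed = child_seed(config$seed, 8)) {
  withr::with_seed(seed, {
    traits <- c(Rl = 500, Rs = 120, Rv = 8, Rd = 0.45, Rt = 900, MRL = 30)
    # cultivar A responds to LN mainly through root size/volume, cultivar B
    # through tip number: contrasting low-nitrogen strategies
    ln_mult <- list(
      A = c(Rl = 1.35, Rs = 1.30, Rv = 1.40, Rd = 0.95, Rt = 1.10, MRL = 1.20),
      B = c(Rl = 1.10, Rs = 1.05, Rv = 1.10, Rd = 1.05, Rt = 1.30, MRL = 1.05)
    )
    names(ln_mult) <- config$cultivars
    grid <- tidyr::expand_grid(
      genotype = config$cultivars, condition = config$conditions,
      replicate = seq_len(config$n_trait_replicates), trait = names(traits))
    mutate(grid, value = purrr::pmap_dbl(
      list(.data$genotype, .data$condition, .data$trait),
      function(g, cond, tr) {
        mu <- traits[[tr]] * if (cond == "LN") ln_mult[[g]][[tr]] else 1
        max(mu * (1 + rnorm(1, 0, 0.08)), 0)
      }))
  })
}

#' Generate the full synthetic fixture
#'
#' Runs every generator under child seeds fanned out from `config$seed`
#' and assembles the complete fixture plus its truth object.
#'
#' @param config A `synthetic_config`.
#' @return An `epi_fixture` list: `config`, `chrom_sizes`, `genes`,
#'   `sample_sheet`, `catalogue`, `signal`, `presence`, `expression`,
#'   `state_tracks`, `motif_regions`, `pwms`, `qtl`, `te`, `traits` and
#'   `truth` (list with `links`, `specific_peaks`, `divergent_bins`,
#'   `motif_hits`, `de_genes`).
#' @export
simulate_epigenome <- function(config = synthetic_config()) {
  genome <- simulate_genome(config)
  pk <- simulate_peaks(config, genome)
  ex <- simulate_expression(config, genome, pk)
  st <- simulate_state_tracks(config, genome)
  mo <- simulate_motif_fixture(config)
  structure(list(
    config = config,
    chrom_sizes = genome$chrom_sizes,
    genes = genome$genes,
    sample_sheet = design_sample_sheet(config),
    catalogue = pk$catalogue,
    signal = pk$signal,
    presence = pk$presence,
    expression = ex$expression,
    state_tracks = st$tracks,
    motif_regions = mo$regions,
    pwms = mo$pwms,
    qtl = simulate_qtl(config, genome),
    te = simulate_te(config, genome),
    traits = simulate_traits(config),
    truth = list(
      links = ex$truth_links,
      specific_peaks = pk$truth_specific,
      divergent_bins = st$truth_divergent,
      motif_hits = mo$truth_motifs,
      de_genes = ex$truth_de
    )
  ), class = "epi_fixture")
}

#' @export
print.epi_fixture <- function(x, ...) {
  cat("<epi_fixture>\n")
  cat(sprintf("  %d chromosomes x %d bp, %d genes, %d peaks, %d samples\n",
              nrow(x$chrom_sizes), x$config$chrom_length_bp, nrow(x$genes),
              nrow(x$catalogue), nrow(x$sample_sheet)))
  cat(sprintf("  truth: %d links, %d specific peaks, %d divergent bins, %d motif placements, %d DE genes\n",
              nrow(x$truth$links), nrow(x$truth$specific_peaks),
              nrow(x$truth$divergent_bins), nrow(x$truth$motif_hits),
              nrow(x$truth$de_genes)))
  invisible(x)
}

#' Write a fixture to disk in standard formats
#'
#' Emits BED (catalogue, per-sample peaks, QTL, TE), GFF3 and flat-TSV
#' gene models, TSV matrices, dense state BEDs, FASTA motif regions,
#' JASPAR-format PWMs, the trait table, a truth JSON sidecar and a
#' manifest of paths with MD5 checksums.
#'
#' @param fixture An `epi_fixture`.
#' @param outdir Output directory (created if needed).
#' @return Manifest tibble (`path`, `md5`), invisibly also written to
#'   `manifest.tsv`.
#' @export
write_fixture <- function(fixture, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(paste0("cannot create output directory: ", outdir))
  p <- function(...) file.path(outdir, ...)
  readr::write_tsv(fixture$chrom_sizes, p("chrom_sizes.tsv"), progress = FALSE)
  write_gff3_genes(fixture$genes, p("genes.gff3"))
  write_gene_tsv(fixture$genes, p("genes.tsv"))
  readr::write_tsv(fixture$sample_sheet, p("sample_sheet.tsv"), progress = FALSE)
  write_bed(select(fixture$catalogue, "chrom", "start", "end", name = "peak_id"),
            p("peaks_catalogue.bed"))
  dir.create(p("peaks"), showWarnings = FALSE)
  for (s in fixture$sample_sheet$sample_id) {
    ids <- filter(fixture$presence, .data$sample_id == s)$peak_id
    sub <- filter(fixture$catalogue, .data$peak_id %in% ids)
    write_bed(select(sub, "chrom", "start", "end", name = "peak_id"),
              p("peaks", paste0(s, ".bed")))
  }
  readr::write_tsv(fixture$signal, p("signal.tsv"), progress = FALSE)
  readr::write_tsv(fixture$expression, p("expression.tsv"), progress = FALSE)
  dir.create(p("states"), showWarnings = FALSE)
  for (s in fixture$sample_sheet$sample_id) {
    tr <- filter(fixture$state_tracks, .data$sample_id == s)
    write_state_bed(tr, p("states", paste0(s, ".bed")),
                    bin_size = fixture$config$bin_size_bp)
  }
  seqs <- Biostrings::DNAStringSet(setNames(fixture$motif_regions$seq,
                                            fixture$motif_regions$region_id))
  Biostrings::writeXStringSet(seqs, p("motif_regions.fasta"))
  readr::write_tsv(select(fixture$motif_regions, "region_id", "group"),
                   p("motif_region_groups.tsv"), progress = FALSE)
  write_jaspar(fixture$pwms, p("motifs.jaspar"))
  write_bed(fixture$qtl, p("qtl.bed"))
  write_bed(fixture$te, p("te.bed"))
  readr::write_tsv(fixture$traits, p("traits.tsv"), progress = FALSE)
  jsonlite::write_json(lapply(fixture$truth, as.data.frame), p("truth.json"),
                       dataframe = "columns", digits = NA)
  cfg <- unclass(fixture$config)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.tsv"))
  manifest <- tibble(path = files,
                     md5 = unname(tools::md5sum(file.path(outdir, files))))
  readr::write_tsv(manifest, p("manifest.tsv"), progress = FALSE)
  manifest
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return An `epi_fixture` with the same components (PWM background and
#'   truth tables restored from their sidecars).
#' @export
read_fixture <- function(dir) {
  p <- function(...) file.path(dir, ...)
  cfg <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  config <- do.call(synthetic_config, cfg)
  sheet <- readr::read_tsv(p("sample_sheet.tsv"), show_col_types = FALSE, progress = FALSE)
  catalogue <- read_bed(p("peaks_catalogue.bed"))
  catalogue <- rename(catalogue, peak_id = "name")
  presence <- purrr::map_dfr(sheet$sample_id, function(s) {
    b <- read_bed(p("peaks", paste0(s, ".bed")))
    tibble(sample_id = s, peak_id = b$name)
  })
  tracks <- purrr::map_dfr(sheet$sample_id, function(s) {
    tr <- read_state_bed(p("states", paste0(s, ".bed")), bin_size = config$bin_size_bp)
    mutate(tr, sample_id = s, .before = 1)
  })
  seqs <- Biostrings::readDNAStringSet(p("motif_regions.fasta"))
  groups <- readr::read_tsv(p("motif_region_groups.tsv"), show_col_types = FALSE,
                            progress = FALSE)
  regions <- left_join(tibble(region_id = names(seqs),
                              seq = unname(as.character(seqs))),
                       groups, by = "region_id")[, c("region_id", "group", "seq")]
  truth_raw <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth <- lapply(truth_raw, function(d) {
    if (length(d) == 0) tibble() else as_tibble(as.data.frame(d))
  })
  structure(list(
    config = config,
    chrom_sizes = readr::read_tsv(p("chrom_sizes.tsv"), show_col_types = FALSE, progress = FALSE),
    genes = read_gene_tsv(p("genes.tsv")),
    sample_sheet = sheet,
    catalogue = catalogue,
    signal = readr::read_tsv(p("signal.tsv"), show_col_types = FALSE, progress = FALSE),
    presence = presence,
    expression = readr::read_tsv(p("expression.tsv"), show_col_types = FALSE, progress = FALSE),
    state_tracks = tracks,
    motif_regions = regions,
    pwms = read_jaspar(p("motifs.jaspar")),
    qtl = read_bed(p("qtl.bed")),
    te = read_bed(p("te.bed")),
    traits = readr::read_tsv(p("traits.tsv"), show_col_types = FALSE, progress = FALSE),
    truth = truth
  ), class = "epi_fixture")
}
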