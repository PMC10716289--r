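# Fisher-exact enrichment machinery, a PWM scanner with an exact null
# computed by dynamic programming, motif enrichment over dynamic regions,
# a simple DE test for synthetic runs, and the cultivar-bias
# classification of genes by DNA-variation vs histone-mark evidence.

#' Fisher exact test on a 2x2 table
#'
#' Cells follow the in-both / in-A-only / in-B-only / in-neither layout.
#' The p-value is the exact hypergeometric probability from
#' `stats::fisher.test`; the odds ratio is the sample odds ratio
#' `ad / bc` (`Inf` when `bc = 0` and `ad > 0`), not the conditional MLE.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param sided `"one_greater"` (enrichment of `a`) or `"two"`.
#' @return Tibble with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(a, b, c, d, sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) abort("all-zero contingency table")
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  alt <- if (sided == "one_greater") "greater" else "two.sided"
  p <- fisher.test(matrix(cells, nrow = 2, byrow = TRUE), alternative = alt)$p.value
  tibble(odds_ratio = or, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via `stats::p.adjust(method = "BH")`, with
#' input validation. The value-to-input mapping is invariant to input
#' order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

dna_letters <- c("A", "C", "G", "T")

new_pwm <- function(motif_id, probs, background = rep(0.25, 4)) {
  if (!is.matrix(probs) || nrow(probs) != 4) abort("PWM needs a 4-row matrix")
  dimnames(probs) <- NULL
  if (ncol(probs) < 4) abort("PWM width must be >= 4")
  sums <- colSums(probs)
  if (any(abs(sums - 1) > 1e-6)) abort("PWM columns must sum to 1")
  rownames(probs) <- dna_letters
  structure(list(motif_id = motif_id, probs = probs,
                 width = ncol(probs), background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (width %d), consensus %s\n", x$motif_id, x$width,
              paste(dna_letters[apply(x$probs, 2, which.max)], collapse = "")))
  invisible(x)
}

#' Build a position weight matrix from a consensus sequence
#'
#' The consensus base takes probability `dominance` at each position and
#' the rest is spread evenly.
#'
#' @param consensus Consensus string over A/C/G/T (width >= 4).
#' @param motif_id Motif identifier.
#' @param dominance Probability of the consensus base (default 0.97).
#' @return A `pwm` object.
#' @export
pwm_from_consensus <- function(consensus, motif_id = consensus, dominance = 0.97) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% dna_letters)) abort("consensus must be over A/C/G/T")
  probs <- vapply(bases, function(b) {
    p <- rep((1 - dominance) / 3, 4)
    p[match(b, dna_letters)] <- dominance
    p
  }, numeric(4))
  new_pwm(motif_id, probs)
}

#' Read / write position weight matrices in JASPAR text format
#'
#' The JASPAR layout is a `>id name` header followed by four rows
#' `A [ ... ]` .. `T [ ... ]`. Counts or probabilities are accepted;
#' columns are normalised to probabilities on read.
#'
#' @param path File path.
#' @return `read_jaspar`: named list of `pwm` objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort("no JASPAR records found")
  pwms <- lapply(seq_along(heads), function(i) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    rows <- lines[heads[i] + 1:4]
    mat <- do.call(rbind, lapply(rows, function(l) {
      nums <- gsub(".*\\[|\\].*", "", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }))
    probs <- sweep(mat, 2, colSums(mat), "/")
    new_pwm(id, probs)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
  pwms
}

#' @rdname read_jaspar
#' @param pwms Named list of `pwm` objects.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(w) {
    c(paste0(">", w$motif_id, " ", w$motif_id),
      vapply(1:4, function(i) {
        sprintf("%s  [ %s ]", dna_letters[i],
                paste(format(w$probs[i, ], digits = 10), collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

# log-odds score matrix with a probability floor to avoid -Inf
pwm_score_matrix <- function(pwm, floor = 1e-4) {
  probs <- pmax(pwm$probs, floor)
  probs <- sweep(probs, 2, colSums(probs), "/")
  log2(probs / pwm$background)
}

reverse_complement_pwm <- function(pwm) {
  probs <- pwm$probs[4:1, ncol(pwm$probs):1, drop = FALSE]
  rownames(probs) <- dna_letters
  new_pwm(pwm$motif_id, probs, pwm$background)
}

# exact null distribution of the log-odds score under the background
# model, by dynamic programming over a discretized score lattice. The
# scanner scores observed windows on the same integer lattice, so lookup
# and null are consistent; the only approximation is the initial rounding
# of the score matrix (bounded by width * delta / 2).
pwm_null_tail <- function(score_mat, background, n_lattice = 1000) {
  rng <- sum(apply(score_mat, 2, max)) - sum(apply(score_mat, 2, min))
  delta <- if (rng > 0) rng / n_lattice else 1
  int_mat <- round(score_mat / delta)
  w <- ncol(int_mat)
  offset <- sum(apply(int_mat, 2, min))
  span <- sum(apply(int_mat, 2, max)) - offset
  dist <- c(1, rep(0, span))  # probability over (int score - offset)
  for (j in seq_len(w)) {
    nxt <- rep(0, span + 1)
    col_min <- min(int_mat[, j])
    for (b in 1:4) {
      shift <- int_mat[b, j] - col_min
      idx <- seq_len(span + 1 - shift)
      nxt[idx + shift] <- nxt[idx + shift] + background[b] * dist[idx]
    }
    dist <- nxt
  }
  tail_p <- rev(cumsum(rev(dist)))
  list(int_mat = int_mat, delta = delta, offset = offset,
       p_of_int = function(k_int) {
         k <- k_int - offset + 1
         k <- pmax(k, 1)
         ifelse(k > length(tail_p), 0, tail_p[k])
       })
}

#' Scan sequences with a position weight matrix
#'
#' Per-position log2-odds scores against the background model on both
#' strands; a position is a hit when the exact null distribution of the
#' score (dynamic programming over a discretized score lattice under the
#' background) gives `P(score >= s) <= p_threshold`. `N` bases score as
#' background (zero log-odds contribution). Sequences shorter than the
#' motif yield no hits.
#'
#' @param regions Tibble with `region_id` and `seq` columns (or a named
#'   character vector of sequences).
#' @param pwm A `pwm` object.
#' @param p_threshold Score-level significance threshold (default 1e-4).
#' @param prob_floor Per-cell probability floor before log-odds.
#' @return Tibble `region_id`, `motif_id`, `start` (1-based), `strand`,
#'   `score`, `p`, `match` (forward-strand subsequence).
#' @export
pwm_scan <- function(regions, pwm, p_threshold = 1e-4, prob_floor = 1e-4) {
  if (!is.data.frame(regions)) {
    regions <- tibble(region_id = names(regions), seq = unname(regions))
  }
  mats <- list(`+` = pwm_score_matrix(pwm, prob_floor),
               `-` = pwm_score_matrix(reverse_complement_pwm(pwm), prob_floor))
  tails <- lapply(mats, pwm_null_tail, background = pwm$background)
  w <- pwm$width
  short <- nchar(regions$seq) < w
  if (any(short)) {
    inform(sprintf("pwm_scan: %d sequence(s) shorter than the motif skipped",
                   sum(short)))
  }
  hits <- purrr::map_dfr(which(!short), function(i) {
    chars <- strsplit(toupper(regions$seq[i]), "")[[1]]
    code <- match(chars, dna_letters)  # NA for N and other ambiguity codes
    L <- length(code)
    n_off <- L - w + 1
    purrr::map_dfr(c("+", "-"), function(strand) {
      sm <- mats[[strand]]
      null <- tails[[strand]]
      scores <- numeric(n_off)
      scores_int <- numeric(n_off)
      for (j in seq_len(w)) {
        contrib <- sm[cbind(code[j:(j + n_off - 1)], j)]
        contrib[is.na(contrib)] <- 0
        scores <- scores + contrib
        contrib_int <- null$int_mat[cbind(code[j:(j + n_off - 1)], j)]
        contrib_int[is.na(contrib_int)] <- 0
        scores_int <- scores_int + contrib_int
      }
      p <- null$p_of_int(scores_int)
      keep <- which(p <= p_threshold)
      if (length(keep) == 0) return(tibble())
      tibble(region_id = regions$region_id[i], motif_id = pwm$motif_id,
             start = keep, strand = strand, score = scores[keep],
             p = p[keep],
             match = substring(regions$seq[i], keep, keep + w - 1))
    })
  })
  if (nrow(hits) == 0) {
    hits <- tibble(region_id = character(), motif_id = character(),
                   start = integer(), strand = character(),
                   score = numeric(), p = numeric(), match = character())
  }
  hits
}

#' Motif enrichment between foreground and background region groups
#'
#' The unit is regions with at least one hit. For each motif a 2x2 table
#' (foreground hit / no-hit vs background hit / no-hit) goes through a
#' one-sided-greater Fisher exact test; BH adjustment is applied across
#' motifs.
#'
#' @param foreground_hits,background_hits Hit tibbles (`region_id`,
#'   `motif_id`), e.g. from [pwm_scan()] over each group.
#' @param n_foreground,n_background Total region counts per group.
#' @return Tibble `motif_id`, `n_fg`, `n_bg`, `odds_ratio`, `p`, `p_adj`.
#' @export
motif_enrichment <- function(foreground_hits, background_hits,
                             n_foreground, n_background) {
  if (n_foreground <= 0) abort("empty foreground region set")
  motifs <- union(unique(foreground_hits$motif_id),
                  unique(background_hits$motif_id))
  if (length(motifs) == 0) abort("no motif hits in either group")
  out <- purrr::map_dfr(motifs, function(m) {
    n_fg <- dplyr::n_distinct(filter(foreground_hits, .data$motif_id == m)$region_id)
    n_bg <- dplyr::n_distinct(filter(background_hits, .data$motif_id == m)$region_id)
    ft <- fisher_enrichment(n_fg, n_foreground - n_fg,
                            n_bg, n_background - n_bg, sided = "one_greater")
    tibble(motif_id = m, n_fg = n_fg, n_bg = n_bg,
           odds_ratio = ft$odds_ratio, p = ft$p)
  })
  mutate(out, p_adj = bh_adjust(.data$p))
}

#' Overlap test between two gene sets within a universe
#'
#' Builds the 2x2 table of membership against the universe and delegates
#' to [fisher_enrichment()] (one-sided greater). `fold` is observed over
#' expected overlap under independence.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return Tibble `n_overlap`, `fold`, `odds_ratio`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0) abort("empty universe")
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  n <- length(universe)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c <- length(setdiff(set_b, set_a))
  d <- n - a - b - c
  expected <- length(set_a) * length(set_b) / n
  ft <- fisher_enrichment(a, b, c, d, sided = "one_greater")
  tibble(n_overlap = a, fold = if (expected > 0) a / expected else NA_real_,
         odds_ratio = ft$odds_ratio, p = ft$p)
}

#' Simple differential-expression test for synthetic runs
#'
#' Welch t on `log2(TPM + 1)` per gene between two sample groups, BH
#' adjustment, and a status call under one of two presets:
#' `"results"` (FDR < 0.05 and fold-change >= 1.5) or `"rnaseq"`
#' (adjusted p < 0.05 and |log2 fold-change| > 1). External DE tables can
#' be supplied to downstream steps instead; this test exists so synthetic
#' runs are self-contained.
#'
#' @param expr Wide expression tibble (`gene_id` + samples).
#' @param group_a,group_b Sample-column vectors.
#' @param preset Threshold preset.
#' @param fdr,fc Cutoffs overriding the preset (fold-change on the
#'   natural scale).
#' @return Tibble `gene_id`, `log2fc` (B over A), `p`, `p_adj`, `de`.
#' @export
de_test <- function(expr, group_a, group_b,
                    preset = c("results", "rnaseq"), fdr = NULL, fc = NULL) {
  preset <- match.arg(preset)
  if (is.null(fdr)) fdr <- 0.05
  if (is.null(fc)) fc <- if (preset == "results") 1.5 else 2
  la <- log2(as.matrix(expr[, group_a, drop = FALSE]) + 1)
  lb <- log2(as.matrix(expr[, group_b, drop = FALSE]) + 1)
  lfc <- rowMeans(lb) - rowMeans(la)
  p <- vapply(seq_len(nrow(la)), function(i) welch_or_pool_p(la[i, ], lb[i, ]),
              numeric(1))
  p[is.na(p)] <- 1
  p_adj <- bh_adjust(p)
  tibble(gene_id = expr$gene_id, log2fc = lfc, p = p, p_adj = p_adj,
         de = p_adj < fdr & abs(lfc) >= log2(fc))
}

#' Classify cultivar-biased genes by regulatory evidence layers
#'
#' For each gene, booleans record whether its regulatory region (the
#' strand-aware promoter window) overlaps (i) DNA variation intervals,
#' (ii) differential H3K27ac peaks and (iii) differential H3K27me3 peaks.
#' The summary gives the fractions of differentially expressed genes
#' carrying each evidence type.
#'
#' @param genes Gene-model tibble.
#' @param de_table Tibble `gene_id`, `de` (e.g. from [de_test()] or an
#'   imported table).
#' @param promoter_variants,diff_ac_peaks,diff_me3_peaks Interval tibbles
#'   (any may be `NULL`, giving all-FALSE booleans for that layer).
#' @param promoter_bp Promoter window size.
#' @return A `bias_classification` object; `tidy()` gives the per-gene
#'   table, `glance()` the DE-gene fractions.
#' @export
classify_bias <- function(genes, de_table, promoter_variants = NULL,
                          diff_ac_peaks = NULL, diff_me3_peaks = NULL,
                          promoter_bp = 3000) {
  genes <- validate_genes(genes)
  missing <- setdiff(de_table$gene_id, genes$gene_id)
  if (length(missing) > 0) {
    warn(sprintf("classify_bias: %d DE-table gene(s) lack coordinates; excluded",
                 length(missing)))
  }
  prom <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = as.integer(ifelse(genes$strand == "+",
                              pmax(0, genes$tss - promoter_bp), genes$tss)),
    end = as.integer(ifelse(genes$strand == "+", genes$tss + 1L,
                            genes$tss + promoter_bp + 1L))
  )
  layer <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, nrow(prom)))
    overlaps_any(prom, as_intervals(iv))
  }
  table <- tibble(
    gene_id = prom$gene_id,
    dna_variation_in_regulatory = layer(promoter_variants),
    h3k27ac_variation = layer(diff_ac_peaks),
    h3k27me3_variation = layer(diff_me3_peaks)
  )
  table <- inner_join(select(de_table, "gene_id", de_status = "de"),
                      table, by = "gene_id")
  de_genes <- filter(table, .data$de_status)
  frac <- function(x) if (nrow(de_genes) > 0) mean(x) else 0
  summary <- tibble(
    n_de_genes = nrow(de_genes),
    frac_dna_variation = frac(de_genes$dna_variation_in_regulatory),
    frac_h3k27ac = frac(de_genes$h3k27ac_variation),
    frac_h3k27me3 = frac(de_genes$h3k27me3_variation)
  )
  structure(list(table = table, summary = summary),
            class = "bias_classification")
}

#' @export
print.bias_classification <- function(x, ...) {
  cat("<bias_classification>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname classify_bias
#' @param x A `bias_classification`.
#' @param ... Unused.
#' @method tidy bias_classification
#' @export
tidy.bias_classification <- function(x, ...) x$table

#' @rdname classify_bias
#' @method glance bias_classification
#' @export
glance.bias_classification <- function(x, ...) x$summary
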