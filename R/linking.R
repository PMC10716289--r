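# Distal regulatory region -> gene assignment: candidate pairs within a
# 0.5 Mb window, cross-sample Pearson correlation of peak signal (FPKM)
# vs gene expression (TPM), an empirical null built from random
# trans-chromosome peak/gene pairs, and z-based p-values.

#' Candidate distal-peak -> gene pairs within a distance window
#'
#' All same-chromosome (peak, gene) pairs whose midpoint-to-TSS distance
#' is at most `window` (closed bound; the default 500 kb is the standard
#' candidate radius for distal-element target assignment). Callers should
#' pre-filter peaks to the distal compartment.
#'
#' @param peaks Interval tibble with `peak_id`.
#' @param genes Gene-model tibble.
#' @param window Maximum distance in bp (default 5e5).
#' @return Tibble `peak_id`, `gene_id`, `chrom`, `distance`.
#' @export
candidate_pairs <- function(peaks, genes, window = 5e5) {
  peaks <- as_tibble(peaks)
  genes <- validate_genes(genes)
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    inform("candidate_pairs: empty peak or gene set")
    return(tibble(peak_id = character(), gene_id = character(),
                  chrom = character(), distance = numeric()))
  }
  p <- mutate(peaks, mid = floor((.data$start + .data$end) / 2))
  out <- inner_join(select(p, "peak_id", "chrom", "mid"),
                    select(genes, "gene_id", "chrom", "tss"),
                    by = "chrom", relationship = "many-to-many")
  out <- mutate(out, distance = abs(.data$mid - .data$tss))
  out <- filter(out, .data$distance <= window)
  distinct(select(out, "peak_id", "gene_id", "chrom", "distance"))
}

align_matrices <- function(signal, expr) {
  s_cols <- setdiff(names(signal), "peak_id")
  e_cols <- setdiff(names(expr), "gene_id")
  shared <- intersect(s_cols, e_cols)
  if (length(shared) < 3) abort("fewer than 3 shared samples between matrices")
  sm <- as.matrix(signal[, shared, drop = FALSE])
  rownames(sm) <- signal$peak_id
  em <- as.matrix(expr[, shared, drop = FALSE])
  rownames(em) <- expr$gene_id
  list(signal = sm, expr = em, samples = shared)
}

rowwise_pearson <- function(x, y) {
  # Pearson r between matched rows of two matrices
  n <- ncol(x)
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  num <- rowSums(xc * yc)
  den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

#' Pearson correlation of candidate pairs across samples
#'
#' Signal (FPKM-like) and expression (TPM) are aligned on shared sample
#' columns; each pair gets the Pearson correlation of its peak row and
#' gene row. Pairs with a constant vector are flagged `NA`.
#'
#' @param pairs Tibble with `peak_id`, `gene_id` (e.g. from
#'   [candidate_pairs()]).
#' @param signal Wide signal tibble (`peak_id` + samples).
#' @param expr Wide expression tibble (`gene_id` + samples).
#' @return `pairs` with an added `r` column.
#' @export
pair_correlation <- function(pairs, signal, expr) {
  al <- align_matrices(signal, expr)
  miss_p <- setdiff(pairs$peak_id, rownames(al$signal))
  miss_g <- setdiff(pairs$gene_id, rownames(al$expr))
  if (length(miss_p) || length(miss_g)) {
    abort("pairs reference peaks/genes absent from the matrices")
  }
  r <- rowwise_pearson(al$signal[pairs$peak_id, , drop = FALSE],
                       al$expr[pairs$gene_id, , drop = FALSE])
  mutate(as_tibble(pairs), r = unname(r))
}

#' Empirical trans-chromosome null for link correlations
#'
#' Draws `n_draws` random (peak, gene) pairs with the peak and the gene on
#' different chromosomes, computes their correlations, and summarises the
#' null as its mean and standard deviation. Degenerate (constant-vector)
#' draws are redrawn. Requires at least two chromosomes.
#'
#' @param signal,expr Wide matrices as in [pair_correlation()].
#' @param peaks Interval tibble with `peak_id`, `chrom`.
#' @param genes Gene-model tibble.
#' @param n_draws Number of null draws (default 10000).
#' @param seed Integer seed.
#' @return A `link_null` object: list with `mu`, `sigma`, `n_draws`,
#'   `seed`, `draws` (tibble `peak_id`, `gene_id`, `r`).
#' @export
build_link_null <- function(signal, expr, peaks, genes, n_draws = 10000,
                            seed = 1) {
  if (length(unique(peaks$chrom)) < 2 || length(unique(genes$chrom)) < 2) {
    abort("trans-chromosome null needs at least two chromosomes")
  }
  al <- align_matrices(signal, expr)
  peaks <- filter(as_tibble(peaks), .data$peak_id %in% rownames(al$signal))
  genes <- filter(as_tibble(genes), .data$gene_id %in% rownames(al$expr))
  peak_chrom <- setNames(peaks$chrom, peaks$peak_id)
  gene_chrom <- setNames(genes$chrom, genes$gene_id)
  withr::with_seed(seed, {
    draws <- NULL
    need <- n_draws
    while (need > 0) {
      pi <- sample(peaks$peak_id, need, replace = TRUE)
      gi <- sample(genes$gene_id, need, replace = TRUE)
      ok <- peak_chrom[pi] != gene_chrom[gi]
      if (!any(ok)) next
      r <- rowwise_pearson(al$signal[pi[ok], , drop = FALSE],
                           al$expr[gi[ok], , drop = FALSE])
      good <- !is.na(r)
      draws <- bind_rows(draws, tibble(peak_id = pi[ok][good],
                                       gene_id = gi[ok][good],
                                       r = unname(r[good])))
      need <- n_draws - nrow(draws)
    }
    structure(list(mu = mean(draws$r), sigma = sd(draws$r),
                   n_draws = n_draws, seed = seed, draws = draws),
              class = "link_null")
  })
}

#' @export
print.link_null <- function(x, ...) {
  cat(sprintf("<link_null> mu = %.4f, sigma = %.4f (%d trans-chromosome draws)\n",
              x$mu, x$sigma, x$n_draws))
  invisible(x)
}

#' @rdname build_link_null
#' @param x A `link_null`.
#' @param ... Unused.
#' @method tidy link_null
#' @export
tidy.link_null <- function(x, ...) x$draws

#' @rdname build_link_null
#' @method glance link_null
#' @export
glance.link_null <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, n_draws = x$n_draws, seed = x$seed)
}

#' Score candidate links against the empirical null
#'
#' `z = (r - mu) / sigma`; the p-value is the standard-normal upper tail
#' for `direction = "positive"` (activating-mark logic) or the two-sided
#' tail. Significance is `p < alpha` on raw p-values by default, or on
#' BH-adjusted p-values with `bh = TRUE`.
#'
#' @param pairs Tibble with an `r` column (from [pair_correlation()]).
#' @param null A `link_null`.
#' @param alpha Significance cutoff (default 0.05).
#' @param direction `"positive"` or `"two_sided"`.
#' @param bh Apply Benjamini-Hochberg before thresholding.
#' @return `pairs` with `z`, `p`, `p_adj`, `significant`.
#' @export
score_links <- function(pairs, null, alpha = 0.05,
                        direction = c("positive", "two_sided"), bh = FALSE) {
  direction <- match.arg(direction)
  if (!inherits(null, "link_null")) abort("null must be a link_null object")
  if (is.na(null$sigma) || null$sigma <= 0) abort("null sigma must be positive")
  z <- (pairs$r - null$mu) / null$sigma
  p <- if (direction == "positive") pnorm(z, lower.tail = FALSE) else 2 * pnorm(-abs(z))
  out <- mutate(as_tibble(pairs), z = z, p = p, p_adj = p.adjust(p, "BH"))
  mutate(out, significant = !is.na(.data$p) &
           (if (bh) .data$p_adj else .data$p) < alpha)
}

#' End-to-end distal-peak -> gene linking
#'
#' Annotates peaks, restricts to the distal compartment, forms candidate
#' pairs within the window, correlates them across samples, builds the
#' trans-chromosome null and scores every pair. Deterministic for a fixed
#' seed.
#'
#' @param signal,expr Wide matrices (`peak_id`/`gene_id` + samples).
#' @param peaks Interval tibble with `peak_id` (the peak catalogue).
#' @param genes Gene-model tibble.
#' @param window Candidate window in bp (default 5e5).
#' @param n_draws Null draws (default 10000).
#' @param alpha,direction,bh Passed to [score_links()].
#' @param promoter_bp Promoter window for the distal filter.
#' @param seed Integer seed.
#' @return A `link_analysis` object: list with `links` (scored pair
#'   tibble), `null`, and `summary` (n pairs, n significant, unique peak
#'   and gene counts among significant links).
#' @export
link_pipeline <- function(signal, expr, peaks, genes, window = 5e5,
                          n_draws = 10000, alpha = 0.05,
                          direction = "positive", bh = FALSE,
                          promoter_bp = 3000, seed = 1) {
  anno <- annotate_compartment(peaks, genes, promoter_bp = promoter_bp)
  distal <- filter(anno, .data$compartment == "distal")
  pairs <- candidate_pairs(distal, genes, window = window)
  pairs <- pair_correlation(pairs, signal, expr)
  null <- build_link_null(signal, expr, peaks, genes, n_draws = n_draws,
                          seed = seed)
  links <- score_links(pairs, null, alpha = alpha, direction = direction, bh = bh)
  sig <- filter(links, .data$significant)
  structure(list(
    links = links, null = null,
    summary = tibble(
      n_candidates = nrow(links),
      n_significant = nrow(sig),
      n_unique_peaks = dplyr::n_distinct(sig$peak_id),
      n_unique_genes = dplyr::n_distinct(sig$gene_id)
    )
  ), class = "link_analysis")
}

#' @export
print.link_analysis <- function(x, ...) {
  cat("<link_analysis>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname link_pipeline
#' @param x A `link_analysis`.
#' @param ... Unused.
#' @method tidy link_analysis
#' @export
tidy.link_analysis <- function(x, ...) x$links

#' @rdname link_pipeline
#' @method glance link_analysis
#' @export
glance.link_analysis <- function(x, ...) {
  bind_cols(x$summary, glance(x$null)[, c("mu", "sigma", "n_draws")])
}

#' Null-vs-observed correlation plot for a link analysis
#'
#' @param object A `link_analysis`.
#' @param ... Unused.
#' @return A ggplot overlaying the null correlation density and the
#'   observed candidate-pair correlations.
#' @method autoplot link_analysis
#' @export
autoplot.link_analysis <- function(object, ...) {
  d <- bind_rows(
    mutate(object$null$draws[, "r"], set = "trans-chromosome null"),
    mutate(object$links[, "r"], set = "candidate pairs")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "Pearson r (signal vs expression)", y = "density")
}
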