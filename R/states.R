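# Chromatin-state track algebra over fixed-width (default 200 bp) bins:
# dense-BED segmentation I/O, dynamic-bin calling, per-category change
# ratios, 1 - Jaccard variability scores, and per-state summaries.

#' Read a dense segmentation BED into a bin-level state track
#'
#' Each BED row is a run of constant state; rows are expanded to bins of
#' `bin_size`. Both `E1`-style and bare numeric state labels are accepted
#' and normalised to character.
#'
#' @param path Dense BED (`chrom`, `start`, `end`, `state`).
#' @param bin_size Bin width in bp (default 200).
#' @return Long tibble `chrom`, `bin` (0-based index), `state`.
#' @export
read_state_bed <- function(path, bin_size = 200) {
  b <- read_bed(path)
  if (is.null(b[["name"]])) abort("segmentation BED needs a 4th (state) column")
  if (any(b$start %% bin_size != 0) || any(b$end %% bin_size != 0)) {
    abort(sprintf("segmentation runs are not aligned to %d bp bins", bin_size))
  }
  n <- (b$end - b$start) / bin_size
  out <- tibble(
    chrom = rep(b$chrom, n),
    bin = unlist(purrr::map2(b$start / bin_size, n,
                             function(s, k) seq.int(s, length.out = k))),
    state = rep(as.character(b[["name"]]), n)
  )
  arrange(out, .data$chrom, .data$bin)
}

#' Write a bin-level state track as a dense segmentation BED
#'
#' Adjacent bins with the same state are collapsed into runs.
#'
#' @param track Long tibble `chrom`, `bin`, `state` (a `sample_id` column
#'   is ignored).
#' @param path Output path.
#' @param bin_size Bin width in bp.
#' @return Invisibly, `path`.
#' @export
write_state_bed <- function(track, path, bin_size = 200) {
  track <- arrange(as_tibble(track), .data$chrom, .data$bin)
  runs <- track |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(1L, diff(.data$bin)) != 1L |
                          .data$state != dplyr::lag(.data$state, default = "\r"))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$bin) * bin_size,
              end = (max(.data$bin) + 1) * bin_size,
              name = .data$state[1], .groups = "drop") |>
    select("chrom", "start", "end", "name")
  write_bed(runs, path)
}

check_comparable <- function(a, b) {
  key_a <- paste(a$chrom, a$bin)
  key_b <- paste(b$chrom, b$bin)
  if (nrow(a) != nrow(b) || !setequal(key_a, key_b)) {
    abort("state tracks are not comparable: different chromosomes or binning")
  }
}

#' Call dynamic bins between two state tracks
#'
#' A bin is dynamic exactly where its state label differs between the two
#' samples. Symmetric in its arguments.
#'
#' @param a,b Long state tracks (`chrom`, `bin`, `state`) on identical
#'   binning.
#' @return Tibble `chrom`, `bin`, `state_a`, `state_b`, `dynamic`.
#' @export
call_dynamic_bins <- function(a, b) {
  a <- arrange(as_tibble(a), .data$chrom, .data$bin)
  b <- arrange(as_tibble(b), .data$chrom, .data$bin)
  check_comparable(a, b)
  out <- inner_join(
    select(a, "chrom", "bin", state_a = "state"),
    select(b, "chrom", "bin", state_b = "state"),
    by = c("chrom", "bin")
  )
  mutate(out, dynamic = .data$state_a != .data$state_b)
}

#' Per-category chromatin-state change ratio
#'
#' For each of the five state categories, the fraction of bins carrying
#' that category in the reference track `a` whose label differs in `b`.
#' With `orientation = "both"` the reverse-direction ratio (reference `b`)
#' and the mean of the two are also reported. Categories with zero bins in
#' the reference are reported as `NA`.
#'
#' @param a,b State tracks on identical binning.
#' @param catmap State-to-category map (default
#'   [default_state_categories()]).
#' @param orientation `"reference"` (ratio w.r.t. `a`) or `"both"`.
#' @return Tibble `category`, `ratio` (and `ratio_rev`, `ratio_mean` for
#'   `"both"`).
#' @export
change_ratio_by_category <- function(a, b, catmap = default_state_categories(),
                                     orientation = c("reference", "both")) {
  orientation <- match.arg(orientation)
  dyn <- call_dynamic_bins(a, b)
  one_way <- function(ref_state, dynamic) {
    d <- tibble(state = ref_state, dynamic = dynamic) |>
      left_join(catmap, by = "state") |>
      group_by(.data$category) |>
      summarise(ratio = mean(.data$dynamic), .groups = "drop")
    full <- tibble(category = unique(catmap$category))
    left_join(full, d, by = "category")
  }
  fwd <- one_way(dyn$state_a, dyn$dynamic)
  if (any(is.na(fwd$ratio))) {
    inform("change_ratio_by_category: categories absent from the reference reported as NA")
  }
  if (orientation == "reference") return(fwd)
  rev <- one_way(dyn$state_b, dyn$dynamic)
  out <- left_join(fwd, rename(rev, ratio_rev = "ratio"), by = "category")
  mutate(out, ratio_mean = (.data$ratio + .data$ratio_rev) / 2)
}

#' Histone-mark variability score across a design factor
#'
#' For each mark, the score over a factor (e.g. `cultivar`, `condition`,
#' `tissue`) is the mean of `1 - Jaccard(peak set pair)` over all sample
#' pairs that differ in that factor while every other design column is
#' held fixed. Scores lie in `[0, 1]`: 0 when all peak sets coincide,
#' 1 when within-stratum pairs are disjoint.
#'
#' @param peaks Long peak tibble: `sample_id`, `chrom`, `start`, `end`
#'   and optionally `mark` (scores are computed per mark).
#' @param sample_sheet Tibble with `sample_id` plus design columns.
#' @param factor Name of the design column to score.
#' @return Tibble `mark`, `factor`, `score`, `n_pairs`.
#' @export
variability_score <- function(peaks, sample_sheet, factor) {
  if (!factor %in% names(sample_sheet)) {
    abort(paste0("factor column not in sample sheet: ", factor))
  }
  peaks <- as_tibble(peaks)
  if (!"mark" %in% names(peaks)) peaks$mark <- "mark"
  others <- setdiff(names(sample_sheet), c("sample_id", factor))
  sheet <- filter(sample_sheet, .data$sample_id %in% unique(peaks$sample_id))
  strata <- if (length(others) == 0) list(all = sheet$sample_id) else {
    split(sheet$sample_id,
          interaction(sheet[others], drop = TRUE, lex.order = TRUE))
  }
  level_of <- setNames(sheet[[factor]], sheet$sample_id)
  purrr::map_dfr(unique(peaks$mark), function(mk) {
    pk <- filter(peaks, .data$mark == mk)
    sets <- split(pk[, c("chrom", "start", "end")], pk$sample_id)
    dists <- purrr::map(strata, function(ids) {
      ids <- intersect(ids, names(sets))
      if (length(unique(level_of[ids])) < 2) {
        warn(sprintf("variability_score: stratum with a single '%s' level skipped", factor))
        return(numeric(0))
      }
      pairs <- utils::combn(ids, 2, simplify = FALSE)
      pairs <- purrr::keep(pairs, function(p) level_of[p[1]] != level_of[p[2]])
      purrr::map_dbl(pairs, function(p) {
        1 - interval_jaccard(sets[[p[1]]], sets[[p[2]]])
      })
    })
    d <- unlist(dists)
    tibble(mark = mk, factor = factor,
           score = if (length(d)) mean(d) else NA_real_,
           n_pairs = length(d))
  })
}

#' Summarise a chromatin-state track
#'
#' Per state: genome coverage fraction (sums to 1 over states), TE
#' enrichment (observed/expected bp overlap with the TE annotation) and
#' the median expression of genes whose TSS bin carries the state.
#'
#' @param track A state track (`chrom`, `bin`, `state`).
#' @param genes Gene-model tibble.
#' @param expr Wide expression tibble (`gene_id` + sample columns);
#'   per-gene expression is the row mean.
#' @param te Interval tibble of transposable elements (optional).
#' @param bin_size Bin width in bp.
#' @return Tibble `state`, `coverage`, `te_enrichment`,
#'   `median_expression`.
#' @export
summarize_states <- function(track, genes, expr = NULL, te = NULL,
                             bin_size = 200) {
  track <- as_tibble(track)
  cov <- track |>
    group_by(.data$state) |>
    summarise(n_bins = n(), .groups = "drop") |>
    mutate(coverage = .data$n_bins / sum(.data$n_bins))

  te_enr <- tibble(state = cov$state, te_enrichment = NA_real_)
  if (!is.null(te) && nrow(te) > 0) {
    te <- merge_intervals(te)
    genome_bp <- nrow(track) * bin_size
    te_bp_total <- interval_bp(te)
    te_enr <- purrr::map_dfr(cov$state, function(s) {
      bins <- filter(track, .data$state == s)
      iv <- tibble(chrom = bins$chrom, start = bins$bin * bin_size,
                   end = (bins$bin + 1) * bin_size)
      obs <- interval_bp(intersect_intervals(iv, te))
      expct <- te_bp_total * (nrow(bins) * bin_size) / genome_bp
      tibble(state = s, te_enrichment = if (expct > 0) obs / expct else NA_real_)
    })
  }

  med_expr <- tibble(state = cov$state, median_expression = NA_real_)
  if (!is.null(expr) && nrow(genes) > 0) {
    em <- rowMeans(as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE]))
    ge <- tibble(gene_id = expr$gene_id, mean_expr = em)
    tss_bins <- mutate(genes, bin = .data$tss %/% bin_size)
    tss_states <- inner_join(tss_bins, track, by = c("chrom", "bin"))
    med_expr <- tss_states |>
      left_join(ge, by = "gene_id") |>
      group_by(.data$state) |>
      summarise(median_expression = median(.data$mean_expr, na.rm = TRUE),
                .groups = "drop")
  }

  cov |>
    left_join(te_enr, by = "state") |>
    left_join(med_expr, by = "state") |>
    select("state", "coverage", "te_enrichment", "median_expression")
}

#' Bar chart of variability scores
#'
#' @param scores Output of [variability_score()] (rows may mix factors).
#' @return A ggplot.
#' @export
plot_variability <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$factor, y = .data$score,
                                       fill = .data$mark)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "variability (mean 1 - Jaccard)")
}

#' Bar chart of per-category state change ratios
#'
#' @param ratios Output of [change_ratio_by_category()].
#' @return A ggplot.
#' @export
plot_change_ratio <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$category, y = .data$ratio)) +
    ggplot2::geom_col(fill = "#00798c") +
    ggplot2::labs(x = NULL, y = "change ratio")
}
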