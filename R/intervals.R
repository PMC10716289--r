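# Genomic interval model: tibbles with chrom/start/end in 0-based half-open
# (BED-native) coordinates. GFF3 input is converted to this convention on read.

#' Validate and normalise a genomic-interval tibble
#'
#' Interval tables are plain tibbles with columns `chrom`, `start`, `end`
#' (0-based, half-open) and optionally `name`, `score`, `strand`. This
#' helper checks the invariants (`0 <= start < end`, non-empty `chrom`) and
#' returns the table sorted by `(chrom, start, end)`.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return A sorted tibble of intervals.
#' @export
as_intervals <- function(x) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("interval table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    return(arrange(x, .data$chrom, .data$start, .data$end))
  }
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    abort("interval table has empty chrom values")
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    bad <- which(x$start < 0 | x$start >= x$end)[1]
    abort(sprintf("invalid interval at row %d: start=%s end=%s (need 0 <= start < end)",
                  bad, x$start[bad], x$end[bad]))
  }
  arrange(x, .data$chrom, .data$start, .data$end)
}

#' Read a BED file into an interval tibble
#'
#' Accepts BED3 to BED6. Coordinates are kept exactly as in the file
#' (0-based, half-open). Rows are normalised to sorted order. Malformed
#' lines (fewer than three fields, non-numeric or empty/inverted
#' coordinates) raise an error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present in the
#'   file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields", idx[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates",
                  idx[which(is.na(start) | is.na(end))[1]]))
  }
  bad <- start < 0 | start >= end
  if (any(bad)) {
    abort(sprintf("malformed BED line %d: start >= end", idx[which(bad)[1]]))
  }
  out <- tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, character(1), 4)
  if (all(nf >= 5)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5)))
  }
  if (all(nf >= 6)) out$strand <- vapply(fields, `[[`, character(1), 6)
  as_intervals(out)
}

#' Write an interval tibble as BED
#'
#' Emits BED3/BED6 depending on the columns present; `write_bed` then
#' `read_bed` round-trips sorted input exactly.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (any(c("name", "score", "strand") %in% names(x))) {
    cols <- c(cols, list(
      x[["name"]] %||% rep(".", nrow(x)),
      x[["score"]] %||% rep(0, nrow(x)),
      x[["strand"]] %||% rep(".", nrow(x))
    ))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat gene-model table
#'
#' The flat format is a TSV with columns `gene_id`, `chrom`, `tss`, `tes`,
#' `strand`. `tss`/`tes` are 0-based positions; on the minus strand
#' `tss > tes` in genomic coordinates.
#'
#' @param path Path to a gene TSV.
#' @return Tibble of gene models.
#' @export
read_gene_tsv <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_genes(g)
}

#' @rdname read_gene_tsv
#' @param genes Gene-model tibble.
#' @export
write_gene_tsv <- function(genes, path) {
  readr::write_tsv(validate_genes(genes), path, progress = FALSE)
  invisible(path)
}

validate_genes <- function(genes) {
  genes <- as_tibble(genes)
  need <- c("gene_id", "chrom", "tss", "tes", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    abort(paste0("gene table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(genes) == 0) return(genes)
  if (!all(genes$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  if (any(genes$tss == genes$tes)) abort("gene with tss == tes")
  plus_bad <- genes$strand == "+" & genes$tss > genes$tes
  minus_bad <- genes$strand == "-" & genes$tss < genes$tes
  if (any(plus_bad | minus_bad)) {
    abort("gene orientation inconsistent with strand (minus-strand genes need tss > tes)")
  }
  genes
}

#' Read gene models from a GFF3 file
#'
#' Uses `gene` features and their `ID` attribute. GFF3 1-based closed
#' coordinates are converted to the package's 0-based convention: on the
#' plus strand TSS = start - 1 and TES = end - 1; on the minus strand
#' TSS = end - 1 and TES = start - 1.
#'
#' @param path Path to a GFF3 file.
#' @return Gene-model tibble (`gene_id`, `chrom`, `tss`, `tes`, `strand`).
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", logical(1))
  fields <- fields[keep]
  if (length(fields) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  tss = integer(), tes = integer(), strand = character()))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start1 <- as.integer(vapply(fields, `[[`, character(1), 4))
  end1 <- as.integer(vapply(fields, `[[`, character(1), 5))
  strand <- vapply(fields, `[[`, character(1), 7)
  attrs <- vapply(fields, `[[`, character(1), 9)
  id <- stringr::str_match(attrs, "ID=([^;]+)")[, 2]
  validate_genes(tibble(
    gene_id = id,
    chrom = chrom,
    tss = ifelse(strand == "+", start1 - 1L, end1 - 1L),
    tes = ifelse(strand == "+", end1 - 1L, start1 - 1L),
    strand = strand
  ))
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3_genes <- function(genes, path) {
  genes <- validate_genes(genes)
  start1 <- ifelse(genes$strand == "+", genes$tss, genes$tes) + 1L
  end1 <- ifelse(genes$strand == "+", genes$tes, genes$tss) + 1L
  lines <- sprintf("%s\tepicontrast\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, start1, end1, genes$strand, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

iranges_by_chrom <- function(x) {
  split(IRanges::IRanges(start = x$start + 1L, end = x$end),
        factor(x$chrom, levels = unique(x$chrom)))
}

ranges_to_tibble <- function(rl) {
  parts <- purrr::imap(as.list(rl), function(r, chr) {
    tibble(chrom = rep(chr, length(r)),
           start = as.integer(IRanges::start(r) - 1L),
           end = as.integer(IRanges::end(r)))
  })
  out <- bind_rows(parts)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
  }
  as_intervals(out)
}

#' Merge overlapping or adjacent intervals
#'
#' Collapses overlapping and book-ended intervals per chromosome
#' (bedtools-merge semantics). Idempotent.
#'
#' @param x Interval tibble.
#' @return Merged interval tibble (`chrom`, `start`, `end`).
#' @export
merge_intervals <- function(x) {
  x <- as_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  rl <- lapply(iranges_by_chrom(x), IRanges::reduce)
  ranges_to_tibble(rl)
}

#' Intersect two interval sets
#'
#' Base-pair intersection of the merged covers of `a` and `b`.
#'
#' @param a,b Interval tibbles.
#' @return Interval tibble covering exactly the bases present in both.
#' @export
intersect_intervals <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  ra <- iranges_by_chrom(filter(a, .data$chrom %in% chroms))
  rb <- iranges_by_chrom(filter(b, .data$chrom %in% chroms))
  rl <- lapply(chroms, function(ch) IRanges::intersect(ra[[ch]], rb[[ch]]))
  names(rl) <- chroms
  ranges_to_tibble(rl)
}

#' Total base pairs covered by an interval set
#'
#' @param x Interval tibble.
#' @return Numeric: bp of the merged cover.
#' @export
interval_bp <- function(x) {
  x <- merge_intervals(x)
  sum(as.numeric(x$end - x$start))
}

#' Jaccard index of two interval sets
#'
#' Base-pair Jaccard: intersection bp / union bp after self-merging each
#' set. Symmetric, in `[0, 1]`. Two empty sets give 0 (with a message),
#' matching the convention that no shared occupancy means no similarity.
#'
#' @param a,b Interval tibbles.
#' @return A single numeric fraction.
#' @export
interval_jaccard <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  inter <- interval_bp(intersect_intervals(a, b))
  union <- interval_bp(a) + interval_bp(b) - inter
  if (union == 0) {
    inform("interval_jaccard: both sets empty; returning 0")
    return(0)
  }
  inter / union
}

#' Annotate peaks by genomic compartment
#'
#' Assigns each peak exactly one of `promoter`, `genic`, `distal`, with
#' precedence promoter > genic > distal. The promoter window is the 3 kb
#' upstream of the TSS (strand-aware, TSS base included); `genic` is the
#' TSS-to-TES body; everything else is `distal`. Peaks on chromosomes
#' absent from the gene set are labelled distal (with a message), not
#' rejected.
#'
#' @param peaks Interval tibble of peaks.
#' @param genes Gene-model tibble.
#' @param promoter_bp Promoter window size upstream of the TSS (default
#'   3000 bp).
#' @param promoter_flank `"upstream"` (default) for the strand-aware
#'   upstream-only window, `"symmetric"` for +/- `promoter_bp` around the
#'   TSS.
#' @return `peaks` with an added `compartment` factor column.
#' @export
annotate_compartment <- function(peaks, genes, promoter_bp = 3000,
                                 promoter_flank = c("upstream", "symmetric")) {
  promoter_flank <- match.arg(promoter_flank)
  peaks <- as_tibble(peaks)
  as_intervals(peaks)  # validation only; input row order is preserved
  genes <- validate_genes(genes)
  if (nrow(peaks) == 0) {
    peaks$compartment <- factor(character(), levels = c("promoter", "genic", "distal"))
    return(peaks)
  }
  prom <- promoter_windows(genes, promoter_bp, promoter_flank)
  body <- gene_bodies(genes)
  in_prom <- overlaps_any(peaks, prom)
  in_body <- overlaps_any(peaks, body)
  missing_chrom <- !(peaks$chrom %in% unique(genes$chrom))
  if (any(missing_chrom)) {
    inform(sprintf("annotate_compartment: %d peak(s) on chromosomes absent from the gene set; labelled distal",
                   sum(missing_chrom)))
  }
  peaks$compartment <- factor(
    ifelse(in_prom, "promoter", ifelse(in_body, "genic", "distal")),
    levels = c("promoter", "genic", "distal")
  )
  peaks
}

# promoter window as 0-based half-open intervals; TSS base included
promoter_windows <- function(genes, promoter_bp, promoter_flank = "upstream") {
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (promoter_flank == "symmetric") {
    start <- pmax(0, genes$tss - promoter_bp)
    end <- genes$tss + promoter_bp + 1L
  } else {
    start <- ifelse(genes$strand == "+", pmax(0, genes$tss - promoter_bp), genes$tss)
    end <- ifelse(genes$strand == "+", genes$tss + 1L, genes$tss + promoter_bp + 1L)
  }
  as_intervals(tibble(chrom = genes$chrom, start = as.integer(start),
                      end = as.integer(end)))
}

gene_bodies <- function(genes) {
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  as_intervals(tibble(
    chrom = genes$chrom,
    start = as.integer(pmin(genes$tss, genes$tes)),
    end = as.integer(pmax(genes$tss, genes$tes))
  ))
}

overlaps_any <- function(x, subject) {
  if (nrow(subject) == 0 || nrow(x) == 0) return(rep(FALSE, nrow(x)))
  out <- rep(FALSE, nrow(x))
  for (ch in intersect(unique(x$chrom), unique(subject$chrom))) {
    xi <- which(x$chrom == ch)
    rx <- IRanges::IRanges(x$start[xi] + 1L, x$end[xi])
    sj <- subject[subject$chrom == ch, ]
    rs <- IRanges::IRanges(sj$start + 1L, sj$end)
    out[xi] <- IRanges::overlapsAny(rx, rs)
  }
  out
}

#' Distance from peak midpoints to gene TSSs
#'
#' The linking distance kernel: `|peak_midpoint - tss|`, with the midpoint
#' at `floor((start + end) / 2)`. Cross-chromosome distances are undefined
#' and raise an error.
#'
#' @param peaks Interval tibble (one or more peaks).
#' @param genes Gene-model tibble, recycled or matched row-wise against
#'   `peaks` (both length 1, or equal lengths).
#' @return Numeric vector of distances in bp.
#' @export
distance_to_tss <- function(peaks, genes) {
  peaks <- as_tibble(peaks)
  genes <- as_tibble(genes)
  n <- max(nrow(peaks), nrow(genes))
  if (nrow(peaks) != n) peaks <- peaks[rep(1, n), ]
  if (nrow(genes) != n) genes <- genes[rep(1, n), ]
  if (any(peaks$chrom != genes$chrom)) {
    abort("distance_to_tss: peak and gene on different chromosomes")
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  abs(mid - genes$tss)
}
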