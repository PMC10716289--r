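# Independent brute-force oracles. These deliberately share no code with
# the package: per-base enumeration for interval algebra, direct
# factorial/tail sums for exact tests, naive scoring for the PWM scanner.

# set of covered bases (0-based) per chromosome
oracle_cover <- function(x) {
  out <- list()
  for (i in seq_len(nrow(x))) {
    ch <- as.character(x$chrom[i])
    out[[ch]] <- union(out[[ch]], seq(x$start[i], x$end[i] - 1))
  }
  out
}

cover_to_intervals <- function(cover) {
  rows <- list()
  for (ch in sort(names(cover))) {
    b <- sort(cover[[ch]])
    if (length(b) == 0) next
    breaks <- c(0, which(diff(b) != 1), length(b))
    for (k in seq_len(length(breaks) - 1)) {
      seg <- b[(breaks[k] + 1):breaks[k + 1]]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = min(seg), end = max(seg) + 1)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

oracle_merge <- function(x) cover_to_intervals(oracle_cover(x))

oracle_jaccard <- function(a, b) {
  ca <- oracle_cover(a)
  cb <- oracle_cover(b)
  inter <- 0
  un <- 0
  for (ch in union(names(ca), names(cb))) {
    inter <- inter + length(intersect(ca[[ch]], cb[[ch]]))
    un <- un + length(union(ca[[ch]], cb[[ch]]))
  }
  if (un == 0) 0 else inter / un
}

oracle_intersect_bp <- function(a, b) {
  ca <- oracle_cover(a)
  cb <- oracle_cover(b)
  sum(vapply(union(names(ca), names(cb)),
             function(ch) length(intersect(ca[[ch]], cb[[ch]])), numeric(1)))
}

# per-base compartment classifier: promoter > genic > distal
oracle_compartment <- function(peak, genes, promoter_bp = 3000) {
  bases <- seq(peak$start, peak$end - 1)
  prom_bases <- c()
  body_bases <- c()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != peak$chrom) next
    if (g$strand == "+") {
      prom_bases <- c(prom_bases, seq(max(0, g$tss - promoter_bp), g$tss))
      body_bases <- c(body_bases, seq(g$tss, g$tes - 1))
    } else {
      prom_bases <- c(prom_bases, seq(g$tss, g$tss + promoter_bp))
      body_bases <- c(body_bases, seq(g$tes, g$tss - 1))
    }
  }
  if (length(intersect(bases, prom_bases)) > 0) return("promoter")
  if (length(intersect(bases, body_bases)) > 0) return("genic")
  "distal"
}

# one-sided (greater on cell a) Fisher p by direct fixed-margin enumeration
oracle_fisher_greater <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  sum(probs[xs >= a])
}

# textbook step-up BH, written longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (k in m:1) {
    running_min <- min(running_min, p[o[k]] * m / k)
    adj[o[k]] <- running_min
  }
  pmin(adj, 1)
}

# naive PWM scan: every offset and strand scored directly, exact tail
# probability by enumerating all 4^w words under the background
oracle_pwm_hits <- function(seqs, probs, p_threshold, bg = rep(0.25, 4),
                            floor = 1e-4) {
  letters4 <- c("A", "C", "G", "T")
  pr <- pmax(probs, floor)
  pr <- sweep(pr, 2, colSums(pr), "/")
  sm_fwd <- log2(pr / bg)
  w <- ncol(sm_fwd)
  sm_rev <- log2((pr[4:1, w:1, drop = FALSE]) / bg)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  word_score <- function(sm) {
    apply(words, 1, function(idx) sum(sm[cbind(idx, 1:w)]))
  }
  word_p <- rep(prod(rep(0.25, w)), nrow(words))
  tail_p <- function(sm, s) {
    ws <- word_score(sm)
    sum(word_p[ws >= s - 1e-9])
  }
  hits <- list()
  for (nm in names(seqs)) {
    chars <- strsplit(seqs[[nm]], "")[[1]]
    idx <- match(chars, letters4)
    L <- length(idx)
    if (L < w) next
    for (off in 1:(L - w + 1)) {
      for (strand in c("+", "-")) {
        sm <- if (strand == "+") sm_fwd else sm_rev
        contrib <- sm[cbind(idx[off:(off + w - 1)], 1:w)]
        contrib[is.na(contrib)] <- 0
        s <- sum(contrib)
        if (tail_p(sm, s) <= p_threshold) {
          hits[[length(hits) + 1]] <- data.frame(
            region_id = nm, start = off, strand = strand, score = s)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(region_id = character(), start = integer(),
                      strand = character(), score = numeric()))
  }
  do.call(rbind, hits)
}

# longhand two-group t statistics
oracle_student_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), nx + ny - 2)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 300) {
  start <- sample(0:(max_pos - 2), n, replace = TRUE)
  len <- sample(1:30, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = pmin(start + len, max_pos))
}
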