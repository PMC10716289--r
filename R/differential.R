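# Quantitative comparison of a histone mark between two sample groups:
# MA transform with pseudocount, robust (least-absolute-deviations)
# M-on-A trend removal over common peaks, replicate-level testing, and the
# |M| > 1 & P < 0.05 differential call.

#' MA transform of two signal vectors
#'
#' `M = log2((a + c) / (b + c))`, `A = 0.5 * log2((a + c) * (b + c))`.
#' Antisymmetric: swapping the arguments negates `M` and preserves `A`.
#'
#' @param x_a,x_b Non-negative signal vectors of equal length.
#' @param pseudocount Pseudocount `c` (default 1 signal unit), bounding
#'   `M` when signal is zero.
#' @return Tibble with columns `M` and `A`.
#' @export
ma_transform <- function(x_a, x_b, pseudocount = 1) {
  if (any(x_a < 0) || any(x_b < 0)) abort("ma_transform: negative signal")
  la <- log2(x_a + pseudocount)
  lb <- log2(x_b + pseudocount)
  tibble(M = la - lb, A = 0.5 * (la + lb))
}

#' Robust M-on-A trend fit over common peaks
#'
#' Least-absolute-deviations line `M ~ A` fitted by iteratively
#' reweighted least squares (20 iterations, tolerance 1e-8). The
#' corrected value is `M' = M - (slope * A + intercept)`; after correction
#' the median `M'` over common peaks is near zero. This is the
#' normalization step that removes global efficiency differences between
#' the two groups.
#'
#' @param ma Tibble with `M` and `A` over the common peaks (at least 10).
#' @param max_iter,tol IRLS controls.
#' @return List with `slope` and `intercept`.
#' @export
fit_ma_rescaling <- function(ma, max_iter = 20, tol = 1e-8) {
  if (nrow(ma) < 10) {
    abort("fit_ma_rescaling: fewer than 10 common peaks; supply merged input")
  }
  x <- ma$A
  y <- ma$M
  beta <- coef(lm(y ~ x))
  delta <- 1e-6
  for (i in seq_len(max_iter)) {
    r <- y - (beta[1] + beta[2] * x)
    w <- 1 / pmax(abs(r), delta)
    beta_new <- coef(lm(y ~ x, weights = w))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(slope = unname(beta[2]), intercept = unname(beta[1]))
}

welch_or_pool_p <- function(a_vals, b_vals) {
  if (length(a_vals) < 2 || length(b_vals) < 2) return(NA_real_)
  if (sd(c(a_vals, b_vals)) == 0) return(1)
  if (sd(a_vals) == 0 && sd(b_vals) == 0) {
    return(if (a_vals[1] == b_vals[1]) 1 else 0)
  }
  t.test(a_vals, b_vals)$p.value
}

poisson_tail_p <- function(x_a, x_b) {
  # single-replicate fallback: treat rescaled signal as pseudo-counts and
  # take a two-sided Poisson tail under the mean of the two values
  ka <- round(x_a)
  kb <- round(x_b)
  lambda <- (ka + kb) / 2
  if (lambda == 0) return(1)
  p_hi <- stats::ppois(max(ka, kb) - 1, lambda, lower.tail = FALSE)
  min(1, 2 * p_hi)
}

#' Differential peaks between two sample groups
#'
#' Implements the two-group comparison: replicate signal is averaged per
#' group, MA-transformed, the M-on-A trend is removed by a robust fit
#' over common peaks, and each peak receives a two-sided p-value (Welch t
#' on log2 replicate signal when both groups have >= 2 replicates, else a
#' Poisson tail on the rescaled values). A peak is called `up_in_A` when
#' `M' > m_threshold` and `p < p_threshold`, `up_in_B` when
#' `M' < -m_threshold` and `p < p_threshold`, otherwise `stable`. The
#' default thresholds (`|M| > 1`, `P < 0.05`) are the standard
#' differential-peak criteria for MA-normalized CUT&Tag/ChIP comparisons.
#'
#' @param signal Wide signal tibble: `peak_id` plus one column per sample
#'   (FPKM-like, non-negative).
#' @param group_a,group_b Character vectors of sample columns forming the
#'   two groups.
#' @param p_threshold,m_threshold Call thresholds.
#' @param pseudocount Passed to [ma_transform()].
#' @param common_peaks Optional peak ids used for the trend fit; default
#'   is all peaks with positive mean signal in both groups.
#' @param allow_single Permit the single-replicate Poisson fallback
#'   (default TRUE).
#' @return A `diff_peaks` object: tibble `peak_id`, `M` (corrected), `A`,
#'   `p`, `call`, with the fit and thresholds as attributes.
#' @export
call_differential <- function(signal, group_a, group_b,
                              p_threshold = 0.05, m_threshold = 1,
                              pseudocount = 1, common_peaks = NULL,
                              allow_single = TRUE) {
  miss <- setdiff(c(group_a, group_b), names(signal))
  if (length(miss) > 0) {
    abort(paste0("samples not in signal matrix: ", paste(miss, collapse = ", ")))
  }
  xa <- as.matrix(signal[, group_a, drop = FALSE])
  xb <- as.matrix(signal[, group_b, drop = FALSE])
  if (any(xa < 0) || any(xb < 0)) abort("negative signal values")
  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  ma <- ma_transform(mean_a, mean_b, pseudocount)
  if (is.null(common_peaks)) {
    common <- mean_a > 0 & mean_b > 0
  } else {
    common <- signal$peak_id %in% common_peaks
  }
  fit <- fit_ma_rescaling(ma[common, , drop = FALSE])
  m_corr <- ma$M - (fit$slope * ma$A + fit$intercept)

  if (ncol(xa) >= 2 && ncol(xb) >= 2) {
    la <- log2(xa + pseudocount)
    lb <- log2(xb + pseudocount)
    p <- vapply(seq_len(nrow(la)),
                function(i) welch_or_pool_p(la[i, ], lb[i, ]), numeric(1))
  } else {
    if (!allow_single) {
      abort("single replicate per side and the count-model fallback is disabled")
    }
    p <- vapply(seq_along(mean_a),
                function(i) poisson_tail_p(mean_a[i], mean_b[i]), numeric(1))
  }
  call <- dplyr::case_when(
    m_corr > m_threshold & p < p_threshold ~ "up_in_A",
    m_corr < -m_threshold & p < p_threshold ~ "up_in_B",
    TRUE ~ "stable"
  )
  res <- tibble(peak_id = signal$peak_id, M = m_corr, A = ma$A, p = p,
                call = factor(call, levels = c("up_in_A", "up_in_B", "stable")))
  structure(list(result = res, fit = fit,
                 thresholds = list(p = p_threshold, m = m_threshold),
                 groups = list(a = group_a, b = group_b)),
            class = "diff_peaks")
}

#' @export
print.diff_peaks <- function(x, ...) {
  cat("<diff_peaks>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname call_differential
#' @param x A `diff_peaks` object.
#' @param ... Unused.
#' @method tidy diff_peaks
#' @export
tidy.diff_peaks <- function(x, ...) x$result

#' @rdname call_differential
#' @method glance diff_peaks
#' @export
glance.diff_peaks <- function(x, ...) {
  tibble(
    n_peaks = nrow(x$result),
    n_up_in_A = sum(x$result$call == "up_in_A"),
    n_up_in_B = sum(x$result$call == "up_in_B"),
    slope = x$fit$slope,
    intercept = x$fit$intercept
  )
}

#' MA plot of a differential comparison
#'
#' @param object A `diff_peaks` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diff_peaks
#' @export
autoplot.diff_peaks <- function(object, ...) {
  d <- object$result
  ggplot2::ggplot(d, ggplot2::aes(x = .data$A, y = .data$M, colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$thresholds$m,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up_in_A = "#d1495b",
                                            up_in_B = "#00798c",
                                            stable = "grey60")) +
    ggplot2::labs(x = "A (mean log2 intensity)", y = "M (corrected log2 ratio)")
}

#' K-means clustering of variable peaks
#'
#' Rows are z-scored per peak, then clustered with `stats::kmeans`
#' (50 random restarts under the given seed, so the assignment is
#' deterministic). This is the grouping used to organise variable peaks
#' into cultivar/tissue/condition specificity classes.
#'
#' @param signal Wide signal tibble (`peak_id` + sample columns),
#'   restricted by the caller to the variable peaks of interest.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param peaks Optional peak ids to restrict to.
#' @return Tibble `peak_id`, `cluster` with the centroid matrix in the
#'   `centers` attribute.
#' @export
kmeans_variable_peaks <- function(signal, k, seed = 1, peaks = NULL) {
  if (!is.null(peaks)) signal <- filter(signal, .data$peak_id %in% peaks)
  m <- as.matrix(signal[, setdiff(names(signal), "peak_id"), drop = FALSE])
  if (k > nrow(m)) abort("k exceeds the number of peaks")
  z <- t(scale(t(m)))
  z[!is.finite(z)] <- 0  # constant rows carry no profile
  fit <- withr::with_seed(seed, kmeans(z, centers = k, nstart = 50, iter.max = 100))
  out <- tibble(peak_id = signal$peak_id, cluster = as.integer(fit$cluster))
  attr(out, "centers") <- fit$centers
  out
}
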