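# Phenotype formulas: the low-nitrogen response ratio (LRR) of root
# traits, nitrate content from the colorimetric assay, and group
# comparisons of trait tables.

#' Low-nitrogen response ratio of a root trait
#'
#' `LRR = (R_LN - R_NN) / R_NN`: the relative change of a root trait
#' under low nitrogen versus normal nitrogen. The sign encodes the
#' direction of the response; the ratio is invariant to a common
#' rescaling of both inputs.
#'
#' @param r_ln Trait value(s) under low nitrogen.
#' @param r_nn Trait value(s) under normal nitrogen (must be > 0).
#' @return Numeric vector of response ratios.
#' @export
lrr <- function(r_ln, r_nn) {
  if (any(r_nn <= 0)) abort("lrr: R_NN must be positive")
  (r_ln - r_nn) / r_nn
}

#' Nitrate content from the colorimetric assay
#'
#' `Y = C * V / W` in ug/g, where `C` is the nitrate concentration read
#' off the standard curve (ug/ml), `V` the extract volume (ml) and `W`
#' the sample fresh weight (g).
#'
#' @param C Concentration in ug/ml (>= 0).
#' @param V Extract volume in ml (> 0).
#' @param W Sample weight in g (> 0).
#' @return Nitrate content in ug/g.
#' @export
nitrate_content <- function(C, V, W) {
  if (any(C < 0)) abort("nitrate_content: C must be non-negative")
  if (any(V <= 0)) abort("nitrate_content: V must be positive")
  if (any(W <= 0)) abort("nitrate_content: W must be positive")
  C * V / W
}

#' Linear standard curve for the nitrate assay
#'
#' Fits `concentration ~ od` on standards and returns a function mapping
#' OD410 readings to concentrations (ug/ml).
#'
#' @param od OD410 readings of the standards.
#' @param conc Known concentrations of the standards (ug/ml).
#' @return A function `f(od) -> concentration`.
#' @export
standard_curve <- function(od, conc) {
  if (length(od) < 2) abort("standard_curve: need at least two standards")
  fit <- lm(conc ~ od)
  function(x) unname(coef(fit)[1] + coef(fit)[2] * x)
}

#' Per-genotype LRR of a root trait with bootstrap confidence interval
#'
#' The design is unpaired, so the LRR is computed on group means; the
#' confidence interval comes from a seeded bootstrap over replicates
#' (1000 resamples).
#'
#' @param traits Trait tibble: `genotype`, `condition` (`NN`/`LN`),
#'   `replicate`, `trait`, `value`.
#' @param trait Trait name to summarise (e.g. `"Rt"`).
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Tibble `genotype`, `lrr`, `ci_lo`, `ci_hi`.
#' @export
lrr_table <- function(traits, trait, n_boot = 1000, conf = 0.95, seed = 1) {
  d <- filter(as_tibble(traits), .data$trait == !!trait)
  if (nrow(d) == 0) abort(paste0("no records for trait ", trait))
  withr::with_seed(seed, {
    purrr::map_dfr(unique(d$genotype), function(g) {
      ln <- filter(d, .data$genotype == g, .data$condition == "LN")$value
      nn <- filter(d, .data$genotype == g, .data$condition == "NN")$value
      if (length(ln) == 0 || length(nn) == 0) {
        abort(paste0("missing condition for genotype ", g))
      }
      est <- lrr(mean(ln), mean(nn))
      boots <- replicate(n_boot, {
        lrr(mean(sample(ln, replace = TRUE)), mean(sample(nn, replace = TRUE)))
      })
      qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      tibble(genotype = g, lrr = est, ci_lo = qs[1], ci_hi = qs[2])
    })
  })
}

#' Two-group comparison of a trait
#'
#' Mean, SD and a two-sided t-test p-value per group pair. The default is
#' the pooled-variance Student test; Welch is available by flag.
#'
#' @param records Trait tibble (`value` plus the grouping column).
#' @param trait Trait name (filtered on the `trait` column when present).
#' @param group_col Column defining the two groups.
#' @param method `"student"` (pooled variance, default) or `"welch"`.
#' @return Tibble with per-group `n`, `mean`, `sd` columns and the shared
#'   `p` value.
#' @export
group_compare <- function(records, trait = NULL, group_col = "genotype",
                          method = c("student", "welch")) {
  method <- match.arg(method)
  d <- as_tibble(records)
  if (!is.null(trait) && "trait" %in% names(d)) {
    d <- filter(d, .data$trait == !!trait)
  }
  groups <- unique(d[[group_col]])
  if (length(groups) != 2) abort("group_compare: need exactly two groups")
  v1 <- d$value[d[[group_col]] == groups[1]]
  v2 <- d$value[d[[group_col]] == groups[2]]
  if (length(v1) < 2 || length(v2) < 2) {
    abort("group_compare: need >= 2 replicates per group")
  }
  p <- if (sd(c(v1, v2)) == 0) 1 else {
    t.test(v1, v2, var.equal = (method == "student"))$p.value
  }
  tibble(group = as.character(groups),
         n = c(length(v1), length(v2)),
         mean = c(mean(v1), mean(v2)),
         sd = c(sd(v1), sd(v2)),
         p = p)
}
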