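# Orchestration: run the analysis stages in dependency order on a
# synthetic fixture (or one loaded from disk), writing provenance-stamped
# TSV outputs, a run log and a checksummed manifest.

#' Build a pipeline run configuration
#'
#' @param stages Stages to run, in dependency order. Available:
#'   `simulate`, `annotate`, `diffpeaks`, `statedyn`, `link`, `enrich`,
#'   `bias`, `traits`.
#' @param fixture_dir Optional directory of a fixture written by
#'   [write_fixture()]; when `NULL`, the `simulate` stage generates one.
#' @param synthetic A [synthetic_config()] for the `simulate` stage
#'   (default built from `seed`).
#' @param promoter_bp,window,m_threshold,p_threshold,alpha,n_draws,k
#'   Stage thresholds (promoter window, link window, differential-call M
#'   and p cutoffs, link significance level, null draws, K-means k).
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "annotate", "diffpeaks",
                                       "statedyn", "link", "enrich", "bias",
                                       "traits"),
                            fixture_dir = NULL,
                            synthetic = NULL,
                            promoter_bp = 3000, window = 5e5,
                            m_threshold = 1, p_threshold = 0.05,
                            alpha = 0.05, n_draws = 10000, k = 4,
                            seed = 1) {
  known <- c("simulate", "annotate", "diffpeaks", "statedyn", "link",
             "enrich", "bias", "traits")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  if (is.list(synthetic) && !inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, synthetic)
  }
  structure(list(stages = stages, fixture_dir = fixture_dir,
                 synthetic = synthetic, promoter_bp = promoter_bp,
                 window = window, m_threshold = m_threshold,
                 p_threshold = p_threshold, alpha = alpha,
                 n_draws = n_draws, k = k, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `synthetic` may be a
#' nested mapping of [synthetic_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order. Every output TSV
#' carries a provenance header (package version, configuration hash,
#' seed); `run.log` records stage timings and record counts. A stage
#' whose inputs were not produced (e.g. `enrich` without `link`) aborts
#' with the missing stage named. Data outputs are byte-identical across
#' reruns with the same configuration and seed.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @return An `epi_run` list: `manifest` (path + md5 over data outputs),
#'   `results` (in-memory stage results), `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("epicontrast %s run, config_hash=%s seed=%d\n",
              the_version(), hash, config$seed), file = log_path)
  logline <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    inform(msg)
  }
  header <- sprintf("# epicontrast %s config_hash=%s seed=%d",
                    the_version(), hash, config$seed)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    writeLines(header, path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
    path
  }
  results <- list()
  ran <- character()
  need <- function(stage, dep) {
    if (!dep %in% ran) {
      abort(sprintf("stage '%s' requires stage '%s', which did not run", stage, dep))
    }
  }
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- fn()
    logline("stage %-9s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    ran <<- c(ran, name)
    out
  }

  fixture <- NULL
  get_fixture <- function() {
    if (is.null(fixture)) {
      fixture <<- if (!is.null(config$fixture_dir)) {
        read_fixture(config$fixture_dir)
      } else {
        simulate_epigenome(config$synthetic)
      }
    }
    fixture
  }
  cultivar_groups <- function(fx) {
    split(fx$sample_sheet$sample_id, fx$sample_sheet$cultivar)
  }

  for (stage in config$stages) {
    switch(stage,
      simulate = {
        results$fixture <- run_stage("simulate", function() {
          fx <- get_fixture()
          write_fixture(fx, file.path(out_dir, "fixture"))
          logline("  fixture: %d peaks, %d genes, %d samples",
                  nrow(fx$catalogue), nrow(fx$genes), nrow(fx$sample_sheet))
          fx
        })
      },
      annotate = {
        results$annotation <- run_stage("annotate", function() {
          fx <- get_fixture()
          anno <- annotate_compartment(fx$catalogue, fx$genes,
                                       promoter_bp = config$promoter_bp)
          emit(anno, "peaks_annotated.tsv")
          frac <- anno |> dplyr::count(.data$compartment) |>
            mutate(fraction = .data$n / sum(.data$n))
          emit(frac, "compartment_fractions.tsv")
          logline("  annotate: %d peaks", nrow(anno))
          anno
        })
      },
      diffpeaks = {
        results$diff <- run_stage("diffpeaks", function() {
          fx <- get_fixture()
          gr <- cultivar_groups(fx)
          dp <- call_differential(fx$signal, gr[[1]], gr[[2]],
                                  p_threshold = config$p_threshold,
                                  m_threshold = config$m_threshold)
          emit(tidy(dp), "diffpeaks.tsv")
          variable <- filter(tidy(dp), .data$call != "stable")$peak_id
          if (length(variable) >= config$k) {
            cl <- kmeans_variable_peaks(fx$signal, k = config$k,
                                        seed = config$seed, peaks = variable)
            emit(cl, "diffpeak_clusters.tsv")
          }
          logline("  diffpeaks: %d/%d differential",
                  sum(tidy(dp)$call != "stable"), nrow(tidy(dp)))
          dp
        })
      },
      statedyn = {
        results$states <- run_stage("statedyn", function() {
          fx <- get_fixture()
          gr <- cultivar_groups(fx)
          a <- filter(fx$state_tracks, .data$sample_id == gr[[1]][1])
          b <- filter(fx$state_tracks, .data$sample_id == gr[[2]][1])
          dyn <- call_dynamic_bins(a, b)
          emit(filter(dyn, .data$dynamic), "dynamic_bins.tsv")
          ratios <- change_ratio_by_category(a, b, orientation = "both")
          emit(ratios, "state_change_ratios.tsv")
          pk <- inner_join(fx$presence, fx$catalogue, by = "peak_id")
          scores <- bind_rows(lapply(c("cultivar", "condition", "tissue"),
                                     function(f) variability_score(pk, fx$sample_sheet, f)))
          emit(scores, "variability_scores.tsv")
          logline("  statedyn: %d dynamic bins", sum(dyn$dynamic))
          list(dynamic = dyn, ratios = ratios, variability = scores)
        })
      },
      link = {
        results$links <- run_stage("link", function() {
          fx <- get_fixture()
          la <- link_pipeline(fx$signal, fx$expression, fx$catalogue, fx$genes,
                              window = config$window, n_draws = config$n_draws,
                              alpha = config$alpha,
                              promoter_bp = config$promoter_bp,
                              seed = config$seed)
          emit(la$links, "links.tsv")
          emit(glance(la), "links_summary.tsv")
          logline("  link: %d candidates, %d significant",
                  la$summary$n_candidates, la$summary$n_significant)
          la
        })
      },
      enrich = {
        results$enrichment <- run_stage("enrich", function() {
          need("enrich", "diffpeaks")
          need("enrich", "link")
          fx <- get_fixture()
          dp <- tidy(results$diff)
          cat_dp <- left_join(fx$catalogue, dp[, c("peak_id", "call")], by = "peak_id")
          in_qtl <- overlaps_any(cat_dp, fx$qtl)
          diffp <- cat_dp$call != "stable"
          qtl_fisher <- fisher_enrichment(sum(diffp & in_qtl), sum(diffp & !in_qtl),
                                          sum(!diffp & in_qtl), sum(!diffp & !in_qtl),
                                          sided = "one_greater")
          emit(qtl_fisher, "qtl_enrichment.tsv")
          gr <- cultivar_groups(fx)
          de <- de_test(fx$expression, gr[[1]], gr[[2]])
          targets <- unique(filter(results$links$links, .data$significant)$gene_id)
          ov <- overlap_test(targets, de$gene_id[de$de], fx$genes$gene_id)
          emit(ov, "link_target_deg_overlap.tsv")
          fg <- filter(fx$motif_regions, .data$group == "foreground")
          bg <- filter(fx$motif_regions, .data$group == "background")
          hits_fg <- bind_rows(lapply(fx$pwms, function(w) pwm_scan(fg, w)))
          hits_bg <- bind_rows(lapply(fx$pwms, function(w) pwm_scan(bg, w)))
          me <- motif_enrichment(hits_fg, hits_bg, nrow(fg), nrow(bg))
          emit(me, "motif_enrichment.tsv")
          logline("  enrich: QTL p=%.3g, %d motifs tested", qtl_fisher$p, nrow(me))
          list(qtl = qtl_fisher, deg_overlap = ov, motifs = me, de = de)
        })
      },
      bias = {
        results$bias <- run_stage("bias", function() {
          need("bias", "diffpeaks")
          fx <- get_fixture()
          gr <- cultivar_groups(fx)
          de <- de_test(fx$expression, gr[[1]], gr[[2]])
          dp <- tidy(results$diff)
          diff_iv <- inner_join(fx$catalogue,
                                filter(dp, .data$call != "stable")[, "peak_id"],
                                by = "peak_id")
          bc <- classify_bias(fx$genes, de, diff_ac_peaks = diff_iv,
                              promoter_bp = config$promoter_bp)
          emit(tidy(bc), "bias_classification.tsv")
          emit(glance(bc), "bias_summary.tsv")
          logline("  bias: %d DE genes", glance(bc)$n_de_genes)
          bc
        })
      },
      traits = {
        results$traits <- run_stage("traits", function() {
          fx <- get_fixture()
          lr <- bind_rows(lapply(unique(fx$traits$trait), function(tr) {
            mutate(lrr_table(fx$traits, tr, seed = config$seed), trait = tr,
                   .before = 1)
          }))
          emit(lr, "trait_lrr.tsv")
          cmp <- bind_rows(lapply(unique(fx$traits$trait), function(tr) {
            d <- filter(fx$traits, .data$condition == "LN")
            mutate(group_compare(d, tr), trait = tr, .before = 1)
          }))
          emit(cmp, "trait_group_compare.tsv")
          logline("  traits: %d traits", dplyr::n_distinct(fx$traits$trait))
          list(lrr = lr, compare = cmp)
        })
      }
    )
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        c("run.log", "manifest.tsv")))
  manifest <- tibble(path = files,
                     md5 = unname(tools::md5sum(file.path(out_dir, files))))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  logline("run complete: %d files in manifest", nrow(manifest))
  structure(list(manifest = manifest, results = results, config_hash = hash),
            class = "epi_run")
}

#' @export
print.epi_run <- function(x, ...) {
  cat(sprintf("<epi_run> config_hash=%s, %d output files\n",
              x$config_hash, nrow(x$manifest)))
  invisible(x)
}
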