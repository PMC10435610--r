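# Pipeline configuration and the end-to-end driver: spectral -> graph ->
# stats, writing every intermediate artifact plus a run manifest.

#' Pipeline configuration
#'
#' Collects the analysis constants: 60 epochs of 4096 samples at 1250 Hz,
#' the six-band catalogue, unit interlayer weight, mean replica
#' aggregation with max-1 normalization, backward-elimination threshold
#' 0.10, alpha 0.05 Bonferroni-corrected over 3 EF aspects.
#'
#' @param fs_hz Sampling frequency (default 1250).
#' @param epoch_length Samples per epoch (default 4096).
#' @param max_epochs Epochs per recording (default 60).
#' @param bands Band catalogue (default [default_bands()]).
#' @param interlayer_weight Interlayer link weight (default 1).
#' @param aggregation Replica aggregation, `"mean"` or `"sum"`.
#' @param elimination_threshold Backward-elimination removal p (default 0.10).
#' @param alpha Significance level (default 0.05).
#' @param m_tests Bonferroni divisor (default 3, one per EF aspect).
#' @param subnet Character vector of subnetwork labels, or a node-set
#'   file path (read with [read_node_set()]).
#' @param seed Integer seed for any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fs_hz = 1250, epoch_length = 4096L,
                            max_epochs = 60L, bands = default_bands(),
                            interlayer_weight = 1,
                            aggregation = c("mean", "sum"),
                            elimination_threshold = 0.10, alpha = 0.05,
                            m_tests = 3L, subnet = NULL, seed = 1L) {
  aggregation <- match.arg(aggregation)
  if (is.character(subnet) && length(subnet) == 1L && file.exists(subnet)) {
    subnet <- read_node_set(subnet)
  }
  structure(list(fs_hz = fs_hz, epoch_length = as.integer(epoch_length),
                 max_epochs = as.integer(max_epochs), bands = bands,
                 interlayer_weight = interlayer_weight,
                 aggregation = aggregation,
                 elimination_threshold = elimination_threshold,
                 alpha = alpha, m_tests = as.integer(m_tests),
                 subnet = subnet, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Per-recording network analysis: time series to frontoparietal centrality
#'
#' Runs the spectral and graph stages for one recording: epoch, band-pass
#' filter, PLI per band, spanning-tree backbone per band, multiplex
#' assembly, multilayer eigenvector centrality, subnetwork mean.
#'
#' @param ts A [time_series].
#' @param config A [pipeline_config]; `config$subnet` must be set.
#' @return List: `connectivity` (per-band [connectivity_matrix]),
#'   `backbones` (per-band trees), `multiplex`, `centrality`, `ec_fpn`.
#' @export
analyze_recording <- function(ts, config) {
  stopifnot(inherits(ts, "time_series"), inherits(config, "pipeline_config"))
  if (is.null(config$subnet)) stop("config$subnet is not set")
  missing <- setdiff(config$subnet, ts$region_labels)
  if (length(missing)) {
    stop("subnetwork labels not in recording: ", paste(missing, collapse = ", "))
  }
  epochs <- segment_epochs(ts, config$epoch_length, config$max_epochs)
  connectivity <- lapply(config$bands, function(b) {
    pli_matrix(epochs, b, ts$fs)
  })
  backbones <- lapply(connectivity, spanning_backbone)
  mplex <- build_multiplex(backbones, config$interlayer_weight)
  cent <- multilayer_eigenvector_centrality(mplex, config$aggregation)
  list(connectivity = connectivity, backbones = backbones,
       multiplex = mplex, centrality = cent,
       ec_fpn = subnetwork_mean(cent, config$subnet))
}

#' Cohort-level statistics stage
#'
#' Given a cohort table (one row per subject x timepoint with `ec_fpn`,
#' `ef_*` Z-scores and covariates), computes: impairment flags per EF
#' score, paired change tests for every EF score and for centrality, and
#' a covariate-screened backward regression of each T1 EF score on T1
#' centrality plus covariates. The Bonferroni threshold
#' `alpha / m_tests` is attached for interpretation.
#'
#' @param cohort Cohort data frame.
#' @param config A [pipeline_config].
#' @param covariate_kinds Named character vector of covariate kinds;
#'   defaults to the generator's catalogue.
#' @param forced_covariates Covariates always entered (still removable by
#'   elimination); default `subtype`.
#' @param reference_levels Reference levels for categorical predictors.
#' @return List: `impairment`, `paired_tests`, `regressions`,
#'   `bonferroni_p`, `screening`.
#' @export
cohort_statistics <- function(cohort, config,
                              covariate_kinds = c(
                                epilepsy = "binary",
                                subtype = "categorical",
                                treatment = "categorical",
                                interval_resection_npa = "continuous",
                                age = "continuous"),
                              forced_covariates = "subtype",
                              reference_levels = list(
                                epilepsy = "no",
                                subtype = "IDH-mutant-codeleted",
                                treatment = "none")) {
  stopifnot(is.data.frame(cohort), inherits(config, "pipeline_config"))
  ef_cols <- grep("^ef_", names(cohort), value = TRUE)
  t1 <- cohort[cohort$timepoint == "T1", , drop = FALSE]
  t2 <- cohort[cohort$timepoint == "T2", , drop = FALSE]

  impairment <- lapply(stats::setNames(ef_cols, ef_cols), function(cc) {
    data.frame(subject_id = cohort$subject_id, timepoint = cohort$timepoint,
               impaired = classify_impairment(cohort[[cc]]),
               stringsAsFactors = FALSE)
  })

  ids <- intersect(t1$subject_id, t2$subject_id)
  paired_tests <- lapply(stats::setNames(c(ef_cols, "ec_fpn"),
                                         c(ef_cols, "ec_fpn")), function(cc) {
    paired_change_test(t1[[cc]][match(ids, t1$subject_id)],
                       t2[[cc]][match(ids, t2$subject_id)])
  })

  candidates <- intersect(names(covariate_kinds), names(cohort))
  candidates <- drop_collinear(t1, candidates)
  screening <- list()
  regressions <- lapply(stats::setNames(ef_cols, ef_cols), function(cc) {
    scr <- screen_covariates(t1, cc, setdiff(candidates, forced_covariates),
                             covariate_kinds, alpha = config$alpha)
    screening[[cc]] <<- scr
    selected <- scr$candidate[scr$selected]
    preds <- unique(c("ec_fpn", intersect(forced_covariates, candidates),
                      selected))
    pred_df <- t1[, preds, drop = FALSE]
    backward_regression(t1[[cc]], pred_df,
                        threshold = config$elimination_threshold,
                        reference_levels = reference_levels)
  })

  list(impairment = impairment, paired_tests = paired_tests,
       regressions = regressions,
       screening = screening,
       bonferroni_p = bonferroni_threshold(config$alpha, config$m_tests))
}

#' Run the full pipeline and write every artifact
#'
#' Executes spectral -> graph -> stats for a set of per-subject,
#' per-timepoint recordings, writes per-band connectivity matrices and
#' backbones, the supra matrix with its JSON sidecar, centrality vectors,
#' the assembled cohort table, per-EF statistics JSON, and a run
#' manifest. Reruns with identical inputs and config produce byte-
#' identical outputs.
#'
#' @param config A [pipeline_config].
#' @param recordings Named list: `recordings[[subject_id]][[timepoint]]`
#'   is a [time_series].
#' @param covariates Data frame with `subject_id` and covariate columns
#'   (constant per subject), merged into the cohort table. Optional EF
#'   columns (`ef_*` per timepoint) may be supplied via `ef_scores`.
#' @param ef_scores Optional data frame `subject_id`, `timepoint`,
#'   `ef_*` columns; when present the stats stage runs.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the cohort table, per-recording results
#'   and (when EF scores were given) the statistics, plus the manifest.
#' @export
run_pipeline <- function(config, recordings, covariates = NULL,
                         ef_scores = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$subnet)) stop("config$subnet is not set (missing node-set)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  rows <- list()
  results <- list()
  counts <- list()
  for (sid in names(recordings)) {
    for (tp in names(recordings[[sid]])) {
      ts <- recordings[[sid]][[tp]]
      res <- analyze_recording(ts, config)
      tag <- paste0(sid, "_", tp)
      for (bn in names(res$connectivity)) {
        write_matrix_tsv(res$connectivity[[bn]],
                         file.path(out_dir, paste0(tag, "_pli_", bn, ".tsv")))
        write_matrix_tsv(res$backbones[[bn]],
                         file.path(out_dir, paste0(tag, "_mst_", bn, ".tsv")))
      }
      write_matrix_tsv(res$multiplex$supra,
                       file.path(out_dir, paste0(tag, "_supra.tsv")),
                       digits = 12L)
      jsonlite::write_json(
        list(layer_order = res$multiplex$layer_order, N = res$multiplex$N,
             L = res$multiplex$L,
             interlayer_weight = res$multiplex$interlayer_weight,
             aggregation = config$aggregation, normalization = "max1"),
        file.path(out_dir, paste0(tag, "_supra.tsv.json")), auto_unbox = TRUE)
      utils::write.table(
        data.frame(label = res$centrality$node_labels,
                   centrality = signif(res$centrality$values, 12)),
        file.path(out_dir, paste0(tag, "_centrality.tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
      rows[[tag]] <- data.frame(subject_id = sid, timepoint = tp,
                                ec_fpn = res$ec_fpn, stringsAsFactors = FALSE)
      results[[tag]] <- res
      counts[[tag]] <- list(bands = length(res$connectivity),
                            epochs = res$connectivity[[1]]$n_epochs_averaged)
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  if (!is.null(ef_scores)) {
    cohort <- merge(cohort, ef_scores, by = c("subject_id", "timepoint"),
                    all.x = TRUE, sort = FALSE)
  }
  if (!is.null(covariates)) {
    cohort <- merge(cohort, covariates, by = "subject_id", all.x = TRUE,
                    sort = FALSE)
  }
  cohort <- cohort[order(cohort$subject_id, cohort$timepoint), , drop = FALSE]
  rownames(cohort) <- NULL
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)

  statistics <- NULL
  if (any(grepl("^ef_", names(cohort)))) {
    kinds_all <- c(epilepsy = "binary", subtype = "categorical",
                   treatment = "categorical",
                   interval_resection_npa = "continuous", age = "continuous")
    kinds <- kinds_all[intersect(names(kinds_all), names(cohort))]
    statistics <- cohort_statistics(cohort, config, covariate_kinds = kinds)
    for (cc in names(statistics$regressions)) {
      r <- statistics$regressions[[cc]]
      jsonlite::write_json(
        list(dependent = cc, retained = r$retained, excluded = r$excluded,
             adj_r2 = r$adj_r2, f_stat = r$f_stat, df = r$df,
             model_p = r$model_p, n = r$n,
             bonferroni_p = round(statistics$bonferroni_p, 4)),
        file.path(out_dir, paste0("regression_", cc, ".json")),
        auto_unbox = TRUE, digits = 10)
    }
    jsonlite::write_json(
      lapply(statistics$paired_tests, function(p)
        list(test_used = p$test_used, statistic = p$statistic,
             p_value = p$p_value, n_pairs = p$n_pairs)),
      file.path(out_dir, "paired_tests.json"), auto_unbox = TRUE, digits = 10)
  }

  manifest <- list(
    tool = paste0("megmultiplex ",
                  as.character(utils::packageVersion("megmultiplex"))),
    config = list(fs_hz = config$fs_hz, epoch_length = config$epoch_length,
                  max_epochs = config$max_epochs,
                  bands = lapply(config$bands, function(b)
                    list(name = b$name, f_lo = b$f_lo, f_hi = b$f_hi)),
                  interlayer_weight = config$interlayer_weight,
                  aggregation = config$aggregation,
                  elimination_threshold = config$elimination_threshold,
                  alpha = config$alpha, m_tests = config$m_tests,
                  subnet = config$subnet, seed = config$seed),
    n_recordings = length(counts),
    stage_counts = counts,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(list(cohort = cohort, results = results, statistics = statistics,
                 manifest = manifest))
}
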