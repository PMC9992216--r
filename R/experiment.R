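#' Experiment configuration
#'
#' Describes a full grid run: simulation settings, SRD groups, segmentation,
#' feature sets, classifiers and scenario(s).
#'
#' @param sim A [sim_config()].
#' @param srd_groups SRD lengths in seconds (default `c(1, 5, 10, 15, 20)`).
#' @param seg A [segmentation_params()].
#' @param feature_sets Subset of `c("NTDF", "TD4", "RMS")`.
#' @param classifiers List of [classifier_spec()].
#' @param scenario `"within"`, `"between"` or `"both"`.
#' @param strict_between Use the held-out-trial Between-SRD variant.
#' @param filter Apply [bandpass_notch()] to every recording before feature
#'   extraction (default `TRUE`).
#' @param notch_hz Notch frequency passed to the filter (default 50).
#' @param output_dir Where per-cell results and summaries are written;
#'   `NULL` keeps everything in memory.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(sim = sim_config(),
                              srd_groups = srdemg::srd_groups(),
                              seg = segmentation_params(),
                              feature_sets = c("NTDF", "TD4", "RMS"),
                              classifiers = list(classifier_spec("LDA"),
                                                 classifier_spec("KNN"),
                                                 classifier_spec("RF")),
                              scenario = c("both", "within", "between"),
                              strict_between = FALSE, filter = TRUE,
                              notch_hz = 50, output_dir = NULL) {
  scenario <- match.arg(scenario)
  if (length(srd_groups) == 0 || length(feature_sets) == 0 ||
      length(classifiers) == 0)
    stop("srd_groups, feature_sets and classifiers must be non-empty")
  if (any(srd_groups > sim$duration_s))
    stop("every SRD group must fit inside sim$duration_s")
  structure(
    list(sim = sim, srd_groups = srd_groups, seg = seg,
         feature_sets = match.arg(feature_sets, c("NTDF", "TD4", "RMS"),
                                  several.ok = TRUE),
         classifiers = classifiers, scenario = scenario,
         strict_between = strict_between, filter = filter,
         notch_hz = notch_hz, output_dir = output_dir),
    class = "experiment_config")
}

#' Desk-scale test profile
#'
#' The grid of the full study shrunk so that a complete run finishes in
#' minutes on one CPU: 1000 Hz sampling (window geometry in samples is
#' preserved: 150/100 ms keep their 9/49/99/149/199 window counts), 4
#' subjects, all five SRD groups. The band upper edge stays at 450 Hz
#' (1000 Hz > 2 x 450 Hz).
#'
#' @param n_subjects Number of subjects (default 4).
#' @param seed Master seed.
#' @param ... Passed on to [experiment_config()].
#' @return An `experiment_config`.
#' @export
test_profile_config <- function(n_subjects = 4L, seed = 1L, ...) {
  experiment_config(sim = sim_config(n_subjects = n_subjects, fs = 1000,
                                     seed = seed), ...)
}

#' Paper-scale profile
#'
#' 8 subjects at 4000 Hz, the acquisition geometry of the emulated protocol.
#'
#' @param seed Master seed.
#' @param ... Passed on to [experiment_config()].
#' @return An `experiment_config`.
#' @export
paper_scale_config <- function(seed = 1L, ...) {
  experiment_config(sim = sim_config(n_subjects = 8L, fs = 4000, seed = seed),
                    ...)
}

.cell_key <- function(scenario, srd_train, feature_set, classifier) {
  sprintf("%s_srd%g_%s_%s", scenario, srd_train, feature_set, classifier)
}

#' Run the full experiment grid
#'
#' Iterates scenario x SRD x feature set x classifier. One "cell" is a
#' (scenario, training SRD, feature set, classifier) combination evaluated
#' over all subjects (and, for Between-SRD, all test SRDs). When
#' `output_dir` is set each cell's tidy results are written to
#' `cells/<key>.csv` as soon as it completes, and cells already on disk are
#' skipped unless `force = TRUE`, so interrupted runs resume. A cell that
#' fails is logged and recorded as missing, not fatal.
#'
#' @param config An [experiment_config()].
#' @param force Recompute cells that already exist on disk.
#' @param quiet Suppress per-cell progress messages.
#' @return List with `results` (tidy data.frame over all cells), `friedman`
#'   (per scenario/feature/classifier rank test of subject-mean CA across
#'   SRD groups), `summary` (mean CA/MCC per scenario, SRD, feature,
#'   classifier), and `missing` (keys of failed cells).
#' @export
run_experiment <- function(config, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  recs <- generate_dataset(config$sim)
  if (config$filter)
    recs <- lapply(recs, bandpass_notch, low_hz = config$sim$band[1],
                   high_hz = config$sim$band[2], notch_hz = config$notch_hz)
  say("dataset: %d recordings (%.1fs)", length(recs),
      as.numeric(Sys.time() - t0, units = "secs"))
  cell_dir <- if (!is.null(config$output_dir))
    file.path(config$output_dir, "cells") else NULL
  if (!is.null(cell_dir)) dir.create(cell_dir, showWarnings = FALSE,
                                     recursive = TRUE)
  scenarios <- if (config$scenario == "both") c("within", "between")
               else config$scenario
  rows <- list()
  missing <- character(0)
  for (fset in config$feature_sets) {
    fm_cache <- NULL  # built lazily: a fully cached feature set never needs it
    for (scen in scenarios) {
      for (spec in config$classifiers) {
        for (srd in config$srd_groups) {
          key <- .cell_key(scen, srd, fset, spec$kind)
          path <- if (!is.null(cell_dir)) file.path(cell_dir,
                                                    paste0(key, ".csv"))
          if (!is.null(path) && file.exists(path) && !force) {
            rows[[key]] <- utils::read.csv(path, stringsAsFactors = FALSE,
                                           colClasses = c(subject = "character"))
            say("cell %s: cached", key)
            next
          }
          if (is.null(fm_cache)) {
            tf <- Sys.time()
            fm_cache <- subject_feature_cache(recs, fset, config$seg)
            say("features %s: %d subjects (%.1fs)", fset, length(fm_cache),
                as.numeric(Sys.time() - tf, units = "secs"))
          }
          tc <- Sys.time()
          res <- tryCatch({
            r <- if (scen == "within")
              within_srd_eval(recs, srd, fset, spec, config$seg,
                              fm_cache = fm_cache)
            else
              between_srd_eval(recs, srd, fset, spec, config$seg,
                               srd_test = config$srd_groups,
                               strict = config$strict_between,
                               fm_cache = fm_cache)
            results_table(r)
          }, error = function(e) {
            say("cell %s FAILED: %s", key, conditionMessage(e))
            NULL
          })
          if (is.null(res)) { missing <- c(missing, key); next }
          rows[[key]] <- res
          if (!is.null(path))
            utils::write.csv(res, path, row.names = FALSE, quote = FALSE)
          say("cell %s: %d rows (%.1fs)", key, nrow(res),
              as.numeric(Sys.time() - tc, units = "secs"))
        }
      }
    }
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summary <- stats::aggregate(cbind(ca, mcc_macro) ~
                                scenario + srd_train + srd_test +
                                feature_set + classifier,
                              data = results, FUN = mean)
  summary <- summary[order(summary$scenario, summary$feature_set,
                           summary$classifier, summary$srd_train,
                           summary$srd_test), ]
  friedman <- .friedman_by_cell(results)
  if (!is.null(config$output_dir)) {
    utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summary, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(friedman,
                         file.path(config$output_dir, "friedman.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(results = results, summary = summary, friedman = friedman,
       missing = missing)
}

# Friedman rank test of subject-level mean CA across SRD groups, one test per
# (scenario, feature set, classifier). Blocks = subjects, treatments = SRD
# (training SRD for the between scenario, averaged over test SRDs).
.friedman_by_cell <- function(results) {
  cells <- unique(results[, c("scenario", "feature_set", "classifier")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- merge(results, cells[i, , drop = FALSE])
    agg <- stats::aggregate(ca ~ subject + srd_train, data = sub, FUN = mean)
    m <- stats::xtabs(ca ~ subject + srd_train, data = agg)
    if (nrow(m) < 2 || ncol(m) < 2) return(NULL)
    ft <- friedman_test(as.matrix(m))
    data.frame(cells[i, , drop = FALSE], statistic = ft$statistic,
               df = ft$df, p_value = ft$p_value, row.names = NULL)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
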