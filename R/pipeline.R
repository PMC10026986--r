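#' Build the coupling feature table from a protocol dataset
#'
#' Runs the estimation chain for every subject: merges the per-condition
#' RR and band-power streams, fits the bidirectional coupling model with
#' [svsdg()], and condenses every coupling series into one value per
#' condition (default: MAD of the z-scored series over the condition
#' window, the study's variability measure).
#'
#' @param dataset A [generate_protocol_dataset()] result.
#' @param condensation \code{"mad"} (default) or \code{"median"}.
#' @param window_s Sliding-window length (default 15 s).
#' @param warmup_beats Kalman warm-up (default 20 beats, so the short
#'   rest period keeps enough coverage).
#' @param stress_levels Named numeric encoding of the conditions
#'   (default rest 0, stressors 1, 4, 5).
#' @param verbose Print per-subject progress (default FALSE).
#' @return A [feature_table()] with one row per subject-condition and
#'   one column per (direction, branch, band, channel).
#' @export
build_feature_table <- function(dataset, condensation = c("mad", "median"),
                                window_s = 15, warmup_beats = 20L,
                                stress_levels = c(rest = 0, stress1 = 1,
                                                  stress2 = 4,
                                                  stress3 = 5),
                                verbose = FALSE) {
  stopifnot(inherits(dataset, "protocol_dataset"))
  condensation <- match.arg(condensation)
  cp <- dataset$condition_plan
  windows <- data.frame(label = cp$label, onset = cp$onset,
                        duration = cp$duration)
  rows <- list()
  for (sub in dataset$subjects) {
    if (verbose) message("subject ", sub$id)
    rr <- merge_rr(lapply(sub$conditions, `[[`, "rr"))
    bp <- merge_bandpower(lapply(sub$conditions, `[[`, "bandpower"))
    fit <- svsdg(rr, bp, window_s = window_s,
                 warmup_beats = warmup_beats)
    feats <- lapply(fit$couplings, function(cs) {
      cd <- condense_markers(cs$sdg, cs$grid, windows, valid = cs$valid,
                             normalize = TRUE)
      stats::setNames(cd[[condensation]], cd$label)
    })
    for (ci in seq_len(nrow(cp))) {
      vals <- vapply(feats, `[[`, numeric(1), cp$label[ci])
      names(vals) <- paste0(names(fit$couplings), ".", condensation)
      rows[[length(rows) + 1L]] <- c(
        list(subject = sub$id, condition = cp$label[ci]),
        as.list(vals))
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  lev <- stress_levels[df$condition]
  if (anyNA(lev)) stop("stress_levels must name every condition")
  cls <- ifelse(df$condition %in% c("rest", "stress1"), "low", "high")
  feature_table(df[, setdiff(names(df), c("subject", "condition")),
                   drop = FALSE],
                subject = df$subject, condition = df$condition,
                stress_level = unname(lev), stress_class = cls)
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: simulate (or accept) a protocol dataset,
#' build the coupling feature table, rank features by MRMR for both the
#' regression and classification targets, produce the condition-wise
#' statistical report, and run both cross-validated models.  All outputs
#' can be written as delimited text with a manifest.
#'
#' @param config A [synthetic_config()] used to simulate data when
#'   \code{dataset} is NULL.
#' @param dataset Optionally a precomputed [generate_protocol_dataset()]
#'   result (takes precedence over \code{config}).
#' @param out_dir Optional output directory; when given, every artifact
#'   is written there along with \code{manifest.csv} (file, md5) and the
#'   serialized configuration.
#' @param n_features Features carried into the CV models (default 5).
#' @param lambda Kernel ridge regularisation (default 0.027).
#' @param n_folds CV folds (default 5).
#' @param nested_selection Re-run MRMR inside every training fold
#'   (default TRUE); otherwise a one-shot ranking on all rows is reused.
#' @param seed Seed for fold assignment and step-6 tie-breaking.
#' @param verbose Progress messages.
#' @return Object of class \code{svsdg_pipeline}: list with
#'   \code{feature_table}, \code{mrmr_regression},
#'   \code{mrmr_classification}, \code{stats_report},
#'   \code{cv_regression}, \code{cv_classification}, \code{config}.
#' @export
run_pipeline <- function(config = synthetic_config(), dataset = NULL,
                         out_dir = NULL, n_features = 5L, lambda = 0.027,
                         n_folds = 5L, nested_selection = TRUE,
                         seed = 1L, verbose = FALSE) {
  if (is.null(dataset)) {
    if (verbose) message("stage simulate: generating protocol dataset")
    dataset <- generate_protocol_dataset(config)
  } else config <- dataset$config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfgkv <- c(n_subjects = config$n_subjects,
               baseline_rate_hz = config$baseline_rate_hz,
               seed = config$seed, n_features = n_features,
               lambda = lambda, n_folds = n_folds,
               nested_selection = nested_selection,
               pipeline_seed = seed)
    writeLines(paste(names(cfgkv), cfgkv, sep = "="),
               file.path(out_dir, "run_config.txt"))
  }
  if (verbose) message("stage features: building coupling feature table")
  ft <- build_feature_table(dataset, verbose = verbose)
  if (verbose) message("stage mrmr")
  mr_reg <- mrmr_rank(ft, ft$stress_level, mode = "regression",
                      seed = seed)
  mr_cls <- mrmr_rank(ft, factor(ft$stress_class),
                      mode = "classification", seed = seed)
  if (verbose) message("stage stats")
  sr <- stress_stats_report(ft)
  if (verbose) message("stage cv")
  sel_reg <- if (nested_selection) NULL else
    mr_reg$feature[seq_len(n_features)]
  sel_cls <- if (nested_selection) NULL else
    mr_cls$feature[seq_len(n_features)]
  cv_reg <- kernel_regression_cv(ft, selected = sel_reg, lambda = lambda,
                                 n_folds = n_folds,
                                 n_features = n_features, seed = seed)
  cv_cls <- kernel_nb_classify_cv(ft, selected = sel_cls,
                                  n_folds = n_folds,
                                  n_features = n_features, seed = seed)
  out <- structure(list(feature_table = ft, mrmr_regression = mr_reg,
                        mrmr_classification = mr_cls, stats_report = sr,
                        cv_regression = cv_reg,
                        cv_classification = cv_cls, config = config,
                        seed = seed),
                   class = "svsdg_pipeline")
  if (!is.null(out_dir)) {
    write_feature_table(ft, file.path(out_dir, "feature_table.csv"))
    utils::write.csv(as.data.frame(mr_reg),
                     file.path(out_dir, "mrmr_regression.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(mr_cls),
                     file.path(out_dir, "mrmr_classification.csv"),
                     row.names = FALSE)
    utils::write.csv(sr$friedman, file.path(out_dir, "friedman.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(fold = cv_reg$fold,
                                observed = cv_reg$observed,
                                predicted = cv_reg$predicted),
                     file.path(out_dir, "cv_regression.csv"),
                     row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- data.frame(file = basename(files),
                           md5 = tools::md5sum(files))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.svsdg_pipeline <- function(x, ...) {
  cat("SV-SDG stress pipeline result\n")
  print(x$feature_table)
  print(x$stats_report)
  print(x$cv_regression)
  print(x$cv_classification)
  cat("top regression features: ",
      paste(utils::head(x$mrmr_regression$feature, 5), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
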