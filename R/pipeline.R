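#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default:
#' the scale profile, the master seed (all stage seeds derive from it),
#' whether success thresholds are derived from the aggregate mixture fits
#' or fixed, the connectivity threshold (0.25), Louvain restarts, FDR
#' alpha, and the quality-score scaling.
#'
#' @param profile `"full"` or `"small"`.
#' @param seed Master integer seed.
#' @param thresholds `"derive"` or a named vector `c(color=, scene=)`.
#' @param cut Connectivity threshold (default 0.25).
#' @param louvain_restarts Louvain restarts (default 100).
#' @param fdr_alpha FDR level (default 0.05).
#' @param quality_scaling `"threshold"` or `"half_circle"`.
#' @param behavioral [behavioral_params()] to simulate under.
#' @param neural [neural_params()] to simulate under.
#' @param run_gppi Include the gPPI stage (default TRUE).
#' @return List of class `run_config`.
#' @export
run_config <- function(profile = c("small", "full"), seed = 1L,
                       thresholds = "derive", cut = 0.25,
                       louvain_restarts = 100L, fdr_alpha = 0.05,
                       quality_scaling = c("threshold", "half_circle"),
                       behavioral = behavioral_params(),
                       neural = neural_params(modulation_pairs = "hippocampal"),
                       run_gppi = TRUE) {
  profile <- match.arg(profile)
  quality_scaling <- match.arg(quality_scaling)
  structure(
    list(profile = profile, seed = as.integer(seed), thresholds = thresholds,
         cut = cut, louvain_restarts = as.integer(louvain_restarts),
         fdr_alpha = fdr_alpha, quality_scaling = quality_scaling,
         behavioral = behavioral, neural = neural, run_gppi = run_gppi),
    class = "run_config"
  )
}

#' Deterministic per-subject, per-stage RNG seed
#'
#' Derives a reproducible seed from the master seed, the subject index and
#' a stage number, kept within the 32-bit integer range, so every
#' stochastic stage of the pipeline can be re-run in isolation.
#'
#' @param master Master integer seed.
#' @param subject Subject index.
#' @param stage Stage number (3 = time-series generation, 4 = Louvain).
#' @return An integer seed.
#' @export
subject_seed <- function(master, subject, stage) {
  (as.integer(master) * 7919L + subject * 104729L + stage * 131L) %% 2147483647L
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> exclude -> aggregate mixture fits -> success
#' thresholds -> trial scoring -> dependency -> background connectivity ->
#' gPPI -> group statistics, entirely in memory. Deterministic given the
#' config (identical configs give identical results). When `out_dir` is
#' given, every table is also written (CSV/JSON) along with a manifest.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_results` with elements `design`,
#'   `trials`, `exclusion`, `fits` (aggregate color/scene mixture fits),
#'   `thresholds`, `scores`, `dependency`, `connectivity` (per-subject
#'   metrics + group contrasts), and `gppi` (network summaries + group
#'   inference + activity betas), plus the `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  design <- study_design(config$profile)
  trials <- generate_design(design, seed = config$seed)
  trials <- generate_behavior(trials, config$behavioral,
                              seed = config$seed + 1L)

  exclusion <- exclude_subjects(trials)
  included <- exclusion$subject[exclusion$included]
  trials_inc <- trials[trials$subject %in% included, ]

  fits <- list(
    color = fit_mixture(trials_inc$err_color_deg),
    scene = fit_mixture(trials_inc$err_scene_deg)
  )
  thresholds <- if (identical(config$thresholds, "derive")) {
    c(color = success_threshold(fits$color),
      scene = success_threshold(fits$scene))
  } else {
    config$thresholds
  }

  scores <- score_trials(trials_inc, thresholds, config$quality_scaling)
  dep <- dependency_analysis(scores)

  conn_metrics <- list()
  gppi_quality <- list()
  gppi_activity <- list()
  for (s in included) {
    sc <- scores[scores$subject == s, ]
    ts_set <- generate_timeseries(sc, config$neural, design, scores = sc,
                                  seed = subject_seed(config$seed, s, 3L))
    bg <- background_connectivity(ts_set, sc, cut = config$cut,
                                  louvain_seed = subject_seed(config$seed, s, 4L),
                                  louvain_restarts = config$louvain_restarts)
    conn_metrics[[length(conn_metrics) + 1L]] <- bg$metrics
    if (isTRUE(config$run_gppi)) {
      gq <- gppi_matrices(ts_set, sc, model = "quality")$quality
      ns <- network_summary(gq)
      gppi_quality[[length(gppi_quality) + 1L]] <-
        cbind(subject = s, ns,
              overall = mean(gq[!is.na(gq)]))
      gppi_activity[[length(gppi_activity) + 1L]] <-
        c(subject = s, activity_glm(ts_set, sc))
    }
  }
  conn_metrics <- do.call(rbind, conn_metrics)
  conn_group <- compare_conditions(conn_metrics)

  gppi_res <- NULL
  if (isTRUE(config$run_gppi)) {
    qsum <- do.call(rbind, gppi_quality)
    cellname <- paste0(qsum$seed_network, "_to_", qsum$target_network)
    wide <- stats::reshape(
      data.frame(subject = qsum$subject, cell = cellname,
                 beta = qsum$mean_beta),
      idvar = "subject", timevar = "cell", direction = "wide"
    )
    mat <- as.matrix(wide[, -1, drop = FALSE])
    colnames(mat) <- sub("^beta\\.", "", colnames(mat))
    overall <- tapply(qsum$overall, qsum$subject, mean)
    act <- do.call(rbind, gppi_activity)
    gppi_res <- list(
      per_subject = qsum,
      network_inference = group_inference(mat, tails = "one",
                                          alpha = config$fdr_alpha),
      overall_beta = group_ttest(as.numeric(overall), 0, "one"),
      activity_betas = act,
      activity_inference = group_inference(
        act[, setdiff(colnames(act), "subject"), drop = FALSE],
        tails = "one", alpha = config$fdr_alpha)
    )
  }

  results <- structure(
    list(design = design, trials = trials, exclusion = exclusion,
         fits = fits, thresholds = thresholds, scores = scores,
         dependency = dep,
         connectivity = list(per_subject = conn_metrics, group = conn_group),
         gppi = gppi_res, config = config),
    class = "pipeline_results"
  )
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

#' Write a results bundle to disk
#'
#' Numeric outputs are written with full precision so runs with identical
#' seeds produce byte-identical bundles.
#'
#' @param results A `pipeline_results`.
#' @param out_dir Output directory (created if missing).
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_trials(results$trials, p("trials.csv"))
  utils::write.csv(results$exclusion, p("exclusion.csv"), row.names = FALSE)
  utils::write.csv(results$scores, p("scores.csv"), row.names = FALSE)
  utils::write.csv(results$dependency$per_subject, p("dependency_subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(results$dependency$group, p("dependency_group.csv"),
                   row.names = FALSE)
  utils::write.csv(results$connectivity$per_subject,
                   p("connectivity_metrics.csv"), row.names = FALSE)
  utils::write.csv(results$connectivity$group, p("connectivity_group.csv"),
                   row.names = FALSE)
  if (!is.null(results$gppi)) {
    utils::write.csv(results$gppi$per_subject, p("gppi_network_subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(results$gppi$network_inference, p("gppi_network_group.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(results$gppi$activity_betas),
                     p("activity_betas.csv"), row.names = FALSE)
  }
  fits_json <- lapply(names(results$fits), function(f) {
    fit <- results$fits[[f]]
    list(feature = f, k = fit$kappa, gamma = fit$gamma, loglik = fit$loglik,
         n = fit$n, threshold_deg = results$thresholds[[f]])
  })
  jsonlite::write_json(fits_json, p("mixture_fits.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("epiconn")),
    profile = results$config$profile,
    seed = results$config$seed,
    cut = results$config$cut,
    louvain_restarts = results$config$louvain_restarts,
    thresholds = as.list(results$thresholds),
    n_subjects_included = sum(results$exclusion$included)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
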