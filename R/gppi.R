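#' HRF-convolved memory-quality modulator for remember events
#'
#' Places each remember trial's 0-3 memory-quality score on its event,
#' mean-centres the scores across remember events (so the regressor
#' captures trial-to-trial variation in quality, not the mere occurrence
#' of retrieval), sets all other time points to zero, and convolves with
#' the canonical HRF per run.
#'
#' @param scores Scored trial table for one subject (with `quality`).
#' @param design The `study_design`.
#' @param values Optional replacement per-trial values (same centering
#'   rules); default `scores$quality`. `NA` values contribute zero.
#' @return Numeric regressor over all concatenated scans.
#' @export
build_quality_modulator <- function(scores, design, values = scores$quality) {
  runs <- sort(unique(scores$run))
  T <- design$scans_per_run
  keep <- !is.na(values)
  centred <- numeric(length(values))
  centred[keep] <- values[keep] - mean(values[keep])
  out <- numeric(T * length(runs))
  for (ri in seq_along(runs)) {
    sel <- scores$run == runs[ri]
    out[(ri - 1L) * T + seq_len(T)] <-
      event_regressor(scores$onset_remember_s[sel], design$event_duration_s,
                      centred[sel], T, design$tr_seconds)
  }
  out
}

#' Fit a generalized psychophysiological interaction model
#'
#' Ordinary least squares of each target ROI time series on: per-run
#' intercepts, the task main-effect regressors, the psychological
#' (memory) regressors, the seed time series, and the interaction of the
#' seed with each psychological regressor. Interactions are formed in
#' BOLD space as the elementwise product of the observed seed series and
#' the HRF-convolved psychological regressor. When several modulators
#' enter one model, each interaction beta is the unique contribution of
#' that modulator. Returns the interaction coefficients (seed-to-target
#' effective-connectivity change per unit modulator).
#'
#' @param target_ts Scans x n_targets matrix (or vector).
#' @param seed_ts Seed time series (length = scans).
#' @param psych Matrix (scans x n_mod) of HRF-convolved psychological
#'   regressors; column names label the modulators.
#' @param run Run index per scan (per-run intercepts).
#' @param task Optional matrix of task main-effect regressors.
#' @return Matrix n_mod x n_targets of interaction betas (rownames =
#'   modulator, colnames = target).
#' @export
fit_gppi <- function(target_ts, seed_ts, psych, run, task = NULL) {
  target_ts <- as.matrix(target_ts)
  psych <- as.matrix(psych)
  if (is.null(colnames(psych))) {
    colnames(psych) <- paste0("mod", seq_len(ncol(psych)))
  }
  n <- nrow(target_ts)
  if (length(seed_ts) != n || nrow(psych) != n || length(run) != n) {
    stop("seed, psych, run and target lengths must match")
  }
  run_f <- factor(run)
  X_int <- seed_ts * psych
  colnames(X_int) <- paste0("ppi_", colnames(psych))
  X <- cbind(
    stats::model.matrix(~ 0 + run_f),
    task,
    psych,
    seed = seed_ts,
    X_int
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("gPPI design matrix is rank deficient (collinear regressors)")
  }
  beta <- qr.coef(qrX, target_ts)
  out <- beta[grepl("^ppi_", rownames(beta)), , drop = FALSE]
  rownames(out) <- sub("^ppi_", "", rownames(out))
  colnames(out) <- colnames(target_ts)
  out
}

#' Seed-to-target gPPI matrices for one subject
#'
#' Runs [fit_gppi()] with every ROI as seed against all other ROIs as
#' targets, on nuisance-denoised series (task regressors are retained in
#' the data and modelled inside the gPPI GLM). Two models are supported:
#' `"quality"` — the composite memory-quality modulator on remember
#' events; `"features"` — the five feature modulators (emotion, color and
#' scene success, color and scene precision) on remember events entering
#' one model, so each interaction matrix reflects the unique modulation.
#'
#' @param ts_set `roi_timeseries` for one subject.
#' @param scores Scored trial table for the same subject.
#' @param model `"quality"` or `"features"`.
#' @param valence_subset For the quality model only: restrict the
#'   modulator to `"negative"` or `"neutral"` trials (other trials
#'   contribute zero; centering is within the subset). Used for the
#'   emotion-moderation analysis, which contrasts the two split models.
#' @return Named list of seed x target matrices (one per modulator;
#'   diagonal `NA`), each with the `network` attribute set.
#' @export
gppi_matrices <- function(ts_set, scores, model = c("quality", "features"),
                          valence_subset = NULL) {
  model <- match.arg(model)
  design <- ts_set$design
  den <- denoise(ts_set)  # nuisance-only: task structure stays in the data
  ev <- build_event_model(scores, design)
  task <- ev$regressors[, c("encoding_task", "remember_task"), drop = FALSE]

  psych <- if (model == "quality") {
    qvals <- if (is.null(valence_subset)) scores$quality else
      ifelse(scores$valence == valence_subset, scores$quality, NA_real_)
    cbind(quality = build_quality_modulator(scores, design, values = qvals))
  } else {
    cbind(
      emotion = build_quality_modulator(scores, design,
                                        values = scores$emotion_score),
      success_color = build_quality_modulator(scores, design,
                                              values = scores$success_color),
      success_scene = build_quality_modulator(scores, design,
                                              values = scores$success_scene),
      precision_color = ev$regressors[, "remember_precision_color"],
      precision_scene = ev$regressors[, "remember_precision_scene"]
    )
  }

  labels <- design$roi_labels
  n <- length(labels)
  mats <- lapply(colnames(psych), function(m) {
    x <- matrix(NA_real_, n, n, dimnames = list(seed = labels, target = labels))
    attr(x, "network") <- design$network_labels
    x
  })
  names(mats) <- colnames(psych)
  for (si in seq_len(n)) {
    targets <- den$ts[, -si, drop = FALSE]
    betas <- fit_gppi(targets, den$ts[, si], psych, den$run, task)
    for (m in rownames(betas)) {
      mats[[m]][si, colnames(targets)] <- betas[m, ]
    }
  }
  mats
}

#' Network-level summary of an asymmetric gPPI matrix
#'
#' Means of the seed-to-target interaction betas over each ordered
#' network pair (PM, AT, HIPP), keeping direction (AT to PM is separate
#' from PM to AT). The HIPP-to-HIPP cell is the within-hippocampus
#' (anterior/posterior) coupling.
#'
#' @param mat Seed x target beta matrix with `NA` diagonal.
#' @param network Network label per ROI (defaults to the `network`
#'   attribute).
#' @return data.frame: `seed_network`, `target_network`, `mean_beta`,
#'   `n_pairs`.
#' @export
network_summary <- function(mat, network = attr(mat, "network")) {
  if (is.null(network)) stop("network assignment required")
  nets <- unique(network)
  out <- expand.grid(seed_network = nets, target_network = nets,
                     stringsAsFactors = FALSE)
  out$mean_beta <- NA_real_
  out$n_pairs <- 0L
  for (i in seq_len(nrow(out))) {
    rows <- network == out$seed_network[i]
    cols <- network == out$target_network[i]
    cell <- mat[rows, cols, drop = FALSE]
    vals <- cell[!is.na(cell)]
    out$mean_beta[i] <- mean(vals)
    out$n_pairs[i] <- length(vals)
  }
  out
}

#' Group inference over per-subject summaries with FDR correction
#'
#' One-sample t tests (one-tailed by default: connectivity is predicted
#' to increase, not decrease, with better memory) per summary cell across
#' subjects, with Benjamini-Hochberg FDR correction across the tested
#' family. Flags raw-significant and FDR-significant cells.
#'
#' @param values Subjects x cells matrix (or data.frame) of per-subject
#'   summaries; column names label the cells.
#' @param tails `"one"` or `"two"`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame per cell: `cell`, `mean`, `se`, `t`, `df`, `p`,
#'   `p_fdr`, `sig_raw`, `sig_fdr`.
#' @export
group_inference <- function(values, tails = c("one", "two"), alpha = 0.05) {
  tails <- match.arg(tails)
  values <- as.matrix(values)
  res <- do.call(rbind, lapply(seq_len(ncol(values)), function(j) {
    tt <- group_ttest(values[, j], 0, tails)
    data.frame(cell = colnames(values)[j], mean = tt$mean, se = tt$se,
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }))
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res$sig_raw <- res$p < alpha
  res$sig_fdr <- res$p_fdr < alpha
  res
}

#' Univariate parametric-modulation GLM on ROI activity
#'
#' Regresses each ROI's (nuisance-denoised) time series on per-run
#' intercepts, the encoding and remember task regressors, and the
#' memory-quality modulator, returning the modulator beta per ROI — how
#' strongly mean regional activity tracks trial-wise memory quality.
#'
#' @param ts_set `roi_timeseries` for one subject.
#' @param scores Scored trial table for the same subject.
#' @return Named numeric vector of modulator betas (one per ROI).
#' @export
activity_glm <- function(ts_set, scores) {
  design <- ts_set$design
  den <- denoise(ts_set)
  ev <- build_event_model(scores, design)
  task <- ev$regressors[, c("encoding_task", "remember_task"), drop = FALSE]
  qmod <- build_quality_modulator(scores, design)
  run_f <- factor(den$run)
  X <- cbind(stats::model.matrix(~ 0 + run_f), task, quality = qmod)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("activity GLM design matrix is rank deficient")
  beta <- qr.coef(qrX, den$ts)
  out <- beta["quality", ]
  names(out) <- colnames(den$ts)
  out
}
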