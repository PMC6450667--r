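#' Neural generating parameters for synthetic ROI time series
#'
#' Ground-truth parameters for the BOLD-like generator. The latent
#' covariance is block-structured: ROIs within a network share a network
#' signal (`within_cov`), all ROIs share a weaker global signal
#' (`between_cov`), and `between_boost_remember` adds a further shared
#' signal whose amplitude follows the HRF-convolved remember-event
#' regressor — the retrieval-specific rise in inter-network coupling the
#' connectivity pipeline is designed to detect. `modulation_pairs` plants
#' seed-to-target coupling that scales with a trial-wise memory modulator,
#' the ground truth recovered by the gPPI stage.
#'
#' @param within_cov Latent covariance between ROIs of the same network
#'   (must be >= `between_cov`).
#' @param between_cov Latent covariance between ROIs of different networks.
#' @param between_boost_remember Additional shared covariance during
#'   remember events (0 disables the retrieval reconfiguration).
#' @param noise_sd White measurement-noise SD.
#' @param event_amplitude Evoked-response amplitude common to all ROIs.
#' @param nuisance_count Number of slow nuisance regressors mixed into the
#'   signal (and returned for denoising).
#' @param modulation_pairs Optional data.frame with columns `seed`,
#'   `target` (ROI labels), `beta` (coupling per unit modulator), and
#'   `modulator` (one of `"quality"`, `"precision_color"`,
#'   `"precision_scene"`); or the string `"hippocampal"` to plant quality
#'   modulation on hippocampal-cortical pairs (see
#'   [hippocampal_modulation_pairs()]).
#' @return List of class `neural_params`.
#' @export
neural_params <- function(within_cov = 0.9, between_cov = 0.1,
                          between_boost_remember = 2.5,
                          noise_sd = 1, event_amplitude = 1,
                          nuisance_count = 6L,
                          modulation_pairs = NULL) {
  if (between_cov < 0 || within_cov < between_cov) {
    stop("need within_cov >= between_cov >= 0 (block covariance must be PSD)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (between_boost_remember < 0) stop("between_boost_remember must be >= 0")
  if (!is.null(modulation_pairs) &&
      !identical(modulation_pairs, "hippocampal")) {
    stopifnot(all(c("seed", "target", "beta", "modulator") %in%
                    names(modulation_pairs)))
  }
  structure(
    list(
      within_cov = within_cov, between_cov = between_cov,
      between_boost_remember = between_boost_remember,
      noise_sd = noise_sd, event_amplitude = event_amplitude,
      nuisance_count = as.integer(nuisance_count),
      modulation_pairs = modulation_pairs
    ),
    class = "neural_params"
  )
}

#' Default hippocampal-cortical memory-modulation ground truth
#'
#' Plants memory-quality coupling (interaction coefficient `beta`) from
#' the medial-temporal representational seeds PRC (AT) and PHC (PM) onto
#' anterior and posterior hippocampus, plus the within-hippocampus pair —
#' the kind of inter-network, hippocampus-centred modulation the gPPI
#' stage is designed to detect. Cortical seeds are never targets, so
#' their observed series stay free of interaction terms and every planted
#' coefficient retains its nominal value. Only pairs whose ROIs exist in
#' the design are kept.
#'
#' The default coefficient is deliberately modest: coupling spread over
#' six pairs adds variance to the hippocampal ROIs during remember
#' events, and a large coefficient would distort the background
#' (correlation-based) connectivity of the same ROIs.
#'
#' @param design A `study_design`.
#' @param beta Planted interaction coefficient (default 0.25).
#' @return data.frame with `seed`, `target`, `beta`, `modulator`.
#' @export
hippocampal_modulation_pairs <- function(design, beta = 0.25) {
  cortical <- intersect(c("PRC", "PHC"), design$roi_labels)
  hipp <- intersect(c("aHIPP", "pHIPP"), design$roi_labels)
  pairs <- rbind(
    expand.grid(seed = cortical, target = hipp, stringsAsFactors = FALSE),
    if (length(hipp) == 2L) data.frame(seed = hipp, target = rev(hipp))
  )
  pairs$beta <- beta
  pairs$modulator <- "quality"
  pairs
}

# Per-trial modulator values used both by the generator (to plant coupling)
# and by the analysis stages (to build regressors). Scores must carry
# success/precision/quality columns (see score_trials()).
modulator_values <- function(scores, which) {
  switch(which,
    quality = scores$quality,
    quality_negative = ifelse(scores$valence == "negative",
                              scores$quality, NA_real_),
    quality_neutral = ifelse(scores$valence == "neutral",
                             scores$quality, NA_real_),
    precision_color = ifelse(scores$success_color == 1L,
                             scores$precision_color, NA_real_),
    precision_scene = ifelse(scores$success_scene == 1L,
                             scores$precision_scene, NA_real_),
    stop("unknown modulator: ", which)
  )
}

#' Simulate multi-run ROI time series with planted connectivity structure
#'
#' For each run, each ROI signal is the sum of (i) a network-structured
#' latent process (shared network signal + shared global signal + a
#' remember-locked shared signal implementing the retrieval coupling
#' boost), (ii) evoked responses to encoding and remember events convolved
#' with the canonical HRF, (iii) slow nuisance components with random ROI
#' loadings, (iv) white noise, and (v) for any planted `modulation_pairs`,
#' an interaction term `beta * seed_signal * modulator_regressor` added to
#' the target ROI, where the modulator regressor is the mean-centred,
#' HRF-convolved trial score on remember events. Generation is
#' bit-reproducible given (`seed`, parameters).
#'
#' @param trials Trial table for one subject (with responses if planted
#'   modulators need scores).
#' @param nparams A [neural_params()] list.
#' @param design The `study_design`.
#' @param scores Optional per-trial scores (required when
#'   `modulation_pairs` is set); see [score_trials()].
#' @param seed Integer RNG seed.
#' @return List of class `roi_timeseries` with `ts` (total scans x ROI
#'   matrix), `run` (run index per scan), `nuisance` (scans x
#'   nuisance_count matrix), `design`, and `trials`.
#' @export
generate_timeseries <- function(trials, nparams = neural_params(), design,
                                scores = NULL, seed = 1L) {
  validate_design(design)
  stopifnot(all(trials$subject == trials$subject[1L]))
  runs <- sort(unique(trials$run))
  n_roi <- design$n_rois
  nets <- design$network_labels
  net_ids <- match(nets, unique(nets))
  set.seed(as.integer(seed))

  mod_pairs <- nparams$modulation_pairs
  if (identical(mod_pairs, "hippocampal")) {
    mod_pairs <- hippocampal_modulation_pairs(design)
  }
  if (!is.null(mod_pairs) && is.null(scores)) {
    stop("`scores` is required when modulation_pairs are planted")
  }

  ts_runs <- list()
  nuis_runs <- list()
  run_of <- integer(0)
  for (r in runs) {
    tr_r <- trials[trials$run == r, , drop = FALSE]
    T <- design$scans_per_run
    a_net <- sqrt(nparams$within_cov - nparams$between_cov)
    a_sh <- sqrt(nparams$between_cov)

    f_net <- matrix(stats::rnorm(T * max(net_ids)), T, max(net_ids))
    g_sh <- stats::rnorm(T)
    h_boost <- stats::rnorm(T)

    w_rem <- event_regressor(tr_r$onset_remember_s, design$event_duration_s,
                             1, T, design$tr_seconds)
    w_rem <- pmax(w_rem, 0)
    if (max(w_rem) > 0) w_rem <- w_rem / max(w_rem)
    boost_amp <- sqrt(nparams$between_boost_remember) * w_rem

    evoked <- nparams$event_amplitude * (
      event_regressor(tr_r$onset_encoding_s, design$event_duration_s, 1,
                      T, design$tr_seconds) +
      event_regressor(tr_r$onset_remember_s, design$event_duration_s, 1,
                      T, design$tr_seconds))

    nuis <- matrix(0, T, nparams$nuisance_count)
    if (nparams$nuisance_count > 0L) {
      for (j in seq_len(nparams$nuisance_count)) {
        w <- cumsum(stats::rnorm(T))
        nuis[, j] <- as.numeric(scale(w))
      }
    }
    load_nuis <- matrix(stats::rnorm(nparams$nuisance_count * n_roi, 0, 0.2),
                        nparams$nuisance_count, n_roi)

    x <- matrix(0, T, n_roi)
    for (i in seq_len(n_roi)) {
      x[, i] <- a_net * f_net[, net_ids[i]] + a_sh * g_sh +
        boost_amp * h_boost + evoked +
        (if (nparams$nuisance_count > 0L) nuis %*% load_nuis[, i] else 0) +
        stats::rnorm(T, 0, nparams$noise_sd)
    }

    if (!is.null(mod_pairs) && nrow(mod_pairs) > 0L) {
      # interaction terms are computed from a snapshot of the base signals,
      # so each planted coefficient is exact regardless of pair order
      sc_r <- scores[scores$run == r, , drop = FALSE]
      x0 <- x
      for (p in seq_len(nrow(mod_pairs))) {
        vals <- modulator_values(sc_r, mod_pairs$modulator[p])
        keep <- !is.na(vals)
        if (!any(keep)) next
        cvals <- vals
        cvals[keep] <- vals[keep] - mean(vals[keep])
        cvals[!keep] <- 0
        m_reg <- event_regressor(sc_r$onset_remember_s, design$event_duration_s,
                                 cvals, T, design$tr_seconds)
        si <- match(mod_pairs$seed[p], design$roi_labels)
        ti <- match(mod_pairs$target[p], design$roi_labels)
        if (is.na(si) || is.na(ti)) stop("modulation pair names unknown ROI")
        x[, ti] <- x[, ti] + mod_pairs$beta[p] * x0[, si] * m_reg
      }
    }

    colnames(x) <- design$roi_labels
    ts_runs[[length(ts_runs) + 1L]] <- x
    nuis_runs[[length(nuis_runs) + 1L]] <- nuis
    run_of <- c(run_of, rep(r, T))
  }

  structure(
    list(
      ts = do.call(rbind, ts_runs),
      run = run_of,
      nuisance = do.call(rbind, nuis_runs),
      design = design,
      trials = trials
    ),
    class = "roi_timeseries"
  )
}
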