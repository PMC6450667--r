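#' Build the task + memory event model for one subject
#'
#' For each condition (encoding and remember), constructs per run: the
#' HRF-convolved condition boxcar (6 s events), and five parametric
#' modulators convolved with the HRF — emotion memory (0 / 0.5 / 1
#' coding), color success, scene success (binary), and color and scene
#' precision. Success and emotion modulators are mean-centred across all
#' trials of the condition; precision modulators are mean-centred within
#' correct trials of that feature only and are zero on incorrect trials.
#' All non-event time points are zero before convolution. Events whose
#' duration extends past the end of a run are clipped with a warning.
#'
#' @param scores Scored trial table for one subject (see [score_trials()]).
#' @param design The `study_design`.
#' @return List of class `event_model`: `regressors` (total scans x 12
#'   matrix, named `<condition>_<regressor>`), `boxcars` (scans x 2
#'   unconvolved condition indicators), `run` (run per scan), and
#'   `conditions`.
#' @export
build_event_model <- function(scores, design) {
  stopifnot(all(scores$subject == scores$subject[1L]))
  runs <- sort(unique(scores$run))
  T <- design$scans_per_run
  run_len <- T * design$tr_seconds
  conds <- c("encoding", "remember")
  onset_col <- c(encoding = "onset_encoding_s", remember = "onset_remember_s")

  if (any(scores$onset_encoding_s + design$event_duration_s > run_len) ||
      any(scores$onset_remember_s + design$event_duration_s > run_len)) {
    warning("some events extend past the run end; they are clipped")
  }

  # per-trial modulator values with the condition-appropriate centering
  center_all <- function(v) v - mean(v)
  prec_centered <- function(success, prec) {
    out <- numeric(length(prec))
    ok <- success == 1L & !is.na(prec)
    out[ok] <- prec[ok] - mean(prec[ok])
    out
  }
  mods <- list(
    emotion = center_all(scores$emotion_score),
    success_color = center_all(scores$success_color),
    success_scene = center_all(scores$success_scene),
    precision_color = prec_centered(scores$success_color,
                                    scores$precision_color),
    precision_scene = prec_centered(scores$success_scene,
                                    scores$precision_scene)
  )

  reg_names <- c(outer(names(mods), conds,
                       function(m, c) paste0(c, "_", m)))
  cols <- c(paste0(conds, "_task"), reg_names)
  out <- matrix(0, T * length(runs), length(cols),
                dimnames = list(NULL, cols))
  box <- matrix(0, T * length(runs), 2, dimnames = list(NULL, conds))
  run_of <- integer(0)
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    sc_r <- scores[scores$run == r, , drop = FALSE]
    rows <- (ri - 1L) * T + seq_len(T)
    for (cond in conds) {
      ons <- sc_r[[onset_col[[cond]]]]
      out[rows, paste0(cond, "_task")] <-
        event_regressor(ons, design$event_duration_s, 1, T, design$tr_seconds)
      box[rows, cond] <-
        event_regressor(ons, design$event_duration_s, 1, T, design$tr_seconds,
                        convolve = FALSE)
      for (m in names(mods)) {
        v <- mods[[m]][scores$run == r]
        out[rows, paste0(cond, "_", m)] <-
          event_regressor(ons, design$event_duration_s, v, T, design$tr_seconds)
      }
    }
    run_of <- c(run_of, rep(r, T))
  }
  structure(
    list(regressors = out, boxcars = box, run = run_of, conditions = conds),
    class = "event_model"
  )
}

dct_highpass_basis <- function(n, tr_seconds, cutoff_s = 128) {
  # SPM-style discrete cosine set: components with period > cutoff_s
  k_max <- floor(2 * n * tr_seconds / cutoff_s)
  if (k_max < 1L) return(NULL)
  t <- seq_len(n) - 0.5
  sapply(seq_len(k_max), function(k) cos(pi * k * t / n))
}

#' Denoise ROI time series run by run
#'
#' Per run: demean, linear detrend, high-pass filter (discrete-cosine
#' basis, cutoff 1/128 Hz), and regress out the nuisance regressors; when
#' `model` is supplied (background-connectivity mode) all task and memory
#' regressors are removed in the same least-squares step, so the residuals
#' reflect covariation independent of trial- and memory-evoked activity.
#' Residuals are concatenated across runs.
#'
#' @details A parametric modulator can be exactly collinear with other
#' regressors on degenerate runs (e.g. every trial of a run correct makes
#' the centred success modulator proportional to the task boxcar). Such
#' redundant event-model columns carry no extra information for the
#' projection, so they are dropped with a warning naming them. Rank
#' deficiency among the base regressors (intercept, trend, cosine set,
#' nuisance) indicates a malformed input and raises a collinearity error
#' naming the offending columns.
#'
#' @param ts_set A `roi_timeseries` (see [generate_timeseries()], or build
#'   one from files).
#' @param model Optional `event_model`; its regressors are removed too.
#' @param cutoff_s High-pass cutoff period in seconds (default 128).
#' @return The `roi_timeseries` with `ts` replaced by residuals.
#' @export
denoise <- function(ts_set, model = NULL, cutoff_s = 128) {
  runs <- sort(unique(ts_set$run))
  res <- ts_set$ts
  for (r in runs) {
    idx <- ts_set$run == r
    n <- sum(idx)
    X <- cbind(intercept = rep(1, n), trend = seq_len(n) - (n + 1) / 2)
    dct <- dct_highpass_basis(n, ts_set$design$tr_seconds, cutoff_s)
    if (!is.null(dct)) X <- cbind(X, dct)
    if (!is.null(ts_set$nuisance) && ncol(ts_set$nuisance) > 0L) {
      X <- cbind(X, ts_set$nuisance[idx, , drop = FALSE])
    }
    n_base <- ncol(X)
    if (!is.null(model)) {
      X <- cbind(X, model$regressors[model$run == r, , drop = FALSE])
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      redundant <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
      names_red <- colnames(X)[redundant]
      names_red[is.na(names_red) | names_red == ""] <-
        paste0("column_", redundant[is.na(names_red) | names_red == ""])
      if (any(redundant <= n_base)) {
        stop("denoising design matrix is rank deficient; offending columns: ",
             paste(names_red, collapse = ", "))
      }
      warning("dropping collinear event-model regressor(s) in run ", r, ": ",
              paste(names_red, collapse = ", "))
      X <- X[, -redundant, drop = FALSE]
      qrX <- qr(X)
    }
    res[idx, ] <- qr.resid(qrX, ts_set$ts[idx, , drop = FALSE])
  }
  out <- ts_set
  out$ts <- res
  out
}

#' Condition weights for HRF-weighted connectivity
#'
#' The HRF-convolved boxcar of a condition's events across the
#' concatenated runs, with negative (undershoot) lobes clipped to zero and
#' normalized to sum 1, so the weighted correlation emphasizes scans
#' acquired while the condition's evoked response was present.
#'
#' @param scores Scored trial table for one subject.
#' @param design The `study_design`.
#' @param condition `"encoding"` or `"remember"`.
#' @return Non-negative weight vector over all scans.
#' @export
condition_weights <- function(scores, design,
                              condition = c("encoding", "remember")) {
  condition <- match.arg(condition)
  onset_col <- if (condition == "encoding") "onset_encoding_s" else
    "onset_remember_s"
  runs <- sort(unique(scores$run))
  T <- design$scans_per_run
  w <- numeric(T * length(runs))
  for (ri in seq_along(runs)) {
    sc_r <- scores[scores$run == runs[ri], , drop = FALSE]
    w[(ri - 1L) * T + seq_len(T)] <-
      event_regressor(sc_r[[onset_col]], design$event_duration_s, 1,
                      T, design$tr_seconds)
  }
  w <- pmax(w, 0)
  if (sum(w) == 0) stop("condition weights are all zero")
  w / sum(w)
}

#' Weighted Pearson correlation matrix between ROI time series
#'
#' Pairwise weighted correlations
#' \deqn{r = \frac{\sum w (x - \bar x_w)(y - \bar y_w)}
#'   {\sqrt{\sum w (x-\bar x_w)^2 \sum w (y-\bar y_w)^2}}}
#' with weighted means. Equal weights reduce to the ordinary Pearson
#' correlation; 0/1 weights to Pearson on the selected scans. The diagonal
#' is set to 0. Zero-variance ROIs yield `NA` entries with a warning.
#'
#' @param ts Scans x ROI matrix (typically denoised residuals).
#' @param weights Non-negative weights, length = rows of `ts`, not all 0.
#' @param network Optional network label per ROI, attached as attribute.
#' @param condition Optional condition label, attached as attribute.
#' @return ROI x ROI symmetric correlation matrix with zero diagonal and
#'   attributes `network` and `condition`.
#' @export
weighted_correlation_matrix <- function(ts, weights, network = NULL,
                                        condition = NULL) {
  if (length(weights) != nrow(ts)) stop("weights length must match scans")
  if (any(weights < 0)) stop("weights must be non-negative")
  sw <- sum(weights)
  if (sw == 0) stop("weights must not be all zero")
  w <- weights / sw
  mu <- colSums(w * ts)
  xc <- sweep(ts, 2, mu)
  cov_w <- crossprod(xc * sqrt(w), xc * sqrt(w))
  v <- diag(cov_w)
  if (any(v <= 0)) warning("zero-variance ROI(s); correlations set to NA")
  denom <- sqrt(outer(v, v))
  denom[denom <= 0] <- NA_real_
  m <- cov_w / denom
  diag(m) <- 0
  dimnames(m) <- list(colnames(ts), colnames(ts))
  attr(m, "network") <- network
  attr(m, "condition") <- condition
  m
}

#' Threshold a connectivity matrix
#'
#' Entries below the cut are set to 0; surviving entries keep their weight
#' (a weighted graph, not a binary one). Negative correlations are always
#' removed at any cut >= 0. The diagonal stays 0.
#'
#' @param m Square connectivity matrix.
#' @param cut Threshold in \[-1, 1\] (default 0.25).
#' @return Thresholded matrix (attributes preserved).
#' @export
threshold_matrix <- function(m, cut = 0.25) {
  if (cut < -1 || cut > 1) stop("cut must lie in [-1, 1]")
  out <- m
  out[out < cut] <- 0
  diag(out) <- 0
  attr(out, "network") <- attr(m, "network")
  attr(out, "condition") <- attr(m, "condition")
  out
}

#' Louvain community detection and weighted modularity
#'
#' Runs the Louvain algorithm on the weighted undirected graph of a
#' thresholded connectivity matrix, restarted `n_restarts` times from
#' different RNG states (the algorithm's greedy passes depend on vertex
#' order), and returns the partition with the highest Newman weighted
#' modularity Q at resolution 1. An empty graph (all zeros) gets Q = 0
#' with singleton communities.
#'
#' @param m Thresholded, non-negative, symmetric matrix.
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of restarts (default 100).
#' @return List with `Q` and `membership` (integer community per ROI).
#' @export
louvain_modularity <- function(m, seed = 1L, n_restarts = 100L) {
  if (any(m < 0)) stop("louvain_modularity requires non-negative weights")
  if (!isSymmetric(unname(m), tol = 1e-10)) stop("matrix must be symmetric")
  n <- nrow(m)
  if (all(m == 0)) {
    return(list(Q = 0, membership = seq_len(n)))
  }
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best_q <- -Inf
  best_mem <- NULL
  for (i in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + i - 1L)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > best_q) {
      best_q <- q
      best_mem <- as.integer(igraph::membership(cl))
    }
  }
  list(Q = best_q, membership = best_mem)
}

#' Within- and between-network density of a thresholded matrix
#'
#' Mean connection strength over all ROI pairs that share a network label
#' (within) and over all cross-network pairs (between). Pairs zeroed by
#' thresholding are included in the means (density reflects both how many
#' connections survive and how strong they are). A network with fewer
#' than 2 ROIs contributes no within pairs and is flagged.
#'
#' @param m Thresholded symmetric matrix.
#' @param network Network label per ROI (defaults to the matrix's
#'   `network` attribute).
#' @return List with `within`, `between`, and `flagged_networks`.
#' @export
network_density <- function(m, network = attr(m, "network")) {
  if (is.null(network)) stop("network assignment required")
  if (length(network) != nrow(m)) stop("network length must match ROIs")
  n <- nrow(m)
  same <- outer(network, network, "==")
  ut <- upper.tri(m)
  counts <- table(network)
  flagged <- names(counts)[counts < 2]
  list(
    within = mean(m[ut & same]),
    between = mean(m[ut & !same]),
    flagged_networks = flagged
  )
}

#' Compare connectivity metrics between encoding and retrieval
#'
#' Given per-subject modularity and density metrics for both conditions,
#' computes: the paired t test on modularity (retrieval - encoding), and
#' the 2 (task) x 2 (within/between) repeated-measures effects, each from
#' its 1-df within-subject contrast (for which F = t^2): the task main
#' effect (mean density change), the network main effect (within vs
#' between), and the task-by-network interaction (whether between-network
#' density changes more than within-network density at retrieval).
#'
#' @param metrics data.frame with one row per subject: columns
#'   `Q_encoding`, `Q_remember`, `within_encoding`, `within_remember`,
#'   `between_encoding`, `between_remember`.
#' @return data.frame of effects: `effect`, `estimate`, `t`, `F`, `df`,
#'   `p` (two-tailed on t).
#' @export
compare_conditions <- function(metrics) {
  need <- c("Q_encoding", "Q_remember", "within_encoding", "within_remember",
            "between_encoding", "between_remember")
  stopifnot(all(need %in% names(metrics)))
  contrast_test <- function(x, label) {
    tt <- group_ttest(x, 0, "two")
    data.frame(effect = label, estimate = tt$mean, t = tt$t, F = tt$t^2,
               df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }
  q_diff <- metrics$Q_remember - metrics$Q_encoding
  task_me <- (metrics$within_remember + metrics$between_remember) / 2 -
    (metrics$within_encoding + metrics$between_encoding) / 2
  net_me <- (metrics$within_encoding + metrics$within_remember) / 2 -
    (metrics$between_encoding + metrics$between_remember) / 2
  interaction <- (metrics$between_remember - metrics$between_encoding) -
    (metrics$within_remember - metrics$within_encoding)
  rbind(
    contrast_test(q_diff, "modularity_remember_minus_encoding"),
    contrast_test(task_me, "density_task_main_effect"),
    contrast_test(net_me, "density_network_main_effect"),
    contrast_test(interaction, "density_task_by_network_interaction")
  )
}

#' Background-connectivity metrics for one subject
#'
#' Full per-subject background pipeline: denoise (removing nuisance and
#' all task + memory regressors), then for each condition compute the
#' HRF-weighted correlation matrix, threshold it, and derive Louvain Q
#' and within/between density.
#'
#' @param ts_set `roi_timeseries` for one subject.
#' @param scores Scored trial table for the same subject.
#' @param cut Correlation threshold (default 0.25).
#' @param louvain_seed,louvain_restarts Louvain settings.
#' @return List with `matrices` (per condition, thresholded), raw
#'   `correlations`, and a one-row `metrics` data.frame.
#' @export
background_connectivity <- function(ts_set, scores, cut = 0.25,
                                    louvain_seed = 1L,
                                    louvain_restarts = 100L) {
  model <- build_event_model(scores, ts_set$design)
  den <- denoise(ts_set, model)
  network <- ts_set$design$network_labels
  out_m <- list()
  raw_m <- list()
  met <- list()
  for (cond in c("encoding", "remember")) {
    w <- condition_weights(scores, ts_set$design, cond)
    r <- weighted_correlation_matrix(den$ts, w, network = network,
                                     condition = cond)
    thr <- threshold_matrix(r, cut)
    lv <- louvain_modularity(thr, seed = louvain_seed,
                             n_restarts = louvain_restarts)
    dens <- network_density(thr, network)
    out_m[[cond]] <- thr
    raw_m[[cond]] <- r
    met[[cond]] <- c(Q = lv$Q, within = dens$within, between = dens$between)
  }
  metrics <- data.frame(
    subject = scores$subject[1L],
    Q_encoding = met$encoding[["Q"]],
    Q_remember = met$remember[["Q"]],
    within_encoding = met$encoding[["within"]],
    within_remember = met$remember[["within"]],
    between_encoding = met$encoding[["between"]],
    between_remember = met$remember[["between"]]
  )
  list(matrices = out_m, correlations = raw_m, metrics = metrics)
}
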