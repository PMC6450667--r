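#' Study design for the object-color-scene-emotion paradigm
#'
#' Describes the dimensions of the experiment the generator emulates:
#' subjects studied trial-unique objects, each with a color from a
#' 360-degree spectrum, a location in a 360-degree panorama scene, and a
#' negative or neutral sound, over study-test blocks scanned as separate
#' runs. The `"full"` profile matches the experiment's scale (28 subjects,
#' 6 blocks x 24 trials = 144 events, 12 ROIs in PM/AT/hippocampal
#' networks, 466 scans per run at TR 1.5 s); the `"small"` profile is a
#' reduced geometry for fast tests.
#'
#' @param profile `"full"` or `"small"`.
#' @param n_subjects Optional override of the number of subjects.
#' @return A list of class `study_design` with fields `n_subjects`,
#'   `n_blocks`, `trials_per_block`, `n_scenes`, `min_separation_deg`,
#'   `n_rois`, `roi_labels`, `network_labels`, `tr_seconds`,
#'   `scans_per_run`, `event_duration_s`, and the within-run onset grid
#'   parameters.
#' @export
study_design <- function(profile = c("full", "small"), n_subjects = NULL) {
  profile <- match.arg(profile)
  d <- if (profile == "full") {
    list(
      profile = "full",
      n_subjects = 28L,
      n_blocks = 6L,
      trials_per_block = 24L,
      n_scenes = 6L,
      min_separation_deg = 45,
      tr_seconds = 1.5,
      scans_per_run = 466L,
      event_duration_s = 6,
      encoding_start_s = 6,
      encoding_spacing_s = 7,
      remember_start_s = 186,
      remember_spacing_s = 20
    )
  } else {
    list(
      profile = "small",
      n_subjects = 4L,
      n_blocks = 2L,
      trials_per_block = 8L,
      n_scenes = 2L,
      min_separation_deg = 45,
      tr_seconds = 1.5,
      scans_per_run = 120L,
      event_duration_s = 6,
      encoding_start_s = 4,
      encoding_spacing_s = 7,
      remember_start_s = 66,
      remember_spacing_s = 12
    )
  }
  if (!is.null(n_subjects)) d$n_subjects <- as.integer(n_subjects)
  d$roi_labels <- if (profile == "full") {
    c("ANG", "PREC", "PCC", "RSC", "PHC",          # posterior-medial
      "PRC", "AMYG", "FUS", "ITC", "OFC",          # anterior-temporal
      "aHIPP", "pHIPP")
  } else {
    c("ANG", "PREC", "PHC", "PRC", "AMYG", "aHIPP", "pHIPP")
  }
  d$network_labels <- network_of(d$roi_labels)
  d$n_rois <- length(d$roi_labels)
  validate_design(d)
  structure(d, class = "study_design")
}

#' Map ROI labels to the PM / AT / HIPP network assignment
#'
#' @param roi_labels Character vector of ROI names.
#' @return Character vector in \{"PM", "AT", "HIPP"\}.
#' @export
network_of <- function(roi_labels) {
  pm <- c("ANG", "PREC", "PCC", "RSC", "PHC")
  at <- c("PRC", "AMYG", "FUS", "ITC", "OFC")
  out <- ifelse(roi_labels %in% pm, "PM",
                ifelse(roi_labels %in% at, "AT",
                       ifelse(roi_labels %in% c("aHIPP", "pHIPP"), "HIPP", NA)))
  if (anyNA(out)) stop("unknown ROI label(s): ",
                       paste(roi_labels[is.na(out)], collapse = ", "))
  out
}

validate_design <- function(d) {
  stopifnot(
    d$n_subjects >= 1, d$n_blocks >= 1, d$trials_per_block >= 1,
    d$min_separation_deg > 0, d$min_separation_deg <= 180,
    d$tr_seconds > 0, d$scans_per_run >= 1
  )
  if (d$trials_per_block %% d$n_scenes != 0) {
    stop("trials_per_block must be a multiple of n_scenes")
  }
  per_scene <- d$trials_per_block / d$n_scenes
  if (per_scene * d$min_separation_deg > 360) {
    stop("separation constraint infeasible: ", per_scene,
         " same-scene trials cannot all be >= ", d$min_separation_deg,
         " degrees apart on a 360-degree circle")
  }
  run_len <- d$scans_per_run * d$tr_seconds
  last_enc <- d$encoding_start_s + (d$trials_per_block - 1) * d$encoding_spacing_s +
    d$event_duration_s
  last_rem <- d$remember_start_s + (d$trials_per_block - 1) * d$remember_spacing_s +
    d$event_duration_s
  if (d$remember_start_s < last_enc) {
    stop("remember events overlap encoding events within the run")
  }
  if (last_rem > run_len) {
    stop("events extend past the end of the run (", last_rem, " > ", run_len, " s)")
  }
  invisible(d)
}

circ_dist_deg <- function(a, b) abs(wrap_error(a, b))

# Sample `n` angles on [0, 360) with pairwise circular distance >= min_sep.
sample_separated_angles <- function(n, min_sep, max_tries = 10000L) {
  if (n * min_sep > 360) stop("separation constraint infeasible")
  for (try in seq_len(max_tries)) {
    ang <- stats::runif(n, 0, 360)
    ok <- TRUE
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        if (any(circ_dist_deg(ang[i], ang[(i + 1L):n]) < min_sep)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) return(ang)
  }
  stop("could not satisfy the angular separation constraint after ",
       max_tries, " attempts")
}

#' Generate the trial table (targets, valence, onsets) for all subjects
#'
#' Lays out the study: within each block every scene appears equally often,
#' valence (negative vs neutral sound) is balanced, and any two trials
#' sharing a panorama scene within a block have target color and scene
#' location at least `min_separation_deg` apart (both features), mirroring
#' the interference-control constraint of the paradigm. Encoding and
#' remember (retrieval-cue) events get non-overlapping onsets within each
#' run; block r is scanned as run r.
#'
#' @param design A `study_design`.
#' @param seed Integer RNG seed.
#' @return A data.frame (one row per trial) with columns `subject`, `block`,
#'   `run`, `trial`, `scene_id`, `target_color_deg`, `target_scene_deg`,
#'   `valence`, `onset_encoding_s`, `onset_remember_s`.
#' @export
generate_design <- function(design, seed = 1L) {
  validate_design(design)
  per_scene <- design$trials_per_block / design$n_scenes
  rows <- vector("list", design$n_subjects * design$n_blocks)
  ri <- 0L
  for (s in seq_len(design$n_subjects)) {
    set.seed(as.integer(seed) + 1000L * s)
    for (b in seq_len(design$n_blocks)) {
      scene <- sample(rep(seq_len(design$n_scenes), per_scene))
      n_tr <- design$trials_per_block
      half <- n_tr %/% 2L
      valence <- sample(rep(c("negative", "neutral"), c(half, n_tr - half)))
      col <- numeric(n_tr)
      loc <- numeric(n_tr)
      for (sc in seq_len(design$n_scenes)) {
        idx <- which(scene == sc)
        col[idx] <- sample_separated_angles(length(idx), design$min_separation_deg)
        loc[idx] <- sample_separated_angles(length(idx), design$min_separation_deg)
      }
      tr <- seq_len(n_tr)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        subject = s, block = b, run = b, trial = tr,
        scene_id = scene,
        target_color_deg = col,
        target_scene_deg = loc,
        valence = valence,
        onset_encoding_s = design$encoding_start_s +
          (tr - 1L) * design$encoding_spacing_s,
        onset_remember_s = design$remember_start_s +
          (tr - 1L) * design$remember_spacing_s,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Behavioural generating parameters
#'
#' Defaults reproduce the response regimes observed in the paradigm the
#' generator emulates: color memory with concentration 5.4 and guess rate
#' 0.33, scene (spatial) memory with concentration 27 and guess rate 0.36,
#' emotion association recalled correctly on 76% of trials. Dependency
#' between features is planted through a per-trial latent memory state
#' (see [generate_behavior()]).
#'
#' @param kappa_color,kappa_scene von Mises concentrations (> 0).
#' @param gamma_color,gamma_scene Guess probabilities in \[0, 1\].
#' @param p_emotion_correct Probability of a correct emotion response.
#' @param p_high_confidence Probability a correct emotion response is
#'   high-confidence.
#' @param dependency_strength Shift (in \[0, 0.5\]) applied to each
#'   feature's retrieval probability by the shared latent memory state;
#'   0 makes features independent.
#' @return List of class `behavioral_params`.
#' @export
behavioral_params <- function(kappa_color = 5.4, gamma_color = 0.33,
                              kappa_scene = 27, gamma_scene = 0.36,
                              p_emotion_correct = 0.76,
                              p_high_confidence = 0.7,
                              dependency_strength = 0.15) {
  p <- list(
    kappa_color = kappa_color, gamma_color = gamma_color,
    kappa_scene = kappa_scene, gamma_scene = gamma_scene,
    p_emotion_correct = p_emotion_correct,
    p_high_confidence = p_high_confidence,
    dependency_strength = dependency_strength
  )
  probs <- c(gamma_color, gamma_scene, p_emotion_correct, p_high_confidence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (kappa_color <= 0 || kappa_scene <= 0) stop("concentrations must be > 0")
  if (dependency_strength < 0 || dependency_strength > 0.5) {
    stop("dependency_strength must lie in [0, 0.5]")
  }
  structure(p, class = "behavioral_params")
}
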