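clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate continuous-report responses with planted feature dependency
#'
#' Each trial draws a latent binary "memory state" (good vs poor encoding
#' of the whole event). The state shifts the probability that each feature
#' is retrieved from memory by +/- `dependency_strength`, which induces
#' across-feature dependency in retrieval success while leaving the
#' marginal guess rates at their nominal gamma values and leaving
#' precision (the von Mises concentration) uncoupled across features.
#' In-memory responses are drawn from a von Mises centred on the target;
#' out-of-memory responses are uniform on the circle. Emotion responses
#' are correct with the (state-shifted) emotion probability; correct
#' responses are high-confidence with `p_high_confidence`.
#'
#' @param trials Trial table from [generate_design()].
#' @param params A [behavioral_params()] list.
#' @param seed Integer RNG seed.
#' @return The trial table with added columns `resp_color_deg`,
#'   `resp_scene_deg`, `err_color_deg`, `err_scene_deg` (wrapped to
#'   (-180, 180\]), `emotion_correct` (0/1), `emotion_confidence`
#'   ("high"/"low"), and the latent ground-truth columns `mem_state`,
#'   `inmem_color`, `inmem_scene` used only for validation.
#' @export
generate_behavior <- function(trials, params = behavioral_params(), seed = 1L) {
  stopifnot(all(c("target_color_deg", "target_scene_deg") %in% names(trials)))
  set.seed(as.integer(seed))
  n <- nrow(trials)
  d <- params$dependency_strength
  state <- stats::rbinom(n, 1L, 0.5)
  shift <- d * (2 * state - 1)

  p_col <- clamp01(1 - params$gamma_color + shift)
  p_scn <- clamp01(1 - params$gamma_scene + shift)
  p_emo <- clamp01(params$p_emotion_correct + shift)

  inmem_col <- stats::rbinom(n, 1L, p_col)
  inmem_scn <- stats::rbinom(n, 1L, p_scn)

  err_col <- numeric(n)
  err_scn <- numeric(n)
  err_col[inmem_col == 1L] <- rvonmises_deg(sum(inmem_col), params$kappa_color)
  err_col[inmem_col == 0L] <- wrap_error(stats::runif(n - sum(inmem_col), 0, 360), 0)
  err_scn[inmem_scn == 1L] <- rvonmises_deg(sum(inmem_scn), params$kappa_scene)
  err_scn[inmem_scn == 0L] <- wrap_error(stats::runif(n - sum(inmem_scn), 0, 360), 0)

  emotion_correct <- stats::rbinom(n, 1L, p_emo)
  high_conf <- stats::rbinom(n, 1L, params$p_high_confidence)

  trials$resp_color_deg <- (trials$target_color_deg + err_col) %% 360
  trials$resp_scene_deg <- (trials$target_scene_deg + err_scn) %% 360
  trials$err_color_deg <- wrap_error(trials$resp_color_deg, trials$target_color_deg)
  trials$err_scene_deg <- wrap_error(trials$resp_scene_deg, trials$target_scene_deg)
  trials$emotion_correct <- emotion_correct
  trials$emotion_confidence <- ifelse(high_conf == 1L, "high", "low")
  trials$mem_state <- state
  trials$inmem_color <- inmem_col
  trials$inmem_scene <- inmem_scn
  trials
}
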