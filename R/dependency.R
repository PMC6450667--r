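#' Corrected dependency between two features' retrieval success
#'
#' For binary success vectors A and B over trials, the observed dependency
#' is the proportion of trials on which the two features were remembered
#' or forgotten together, P(AB) + P(A'B'). The expected dependency under
#' an independent model that accounts for overall accuracy is
#' P(A)P(B) + P(A')P(B'). The corrected dependency is their difference:
#' positive values mean the features are bound (remembered together) more
#' than marginal accuracy alone predicts.
#'
#' @param successA,successB Binary (0/1) vectors of equal length >= 2.
#' @param pair Optional label for the feature pair.
#' @return A one-row data.frame with `pair`, `observed`, `expected`,
#'   `corrected`.
#' @export
corrected_dependency <- function(successA, successB, pair = "A-B") {
  if (length(successA) != length(successB)) {
    stop("success vectors must have equal length")
  }
  keep <- !is.na(successA) & !is.na(successB)
  a <- as.integer(successA[keep])
  b <- as.integer(successB[keep])
  if (length(a) < 2L) stop("need at least 2 complete trials")
  if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L))) {
    stop("success vectors must be binary 0/1")
  }
  p_a <- mean(a)
  p_b <- mean(b)
  observed <- mean(a == b)
  expected <- p_a * p_b + (1 - p_a) * (1 - p_b)
  data.frame(pair = pair, observed = observed, expected = expected,
             corrected = observed - expected, stringsAsFactors = FALSE)
}

fisher_z <- function(r, clip = 1 - 1e-7) atanh(pmin(clip, pmax(-clip, r)))

safe_cor_z <- function(x, y, min_n = 3L) {
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n < min_n || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
    return(list(z = NA_real_, n = n))
  }
  list(z = fisher_z(stats::cor(x[keep], y[keep])), n = n)
}

#' Within-subject precision/success correlations (Fisher z)
#'
#' Three Pearson correlations per subject, Fisher-z transformed:
#' (1) color precision (on color-correct trials) vs scene success,
#' (2) scene precision (on scene-correct trials) vs color success, and
#' (3) color precision vs scene precision restricted to trials where both
#' features were successfully recalled. Correlations with fewer than
#' `min_n` usable trials or a degenerate (constant) variable are returned
#' as `NA` along with the usable-trial count. r is clipped to
#' +/-(1 - 1e-7) before atanh so perfect correlations stay finite.
#'
#' @param scores Scored trial table for one subject (see [score_trials()]).
#' @param min_n Minimum usable trials per correlation (default 3).
#' @return data.frame with `measure`, `z`, `n_trials`.
#' @export
precision_correlations <- function(scores, min_n = 3L) {
  cc <- scores$success_color == 1L
  sc <- scores$success_scene == 1L
  r1 <- safe_cor_z(scores$precision_color[cc], scores$success_scene[cc], min_n)
  r2 <- safe_cor_z(scores$precision_scene[sc], scores$success_color[sc], min_n)
  both <- cc & sc
  r3 <- safe_cor_z(scores$precision_color[both], scores$precision_scene[both],
                   min_n)
  data.frame(
    measure = c("colorPrec_sceneSucc", "scenePrec_colorSucc",
                "colorPrec_scenePrec"),
    z = c(r1$z, r2$z, r3$z),
    n_trials = c(r1$n, r2$n, r3$n),
    stringsAsFactors = FALSE
  )
}

#' One-sample / paired t test over subjects
#'
#' Thin wrapper around the standard t statistic with df = n - 1, used for
#' group-level tests on per-subject dependency, correlation, and
#' connectivity summaries. Supplying `paired_with` tests the per-subject
#' differences `values - paired_with`. Zero-variance input yields an
#' infinite t and is flagged rather than erroring.
#'
#' @param values Per-subject values.
#' @param mu0 Null mean (default 0).
#' @param tails `"two"` or `"one"` (one-tailed tests the alternative
#'   mean > mu0).
#' @param paired_with Optional second per-subject vector for a paired test.
#' @return One-row data.frame: `mean`, `se`, `t`, `df`, `p`, `n`,
#'   `zero_variance`.
#' @export
group_ttest <- function(values, mu0 = 0, tails = c("two", "one"),
                        paired_with = NULL) {
  tails <- match.arg(tails)
  if (!is.null(paired_with)) {
    if (length(paired_with) != length(values)) stop("paired lengths differ")
    values <- values - paired_with
  }
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("group_ttest needs at least 2 subjects")
  m <- mean(values)
  s <- stats::sd(values)
  zero_var <- s == 0
  se <- s / sqrt(n)
  tval <- if (zero_var) {
    if (m == mu0) 0 else sign(m - mu0) * Inf
  } else {
    (m - mu0) / se
  }
  df <- n - 1
  p <- if (tails == "two") 2 * stats::pt(-abs(tval), df) else
    stats::pt(tval, df, lower.tail = FALSE)
  data.frame(mean = m, se = se, t = tval, df = df, p = p, n = n,
             zero_variance = zero_var)
}

#' Per-subject dependency and precision-correlation table
#'
#' Runs [corrected_dependency()] for the emotion-color, emotion-scene and
#' color-scene pairs and [precision_correlations()] within every subject,
#' then one-sample t tests (vs 0, two-tailed) across subjects.
#'
#' @param scores Scored trial table for all (included) subjects.
#' @return List with `per_subject` (tidy data.frame: subject, measure,
#'   value) and `group` (data.frame of t tests per measure).
#' @export
dependency_analysis <- function(scores) {
  subs <- sort(unique(scores$subject))
  per <- lapply(subs, function(s) {
    sc <- scores[scores$subject == s, ]
    emo <- as.integer(sc$emotion_score > 0)
    dep <- rbind(
      corrected_dependency(emo, sc$success_color, "emotion-color"),
      corrected_dependency(emo, sc$success_scene, "emotion-scene"),
      corrected_dependency(sc$success_color, sc$success_scene, "color-scene")
    )
    pc <- precision_correlations(sc)
    data.frame(
      subject = s,
      measure = c(paste0("dependency_", dep$pair), pc$measure),
      value = c(dep$corrected, pc$z),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  measures <- unique(per$measure)
  group <- do.call(rbind, lapply(measures, function(m) {
    v <- per$value[per$measure == m]
    cbind(measure = m, group_ttest(v, 0, "two"))
  }))
  list(per_subject = per, group = group)
}
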