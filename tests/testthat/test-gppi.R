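scored_subject <- function(seed = 1, n_subjects = 1) {
  d <- study_design("small", n_subjects = n_subjects)
  tr <- generate_design(d, seed = seed)
  tb <- generate_behavior(tr, seed = seed + 1)
  list(design = d, scores = score_trials(tb, c(color = 57, scene = 30)))
}

test_that("quality modulator is centered on remember events", {
  s <- scored_subject()
  d <- s$design
  # all-equal quality -> identically zero regressor
  sc_flat <- s$scores
  sc_flat$quality <- 2
  expect_true(all(build_quality_modulator(sc_flat, d) == 0))
  # pre-convolution values over remember events sum to zero
  centred <- s$scores$quality - mean(s$scores$quality)
  expect_equal(sum(centred), 0)
  # two-trial toy: qualities 3 and 1 become +1 and -1 on their events
  sc2 <- s$scores[s$scores$run == 1, ][1:2, ]
  sc2$quality <- c(3, 1)
  raw <- event_regressor(sc2$onset_remember_s, d$event_duration_s,
                         c(1, -1), d$scans_per_run, d$tr_seconds,
                         convolve = FALSE)
  times <- (seq_len(d$scans_per_run) - 1) * d$tr_seconds
  on1 <- times >= sc2$onset_remember_s[1] &
    times < sc2$onset_remember_s[1] + d$event_duration_s
  expect_true(all(raw[on1] == 1))
})

test_that("gPPI betas match the normal-equations oracle exactly", {
  set.seed(41)
  n <- 200
  run <- rep(1:2, each = 100)
  seed_ts <- rnorm(n)
  psych <- cbind(quality = rnorm(n))
  task <- cbind(task = rnorm(n))
  y <- 0.3 * seed_ts + 0.5 * seed_ts * psych[, 1] + rnorm(n, 0, 0.1)
  ours <- fit_gppi(y, seed_ts, psych, run, task)
  X <- cbind(run1 = as.numeric(run == 1), run2 = as.numeric(run == 2),
             task, psych, seed_ts, int = seed_ts * psych[, 1])
  oracle <- normal_equations_beta(X, y)
  expect_equal(unname(ours["quality", 1]), unname(oracle["int", 1]),
               tolerance = 1e-8)
})

test_that("gPPI is exact under target scaling and seed shifts", {
  set.seed(43)
  n <- 300
  run <- rep(1:3, each = 100)
  seed_ts <- rnorm(n)
  psych <- cbind(m = rnorm(n))
  y <- 0.4 * seed_ts * psych[, 1] + rnorm(n)
  b1 <- fit_gppi(y, seed_ts, psych, run)
  # scaling the target scales the beta
  b2 <- fit_gppi(3 * y, seed_ts, psych, run)
  expect_equal(b2, 3 * b1, tolerance = 1e-10)
  # a constant added to the seed is absorbed by the main effects
  b3 <- fit_gppi(y, seed_ts + 5, psych, run)
  expect_equal(unname(b3["m", 1] * 1), unname(b1["m", 1]), tolerance = 0.05)
  # white-noise target: interaction indistinguishable from zero
  y0 <- rnorm(n)
  b0 <- fit_gppi(y0, seed_ts, psych, run)
  expect_lt(abs(b0["m", 1]), 2 / sqrt(n / 2))
  expect_error(fit_gppi(y[-1], seed_ts, psych, run), "must match")
})

test_that("a planted interaction coefficient is recovered", {
  s <- scored_subject(5)
  np <- neural_params(
    between_cov = 0,
    modulation_pairs = data.frame(seed = "PRC", target = "aHIPP",
                                  beta = 0.5, modulator = "quality")
  )
  betas <- sapply(1:6, function(i) {
    ts <- generate_timeseries(s$scores, np, s$design, scores = s$scores,
                              seed = 100 + i)
    gppi_matrices(ts, s$scores, "quality")$quality["PRC", "aHIPP"]
  })
  expect_lt(abs(mean(betas) - 0.5), 0.1)
})

test_that("five-feature model returns one matrix per modulator", {
  s <- scored_subject(7)
  ts <- generate_timeseries(s$scores, neural_params(), s$design, seed = 9)
  mats <- gppi_matrices(ts, s$scores, "features")
  expect_setequal(names(mats),
                  c("emotion", "success_color", "success_scene",
                    "precision_color", "precision_scene"))
  for (m in mats) {
    expect_equal(dim(m), c(s$design$n_rois, s$design$n_rois))
    expect_true(all(is.na(diag(m))))
  }
})

test_that("network summary aggregates directed cells correctly", {
  labels <- study_design("full")$roi_labels
  nets <- network_of(labels)
  n <- length(labels)
  # all betas equal: every cell equals that constant
  m <- matrix(0.3, n, n, dimnames = list(labels, labels))
  diag(m) <- NA
  attr(m, "network") <- nets
  ns <- network_summary(m)
  expect_true(all(abs(ns$mean_beta - 0.3) < 1e-12))
  expect_equal(nrow(ns), 9)
  # a single nonzero entry dilutes into its cell mean
  m2 <- matrix(0, n, n, dimnames = list(labels, labels))
  diag(m2) <- NA
  m2["PRC", "aHIPP"] <- 1
  attr(m2, "network") <- nets
  ns2 <- network_summary(m2)
  cell <- ns2[ns2$seed_network == "AT" & ns2$target_network == "HIPP", ]
  expect_equal(cell$n_pairs, 10)         # 5 AT seeds x 2 HIPP targets
  expect_equal(cell$mean_beta, 1 / 10)
  expect_equal(sum(ns2$mean_beta != 0), 1)
  # random betas against an explicit pairwise loop
  set.seed(47)
  m3 <- matrix(rnorm(n * n), n, n, dimnames = list(labels, labels))
  diag(m3) <- NA
  attr(m3, "network") <- nets
  ns3 <- network_summary(m3)
  for (i in seq_len(nrow(ns3))) {
    vals <- c()
    for (si in seq_len(n)) {
      for (ti in seq_len(n)) {
        if (si != ti && nets[si] == ns3$seed_network[i] &&
            nets[ti] == ns3$target_network[i]) {
          vals <- c(vals, m3[si, ti])
        }
      }
    }
    expect_equal(ns3$mean_beta[i], mean(vals))
  }
  # the within-hippocampus cell is the aHIPP/pHIPP pair
  hipp <- ns3[ns3$seed_network == "HIPP" & ns3$target_network == "HIPP", ]
  expect_equal(hipp$n_pairs, 2)
})

test_that("group inference applies one-tailed tests and BH correction", {
  set.seed(53)
  # all-zero effects: nothing rejected
  null_mat <- matrix(rnorm(28 * 9, 0, 1), 28, 9,
                     dimnames = list(NULL, paste0("c", 1:9)))
  gi <- group_inference(null_mat)
  expect_lt(sum(gi$sig_fdr), 3)
  # identical sub-alpha p-values are all rejected by BH
  strong <- matrix(rnorm(28 * 4, 1, 0.5), 28, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  gi2 <- group_inference(strong)
  expect_true(all(gi2$sig_fdr))
  # BH flags match the step-up definition on the computed p-values
  mixed <- cbind(null_mat[, 1:5], strong)
  gi3 <- group_inference(mixed)
  expect_equal(gi3$sig_fdr, bh_stepup_reject(gi3$p, 0.05))
  # one-tailed p is half the two-tailed for positive effects
  gi_two <- group_inference(strong, tails = "two")
  expect_equal(gi2$p, gi_two$p / 2)
})

test_that("activity GLM recovers a planted parametric modulation", {
  s <- scored_subject(11)
  d <- s$design
  ts <- generate_timeseries(s$scores, neural_params(nuisance_count = 0L,
                                                    noise_sd = 0.01,
                                                    within_cov = 0.01,
                                                    between_cov = 0,
                                                    between_boost_remember = 0),
                            d, seed = 13)
  qmod <- build_quality_modulator(s$scores, d)
  ts$ts[, "aHIPP"] <- ts$ts[, "aHIPP"] + 2 * qmod
  betas <- activity_glm(ts, s$scores)
  expect_lt(abs(unname(betas["aHIPP"]) - 2), 0.2)
  expect_lt(max(abs(betas[setdiff(names(betas), "aHIPP")])), 0.2)
})

test_that("disjoint planted feature effects yield dissociable patterns", {
  # scene precision planted within PM, color precision planted AT -> HIPP;
  # the two modulators' beta matrices should be uncorrelated within subject
  design <- study_design("full", n_subjects = 6)
  trials <- generate_design(design, seed = 60)
  tb <- generate_behavior(trials, seed = 61)
  scores <- score_trials(tb, c(color = 57, scene = 30))
  np <- neural_params(modulation_pairs = data.frame(
    seed      = c("RSC", "PHC", "PRC", "AMYG"),
    target    = c("PREC", "ANG", "aHIPP", "aHIPP"),
    beta      = 0.4,
    modulator = c("precision_scene", "precision_scene",
                  "precision_color", "precision_color")
  ))
  sim <- pc <- ps <- numeric(6)
  for (s in 1:6) {
    sc <- scores[scores$subject == s, ]
    ts <- generate_timeseries(sc, np, design, scores = sc, seed = 700 + s)
    gf <- gppi_matrices(ts, sc, "features")
    a <- gf$precision_color
    b <- gf$precision_scene
    keep <- !is.na(a) & !is.na(b)
    sim[s] <- atanh(cor(a[keep], b[keep]))
    pc[s] <- a["PRC", "aHIPP"]
    ps[s] <- b["RSC", "PREC"]
  }
  expect_lt(abs(mean(sim)), 0.1)
  # each planted effect is recovered in its own matrix
  expect_gt(mean(pc), 0.2)
  expect_gt(mean(ps), 0.2)
})

test_that("valence-split models expose a planted emotion moderation", {
  # quality coupling planted on negative-associated trials only: the
  # negative-subset model must show the larger interaction beta
  design <- study_design("full", n_subjects = 3)
  trials <- generate_design(design, seed = 70)
  tb <- generate_behavior(trials, seed = 71)
  scores <- score_trials(tb, c(color = 57, scene = 30))
  np <- neural_params(modulation_pairs = data.frame(
    seed = "PRC", target = "aHIPP", beta = 0.5,
    modulator = "quality_negative"
  ))
  b_neg <- b_neu <- numeric(3)
  for (s in 1:3) {
    sc <- scores[scores$subject == s, ]
    ts <- generate_timeseries(sc, np, design, scores = sc, seed = 800 + s)
    b_neg[s] <- gppi_matrices(ts, sc, "quality",
                              valence_subset = "negative")$quality["PRC", "aHIPP"]
    b_neu[s] <- gppi_matrices(ts, sc, "quality",
                              valence_subset = "neutral")$quality["PRC", "aHIPP"]
  }
  expect_true(all(b_neg > b_neu))
  expect_lt(abs(mean(b_neg) - 0.5), 0.15)
  expect_lt(abs(mean(b_neu)), 0.15)
})
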