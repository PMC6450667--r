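small_scored_subject <- function(seed = 1) {
  d <- study_design("small", n_subjects = 1)
  tr <- generate_design(d, seed = seed)
  tb <- generate_behavior(tr, seed = seed + 1)
  list(design = d, scores = score_trials(tb, c(color = 57, scene = 30)))
}

test_that("event regressors peak 5-6 s after onset and respect centering", {
  s <- small_scored_subject()
  ev <- build_event_model(s$scores, s$design)
  # single-event HRF shape: peak lag of the kernel itself
  h <- canonical_hrf(0.1)
  peak_s <- (which.max(h) - 1) * 0.1
  expect_gte(peak_s, 4.5)
  expect_lte(peak_s, 6.5)
  # success modulator sums to ~0 before convolution: check via the
  # pre-convolution values (centering across all trials of the condition)
  expect_equal(sum(s$scores$success_color - mean(s$scores$success_color)), 0)
  # precision modulators are zero on incorrect trials by construction
  bad <- s$scores$success_scene == 0
  prec <- ifelse(s$scores$success_scene == 1,
                 s$scores$precision_scene - mean(s$scores$precision_scene[!bad]),
                 0)
  expect_true(all(prec[bad] == 0))
  expect_equal(ncol(ev$regressors), 12)  # 2 task + 2 x 5 modulators
  expect_equal(nrow(ev$regressors),
               s$design$scans_per_run * s$design$n_blocks)
})

test_that("denoising removes trends, task structure, and nuisance", {
  s <- small_scored_subject(3)
  d <- s$design
  np <- neural_params(nuisance_count = 3L)
  ts <- generate_timeseries(s$scores, np, d, seed = 5)
  model <- build_event_model(s$scores, d)
  # a pure linear trend vanishes
  ts_lin <- ts
  ts_lin$ts <- matrix(rep(seq_len(nrow(ts$ts)), ncol(ts$ts)), ncol = ncol(ts$ts))
  colnames(ts_lin$ts) <- colnames(ts$ts)
  den_lin <- denoise(ts_lin)
  expect_lt(max(abs(den_lin$ts)), 1e-8)
  # a time series equal to one task regressor vanishes
  ts_task <- ts
  ts_task$ts <- matrix(model$regressors[, "remember_task"],
                       nrow(ts$ts), ncol(ts$ts))
  colnames(ts_task$ts) <- colnames(ts$ts)
  den_task <- denoise(ts_task, model)
  expect_lt(max(abs(den_task$ts)), 1e-8)
  # residuals are orthogonal to every regressor column, run by run
  den <- denoise(ts, model)
  for (r in unique(den$run)) {
    idx <- den$run == r
    X <- cbind(model$regressors[idx, ], ts$nuisance[idx, ])
    dots <- crossprod(X, den$ts[idx, ])
    expect_lt(max(abs(dots)), 1e-6)
  }
})

test_that("rank-deficient denoising designs raise a collinearity error", {
  s <- small_scored_subject(7)
  ts <- generate_timeseries(s$scores, neural_params(nuisance_count = 2L),
                            s$design, seed = 8)
  ts$nuisance[, 2] <- ts$nuisance[, 1]  # duplicate nuisance column
  expect_error(denoise(ts), "rank deficient")
})

test_that("weighted correlation reduces to Pearson for flat/binary weights", {
  set.seed(11)
  x <- matrix(rnorm(400 * 6), 400, 6, dimnames = list(NULL, letters[1:6]))
  r_eq <- weighted_correlation_matrix(x, rep(1, 400))
  r_ref <- cor(x)
  diag(r_ref) <- 0
  expect_equal(unclass(r_eq), r_ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  w01 <- rep(c(0, 1), each = 200)
  r_bin <- weighted_correlation_matrix(x, w01)
  r_sub <- cor(x[w01 == 1, ])
  diag(r_sub) <- 0
  expect_equal(unclass(r_bin), r_sub, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(weighted_correlation_matrix(x, rep(0, 400)), "all zero")
})

test_that("weighted correlation matches the explicit loop oracle", {
  set.seed(13)
  x <- matrix(rnorm(300 * 10), 300, 10)
  w <- runif(300)
  r <- weighted_correlation_matrix(x, w)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(r[i, j], loop_weighted_cor(x[, i], x[, j], w),
                   tolerance = 1e-12)
    }
  }
})

test_that("thresholding zeroes sub-cut entries and keeps weights", {
  m <- matrix(0.2, 6, 6)
  diag(m) <- 0
  expect_true(all(threshold_matrix(m, 0.25) == 0))
  set.seed(17)
  m2 <- matrix(runif(36, -1, 1), 6, 6)
  m2 <- (m2 + t(m2)) / 2
  diag(m2) <- 0
  thr <- threshold_matrix(m2, 0.25)
  expect_equal(thr[m2 >= 0.25], m2[m2 >= 0.25])
  expect_true(all(thr[m2 < 0.25] == 0))
  # cut of -1 is the identity off-diagonal
  expect_equal(threshold_matrix(m2, -1), m2, ignore_attr = TRUE)
})

test_that("Louvain modularity: cliques, complete graph, empty graph", {
  two_cliques <- matrix(0, 12, 12)
  two_cliques[1:6, 1:6] <- 1
  two_cliques[7:12, 7:12] <- 1
  diag(two_cliques) <- 0
  lv <- louvain_modularity(two_cliques, seed = 1, n_restarts = 10)
  expect_equal(lv$Q, 0.5)
  expect_equal(length(unique(lv$membership)), 2L)
  complete <- matrix(1, 8, 8)
  diag(complete) <- 0
  expect_lt(louvain_modularity(complete, seed = 1, n_restarts = 10)$Q, 0.05)
  empty <- matrix(0, 5, 5)
  lv0 <- louvain_modularity(empty)
  expect_equal(lv0$Q, 0)
  expect_equal(lv0$membership, 1:5)
})

test_that("Louvain matches exhaustive maximum modularity on 9 nodes", {
  set.seed(19)
  for (rep in 1:3) {
    m <- matrix(0, 9, 9)
    blocks <- list(1:3, 4:6, 7:9)
    for (b in blocks) m[b, b] <- 0.6 + runif(9, -0.05, 0.05)
    m[m == 0] <- 0.05
    m <- (m + t(m)) / 2
    diag(m) <- 0
    oracle <- exhaustive_max_modularity(m)
    lv <- louvain_modularity(m, seed = rep, n_restarts = 50)
    expect_equal(lv$Q, oracle$Q, tolerance = 0.01)
    # planted three-block labels recovered
    for (b in blocks) {
      expect_equal(length(unique(lv$membership[b])), 1L)
    }
    expect_equal(length(unique(lv$membership)), 3L)
  }
})

test_that("Q is invariant under ROI permutation", {
  set.seed(23)
  m <- matrix(runif(64, 0, 0.5), 8, 8)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  perm <- sample(8)
  q1 <- louvain_modularity(m, seed = 2, n_restarts = 30)$Q
  q2 <- louvain_modularity(m[perm, perm], seed = 2, n_restarts = 30)$Q
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("network density matches the pairwise-loop oracle", {
  nets <- c("PM", "PM", "PM", "AT", "AT", "HIPP")
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- 0.5
  m[4:5, 4:5] <- 0.5
  m[1:3, 4:6] <- 0.1
  m[4:6, 1:3] <- 0.1
  m[4:5, 6] <- 0.1
  m[6, 4:5] <- 0.1
  diag(m) <- 0
  thr <- threshold_matrix(m, 0.25)
  dens <- network_density(thr, nets)
  expect_equal(dens$within, 0.5)    # all surviving within-pairs are 0.5
  expect_equal(dens$between, 0)     # 0.1 entries were zeroed
  expect_equal(dens$flagged_networks, "HIPP")  # one-ROI network
  # all entries equal and above the cut: within == between
  m2 <- matrix(0.4, 6, 6)
  diag(m2) <- 0
  d2 <- network_density(threshold_matrix(m2, 0.25), nets)
  expect_equal(d2$within, 0.4)
  expect_equal(d2$between, 0.4)
  # random matrix against the loop oracle
  set.seed(29)
  m3 <- matrix(runif(144, -0.3, 0.9), 12, 12)
  m3 <- (m3 + t(m3)) / 2
  diag(m3) <- 0
  nets12 <- network_of(study_design("full")$roi_labels)
  thr3 <- threshold_matrix(m3, 0.25)
  dens3 <- network_density(thr3, nets12)
  oracle <- loop_network_density(thr3, nets12)
  expect_equal(dens3$within, oracle$within, tolerance = 1e-12)
  expect_equal(dens3$between, oracle$between, tolerance = 1e-12)
})

test_that("higher cuts never increase density", {
  set.seed(31)
  m <- matrix(runif(144, -0.2, 0.8), 12, 12)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  nets <- network_of(study_design("full")$roi_labels)
  cuts <- c(0, 0.1, 0.2, 0.25, 0.3)
  dens <- sapply(cuts, function(ct) {
    d <- network_density(threshold_matrix(m, ct), nets)
    c(d$within, d$between)
  })
  expect_true(all(diff(dens[1, ]) <= 1e-12))
  expect_true(all(diff(dens[2, ]) <= 1e-12))
})

test_that("condition comparison: identical conditions give zero effects", {
  metrics <- data.frame(
    Q_encoding = runif(10, 0.3, 0.6), within_encoding = runif(10),
    between_encoding = runif(10)
  )
  metrics$Q_remember <- metrics$Q_encoding
  metrics$within_remember <- metrics$within_encoding
  metrics$between_remember <- metrics$between_encoding
  res <- compare_conditions(metrics)
  # every condition contrast vanishes; the network main effect (within vs
  # between) is not a condition effect and stays nonzero
  cond_rows <- res$effect != "density_network_main_effect"
  expect_true(all(res$t[cond_rows] == 0))
  expect_true(all(res$F[cond_rows] == 0))
})

test_that("each 1-df F equals the squared paired t on its contrast", {
  set.seed(37)
  metrics <- data.frame(
    Q_encoding = runif(15, 0.4, 0.6), Q_remember = runif(15, 0.2, 0.5),
    within_encoding = runif(15, 0.3, 0.5), within_remember = runif(15, 0.3, 0.6),
    between_encoding = runif(15, 0, 0.2), between_remember = runif(15, 0.1, 0.4)
  )
  res <- compare_conditions(metrics)
  expect_equal(res$F, res$t^2, tolerance = 1e-12)
  q_t <- t.test(metrics$Q_remember - metrics$Q_encoding)$statistic
  expect_equal(res$t[res$effect == "modularity_remember_minus_encoding"],
               unname(q_t))
})
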