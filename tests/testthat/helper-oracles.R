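# Independent oracles used to cross-check the implementation. These are
# deliberately naive (loops, enumeration, normal equations) so they share no
# code path with the package functions they verify.

# Weighted Pearson correlation between two vectors, written as an explicit
# loop over scans.
loop_weighted_cor <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  num <- den_x <- den_y <- 0
  for (t in seq_along(x)) {
    num <- num + w[t] * (x[t] - mx) * (y[t] - my)
    den_x <- den_x + w[t] * (x[t] - mx)^2
    den_y <- den_y + w[t] * (y[t] - my)^2
  }
  num / sqrt(den_x * den_y)
}

# Within/between network density via an explicit pair loop.
loop_network_density <- function(m, network) {
  n <- nrow(m)
  w_vals <- c()
  b_vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (network[i] == network[j]) w_vals <- c(w_vals, m[i, j])
      else b_vals <- c(b_vals, m[i, j])
    }
  }
  list(within = mean(w_vals), between = mean(b_vals))
}

# Newman weighted modularity of a given partition.
partition_modularity <- function(m, membership) {
  k <- rowSums(m)
  two_m <- sum(m)
  if (two_m == 0) return(0)
  q <- 0
  n <- nrow(m)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + m[i, j] - k[i] * k[j] / two_m
      }
    }
  }
  q / two_m
}

# All set partitions of 1..n (restricted-growth strings), for exhaustive
# modularity maximisation on small graphs.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxval) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxval + 1L)) {
      grow(c(prefix, v), max(maxval, v))
    }
  }
  grow(integer(0), 0L)
  out
}

# Exhaustive maximum-modularity partition.
exhaustive_max_modularity <- function(m) {
  best_q <- -Inf
  best_p <- NULL
  for (p in all_partitions(nrow(m))) {
    q <- partition_modularity(m, p)
    if (q > best_q) {
      best_q <- q
      best_p <- p
    }
  }
  list(Q = best_q, membership = best_p)
}

# Ordinary least squares via the normal equations.
normal_equations_beta <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Benjamini-Hochberg step-up rejections written from the definition.
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) / m * alpha)
  reject <- logical(m)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# A small scored trial table built by hand (no simulation), for scoring and
# modulator tests.
toy_scored_table <- function() {
  tr <- data.frame(
    subject = 1L, block = 1L, run = 1L, trial = 1:4,
    scene_id = 1L,
    target_color_deg = c(100, 200, 300, 40),
    target_scene_deg = c(10, 120, 250, 330),
    valence = c("negative", "neutral", "negative", "neutral"),
    onset_encoding_s = c(4, 11, 18, 25),
    onset_remember_s = c(66, 78, 90, 102)
  )
  tr$err_color_deg <- c(0, 30, -120, 57)
  tr$err_scene_deg <- c(15, -15, 31, 0)
  tr$resp_color_deg <- (tr$target_color_deg + tr$err_color_deg) %% 360
  tr$resp_scene_deg <- (tr$target_scene_deg + tr$err_scene_deg) %% 360
  tr$emotion_correct <- c(1L, 1L, 0L, 1L)
  tr$emotion_confidence <- c("high", "low", "low", "high")
  tr
}

# A reduced two-network design used by generator and connectivity tests.
tiny_design <- function(n_subjects = 1L, rois = c("ANG", "PREC", "PCC",
                                                  "PRC", "AMYG", "FUS")) {
  d <- study_design("small", n_subjects = n_subjects)
  d$roi_labels <- rois
  d$network_labels <- network_of(rois)
  d$n_rois <- length(rois)
  d
}
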