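#!/usr/bin/env Rscript
# Memory-modulated effective connectivity (gPPI). Model 1: remember events
# parametrically modulated by the composite 0-3 memory-quality score; the
# seed x modulator interaction gives an asymmetric seed -> target matrix per
# subject, summarized over the 3 x 3 directed network pairs and tested with
# one-tailed t tests under BH-FDR. Model 2: the five feature modulators
# (emotion, color/scene success, color/scene precision) enter one model, so
# each beta is the unique contribution of that feature. A univariate GLM
# checks which ROIs' mean activity tracks memory quality.

library(epiconn)

seed <- jsonlite::read_json("results/ground_truth.json")$seed
design <- study_design("full")
scores <- read.csv("results/scores.csv")
np <- neural_params(modulation_pairs = "hippocampal")

subjects <- sort(unique(scores$subject))
qual_cells <- NULL
overall <- numeric(0)
act <- NULL
prec_color <- prec_scene <- NULL
for (s in subjects) {
  sc <- scores[scores$subject == s, ]
  ts <- generate_timeseries(sc, np, design, scores = sc,
                            seed = subject_seed(seed, s, 3L))
  gq <- gppi_matrices(ts, sc, model = "quality")$quality
  ns <- network_summary(gq)
  qual_cells <- rbind(qual_cells,
                      setNames(ns$mean_beta,
                               paste0(ns$seed_network, "_to_",
                                      ns$target_network)))
  overall <- c(overall, mean(gq[!is.na(gq)]))
  gf <- gppi_matrices(ts, sc, model = "features")
  nc <- network_summary(gf$precision_color)
  nsn <- network_summary(gf$precision_scene)
  prec_color <- rbind(prec_color,
                      setNames(nc$mean_beta,
                               paste0(nc$seed_network, "_to_",
                                      nc$target_network)))
  prec_scene <- rbind(prec_scene,
                      setNames(nsn$mean_beta,
                               paste0(nsn$seed_network, "_to_",
                                      nsn$target_network)))
  act <- rbind(act, activity_glm(ts, sc))
}

ov <- group_ttest(overall, 0, "one")
cat(sprintf("Memory quality, all ROI pairs: mean beta %.3f, t(%d) = %.2f, p = %.2g\n",
            ov$mean, ov$df, ov$t, ov$p))

gi <- group_inference(qual_cells, tails = "one")
write.csv(gi, "results/gppi_network_group.csv", row.names = FALSE)
write.csv(as.data.frame(qual_cells), "results/gppi_network_subjects.csv",
          row.names = FALSE)
cat("Network-level quality modulation (one-tailed, BH-FDR):\n")
for (i in seq_len(nrow(gi))) {
  g <- gi[i, ]
  cat(sprintf("  %-14s mean %+.4f, t = %6.2f, p_fdr = %.3g%s\n",
              g$cell, g$mean, g$t, g$p_fdr,
              ifelse(g$sig_fdr, "  *", "")))
}

gic <- group_inference(prec_color, tails = "one")
gis <- group_inference(prec_scene, tails = "one")
write.csv(gic, "results/gppi_precision_color_group.csv", row.names = FALSE)
write.csv(gis, "results/gppi_precision_scene_group.csv", row.names = FALSE)
# pattern similarity between the two precision modulators' matrices; in
# this cohort a COMPOSITE quality coupling is planted, and both precision
# scores feed the quality score, so the two feature matrices inherit the
# same hippocampal pattern and similarity is positive by construction
sim <- sapply(seq_len(nrow(prec_color)), function(i) {
  atanh(min(1 - 1e-7, max(-1 + 1e-7, cor(prec_color[i, ], prec_scene[i, ]))))
})
st <- group_ttest(sim, 0, "two")
cat(sprintf("Color vs scene precision pattern similarity: mean z %.3f, t(%d) = %.2f, p = %.2f\n",
            st$mean, st$df, st$t, st$p))
cat("(positive by construction here: the planted coupling is the shared\n")
cat(" composite quality score, which both feature precisions feed)\n")

# dissociation scenario: disjoint feature-specific couplings -- scene
# precision within PM, color precision AT -> hippocampus; the two beta
# matrices should then be uncorrelated within subject while each planted
# effect is recovered in its own matrix
cat("Dissociation scenario (disjoint planted feature couplings):\n")
np_feat <- neural_params(modulation_pairs = data.frame(
  seed      = c("RSC", "PHC", "PRC", "AMYG"),
  target    = c("PREC", "ANG", "aHIPP", "aHIPP"),
  beta      = 0.4,
  modulator = c("precision_scene", "precision_scene",
                "precision_color", "precision_color")
))
sim_d <- pc_d <- ps_d <- numeric(length(subjects))
for (i in seq_along(subjects)) {
  sc <- scores[scores$subject == subjects[i], ]
  ts <- generate_timeseries(sc, np_feat, design, scores = sc,
                            seed = subject_seed(seed, subjects[i], 5L))
  gf <- gppi_matrices(ts, sc, "features")
  a <- gf$precision_color
  b <- gf$precision_scene
  keep <- !is.na(a) & !is.na(b)
  sim_d[i] <- atanh(cor(a[keep], b[keep]))
  pc_d[i] <- a["PRC", "aHIPP"]
  ps_d[i] <- b["RSC", "PREC"]
}
std <- group_ttest(sim_d, 0, "two")
cat(sprintf("  pattern similarity: mean z %+.3f, t(%d) = %.2f, p = %.2f\n",
            std$mean, std$df, std$t, std$p))
cat(sprintf("  recovered couplings: color PRC->aHIPP %.2f, scene RSC->PREC %.2f (planted 0.4)\n",
            mean(pc_d), mean(ps_d)))
write.csv(data.frame(subject = subjects, similarity_z = sim_d,
                     color_PRC_aHIPP = pc_d, scene_RSC_PREC = ps_d),
          "results/gppi_dissociation.csv", row.names = FALSE)

ai <- group_inference(act, tails = "one")
write.csv(ai, "results/activity_group.csv", row.names = FALSE)
cat("ROI activity tracking memory quality (FDR-significant):",
    paste(ai$cell[ai$sig_fdr], collapse = ", "), "\n")
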