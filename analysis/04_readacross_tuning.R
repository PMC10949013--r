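#!/usr/bin/env Rscript
# Tune the read-across hyperparameters on the damage training set
# (sub-training / sub-test split) and evaluate the tuned configurations
# on the held-out test set, per method (ED / GK / LK).

suppressMessages(library(nanoqspr))
seed <- if (length(a <- commandArgs(TRUE)) >= 1) as.integer(a[1]) else 1L

t2 <- impute_zeta(published_model("model1"),
                  descriptor_table(read.csv("results/data/dataset2_synthetic.csv")))
feats <- c("sum_chi_per_nO", "sq_sum_epsilon_N", "d1_metal", "metal_alpha",
           "time_h", "zeta_mv", "electrons_active_m", "valence")
tr <- t2[t2$set_label == "train", ]
te <- t2[t2$set_label == "test", ]

grid <- expand.grid(sigma = c(0.5, 1, 1.75, 3),
                    gamma = c(0.5, 1, 1.75, 3),
                    distance_threshold = c(1, 2.5, 5),
                    similarity_threshold = 0,
                    n_neighbors = c(5, 10))
best <- optimize_hyperparams(tr, "damage", feats, grid, seed = seed)

rows <- lapply(names(best), function(m) {
  cfg <- best[[m]]$config
  pr <- ra_predict(te, tr, "damage", feats, cfg)
  data.frame(method = m, sigma = cfg$sigma, gamma = cfg$gamma,
             distance_threshold = cfg$distance_threshold,
             similarity_threshold = cfg$similarity_threshold,
             n_neighbors = cfg$n_neighbors,
             q2f1_subtest = best[[m]]$q2f1,
             q2f1_test = q2_f1(te$damage, pr$predictions, mean(tr$damage)),
             q2f2_test = q2_f2(te$damage, pr$predictions),
             mae_test = mae(te$damage, pr$predictions),
             rmsep_test = rmsep(te$damage, pr$predictions),
             n_fallback = sum(pr$fallback))
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/readacross_tuning.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)
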