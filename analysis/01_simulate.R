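#!/usr/bin/env Rscript
# Generate the synthetic analogues of the two study tables: dataset I
# (18 oxides with zeta potential, mV) and dataset II (oxide x dose x
# exposure-time design, 132 rows, cell-damage response). Writes both
# under results/data/.

suppressMessages(library(nanoqspr))
seed <- if (length(a <- commandArgs(TRUE)) >= 1) as.integer(a[1]) else 1L

spec <- synth_spec()
d1 <- generate_dataset1(spec, seed)
d2 <- generate_dataset2(spec, seed + 1000L)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write.csv(d1, "results/data/dataset1_synthetic.csv", row.names = FALSE)
write.csv(d2, "results/data/dataset2_synthetic.csv", row.names = FALSE)

cat(sprintf("dataset I:  %d oxides (%d train / %d test), zeta %0.1f..%0.1f mV\n",
            nrow(d1), sum(d1$set_label == "train"), sum(d1$set_label == "test"),
            min(d1$zeta_mv), max(d1$zeta_mv)))
cat(sprintf("dataset II: %d rows over %d oxides, doses {%s} ug/mL, times 1-7 h\n",
            nrow(d2), length(unique(d2$formula)),
            paste(sort(unique(d2$dose_ug_ml)), collapse = ",")))
cat(sprintf("            damage %0.2f..%0.2f (%d train / %d test)\n",
            min(d2$damage), max(d2$damage),
            sum(d2$set_label == "train"), sum(d2$set_label == "test")))
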