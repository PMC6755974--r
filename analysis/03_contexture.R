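#!/usr/bin/env Rscript
# Stage 3 -- immune-contexture statistics.
#
# Mean-centers the per-patient immune features within stain batches, compares
# ALL against controls feature by feature (Mann-Whitney U with
# Benjamini-Hochberg control), reports the significant log2 median ratios,
# clusters features and patients (Spearman distance, ward.D2), and correlates
# every feature against the CD4+PD1+TIM3+ anchor.

library(immunotma)

out <- "results/analysis"
profiles <- read.csv(file.path(out, "patient_profiles.csv"))
subjects <- read.csv(file.path(out, "subjects.csv"))

feats <- setdiff(names(profiles), c("patient_id", "batch", "n_spots"))
fm <- as.matrix(profiles[feats])
rownames(fm) <- profiles$patient_id
fm_centered <- suppressWarnings(mean_center_batches(fm, profiles$batch))
grp <- subjects$group[match(profiles$patient_id, subjects$patient_id)]

comparison <- compare_groups(fm_centered, grp, levels = c("ALL", "control"),
                             ratio_data = fm)
write.csv(comparison, file.path(out, "contexture_comparison.csv"),
          row.names = FALSE)
ratios <- log2_ratio_table(comparison)
write.csv(ratios, file.path(out, "log2_ratios.csv"), row.names = FALSE)

usable <- apply(fm_centered, 2, function(v)
  sum(!is.na(v)) >= 3 && sd(v, na.rm = TRUE) > 0)
cl <- hierarchical_cluster(t(fm_centered[, usable, drop = FALSE]))
write.csv(data.frame(feature = colnames(fm_centered)[usable][cl$row_order]),
          file.path(out, "feature_cluster_order.csv"), row.names = FALSE)

anchor <- correlate_markers(fm[, usable, drop = FALSE], "CD4_PD1_TIM3")
write.csv(anchor, file.path(out, "anchor_correlations.csv"),
          row.names = FALSE)

message(sum(comparison$significant), " of ", nrow(comparison),
        " features differ between ALL and control at q < 0.05; ",
        "largest |log2 ratio| ",
        if (nrow(ratios)) round(max(abs(ratios$log2_ratio), na.rm = TRUE), 2)
        else NA)
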