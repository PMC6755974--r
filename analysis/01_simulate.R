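#!/usr/bin/env Rscript
# Stage 1 -- simulate the study inputs.
#
# Generates (a) an ALL cohort with planted hazard structure on age, platelet
# count and the CD4+PD1+TIM3+ exhausted T-cell fraction, plus healthy
# controls, and (b) duplicate mIHC TMA spot images per subject, each with a
# planted inter-round shift, written as multi-page TIFFs with JSON sidecars.
# Everything downstream is recomputable from the files written here.

library(immunotma)

out <- "results/analysis"
spot_dir <- "scratch/analysis_spots"   # image scratch; tables go to results/
dir.create(out, recursive = TRUE, showWarnings = FALSE)
dir.create(spot_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

n_patients <- 48L; n_controls <- 10L; spots_per <- 2L
cells_per_spot <- 300L; canvas <- 384L; noise_sd <- 0.03

cohort <- generate_cohort(cohort_spec(n = n_patients, censor_rate = 0.2,
                                      seed = seed))
write.csv(cohort$covariates, file.path(out, "covariates.csv"),
          row.names = FALSE)
write.csv(cohort$survival, file.path(out, "survival.csv"), row.names = FALSE)
write.csv(cohort$mrd, file.path(out, "mrd.csv"), row.names = FALSE)

set.seed(immunotma:::substream_seed(seed, "controls"))
ctrl_pd1tim3 <- rgamma(n_controls, shape = 0.3, scale = 0.12)

subjects <- data.frame(
  patient_id = c(cohort$covariates$patient_id,
                 sprintf("C%04d", seq_len(n_controls))),
  group = rep(c("ALL", "control"), c(n_patients, n_controls)),
  pd1tim3 = c(cohort$covariates$cd4_pd1_tim3, ctrl_pd1tim3),
  batch = rep_len(c("batch1", "batch2"), n_patients + n_controls))
write.csv(subjects, file.path(out, "subjects.csv"), row.names = FALSE)

props <- immunotma:::patient_proportions
for (i in seq_len(nrow(subjects))) {
  for (s in seq_len(spots_per)) {
    sseed <- immunotma:::substream_seed(
      seed, paste0("spot_", subjects$patient_id[i], "_", s))
    set.seed(sseed)
    shift <- sample(seq(-12, 12, by = 4), 2)
    spec <- spot_spec(canvas = canvas, n_cells = cells_per_spot,
                      proportions = props(subjects$pd1tim3[i],
                                          subjects$group[i] == "control"),
                      noise_sd = noise_sd, shift = shift, seed = sseed)
    spot <- generate_tma_spot(spec)
    write_spot_images(spot, file.path(spot_dir,
                                      paste0(subjects$patient_id[i],
                                             "_spot", s)))
  }
}

message("simulated ", nrow(subjects), " subjects (",
        n_patients, " ALL + ", n_controls, " controls); tables -> ", out,
        "; ", nrow(subjects) * spots_per, " TMA spot images -> ", spot_dir)
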