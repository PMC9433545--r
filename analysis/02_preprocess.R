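#!/usr/bin/env Rscript
# Stage 2: time-series cleaning. Discard 10 volumes, linear detrend, ideal
# 0.01-0.1 Hz band-pass, FD scrubbing (> 0.5 mm, window t-1..t+2) with
# linear interpolation, Friston-24 nuisance regression; subjects with mean
# FD > 0.3 mm are excluded. QC table to results/, cleaned series to scratch/.

library(adhdnet)

cohort <- read_cohort("scratch/cohort")
cfg <- preprocess_config()
dir.create("scratch/clean", recursive = TRUE, showWarnings = FALSE)

qc <- do.call(rbind, lapply(cohort$subjects, function(s) {
  pp <- preprocess_subject(s$timeseries, s$motion, cfg)
  if (pp$qc$keep) {
    saveRDS(pp$timeseries, file.path("scratch/clean",
                                     paste0(s$subject_id, ".rds")))
  }
  data.frame(subject_id = s$subject_id, group = s$group,
             mean_fd = pp$qc$mean_fd, n_censored = pp$qc$n_censored,
             keep = pp$qc$keep)
}))
write.table(qc, "results/02_qc.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

message(sprintf("kept %d of %d subjects (mean FD range %.3f-%.3f mm, %d censored volumes median)",
                sum(qc$keep), nrow(qc), min(qc$mean_fd), max(qc$mean_fd),
                median(qc$n_censored)))
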