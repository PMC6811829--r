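#!/usr/bin/env Rscript

# Build the synthetic study: one rendered imaging session (the pixel-level
# fixture) and trace-level population sessions for the three treatment
# conditions plus the top-down axon condition. Writes session metadata,
# stimulus logs, locomotion traces and timelines under results/sessions/.

suppressPackageStartupMessages(library(capipe))
out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 1L

message("Rendering the 20-cell imaging session ...")
img <- standard_imaging_session(rng_seed = 42L)
write_locomotion_csv(img$locomotion, file.path(out_dir, "imaging_locomotion.csv"))
write_timeline_csv(img$timeline, file.path(out_dir, "imaging_timeline.csv"))
write_rois_json(lapply(seq_along(img$masks), function(i) {
  structure(list(id = i, pixels = img$masks[[i]], kind = "soma",
                 cell_type = img$cells[[i]]$cell_type, quality = NA_real_),
            class = "roi_mask")
}), img$config$field_px, file.path(out_dir, "imaging_truth_rois.json"))
message("  ", length(img$cells), " cells, ",
        img$timeline$n_frames, " frames, field ",
        paste(img$config$field_px, collapse = "x"))

conds <- data.frame(
  name = c("saline", "mk801", "mk801_muscimol", "axons_mk801"),
  treatment = c("saline", "mk801", "mk801_muscimol", "mk801"),
  gain = c(NA, NA, NA, 3.0))
summaries <- list()
for (i in seq_len(nrow(conds))) {
  g <- if (is.na(conds$gain[i])) NULL else conds$gain[i]
  ses <- standard_population_session(conds$treatment[i], drug_gain = g,
                                     rng_seed = seed + i)
  message("Simulated ", conds$name[i], " session: gain ",
          ses$config$drug_gain, ", ", ncol(ses$traces), " cells")
  if (i == 1L) {
    ev <- standard_evoked_session("saline", rng_seed = seed + 10L)
    write_stim_log_csv(ev$stim_log, file.path(out_dir, "evoked_stim_log.csv"))
  }
  summaries[[conds$name[i]]] <- list(
    treatment = ses$config$treatment, drug_gain = ses$config$drug_gain,
    n_cells = ncol(ses$traces), n_frames = ses$timeline$n_frames,
    seed = ses$config$rng_seed, config_hash = hash_config(ses$config))
}
jsonlite::write_json(summaries, file.path(out_dir, "population_sessions.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("Session metadata written to ", out_dir)
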