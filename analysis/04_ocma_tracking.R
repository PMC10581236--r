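#!/usr/bin/env Rscript
# Label-free angiography: perfusion maps by high-pass temporal filtering,
# background-normalised stallograms, and longitudinal tracking of 15
# occluded vessels across pre/0h/2h/4h/24h. Writes
# results/stallogram_trace.csv and results/tracking_summary.csv.

suppressMessages(library(capstall))
dir.create("results", showWarnings = FALSE)
seed <- 1L
labels <- c("pre", "0h", "2h", "4h", "24h")

# single-vessel stallogram across the insult
spec <- angio_spec(volume_shape = c(40, 40), voxel_size = 2,
                   vessel_segments = list(
                     list(a = c(5, 5), b = c(35, 35), radius_um = 3,
                          perfused = TRUE)),
                   frames_per_timepoint = 16, dynamic_contrast = 0.5,
                   noise_sd = 0.05, seed = seed)
sched <- matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE), 5, 1)
series <- generate_angio_timeseries(spec, labels, schedule = sched)
angios <- lapply(series, compute_angiogram)
vroi <- attr(series, "mask")
tr <- stallogram(angios, vroi, !vroi, times = c(-600, 0, 7200, 14400, 86400))
cat("stallogram (normalized vessel intensity; 1 = background):\n")
print(tr)
utils::write.csv(tr, "results/stallogram_trace.csv", row.names = FALSE)

# 15 tracked vessels, blocked at 0-4 h, re-perfused at 24 h
recovered <- vapply(1:15, function(v) {
  sp_v <- angio_spec(volume_shape = c(32, 32), voxel_size = 2,
                     vessel_segments = list(
                       list(a = c(5, 5), b = c(28, 28), radius_um = 3,
                            perfused = TRUE)),
                     frames_per_timepoint = 12, dynamic_contrast = 0.5,
                     noise_sd = 0.05, seed = seed + 10L + v)
  s_v <- generate_angio_timeseries(sp_v, labels, schedule = sched)
  a_v <- lapply(s_v, compute_angiogram)
  m_v <- attr(s_v, "mask")
  identical(track_insult(a_v, m_v, !m_v)$recovered_at, "24h")
}, logical(1))
cat(sprintf("vessels recovered at 24 h: %d / 15\n", sum(recovered)))
utils::write.csv(data.frame(quantity = "vessels_recovered_24h",
                            value = sum(recovered), n = 15),
                 "results/tracking_summary.csv", row.names = FALSE)
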