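#!/usr/bin/env Rscript
# Stage 1: design the photoreceptor-directed stimuli on the synthetic
# multiprimary device.
#
# Designs (a) the melanopsin-directed background pair delivering a nominal
# 350% melanopic Weber contrast with the L, M and S cones silenced, (b) the
# cone-directed (Weber positive control) background pair, and (c) the +/-5%
# LMS flicker arms on each melanopic background. Writes the spectra and a
# design report under results/design/.

library(melflick)

out <- "results/design"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sens <- default_sensitivities()
device <- make_synthetic_device(seed = 1)

pair <- solve_background_pair(device, sens, target_contrast = 3.5)
ctrl <- solve_background_pair(device, sens, target_contrast = 3.5,
                              direction = "LMS")
spec_low <- solve_flicker_modulation(device, sens, pair$low_settings)
spec_high <- solve_flicker_modulation(device, sens, pair$high_settings)

write_sensitivities_csv(sens, file.path(out, "sensitivities.csv"))
write_spectrum_csv(device_spectrum(device, pair$low_settings),
                   file.path(out, "background_low_mel.csv"))
write_spectrum_csv(device_spectrum(device, pair$high_settings),
                   file.path(out, "background_high_mel.csv"))
write_spectrum_csv(device_spectrum(device, spec_low$positive_arm_settings),
                   file.path(out, "flicker_pos_low_mel.csv"))
write_spectrum_csv(device_spectrum(device, spec_high$positive_arm_settings),
                   file.path(out, "flicker_pos_high_mel.csv"))

e_lo <- excitation(device_spectrum(device, pair$low_settings), sens)
e_hi <- excitation(device_spectrum(device, pair$high_settings), sens)

report <- c(
  "Stimulus design report (synthetic 8-primary device, seed 1)",
  sprintf("Melanopic pair: Mel Weber contrast %.6f (target 3.5) -> excitation ratio %.4f",
          pair$achieved_contrasts[["Mel"]], e_hi[["Mel"]] / e_lo[["Mel"]]),
  sprintf("  residual cone contrasts: L %.2e, M %.2e, S %.2e",
          pair$achieved_contrasts[["L"]], pair$achieved_contrasts[["M"]],
          pair$achieved_contrasts[["S"]]),
  sprintf("Cone-directed control pair: LMS contrast %.4f; residual Mel %.2e",
          ctrl$achieved_contrasts[["L"]], ctrl$achieved_contrasts[["Mel"]]),
  sprintf("Flicker arms (low bg): per-cone contrast %.6f, Mel residual %.2e",
          spec_low$achieved_contrasts[["L"]],
          spec_low$achieved_contrasts[["Mel"]]),
  sprintf("Flicker arms (high bg): per-cone contrast %.6f, Mel residual %.2e",
          spec_high$achieved_contrasts[["L"]],
          spec_high$achieved_contrasts[["Mel"]]))
writeLines(report, file.path(out, "design_report.txt"))
writeLines(report)
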