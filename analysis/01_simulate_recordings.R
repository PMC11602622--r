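#!/usr/bin/env Rscript
# Generate the synthetic study data used by the downstream analysis steps:
# single-wavelength (fly-style GCaMP) traces with blank recordings, and a
# dual-wavelength (bee-style Fura-2) ratiometric stack with ROIs. Ground
# truth is written alongside so every later step can be checked.
#
# Tables go to results/; binary image stacks go to scratch/.

suppressMessages(library(calcitune))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
set.seed(1)

message("-- fly-style single-wavelength recordings (log photobleaching) --")
cfg_fly <- sim_config(preset = "fly", bleach = list(model = "log", a = 1, b = -0.01),
                      noise_sd = 0.5, seed = 11L)
planted <- c(0.005, 0.01, 0.02, 0.05)   # 0.5-5% dF/F0, screen-like range
traces <- lapply(seq_along(planted), function(i)
  simulate_trace(cfg_fly, planted[i], replicate = i))
blank <- simulate_trace(cfg_fly, 0, replicate = 99L)

long <- do.call(rbind, c(
  lapply(seq_along(traces), function(i)
    data.frame(animal = paste0("fly", i), stimulus = sprintf("amp_%g", planted[i]),
               frame = seq_len(cfg_fly$n_frames), value = traces[[i]]$trace$values)),
  list(data.frame(animal = "fly_blank", stimulus = "blank",
                  frame = seq_len(cfg_fly$n_frames), value = blank$trace$values))))
write_table_csv(long, "results/01_fly_traces.csv")
write_table_csv(data.frame(stimulus = sprintf("amp_%g", planted),
                           true_amplitude = planted),
                "results/01_fly_ground_truth.csv")

message("-- bee-style ratiometric stack (two wavelengths, shared bleach) --")
cfg_bee <- sim_config(preset = "bee", bleach = list(model = "log", a = 1, b = -0.01),
                      noise_sd = 2, seed = 12L)
rois <- roi_set(list(MG2   = cbind(x = c(3, 12, 12, 3),  y = c(3, 3, 12, 12)),
                     MG1   = cbind(x = c(18, 27, 27, 18), y = c(3, 3, 12, 12)),
                     bgGlo = cbind(x = c(3, 12, 12, 3),  y = c(18, 18, 27, 27))))
amps <- c(MG2 = 0.0101, MG1 = 0.002, bgGlo = 0)  # strong MG2, weak MG1, silent
sim <- simulate_ratiometric_stack(cfg_bee, rois, amps, image_dim = c(32L, 32L))
write_stack(sim$f340, "scratch/01_bee_340.tif")
write_stack(sim$f380, "scratch/01_bee_380.tif")
write_rois(rois, "results/01_bee_rois.json")
write_protocol(cfg_bee$protocol, "results/01_bee_protocol.yaml")
write_table_csv(data.frame(roi = names(amps), true_delta_r_over_r = unname(amps)),
                "results/01_bee_ground_truth.csv")

message("wrote results/01_* tables and scratch/01_bee_{340,380}.tif")
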