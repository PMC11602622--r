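#!/usr/bin/env Rscript
# Tuning-breadth analysis of a simulated four-receptor deorphanization screen
# over a 22-odorant panel (plus solvent): per-receptor lifetime sparseness,
# Friedman + Dunn tests against solvent, min-max normalized spectra, and a
# UPGMA dendrogram of the response patterns.
#
# The planted spectra mimic the qualitative receptor phenotypes of the OR11
# orthologs: one strongly 9-ODA-specialist receptor, two receptors with a
# few weak secondary ligands, one broader receptor.

suppressMessages(library(calcitune))
dir.create("results", showWarnings = FALSE)

odorants <- c("9-ODA", "t2-hexenoic", "2-oxovaleric", "6m5h-2-one",
              "heptanoic", "propionic", "t2-hexenal", "2-oxooctanoic",
              "t3-hexenoic", paste0("odor", 10:22))
spectra <- rbind(
  AcerOR11  = c(1.8, 0.45, 0.35, 0.30, rep(0, 18)),
  AdorOR11  = c(2.2, 0.50, 0.40, 0.35, 0.30, 0.25, 0.30, 0.25, rep(0, 14)),
  AmelOR11  = c(2.0, 0.40, 0.30, rep(0, 19)),
  AflorOR11 = c(1.2, rep(0, 21)))
colnames(spectra) <- odorants

pan <- simulate_response_panel(spectra, noise_sd = 0.12, n_animals = 12,
                               seed = 33L)
write_table_csv(pan$responses, "results/03_panel_responses.csv")
means <- response_spectra(pan$responses)

message("-- lifetime sparseness per receptor (controls included) --")
sp_tab <- do.call(rbind, lapply(rownames(means), function(r) {
  s <- sparseness(means[r, ])
  data.frame(receptor = r, S = round(s$S, 3), n_stimuli = s$n,
             negatives_clamped = s$n_clamped)
}))
print(sp_tab)
write_table_csv(sp_tab, "results/03_sparseness.csv")

message("-- Friedman + Dunn vs solvent, per receptor --")
fr_tab <- do.call(rbind, lapply(rownames(means), function(r) {
  sub <- pan$responses[pan$responses$receptor == r, ]
  m <- t(vapply(split(sub, sub$animal),
                function(d) d$amplitude[match(colnames(means), d$stimulus)],
                numeric(ncol(means))))
  colnames(m) <- colnames(means)
  res <- friedman_with_dunn(m, control = "solvent")
  ph <- res$posthoc
  data.frame(receptor = r, chi_sq = res$statistic, p = res$p,
             n_sig_vs_solvent = sum(ph$p_adj < 0.05))
}))
print(fr_tab, digits = 3)
write_table_csv(fr_tab, "results/03_friedman.csv")

message("-- normalized spectra (9-ODA = 100%, solvent = 0%) and clustering --")
norm <- t(apply(means, 1, function(r)
  normalize_spectrum(r, "9-ODA", "solvent", clip = TRUE)))
write_table_csv(data.frame(receptor = rownames(norm), norm, check.names = FALSE),
                "results/03_normalized_spectra.csv")

dres <- cluster_receptors(norm)
print(dres)
write_dendrogram_newick(dres, "results/03_dendrogram.nwk")
fs <- first_split(dres)
message("first split: {", paste(fs[[1]], collapse = ", "), "} vs {",
        paste(fs[[2]], collapse = ", "), "}")
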