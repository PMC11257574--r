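#!/usr/bin/env Rscript
# Generate the synthetic inputs for the downstream analyses and write
# them through the same on-disk formats the readers consume (PDB/mmCIF,
# PAE JSON, TIFF stacks, FRAP CSV), each next to its ground truth.

suppressMessages(library(septexo))
seed <- 1L
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# A pairwise model with six planted interface contacts, in both formats
pm <- make_pair_model(n_res_a = 30, n_res_b = 30, n_planted_contacts = 6,
                      seed = seed)
write_structure(pm$model, file.path(out, "pair.pdb"))
write_structure(pm$model, file.path(out, "pair.cif"))
jsonlite::write_json(pm$truth[c("planted", "seed")],
                     file.path(out, "pair.truth.json"),
                     auto_unbox = TRUE, digits = NA)

# Its PAE matrix (low error on planted contact blocks) in both dialects
n <- 60
pae <- matrix(15, n, n)
idx <- pm$truth$planted
pae[cbind(idx$res_a, 30 + idx$res_b)] <- 2
pae[cbind(30 + idx$res_b, idx$res_a)] <- 2
diag(pae) <- 0
write_pae(pae, file.path(out, "pair_pae_colabfold.json"), "colabfold")
write_pae(pae, file.path(out, "pair_pae_af3.json"), "af3",
          chain_ids = rep(c("A", "B"), each = 30))

# An assembled complex with labelled buried/exposed residues
cx <- make_complex_model(n_chains = 4, residues_per_chain = 10,
                         buried_fraction = 0.3, seed = seed)
write_structure(cx$model, file.path(out, "complex.pdb"))
utils::write.csv(cx$truth, file.path(out, "complex.truth.csv"),
                 row.names = FALSE)

# Division-plane stacks: rim ring and centre disk, Poisson noise
for (pat in c("ring", "disk")) {
  st <- make_division_stack(pat, poisson_noise = TRUE, seed = seed)
  write_stack(st$stack, file.path(out, paste0(pat, ".tif")))
}

# FRAP traces for both acquisition designs (0.33 s / 150 frames and
# 10 s / 70 frames), with acquisition bleaching, background and noise
for (d in list(list(name = "fast", dt = 0.33, n_post = 150L),
               list(name = "slow", dt = 10, n_post = 70L))) {
  tr <- make_frap_trace(m1 = 100, m2 = -100, m3 = 0.05, dt = d$dt,
                        n_post = d$n_post, acquisition_bleach_rate = 0.002,
                        background_level = 20, noise_sd = 2, seed = seed)
  write_frap_trace(tr$trace, file.path(out, paste0("frap_", d$name, ".csv")))
  jsonlite::write_json(tr$truth[c("m1", "m2", "m3", "t_half", "seed")],
                       file.path(out, paste0("frap_", d$name, ".truth.json")),
                       auto_unbox = TRUE, digits = NA)
}

cat("wrote synthetic fixtures to", out, "\n")
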