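#!/usr/bin/env Rscript

## Stage 1: generate the synthetic lambda-trajectory panel used by the
## downstream stages.  Five archetypes of acidic-residue behaviour, each
## simulated over pH 1-8 with the full 3-monomer x 3-replica hierarchy:
##   - solvent_exposed : ordinary titration near the model pKa (3.6)
##   - constriction    : strongly down-shifted pKa (1.5)
##   - locked_charged  : deprotonated throughout the scan (pKa 0.5 -> "< 1")
##   - locked_neutral  : protonated throughout the scan (pKa 10 -> "> 8")
##   - two_state       : slow exchange between conformers with pKa 2.5/4.5,
##                       the microstate-heterogeneity archetype
suppressPackageStartupMessages(library(phtitr))

out_dir <- "results/sim_panel"

models <- list(
  solvent_exposed = titration_model(3.6),
  constriction    = titration_model(1.5),
  locked_charged  = titration_model(0.5),
  locked_neutral  = titration_model(10),
  two_state       = titration_model(c(2.5, 4.5), exchange_time = 50))

spec <- panel_spec(models, pH_grid = 1:8, n_monomers = 3, n_replicas = 3,
                   duration = 50, seed = 20)
man <- generate_dataset(spec, out_dir, overwrite = TRUE)

cat(sprintf("wrote %d trajectories (%d residues x %d monomers x %d replicas x %d pH) to %s\n",
            nrow(man$entries), length(models), spec$n_monomers,
            spec$n_replicas, length(spec$pH_grid), out_dir))
cat("manifest:", file.path(out_dir, "manifest.json"), "\n")
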