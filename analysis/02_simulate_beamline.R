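#!/usr/bin/env Rscript
# Step 2 - forward simulation of the fibre imager. Generates per-fibre
# absorbance traces for the degraded proton beam at 2 nA, twice (replicate
# acquisitions, as on the beamline), from a ground truth in which the
# ferric yield falls from 15 to 5 molecules/100 eV as the local energy
# loss rises towards the Bragg peak. Detector noise, ferric diffusion and
# the saturating dose response are all on.

suppressPackageStartupMessages(library(braggfricke))
dir.create("results", showWarnings = FALSE)

seed <- 20260927L
dp <- read_elf("results/elf_proton.tsv")
beam <- beam_spec(projectile("proton"), 64, 0.3, current = 2e-9)
dp$beam <- beam
dp$stack <- material_stack(list(
  list(material = bf_material("pmma"), thickness = 23.57),
  list(material = bf_material("super_fricke"), thickness = 10)
), sample = 2)

fa <- fibre_array()
acq <- acquisition_spec(duration = 20, beam_on_time = 2)

# LET-dependent truth: yield drops where the energy loss is high
G_molec <- 15 - 10 * dp$elf / max(dp$elf)
gt <- ground_truth(dp, beam, convert_yield(G_molec, "molec_100eV", "mol_J"))

for (rep in 1:2) {
  rec <- simulate_acquisition(gt, fa, acq, seed = seed + rep)
  write_traces(rec, sprintf("results/traces_proton_2nA_rep%d.tsv", rep))
}
truth <- fibre_average(dp$depth, G_molec * dp$elf, fa)
truth$value <- truth$value / fibre_average(dp$depth, dp$elf, fa)$value
names(truth)[names(truth) == "value"] <- "G_molec_100eV_truth"
write.table(truth, "results/truth_proton.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

write_manifest("results/simulation_manifest.json",
               config = list(beam = "proton 64 MeV + 23.57 mm PMMA",
                             current_nA = 2, duration_s = 20,
                             beam_on_s = 2, replicates = 2),
               seed = seed,
               files = c("results/traces_proton_2nA_rep1.tsv",
                         "results/traces_proton_2nA_rep2.tsv"))

rec <- read_traces("results/traces_proton_2nA_rep1.tsv", beam_on_time = 2)
early <- rec[rec$time_s > 2 & rec$time_s <= 3, ]  # the slope-fit window
cat("== synthetic acquisition ==\n")
cat(sprintf("  2 replicates, 20 fibres x %d frames, seed %d\n",
            length(unique(rec$time_s)), seed))
cat(sprintf("  absorbance after 1 s of beam: %.2f on fibre %d (steepest)\n",
            max(early$absorbance), early$fibre[which.max(early$absorbance)]))
cat("written: results/traces_proton_2nA_rep{1,2}.tsv, results/truth_proton.tsv\n")
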