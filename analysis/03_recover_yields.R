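#!/usr/bin/env Rscript
# Step 3 - inverse analysis. Runs the yield pipeline on the simulated
# replicate traces: beam-on detection, per-fibre initial slopes (r2-scan
# compromise rule), Bragg-peak localisation, fibre-binned ELF, per-fibre
# G(Fe3+) with shift-based uncertainty bands; then compares against the
# simulation ground truth.

suppressPackageStartupMessages(library(braggfricke))

dp <- read_elf("results/elf_proton.tsv")
beam <- beam_spec(projectile("proton"), 64, 0.3, current = 2e-9)
fa <- fibre_array()

reps <- lapply(1:2, function(r)
  read_traces(sprintf("results/traces_proton_2nA_rep%d.tsv", r),
              beam_on_time = 2))

res <- recover_yields(reps, dp, beam, fa, scan = TRUE, align = FALSE)
write_yields(res$yields, "results/yields_proton.tsv")

truth <- read.table("results/truth_proton.tsv", header = TRUE, sep = "\t")

cat("== inverse pipeline ==\n")
cat(sprintf("  beam-on detected at t0 = %.1f s\n", res$t0))
cat(sprintf("  absorption maximum (steepest slope) on fibre %d (depth %.2f mm)\n",
            res$bp$fibre, res$bp$depth_mm))
cat("  (with this LET-dependent truth the absorption maximum sits slightly\n")
cat("   proximal of the energy-loss maximum; the ELF is binned on its own\n")
cat("   calibrated axis)\n")

y <- res$yields
ok <- !is.na(y$G_molec_100eV)
m <- merge(y[ok, ], truth, by = "fibre")
m <- m[order(-m$fibre), ]
cat(sprintf("  reported fibres: %d (ELF floor %.0f%% of max)\n",
            sum(ok), 100 * 0.01))
cat(sprintf("  G at entrance fibres (18-20): %.1f molecules/100 eV\n",
            mean(m$G_molec_100eV[m$fibre >= 18])))
imin <- which.min(m$G_molec_100eV)
cat(sprintf("  minimum G = %.2f molecules/100 eV on fibre %d (truth %.2f)\n",
            m$G_molec_100eV[imin], m$fibre[imin],
            m$G_molec_100eV_truth[imin]))
post <- m[m$fibre < m$fibre[which.max(m$elf)] &
            m$elf >= 0.1 * max(m$elf), ]
if (nrow(post) > 1 && all(diff(post$G_molec_100eV) > 0)) {
  cat(sprintf(
    "  post-peak yield recovery: G rises to %.1f over %d fibres (%.2f mm)\n",
    max(post$G_molec_100eV), nrow(post), nrow(post) * fa$width_mm))
}
sel <- m$elf >= 0.1 * max(m$elf)
err <- abs(m$G_molec_100eV - m$G_molec_100eV_truth) / m$G_molec_100eV_truth
cat(sprintf("  worst deviation from truth on ELF>=10%% fibres: %.1f%%\n",
            100 * max(err[sel])))
covered <- m$G_molec_100eV_truth >= m$band_lo / 1.036e-7 &
  m$G_molec_100eV_truth <= m$band_hi / 1.036e-7
cat(sprintf("  shift-band coverage of truth: %d / %d fibres\n",
            sum(covered[sel]), sum(sel)))
cat("written: results/yields_proton.tsv\n")
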