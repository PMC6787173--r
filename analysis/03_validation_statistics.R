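#!/usr/bin/env Rscript
# Validation-arm computations on simulated assay tables calibrated to the
# screen's validated-hit scenario: repeated-measures ANOVA with
# Greenhouse-Geisser correction and Dunnett post-hoc vs NT, qPCR 2^(-dCT),
# dual-luciferase normalization and gentamicin-protection CFU/ml.

suppressPackageStartupMessages(library(phagoscreen))
dir.create("results", showWarnings = FALSE)
set.seed(20260920L)

## Repeated-measures validation of the % FITC+ readout across 6 independent
## experiments: NT ~30%, miR hit ~14%, CytoD ~7% with a shared per-experiment
## level (transfection batches differ far more than wells within a batch).
n_exp <- 6
batch <- rnorm(n_exp, 0, 6)
m <- cbind(
  NT = pmax(1, 30.1 + batch + rnorm(n_exp, 0, 4)),
  `miR-124-5p` = pmax(1, 13.9 + batch + rnorm(n_exp, 0, 4)),
  CytoD = pmax(1, 7.4 + batch + rnorm(n_exp, 0, 2))
)
rm_res <- rm_anova_gg(m)
dn_res <- dunnett_rm(m, control = "NT")
utils::write.csv(cbind(experiment = seq_len(n_exp), as.data.frame(m)),
                 "results/validation_rm_table.csv", row.names = FALSE)
utils::write.csv(dn_res, "results/validation_dunnett.csv", row.names = FALSE)
cat(sprintf(
  "RM-ANOVA: F = %.2f on (%.2f, %.2f) df (GG epsilon = %.3f), p = %.2g.\n",
  rm_res$F, rm_res$df1, rm_res$df2, rm_res$epsilon, rm_res$p))
for (i in seq_len(nrow(dn_res))) {
  cat(sprintf("  %s vs NT: delta = %.1f%%, Dunnett p = %.3g\n",
              dn_res$condition[i], dn_res$estimate[i], dn_res$p_adj[i]))
}

## qPCR: miR-124-5p induction and an n.d. (not detected) monocyte sample,
## normalized to miR-93-3p.
qpcr <- simulate_qpcr_table(c(Mo_1 = 0, Mo_2 = 0, MQ_1 = 1.2, MQ_2 = 0.9),
                            seed = 7)
expr <- ddct(qpcr$ct_target, qpcr$ct_reference, qpcr$detected)
qpcr$rel_expr <- expr$rel_expr
utils::write.csv(qpcr, "results/validation_qpcr.csv", row.names = FALSE)
cat(sprintf("qPCR: %d/%d samples detected; detected rel. expr. %s.\n",
            attr(expr, "n_detected"), nrow(qpcr),
            paste(sprintf("%.2f", expr$rel_expr[expr$detected]),
                  collapse = ", ")))

## Dual luciferase: planted 40% repression of the WT binding-site reporter.
plate <- simulate_luciferase_plate(repression = c(WT = 0.6, MUT = 1.0),
                                   n_wells = 6, seed = 8)
luc <- luciferase_relative(plate)
utils::write.csv(luc, "results/validation_luciferase.csv", row.names = FALSE)
for (con in c("WT", "MUT")) {
  arm <- luc$construct == con & luc$arm == "miR"
  tt <- ttest(luc$rel_activity[arm],
              luc$rel_activity[luc$construct == con & luc$arm == "NT"])
  cat(sprintf("Luciferase %s: rel. activity %.2f (t-test vs NT p = %.3g)\n",
              con, mean(luc$rel_activity[arm]), tt$p))
}

## Gentamicin protection: recover a titre from a spot-plated series.
series <- simulate_spot_series(8e6, dilutions = 0:6, seed = 9)
cfu <- cfu_per_ml(series$counts, series$dilutions)
cat(sprintf(
  "CFU assay: %.2g CFU/ml from dilution 10^-%d (mean %.1f colonies/spot, CV %.2f).\n",
  cfu$cfu_per_ml, cfu$dilution, cfu$mean_count, cfu$cv))
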