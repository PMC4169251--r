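#!/usr/bin/env Rscript
# Transcription-factor binding and methylation: score both alleles of SNPs
# inside motif instances, regress nearby methylation on predicted binding
# affinity, compare per-TF sharing with a matched permutation null, and
# correlate TF expression with methylation near its binding sites.

suppressPackageStartupMessages(library(cismeth))
dir.create("results/tfmeth", showWarnings = FALSE, recursive = TRUE)

geno <- read_dosage_tsv("results/sim/dosages.tsv")
sim_beta <- read_beta_tsv("results/sim/beta.tsv")
sim_manifest <- read_manifest_bed("results/sim/probes.bed")

pw <- pwm(matrix(c(8, 1, 1, 1,
                   1, 8, 1, 1,
                   1, 1, 8, 1,
                   2, 2, 2, 2,
                   1, 1, 1, 8), 5, 4, byrow = TRUE), name = "TF1")

# motif instances whose SNPs disrupt predicted binding, coupled negatively
# to nearby methylation (higher predicted affinity, lower methylation)
bind <- simulate_binding_fixture(pw, geno, n_sites = 50, coupling = -2,
                                 seed = 301)
bnorm <- quantile_normalize(bind$beta, "two_stage")
res <- binding_snp_meth_assoc(bind$sites, bnorm, geno, bind$manifest,
                              window = 500, fdr = 0.10)
summ <- res$summary

# permutation universe: binding-site SNPs of any TF with a CpG within 500 bp
geno_bg <- simulate_genotypes(sim_config(n_samples = 64, n_snps = 2000,
                                         n_probes = 10, region_length = 1e6,
                                         seed = 302))
bg <- simulate_binding_fixture(pw, geno_bg, n_sites = 150, coupling = 0,
                               seed = 303)
bg$sites$tf <- "backgroundTF"
bg_res <- binding_snp_meth_assoc(bg$sites, quantile_normalize(bg$beta),
                                 geno_bg, bg$manifest, window = 500)
nul <- binding_matched_null(summ$prop_significant, summ$n_tested,
                            rbind(res$assoc, bg_res$assoc), B = 999, seed = 304)
tab2 <- data.frame(tf = summ$tf, n_snps_tested = summ$n_tested,
                   prop_significant = summ$prop_significant,
                   null_mean = nul$null_mean, empirical_p = nul$empirical_p,
                   n_positive = summ$n_positive, n_negative = summ$n_negative)
cat("per-TF binding-affinity association summary:\n")
print(tab2, row.names = FALSE)
utils::write.table(tab2, "results/tfmeth/tf_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$assoc, "results/tfmeth/binding_associations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# TF expression vs methylation near its sites, on data normalized by
# individual then probe, without PC removal (a trans effect would load on
# the removed components)
set.seed(305)
expr <- normalize_expression(
  stats::setNames(stats::rlnorm(64, 3, 0.5), rownames(bind$beta)))
coupled <- stats::plogis(stats::qlogis(bind$beta) -
                           matrix(expr, 64, ncol(bind$beta)))
far <- sim_manifest; far$pos <- far$pos + 2e7
tfres <- tf_expression_meth_assoc(expr,
                                  quantile_normalize(cbind(coupled, sim_beta)),
                                  bind$sites, rbind(bind$manifest, far),
                                  window = 500, n_perm = 200, seed = 306)
sig <- tfres$table[tfres$table$p_value < 0.01, ]
cat(sprintf("expression-methylation: %d/%d near-site probes at p < 0.01, %.0f%% negative r\n",
            nrow(sig), nrow(tfres$table), 100 * mean(sig$r < 0)))
utils::write.table(tfres$table, "results/tfmeth/expression_associations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tfres$null_band, "results/tfmeth/expression_null_band.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
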