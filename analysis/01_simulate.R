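#!/usr/bin/env Rscript
# Generate the synthetic cohort every later stage consumes: 64 individuals,
# 2000 array CpGs and 8000 common SNPs on 4 Mb, 10% of probes with a planted
# cis effect (1.5 sd latent, 1.5 kb regional span), four hidden confounders,
# plus low-coverage bisulfite reads for ten individuals.

suppressPackageStartupMessages(library(cismeth))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_samples = 64, n_probes = 2000, n_snps = 8000,
                  region_length = 4e6, causal_fraction = 0.1,
                  effect_size = 1.5, regional_effect_span = 1500,
                  n_confounders = 4, confounder_sd = 0.5, seed = 20260921L)
geno <- simulate_genotypes(cfg)
sim <- simulate_methylation(geno, cfg)

write_dosage_tsv(geno, "results/sim/dosages.tsv")
write_vcf_minimal(geno, "results/sim/genotypes.vcf")
write_beta_tsv(sim$beta, "results/sim/beta.tsv")
write_manifest_bed(sim$manifest, "results/sim/probes.bed")
utils::write.table(sim$truth$causal_pairs, "results/sim/truth_causal.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$affected, "results/sim/truth_affected.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

seq_samples <- rownames(sim$beta)[1:10]
reads <- simulate_bisulfite_reads(sim$beta[seq_samples, , drop = FALSE],
                                  sim$manifest, mean_coverage = 2.4,
                                  conversion_efficiency = 0.99, seed = 20260922L)
write_bismark_cov(reads, "results/sim/coverage")

cat(sprintf("cohort: %d samples, %d probes, %d SNPs (median MAF %.2f)\n",
            cfg$n_samples, cfg$n_probes, cfg$n_snps, stats::median(geno$snps$maf)))
cat(sprintf("planted: %d causal CpGs, %d probes inside regional spans\n",
            nrow(sim$truth$causal_pairs),
            length(unique(sim$truth$affected$probe_id))))
cat(sprintf("bisulfite reads: %d covered (sample, site) pairs over %d individuals\n",
            nrow(reads), length(seq_samples)))
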