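#!/usr/bin/env Rscript
# Cross-phenotype QTL sharing: a linked quantitative phenotype is mapped,
# its QTL SNPs are tested for association with nearby methylation, and the
# observed sharing is compared with a matched-count permutation null.
# A random SNP set and a chromatin-annotation contrast complete the picture.

suppressPackageStartupMessages(library(cismeth))
dir.create("results/overlap", showWarnings = FALSE, recursive = TRUE)

resid <- read_beta_tsv("results/preprocess/normalized.tsv")
manifest <- read_manifest_bed("results/sim/probes.bed")
manifest <- manifest[manifest$probe_id %in% colnames(resid), ]
geno <- read_dosage_tsv("results/sim/dosages.tsv")
truth <- utils::read.delim("results/sim/truth_causal.tsv")
mq <- utils::read.delim("results/meqtl/meqtls.tsv")

# a secondary phenotype driven by a subset of the methylation QTLs
set.seed(77)
shared_snps <- sample(unique(truth$snp_id), 40)
ph <- simulate_linked_phenotype(geno, snp_ids = shared_snps, effect = 0.8,
                                noise_sd = 1, seed = 78)
fg_dir <- stats::setNames(sign(ph$info$effect), ph$info$snp_id)

rows <- list()
run_fg <- function(fg, label, dir = NULL, seed) {
  res <- suppressWarnings(
    enrich_foreground(fg, resid, geno, manifest, window = 3000, fdr = 0.10,
                      B = 999, seed = seed, fg_direction = dir, label = label))
  cat(sprintf("%-12s n=%3d  prop.sig=%.3f  null=%.3f  emp.p=%.4g  +%d/-%d\n",
              label, res$n_tested, res$prop_significant, res$null_mean,
              res$empirical_p, res$n_positive, res$n_negative))
  data.frame(label = label, n_tested = res$n_tested,
             prop_significant = res$prop_significant,
             null_mean = res$null_mean, empirical_p = res$empirical_p,
             n_positive = res$n_positive, n_negative = res$n_negative)
}
cat("foreground enrichment (matched-count permutation, B = 999):\n")
rows[[1]] <- run_fg(ph$info$snp_id, "linkedQTL", fg_dir, seed = 101)
uni <- snp_universe(geno, manifest)
set.seed(102)
rows[[2]] <- run_fg(sample(setdiff(uni, shared_snps), 40), "random", seed = 103)

summary_tab <- do.call(rbind, rows)
utils::write.table(summary_tab, "results/overlap/enrichment_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# chromatin-annotation contrast of meQTL CpGs
ann_rows <- lapply(c("promoter", "enhancer", "other"), function(f) {
  a <- annotation_enrichment(mq$probe_id, manifest, f)
  data.frame(feature = f, chi_square = a$chi_square, p_value = a$p_value,
             direction = a$direction)
})
ann_tab <- do.call(rbind, ann_rows)
print(ann_tab, row.names = FALSE)
utils::write.table(ann_tab, "results/overlap/annotation_enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
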