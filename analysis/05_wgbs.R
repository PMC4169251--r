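#!/usr/bin/env Rscript
# Bisulfite sequencing: concordance of the sequencing methylation levels
# with the array, and the genotype-stratified aggregate methylation curves
# around meQTL CpGs (high vs het vs low homozygote classes).

suppressPackageStartupMessages(library(cismeth))
dir.create("results/wgbs", showWarnings = FALSE, recursive = TRUE)

beta <- read_beta_tsv("results/sim/beta.tsv")
manifest <- read_manifest_bed("results/sim/probes.bed")
geno <- read_dosage_tsv("results/sim/dosages.tsv")
mq <- utils::read.delim("results/meqtl/meqtls.tsv")
reads <- read_bismark_cov(list.files("results/sim/coverage", full.names = TRUE))

levels_tab <- site_methylation(reads, min_reads = 1)
cat(sprintf("sequenced sites: %d covered (sample, site) pairs; median coverage %d\n",
            nrow(levels_tab), stats::median(levels_tab$n_total)))

cc <- array_seq_concordance(beta, reads, manifest, min_reads = 5)
cat(sprintf("array vs sequencing site means: Spearman rho = %.3f over %d sites\n",
            cc$rho, cc$n_sites))
utils::write.table(cc$table, "results/wgbs/concordance.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

agg <- suppressMessages(
  genotype_stratified_aggregate(reads, mq, geno, manifest,
                                span = 6000, window = 51, step = 25))
utils::write.table(agg, "results/wgbs/aggregate_curves.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
wide <- merge(agg[agg$class == "high", c("offset", "level")],
              agg[agg$class == "low", c("offset", "level")], by = "offset")
gap <- wide$level.x - wide$level.y
cat(sprintf("high-low homozygote gap: %.3f within +/-1.5 kb, %.3f beyond 2.5 kb (%d windows/class)\n",
            mean(gap[abs(wide$offset) <= 1500], na.rm = TRUE),
            mean(gap[abs(wide$offset) > 2500], na.rm = TRUE),
            attr(agg, "n_windows")))
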