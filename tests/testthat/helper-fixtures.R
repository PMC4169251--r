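# Shared fixture builders. Everything is generated in code at test time.

# Small genotype table with explicit dosages (samples x snps).
make_geno <- function(dosages, pos = NULL, chrom = "chr1") {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("s%03d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp%03d", seq_len(ncol(dosages)))
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 100
  f <- colMeans(dosages) / 2
  structure(list(dosages = dosages,
                 snps = data.frame(snp_id = colnames(dosages), chrom = chrom,
                                   pos = pos, maf = pmin(f, 1 - f))),
            class = "genotype_table")
}

make_manifest <- function(pos, chrom = "chr1", annotation = "other",
                          probe_id = NULL) {
  if (is.null(probe_id)) probe_id <- sprintf("cg%03d", seq_along(pos))
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
             annotation = annotation)
}

# Default planted fixture used by several recovery tests.
planted_fixture <- function(seed = 1, n_probes = 400, n_snps = 2400,
                            region_length = 8e5, causal_fraction = 0.2,
                            effect_size = 1.5, n_confounders = 0, ...) {
  cfg <- sim_config(seed = seed, n_probes = n_probes, n_snps = n_snps,
                    region_length = region_length,
                    causal_fraction = causal_fraction,
                    effect_size = effect_size, n_confounders = n_confounders,
                    ...)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_methylation(geno, cfg)
  c(sim, list(geno = geno, cfg = cfg))
}

# Independent textbook OLS + t-test oracle for a single regression.
ols_oracle <- function(y, x) {
  fit <- summary(stats::lm(y ~ x))
  co <- fit$coefficients
  list(slope = co[2, 1], se = co[2, 2], t = co[2, 3], p = co[2, 4])
}

# Toy width-2 PWM used in the scoring worked examples (no pseudocount so
# hand-computed log-odds are exact).
toy_pwm <- function() {
  m <- rbind(c(0.5, 1/6, 1/6, 1/6),
             c(0.25, 0.25, 0.25, 0.25))
  pwm(m, name = "toy", pseudocount = 0)
}
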