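# PWM scoring, allele deltas, affinity-methylation regression, and
# TF-expression correlation.

test_that("log-odds PWM scoring matches hand-computed values", {
  pw <- toy_pwm()
  # uniform column contributes 0; p(A,1)=0.5 over background 0.25 gives 1 bit
  expect_equal(pwm_score(pw, "AC"), 1.0, tolerance = 1e-12)
  expect_equal(pwm_score(pw, "CG"), log2((1 / 6) / 0.25), tolerance = 1e-12)

  unif <- pwm(matrix(0.25, 3, 4), pseudocount = 0)
  for (s in c("ACG", "TTT", "GAT"))
    expect_equal(pwm_score(unif, s), 0, tolerance = 1e-12)

  # consensus scores at least as high as any other sequence
  set.seed(1)
  rand <- pwm(matrix(stats::rgamma(5 * 4, 1), 5, 4), pseudocount = 1e-3)
  cons <- paste(c("A", "C", "G", "T")[apply(rand$probs, 1, which.max)],
                collapse = "")
  seqs <- replicate(50, paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = ""))
  expect_true(all(vapply(seqs, function(s) pwm_score(rand, s), numeric(1)) <=
                    pwm_score(rand, cons) + 1e-12))

  expect_error(pwm_score(pw, "AN"), "base")
  expect_error(pwm_score(pw, "A"), "width")
  expect_error(pwm(matrix(0.25, 0, 4)), "width")
})

test_that("allele scoring substitutes, strand-flips, and differences correctly", {
  pw <- toy_pwm()
  site <- data.frame(chrom = "chr1", start = 100, end = 102, strand = "+",
                     tf = "toy", snp_id = "rs1", offset = 0, ref = "A", alt = "C")
  got <- allele_scores(site, pw, ref_context = "AC")
  expect_equal(got$score_ref, 1.0, tolerance = 1e-12)
  expect_equal(got$score_alt, log2((1 / 6) / 0.25), tolerance = 1e-12)
  expect_equal(got$delta, log2((1 / 6) / 0.25) - 1.0, tolerance = 1e-12)

  # ref == alt: delta exactly 0
  same <- site; same$alt <- "A"
  expect_equal(allele_scores(same, pw, "AC")$delta, 0)

  # a minus-strand site scores the reverse complement: plus-strand window
  # "GT" read on the minus strand is "AC"
  minus <- data.frame(chrom = "chr1", start = 100, end = 102, strand = "-",
                      tf = "toy", snp_id = "rs2", offset = 1, ref = "T", alt = "G")
  gm <- allele_scores(minus, pw, ref_context = "GT")
  expect_equal(gm$score_ref, 1.0, tolerance = 1e-12)   # revcomp(GT) = AC
  expect_equal(gm$score_alt, log2((1 / 6) / 0.25), tolerance = 1e-12)  # revcomp(GG) = CC

  # consistency: score_ref equals pwm_score on the unmodified window
  set.seed(2)
  rand <- pwm(matrix(stats::rgamma(4 * 4, 1), 4, 4))
  ctx <- "ACGT"
  s4 <- data.frame(chrom = "chr1", start = 1, end = 5, strand = "+",
                   tf = "m", snp_id = "rs3", offset = 2, ref = "G", alt = "T")
  expect_equal(allele_scores(s4, rand, ctx)$score_ref, pwm_score(rand, ctx))

  indel <- site; indel$alt <- "CT"
  expect_error(allele_scores(indel, pw, "AC"), "indel")
  off_bad <- site; off_bad$offset <- 5
  expect_error(allele_scores(off_bad, pw, "AC"), "offset")
})

test_that("affinity covariate is affine in dosage and reproduces the dosage test", {
  set.seed(3)
  cfg <- sim_config(n_samples = 64, n_snps = 200, n_probes = 10,
                    region_length = 2e5, seed = 4)
  geno <- simulate_genotypes(cfg)
  pw <- pwm(matrix(c(8, 1, 1, 1, 1, 8, 1, 1, 1, 1, 8, 1), 3, 4, byrow = TRUE),
            name = "TFY")
  fx <- simulate_binding_fixture(pw, geno, n_sites = 15, coupling = -1.5, seed = 5)
  norm <- quantile_normalize(fx$beta)
  res <- binding_snp_meth_assoc(fx$sites, norm, geno, fx$manifest)
  expect_gt(nrow(res$assoc), 0)
  # same t and p as regressing on raw dosage (scale-invariance of OLS t)
  for (k in seq_len(min(5, nrow(res$assoc)))) {
    row <- res$assoc[k, ]
    y <- norm$values[, row$probe_id]
    x <- geno$dosages[rownames(norm$values), row$snp_id]
    oracle <- ols_oracle(y, x)
    expect_equal(abs(row$t_stat), abs(oracle$t), tolerance = 1e-8)
    expect_equal(row$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("negative coupling yields enriched, negatively-signed associations", {
  cfg <- sim_config(n_samples = 64, n_snps = 400, n_probes = 10,
                    region_length = 4e5, seed = 6)
  geno <- simulate_genotypes(cfg)
  pw <- pwm(matrix(c(8, 1, 1, 1, 1, 8, 1, 1, 1, 1, 8, 1, 2, 2, 2, 2),
                   4, 4, byrow = TRUE), name = "STAT5like")
  fx <- simulate_binding_fixture(pw, geno, n_sites = 40, coupling = -2, seed = 7)
  norm <- quantile_normalize(fx$beta)
  res <- binding_snp_meth_assoc(fx$sites, norm, geno, fx$manifest)
  summ <- res$summary
  expect_gt(summ$prop_significant, 0.5)
  expect_gt(summ$n_negative, 4 * max(summ$n_positive, 1))

  # the permutation universe is dominated by uncoupled binding-site SNPs
  geno2 <- simulate_genotypes(sim_config(n_samples = 64, n_snps = 400,
                                         n_probes = 10, region_length = 4e5,
                                         seed = 66))
  bg <- simulate_binding_fixture(pw, geno2, n_sites = 160, coupling = 0, seed = 67)
  bg$sites$tf <- "background"
  res_bg <- binding_snp_meth_assoc(bg$sites, quantile_normalize(bg$beta),
                                   geno2, bg$manifest)
  universe <- rbind(res$assoc, res_bg$assoc)
  nul <- binding_matched_null(summ$prop_significant, summ$n_tested, universe,
                              B = 199, seed = 8)
  expect_gt(summ$prop_significant, 2 * nul$null_mean)
  expect_lte(nul$empirical_p, 0.05)
})

test_that("zero-delta sites and distant probes produce no tests", {
  geno <- make_geno(matrix(c(0, 1, 2, 1, 0, 2), 6, 1), pos = 1000)
  pw <- toy_pwm()
  # delta = 0: the covariate is constant in dosage
  sites0 <- data.frame(chrom = "chr1", start = 999, end = 1001, strand = "+",
                       tf = "toy", snp_id = "snp001", offset = 1,
                       ref = "C", alt = "G")
  sc0 <- allele_scores(sites0, pw, "AC")     # position 2 is uniform: delta 0
  expect_equal(sc0$delta, 0)
  mf <- make_manifest(1100, probe_id = "cgZ")
  meth <- matrix(stats::rnorm(6), 6, 1,
                 dimnames = list(rownames(geno$dosages), "cgZ"))
  res0 <- binding_snp_meth_assoc(sc0, meth, geno, mf)
  expect_equal(nrow(res0$assoc), 0)

  # probe 600 bp from the motif: outside the 500 bp window
  sites1 <- data.frame(chrom = "chr1", start = 999, end = 1001, strand = "+",
                       tf = "toy", snp_id = "snp001", offset = 0,
                       ref = "A", alt = "C")
  sc1 <- allele_scores(sites1, pw, "AC")
  mf_far <- make_manifest(1601, probe_id = "cgZ")
  res1 <- binding_snp_meth_assoc(sc1, meth, geno, mf_far)
  expect_equal(nrow(res1$assoc), 0)
})

test_that("TF expression-methylation correlation is exact and calibrated", {
  set.seed(9)
  n <- 56
  vals <- matrix(stats::rnorm(n * 60), n, 60,
                 dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%03d", 1:60)))
  mf <- make_manifest(seq_len(60) * 200, probe_id = colnames(vals))
  sites <- data.frame(chrom = "chr1", start = c(150, 6000), end = c(170, 6020))

  # expression equal to one probe's methylation: r = 1 at that probe
  expr <- stats::setNames(vals[, "cg001"], rownames(vals))
  res <- tf_expression_meth_assoc(expr, vals, sites, mf)
  expect_equal(res$table$r[res$table$probe_id == "cg001"], 1, tolerance = 1e-12)
  expect_lt(res$table$p_value[res$table$probe_id == "cg001"], 1e-100)
  # probes outside 500 bp of both sites are not tested
  expect_false("cg020" %in% res$table$probe_id)
  # oracle check against cor.test
  ct <- stats::cor.test(expr, vals[, "cg002"])
  expect_equal(res$table$p_value[res$table$probe_id == "cg002"], ct$p.value,
               tolerance = 1e-10)

  expect_error(tf_expression_meth_assoc(rep(1, n), vals, sites, mf),
               "zero variance")

  # permuted expression: p-values uniform across 50 permutation seeds
  ps <- numeric(0)
  for (s in 1:50) {
    set.seed(400 + s)
    ps <- c(ps, tf_expression_meth_assoc(sample(unname(expr)), vals, sites,
                                         mf)$table$p_value)
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("coupled expression produces excess small p-values with negative correlations", {
  set.seed(10)
  n <- 56
  expr <- stats::rnorm(n)
  # 40 probes near sites, half coupled negatively to expression
  vals <- matrix(stats::rnorm(n * 40), n, 40,
                 dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%03d", 1:40)))
  vals[, 1:20] <- vals[, 1:20] - 1.2 * expr
  mf <- make_manifest(seq_len(40) * 100, probe_id = colnames(vals))
  sites <- data.frame(chrom = "chr1", start = 0, end = 4100)
  res <- tf_expression_meth_assoc(stats::setNames(expr, rownames(vals)),
                                  vals, sites, mf, n_perm = 200, seed = 11)
  obs <- sort(-log10(res$table$p_value), decreasing = TRUE)
  # observed order statistics break out of the 97.5% permutation band
  expect_gt(sum(obs > res$null_band$hi), 10)
  sig <- res$table[res$table$p_value < 0.01, ]
  expect_gt(nrow(sig), 10)
  expect_gt(mean(sig$r < 0), 0.9)
})

test_that("expression normalization is the rank-normal transform", {
  x <- c(a = 5, b = 1, c = 3)
  out <- normalize_expression(x)
  expect_equal(names(out), names(x))
  expect_equal(unname(out), stats::qnorm(c(2.5, 0.5, 1.5) / 3))
})
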