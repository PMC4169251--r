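# Cis scan, q-values, lead-SNP calling, candidate-causal filter, and
# probe-pair correlation audit.

test_that("scan p-values match the textbook OLS oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- 64
    dos <- stats::rbinom(n, 2, stats::runif(1, 0.1, 0.5))
    if (stats::var(dos) == 0) next
    y <- stats::rnorm(n)
    geno <- make_geno(matrix(dos, ncol = 1), pos = 150)
    mf <- make_manifest(100)
    meth <- matrix(y, ncol = 1, dimnames = list(rownames(geno$dosages), "cg001"))
    got <- cis_scan(meth, geno, mf, maf_min = 0)
    oracle <- ols_oracle(y, dos)
    expect_lt(abs(got$p_value - oracle$p), 1e-10)
    expect_lt(abs(got$effect - oracle$slope), 1e-10)
    expect_lt(abs(got$t_stat - oracle$t), 1e-8)
    expect_equal(got$distance, 50)
  }
})

test_that("scan respects the cis window and the strict MAF threshold", {
  n <- 50
  dos <- cbind(snpA = rep(0:1, c(46, 4)),   # maf 0.04
               snpB = rep(0:1, c(44, 6)),   # maf 0.06
               snpC = rep(1L, 50),          # zero variance
               snpD = rep(0:2, c(20, 15, 15)))
  geno <- make_geno(dos, pos = c(1000, 1200, 1400, 9000))
  mf <- make_manifest(c(1100, 5000))
  set.seed(3)
  meth <- matrix(stats::rnorm(n * 2), n, 2,
                 dimnames = list(rownames(geno$dosages), mf$probe_id))
  got <- suppressMessages(cis_scan(meth, geno, mf, window = 3000, maf_min = 0.05))
  expect_false("snpA" %in% got$snp_id)           # below threshold
  expect_true("snpB" %in% got$snp_id)            # above threshold
  expect_false("snpC" %in% got$snp_id)           # constant dosage skipped
  # snpD is 8000 bp from cg001 (excluded) and 4000 bp from cg002 (excluded at 3 kb)
  expect_false(any(got$snp_id == "snpD"))
  got5 <- suppressMessages(cis_scan(meth, geno, mf, window = 4000, maf_min = 0.05))
  expect_true(any(got5$snp_id == "snpD" & got5$probe_id == "cg002"))

  expect_warning(cis_scan(meth, geno, mf, maf_min = 0.6), "MAF")
  expect_error(cis_scan(meth[1:3, ], make_geno(dos[1:3, ], pos = c(1000, 1200, 1400, 9000)), mf),
               "4 samples")
})

test_that("q-value machinery reproduces BH at pi0 = 1 and stays monotone", {
  # hand-computed BH step-up on the worked list
  q <- estimate_qvalues(c(0.01, 0.02, 0.04, 0.5), pi0 = 1)
  expect_equal(q$q_values, c(0.04, 0.04, 0.16 / 3, 0.5), tolerance = 1e-12)

  expect_equal(estimate_qvalues(rep(1, 5), pi0 = 1)$q_values, rep(1, 5))

  set.seed(5)
  for (i in 1:5) {
    p <- stats::runif(500)^(sample(1:3, 1))
    qv <- estimate_qvalues(p)$q_values
    o <- order(p)
    expect_true(all(diff(qv[o]) >= -1e-12))        # monotone in p
    expect_equal(estimate_qvalues(p, pi0 = 1)$q_values,
                 stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(qv <= estimate_qvalues(p, pi0 = 1)$q_values + 1e-12))
  }
  expect_error(estimate_qvalues(c(0.5, 1.2)), "0, 1")
  expect_equal(length(estimate_qvalues(numeric(0))$q_values), 0)
})

test_that("meQTL calling keeps one lead SNP per significant probe", {
  assoc <- data.frame(probe_id = c("cg1", "cg1", "cg2", "cg3"),
                      snp_id = c("s1", "s2", "s3", "s4"),
                      cpg_pos = c(100, 100, 500, 900),
                      snp_pos = c(150, 120, 480, 950),
                      distance = c(50, 20, 20, 50),
                      effect = c(1, 0.5, -1, 0.2),
                      se = 0.1, t_stat = 5,
                      p_value = c(1e-8, 1e-3, 1e-4, 0.2),
                      q_value = c(1e-6, 1e-2, 1e-3, 0.3),
                      direction = c(1, 1, -1, 1))
  mq <- call_meqtls(assoc, fdr = 0.10)
  expect_equal(nrow(mq), 2)                      # cg3 not significant
  expect_equal(mq$snp_id[mq$probe_id == "cg1"], "s1")  # most significant wins
  expect_equal(mq$effect[mq$probe_id == "cg2"], -1)

  # tie on p: smaller distance wins, then smaller position
  tie <- assoc[1:2, ]
  tie$p_value <- c(1e-5, 1e-5); tie$q_value <- 1e-4
  expect_equal(call_meqtls(tie)$snp_id, "s2")

  none <- assoc; none$q_value <- 0.5
  expect_equal(nrow(call_meqtls(none)), 0)
})

test_that("candidate-causal filter applies the inclusive two-order gap rule", {
  base <- data.frame(cpg_pos = 100, se = 1, t_stat = 1, effect = 1,
                     q_value = 0.01, direction = 1)
  mk <- function(probe, ps) cbind(data.frame(probe_id = probe,
                                             snp_id = sprintf("%s_s%d", probe, seq_along(ps)),
                                             snp_pos = 100 + seq_along(ps),
                                             distance = seq_along(ps),
                                             p_value = ps), base)
  aw <- rbind(mk("cg1", c(1e-8, 1e-5)),   # 3 orders: candidate
              mk("cg2", c(1e-8, 1e-6)),   # exactly 2 orders: candidate
              mk("cg3", c(1e-8, 1e-7)),   # 1 order: no
              mk("cg4", 1e-9))            # single SNP: excluded
  out <- suppressMessages(find_candidate_causal(aw))
  expect_setequal(out$probe_id, c("cg1", "cg2"))
  expect_equal(attr(out, "n_single_snp"), 1L)
  expect_equal(out$log10_gap[out$probe_id == "cg1"], 3)
  expect_equal(out$snp_id[out$probe_id == "cg2"], "cg2_s1")
})

test_that("candidate-causal filter points at the true causal SNP on an LD fixture", {
  hits <- 0L; flagged <- 0L
  for (seed in 1:3) {
    fx <- planted_fixture(seed = 300 + seed, n_probes = 250, n_snps = 1500,
                          region_length = 5e5, causal_fraction = 0.2,
                          effect_size = 2, regional_effect_span = 0)
    norm <- quantile_normalize(fx$beta)
    wide <- suppressMessages(cis_scan(norm, fx$geno, fx$manifest, window = 5000))
    cand <- suppressMessages(find_candidate_causal(wide))
    truth <- fx$truth$causal_pairs
    m <- match(cand$probe_id, truth$probe_id)
    ok <- !is.na(m)
    flagged <- flagged + sum(ok)
    hits <- hits + sum(cand$snp_id[ok] == truth$snp_id[m[ok]])
  }
  expect_gt(flagged, 10)
  expect_gte(hits / flagged, 0.8)
})

test_that("scan p-values are uniform under a permuted-genotype null", {
  fx <- suppressWarnings(
    planted_fixture(seed = 77, n_probes = 650, n_snps = 1950,
                    region_length = 5e5, causal_fraction = 0.2,
                    effect_size = 1.5))
  norm <- quantile_normalize(fx$beta)
  set.seed(88)
  perm <- fx$geno
  perm$dosages <- perm$dosages[sample(nrow(perm$dosages)), , drop = FALSE]
  rownames(perm$dosages) <- rownames(fx$geno$dosages)
  assoc <- cis_scan(norm, perm, fx$manifest)
  expect_gt(nrow(assoc), 1e4)
  ks <- suppressWarnings(stats::ks.test(assoc$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  # random-window null: probes paired with SNPs from a distant random window
  shuffled_manifest <- fx$manifest
  shuffled_manifest$pos <- sample(fx$manifest$pos)
  assoc2 <- cis_scan(norm, perm, shuffled_manifest)
  ks2 <- suppressWarnings(stats::ks.test(assoc2$p_value, "punif"))
  expect_gt(ks2$p.value, 0.01)
})

test_that("probe-pair correlation audit counts significantly correlated neighbors", {
  set.seed(15)
  n <- 40
  vals <- matrix(stats::rnorm(n * 4), n, 4,
                 dimnames = list(NULL, c("cg1", "cg2", "cg3", "cg4")))
  vals[, 2] <- vals[, 1]                       # duplicated probe pair
  mf <- make_manifest(c(100, 600, 4000, 12000), probe_id = colnames(vals))
  mq <- data.frame(probe_id = colnames(vals))
  out <- probe_pair_correlation(vals, mq, mf, raw_values = vals)
  pair12 <- out$pairs[out$pairs$probe_a == "cg1" & out$pairs$probe_b == "cg2", ]
  expect_equal(pair12$r_norm, 1)
  expect_lt(pair12$p_norm, 1e-12)
  # cg3-cg4 are 8 kb apart: not tested
  expect_false(any(out$pairs$probe_a == "cg3" & out$pairs$probe_b == "cg4"))
  expect_equal(out$n_sig_probes_normalized, out$n_sig_probes_untransformed)

  # independent probes: about alpha of pairs significant
  set.seed(16)
  vals2 <- matrix(stats::rnorm(50 * 200), 50, 200,
                  dimnames = list(NULL, sprintf("cg%03d", 1:200)))
  mf2 <- make_manifest(rep(1:20 * 1e5, each = 10) + rep(1:10 * 100, 20),
                       probe_id = colnames(vals2))
  out2 <- probe_pair_correlation(vals2, data.frame(probe_id = colnames(vals2)), mf2)
  expect_gt(out2$n_pairs, 500)
  expect_lt(abs(mean(out2$pairs$p_norm < 0.05) - 0.05), 0.02)
})
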