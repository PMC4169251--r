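# Synthetic-data generators: genotypes with LD blocks, bimodal methylation
# with planted cis effects and hidden confounders, binomial bisulfite reads,
# linked quantitative phenotypes, and motif/PWM binding fixtures.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic cohort. Defaults
#' emulate a 64-sample lymphoblastoid methylation study: common variants,
#' 2 kb LD blocks, regional cis effects spanning 1.5 kb either side of the
#' causal CpG, and a handful of hidden confounders that load on the leading
#' principal components.
#'
#' @param n_samples number of individuals (>= 4).
#' @param n_probes number of array probes (CpGs).
#' @param n_snps number of SNPs.
#' @param region_length length in bp of the simulated region; probe and SNP
#'   positions are drawn uniformly from it.
#' @param maf_range length-2 numeric in (0, 0.5]; each LD block draws its
#'   allele frequency uniformly from this range.
#' @param ld_block_size bp; SNPs within the same block share haplotype
#'   structure and are therefore correlated.
#' @param causal_fraction fraction of probes given a planted cis effect.
#' @param effect_size per-dosage-unit shift on the latent (logit) scale, in
#'   units of the residual sd (which is 1).
#' @param regional_effect_span bp; the planted effect is shared by all probes
#'   within this distance of the causal CpG (the regional correlation of
#'   methylation around a meQTL).
#' @param n_confounders number of hidden confounders.
#' @param confounder_sd sd of per-probe confounder loadings on the latent
#'   scale; 0 disables confounding even when `n_confounders > 0`.
#' @param seed integer seed; all generators derive their streams from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 64, n_probes = 1000, n_snps = 3000,
                       region_length = 1e6, maf_range = c(0.1, 0.5),
                       ld_block_size = 2000, causal_fraction = 0.1,
                       effect_size = 1.5, regional_effect_span = 1500,
                       n_confounders = 4, confounder_sd = 0.5, seed = 1L) {
  if (n_samples < 4) .stopf("n_samples must be >= 4")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    .stopf("maf_range must be an increasing pair within (0, 0.5]")
  if (effect_size < 0) .stopf("effect_size must be >= 0")
  if (regional_effect_span < 0) .stopf("regional_effect_span must be >= 0")
  if (causal_fraction < 0 || causal_fraction > 1)
    .stopf("causal_fraction must be in [0, 1]")
  cfg <- list(n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
              n_snps = as.integer(n_snps), region_length = region_length,
              maf_range = maf_range, ld_block_size = ld_block_size,
              causal_fraction = causal_fraction, effect_size = effect_size,
              regional_effect_span = regional_effect_span,
              n_confounders = as.integer(n_confounders),
              confounder_sd = confounder_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate genotype dosages with block LD structure
#'
#' Draws integer dosages in \{0, 1, 2\} for `cfg$n_snps` SNPs at positions
#' uniform on `[0, region_length)`. SNPs falling in the same LD block share a
#' block allele frequency, and each chromosome copy follows a latent block
#' haplotype with high fidelity, so adjacent SNPs are correlated -- enough LD
#' to exercise the candidate-causal filter without a coalescent simulation.
#'
#' @param cfg a [sim_config()].
#' @param chrom chromosome name used for all SNPs.
#' @param ld_fidelity probability that a SNP allele copies its chromosome's
#'   block haplotype rather than being redrawn independently; pairwise
#'   dosage correlation within a block is about `ld_fidelity^2`.
#' @return a `genotype_table`: list with `dosages` (samples x SNPs integer
#'   matrix) and `snps` (data.frame of snp_id, chrom, pos, maf with the
#'   empirical minor allele frequency).
#' @export
simulate_genotypes <- function(cfg, chrom = "chr1", ld_fidelity = 0.95) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_snps == 0) .stopf("n_snps is 0: refusing to build an empty genotype table")
  set.seed(cfg$seed)
  n <- cfg$n_samples
  pos <- sort(sample.int(cfg$region_length, cfg$n_snps, replace = FALSE))
  block <- pos %/% cfg$ld_block_size
  ublock <- unique(block)
  f_block <- stats::runif(length(ublock), cfg$maf_range[1], cfg$maf_range[2])
  f <- f_block[match(block, ublock)]

  dos <- matrix(0L, n, cfg$n_snps)
  for (copy in 1:2) {
    # latent haplotype indicator per (sample, block)
    z_block <- matrix(stats::rbinom(n * length(ublock), 1L, f_block),
                      n, length(ublock), byrow = TRUE)
    z <- z_block[, match(block, ublock), drop = FALSE]
    keep <- matrix(stats::rbinom(n * cfg$n_snps, 1L, ld_fidelity), n, cfg$n_snps)
    fresh <- matrix(stats::rbinom(n * cfg$n_snps, 1L,
                                  rep(f, each = n)), n, cfg$n_snps)
    dos <- dos + ifelse(keep == 1L, z, fresh)
  }
  snp_id <- sprintf("snp%05d", seq_len(cfg$n_snps))
  dimnames(dos) <- list(sprintf("s%03d", seq_len(n)), snp_id)
  fhat <- colMeans(dos) / 2
  geno <- list(dosages = dos,
               snps = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                                 maf = pmin(fhat, 1 - fhat)))
  class(geno) <- "genotype_table"
  geno
}

#' Simulate a bimodal methylation matrix with planted cis effects
#'
#' Each probe gets a latent baseline drawn from a two-component mixture on
#' the logit scale (so marginal beta values are bimodal, as on methylation
#' arrays). For a `causal_fraction` of probes a nearby SNP is chosen and its
#' dosage shifts the latent value of every probe within
#' `regional_effect_span` of the causal CpG (boxcar decay by default).
#' Hidden confounders add a low-rank term; unit-sd Gaussian noise completes
#' the latent value, which is mapped through the inverse logit to (0, 1).
#'
#' @param geno a `genotype_table` from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @param decay `"boxcar"` (constant within the span) or `"gaussian"`
#'   (weight `exp(-d^2 / (2 (span/2)^2))`).
#' @param max_causal_dist bp; causal SNPs are drawn among SNPs within this
#'   distance of the probe so that planted pairs are inside the cis window.
#' @return list with `beta` (samples x probes matrix in (0,1)), `manifest`
#'   (probe_id, chrom, pos, annotation), and `truth` (list: `causal_pairs`
#'   data.frame probe_id/snp_id/effect, `affected` data.frame of every probe
#'   receiving each causal SNP's effect with its weight,
#'   `confounder_loadings`, `shared_qtl_snps`).
#' @export
simulate_methylation <- function(geno, cfg, decay = c("boxcar", "gaussian"),
                                 max_causal_dist = 1000) {
  stopifnot(inherits(geno, "genotype_table"), inherits(cfg, "sim_config"))
  decay <- match.arg(decay)
  if (ncol(geno$dosages) == 0) .stopf("empty genotype table")
  if (cfg$causal_fraction > 1) .stopf("causal_fraction must be <= 1")
  set.seed(cfg$seed + 1L)
  n <- nrow(geno$dosages); P <- cfg$n_probes
  chrom <- geno$snps$chrom[1]

  probe_pos <- sort(sample.int(cfg$region_length, P, replace = FALSE))
  probe_id <- sprintf("cg%05d", seq_len(P))
  manifest <- data.frame(probe_id = probe_id, chrom = chrom, pos = probe_pos,
                         annotation = sample(c("promoter", "enhancer", "insulator", "other"),
                                             P, replace = TRUE,
                                             prob = c(0.25, 0.2, 0.05, 0.5)))

  # bimodal baselines: mostly near-unmethylated or near-methylated probes
  comp <- stats::rbinom(P, 1L, 0.5)
  base <- stats::rnorm(P, mean = ifelse(comp == 1L, 2.5, -2.5), sd = 0.6)

  latent <- matrix(stats::rnorm(n * P), n, P)  # unit residual sd
  latent <- sweep(latent, 2, base, "+")

  L <- NULL
  if (cfg$n_confounders > 0) {
    L <- matrix(stats::rnorm(n * cfg$n_confounders), n, cfg$n_confounders)
    W <- matrix(stats::rnorm(cfg$n_confounders * P, sd = cfg$confounder_sd),
                cfg$n_confounders, P)
    latent <- latent + L %*% W
  }

  n_causal <- round(cfg$causal_fraction * P)
  causal_pairs <- data.frame(probe_id = character(0), snp_id = character(0),
                             effect = numeric(0))
  affected <- data.frame(probe_id = character(0), snp_id = character(0),
                         effect = numeric(0), weight = numeric(0),
                         causal = logical(0))
  if (n_causal > 0 && cfg$effect_size > 0) {
    # eligible probes have at least one SNP within max_causal_dist
    nearest <- vapply(probe_pos, function(p) min(abs(geno$snps$pos - p)), numeric(1))
    eligible <- which(nearest <= max_causal_dist)
    if (length(eligible) < n_causal) {
      .warnf("only %d probes have a SNP within %d bp; planting %d causal effects",
             length(eligible), max_causal_dist, length(eligible))
      n_causal <- length(eligible)
    }
    # meQTL loci are sparse and distinct: thin the causal set so no two
    # regional spans overlap (interfering opposite-sign effects would make
    # the planted truth ambiguous)
    min_sep <- 2 * cfg$regional_effect_span
    cand <- sample(eligible)
    causal_idx <- integer(0)
    for (j in cand) {
      if (length(causal_idx) == n_causal) break
      if (!length(causal_idx) ||
          all(abs(probe_pos[causal_idx] - probe_pos[j]) > min_sep))
        causal_idx <- c(causal_idx, j)
    }
    if (length(causal_idx) < n_causal) {
      .warnf("could only place %d non-overlapping causal effects of %d requested",
             length(causal_idx), n_causal)
      n_causal <- length(causal_idx)
    }
    causal_idx <- sort(causal_idx)
    sgn <- sample(c(-1, 1), n_causal, replace = TRUE)
    snp_idx <- vapply(causal_idx, function(j) {
      cand <- which(abs(geno$snps$pos - probe_pos[j]) <= max_causal_dist)
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    causal_pairs <- data.frame(probe_id = probe_id[causal_idx],
                               snp_id = geno$snps$snp_id[snp_idx],
                               effect = sgn * cfg$effect_size)
    aff <- vector("list", n_causal)
    for (k in seq_len(n_causal)) {
      d <- abs(probe_pos - probe_pos[causal_idx[k]])
      if (decay == "boxcar") {
        hit <- which(d <= cfg$regional_effect_span)
        w <- rep(1, length(hit))
      } else {
        hit <- which(d <= 3 * cfg$regional_effect_span)
        w <- exp(-d[hit]^2 / (2 * (cfg$regional_effect_span / 2)^2))
      }
      eff <- causal_pairs$effect[k]
      dos <- geno$dosages[, snp_idx[k]]
      latent[, hit] <- latent[, hit] + outer(dos, w * eff)
      aff[[k]] <- data.frame(probe_id = probe_id[hit],
                             snp_id = causal_pairs$snp_id[k],
                             effect = eff, weight = w,
                             causal = hit == causal_idx[k])
    }
    affected <- do.call(rbind, aff)
  }

  beta <- stats::plogis(latent)
  dimnames(beta) <- list(rownames(geno$dosages), probe_id)
  truth <- list(causal_pairs = causal_pairs, affected = affected,
                confounder_loadings = L, shared_qtl_snps = character(0))
  list(beta = beta, manifest = manifest, truth = truth)
}

#' Simulate bisulfite sequencing read counts
#'
#' Per (sample, CpG), total reads are Poisson with the given mean coverage
#' and methylated counts are binomial with success probability equal to the
#' true methylation fraction adjusted for conversion failure: an unconverted
#' unmethylated cytosine reads as methylated, so the observed-methylated
#' probability is `beta + (1 - beta) * (1 - conversion_efficiency)`.
#'
#' @param beta samples x probes matrix of methylation fractions in [0, 1].
#' @param manifest probe manifest giving each CpG's chrom and position.
#' @param mean_coverage mean reads per site per sample (study scale: 2.4).
#' @param conversion_efficiency fraction of unmethylated C successfully
#'   converted (study scale: > 0.99).
#' @param seed integer seed.
#' @param drop_uncovered drop rows with zero total reads (the on-disk
#'   convention for coverage files).
#' @return data.frame with sample_id, chrom, pos, n_meth, n_total.
#' @export
simulate_bisulfite_reads <- function(beta, manifest, mean_coverage = 2.4,
                                     conversion_efficiency = 0.99, seed = 1L,
                                     drop_uncovered = TRUE) {
  if (mean_coverage < 0) .stopf("mean_coverage must be >= 0")
  if (conversion_efficiency <= 0 || conversion_efficiency > 1)
    .stopf("conversion_efficiency must be in (0, 1]")
  stopifnot(identical(colnames(beta), manifest$probe_id))
  set.seed(seed)
  n <- nrow(beta); P <- ncol(beta)
  tot <- matrix(stats::rpois(n * P, mean_coverage), n, P)
  p_obs <- beta + (1 - beta) * (1 - conversion_efficiency)
  met <- matrix(stats::rbinom(n * P, as.vector(tot), as.vector(p_obs)), n, P)
  out <- data.frame(sample_id = rep(rownames(beta), P),
                    chrom = rep(manifest$chrom, each = n),
                    pos = rep(manifest$pos, each = n),
                    n_meth = as.vector(met), n_total = as.vector(tot))
  if (drop_uncovered) out <- out[out$n_total > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate quantitative phenotypes sharing QTLs with methylation
#'
#' One trait per selected SNP: `trait = dosage * effect * sign + noise`,
#' with a random recorded sign per trait so direction-classification tests
#' have ground truth. By default traits are driven by the methylation-causal
#' SNPs in `truth`, yielding a positive shared-QTL fixture.
#'
#' @param geno a `genotype_table`.
#' @param truth truth list from [simulate_methylation()]; ignored when
#'   `snp_ids` is given.
#' @param effect per-dosage-unit effect magnitude (trait sd units; noise has
#'   sd `noise_sd`).
#' @param noise_sd residual sd.
#' @param snp_ids optional explicit SNP set (one trait each).
#' @param seed integer seed.
#' @return list with `traits` (samples x traits matrix) and `info`
#'   (trait_id, snp_id, effect with its sign).
#' @export
simulate_linked_phenotype <- function(geno, truth = NULL, effect = 0.5,
                                      noise_sd = 1, snp_ids = NULL, seed = 1L) {
  if (is.null(snp_ids)) {
    if (is.null(truth) || nrow(truth$causal_pairs) == 0)
      .stopf("no shared-QTL SNPs: supply snp_ids or a truth table with causal pairs")
    snp_ids <- unique(truth$causal_pairs$snp_id)
  }
  stopifnot(all(snp_ids %in% colnames(geno$dosages)))
  set.seed(seed)
  k <- length(snp_ids)
  sgn <- sample(c(-1, 1), k, replace = TRUE)
  dos <- geno$dosages[, snp_ids, drop = FALSE]
  traits <- sweep(dos, 2, sgn * effect, "*") +
    matrix(stats::rnorm(nrow(dos) * k, sd = noise_sd), nrow(dos), k)
  trait_id <- sprintf("trait%04d", seq_len(k))
  colnames(traits) <- trait_id
  list(traits = traits,
       info = data.frame(trait_id = trait_id, snp_id = snp_ids,
                         effect = sgn * effect))
}

#' Simulate a motif/SNP binding fixture with methylation coupling
#'
#' Places `n_sites` motif instances, each overlapping one SNP whose two
#' alleles score differently under `pwm`. A probe is placed within
#' `probe_dist` of each SNP and its methylation is generated with latent
#' mean `coupling` times the individual's expected allele score
#' (`score_ref + dosage/2 * delta`), plus unit Gaussian noise, through the
#' inverse logit. Sites whose alleles score identically are excluded.
#'
#' @param pwm a [pwm()] object.
#' @param geno a `genotype_table`.
#' @param n_sites number of motif instances to attempt.
#' @param coupling signed latent effect per bit of predicted affinity.
#' @param seed integer seed.
#' @param probe_dist max distance from SNP to its coupled probe (bp).
#' @return list with `sites` (a `binding_site_snp` data.frame: chrom, start,
#'   end, strand, tf, snp_id, offset of the SNP within the genomic motif
#'   window, ref, alt, score_ref, score_alt, delta), `beta`, `manifest`,
#'   and `truth` (coupling, per-site probe).
#' @export
simulate_binding_fixture <- function(pwm, geno, n_sites = 50, coupling = -1,
                                     seed = 1L, probe_dist = 250) {
  stopifnot(inherits(pwm, "pwm"))
  w <- nrow(pwm$probs)
  if (w == 0) .stopf("pwm has width 0")
  set.seed(seed)
  n <- nrow(geno$dosages)
  bases <- c("A", "C", "G", "T")
  snp_take <- sample(ncol(geno$dosages), n_sites)

  rows <- vector("list", n_sites)
  ctx <- character(n_sites)
  for (i in seq_len(n_sites)) {
    si <- snp_take[i]
    offset <- sample.int(w, 1L) - 1L
    context <- sample(bases, w, replace = TRUE)
    ref <- context[offset + 1L]
    alt <- sample(setdiff(bases, ref), 1L)
    strand <- sample(c("+", "-"), 1L)
    start <- geno$snps$pos[si] - offset
    rows[[i]] <- data.frame(chrom = geno$snps$chrom[si], start = start,
                            end = start + w, strand = strand,
                            tf = pwm$name, snp_id = geno$snps$snp_id[si],
                            offset = offset, ref = ref, alt = alt)
    ctx[i] <- paste(context, collapse = "")
  }
  sites <- do.call(rbind, rows)
  scored <- allele_scores(sites, pwm, ref_context = ctx)
  keep <- scored$delta != 0
  scored <- scored[keep, , drop = FALSE]
  ctx <- ctx[keep]
  if (nrow(scored) == 0) .stopf("no site with distinct allele scores; widen the pwm")

  # coupled probes
  probe_pos <- scored$start + scored$offset +
    sample(seq(-probe_dist, probe_dist), nrow(scored), replace = TRUE)
  probe_id <- sprintf("cgTF%04d", seq_len(nrow(scored)))
  manifest <- data.frame(probe_id = probe_id, chrom = scored$chrom,
                         pos = pmax(probe_pos, 0), annotation = "other")
  dos <- geno$dosages[, scored$snp_id, drop = FALSE]
  affinity <- sweep(sweep(dos / 2, 2, scored$delta, "*"), 2, scored$score_ref, "+")
  latent <- coupling * scale(affinity, scale = FALSE) +
    matrix(stats::rnorm(n * nrow(scored)), n)
  beta <- stats::plogis(latent)
  dimnames(beta) <- list(rownames(geno$dosages), probe_id)
  list(sites = scored, beta = beta, manifest = manifest,
       truth = data.frame(snp_id = scored$snp_id, probe_id = probe_id,
                          delta = scored$delta, coupling = coupling),
       ref_context = ctx)
}
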