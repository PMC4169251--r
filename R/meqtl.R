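# Cis meQTL mapping: windowed association scan by ordinary least squares,
# Storey q-value FDR control, lead-SNP calling, candidate-causal filtering,
# and the audit of correlation between nearby meQTL probes.

# Build (probe, SNP) cis pairs within `window` bp on shared chromosomes.
# Returns integer index vectors into the probe and SNP tables.
.cis_pairs <- function(manifest, snps, window) {
  pi <- integer(0); si <- integer(0)
  for (ch in intersect(unique(manifest$chrom), unique(snps$chrom))) {
    p_idx <- which(manifest$chrom == ch)
    s_idx <- which(snps$chrom == ch)
    sp <- snps$pos[s_idx]
    o <- order(sp)
    s_idx <- s_idx[o]; sp <- sp[o]
    lo <- findInterval(manifest$pos[p_idx] - window - 0.5, sp) + 1L
    hi <- findInterval(manifest$pos[p_idx] + window + 0.5, sp)
    n_each <- pmax(hi - lo + 1L, 0L)
    keep <- n_each > 0L
    if (!any(keep)) next
    pi <- c(pi, rep(p_idx[keep], n_each[keep]))
    si <- c(si, s_idx[unlist(mapply(seq.int, lo[keep], hi[keep],
                                    SIMPLIFY = FALSE), use.names = FALSE)])
  }
  list(probe = pi, snp = si)
}

#' Cis association scan between methylation and genotype dosage
#'
#' For every (probe, SNP) pair with `|snp_pos - cpg_pos| <= window` and SNP
#' minor allele frequency strictly above `maf_min`, fits
#' `methylation ~ intercept + dosage` by ordinary least squares and reports
#' the slope, its standard error, the t statistic, and the two-sided
#' p-value on `n - 2` degrees of freedom. Pairs whose dosage vector has
#' zero variance are skipped (with a message). Pooled Storey q-values over
#' all tests in the scan are appended.
#'
#' @param meth a `normalized_methylation` object or samples x probes matrix.
#' @param geno a `genotype_table`.
#' @param manifest probe manifest restricted to the probes to scan.
#' @param window max SNP-CpG distance in bp (default 3000, i.e. a 6 kb
#'   window centered on the probe; the boundary is inclusive).
#' @param maf_min minor allele frequency threshold (strict inequality).
#' @param qvalues append pooled q-values (set `FALSE` to defer FDR control).
#' @return an association data.frame: probe_id, snp_id, cpg_pos, snp_pos,
#'   distance, effect, se, t_stat, p_value, q_value, direction.
#' @export
cis_scan <- function(meth, geno, manifest, window = 3000, maf_min = 0.05,
                     qvalues = TRUE) {
  if (window <= 0) .stopf("window must be positive")
  values <- .meth_values(meth)
  al <- .align_samples(geno, values)
  n <- nrow(al$values)
  if (n < 4) .stopf("fewer than 4 samples")

  snps <- geno$snps
  pass <- snps$maf > maf_min
  if (!any(pass)) {
    .warnf("no SNP passes the MAF filter (> %g); empty scan", maf_min)
    return(.empty_assoc())
  }
  snps <- snps[pass, , drop = FALSE]
  X <- al$dosages[, pass, drop = FALSE]

  manifest <- manifest[manifest$probe_id %in% colnames(al$values), , drop = FALSE]
  pr <- .cis_pairs(manifest, snps, window)
  if (!length(pr$probe)) return(.empty_assoc())

  Y <- al$values[, manifest$probe_id, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sx2 <- colSums(Xc^2)
  sy2 <- colSums(Yc^2)

  zerovar <- sx2[pr$snp] == 0
  if (any(zerovar)) {
    message(sum(zerovar), " pair(s) skipped: dosage vector has zero variance")
    pr$probe <- pr$probe[!zerovar]; pr$snp <- pr$snp[!zerovar]
  }
  if (!length(pr$probe)) return(.empty_assoc())

  m <- length(pr$probe)
  sxy <- numeric(m)
  chunk <- 200000L
  for (st in seq(1L, m, by = chunk)) {
    en <- min(st + chunk - 1L, m)
    ii <- st:en
    sxy[ii] <- colSums(Xc[, pr$snp[ii], drop = FALSE] *
                         Yc[, pr$probe[ii], drop = FALSE])
  }
  slope <- sxy / sx2[pr$snp]
  rss <- pmax(sy2[pr$probe] - sxy^2 / sx2[pr$snp], 0)
  se <- sqrt(rss / ((n - 2) * sx2[pr$snp]))
  t_stat <- ifelse(se > 0, slope / se, sign(slope) * Inf)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)

  out <- data.frame(probe_id = manifest$probe_id[pr$probe],
                    snp_id = snps$snp_id[pr$snp],
                    cpg_pos = manifest$pos[pr$probe],
                    snp_pos = snps$pos[pr$snp],
                    distance = abs(snps$pos[pr$snp] - manifest$pos[pr$probe]),
                    effect = slope, se = se, t_stat = t_stat, p_value = p,
                    q_value = NA_real_, direction = sign(slope))
  if (qvalues && nrow(out))
    out$q_value <- estimate_qvalues(out$p_value)$q_values
  out
}

.empty_assoc <- function() {
  data.frame(probe_id = character(0), snp_id = character(0),
             cpg_pos = numeric(0), snp_pos = numeric(0), distance = numeric(0),
             effect = numeric(0), se = numeric(0), t_stat = numeric(0),
             p_value = numeric(0), q_value = numeric(0), direction = numeric(0))
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' Estimates the null proportion pi0 on the lambda grid
#' `mean(p > lambda) / (1 - lambda)`, smooths the profile with a cubic
#' smoothing spline and extrapolates at the largest lambda, clipping the
#' estimate to (0, 1]. q-values are the step-up tail minima
#' `min_{p_(j) >= p_(i)} pi0 * m * p_(j) / j`; with `pi0 = 1` the result is
#' exactly the Benjamini-Hochberg adjusted p-value. For inputs too small to
#' estimate pi0 stably (fewer than 100 p-values) pi0 defaults to 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param pi0 optionally force the null proportion (e.g. `1` for BH).
#' @param lambda grid for the pi0 profile.
#' @return list with `q_values` (same order as `p`) and `pi0`.
#' @export
estimate_qvalues <- function(p, pi0 = NULL,
                             lambda = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p)) return(list(q_values = numeric(0), pi0 = NA_real_))
  if (anyNA(p) || any(p < 0 | p > 1)) .stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- 1
    } else {
      prof <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      pi0 <- tryCatch({
        fit <- stats::smooth.spline(lambda, prof, df = 3)
        stats::predict(fit, x = max(lambda))$y
      }, error = function(e) 1)
      pi0 <- min(pi0, 1)
      if (!is.finite(pi0)) pi0 <- 1
      if (pi0 <= 0)  # clip to (0, 1]: fall back to the smallest positive profile point
        pi0 <- if (any(prof > 0)) min(prof[prof > 0], 1) else .Machine$double.eps
    }
  }
  if (pi0 <= 0 || pi0 > 1) .stopf("pi0 must be in (0, 1]")
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / seq(m, 1)))[ro]
  list(q_values = q, pi0 = pi0)
}

#' Call meQTL probes and their lead SNPs
#'
#' A probe is a meQTL probe when its smallest q-value is at or below `fdr`.
#' Per probe only the single most significant SNP is retained as the lead
#' (ties broken by smaller SNP-CpG distance, then smaller SNP position), so
#' the count of rows is the count of meQTL CpG sites.
#'
#' @param assoc association table from [cis_scan()] with q-values populated.
#' @param fdr FDR level (default 0.10).
#' @return data.frame with one row per meQTL probe: probe_id, snp_id,
#'   distance, effect, p_value, q_value; attribute `fdr`.
#' @export
call_meqtls <- function(assoc, fdr = 0.10) {
  if (nrow(assoc) == 0 || all(is.na(assoc$q_value)))
    .stopf("q_value column must be populated (run cis_scan or estimate_qvalues)")
  sig_probes <- unique(assoc$probe_id[assoc$q_value <= fdr])
  if (!length(sig_probes)) {
    out <- assoc[integer(0), c("probe_id", "snp_id", "distance", "effect",
                               "p_value", "q_value")]
    attr(out, "fdr") <- fdr
    return(out)
  }
  sub <- assoc[assoc$probe_id %in% sig_probes, , drop = FALSE]
  o <- order(sub$probe_id, sub$p_value, sub$distance, sub$snp_pos)
  sub <- sub[o, , drop = FALSE]
  lead <- sub[!duplicated(sub$probe_id),
              c("probe_id", "snp_id", "distance", "effect", "p_value", "q_value")]
  rownames(lead) <- NULL
  attr(lead, "fdr") <- fdr
  lead
}

#' Flag candidate causal meQTL SNPs by p-value gap
#'
#' Within a widened window around each probe, a lead SNP is a candidate
#' causal variant when its p-value is at least `gap_orders` orders of
#' magnitude smaller than the second-best SNP's (boundary inclusive).
#' Probes with a single tested SNP are excluded (no second p-value) and
#' counted in the attribute `n_single_snp`.
#'
#' @param assoc_wide association table computed with the widened window
#'   (i.e. [cis_scan()] with `window = wide_window / 2`).
#' @param gap_orders required log10 p-value gap (default 2).
#' @param wide_window full width in bp of the window used for `assoc_wide`
#'   (recorded for reporting; default 10000).
#' @return data.frame (probe_id, snp_id, log10_gap, distance) with
#'   attributes `median_distance`, `frac_beyond_3kb`, `n_single_snp`.
#' @export
find_candidate_causal <- function(assoc_wide, gap_orders = 2,
                                  wide_window = 10000) {
  if (nrow(assoc_wide) == 0) .stopf("empty association table")
  o <- order(assoc_wide$probe_id, assoc_wide$p_value, assoc_wide$distance,
             assoc_wide$snp_pos)
  a <- assoc_wide[o, , drop = FALSE]
  first <- !duplicated(a$probe_id)
  n_per <- table(a$probe_id)
  lead <- a[first, , drop = FALSE]
  second_idx <- which(first) + 1L
  has_second <- lead$probe_id %in% names(n_per)[n_per >= 2]
  n_single <- sum(!has_second)
  if (n_single)
    message(n_single, " probe(s) with a single tested SNP excluded from the causal filter")
  lead <- lead[has_second, , drop = FALSE]
  second_p <- a$p_value[second_idx[has_second]]
  gap <- log10(second_p) - log10(lead$p_value)
  is_cand <- gap >= gap_orders
  out <- data.frame(probe_id = lead$probe_id[is_cand],
                    snp_id = lead$snp_id[is_cand],
                    log10_gap = gap[is_cand],
                    distance = lead$distance[is_cand])
  rownames(out) <- NULL
  attr(out, "median_distance") <- if (nrow(out)) stats::median(out$distance) else NA_real_
  attr(out, "frac_beyond_3kb") <- if (nrow(out)) mean(out$distance > 3000) else NA_real_
  attr(out, "n_single_snp") <- n_single
  attr(out, "wide_window") <- wide_window
  out
}

#' Correlation between nearby meQTL probes
#'
#' For every pair of meQTL probes within `max_dist` of each other, computes
#' the Pearson correlation across samples and its t-test p-value, on the
#' normalized matrix and (optionally) the untransformed beta matrix, and
#' counts the probes appearing in at least one significant pair -- the
#' audit that the meQTL count is not inflated by correlated neighboring
#' probes.
#'
#' @param norm_values samples x probes matrix on the normalized scale.
#' @param meqtls meQTL set from [call_meqtls()].
#' @param manifest probe manifest.
#' @param raw_values optional samples x probes matrix of untransformed
#'   beta values.
#' @param max_dist bp (default 5000).
#' @param alpha significance level for the pair test.
#' @return list with `pairs` (probe_a, probe_b, distance, r_norm, p_norm
#'   and, when raw values are given, r_raw, p_raw), `n_pairs`,
#'   `n_sig_probes_normalized`, `n_sig_probes_untransformed` (NA without
#'   raw values).
#' @export
probe_pair_correlation <- function(norm_values, meqtls, manifest,
                                   raw_values = NULL, max_dist = 5000,
                                   alpha = 0.05) {
  ids <- intersect(meqtls$probe_id, colnames(norm_values))
  if (length(ids) < 2) .stopf("need at least 2 meQTL probes")
  mf <- manifest[match(ids, manifest$probe_id), , drop = FALSE]
  pairs <- list()
  for (ch in unique(mf$chrom)) {
    idx <- which(mf$chrom == ch)
    o <- idx[order(mf$pos[idx])]
    for (ii in seq_along(o)) {
      jj <- ii + 1L
      while (jj <= length(o) && mf$pos[o[jj]] - mf$pos[o[ii]] <= max_dist) {
        pairs[[length(pairs) + 1L]] <- c(o[ii], o[jj])
        jj <- jj + 1L
      }
    }
  }
  if (!length(pairs)) {
    return(list(pairs = data.frame(), n_pairs = 0L,
                n_sig_probes_normalized = 0L,
                n_sig_probes_untransformed = if (is.null(raw_values)) NA_integer_ else 0L))
  }
  pm <- do.call(rbind, pairs)
  a <- ids[pm[, 1]]; b <- ids[pm[, 2]]
  n <- nrow(norm_values)
  corp <- function(values) {
    r <- vapply(seq_along(a),
                function(k) stats::cor(values[, a[k]], values[, b[k]]), numeric(1))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    list(r = r, p = p)
  }
  cn <- corp(norm_values)
  out <- data.frame(probe_a = a, probe_b = b,
                    distance = abs(mf$pos[pm[, 2]] - mf$pos[pm[, 1]]),
                    r_norm = cn$r, p_norm = cn$p)
  sig_n <- length(unique(c(a[cn$p < alpha], b[cn$p < alpha])))
  sig_r <- NA_integer_
  if (!is.null(raw_values)) {
    cr <- corp(raw_values)
    out$r_raw <- cr$r; out$p_raw <- cr$p
    sig_r <- length(unique(c(a[cr$p < alpha], b[cr$p < alpha])))
  }
  list(pairs = out, n_pairs = nrow(out),
       n_sig_probes_normalized = sig_n, n_sig_probes_untransformed = sig_r)
}
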