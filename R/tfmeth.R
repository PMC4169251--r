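# Transcription-factor binding and methylation: PWM log-odds scoring of
# SNP alleles inside motif instances, association of predicted affinity
# with methylation within 500 bp, and TF-expression-methylation correlation
# near binding sites.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Rows are motif positions, columns base probabilities for A, C, G, T.
#' Counts or probabilities are accepted; rows are normalized and a
#' pseudocount is spread over the four bases so no probability is zero
#' (`(p + pseudocount) / (1 + 4 * pseudocount)` per row).
#'
#' @param probs width x 4 numeric matrix (columns A, C, G, T) of
#'   probabilities or counts.
#' @param name motif/TF name.
#' @param background base frequencies (must sum to 1; default uniform).
#' @param pseudocount probability mass added per base (default 1e-3; use 0
#'   for exact toy matrices).
#' @return a `pwm` object.
#' @export
pwm <- function(probs, name = "motif", background = rep(0.25, 4),
                pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (nrow(probs) == 0) .stopf("pwm width must be positive")
  if (ncol(probs) != 4) .stopf("pwm must have 4 columns (A, C, G, T)")
  if (abs(sum(background) - 1) > 1e-6) .stopf("background must sum to 1")
  if (pseudocount < 0) .stopf("pseudocount must be >= 0")
  p <- probs / rowSums(probs)
  p <- (p + pseudocount) / (1 + 4 * pseudocount)
  colnames(p) <- BASES
  structure(list(name = name, probs = p, background = background,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Log-odds PWM score of a sequence
#'
#' `sum_i log2(p(b_i, i) / background(b_i))` over the motif positions; the
#' score of a sequence drawn from the background model is 0 bits in
#' expectation under a uniform PWM.
#'
#' @param pwm a [pwm()] object.
#' @param sequence character string (or vector of bases) of length equal
#'   to the motif width, over A/C/G/T. Ambiguous bases are an error; mask
#'   such sites upstream.
#' @return score in bits.
#' @export
pwm_score <- function(pwm, sequence) {
  stopifnot(inherits(pwm, "pwm"))
  b <- if (length(sequence) == 1L) strsplit(toupper(sequence), "")[[1]] else toupper(sequence)
  w <- nrow(pwm$probs)
  if (length(b) != w) .stopf("sequence length %d != motif width %d", length(b), w)
  idx <- match(b, BASES)
  if (anyNA(idx)) .stopf("ambiguous or invalid base in sequence: %s",
                         paste(b[is.na(idx)], collapse = ","))
  sum(log2(pwm$probs[cbind(seq_len(w), idx)] / pwm$background[idx]))
}

#' Score both alleles of SNPs inside motif instances
#'
#' For each site, substitutes the reference and alternate base at the
#' SNP's offset within the genomic motif window and scores the window on
#' the annotated motif strand (minus-strand windows are
#' reverse-complemented before scoring, which reverse-complements the
#' substituted allele). `delta = score_alt - score_ref`.
#'
#' @param sites data.frame with chrom, start, end, strand, tf, snp_id,
#'   offset (0-based position of the SNP within the plus-strand genomic
#'   window), ref, alt (single bases; indels are rejected).
#' @param pwm a [pwm()] object (or named list of pwm objects keyed by the
#'   `tf` column).
#' @param ref_context character vector of plus-strand genomic window
#'   sequences, one per site, of length equal to the motif width.
#' @return a `binding_site_snp` data.frame: the input plus score_ref,
#'   score_alt, delta (bits).
#' @export
allele_scores <- function(sites, pwm, ref_context) {
  stopifnot(nrow(sites) == length(ref_context))
  pwms <- if (inherits(pwm, "pwm")) stats::setNames(list(pwm), pwm$name) else pwm
  out <- sites
  out$score_ref <- NA_real_; out$score_alt <- NA_real_
  for (i in seq_len(nrow(sites))) {
    if (nchar(sites$ref[i]) != 1L || nchar(sites$alt[i]) != 1L)
      .stopf("site %d: indel alleles are not supported (SNVs only)", i)
    pw <- if (inherits(pwm, "pwm")) pwm else pwms[[sites$tf[i]]]
    if (is.null(pw)) .stopf("no PWM supplied for TF '%s'", sites$tf[i])
    w <- nrow(pw$probs)
    ctx <- strsplit(toupper(ref_context[i]), "")[[1]]
    if (length(ctx) != w) .stopf("site %d: context length != motif width", i)
    off <- sites$offset[i]
    if (off < 0 || off >= w) .stopf("site %d: SNP offset outside the motif", i)
    score1 <- function(allele) {
      s <- ctx; s[off + 1L] <- toupper(allele)
      s <- paste(s, collapse = "")
      if (identical(sites$strand[i], "-")) s <- .revcomp(s)
      pwm_score(pw, s)
    }
    out$score_ref[i] <- score1(sites$ref[i])
    out$score_alt[i] <- score1(sites$alt[i])
  }
  out$delta <- out$score_alt - out$score_ref
  class(out) <- c("binding_site_snp", class(out))
  out
}

# probes within `window` bp of the interval [start, end) on the same chrom
.probes_near_interval <- function(manifest, chrom, start, end, window) {
  d_left <- start - manifest$pos
  d_right <- manifest$pos - (end - 1)
  which(manifest$chrom == chrom & pmax(d_left, d_right, 0) <= window)
}

#' Associate predicted binding-affinity changes with methylation
#'
#' Per individual the predicted-affinity covariate at a site is the
#' dosage-weighted mean allele score `score_ref + (dosage / 2) * delta`,
#' which is affine in dosage, so the test is the dosage regression up to
#' scale -- but the sign follows the PWM score: a positive slope means
#' higher predicted affinity goes with higher methylation. Each site is
#' tested against every probe within `window` bp of the motif; q-values
#' are computed per TF over that TF's tests, and a SNP counts as
#' significant when any of its probes passes.
#'
#' @param sites a `binding_site_snp` data.frame from [allele_scores()].
#' @param meth normalized methylation (two-stage, no PC removal).
#' @param geno a `genotype_table`.
#' @param manifest probe manifest.
#' @param window bp from motif to probe (default 500).
#' @param fdr FDR level for the per-TF summary (default 0.10).
#' @return list: assoc (site-probe association rows with slope, t, p, q),
#'   summary (per TF: n_snps, n_tested, prop_significant, n_positive,
#'   n_negative among significant SNPs).
#' @export
binding_snp_meth_assoc <- function(sites, meth, geno, manifest, window = 500,
                                   fdr = 0.10) {
  values <- .meth_values(meth)
  al <- .align_samples(geno, values)
  n <- nrow(al$values)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    snp <- sites$snp_id[i]
    j <- match(snp, geno$snps$snp_id)
    if (is.na(j)) .stopf("site SNP %s absent from the genotype table", snp)
    dos <- al$dosages[, j]
    covar <- sites$score_ref[i] + dos / 2 * sites$delta[i]
    if (stats::var(covar) == 0) next  # delta 0 or monomorphic: skip
    hits <- .probes_near_interval(manifest, sites$chrom[i], sites$start[i],
                                  sites$end[i], window)
    if (!length(hits)) next
    xc <- covar - mean(covar)
    sx2 <- sum(xc^2)
    for (h in hits) {
      y <- al$values[, manifest$probe_id[h]]
      yc <- y - mean(y)
      sxy <- sum(xc * yc)
      slope <- sxy / sx2
      rss <- max(sum(yc^2) - sxy^2 / sx2, 0)
      se <- sqrt(rss / ((n - 2) * sx2))
      tt <- if (se > 0) slope / se else sign(slope) * Inf
      rows[[length(rows) + 1L]] <-
        data.frame(tf = sites$tf[i], snp_id = snp,
                   probe_id = manifest$probe_id[h],
                   effect = slope, t_stat = tt,
                   p_value = 2 * stats::pt(-abs(tt), df = n - 2))
    }
  }
  if (!length(rows))
    return(list(assoc = data.frame(), summary = data.frame()))
  assoc <- do.call(rbind, rows)
  assoc$q_value <- NA_real_
  summ <- list()
  for (tf in unique(assoc$tf)) {
    sel <- assoc$tf == tf
    assoc$q_value[sel] <- estimate_qvalues(assoc$p_value[sel])$q_values
    sub <- assoc[sel, , drop = FALSE]
    o <- order(sub$snp_id, sub$p_value)
    lead <- sub[o, ][!duplicated(sub$snp_id[o]), , drop = FALSE]
    minq <- vapply(split(sub$q_value, sub$snp_id), min, numeric(1))
    sig <- minq[lead$snp_id] <= fdr
    dirs <- classify_direction(lead$effect[sig])
    summ[[length(summ) + 1L]] <-
      data.frame(tf = tf, n_snps = sum(sites$tf == tf), n_tested = nrow(lead),
                 prop_significant = mean(sig),
                 n_positive = dirs[["n_positive"]],
                 n_negative = dirs[["n_negative"]])
  }
  list(assoc = assoc, summary = do.call(rbind, summ))
}

#' Matched permutation null for per-TF binding enrichment
#'
#' Resamples matched numbers of SNPs from the universe of binding-site
#' SNPs with a probe within `window` bp and recomputes the significant
#' proportion on each draw (q-values per draw), giving the null mean and
#' the `(b + 1) / (B + 1)` empirical p-value for one TF's observed
#' proportion.
#'
#' @param observed observed per-TF significant proportion.
#' @param n_fg number of SNPs in the TF's foreground.
#' @param universe_assoc association rows (from
#'   [binding_snp_meth_assoc()]`$assoc`) over the universe sites.
#' @param B,seed,fdr as in [matched_permutation_null()].
#' @return list: null, null_mean, empirical_p, B.
#' @export
binding_matched_null <- function(observed, n_fg, universe_assoc, B = 999,
                                 seed = 1L, fdr = 0.10) {
  if (B <= 0) .stopf("B must be positive")
  p_list <- .p_by_snp(universe_assoc)
  if (n_fg > length(p_list)) .stopf("n_fg exceeds the universe size")
  set.seed(seed)
  null <- replicate(B, {
    ids <- sample(names(p_list), n_fg)
    .draw_prop_significant(p_list, ids, fdr)
  })
  list(null = null, null_mean = mean(null),
       empirical_p = (sum(null >= observed) + 1) / (B + 1), B = B)
}

#' Correlate TF expression with methylation near its binding sites
#'
#' Pearson correlation between a TF's per-sample expression (RPKM,
#' quantile-normalized) and methylation at each probe within `window` bp
#' of any of the TF's binding sites, using two-stage-normalized
#' methylation without PC removal (a trans effect of TF abundance would be
#' absorbed by PCs). A pointwise null band for the ordered -log10 p-values
#' is built by permuting the expression vector.
#'
#' @param expr numeric vector of per-sample expression, aligned to the
#'   methylation rows (names matched when present).
#' @param meth normalized methylation without PC removal.
#' @param sites data.frame of binding-site intervals (chrom, start, end).
#' @param manifest probe manifest.
#' @param window bp (default 500).
#' @param n_perm permutations for the null band (0 disables).
#' @param seed integer seed.
#' @return list: table (probe_id, r, p_value), null_band (rank, lo, hi of
#'   ordered -log10 p at 2.5/97.5 percentiles), n_perm.
#' @export
tf_expression_meth_assoc <- function(expr, meth, sites, manifest,
                                     window = 500, n_perm = 0, seed = 1L) {
  values <- .meth_values(meth)
  if (!is.null(names(expr)) && !is.null(rownames(values))) {
    common <- intersect(names(expr), rownames(values))
    expr <- expr[common]; values <- values[common, , drop = FALSE]
  }
  if (length(expr) != nrow(values))
    .stopf("expression vector not aligned to methylation samples")
  if (stats::var(expr) == 0) .stopf("expression vector has zero variance")
  hits <- integer(0)
  for (i in seq_len(nrow(sites)))
    hits <- c(hits, .probes_near_interval(manifest, sites$chrom[i],
                                          sites$start[i], sites$end[i], window))
  hits <- sort(unique(hits))
  probes <- intersect(manifest$probe_id[hits], colnames(values))
  if (!length(probes)) .stopf("no probe within %d bp of any binding site", window)
  Y <- values[, probes, drop = FALSE]
  n <- nrow(Y)
  pvec <- function(x) {
    r <- as.vector(stats::cor(x, Y))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
  }
  obs <- pvec(expr)
  tab <- data.frame(probe_id = probes, r = obs$r, p_value = obs$p)
  band <- NULL
  if (n_perm > 0) {
    set.seed(seed)
    mat <- replicate(n_perm, sort(-log10(pvec(sample(expr))$p), decreasing = TRUE))
    band <- data.frame(rank = seq_along(probes),
                       lo = apply(mat, 1, stats::quantile, 0.025),
                       hi = apply(mat, 1, stats::quantile, 0.975))
  }
  list(table = tab, null_band = band, n_perm = n_perm)
}

#' Quantile-normalize an expression vector
#'
#' Rank-to-standard-normal transform of per-sample RPKM values, the
#' standardization used before correlating TF expression with methylation.
#'
#' @param x numeric vector (RPKM per sample).
#' @return normalized vector with the same names.
#' @export
normalize_expression <- function(x) {
  out <- rank_normal(x)
  names(out) <- names(x)
  out
}
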