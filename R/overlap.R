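# Cross-phenotype QTL sharing: test foreground SNP sets (eQTLs, dsQTLs,
# histone/PolII QTLs, GWAS hits) for association with nearby methylation,
# compare against a matched-count permutation null, classify effect
# directions, and test annotation enrichment of meQTL CpGs.

#' SNPs eligible for matched resampling
#'
#' The permutation universe: all SNPs passing the MAF filter that lie
#' within `window` bp of at least one methylation probe.
#'
#' @param geno a `genotype_table`.
#' @param manifest probe manifest.
#' @param window bp (default 3000).
#' @param maf_min MAF threshold (strict).
#' @return character vector of SNP ids.
#' @export
snp_universe <- function(geno, manifest, window = 3000, maf_min = 0.05) {
  snps <- geno$snps[geno$snps$maf > maf_min, , drop = FALSE]
  pr <- .cis_pairs(manifest, snps, window)
  sort(unique(snps$snp_id[pr$snp]))
}

# Split scan p-values by SNP id -> named list of numeric vectors.
.p_by_snp <- function(assoc) split(assoc$p_value, assoc$snp_id)

# Proportion of the drawn SNPs significant at `fdr` when q-values are
# computed over the draw's own pooled tests. Exploits monotonicity of the
# q transform: a SNP's min q is the q at its min p.
.draw_prop_significant <- function(p_list, ids, fdr) {
  sub <- p_list[ids]
  ps <- unlist(sub, use.names = FALSE)
  q <- estimate_qvalues(ps)$q_values
  grp <- rep.int(seq_along(sub), lengths(sub))
  minq <- vapply(split(q, grp), min, numeric(1))
  mean(minq <= fdr)
}

#' Test a foreground SNP set for association with nearby methylation
#'
#' Runs the cis regression for each foreground SNP against all probes
#' within `window` bp, computes Storey q-values over this foreground's
#' tests only (an independent FDR per foreground class), and reports the
#' fraction of SNPs with at least one association at `fdr`. Direction
#' counts use the sign of each significant SNP's most significant
#' methylation slope, multiplied by the foreground phenotype's effect sign
#' when provided.
#'
#' @param fg character vector of foreground SNP ids (must be in `geno`).
#' @param meth normalized methylation (object or matrix).
#' @param geno a `genotype_table`.
#' @param manifest probe manifest.
#' @param window bp (default 3000).
#' @param fdr FDR level (default 0.10).
#' @param fg_direction optional named numeric (+1/-1) per foreground SNP:
#'   the sign of the QTL effect on the foreground phenotype.
#' @param label foreground label for reporting.
#' @return an `enrichment_result` list: label, n_tested, prop_significant,
#'   n_positive, n_negative, snp_summary (per-SNP lead association),
#'   assoc (all tests). Null fields are added by
#'   [matched_permutation_null()] / [enrich_foreground()].
#' @export
test_foreground <- function(fg, meth, geno, manifest, window = 3000,
                            fdr = 0.10, fg_direction = NULL,
                            label = "foreground") {
  missing_snps <- setdiff(fg, geno$snps$snp_id)
  if (length(missing_snps))
    .stopf("%d foreground SNP(s) absent from the genotype table", length(missing_snps))
  sub <- .subset_geno(geno, fg)
  assoc <- cis_scan(meth, sub, manifest, window = window, maf_min = -1,
                    qvalues = TRUE)
  dropped <- setdiff(fg, unique(assoc$snp_id))
  if (length(dropped))
    .warnf("%d foreground SNP(s) with no probe within %d bp dropped from n_tested",
           length(dropped), window)
  if (nrow(assoc) == 0)
    return(structure(list(label = label, n_tested = 0L, prop_significant = NA_real_,
                          n_positive = 0L, n_negative = 0L,
                          snp_summary = data.frame(), assoc = assoc),
                     class = "enrichment_result"))
  o <- order(assoc$snp_id, assoc$p_value, assoc$distance)
  a <- assoc[o, , drop = FALSE]
  lead <- a[!duplicated(a$snp_id), , drop = FALSE]
  minq <- vapply(split(assoc$q_value, assoc$snp_id), min, numeric(1))
  lead$min_q <- minq[lead$snp_id]
  lead$significant <- lead$min_q <= fdr
  sig <- lead[lead$significant, , drop = FALSE]
  dirs <- classify_direction(sig$effect,
                             if (is.null(fg_direction)) NULL
                             else fg_direction[sig$snp_id])
  structure(list(label = label, n_tested = nrow(lead),
                 prop_significant = mean(lead$significant),
                 n_positive = dirs["n_positive"], n_negative = dirs["n_negative"],
                 snp_summary = lead, assoc = assoc, fdr = fdr),
            class = "enrichment_result")
}

.subset_geno <- function(geno, snp_ids) {
  idx <- match(snp_ids, geno$snps$snp_id)
  out <- list(dosages = geno$dosages[, idx, drop = FALSE],
              snps = geno$snps[idx, , drop = FALSE])
  class(out) <- "genotype_table"
  out
}

#' Matched-count permutation null for foreground enrichment
#'
#' Repeats the foreground test on `B` random SNP sets of the same size,
#' drawn without replacement from the universe of SNPs within `window` of a
#' probe, and returns the null distribution of the significant proportion
#' and the empirical p-value `(b + 1) / (B + 1)` where `b` counts null
#' proportions at or above the observed one (never exactly zero). With the
#' per-SNP cache enabled (default) the cis regressions are computed once
#' over the universe and only the per-draw q-values are recomputed, which
#' is exactly equivalent to rescanning each draw.
#'
#' @param observed observed significant proportion.
#' @param n_fg foreground size to match.
#' @param universe character vector of eligible SNP ids
#'   (see [snp_universe()]).
#' @param meth,geno,manifest,window,fdr as in [test_foreground()].
#' @param B number of permutations.
#' @param seed integer seed.
#' @param cache reuse one universe-wide scan across draws.
#' @return list: null (length-B proportions), null_mean, empirical_p, B.
#' @export
matched_permutation_null <- function(observed, n_fg, universe, meth, geno,
                                     manifest, window = 3000, fdr = 0.10,
                                     B = 999, seed = 1L, cache = TRUE) {
  if (B <= 0) .stopf("B must be positive")
  if (n_fg > length(universe)) .stopf("n_fg exceeds the universe size")
  set.seed(seed)
  draws <- replicate(B, sample(universe, n_fg), simplify = FALSE)
  if (cache) {
    sub <- .subset_geno(geno, universe)
    assoc <- cis_scan(meth, sub, manifest, window = window, maf_min = -1,
                      qvalues = FALSE)
    p_list <- .p_by_snp(assoc)
    null <- vapply(draws, function(ids) {
      ids <- ids[ids %in% names(p_list)]
      .draw_prop_significant(p_list, ids, fdr)
    }, numeric(1))
  } else {
    null <- vapply(draws, function(ids) {
      res <- suppressWarnings(
        test_foreground(ids, meth, geno, manifest, window = window, fdr = fdr))
      res$prop_significant
    }, numeric(1))
  }
  empirical_p <- (sum(null >= observed) + 1) / (B + 1)
  list(null = null, null_mean = mean(null), empirical_p = empirical_p, B = B)
}

#' Foreground enrichment with its permutation null
#'
#' Convenience wrapper running [test_foreground()] and
#' [matched_permutation_null()] and merging the results into a complete
#' enrichment record (the per-foreground row of a sharing summary table).
#'
#' @inheritParams test_foreground
#' @inheritParams matched_permutation_null
#' @param universe optional precomputed universe; defaults to
#'   [snp_universe()] with `maf_min = 0.05`.
#' @return an `enrichment_result` with null_mean, empirical_p, B filled in.
#' @export
enrich_foreground <- function(fg, meth, geno, manifest, window = 3000,
                              fdr = 0.10, B = 999, seed = 1L,
                              fg_direction = NULL, label = "foreground",
                              universe = NULL) {
  res <- test_foreground(fg, meth, geno, manifest, window = window, fdr = fdr,
                         fg_direction = fg_direction, label = label)
  if (is.null(universe))
    universe <- snp_universe(geno, manifest, window = window)
  nul <- matched_permutation_null(res$prop_significant, res$n_tested, universe,
                                  meth, geno, manifest, window = window,
                                  fdr = fdr, B = B, seed = seed)
  res$null <- nul$null
  res$null_mean <- nul$null_mean
  res$empirical_p <- nul$empirical_p
  res$B <- nul$B
  res
}

#' Classify association directions
#'
#' The direction of a shared QTL is the sign of the methylation slope
#' multiplied by the sign of the foreground phenotype effect when the
#' latter is supplied; zero slopes count as neither.
#'
#' @param slopes methylation slopes (one lead association per SNP).
#' @param fg_direction optional matching vector of foreground effect signs.
#' @return named integer vector `c(n_positive, n_negative)`.
#' @export
classify_direction <- function(slopes, fg_direction = NULL) {
  s <- sign(slopes)
  if (!is.null(fg_direction)) s <- s * sign(fg_direction)
  c(n_positive = sum(s > 0, na.rm = TRUE), n_negative = sum(s < 0, na.rm = TRUE))
}

#' Annotation enrichment of meQTL CpGs
#'
#' Builds the 2x2 contingency table (meQTL CpGs in/out of the feature
#' against all other probes in/out) and computes Pearson's chi-square
#' statistic without continuity correction, with its 1-df p-value and the
#' enrichment direction.
#'
#' @param meqtl_probes character vector of meQTL probe ids.
#' @param manifest probe manifest with an `annotation` column; the table is
#'   built over all probes in the manifest.
#' @param feature annotation label to test (e.g. `"promoter"`).
#' @return list: feature, table (2x2 matrix: rows meQTL/other, columns
#'   in/out of feature), chi_square, p_value, direction
#'   (`"enriched"`/`"depleted"`).
#' @export
annotation_enrichment <- function(meqtl_probes, manifest, feature) {
  if (!"annotation" %in% names(manifest))
    .stopf("manifest has no annotation column")
  is_meqtl <- manifest$probe_id %in% meqtl_probes
  in_feat <- manifest$annotation == feature
  a <- sum(is_meqtl & in_feat)
  b <- sum(!is_meqtl & in_feat)
  cc <- sum(is_meqtl & !in_feat)
  d <- sum(!is_meqtl & !in_feat)
  tab <- matrix(c(a, b, cc, d), 2, 2,
                dimnames = list(c("meQTL", "other"), c("in_feature", "out")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    .stopf("expected cell count below 1; use an exact test instead")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(feature = feature, table = tab,
       chi_square = unname(ct$statistic), p_value = ct$p.value,
       direction = if (a >= expected[1, 1]) "enriched" else "depleted")
}
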