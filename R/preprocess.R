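# Probe filtering, rank-based quantile normalization to a standard normal,
# and PCA confounder removal with data-driven choice of the number of PCs.

#' Rank-to-normal transform of a numeric vector
#'
#' Maps values to standard-normal quantiles at `(rank - 0.5) / n`, with
#' average ranks for ties; keeps extremes finite. A constant vector maps to
#' all zeros with a warning.
#'
#' @param x numeric vector without missing values.
#' @return numeric vector of the same length on the standard-normal scale.
#' @export
rank_normal <- function(x) {
  if (anyNA(x)) .stopf("missing values are not allowed; impute or drop them first")
  n <- length(x)
  if (n == 0) return(numeric(0))
  if (length(unique(x)) == 1L) {
    .warnf("constant vector: all values map to 0")
    return(rep(0, n))
  }
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

#' Quantile-normalize a beta matrix to a standard normal
#'
#' The default `two_stage` strategy rank-normalizes across all probes within
#' each individual, and then across all individuals at each probe, so that
#' every probe column carries exact standard-normal scores. `by_individual`
#' and `by_probe` apply only the respective stage; `none` returns the input
#' untouched. All strategies are rank-preserving along the normalized axis.
#'
#' @param beta samples x probes matrix of beta values in [0, 1] (rows are
#'   individuals). Missing values are rejected.
#' @param strategy one of `"two_stage"`, `"by_individual"`, `"by_probe"`,
#'   `"none"`.
#' @return a `normalized_methylation` object: list with `values` (samples x
#'   probes matrix), `strategy`, and `n_pcs_removed` (0 here).
#' @export
quantile_normalize <- function(beta,
                               strategy = c("two_stage", "by_individual",
                                            "by_probe", "none")) {
  strategy <- match.arg(strategy)
  if (!is.matrix(beta)) .stopf("beta must be a samples x probes matrix")
  if (anyNA(beta)) .stopf("missing beta values are not allowed; impute upstream")
  values <- beta
  if (strategy %in% c("two_stage", "by_individual"))
    values <- t(apply(values, 1, rank_normal))
  if (strategy %in% c("two_stage", "by_probe"))
    values <- apply(values, 2, rank_normal)
  dimnames(values) <- dimnames(beta)
  structure(list(values = values, strategy = strategy, n_pcs_removed = 0L),
            class = "normalized_methylation")
}

#' Filter array probes by mappability, chromosome, and SNP overlap
#'
#' Applies the three exclusion rules in order -- (1) probes that do not map
#' uniquely, (2) probes on sex chromosomes, (3) probes whose target interval
#' contains a segregating SNP -- with first-rule-wins accounting, and
#' returns the retained manifest. The target interval is the
#' `probe_interval` bases ending at the CpG cytosine (inclusive).
#'
#' @param manifest probe manifest data.frame (probe_id, chrom, pos, ...).
#' @param snp_positions data.frame with chrom and pos columns, or a numeric
#'   vector of positions when the manifest has a single chromosome.
#' @param sex_chroms chromosome names treated as sex chromosomes.
#' @param nonunique_probes probe ids flagged as not uniquely mapped
#'   (mappability is an input flag set, not recomputed here).
#' @param probe_interval length in bp of the probe target interval.
#' @return the filtered manifest, with attribute `removed`: named counts per
#'   rule (first rule wins when a probe violates several).
#' @export
filter_probes <- function(manifest, snp_positions = NULL,
                          sex_chroms = c("chrX", "chrY", "X", "Y"),
                          nonunique_probes = character(0),
                          probe_interval = 50) {
  stopifnot(nrow(manifest) > 0)
  known <- c(paste0("chr", c(1:22, "X", "Y", "M")), c(1:22, "X", "Y", "MT"))
  unknown <- setdiff(unique(manifest$chrom), known)
  if (length(unknown))
    .warnf("unknown chromosome names pass through unfiltered: %s",
           paste(unknown, collapse = ", "))

  bad_map <- manifest$probe_id %in% nonunique_probes
  bad_sex <- !bad_map & manifest$chrom %in% sex_chroms

  bad_snp <- rep(FALSE, nrow(manifest))
  if (!is.null(snp_positions)) {
    if (is.numeric(snp_positions))
      snp_positions <- data.frame(chrom = manifest$chrom[1], pos = snp_positions)
    for (ch in unique(manifest$chrom)) {
      sp <- sort(snp_positions$pos[snp_positions$chrom == ch])
      if (!length(sp)) next
      idx <- which(manifest$chrom == ch)
      lo <- manifest$pos[idx] - probe_interval + 1
      hi <- manifest$pos[idx]
      # any SNP in [lo, hi]?
      n_before_hi <- findInterval(hi, sp)
      n_before_lo <- findInterval(lo - 1, sp)
      bad_snp[idx] <- n_before_hi > n_before_lo
    }
  }
  bad_snp <- bad_snp & !bad_map & !bad_sex

  keep <- !(bad_map | bad_sex | bad_snp)
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(nonunique = sum(bad_map),
                            sex_chromosome = sum(bad_sex),
                            snp_overlap = sum(bad_snp))
  out
}

#' Remove principal components from a normalized methylation matrix
#'
#' Computes sample-space principal components of the (column-centered)
#' matrix, regresses each probe's values on the top `k` components, and
#' returns the residuals, which are exactly orthogonal to the removed PCs.
#' This is how hidden confounders that load on leading PCs are absorbed
#' before the cis scan.
#'
#' @param norm a `normalized_methylation` object (or samples x probes
#'   matrix).
#' @param k number of components to remove; must be `< n_samples`. `k = 0`
#'   returns the input unchanged.
#' @return a `normalized_methylation` object with `n_pcs_removed = k`.
#' @export
remove_pcs <- function(norm, k) {
  values <- .meth_values(norm)
  n <- nrow(values)
  if (k >= n) .stopf("k must be smaller than the number of samples (%d)", n)
  strategy <- if (is.list(norm) && !is.null(norm$strategy)) norm$strategy else "none"
  if (k == 0)
    return(structure(list(values = values, strategy = strategy,
                          n_pcs_removed = 0L),
                     class = "normalized_methylation"))
  ctr <- sweep(values, 2, colMeans(values))
  sv <- svd(ctr, nu = k, nv = 0)
  U <- sv$u                                  # n x k orthonormal sample scores
  resid <- ctr - U %*% (t(U) %*% ctr)
  dimnames(resid) <- dimnames(values)
  structure(list(values = resid, strategy = strategy, n_pcs_removed = as.integer(k)),
            class = "normalized_methylation")
}

#' Choose the number of PCs to remove by meQTL yield
#'
#' Runs the cis scan after removing each candidate number of components and
#' returns the `k` that maximizes the number of probes with at least one
#' association at the given FDR (ties broken toward smaller `k`). This is
#' the data-driven analogue of picking the removal depth that maximizes
#' power.
#'
#' @param norm a `normalized_methylation` object (before PC removal).
#' @param geno a `genotype_table`.
#' @param manifest probe manifest.
#' @param k_grid integer vector of candidate `k` values.
#' @param fdr FDR level for counting meQTL probes.
#' @param window,maf_min passed to [cis_scan()].
#' @return list with `k` (the selected value) and `table` (data.frame of
#'   k and meQTL probe count).
#' @export
select_num_pcs <- function(norm, geno, manifest, k_grid = 0:8, fdr = 0.10,
                           window = 3000, maf_min = 0.05) {
  if (!length(k_grid)) .stopf("k_grid must be nonempty")
  k_grid <- sort(unique(as.integer(k_grid)))
  counts <- vapply(k_grid, function(k) {
    res <- remove_pcs(norm, k)
    assoc <- cis_scan(res, geno, manifest, window = window, maf_min = maf_min)
    if (nrow(assoc) == 0) return(0L)
    nrow(call_meqtls(assoc, fdr = fdr))
  }, integer(1))
  best <- k_grid[which.max(counts)]  # which.max takes the first maximum: smallest k
  list(k = best, table = data.frame(k = k_grid, n_meqtl_probes = counts))
}

#' Associate principal components with known covariates
#'
#' For each (PC, covariate) pair reports a Pearson correlation test p-value
#' (continuous covariates) or a one-way ANOVA F-test p-value (categorical),
#' together with the variance explained by each component -- the standard
#' audit that leading PCs do not track known batch or donor factors.
#'
#' @param norm a `normalized_methylation` object or matrix.
#' @param covariates data.frame of known factors, rows aligned to samples.
#' @param n_pcs number of leading components to test.
#' @return data.frame (pc, covariate, statistic, p_value) with attribute
#'   `var_explained` (per-PC proportion; sums to <= 1).
#' @export
pc_confounder_report <- function(norm, covariates, n_pcs = 5) {
  values <- .meth_values(norm)
  if (nrow(covariates) != nrow(values))
    .stopf("covariates must have one row per sample")
  pca <- stats::prcomp(values, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  rows <- list()
  for (j in seq_len(n_pcs)) {
    pc <- pca$x[, j]
    for (cv in names(covariates)) {
      x <- covariates[[cv]]
      if (is.numeric(x)) {
        ct <- stats::cor.test(pc, x)
        rows[[length(rows) + 1L]] <-
          data.frame(pc = j, covariate = cv, statistic = unname(ct$estimate),
                     p_value = ct$p.value)
      } else {
        x <- factor(x)
        if (nlevels(x) < 2) {
          .warnf("covariate '%s' has a single level; skipped", cv)
          next
        }
        fit <- stats::aov(pc ~ x)
        sm <- summary(fit)[[1]]
        rows[[length(rows) + 1L]] <-
          data.frame(pc = j, covariate = cv, statistic = sm$`F value`[1],
                     p_value = sm$`Pr(>F)`[1])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(pc = integer(0), covariate = character(0),
                         statistic = numeric(0), p_value = numeric(0))
  rownames(out) <- NULL
  attr(out, "var_explained") <- ve[seq_len(n_pcs)]
  out
}
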