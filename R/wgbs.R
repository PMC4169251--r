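# Bisulfite sequencing: per-site methylation levels, array-sequencing
# concordance, and genotype-stratified sliding-window aggregation of read
# counts around meQTL CpGs.

.check_counts <- function(counts) {
  need <- c("sample_id", "chrom", "pos", "n_meth", "n_total")
  if (!all(need %in% names(counts)))
    .stopf("counts must have columns %s", paste(need, collapse = ", "))
  if (any(counts$n_meth > counts$n_total))
    .stopf("corrupt counts: n_meth exceeds n_total")
  if (any(counts$n_meth < 0 | counts$n_total < 0))
    .stopf("corrupt counts: negative read counts")
  invisible(counts)
}

#' Per-site methylation levels from read counts
#'
#' The methylation level of a site in a sample is the number of methylated
#' reads divided by the total coverage; sites with coverage below
#' `min_reads` are marked missing.
#'
#' @param counts data.frame with sample_id, chrom, pos, n_meth, n_total.
#' @param min_reads minimum total reads for a defined level (default 1).
#' @return the input with a `level` column (NA below the coverage cutoff).
#' @export
site_methylation <- function(counts, min_reads = 1) {
  .check_counts(counts)
  level <- ifelse(counts$n_total >= min_reads,
                  counts$n_meth / counts$n_total, NA_real_)
  counts$level <- level
  counts
}

#' Concordance between array beta values and sequencing methylation
#'
#' Per shared CpG site, compares the mean untransformed beta value across
#' all array samples with the mean of per-sample sequencing levels over
#' samples with at least `min_reads` reads at the site, using the Spearman
#' rank correlation (the levels are far from normal).
#'
#' @param beta samples x probes matrix of untransformed beta values.
#' @param counts bisulfite counts data.frame.
#' @param manifest probe manifest mapping probe ids to (chrom, pos).
#' @param min_reads per-sample coverage required for a sample to enter a
#'   site's sequencing mean (default 5).
#' @return list: rho (Spearman), n_sites, and the per-site table.
#' @export
array_seq_concordance <- function(beta, counts, manifest, min_reads = 5) {
  .check_counts(counts)
  counts <- counts[counts$n_total >= min_reads, , drop = FALSE]
  if (!nrow(counts)) .stopf("no site reaches %d reads in any sample", min_reads)
  key <- paste(counts$chrom, counts$pos)
  lev <- counts$n_meth / counts$n_total
  seq_mean <- tapply(lev, key, mean)

  mkey <- paste(manifest$chrom, manifest$pos)
  shared <- mkey %in% names(seq_mean)
  if (sum(shared) < 3) .stopf("fewer than 3 CpG sites shared between array and sequencing")
  probes <- manifest$probe_id[shared]
  arr_mean <- colMeans(beta[, probes, drop = FALSE])
  tab <- data.frame(probe_id = probes,
                    array_mean = unname(arr_mean),
                    seq_mean = unname(seq_mean[mkey[shared]]))
  rho <- stats::cor(tab$array_mean, tab$seq_mean, method = "spearman")
  list(rho = rho, n_sites = nrow(tab), table = tab)
}

#' Genotype-stratified aggregate methylation around meQTL CpGs
#'
#' For each meQTL, sequenced individuals are split by (rounded) genotype
#' class oriented by the array association so that `high` is the homozygote
#' class associated with higher methylation. Methylated and total reads are
#' pooled in sliding windows across a span centered on the associated CpG:
#' within one (meQTL, class, window) the level is the summed methylated
#' reads over summed total reads (sum-then-divide), and the reported curve
#' is the unweighted mean of those per-meQTL levels across meQTLs, omitting
#' windows without reads. Flipping allele labels leaves the curves
#' unchanged because classes are defined by methylation direction.
#'
#' @param counts bisulfite counts data.frame.
#' @param meqtls meQTL set from [call_meqtls()] (probe_id, snp_id, effect).
#' @param geno a `genotype_table` covering the sequenced samples.
#' @param manifest probe manifest locating each meQTL CpG.
#' @param span full width of the aggregated region in bp (default 5000).
#' @param window window width in bp (default 51).
#' @param step window step in bp (default 25).
#' @return data.frame (offset = window center relative to the CpG, class in
#'   low/het/high, level, n_meqtls, n_reads); attribute `n_windows`.
#' @export
genotype_stratified_aggregate <- function(counts, meqtls, geno, manifest,
                                          span = 5000, window = 51, step = 25) {
  .check_counts(counts)
  if (!nrow(meqtls)) .stopf("empty meQTL set")
  samples <- intersect(unique(counts$sample_id), rownames(geno$dosages))
  if (length(samples) < 2) .stopf("fewer than 2 sequenced individuals with genotypes")
  counts <- counts[counts$sample_id %in% samples, , drop = FALSE]

  n_windows <- floor((span - window) / step) + 1L
  starts <- -span / 2 + step * (0:(n_windows - 1L))
  centers <- starts + (window - 1) / 2
  classes <- c("low", "het", "high")

  sum_lev <- matrix(0, n_windows, 3, dimnames = list(NULL, classes))
  n_con <- matrix(0L, n_windows, 3, dimnames = list(NULL, classes))
  reads <- matrix(0, n_windows, 3, dimnames = list(NULL, classes))

  single_class <- 0L
  for (i in seq_len(nrow(meqtls))) {
    pid <- meqtls$probe_id[i]
    mrow <- match(pid, manifest$probe_id)
    if (is.na(mrow)) next
    cpg_chrom <- manifest$chrom[mrow]; cpg_pos <- manifest$pos[mrow]
    dos <- round(geno$dosages[samples, meqtls$snp_id[i]])
    # orient: "high" = homozygote with higher methylation
    cls <- if (meqtls$effect[i] >= 0) c("low", "het", "high")[dos + 1L]
           else c("high", "het", "low")[dos + 1L]
    names(cls) <- samples
    if (length(unique(cls)) == 1L) single_class <- single_class + 1L

    sub <- counts[counts$chrom == cpg_chrom &
                    abs(counts$pos - cpg_pos) <= span / 2, , drop = FALSE]
    if (!nrow(sub)) next
    rel <- sub$pos - cpg_pos
    # window index range containing each site: start_i <= rel < start_i + window
    i_hi <- floor((rel + span / 2) / step)
    i_lo <- floor((rel - window + span / 2) / step) + 1L
    i_lo <- pmax(i_lo, 0L); i_hi <- pmin(i_hi, n_windows - 1L)
    reps <- pmax(i_hi - i_lo + 1L, 0L)
    ok <- reps > 0L
    if (!any(ok)) next
    widx <- unlist(mapply(seq.int, i_lo[ok], i_hi[ok], SIMPLIFY = FALSE),
                   use.names = FALSE) + 1L
    rows <- rep(which(ok), reps[ok])
    cl <- cls[sub$sample_id[rows]]
    gm <- rowsum(cbind(sub$n_meth[rows], sub$n_total[rows]),
                 group = paste(widx, cl, sep = ":"))
    parts <- strsplit(rownames(gm), ":", fixed = TRUE)
    wi <- as.integer(vapply(parts, `[[`, "", 1L))
    ci <- match(vapply(parts, `[[`, "", 2L), classes)
    has_reads <- gm[, 2] > 0
    idx <- cbind(wi[has_reads], ci[has_reads])
    sum_lev[idx] <- sum_lev[idx] + gm[has_reads, 1] / gm[has_reads, 2]
    n_con[idx] <- n_con[idx] + 1L
    reads[idx] <- reads[idx] + gm[has_reads, 2]
  }
  if (single_class)
    message(single_class,
            " meQTL(s) had all sequenced individuals in one genotype class")
  out <- data.frame(offset = rep(centers, 3),
                    class = factor(rep(classes, each = n_windows),
                                   levels = classes),
                    level = as.vector(ifelse(n_con > 0, sum_lev / n_con, NA_real_)),
                    n_meqtls = as.vector(n_con),
                    n_reads = as.vector(reads))
  attr(out, "n_windows") <- n_windows
  out
}
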