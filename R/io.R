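# Plain-text readers and writers for the pipeline's interchange formats:
# dosage and beta matrices (tab-delimited, samples as columns), BED probe
# manifests, Bismark-coverage-style bisulfite counts, SNP lists, minimal
# VCF, and JASPAR / MEME-minimal PWMs.

#' Write / read a genotype dosage matrix
#'
#' Tab-delimited with SNPs as rows and samples as columns; the first four
#' columns are snp_id, chrom, pos, maf.
#'
#' @param geno a `genotype_table`.
#' @param path output file.
#' @export
write_dosage_tsv <- function(geno, path) {
  tab <- cbind(geno$snps, as.data.frame(t(geno$dosages)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @return `read_dosage_tsv` returns a `genotype_table`.
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  meta <- tab[, c("snp_id", "chrom", "pos", "maf")]
  dos <- t(as.matrix(tab[, setdiff(names(tab), names(meta)), drop = FALSE]))
  colnames(dos) <- meta$snp_id
  structure(list(dosages = dos, snps = meta), class = "genotype_table")
}

#' Write / read a methylation value matrix
#'
#' Tab-delimited with probes as rows and samples as columns.
#'
#' @param values samples x probes matrix.
#' @param path file path.
#' @export
write_beta_tsv <- function(values, path) {
  tab <- data.frame(probe_id = colnames(values), t(values), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @return `read_beta_tsv` returns a samples x probes matrix.
#' @export
read_beta_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- tab[[1]]
  m
}

#' Write / read a probe manifest as BED
#'
#' BED with 0-based half-open 1-bp intervals at the CpG cytosine; the name
#' field carries the probe id and an optional 5th data column the
#' chromatin-state annotation.
#'
#' @param manifest probe manifest data.frame.
#' @param path file path.
#' @export
write_manifest_bed <- function(manifest, path) {
  tab <- data.frame(chrom = manifest$chrom, start = manifest$pos,
                    end = manifest$pos + 1, name = manifest$probe_id)
  if (!is.null(manifest$annotation)) tab$annotation <- manifest$annotation
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_bed
#' @return `read_manifest_bed` returns a probe manifest data.frame.
#' @export
read_manifest_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE)
  out <- data.frame(probe_id = tab[[4]], chrom = tab[[1]], pos = tab[[2]])
  if (ncol(tab) >= 5) out$annotation <- tab[[5]]
  out
}

#' Write / read Bismark-coverage-style bisulfite counts
#'
#' One file per sample: chrom, start, end (0-based half-open, 1 bp),
#' methylated count, unmethylated count.
#'
#' @param counts counts data.frame (sample_id, chrom, pos, n_meth,
#'   n_total).
#' @param dir output directory; files are named `<sample_id>.cov`.
#' @export
write_bismark_cov <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(counts$sample_id)) {
    sub <- counts[counts$sample_id == s, , drop = FALSE]
    tab <- data.frame(chrom = sub$chrom, start = sub$pos, end = sub$pos + 1,
                      n_meth = sub$n_meth, n_unmeth = sub$n_total - sub$n_meth)
    utils::write.table(tab, file.path(dir, paste0(s, ".cov")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_bismark_cov
#' @param files named character vector of coverage files (names = sample
#'   ids; basenames used otherwise).
#' @return `read_bismark_cov` returns a counts data.frame.
#' @export
read_bismark_cov <- function(files) {
  if (is.null(names(files)))
    names(files) <- sub("\\.cov$", "", basename(files))
  out <- lapply(names(files), function(s) {
    tab <- utils::read.delim(files[[s]], header = FALSE)
    data.frame(sample_id = s, chrom = tab[[1]], pos = tab[[2]],
               n_meth = tab[[4]], n_total = tab[[4]] + tab[[5]])
  })
  do.call(rbind, out)
}

#' Read a SNP list
#'
#' One SNP id (or chrom:pos token) per line; an optional second column
#' carries the foreground phenotype effect sign.
#'
#' @param path file path.
#' @return data.frame with snp_id and (if present) direction.
#' @export
read_snp_list <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(snp_id = as.character(tab[[1]]))
  if (ncol(tab) >= 2) out$direction <- as.numeric(tab[[2]])
  out
}

#' Write a minimal VCF of simulated genotypes
#'
#' Unphased hard genotypes derived from rounded dosages; enough structure
#' for interoperability with standard VCF tooling, nothing more.
#'
#' @param geno a `genotype_table`.
#' @param path output file.
#' @export
write_vcf_minimal <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=cismeth-simdata",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosages)),
                     collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno$dosages))) {
    calls <- gt[round(geno$dosages[, j]) + 1L]
    writeLines(paste(c(geno$snps$chrom[j], geno$snps$pos[j],
                       geno$snps$snp_id[j], "A", "G", ".", "PASS", ".",
                       "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read PWMs in JASPAR format
#'
#' Parses the JASPAR text layout: a `>ID NAME` header followed by four
#' rows `A [ counts... ]` (brackets optional).
#'
#' @param path file path.
#' @param pseudocount,background passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
read_pwm_jaspar <- function(path, pseudocount = 1e-3,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  out <- list()
  for (k in seq_along(heads)) {
    name <- trimws(sub("^>\\S*\\s*", "", lines[heads[k]]))
    if (!nzchar(name)) name <- sub("^>", "", strsplit(lines[heads[k]], "\\s+")[[1]][1])
    block <- lines[(heads[k] + 1):(if (k < length(heads)) heads[k + 1] - 1 else length(lines))]
    rows <- lapply(block[1:4], function(l) {
      body <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(body, gregexpr("[0-9.eE+-]+", body))[[1]])
    })
    base_order <- toupper(substr(trimws(block[1:4]), 1, 1))
    mat <- do.call(cbind, rows[match(BASES, base_order)])
    out[[name]] <- pwm(mat, name = name, background = background,
                       pseudocount = pseudocount)
  }
  out
}

#' Read PWMs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections
#' (alphabet ACGT).
#'
#' @param path file path.
#' @param pseudocount,background passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
read_pwm_meme <- function(path, pseudocount = 1e-3,
                          background = rep(0.25, 4)) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF", lines)
  out <- list()
  for (k in seq_along(motif_at)) {
    name <- strsplit(trimws(lines[motif_at[k]]), "\\s+")[[1]][2]
    upto <- if (k < length(motif_at)) motif_at[k + 1] - 1 else length(lines)
    block <- lines[motif_at[k]:upto]
    lp <- grep("letter-probability matrix", block)
    if (!length(lp)) next
    rows <- list()
    for (l in block[(lp + 1):length(block)]) {
      nums <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (length(nums) != 4 || anyNA(nums)) break
      rows[[length(rows) + 1L]] <- nums
    }
    out[[name]] <- pwm(do.call(rbind, rows), name = name,
                       background = background, pseudocount = pseudocount)
  }
  out
}
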