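# Population VCF simulation: segregating sites are sprinkled along each
# configured region at Watterson density theta * a1 per bp, derived-allele
# counts follow the standard neutral site-frequency spectrum (P(i) ~ 1/i),
# and haplotypes are paired into phased diploid genotypes.

harmonic <- function(n) sum(1 / seq_len(n))

resolve_region <- function(name, config) {
  cl <- config$chrom_lengths
  if (name %in% names(cl))
    return(region(name, 0, cl[[name]]))
  if (identical(name, "SDR")) return(config$sdr_span)
  if (identical(name, "PAR")) return(config$par_span)
  stop("region '", name, "' matches no chromosome and no configured span")
}

#' Simulate a population VCF with region-specific diversity
#'
#' For each entry of `config$theta_by_region`, biallelic SNPs are placed so
#' that the expected per-site (SNP) nucleotide diversity equals theta: the
#' number of segregating SNPs is Poisson with mean `theta * a1 * L`
#' (`a1 = sum(1/i)`, Watterson's constant), and each site's derived-allele
#' count i is drawn with probability proportional to `1/i`. Short (1-3 bp)
#' insertions and deletions are added on top so that they make up
#' `indel_fraction` of all variants. Genotypes are phased diploids over
#' `n_haplotypes / 2` samples.
#'
#' @param config A [sim_config()].
#' @param out_vcf Optional path for a VCF v4.2 file with `##contig` headers.
#' @return List with `variants` (data.frame: chrom, pos (1-based), ref, alt,
#'   class, region, derived count `j`), `gt` (haplotype 0/1 matrix, sites x
#'   haplotypes), `samples`, and `theta_truth`.
#' @export
simulate_population_vcf <- function(config, out_vcf = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_haplotypes
  a1 <- harmonic(n - 1L)
  sfs_p <- (1 / seq_len(n - 1L)) / a1
  with_seed(sub_seed(config$seed, 4L), {
    recs <- list(); gts <- list()
    for (rn in names(config$theta_by_region)) {
      reg <- resolve_region(rn, config)
      theta <- config$theta_by_region[[rn]]
      L <- reg$end - reg$start
      # theta calibrates SNP diversity; indels are sprinkled on top at
      # indel_fraction of the total variant count
      n_snp <- stats::rpois(1, theta * a1 * L)
      n_ind <- stats::rpois(1, theta * a1 * L * config$indel_fraction /
                              max(1e-9, 1 - config$indel_fraction))
      n_sites <- min(n_snp + n_ind, L)
      if (n_sites == 0) next
      pos <- sort(sample.int(L, n_sites)) + reg$start  # 1-based positions
      j <- sample.int(n - 1L, n_sites, replace = TRUE, prob = sfs_p)
      is_indel <- sample(rep(c(TRUE, FALSE),
                             c(min(n_ind, n_sites), n_sites - min(n_ind, n_sites))))
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n_sites, replace = TRUE)
      alt <- vapply(seq_len(n_sites), function(k) {
        if (!is_indel[k]) return(sample(setdiff(bases, ref[k]), 1))
        ins <- stats::runif(1) < 0.5
        tail <- paste(sample(bases, sample.int(3L, 1L), replace = TRUE),
                      collapse = "")
        if (ins) paste0(ref[k], tail) else ref[k]
      }, character(1))
      # deletions need the longer allele in REF
      del <- is_indel & nchar(alt) == nchar(ref)
      if (any(del)) {
        longer <- vapply(which(del), function(k)
          paste0(ref[k], paste(sample(bases, sample.int(3L, 1L), replace = TRUE),
                               collapse = "")), character(1))
        ref[del] <- longer
      }
      cls <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
                    ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
      gt <- matrix(0L, n_sites, n)
      for (k in seq_len(n_sites))
        gt[k, sample.int(n, j[k])] <- 1L
      recs[[rn]] <- data.frame(chrom = reg$chrom, pos = pos, ref = ref,
                               alt = alt, class = cls, region = rn, j = j,
                               stringsAsFactors = FALSE)
      gts[[rn]] <- gt
    }
    if (!length(recs)) stop("no variants simulated; all thetas empty?")
    variants <- do.call(rbind, recs)
    gt <- do.call(rbind, gts)
    ord <- order(match(variants$chrom, names(config$chrom_lengths)),
                 variants$pos)
    variants <- variants[ord, ]; gt <- gt[ord, , drop = FALSE]
    # drop duplicate positions across overlapping regions (keep first)
    dup <- duplicated(variants[, c("chrom", "pos")])
    variants <- variants[!dup, ]; gt <- gt[!dup, , drop = FALSE]
    rownames(variants) <- NULL
    samples <- sprintf("S%02d", seq_len(n %/% 2L))
    res <- list(variants = variants, gt = gt, samples = samples,
                theta_truth = config$theta_by_region)
    if (!is.null(out_vcf)) write_sim_vcf(res, config, out_vcf)
    res
  })
}

# VCF v4.2 writer with ##contig headers and phased diploid GT columns
write_sim_vcf <- function(sim, config, path) {
  v <- sim$variants; gt <- sim$gt
  hap_pairs <- matrix(seq_len(ncol(gt)), nrow = 2)
  gt_str <- apply(hap_pairs, 2, function(pr)
    paste(gt[, pr[1]], gt[, pr[2]], sep = "|"))
  if (is.null(dim(gt_str))) gt_str <- matrix(gt_str, nrow = 1)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=SDRtools-simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(config$chrom_lengths),
            as.integer(config$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sim$samples), collapse = "\t"))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(body, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
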