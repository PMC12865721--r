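# Variant classification and population statistics: per-class counts and
# densities, windowed nucleotide diversity and Tajima's D, Hudson's FST,
# and the X-versus-Y reference contrast.

# ---- VCF ingestion ---------------------------------------------------------

# parse ##contig=<ID=...,length=...> header lines
contig_lengths_from_meta <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  id <- sub(".*[<,]ID=([^,>]+).*", "\\1", ln)
  len <- suppressWarnings(as.numeric(sub(".*[<,]length=([0-9]+).*", "\\1", ln)))
  stats::setNames(len, id)
}

read_variant_table <- function(vcf) {
  if (inherits(vcf, "vcfR")) {
    obj <- vcf
  } else if (is.character(vcf) && length(vcf) == 1L) {
    obj <- vcfR::read.vcfR(vcf, verbose = FALSE)
  } else {
    stop("vcf must be a path or a vcfR object")
  }
  fix <- as.data.frame(obj@fix, stringsAsFactors = FALSE)
  list(fix = data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE),
       gt = if (!is.null(obj@gt) && ncol(obj@gt) > 1) obj@gt else NULL,
       contig_lengths = contig_lengths_from_meta(obj@meta))
}

classify_one <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1 & na == 1, "SNP",
    ifelse(na > nr & substr(alt, 1, 1) == substr(ref, 1, 1), "insertion",
      ifelse(nr > na & substr(ref, 1, 1) == substr(alt, 1, 1), "deletion",
             "other")))
}

#' Classify variants and summarize counts and density
#'
#' Splits multi-allelic records per alternate allele, classifies each allele
#' (equal length 1 = SNP; longer ALT sharing the anchor base = insertion;
#' longer REF sharing the anchor base = deletion; anything else = other), and
#' summarizes per-class counts, the total, and the density per kb from
#' `##contig` header lengths.
#'
#' @param vcf VCF path, `vcfR` object, or data.frame with `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param chrom_lengths Optional named lengths overriding `##contig`
#'   headers.
#' @return List with `variants` (classified allele table), `counts` (named:
#'   SNP, insertion, deletion, other), `n_indels`, `total`, and
#'   `density_per_kb` (`NA` when no lengths are known).
#' @export
classify_variants <- function(vcf, chrom_lengths = NULL) {
  if (is.data.frame(vcf)) {
    fix <- vcf[, c("chrom", "pos", "ref", "alt")]
    meta_len <- NULL
  } else {
    tab <- read_variant_table(vcf)
    fix <- tab$fix
    meta_len <- tab$contig_lengths
  }
  if (is.null(chrom_lengths)) chrom_lengths <- meta_len
  for (ch in unique(fix$chrom)) {
    p <- fix$pos[fix$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on ", ch)
  }
  # split multi-allelic records
  alts <- strsplit(fix$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  variants <- data.frame(chrom = fix$chrom[idx], pos = fix$pos[idx],
                         ref = fix$ref[idx], alt = unlist(alts),
                         stringsAsFactors = FALSE)
  variants$class <- classify_one(variants$ref, variants$alt)
  counts <- table(factor(variants$class,
                         levels = c("SNP", "insertion", "deletion", "other")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- nrow(variants)
  dens <- NA_real_
  if (!is.null(chrom_lengths)) {
    used <- chrom_lengths[unique(variants$chrom)]
    if (anyNA(used))
      stop("missing contig length for: ",
           paste(unique(variants$chrom)[is.na(used)], collapse = ", "))
    dens <- total / (sum(used) / 1000)
  }
  list(variants = variants, counts = counts,
       n_indels = unname(counts["insertion"] + counts["deletion"]),
       total = total, density_per_kb = dens)
}

# ---- allele counts from genotypes -----------------------------------------

#' Per-site derived-allele counts from a VCF genotype matrix
#'
#' Keeps biallelic SNPs only. Parses phased or unphased diploid GT fields;
#' missing alleles reduce the per-site haplotype count.
#'
#' @param vcf VCF path or `vcfR` object (must carry genotypes), or a list
#'   with `variants` and a 0/1 haplotype matrix `gt` as produced by
#'   [simulate_population_vcf()].
#' @return Data frame: `chrom`, `pos`, `j` (derived count), `n` (haplotypes
#'   with a called allele).
#' @export
vcf_allele_counts <- function(vcf) {
  if (is.list(vcf) && !is.null(vcf$gt) && !is.null(vcf$variants)) {
    keep <- vcf$variants$class == "SNP"
    return(data.frame(chrom = vcf$variants$chrom[keep],
                      pos = vcf$variants$pos[keep],
                      j = as.integer(rowSums(vcf$gt[keep, , drop = FALSE])),
                      n = ncol(vcf$gt), stringsAsFactors = FALSE))
  }
  tab <- read_variant_table(vcf)
  if (is.null(tab$gt)) stop("VCF carries no genotype columns")
  fix <- tab$fix
  keep <- nchar(fix$ref) == 1 & nchar(fix$alt) == 1 & !grepl(",", fix$alt)
  gt <- tab$gt[keep, -1, drop = FALSE]  # drop FORMAT column
  gt_only <- sub(":.*", "", gt)
  alleles <- t(apply(gt_only, 1, function(row)
    unlist(strsplit(row, "[|/]"))))
  j <- apply(alleles, 1, function(a) sum(a == "1"))
  n <- apply(alleles, 1, function(a) sum(a %in% c("0", "1")))
  data.frame(chrom = fix$chrom[keep], pos = fix$pos[keep],
             j = as.integer(j), n = as.integer(n), stringsAsFactors = FALSE)
}

# ---- diversity statistics --------------------------------------------------

#' Nucleotide diversity over a window
#'
#' `pi = (1/L) * sum_sites 2 j (n - j) / (n (n - 1))`, the mean pairwise
#' difference per site; sites with fewer than 2 called haplotypes are
#' skipped.
#'
#' @param j Derived-allele counts per site.
#' @param n Called haplotypes per site (recycled if scalar).
#' @param window_length Window length L in bp.
#' @return Per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(j, n, window_length) {
  stopifnot(window_length > 0)
  if (!length(j)) return(0)
  n <- rep_len(n, length(j))
  ok <- n >= 2
  sum(2 * j[ok] * (n[ok] - j[ok]) / (n[ok] * (n[ok] - 1))) / window_length
}

#' Tajima's D
#'
#' Standard normalized difference between the mean-pairwise-difference and
#' segregating-sites estimators of theta. Undefined (`NA`) when `S = 0`.
#'
#' @param S Number of segregating sites in the window.
#' @param n Number of haplotypes (>= 4).
#' @param pi_sum Sum over sites of per-site pairwise diversity (i.e. `pi *
#'   L`).
#' @return Tajima's D, or `NA_real_` when `S = 0`.
#' @export
tajimas_d <- function(S, n, pi_sum) {
  if (n < 4) stop("Tajima's D needs n >= 4 haplotypes")
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Windowed diversity statistics from per-site allele counts
#'
#' @param counts Data frame from [vcf_allele_counts()].
#' @param window Window size in bp.
#' @param chrom_lengths Named chromosome lengths defining the window grid.
#' @return Data frame per window: `chrom`, `start`, `end`, `n_haplotypes`
#'   (modal per-site n), `S`, `pi`, `tajimas_d`.
#' @export
windowed_diversity <- function(counts, window, chrom_lengths) {
  grid <- window_grid(chrom_lengths, window)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    w <- counts[counts$chrom == grid$chrom[k] &
                  counts$pos > grid$start[k] & counts$pos <= grid$end[k], ]
    w <- w[w$n >= 2, , drop = FALSE]
    seg <- w$j > 0 & w$j < w$n
    S <- sum(seg)
    L <- grid$end[k] - grid$start[k]
    pi_sum <- sum(2 * w$j * (w$n - w$j) / (w$n * (w$n - 1)))
    n_mode <- if (nrow(w)) as.integer(stats::median(w$n)) else NA_integer_
    data.frame(chrom = grid$chrom[k], start = grid$start[k], end = grid$end[k],
               n_haplotypes = n_mode, S = S, pi = pi_sum / L,
               tajimas_d = if (S > 0 && !is.na(n_mode) && n_mode >= 4)
                 tajimas_d(S, n_mode, pi_sum) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Hudson's FST from per-site allele counts in two groups
#'
#' Ratio-of-averages Hudson estimator:
#' per site `N_h = (p1 - p2)^2 - p1 (1 - p1)/(n1 - 1) - p2 (1 - p2)/(n2 - 1)`
#' and `D_h = p1 (1 - p2) + p2 (1 - p1)`; `FST = sum(N_h) / sum(D_h)`.
#' Sites with fewer than 2 called haplotypes in either group are skipped.
#'
#' @param c1,c2 Derived-allele counts per site in groups 1 and 2.
#' @param n1,n2 Called haplotypes per site (recycled if scalar).
#' @return List with `fst`, `n_sites`, and `pi_within` (per-site mean
#'   within-group diversity at the used sites, per group).
#' @export
hudson_fst <- function(c1, n1, c2, n2) {
  stopifnot(length(c1) == length(c2))
  n1 <- rep_len(n1, length(c1)); n2 <- rep_len(n2, length(c2))
  ok <- n1 >= 2 & n2 >= 2
  if (!any(ok)) stop("no site has >= 2 called haplotypes in both groups")
  p1 <- c1[ok] / n1[ok]; p2 <- c2[ok] / n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1[ok] - 1) - p2 * (1 - p2) / (n2[ok] - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(fst = sum(num) / sum(den), n_sites = sum(ok),
       pi_within = c(mean(2 * c1[ok] * (n1[ok] - c1[ok]) /
                            (n1[ok] * (n1[ok] - 1))),
                     mean(2 * c2[ok] * (n2[ok] - c2[ok]) /
                            (n2[ok] * (n2[ok] - 1)))))
}

#' Contrast X- and Y-referenced call-set summaries
#'
#' @param summary_x,summary_y Lists with elements drawn from
#'   [classify_variants()] output (`counts`, `total`, `density_per_kb`) plus
#'   optional `mean_pi` and `mean_tajimas_d`.
#' @return Data frame with one row per quantity and columns `X`, `Y`,
#'   `ratio_X_over_Y`.
#' @export
contrast_references <- function(summary_x, summary_y) {
  if (is.null(summary_x$total) || is.null(summary_y$total) ||
      summary_y$total == 0)
    stop("both summaries must carry non-empty variant totals")
  grab <- function(s) c(
    SNP = unname(s$counts["SNP"]), insertion = unname(s$counts["insertion"]),
    deletion = unname(s$counts["deletion"]),
    indels = unname(s$counts["insertion"] + s$counts["deletion"]),
    total = s$total, density_per_kb = s$density_per_kb,
    mean_pi = s$mean_pi %||% NA_real_,
    mean_tajimas_d = s$mean_tajimas_d %||% NA_real_)
  x <- grab(summary_x); y <- grab(summary_y)
  data.frame(quantity = names(x), X = unname(x), Y = unname(y),
             ratio_X_over_Y = unname(x / y), stringsAsFactors = FALSE)
}
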