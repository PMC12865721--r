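# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results by different algorithms than
# the package implementation.

GC_TABLE <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GC_TABLE)[GC_TABLE == "*"]
SENSE_CODONS <- setdiff(names(GC_TABLE), STOP_CODONS)

# recursive (depth-first) pathway enumeration between two codons; returns
# pathway-averaged synonymous/nonsynonymous step counts, excluding pathways
# through stop codons unless all pass through one
oracle_ng_diffs <- function(a, b) {
  paths <- list()
  recurse <- function(cur, sd, nd, via_stop) {
    if (cur == b) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd, stop = via_stop)
      return(invisible())
    }
    ca <- strsplit(cur, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    for (p in which(ca != cb)) {
      nxt_v <- ca; nxt_v[p] <- cb[p]
      nxt <- paste(nxt_v, collapse = "")
      syn <- GC_TABLE[[cur]] == GC_TABLE[[nxt]]
      recurse(nxt, sd + syn, nd + !syn,
              via_stop || (nxt %in% STOP_CODONS && nxt != b))
    }
  }
  recurse(a, 0L, 0L, FALSE)
  m <- do.call(rbind, paths)
  keep <- m[, "stop"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(sd = mean(m[keep, "sd"]), nd = mean(m[keep, "nd"]))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# maximal strictly unit-descending runs of length >= 2 in a permutation
oracle_inverted_runs <- function(y) {
  n <- length(y)
  runs <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && y[j + 1L] == y[j] - 1L) j <- j + 1L
    if (j > i) runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  runs
}

# candidate-run merging as union-find over all candidate pairs: windows u, v
# are linked when |u - v| <= max_gap + 1; each component spans min..max
oracle_merged_runs <- function(cand, max_gap) {
  idx <- which(cand)
  if (!length(idx)) return(matrix(integer(0), ncol = 2))
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (abs(idx[a] - idx[b]) <= max_gap + 1L) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  out <- t(vapply(split(idx, roots), function(v) c(min(v), max(v)),
                  integer(2)))
  dimnames(out) <- NULL
  out[order(out[, 1]), , drop = FALSE]
}

# average pairwise difference per site over all haplotype pairs
oracle_pi_bruteforce <- function(gt, L) {
  n <- ncol(gt)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(gt[, i] != gt[, j])
  tot / choose(n, 2) / L
}

# explicit per-site Hudson estimator summation
oracle_hudson_fst <- function(c1, n1, c2, n2) {
  num <- den <- 0
  for (k in seq_along(c1)) {
    p1 <- c1[k] / n1[k]; p2 <- c2[k] / n2[k]
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1[k] - 1) -
      p2 * (1 - p2) / (n2[k] - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

random_test_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste(c("ATG", sample(SENSE_CODONS, n_codons - 1L, replace = TRUE)),
        collapse = "")
}

# flat VCF with prescribed class counts (single contig, unit positions)
build_class_vcf <- function(n_snp, n_ins, n_del, contig, contig_len, path,
                            seed = 1) {
  n <- n_snp + n_ins + n_del
  set.seed(seed)
  cls <- sample(rep(c("S", "I", "D"), c(n_snp, n_ins, n_del)))
  ref <- ifelse(cls == "S", "A", ifelse(cls == "I", "A", "AT"))
  alt <- ifelse(cls == "S", "T", ifelse(cls == "I", "AT", "A"))
  dt <- data.table::data.table(CHROM = contig, POS = seq_len(n), ID = ".",
                               REF = ref, ALT = alt, QUAL = ".",
                               FILTER = "PASS", INFO = ".")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", contig,
                       as.integer(contig_len)),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t")), path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE)
  path
}
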