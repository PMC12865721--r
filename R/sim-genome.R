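# Toy sex-chromosome genome: autosome(s), an X, and a Y whose SDR carries
# gametologs (placed in a possibly inverted order), Y-specific genes, and a
# PAR shared with the X. Gene sizes are auto-scaled to the region so the
# defaults stay desk-sized.

apply_inversion_runs <- function(n, runs) {
  ord <- seq_len(n)
  if (length(runs)) {
    ends <- do.call(rbind, lapply(runs, function(r) c(r[1], r[2])))
    o <- order(ends[, 1])
    ends <- ends[o, , drop = FALSE]
    if (any(ends[, 1] < 1 | ends[, 2] > n))
      stop("inversion runs must lie within [1, ", n, "]")
    if (nrow(ends) > 1 && any(ends[-1, 1] <= ends[-nrow(ends), 2]))
      stop("inversion runs overlap")
    for (i in seq_len(nrow(ends)))
      ord[ends[i, 1]:ends[i, 2]] <- rev(ord[ends[i, 1]:ends[i, 2]])
  }
  ord
}

random_cds <- function(n_codons) {
  sense <- setdiff(ng_all_codons(), NG_STOPS)
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)), collapse = "")
}

# assign gene slots inside [start, end); returns start coordinates
region_slots <- function(start, end, n) {
  if (n == 0L) return(numeric(0))
  width <- (end - start) / n
  if (width < 80) stop("region [", start, ", ", end, ") too small for ", n, " genes")
  floor(start + (seq_len(n) - 1) * width + 10)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a sex-chromosome genome with known truth
#'
#' Builds chromosome sequences per `config$chrom_lengths`, evolves SDR
#' gametolog pairs to their target Ks, embeds Y copies along the SDR in the
#' anchor order implied by `config$inversion_spec`, adds X-/Y-specific genes
#' and near-identical PAR pairs, and returns gene models plus a truth set.
#' Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; writes `genome.fa` (60-column FASTA),
#'   `genes.gff3` and `cds.fa` when given.
#' @return List with `genome` (named character), `genes` (data.frame: id,
#'   chrom, start, end, strand, role, region), `cds` (named character) and
#'   `truth` (list: `sdr_truth`, `par_truth`, `gametolog_truth`,
#'   `inversion_truth`).
#' @export
simulate_sex_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$chrom_lengths
  sdr <- config$sdr_span; par <- config$par_span
  x_name <- "X"
  if (!x_name %in% names(cl)) stop("config must include an 'X' chromosome")
  par_len <- par$end - par$start
  x_len <- cl[[x_name]]
  if (x_len <= par_len) stop("X chromosome shorter than the PAR")

  with_seed(sub_seed(config$seed, 1L), {
    n_pair <- config$n_gametologs
    n_ysp <- config$n_y_specific
    n_xsp <- config$n_x_specific
    n_par <- config$n_par_pairs

    # gene sizes scaled to the tightest region
    slot_sdr <- (sdr$end - sdr$start) / max(1, n_pair + n_ysp)
    slot_xc <- (x_len - par_len) / max(1, n_pair + n_xsp)
    slot_par <- par_len / max(1, n_par)
    max_cod <- function(slot) max(12L, as.integer((slot - 40) / 3))
    cod_sdr <- max_cod(min(slot_sdr, slot_xc))
    cod_par <- max_cod(slot_par)

    # evolve SDR gametologs
    targets <- pmin(pmax(stats::rnorm(n_pair, config$true_ks, config$ks_sd), 0), 0.74)
    lens <- sample(max(12L, cod_sdr %/% 2L):cod_sdr, n_pair, replace = TRUE)
    pairs <- lapply(seq_len(n_pair), function(i)
      evolve_pair(targets[i], config$true_ka, lens[i]))
    # near-identical PAR pairs (still recombining)
    par_lens <- sample(max(12L, cod_par %/% 2L):cod_par, max(n_par, 1L), replace = TRUE)
    par_pairs <- lapply(seq_len(n_par), function(i)
      evolve_pair(0.01, 0, par_lens[i]))
    xsp_cds <- vapply(seq_len(n_xsp), function(i)
      random_cds(sample(max(12L, cod_sdr %/% 2L):cod_sdr, 1L)), character(1))
    ysp_cds <- vapply(seq_len(n_ysp), function(i)
      random_cds(sample(max(12L, cod_sdr %/% 2L):cod_sdr, 1L)), character(1))

    genes <- list(); cds <- character(0)
    add_gene <- function(id, chrom, start, cds_seq, strand, role, reg) {
      genes[[length(genes) + 1L]] <<- data.frame(
        id = id, chrom = chrom, start = start,
        end = start + nchar(cds_seq), strand = strand, role = role,
        region = reg, stringsAsFactors = FALSE)
      cds[id] <<- cds_seq
    }

    # --- Y chromosome: SDR gametologs in inverted anchor order + Y-specific
    y_order <- apply_inversion_runs(n_pair, config$inversion_spec)
    sdr_n <- n_pair + n_ysp
    sdr_starts <- region_slots(sdr$start, sdr$end, sdr_n)
    ysp_slots <- if (n_ysp)
      utils::head(seq(1L, sdr_n, by = max(1L, sdr_n %/% n_ysp)), n_ysp) else integer(0)
    pair_slots <- setdiff(seq_len(sdr_n), ysp_slots)
    for (k in seq_along(pair_slots)) {
      i <- y_order[k]
      add_gene(sprintf("pair%03d__Y", i), sdr$chrom, sdr_starts[pair_slots[k]],
               pairs[[i]]$y, if (k %% 2) "+" else "-", "gametolog_y", "SDR")
    }
    for (k in seq_along(ysp_slots))
      add_gene(sprintf("yspec%03d", k), sdr$chrom, sdr_starts[ysp_slots[k]],
               ysp_cds[k], if (k %% 2) "+" else "-", "y_specific", "SDR")
    # PAR on Y
    par_starts <- region_slots(par$start, par$end, n_par)
    for (i in seq_len(n_par))
      add_gene(sprintf("parpair%03d__Y", i), par$chrom, par_starts[i],
               par_pairs[[i]]$y, "+", "par_pair_y", "PAR")

    # --- X chromosome: counterpart in collinear order + X-specific, then PAR
    xc_n <- n_pair + n_xsp
    xc_starts <- region_slots(0, x_len - par_len, xc_n)
    xsp_slots <- if (n_xsp)
      utils::head(seq(1L, xc_n, by = max(1L, xc_n %/% n_xsp)), n_xsp) else integer(0)
    xpair_slots <- setdiff(seq_len(xc_n), xsp_slots)
    for (k in seq_along(xpair_slots))
      add_gene(sprintf("pair%03d__X", k), x_name, xc_starts[xpair_slots[k]],
               pairs[[k]]$x, if (k %% 2) "+" else "-", "gametolog_x",
               "X-counterpart")
    for (k in seq_along(xsp_slots))
      add_gene(sprintf("xspec%03d", k), x_name, xc_starts[xsp_slots[k]],
               xsp_cds[k], if (k %% 2) "+" else "-", "x_specific",
               "X-counterpart")
    xpar_starts <- region_slots(x_len - par_len, x_len, n_par)
    for (i in seq_len(n_par))
      add_gene(sprintf("parpair%03d__X", i), x_name, xpar_starts[i],
               par_pairs[[i]]$x, "+", "par_pair_x", "PAR")

    genes <- do.call(rbind, genes)

    # --- background sequence with CDS spliced in
    genome <- vapply(names(cl), function(ch) {
      s <- sample(c("A", "C", "G", "T"), cl[[ch]], replace = TRUE)
      g <- genes[genes$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(g))) {
        seq_in <- if (g$strand[j] == "+") cds[[g$id[j]]] else revcomp(cds[[g$id[j]]])
        s[(g$start[j] + 1):g$end[j]] <- strsplit(seq_in, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))

    truth <- list(
      sdr_truth = sdr, par_truth = par,
      gametolog_truth = data.frame(
        pair_id = sprintf("pair%03d", seq_len(n_pair)),
        x_id = sprintf("pair%03d__X", seq_len(n_pair)),
        y_id = sprintf("pair%03d__Y", seq_len(n_pair)),
        true_ks = targets,
        realised_ks = vapply(pairs, `[[`, numeric(1), "realised_ks"),
        stringsAsFactors = FALSE),
      inversion_truth = config$inversion_spec,
      x_specific = sprintf("xspec%03d", seq_len(n_xsp)),
      y_specific = sprintf("yspec%03d", seq_len(n_ysp)))

    res <- list(genome = genome, genes = genes, cds = cds, truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(genome, file.path(out_dir, "genome.fa"))
      write_fasta(cds, file.path(out_dir, "cds.fa"))
      write_gff3(genes, cl, file.path(out_dir, "genes.gff3"))
    }
    res
  })
}

# minimal deterministic GFF3 writer: gene/mRNA/CDS per gene model
write_gff3 <- function(genes, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       as.integer(chrom_lengths[[ch]])), con)
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, ]
    s1 <- as.integer(g$start) + 1L  # GFF3 is 1-based inclusive
    e1 <- as.integer(g$end)
    writeLines(c(
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom, s1, e1, g$strand, g$id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, s1, e1, g$strand, g$id, g$id),
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
              g$chrom, s1, e1, g$strand, g$id, g$id)), con)
  }
  invisible(path)
}
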